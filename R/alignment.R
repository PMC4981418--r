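## Alignment container and IUPAC machinery shared by every stage.

#' IUPAC nucleotide ambiguity expansion
#'
#' Maps every legal residue to the set of unambiguous bases it stands for.
#' Direct Sanger reads of multicopy loci record intraindividual polymorphism
#' as two- or three-fold ambiguity codes; these expansions drive the
#' additivity logic.
#'
#' @format Named list; each element a character vector over A, C, G, T.
#' @keywords internal
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.GAP <- "-"
.ALPHABET <- c(names(.IUPAC), .GAP)

#' Known sample group labels
#'
#' Group labels used throughout: the two parental pools (diploid paternal
#' candidates, tetraploid maternal candidates), the putative allohexaploid
#' hybrids, outgroup taxa, and unassigned.
#'
#' @export
GROUP_LEVELS <- c("parentA_diploid", "parentB_tetraploid",
                  "hybrid_hexaploid", "outgroup", "unassigned")

#' Expand a residue to its base set
#'
#' @param residue Single upper-case residue character.
#' @return Character vector of unambiguous bases. Gap and `N` expand to the
#'   full base set and carry attribute `uninformative = TRUE`.
#' @examples
#' iupac_set("Y")   # C, T
#' @export
iupac_set <- function(residue) {
  if (identical(residue, .GAP) || identical(residue, "N")) {
    out <- c("A", "C", "G", "T")
    attr(out, "uninformative") <- TRUE
    return(out)
  }
  s <- .IUPAC[[residue]]
  if (is.null(s)) stop("illegal residue '", residue, "'", call. = FALSE)
  s
}

#' Collapse a base set to its IUPAC code
#'
#' Inverse of [iupac_set()]: the unique residue whose expansion equals the
#' given non-empty subset of A, C, G, T.
#'
#' @param bases Character vector of unambiguous bases.
#' @return Single residue character.
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(bases))
  key <- paste(bases, collapse = "")
  code <- .IUPAC_REVERSE[[key]]
  if (is.null(code)) stop("not a base set: ", key, call. = FALSE)
  code
}

.IUPAC_REVERSE <- local({
  rev <- lapply(names(.IUPAC), function(nm) nm)
  names(rev) <- vapply(.IUPAC, function(b) paste(sort(b), collapse = ""), "")
  rev
})

## expected mismatch fraction between uniform draws from the two expanded
## state sets, for every residue pair (used by the "average" distance policy)
.P_MISMATCH <- local({
  codes <- names(.IUPAC)
  m <- matrix(NA_real_, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    sa <- .IUPAC[[a]]; sb <- .IUPAC[[b]]
    m[a, b] <- 1 - length(intersect(sa, sb)) / (length(sa) * length(sb))
  }
  m
})

#' Construct an aligned sequence set
#'
#' The central container: a character matrix of upper-case residues (rows =
#' sequences, columns = 1-based alignment positions) plus a per-sequence
#' metadata table with taxon and group labels.
#'
#' @param x Named character vector of residue strings (one per sequence), or
#'   a character matrix of single residues with rownames.
#' @param taxon Optional character vector of taxon names (recycled if length
#'   1); defaults to the sequence ids.
#' @param group Optional character vector of group labels drawn from
#'   [GROUP_LEVELS]; defaults to `"unassigned"`.
#' @return Object of class `dna_alignment` with elements `seq` (character
#'   matrix) and `meta` (data.frame with columns id, taxon, group).
#' @examples
#' aln <- alignment(c(d1 = "ACGT", d2 = "ACYT"),
#'                  group = c("parentA_diploid", "hybrid_hexaploid"))
#' aln
#' @export
alignment <- function(x, taxon = NULL, group = NULL) {
  if (is.matrix(x)) {
    m <- x
  } else {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
      stop("sequences must be named", call. = FALSE)
    lens <- nchar(x)
    if (length(unique(lens)) > 1) {
      bad <- names(x)[which(lens != lens[1])[1]]
      stop("alignment error: sequence '", bad, "' has length ",
           nchar(x[[bad]]), ", expected ", lens[1], call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  }
  mode(m) <- "character"
  m[] <- toupper(m)
  if (anyDuplicated(rownames(m)))
    stop("duplicated sequence ids", call. = FALSE)
  bad <- !(m %in% .ALPHABET)
  if (any(bad)) {
    idx <- which(bad)[1]
    r <- (idx - 1) %% nrow(m) + 1
    cc <- (idx - 1) %/% nrow(m) + 1
    stop("parse error: illegal character '", m[r, cc], "' in sequence '",
         rownames(m)[r], "' at column ", cc, call. = FALSE)
  }
  n <- nrow(m)
  taxon <- if (is.null(taxon)) rownames(m) else rep_len(taxon, n)
  group <- if (is.null(group)) rep("unassigned", n) else rep_len(group, n)
  if (!all(group %in% GROUP_LEVELS))
    stop("unknown group label(s): ",
         paste(setdiff(group, GROUP_LEVELS), collapse = ", "), call. = FALSE)
  structure(
    list(seq = m,
         meta = data.frame(id = rownames(m), taxon = taxon, group = group,
                           stringsAsFactors = FALSE)),
    class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment: ", nrow(x$seq), " sequences x ", ncol(x$seq),
      " columns\n", sep = "")
  tab <- table(factor(x$meta$group, levels = GROUP_LEVELS))
  tab <- tab[tab > 0]
  if (length(tab))
    cat("groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dna_alignment <- function(object, ...) {
  amb <- setdiff(names(.IUPAC), c("A", "C", "G", "T", "N"))
  cat("DNA alignment\n")
  cat("  sequences:       ", nrow(object$seq), "\n")
  cat("  columns:         ", ncol(object$seq), "\n")
  cat("  ambiguity cells: ", sum(object$seq %in% amb), "\n")
  cat("  gap cells:       ", sum(object$seq == .GAP), "\n")
  invisible(object)
}

#' Number of sequences / columns
#' @param aln A `dna_alignment`.
#' @return Integer.
#' @export
n_seq <- function(aln) nrow(aln$seq)

#' @rdname n_seq
#' @export
aln_length <- function(aln) ncol(aln$seq)

#' Sequences as residue strings
#' @param aln A `dna_alignment`.
#' @return Named character vector.
#' @export
seq_strings <- function(aln) {
  out <- apply(aln$seq, 1, paste, collapse = "")
  names(out) <- rownames(aln$seq)
  out
}

#' Subset an alignment by sequence and/or column
#'
#' @param aln A `dna_alignment`.
#' @param ids Sequence ids (or logical/integer index over rows); default all.
#' @param cols 1-based column indices; default all.
#' @return A `dna_alignment`.
#' @export
subset_alignment <- function(aln, ids = NULL, cols = NULL) {
  ri <- if (is.null(ids)) seq_len(nrow(aln$seq)) else ids
  if (is.character(ri)) {
    miss <- setdiff(ri, rownames(aln$seq))
    if (length(miss)) stop("unknown id(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
    ri <- match(ri, rownames(aln$seq))
  }
  ci <- if (is.null(cols)) seq_len(ncol(aln$seq)) else cols
  m <- aln$seq[ri, ci, drop = FALSE]
  meta <- aln$meta[ri, , drop = FALSE]
  structure(list(seq = m,
                 meta = `rownames<-`(meta, NULL)),
            class = "dna_alignment")
}

#' Sequence ids belonging to a group
#' @param aln A `dna_alignment`.
#' @param group One or more labels from [GROUP_LEVELS].
#' @return Character vector of ids.
#' @export
group_ids <- function(aln, group) {
  aln$meta$id[aln$meta$group %in% group]
}
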