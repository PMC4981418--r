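## Ambiguity-aware uncorrected p-distances and group nucleotide diversities.

#' Pairwise p-distance between two aligned sequences
#'
#' Uncorrected proportion of differing sites with pairwise deletion: columns
#' where either sequence has a gap or N are dropped. Two policies handle
#' IUPAC ambiguity codes:
#' \describe{
#'   \item{average}{a column scores the expected mismatch fraction between
#'     the two uniform distributions over the expanded state sets,
#'     `1 - |A\\*B| / (|A||B|)` with `A\\*B` the intersection — the
#'     "ambiguous states as average" convention.}
#'   \item{exclude}{columns where either sequence carries an ambiguity code
#'     are dropped from the comparison.}
#' }
#'
#' @param s1,s2 Residue strings or residue vectors of equal length.
#' @param policy `"average"` (default) or `"exclude"`.
#' @return List with `distance` (proportion in \[0, 1\]) and `n_valid`
#'   (number of compared columns).
#' @examples
#' p_distance("AY", "AC")$distance   # 0.25: half a mismatch over 2 sites
#' @export
p_distance <- function(s1, s2, policy = c("average", "exclude")) {
  policy <- match.arg(policy)
  a <- .as_residues(s1); b <- .as_residues(s2)
  if (length(a) != length(b)) stop("unequal sequence lengths", call. = FALSE)
  drop <- a %in% c(.GAP, "N") | b %in% c(.GAP, "N")
  if (policy == "exclude")
    drop <- drop | a %in% .AMBIGUITY_CODES | b %in% .AMBIGUITY_CODES
  a <- a[!drop]; b <- b[!drop]
  if (!length(a)) stop("no valid sites to compare", call. = FALSE)
  mis <- .P_MISMATCH[cbind(a, b)]
  list(distance = sum(mis) / length(a), n_valid = length(a))
}

#' All pairwise p-distances of an alignment
#'
#' @param aln A `dna_alignment`.
#' @param policy See [p_distance()].
#' @return Object of class `distance_matrix`: list with `d` (symmetric
#'   numeric matrix), `valid_sites` (integer matrix of compared-site
#'   counts) and `meta` (the alignment's metadata).
#' @export
distance_matrix <- function(aln, policy = c("average", "exclude")) {
  policy <- match.arg(policy)
  n <- n_seq(aln)
  ids <- rownames(aln$seq)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  vs <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(vs) <- ncol(aln$seq)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      pd <- p_distance(aln$seq[i, ], aln$seq[j, ], policy)
      d[i, j] <- d[j, i] <- pd$distance
      vs[i, j] <- vs[j, i] <- pd$n_valid
    }
  }
  structure(list(d = d, valid_sites = vs, meta = aln$meta),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("pairwise p-distance matrix over", nrow(x$d), "sequences\n")
  print(round(x$d, 4))
  invisible(x)
}

#' Mean nucleotide diversity within or between groups
#'
#' Within-group diversity is the unweighted mean p-distance over all
#' unordered pairs inside the group; between-group diversity averages over
#' all cross pairs. Computed at the level of the sequences present (pass
#' ribotype representatives to work at sequence-type level).
#'
#' @param dm A `distance_matrix`.
#' @param groupA Group label (see [GROUP_LEVELS]) or explicit id vector.
#' @param groupB Optional second group for a between-group mean.
#' @return Mean p-distance (proportion).
#' @examples
#' aln <- alignment(c(a = "ACGT", b = "ACGA", c = "TCGA"),
#'                  group = c("parentA_diploid", "parentA_diploid",
#'                            "parentB_tetraploid"))
#' dm <- distance_matrix(aln)
#' group_mean_diversity(dm, "parentA_diploid")
#' group_mean_diversity(dm, "parentA_diploid", "parentB_tetraploid")
#' @export
group_mean_diversity <- function(dm, groupA, groupB = NULL) {
  pick <- function(g) {
    if (all(g %in% GROUP_LEVELS)) dm$meta$id[dm$meta$group %in% g] else g
  }
  a <- pick(groupA)
  if (!length(a)) stop("empty group", call. = FALSE)
  ia <- match(a, rownames(dm$d))
  if (anyNA(ia)) stop("unknown id(s) in groupA", call. = FALSE)
  if (is.null(groupB)) {
    if (length(ia) < 2)
      stop("within-group diversity needs at least two sequences",
           call. = FALSE)
    sub <- dm$d[ia, ia, drop = FALSE]
    return(mean(sub[upper.tri(sub)]))
  }
  b <- pick(groupB)
  if (!length(b)) stop("empty group", call. = FALSE)
  ib <- match(b, rownames(dm$d))
  if (anyNA(ib)) stop("unknown id(s) in groupB", call. = FALSE)
  mean(dm$d[ia, ib, drop = FALSE])
}

#' Write a distance matrix in PHYLIP format
#'
#' @param dm A `distance_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(dm, path) {
  ids <- rownames(dm$d)
  lines <- c(sprintf("%5d", nrow(dm$d)),
             vapply(seq_along(ids), function(i)
               paste(formatC(ids[i], width = -10),
                     paste(sprintf("%.6f", dm$d[i, ]), collapse = " ")),
               ""))
  writeLines(lines, path)
  invisible(path)
}
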