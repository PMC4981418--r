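## FASTA / sample-sheet I/O, ribotype collapsing, repeat masking.

#' Read an aligned FASTA file
#'
#' Reads an aligned multi-FASTA (IUPAC ambiguity codes and gaps allowed) and
#' optionally joins a sample sheet assigning each sequence to a taxon and
#' group. Ragged input is rejected with the offending sequence named.
#'
#' @param path FASTA file path.
#' @param samplesheet Optional TSV path with columns `id`, `taxon`, `group`
#'   (and optional `latitude`, `longitude`); every FASTA id must appear.
#' @return A `dna_alignment`.
#' @seealso [write_alignment()], [read_samplesheet()]
#' @examples
#' fa <- system.file("extdata", "its_demo_synthetic.fasta",
#'                   package = "allohex")
#' sheet <- system.file("extdata", "its_demo_synthetic_samples.tsv",
#'                      package = "allohex")
#' read_alignment(fa, sheet)
#' @export
read_alignment <- function(path, samplesheet = NULL) {
  dnb <- ape::read.FASTA(path)
  if (length(dnb) == 0) stop("no sequences in ", path, call. = FALSE)
  ch <- lapply(as.character(dnb), function(v) paste(toupper(v), collapse = ""))
  strs <- unlist(ch)
  ## '?' occasionally appears as missing data in nexus-derived FASTA
  strs <- gsub("?", "N", strs, fixed = TRUE)
  aln <- alignment(strs)
  if (!is.null(samplesheet)) {
    sheet <- read_samplesheet(samplesheet)
    miss <- setdiff(aln$meta$id, sheet$id)
    if (length(miss))
      stop("sample sheet is missing id(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    i <- match(aln$meta$id, sheet$id)
    aln$meta$taxon <- sheet$taxon[i]
    aln$meta$group <- sheet$group[i]
    if (!all(aln$meta$group %in% GROUP_LEVELS))
      stop("sample sheet has unknown group label(s)", call. = FALSE)
  }
  aln
}

#' Read a sample sheet
#'
#' @param path TSV with header columns `id`, `taxon`, `group` and optional
#'   `latitude`, `longitude`.
#' @return data.frame.
#' @export
read_samplesheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  need <- c("id", "taxon", "group")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sheet
}

#' Write an alignment as FASTA (with optional sample sheet)
#'
#' @param aln A `dna_alignment`.
#' @param path Output FASTA path.
#' @param samplesheet Optional path; if given, the metadata table is written
#'   there as TSV.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, samplesheet = NULL) {
  dnb <- ape::as.DNAbin(tolower(aln$seq))
  ape::write.FASTA(dnb, path)
  if (!is.null(samplesheet))
    utils::write.table(aln$meta, samplesheet, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Collapse identical sequences into ribotypes/haplotypes
#'
#' Two sequences share a type if and only if their residue strings are
#' identical, ambiguity codes and gaps included: a direct Sanger consensus
#' carrying a distinct intraindividual polymorphism pattern is a distinct
#' ribotype. Type ids are assigned in order of first appearance.
#'
#' @param aln A `dna_alignment`.
#' @param label Noun used in printing ("ribotype" for nuclear ITS,
#'   "haplotype" for cpDNA).
#' @return Object of class `ribotype_table`: list with `table` (data.frame:
#'   type id, representative id, frequency, one `freq_<group>` column per
#'   group present), `members` (list of id vectors) and `representatives`
#'   (`dna_alignment` of one sequence per type).
#' @examples
#' aln <- alignment(c(a = "ACGT", b = "ACGT", c = "ACYT"))
#' collapse_ribotypes(aln)
#' @export
collapse_ribotypes <- function(aln, label = "ribotype") {
  if (n_seq(aln) == 0) stop("empty alignment", call. = FALSE)
  strs <- seq_strings(aln)
  key <- match(strs, unique(strs))
  n_types <- max(key)
  members <- split(aln$meta$id, key)
  names(members) <- as.character(seq_len(n_types))
  rep_ids <- vapply(members, `[[`, "", 1)
  groups_present <- unique(aln$meta$group)
  tab <- data.frame(
    type_id = seq_len(n_types),
    representative = unname(rep_ids),
    frequency = vapply(members, length, 0L),
    stringsAsFactors = FALSE)
  for (g in groups_present) {
    gids <- group_ids(aln, g)
    tab[[paste0("freq_", g)]] <-
      vapply(members, function(mm) sum(mm %in% gids), 0L)
  }
  rownames(tab) <- NULL
  structure(list(table = tab, members = unname(members),
                 representatives = subset_alignment(aln, unname(rep_ids)),
                 label = label),
            class = "ribotype_table")
}

#' @export
print.ribotype_table <- function(x, ...) {
  cat(nrow(x$table), " unique ", x$label, "s from ",
      sum(x$table$frequency), " sequences\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' @export
summary.ribotype_table <- function(object, ...) {
  cat("unique ", object$label, "s: ", nrow(object$table), "\n", sep = "")
  cat("sequences:       ", sum(object$table$frequency), "\n")
  cat("max frequency:   ", max(object$table$frequency), "\n")
  invisible(object)
}

#' Mask mononucleotide-repeat columns
#'
#' Long homopolymer runs in chloroplast spacers vary in length by replication
#' slippage and are prone to homoplasy; columns falling inside any run of a
#' single base of at least `min_run` residues (in any sequence; gaps inside a
#' run do not break it) are removed for all sequences, keeping the alignment
#' rectangular.
#'
#' @param aln A `dna_alignment`.
#' @param min_run Minimum homopolymer length to mask (default 8).
#' @return List with `alignment` (the reduced `dna_alignment`) and `masked`
#'   (data.frame of removed 1-based column ranges `start`, `end`).
#' @examples
#' aln <- alignment(c(a = "TAAAAAAAAG", b = "TAAAAAAAAG"))
#' mask_mononucleotide_repeats(aln)$masked
#' @export
mask_mononucleotide_repeats <- function(aln, min_run = 8L) {
  if (min_run < 2) stop("min_run must be >= 2", call. = FALSE)
  L <- aln_length(aln)
  drop <- rep(FALSE, L)
  for (r in seq_len(n_seq(aln))) {
    v <- aln$seq[r, ]
    pos <- which(v != .GAP)
    if (!length(pos)) next
    base <- v[pos]
    run_id <- cumsum(c(TRUE, base[-1] != base[-length(base)]))
    for (rn in split(pos, run_id)) {
      if (length(rn) >= min_run)
        drop[rn[1]:rn[length(rn)]] <- TRUE   # interior gap columns included
    }
  }
  keep <- which(!drop)
  ranges <- .runs_to_ranges(which(drop))
  list(alignment = subset_alignment(aln, cols = keep), masked = ranges)
}

## consecutive integers -> data.frame(start, end)
.runs_to_ranges <- function(idx) {
  if (!length(idx))
    return(data.frame(start = integer(), end = integer()))
  brk <- cumsum(c(TRUE, diff(idx) != 1))
  out <- do.call(rbind, lapply(split(idx, brk), function(v)
    data.frame(start = v[1], end = v[length(v)])))
  rownames(out) <- NULL
  out
}
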