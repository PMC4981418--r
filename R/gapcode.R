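## Indel inventory and simple indel coding (Simmons & Ochoterena 2000 style),
## plus A/T pseudo-nucleotide recoding so a network built on substitutions can
## weight every indel as one mutational step regardless of length.

#' Inventory indel events in an alignment
#'
#' An indel event is a distinct maximal gap extent: a run of gap characters in
#' one sequence flanked by residues (or the alignment end), merged across
#' sequences sharing exactly the same (start, end). Terminal gaps are treated
#' as missing data, not events.
#'
#' @param aln A `dna_alignment`.
#' @return data.frame with columns `start`, `end`, `length` (1-based,
#'   inclusive) and list-column `members` (ids carrying that exact extent),
#'   sorted by (start, end).
#' @examples
#' aln <- alignment(c(a = "AC--GT", b = "ACGTGT"))
#' find_indels(aln)
#' @export
find_indels <- function(aln) {
  L <- aln_length(aln)
  ev <- list()
  for (r in seq_len(n_seq(aln))) {
    v <- aln$seq[r, ]
    gaps <- .runs_to_ranges(which(v == .GAP))
    if (!nrow(gaps)) next
    ## drop terminal gaps
    gaps <- gaps[gaps$start > 1 & gaps$end < L, , drop = FALSE]
    for (k in seq_len(nrow(gaps))) {
      key <- paste(gaps$start[k], gaps$end[k], sep = ":")
      ev[[key]] <- c(ev[[key]], rownames(aln$seq)[r])
    }
  }
  if (!length(ev))
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), members = I(list())))
  se <- do.call(rbind, strsplit(names(ev), ":"))
  out <- data.frame(start = as.integer(se[, 1]), end = as.integer(se[, 2]))
  out$length <- out$end - out$start + 1L
  out$members <- I(unname(ev))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simple indel coding
#'
#' Scores each distinct gap extent as one binary presence/absence character:
#' a sequence with exactly that extent scores `1`; a sequence whose own
#' longer gap strictly contains the extent scores `?` (inapplicable: the
#' shorter indel cannot be observed inside a larger deletion); every other
#' sequence scores `0`. Terminal gaps are missing data and produce no
#' character.
#'
#' @param aln A `dna_alignment`.
#' @return Object of class `indel_matrix`: list with `events` (as
#'   [find_indels()]) and `states` (character matrix, rows = sequence ids,
#'   columns = characters, entries "0"/"1"/"?").
#' @examples
#' aln <- alignment(c(a = "A----T", b = "AG--CT", c = "AGGCCT"))
#' simple_indel_coding(aln)$states
#' @export
simple_indel_coding <- function(aln) {
  events <- find_indels(aln)
  ids <- rownames(aln$seq)
  states <- matrix("0", nrow = length(ids), ncol = nrow(events),
                   dimnames = list(ids, NULL))
  if (nrow(events)) {
    ## per sequence, its own internal gap extents
    own <- lapply(seq_along(ids), function(r) {
      v <- aln$seq[r, ]
      g <- .runs_to_ranges(which(v == .GAP))
      g[g$start > 1 & g$end < aln_length(aln), , drop = FALSE]
    })
    for (k in seq_len(nrow(events))) {
      s <- events$start[k]; e <- events$end[k]
      for (r in seq_along(ids)) {
        g <- own[[r]]
        if (!nrow(g)) next
        exact <- any(g$start == s & g$end == e)
        contains <- any(g$start <= s & g$end >= e &
                          (g$end - g$start > e - s))
        if (exact) states[r, k] <- "1"
        else if (contains) states[r, k] <- "?"
      }
    }
  }
  structure(list(events = events, states = states), class = "indel_matrix")
}

#' @export
print.indel_matrix <- function(x, ...) {
  cat("simple indel coding: ", nrow(x$events), " characters, ",
      nrow(x$states), " sequences\n", sep = "")
  if (nrow(x$events)) {
    df <- x$events[, c("start", "end", "length")]
    df$n_present <- colSums(x$states == "1")
    print(df)
  }
  invisible(x)
}

#' Append indel characters as A/T pseudo-nucleotide columns
#'
#' Recodes each binary indel character as one extra alignment column
#' (presence `1` -> "T", absence `0` -> "A", inapplicable `?` -> "N") so a
#' substitution-based network treats each indel as exactly one mutational
#' step, whatever its length. The original gap columns are retained; the
#' network step counter skips gaps as missing data.
#'
#' @param aln A `dna_alignment` (must be the one `m` was derived from).
#' @param m An `indel_matrix` from [simple_indel_coding()].
#' @return A `dna_alignment` of length `aln_length(aln) + ncol(m$states)`.
#' @export
recode_indels_as_nucleotide <- function(aln, m) {
  if (!identical(sort(rownames(m$states)), sort(rownames(aln$seq))))
    stop("sequence ids of alignment and indel matrix differ", call. = FALSE)
  st <- m$states[rownames(aln$seq), , drop = FALSE]
  extra <- matrix("A", nrow = nrow(st), ncol = ncol(st))
  extra[st == "1"] <- "T"
  extra[st == "?"] <- "N"
  out <- aln
  out$seq <- cbind(aln$seq, extra)
  colnames(out$seq) <- NULL
  out
}

#' Decode appended indel columns back to a binary matrix
#'
#' Inverse of [recode_indels_as_nucleotide()] for the appended block.
#'
#' @param aln Recoded `dna_alignment`.
#' @param n_characters Number of appended indel columns.
#' @return Character matrix of "0"/"1"/"?".
#' @export
decode_indel_columns <- function(aln, n_characters) {
  if (n_characters == 0)
    return(matrix(character(), nrow = n_seq(aln), ncol = 0,
                  dimnames = list(rownames(aln$seq), NULL)))
  L <- aln_length(aln)
  block <- aln$seq[, (L - n_characters + 1):L, drop = FALSE]
  out <- matrix("0", nrow = nrow(block), ncol = ncol(block),
                dimnames = list(rownames(aln$seq), NULL))
  out[block == "T"] <- "1"
  out[block == "N"] <- "?"
  out
}

#' Summarize an indel inventory
#'
#' @param events data.frame from [find_indels()].
#' @return List with `count`, `min_length`, `max_length` (the latter two `NA`
#'   when the inventory is empty).
#' @export
indel_summary <- function(events) {
  if (!nrow(events))
    return(list(count = 0L, min_length = NA_integer_,
                max_length = NA_integer_))
  list(count = nrow(events),
       min_length = min(events$length),
       max_length = max(events$length))
}
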