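## Independent brute-force oracles and small fixture builders. These are
## deliberately written from the definitions, not by calling package
## internals, so they can disagree with the implementation.

## --- gap runs via regex (independent of the package's run finder) --------
oracle_gap_runs <- function(s) {
  m <- gregexpr("-+", s)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

## brute-force simple indel coding from the published rules
oracle_simple_indel_coding <- function(strs) {
  L <- nchar(strs[1])
  runs <- lapply(strs, oracle_gap_runs)
  ## internal (non-terminal) extents only
  internal <- lapply(runs, function(r)
    r[r$start > 1 & r$end < L, , drop = FALSE])
  keys <- unique(do.call(rbind, internal))
  keys <- keys[order(keys$start, keys$end), , drop = FALSE]
  states <- matrix("0", nrow = length(strs), ncol = nrow(keys),
                   dimnames = list(names(strs), NULL))
  for (k in seq_len(nrow(keys))) {
    s <- keys$start[k]; e <- keys$end[k]
    for (i in seq_along(strs)) {
      r <- internal[[i]]
      if (any(r$start == s & r$end == e)) states[i, k] <- "1"
      else if (any(r$start <= s & r$end >= e &
                     (r$end - r$start) > (e - s))) states[i, k] <- "?"
    }
  }
  list(events = keys, states = states)
}

## --- exhaustive diagnostic-site finder -----------------------------------
oracle_diagnostic_sites <- function(aln, idsA, idsB) {
  expand <- function(ch) switch(ch,
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
    D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
    stop("bad residue"))
  mA <- aln$seq[match(idsA, rownames(aln$seq)), , drop = FALSE]
  mB <- aln$seq[match(idsB, rownames(aln$seq)), , drop = FALSE]
  out <- integer()
  for (j in seq_len(ncol(mA))) {
    col <- c(mA[, j], mB[, j])
    if (any(col %in% c("-", "N"))) next
    sa <- unique(unlist(lapply(mA[, j], expand)))
    sb <- unique(unlist(lapply(mB[, j], expand)))
    hit <- FALSE
    for (x in sa) for (y in sb) if (x == y) hit <- TRUE
    if (!hit) out <- c(out, j)
  }
  out
}

## --- brute-force p-distance on tiny inputs -------------------------------
oracle_mean_pairwise <- function(strs, ids1, ids2 = NULL) {
  pd <- function(a, b) {
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    keep <- !(va %in% c("-", "N")) & !(vb %in% c("-", "N"))
    mean(va[keep] != vb[keep])
  }
  if (is.null(ids2)) {
    pairs <- utils::combn(ids1, 2)
    mean(apply(pairs, 2, function(p) pd(strs[[p[1]]], strs[[p[2]]])))
  } else {
    mean(outer(ids1, ids2, Vectorize(function(i, j) pd(strs[[i]],
                                                       strs[[j]]))))
  }
}

## --- minimum spanning construction over observed haplotypes --------------
## Enumerates all labelled spanning trees (Pruefer sequences) of the
## complete graph on the observed haplotypes and returns the minimum total
## step weight: the cheapest way to connect everything with unit-mutation
## edges and inferred intermediates.
oracle_min_spanning_steps <- function(D) {
  n <- nrow(D)
  if (n == 2) return(D[1, 2])
  prufer <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(prufer))) {
    seqp <- prufer[r, ]
    degree <- rep(1L, n)
    for (v in seqp) degree[v] <- degree[v] + 1L
    w <- 0
    avail <- degree
    sq <- seqp
    for (v in sq) {
      leaf <- which(avail == 1L)[1]
      w <- w + D[leaf, v]
      avail[leaf] <- 0L
      avail[v] <- avail[v] - 1L
    }
    last <- which(avail == 1L)
    w <- w + D[last[1], last[2]]
    best <- min(best, w)
  }
  best
}

## --- Monte-Carlo oracle for the parsimony probability --------------------
## Simulates per-site Poisson mutation counts under Jukes-Cantor and
## estimates P(total mutations == j | j sites visibly differ).
oracle_parsimony_mc <- function(j, m, b, nsim = 40000) {
  hits <- 0L; total <- 0L
  for (s in seq_len(nsim)) {
    k <- stats::rpois(m, b)
    p_diff <- 3 / 4 * (1 - (-1 / 3)^k)   # visible difference given k hits
    differs <- stats::runif(m) < p_diff
    if (sum(differs) == j) {
      total <- total + 1L
      if (sum(k) == j) hits <- hits + 1L
    }
  }
  c(estimate = hits / total, n = total)
}

## --- random small gapped alignments for property tests -------------------
random_gapped_alignment <- function(n_seq = 4, len = 15) {
  strs <- vapply(seq_len(n_seq), function(i) {
    v <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    n_gaps <- sample(0:2, 1)
    for (g in seq_len(n_gaps)) {
      w <- sample(1:4, 1)
      st <- sample(seq_len(len - w + 1), 1)
      v[st:(st + w - 1)] <- "-"
    }
    paste(v, collapse = "")
  }, "")
  names(strs) <- paste0("s", seq_len(n_seq))
  strs
}
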