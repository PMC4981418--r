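## Statistical-parsimony (TCS-style) haplotype network: unit-mutation edges,
## inferred intermediate haplotypes, and the 95% connection limit.

#' Mutational steps between two haplotypes
#'
#' Counts columns at which both sequences carry differing unambiguous bases.
#' Gaps, N and ambiguity codes are missing data for step counting (gap
#' characters are handled upstream by simple indel coding, whose appended
#' A/T pseudo-nucleotide columns each contribute one step per indel).
#'
#' @param h1,h2 Residue strings or vectors of equal length.
#' @return Integer step count.
#' @export
mutation_steps <- function(h1, h2) {
  a <- .as_residues(h1); b <- .as_residues(h2)
  if (length(a) != length(b)) stop("unequal sequence lengths", call. = FALSE)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  sum(ok & a != b)
}

#' Probability that j observed differences are parsimonious
#'
#' Probability that two sequences of `n_sites` comparable sites showing `j`
#' differences are separated by exactly `j` substitutions — i.e. that no
#' site experienced superimposed (parallel, reverse or multiple) changes.
#' Sites mutate independently with Poisson counts of mean `b` under a
#' Jukes-Cantor four-state model; unless supplied, `b` is moment-matched to
#' the observed per-site divergence `j / n_sites` through the Jukes-Cantor
#' saturation curve. Conditioning on the observed pattern gives
#' \deqn{P = (b e^{-b} / H)^j (e^{-b} / (1-H))^{n-j}}
#' with \eqn{H = 3/4 (1 - e^{-4b/3})} the expected proportion of visibly
#' differing sites.
#'
#' @param j Number of observed differences (steps), >= 1.
#' @param n_sites Number of compared sites.
#' @param b Optional expected substitutions per site; default moment-matched
#'   to `j / n_sites`.
#' @return Probability in \[0, 1\]; 0 when the observed divergence is at or
#'   beyond Jukes-Cantor saturation.
#' @export
parsimony_probability <- function(j, n_sites, b = NULL) {
  stopifnot(j >= 1, n_sites >= j)
  H_obs <- j / n_sites
  if (is.null(b)) {
    if (H_obs >= 3 / 4) return(0)
    b <- -3 / 4 * log(1 - 4 * H_obs / 3)
  }
  H <- 3 / 4 * (1 - exp(-4 * b / 3))
  if (H <= 0 || H >= 1) return(0)
  exp(j * (log(b) - b - log(H)) + (n_sites - j) * (-b - log(1 - H)))
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps `j` for which
#' [parsimony_probability()] exceeds `alpha`; haplotype pairs farther apart
#' than this are not connected. Single-step connections are always allowed
#' (a lone observed difference is taken at face value), so the limit is at
#' least 1. The limit is non-decreasing in `n_sites`: longer sequences make
#' superimposed changes at any one site less likely for the same step count.
#'
#' @param n_sites Number of scored sites (original columns plus appended
#'   indel characters).
#' @param alpha Parsimony confidence (default 0.95, the conventional 95%
#'   connection limit).
#' @return Integer limit >= 1.
#' @examples
#' connection_limit(1184)
#' @export
connection_limit <- function(n_sites, alpha = 0.95) {
  stopifnot(n_sites >= 1, alpha > 0, alpha < 1)
  j <- 1L
  while (j + 1L <= n_sites &&
         parsimony_probability(j + 1L, n_sites) > alpha) {
    j <- j + 1L
  }
  j
}

#' Build a TCS-style haplotype network
#'
#' Agglomerative statistical parsimony: all haplotype pairs one step apart
#' are joined first; then, at increasing distance `d` up to the connection
#' limit, pairs in distinct components are joined through chains of `d - 1`
#' inferred (unsampled) intermediate haplotypes. All equally parsimonious
#' alternative connections arising at the joining distance are retained, so
#' the network may contain loops (reported, never resolved automatically).
#' Haplotypes farther than the limit from every connected group remain in
#' separate components.
#'
#' @param haps A `dna_alignment` of unique haplotypes (typically ribotype or
#'   haplotype representatives on the indel-recoded alignment).
#' @param limit Connection limit in steps; default computed by
#'   [connection_limit()] from the alignment length.
#' @param frequencies Optional named vector of observed counts per haplotype
#'   id (default 1 each).
#' @param alpha Confidence used when `limit` is computed.
#' @return Object of class `haplotype_network`: list with `graph` (igraph;
#'   node attributes `name`, `inferred`, `frequency`, `group`), `limit`,
#'   `steps` (observed pairwise step matrix), `components` (membership for
#'   observed haplotypes), `has_loops`.
#' @export
build_network <- function(haps, limit = NULL, frequencies = NULL,
                          alpha = 0.95) {
  ids <- rownames(haps$seq)
  if (anyDuplicated(seq_strings(haps)))
    stop("duplicate haplotypes; collapse before building the network",
         call. = FALSE)
  n <- length(ids)
  if (is.null(limit)) limit <- connection_limit(aln_length(haps), alpha)
  if (limit < 1) stop("limit must be >= 1", call. = FALSE)
  D <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- mutation_steps(haps$seq[i, ], haps$seq[j, ])
  freq <- rep(1, n); names(freq) <- ids
  if (!is.null(frequencies)) freq[names(frequencies)] <- frequencies
  grp <- haps$meta$group[match(ids, haps$meta$id)]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  igraph::V(g)$inferred <- FALSE
  igraph::V(g)$frequency <- unname(freq[ids])
  igraph::V(g)$group <- grp
  ## distance 1: every unit pair, loops included
  if (n > 1) {
    unit <- which(D == 1 & upper.tri(D), arr.ind = TRUE)
    if (nrow(unit))
      g <- igraph::add_edges(g, as.vector(t(cbind(ids[unit[, 1]],
                                                  ids[unit[, 2]]))))
  }
  mv <- 0L
  d <- 2L
  while (d <= limit && n > 1) {
    comp <- igraph::components(g)$membership
    pairs <- which(D == d & upper.tri(D), arr.ind = TRUE)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (comp[ids[i]] == comp[ids[j]]) next
      inter <- paste0("mv", mv + seq_len(d - 1L))
      mv <- mv + d - 1L
      g <- igraph::add_vertices(g, d - 1L, name = inter, inferred = TRUE,
                                frequency = 0, group = "inferred")
      chain <- c(ids[i], inter, ids[j])
      g <- igraph::add_edges(g, as.vector(t(cbind(chain[-length(chain)],
                                                  chain[-1]))))
    }
    d <- d + 1L
  }
  comp_all <- igraph::components(g)$membership
  has_loops <- igraph::ecount(g) >
    igraph::vcount(g) - igraph::components(g)$no
  structure(list(graph = g, limit = limit, steps = D,
                 components = comp_all[ids], has_loops = has_loops),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  g <- x$graph
  n_obs <- sum(!igraph::V(g)$inferred)
  cat("statistical-parsimony haplotype network\n")
  cat("  observed haplotypes: ", n_obs, "\n", sep = "")
  cat("  inferred intermediates: ", igraph::vcount(g) - n_obs, "\n",
      sep = "")
  cat("  edges (one step each): ", igraph::ecount(g), "\n", sep = "")
  cat("  connection limit: ", x$limit, " steps\n", sep = "")
  cat("  components: ", length(unique(x$components)), "\n", sep = "")
  if (x$has_loops)
    cat("  note: network contains loops (alternative equally parsimonious",
        "connections retained)\n")
  invisible(x)
}

#' @export
summary.haplotype_network <- function(object, ...) {
  print(object)
  cat("observed step matrix:\n")
  print(object$steps)
  invisible(object)
}

#' Plot a haplotype network
#'
#' Observed haplotypes as circles scaled by frequency, inferred
#' intermediates as small black squares, one edge per mutational step.
#'
#' @param x A `haplotype_network`.
#' @param ... Passed to `plot.igraph`.
#' @export
plot.haplotype_network <- function(x, ...) {
  g <- x$graph
  inf <- igraph::V(g)$inferred
  shape <- ifelse(inf, "square", "circle")
  size <- ifelse(inf, 4, 8 + 4 * sqrt(pmax(igraph::V(g)$frequency, 1) - 1))
  col <- ifelse(inf, "black", "lightsteelblue")
  lab <- ifelse(inf, NA, igraph::V(g)$name)
  plot(g, vertex.shape = shape, vertex.size = size, vertex.color = col,
       vertex.label = lab, vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' Export a haplotype network
#'
#' @param net A `haplotype_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_dot <- function(net, path) {
  g <- net$graph
  ## DOT has no boolean attribute type
  igraph::V(g)$inferred <- as.integer(igraph::V(g)$inferred)
  igraph::write_graph(g, path, format = "dot")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edges <- function(net, path) {
  e <- igraph::as_edgelist(net$graph)
  df <- data.frame(from = e[, 1], to = e[, 2], steps = 1L)
  df <- df[order(df$from, df$to), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
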