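test_that("mutation steps count unambiguous base differences only", {
  expect_equal(mutation_steps("ACGT", "ACGT"), 0)
  expect_equal(mutation_steps("ACGT", "ACGA"), 1)
  ## SNP plus recoded indel column
  expect_equal(mutation_steps("ACGTT", "ACATA"), 2)
  ## gaps, N and ambiguity codes are missing data
  expect_equal(mutation_steps("A-GT", "ACGT"), 0)
  expect_equal(mutation_steps("ANGT", "ACGT"), 0)
  expect_equal(mutation_steps("AYGT", "ACGT"), 0)
  expect_error(mutation_steps("ACG", "AC"), "length")
})

test_that("parsimony probability behaves and matches its Monte-Carlo oracle", {
  ## more sites make the same step count safer
  expect_gt(parsimony_probability(5, 2000),
            parsimony_probability(5, 200))
  ## saturation gives zero
  expect_equal(parsimony_probability(9, 10), 0)
  ## Monte-Carlo cross-check of the conditional probability at fixed
  ## substitution intensity
  set.seed(21)
  for (j in 2:3) {
    mc <- oracle_parsimony_mc(j, m = 40, b = 0.05, nsim = 60000)
    expect_gt(mc[["n"]], 500)  # enough conditional draws
    expect_equal(parsimony_probability(j, 40, b = 0.05),
                 mc[["estimate"]], tolerance = 0.03)
  }
})

test_that("connection limit is monotone in sites and at least one step", {
  lims <- vapply(c(2, 10, 100, 600, 1184, 5000), connection_limit, 0L)
  expect_true(all(diff(lims) >= 0))
  expect_true(all(lims >= 1))
  ## the limit is the largest j clearing the confidence threshold
  lim <- connection_limit(1184)
  expect_gt(parsimony_probability(lim, 1184), 0.95)
  expect_lte(parsimony_probability(lim + 1, 1184), 0.95)
  ## stricter confidence shortens the limit
  expect_lte(connection_limit(1184, alpha = 0.99), lim)
})

haps_from <- function(strs, groups = NULL) {
  alignment(strs, group = if (is.null(groups)) "unassigned" else groups)
}

test_that("unit-distance pairs and inferred intermediates", {
  ## two haplotypes one step apart: a single edge, no intermediates
  net <- build_network(haps_from(c(H1 = "AAAA", H2 = "AAAT")), limit = 5)
  expect_equal(igraph::vcount(net$graph), 2)
  expect_equal(igraph::ecount(net$graph), 1)
  ## distance three: two inferred intermediates on the path
  net3 <- build_network(haps_from(c(H1 = "AAAA", H2 = "ATTT")), limit = 5)
  expect_equal(sum(igraph::V(net3$graph)$inferred), 2)
  expect_equal(igraph::ecount(net3$graph), 3)
  expect_equal(
    as.numeric(igraph::distances(net3$graph, "H1", "H2")), 3)
})

test_that("pairs beyond the connection limit stay in separate components", {
  net <- build_network(haps_from(c(H1 = "AAAAAA", H2 = "TTTTTT")),
                       limit = 3)
  expect_equal(length(unique(net$components)), 2)
  ## with a generous limit everything connects
  net2 <- build_network(haps_from(c(H1 = "AAAAAA", H2 = "TTTTTT")),
                        limit = 6)
  expect_equal(length(unique(net2$components)), 1)
})

test_that("network equals the brute-force minimum spanning construction", {
  ## hand-built toy: H1-H2 (1 step), H2-H3 (2), H3-H4 (1)
  strs <- c(H1 = "AAAAAA", H2 = "AAAAAT", H3 = "AAGCAT", H4 = "AAGCCT")
  haps <- haps_from(strs)
  net <- build_network(haps, limit = 6)
  D <- net$steps
  ## brute force over all labelled spanning trees of the observed nodes
  want_total <- oracle_min_spanning_steps(D)
  expect_equal(igraph::ecount(net$graph), want_total)
  expect_equal(length(unique(net$components)), 1)
  ## geodesics never undercut the raw mutational distance
  dmat <- igraph::distances(net$graph, rownames(D), rownames(D))
  expect_true(all(dmat >= D - 1e-9))
  ## inferred nodes on a geodesic = step distance minus one
  expect_equal(sum(igraph::V(net$graph)$inferred), 1)
})

test_that("random small networks respect the spanning lower bound", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    strs <- vapply(seq_len(n), function(k)
      paste(sample(c("A", "C"), 12, TRUE), collapse = ""), "")
    names(strs) <- paste0("H", seq_len(n))
    strs <- strs[!duplicated(strs)]
    if (length(strs) < 3) next
    haps <- haps_from(strs)
    net <- build_network(haps, limit = 12)
    expect_equal(length(unique(net$components)), 1)
    ## connected with at least the minimum spanning number of steps, and
    ## no more than the steps of all retained alternative connections
    expect_gte(igraph::ecount(net$graph),
               oracle_min_spanning_steps(net$steps))
    dmat <- igraph::distances(net$graph, rownames(net$steps),
                              rownames(net$steps))
    expect_true(all(dmat >= net$steps - 1e-9))
  }
})

test_that("input order does not change the network topology", {
  strs <- c(H1 = "AAAAAA", H2 = "AAAAAT", H3 = "AAGCAT", H4 = "AAGCCT")
  net1 <- build_network(haps_from(strs), limit = 6)
  net2 <- build_network(haps_from(strs[c(3, 1, 4, 2)]), limit = 6)
  expect_true(igraph::isomorphic(net1$graph, net2$graph))
})

test_that("duplicate haplotypes are rejected", {
  expect_error(build_network(haps_from(c(a = "AAAA", b = "AAAA")),
                             limit = 2), "duplicate")
})

test_that("frequencies and groups travel as node attributes, exports work", {
  strs <- c(H1 = "AAAA", H2 = "AAAT")
  haps <- haps_from(strs, c("parentB_tetraploid", "hybrid_hexaploid"))
  net <- build_network(haps, limit = 3, frequencies = c(H1 = 5, H2 = 2))
  v <- igraph::V(net$graph)
  expect_equal(v$frequency[match("H1", v$name)], 5)
  expect_equal(v$group[match("H2", v$name)], "hybrid_hexaploid")
  g1 <- withr::local_tempfile(fileext = ".graphml")
  g2 <- withr::local_tempfile(fileext = ".dot")
  g3 <- withr::local_tempfile(fileext = ".tsv")
  write_network_graphml(net, g1)
  write_network_dot(net, g2)
  write_network_edges(net, g3)
  expect_true(all(file.exists(g1, g2, g3)))
  edges <- read.delim(g3)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$steps, 1)
})
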