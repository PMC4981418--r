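test_that("parameter validation catches impossible settings", {
  expect_error(synth_params(n_diagnostic_target = 1000, length = 624))
  expect_error(synth_params(h = 1.2))
  expect_error(synth_params(h = 0.8, h_paternal = 0.5))
})

test_that("identical seed and parameters give byte-identical output", {
  p <- synth_params(n_hybrids = 5, seed = 99)
  s1 <- simulate_its_dataset(p)
  s2 <- simulate_its_dataset(p)
  expect_identical(seq_strings(s1$alignment), seq_strings(s2$alignment))
  c1 <- simulate_cpdna(p)
  c2 <- simulate_cpdna(p)
  expect_identical(seq_strings(c1$alignment), seq_strings(c2$alignment))
  ## a different seed changes the data
  s3 <- simulate_its_dataset(synth_params(n_hybrids = 5, seed = 100))
  expect_false(identical(seq_strings(s1$alignment),
                         seq_strings(s3$alignment)))
  ## FASTA serialization is deterministic too
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(s1$alignment, f1)
  write_alignment(s2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted diagnostic sites are recovered exactly when d_within = 0", {
  p <- synth_params(d_within = 0, n_diagnostic_target = 37, seed = 4)
  pools <- simulate_parental_pools(p)
  prof <- diagnostic_sites(pools$alignment)
  expect_identical(prof$column, pools$truth$diagnostic_columns)
  ## and none with a zero target
  p0 <- synth_params(d_within = 0, n_diagnostic_target = 0, seed = 4)
  prof0 <- diagnostic_sites(simulate_parental_pools(p0)$alignment)
  expect_equal(nrow(prof0), 0)
})

test_that("within-clade diversity is calibrated to d_within", {
  ## average realized within-clade p-distance over seeds tracks the dial
  p <- synth_params(d_within = 0.004, n_parentA_ribotypes = 8, seed = 1)
  divs <- vapply(1:20, function(s) {
    pools <- simulate_parental_pools(p, seed = s)
    dm <- distance_matrix(pools$alignment)
    group_mean_diversity(dm, "parentA_diploid")
  }, 0)
  expect_equal(mean(divs), 0.004, tolerance = 0.15)
})

test_that("h = 1 collapses every hybrid onto its maternal ribotype", {
  p <- synth_params(h = 1, p_chimera = 0, d_within = 0, n_hybrids = 8,
                    seed = 12)
  sim <- simulate_its_dataset(p)
  prof <- diagnostic_sites(sim$alignment)
  scan <- additivity_scan(sim$alignment, prof)
  df <- as.data.frame(scan)
  expect_true(all(df$category == "fully_homogenized"))
  expect_true(all(df$direction == "toward_B"))
  for (hid in names(sim$truth$hybrids)) {
    m_id <- sim$truth$hybrids[[hid]]$maternal
    expect_identical(unname(seq_strings(sim$alignment)[hid]),
                     unname(seq_strings(sim$alignment)[m_id]))
  }
})

test_that("h = 0 keeps every hybrid fully additive at all planted sites", {
  p <- synth_params(h = 0, p_chimera = 0, d_within = 0, n_hybrids = 8,
                    seed = 13)
  sim <- simulate_its_dataset(p)
  prof <- diagnostic_sites(sim$alignment)
  scan <- additivity_scan(sim$alignment, prof)
  df <- as.data.frame(scan)
  expect_true(all(df$category == "fully_additive"))
  expect_true(all(df$n_additive == nrow(prof)))
})

test_that("chimeras are ambiguity-free and truth labels every outcome", {
  p <- synth_params(h = 0.5, p_chimera = 1, d_within = 0, n_hybrids = 6,
                    seed = 14)
  sim <- simulate_its_dataset(p)
  for (hid in names(sim$truth$hybrids)) {
    rec <- sim$truth$hybrids[[hid]]
    expect_true(rec$chimera)
    expect_equal(length(intraindividual_polymorphism(sim$alignment,
                                                     id = hid)), 0)
    expect_true(all(rec$outcome %in% c("converted_maternal",
                                       "converted_paternal")))
  }
})

test_that("truth-derived additivity matches the scored reports", {
  p <- synth_params(h = 0.7, p_chimera = 0, d_within = 0, n_hybrids = 30,
                    seed = 15)
  sim <- simulate_its_dataset(p)
  prof <- diagnostic_sites(sim$alignment)
  scan <- additivity_scan(sim$alignment, prof)
  for (hid in names(sim$truth$hybrids)) {
    want <- truth_expected_additivity(sim$truth, hid)
    expect_equal(scan$reports[[hid]]$n_additive,
                 want$n_additive_expected)
    expect_equal(want$n_diagnostic, nrow(prof))
  }
})

test_that("homogenization estimator recovers h within its binomial CI", {
  p <- synth_params(h = 0.8, p_chimera = 0, d_within = 0, n_hybrids = 200,
                    seed = 16)
  sim <- simulate_its_dataset(p)
  prof <- diagnostic_sites(sim$alignment)
  scan <- additivity_scan(sim$alignment, prof)
  df <- as.data.frame(scan)
  est <- mean(1 - df$n_additive / nrow(prof))
  n_trials <- 200 * nrow(prof)
  se <- sqrt(0.8 * 0.2 / n_trials)
  expect_lt(abs(est - 0.8), 1.96 * se * 1.5)
})

test_that("cpDNA simulation plants recoverable haplotype structure", {
  p <- synth_params(seed = 17)
  sim <- simulate_cpdna(p)
  res <- run_cpdna_branch(sim$alignment)
  ## every distinct simulated haplotype is recovered
  n_true <- length(unique(sim$truth$haplotype_of))
  expect_equal(nrow(res$haplotypes$table), n_true)
  ## hexaploids share a tetraploid haplotype: maternal call
  expect_equal(res$maternal_call, "parentB_tetraploid")
  ## repeat jitter is confined to the masked columns
  expect_true(nrow(res$masked) >= 1)
  jit_cols <- sim$truth$repeat_columns
  expect_true(all(jit_cols >= res$masked$start[1] &
                  jit_cols <= res$masked$end[nrow(res$masked)]))
})

test_that("planted single indel appears in inventory and as one network step", {
  ## two haplotypes separated by one long indel only
  left <- strrep("ACGT", 5)
  mid <- strrep("G", 385)
  right <- strrep("TGCA", 5)
  aln <- alignment(c(h1 = paste0(left, mid, right),
                     h2 = paste0(left, strrep("-", 385), right)))
  ev <- find_indels(aln)
  expect_equal(ev$length, 385)
  m <- simple_indel_coding(aln)
  rec <- recode_indels_as_nucleotide(aln, m)
  net <- build_network(rec, limit = 5)
  expect_equal(igraph::ecount(net$graph), 1)
})
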