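make_parents <- function(strsA, strsB) {
  strs <- c(strsA, strsB)
  alignment(strs, group = c(rep("parentA_diploid", length(strsA)),
                            rep("parentB_tetraploid", length(strsB))))
}

test_that("variable sites count distinct non-gap residues", {
  expect_equal(find_variable_sites(alignment(c(a = "ACGT", b = "ACGA"))), 4)
  expect_equal(length(find_variable_sites(alignment(c(a = "ACGT",
                                                      b = "ACGT")))), 0)
  ## gap-only difference is not a variable site
  expect_equal(length(find_variable_sites(alignment(c(a = "AC-T",
                                                      b = "ACGT")))), 0)
  ## ambiguity code vs plain base is variation
  expect_equal(find_variable_sites(alignment(c(a = "ACGT", b = "ACGY"))), 4)
})

test_that("intraindividual polymorphism finds 2- and 3-fold codes, not N", {
  expect_equal(intraindividual_polymorphism("ACYT"), 3)
  expect_equal(length(intraindividual_polymorphism("ACGT")), 0)
  expect_equal(intraindividual_polymorphism("NRWB-T"), c(2, 3, 4))
})

test_that("diagnostic sites require disjoint group-wide state sets", {
  aln <- make_parents(c(a1 = "CCAG", a2 = "CYAG"), c(b1 = "TCAC"))
  prof <- diagnostic_sites(aln)
  ## column 1: A = {C}, B = {T} disjoint; column 2: A = {C,T} meets B = {C};
  ## column 3 invariant; column 4: {G} vs {C} disjoint
  expect_equal(prof$column, c(1, 4))
  expect_equal(prof$setA[[1]], "C")
  expect_equal(prof$setB[[1]], "T")
  ## columns with parental gap or N are skipped
  aln2 <- make_parents(c(a1 = "C-AG"), c(b1 = "TCAC"))
  expect_equal(diagnostic_sites(aln2)$column, c(1, 4))
})

test_that("diagnostic sites match the exhaustive oracle on random alignments", {
  set.seed(11)
  for (i in 1:30) {
    nA <- sample(2:3, 1); nB <- sample(2:3, 1); len <- sample(10:30, 1)
    mk <- function(n, pfx) {
      v <- vapply(seq_len(n), function(k)
        paste(sample(c("A", "C", "G", "T", "Y", "R", "W"), len,
                     replace = TRUE, prob = c(rep(0.2, 4), rep(0.066, 3))),
              collapse = ""), "")
      setNames(v, paste0(pfx, seq_len(n)))
    }
    aln <- make_parents(mk(nA, "a"), mk(nB, "b"))
    got <- diagnostic_sites(aln)$column
    want <- oracle_diagnostic_sites(aln, paste0("a", 1:nA),
                                    paste0("b", 1:nB))
    expect_equal(got, want)
  }
})

test_that("site-state classification truth table", {
  expect_equal(classify_site_state("Y", "T", "C"), "additive")
  expect_equal(classify_site_state("C", "T", "C"), "parentB_like")
  expect_equal(classify_site_state("T", "T", "C"), "parentA_like")
  expect_equal(classify_site_state("G", "T", "C"), "inconclusive")
  ## missing data is inconclusive
  expect_equal(classify_site_state("N", "T", "C"), "inconclusive")
  expect_equal(classify_site_state("-", "T", "C"), "inconclusive")
  ## multi-state parental sets
  expect_equal(classify_site_state("M", c("A", "G"), "C"), "additive")
  expect_equal(classify_site_state("R", c("A", "G"), "C"), "parentA_like")
  ## strict mode refuses third states inside the observed set
  expect_equal(classify_site_state("B", "T", "C", strict = TRUE),
               "inconclusive")
  expect_equal(classify_site_state("B", "T", "C"), "additive")
  expect_error(classify_site_state("A", "T", "T"), "disjoint")
})

test_that("classification is symmetric under swapping the parental sets", {
  codes <- c("A", "C", "G", "T", "Y", "R", "W", "K", "M", "S", "B", "N")
  swap <- c(parentA_like = "parentB_like", parentB_like = "parentA_like",
            additive = "additive", inconclusive = "inconclusive")
  for (obs in codes) {
    c1 <- classify_site_state(obs, "T", "C")
    c2 <- classify_site_state(obs, "C", "T")
    expect_identical(unname(swap[c1]), c2)
  }
})

test_that("a perfect IUPAC union of one member per side is fully additive", {
  set.seed(3)
  for (i in 1:10) {
    len <- 40
    a <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    b <- a
    flip <- sample(len, 12)
    b[flip] <- vapply(a[flip], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    aln <- make_parents(setNames(paste(a, collapse = ""), "a1"),
                        setNames(paste(b, collapse = ""), "b1"))
    prof <- diagnostic_sites(aln)
    hyb <- vapply(seq_len(len), function(j)
      if (a[j] == b[j]) a[j] else iupac_code(c(a[j], b[j])), "")
    rep <- score_ribotype(paste(hyb, collapse = ""), prof)
    expect_equal(rep$n_additive, nrow(prof))
    expect_equal(rep$category, "fully_additive")
  }
})

test_that("homogenization is monotone in the number of converted sites", {
  a <- strrep("A", 30); b <- strrep("G", 30)
  aln <- make_parents(c(a1 = a), c(b1 = b))
  prof <- diagnostic_sites(aln)
  D <- nrow(prof)
  expect_equal(D, 30)
  prev <- D + 1
  for (k in c(0, 5, 10, 29, 30)) {
    hyb <- c(rep("G", k), rep("R", D - k))   # k sites converted toward B
    rep <- score_ribotype(paste(hyb, collapse = ""), prof)
    expect_equal(rep$n_additive, D - k)
    expect_lt(rep$n_additive, prev)
    prev <- rep$n_additive
  }
})

test_that("score_ribotype categories and direction cover the spectrum", {
  a <- strrep("A", 20); b <- strrep("G", 20)
  aln <- make_parents(c(a1 = a), c(b1 = b))
  prof <- diagnostic_sites(aln)
  ## equal to a parental-B member: fully homogenized toward B
  rb <- score_ribotype(b, prof)
  expect_equal(rb$category, "fully_homogenized")
  expect_equal(rb$direction, "toward_B")
  expect_equal(rb$n_parentB, 20)
  ## ambiguity-free mixture of both sides: chimeric
  rc <- score_ribotype(paste0(strrep("A", 2), strrep("G", 18)), prof)
  expect_equal(rc$category, "chimeric")
  expect_equal(rc$n_parentA, 2)
  ## partial additivity below threshold
  rp <- score_ribotype(paste0(strrep("R", 5), strrep("G", 15)), prof)
  expect_equal(rp$category, "partially_homogenized")
  expect_equal(rp$direction, "toward_B")
  ## at threshold: fully additive
  ra <- score_ribotype(paste0(strrep("R", 18), strrep("G", 2)), prof)
  expect_equal(ra$category, "fully_additive")
  ## tied parental counts flag a direction tie
  rt <- score_ribotype(paste0(strrep("A", 10), strrep("G", 10)), prof)
  expect_equal(rt$direction, "none")
  expect_true(rt$direction_tie)
})

test_that("homogenization spectrum weights ribotypes by frequency", {
  a <- strrep("A", 10); b <- strrep("G", 10)
  aln <- alignment(c(a1 = a, b1 = b, h1 = b, h2 = b, h3 = b,
                     h4 = strrep("R", 10)),
                   group = c("parentA_diploid", "parentB_tetraploid",
                             rep("hybrid_hexaploid", 4)))
  rt <- collapse_ribotypes(aln)
  prof <- diagnostic_sites(aln)
  hyb_reps <- rt$table$representative[rt$table$freq_hybrid_hexaploid > 0]
  scan <- additivity_scan(aln, prof, ids = hyb_reps)
  spec <- homogenization_spectrum(scan, rt, group = "hybrid_hexaploid")
  fh <- spec$categories[spec$categories$category == "fully_homogenized", ]
  expect_equal(fh$n_ribotypes, 1)
  expect_equal(fh$n_individuals, 3)
  fa <- spec$categories[spec$categories$category == "fully_additive", ]
  expect_equal(fa$n_individuals, 1)
  expect_equal(sort(spec$polymorphism$n_polymorphic_sites), c(0, 10))
})

test_that("synapomorphies are private shared states", {
  aln <- make_parents(c(a1 = "GTTA", a2 = "GTTA", a3 = "GCTA"),
                      c(b1 = "ACTA", b2 = "ACTA"))
  syn <- synapomorphy_check(aln, c("a1", "a2", "a3"))
  expect_equal(syn$column, 1)
  expect_equal(syn$state, "G")
  ## subgroup signal: a1/a2 privately share T at column 2
  syn2 <- synapomorphy_check(aln, c("a1", "a2"),
                             background_ids = c("a3", "b1", "b2"))
  expect_equal(syn2$column, 2)
  expect_equal(syn2$state, "T")
  ## no private shared states for a mixed pair
  expect_equal(nrow(synapomorphy_check(aln, c("a1", "a3"))), 0)
})
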