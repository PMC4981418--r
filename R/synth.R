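## Seeded generators emulating the statistical structure the analysis
## assumes: two parental ITS clades separated by planted diagnostic sites,
## allohexaploid hybrids whose rDNA arrays are homogenized site-by-site
## toward the maternal ribotype, and chloroplast haplotypes diverging by
## SNPs, indels and homopolymer length noise. Every generator returns its
## ground truth so downstream reports can be checked exactly.

#' Generator parameters
#'
#' Defaults mirror the study conditions of a diploid x tetraploid
#' allohexaploid system: a 624-column ITS alignment, 37 diagnostic sites
#' between the parental clades, within-clade diversity ~0.3%, and
#' homogenization biased toward the maternal (tetraploid) ribotype.
#'
#' @param length ITS alignment columns.
#' @param n_parentA_ribotypes,n_parentB_ribotypes Parental ribotypes per
#'   clade (A = diploid, B = tetraploid).
#' @param n_hybrids Number of hexaploid hybrids to simulate.
#' @param d_within Expected within-clade pairwise p-distance.
#' @param n_diagnostic_target Fixed inter-clade differences to plant.
#' @param h Per-site probability that a hybrid keeps only the maternal
#'   state at a site where its parents differ (concerted-evolution
#'   conversion rate).
#' @param h_paternal Per-site probability of conversion to the paternal
#'   state instead (default 0).
#' @param p_chimera Probability that a hybrid is homogenized with an
#'   independent random direction at every site, yielding an ambiguity-free
#'   chimeric sequence.
#' @param maternal Which parental group is maternal (default tetraploid).
#' @param cp_length cpDNA alignment columns.
#' @param cp_n_haplotypes Haplotypes to simulate on the cpDNA genealogy.
#' @param cp_indel_lengths Candidate indel lengths (bp).
#' @param seed Base RNG seed.
#' @return List of validated parameters (class `synth_params`).
#' @export
synth_params <- function(length = 624L,
                         n_parentA_ribotypes = 6L,
                         n_parentB_ribotypes = 4L,
                         n_hybrids = 20L,
                         d_within = 0.003,
                         n_diagnostic_target = 37L,
                         h = 0.9,
                         h_paternal = 0,
                         p_chimera = 0.05,
                         maternal = c("parentB_tetraploid",
                                      "parentA_diploid"),
                         cp_length = 1184L,
                         cp_n_haplotypes = 7L,
                         cp_indel_lengths = c(1L, 150L, 385L),
                         seed = 1L) {
  maternal <- match.arg(maternal)
  p <- list(length = as.integer(length),
            n_parentA_ribotypes = as.integer(n_parentA_ribotypes),
            n_parentB_ribotypes = as.integer(n_parentB_ribotypes),
            n_hybrids = as.integer(n_hybrids),
            d_within = d_within,
            n_diagnostic_target = as.integer(n_diagnostic_target),
            h = h, h_paternal = h_paternal, p_chimera = p_chimera,
            maternal = maternal,
            cp_length = as.integer(cp_length),
            cp_n_haplotypes = as.integer(cp_n_haplotypes),
            cp_indel_lengths = as.integer(cp_indel_lengths),
            seed = as.integer(seed))
  stopifnot(p$length > 0,
            p$n_diagnostic_target >= 0,
            p$n_diagnostic_target <= p$length,
            p$h >= 0, p$h <= 1,
            p$h_paternal >= 0, p$h + p$h_paternal <= 1,
            p$p_chimera >= 0, p$p_chimera <= 1,
            p$d_within >= 0,
            p$cp_n_haplotypes >= 1)
  class(p) <- "synth_params"
  p
}

## run code under a fixed seed without clobbering the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.BASES <- c("A", "C", "G", "T")

## random base vector avoiding homopolymer runs of >= max_run
.random_bases <- function(n, max_run = 5L) {
  v <- sample(.BASES, n, replace = TRUE)
  repeat {
    r <- rle(v)
    bad <- which(r$lengths >= max_run)
    if (!length(bad)) break
    ends <- cumsum(r$lengths)
    for (k in bad) {
      pos <- ends[k]
      v[pos] <- sample(setdiff(.BASES, v[pos]), 1)
    }
  }
  v
}

.other_base <- function(b) vapply(b, function(x)
  sample(setdiff(.BASES, x), 1), "")

#' Simulate the two parental ribotype pools
#'
#' Builds a random ancestral ITS sequence, plants exactly
#' `n_diagnostic_target` fixed differences between clade A (diploid) and
#' clade B (tetraploid), and adds Poisson within-clade variation at random
#' other columns calibrated so the expected within-clade pairwise
#' p-distance is `d_within`. The realized diagnostic site set (which can
#' grow if a private mutation happens to become fixed-disjoint) is recorded
#' in the truth.
#'
#' @param p A `synth_params`.
#' @param seed RNG seed (default derived from `p$seed`).
#' @return List with `alignment` (a `dna_alignment` of labeled parental
#'   ribotypes) and `truth` (list: `diagnostic_columns`, `stateA`, `stateB`,
#'   `ancestral`, per-ribotype private mutations).
#' @export
simulate_parental_pools <- function(p, seed = p$seed) {
  .with_seed(seed, {
    L <- p$length
    anc <- .random_bases(L)
    diag_cols <- sort(sample.int(L, p$n_diagnostic_target))
    stateA <- anc[diag_cols]
    stateB <- .other_base(stateA)
    consA <- anc
    consB <- anc; consB[diag_cols] <- stateB
    lambda <- p$d_within * L / 2   # pairwise diff ~ sum of two private sets
    make_clade <- function(cons, n, prefix) {
      seqs <- list(); muts <- list()
      free <- setdiff(seq_len(L), diag_cols)
      for (r in seq_len(n)) {
        k <- stats::rpois(1, lambda)
        cols <- if (k > 0) sample(free, min(k, length(free))) else integer()
        s <- cons
        if (length(cols)) s[cols] <- .other_base(s[cols])
        seqs[[paste0(prefix, r)]] <- paste(s, collapse = "")
        muts[[paste0(prefix, r)]] <- sort(cols)
      }
      list(seqs = seqs, muts = muts)
    }
    A <- make_clade(consA, p$n_parentA_ribotypes, "pA")
    B <- make_clade(consB, p$n_parentB_ribotypes, "pB")
    strs <- c(unlist(A$seqs), unlist(B$seqs))
    aln <- alignment(strs,
                     group = c(rep("parentA_diploid",
                                   p$n_parentA_ribotypes),
                               rep("parentB_tetraploid",
                                   p$n_parentB_ribotypes)))
    truth <- list(diagnostic_columns = diag_cols,
                  stateA = stateA, stateB = stateB,
                  ancestral = paste(anc, collapse = ""),
                  private_mutations = c(A$muts, B$muts))
    list(alignment = aln, truth = truth)
  })
}

#' Simulate allohexaploid hybrids under concerted evolution
#'
#' Each hybrid combines one maternal and one paternal parental ribotype. At
#' every column where the two differ, the site is kept additive (the IUPAC
#' union of both states) with probability `1 - h - h_paternal`, converted to
#' the maternal state with probability `h`, or to the paternal state with
#' probability `h_paternal`. With probability `p_chimera` the hybrid is
#' instead fully homogenized with an independent uniform random direction at
#' every differing site, producing an ambiguity-free chimeric sequence.
#'
#' @param parents Output of [simulate_parental_pools()] (list with
#'   `alignment` and `truth`), or a parental `dna_alignment` plus `truth`.
#' @param p A `synth_params`.
#' @param seed RNG seed (default `p$seed + 1`).
#' @return List with `alignment` (parents and hybrids combined; hybrids are
#'   labeled `hybrid_hexaploid`) and `truth` extended with a per-hybrid
#'   table (`hybrids`: maternal/paternal ribotype ids, chimera flag,
#'   per-site outcomes, counts, expected category).
#' @export
simulate_hybrids <- function(parents, p, seed = p$seed + 1L) {
  aln <- parents$alignment
  truth <- parents$truth
  mat_grp <- p$maternal
  pat_grp <- setdiff(c("parentA_diploid", "parentB_tetraploid"), mat_grp)
  mat_ids <- group_ids(aln, mat_grp)
  pat_ids <- group_ids(aln, pat_grp)
  if (!length(mat_ids) || !length(pat_ids))
    stop("empty parental pool", call. = FALSE)
  .with_seed(seed, {
    hyb_strs <- character(p$n_hybrids)
    rec <- vector("list", p$n_hybrids)
    for (hh in seq_len(p$n_hybrids)) {
      m_id <- sample(mat_ids, 1); f_id <- sample(pat_ids, 1)
      m <- aln$seq[match(m_id, rownames(aln$seq)), ]
      f <- aln$seq[match(f_id, rownames(aln$seq)), ]
      differ <- which(m != f)
      s <- m
      is_chim <- stats::runif(1) < p$p_chimera
      outcome <- rep("identical", length(differ))
      if (is_chim) {
        take_m <- stats::runif(length(differ)) < 0.5
        s[differ] <- ifelse(take_m, m[differ], f[differ])
        outcome <- ifelse(take_m, "converted_maternal",
                          "converted_paternal")
      } else {
        u <- stats::runif(length(differ))
        for (k in seq_along(differ)) {
          j <- differ[k]
          if (u[k] < p$h) {
            s[j] <- m[j]; outcome[k] <- "converted_maternal"
          } else if (u[k] < p$h + p$h_paternal) {
            s[j] <- f[j]; outcome[k] <- "converted_paternal"
          } else {
            s[j] <- iupac_code(union(iupac_set(m[j]), iupac_set(f[j])))
            outcome[k] <- "kept_additive"
          }
        }
      }
      hyb_strs[hh] <- paste(s, collapse = "")
      rec[[hh]] <- list(maternal = m_id, paternal = f_id,
                        chimera = is_chim, differing_columns = differ,
                        outcome = outcome)
    }
    names(hyb_strs) <- sprintf("hyb%d", seq_len(p$n_hybrids))
    hyb_aln <- alignment(hyb_strs, group = "hybrid_hexaploid")
    comb <- alignment(c(seq_strings(aln), seq_strings(hyb_aln)),
                      taxon = c(aln$meta$taxon, hyb_aln$meta$taxon),
                      group = c(aln$meta$group, hyb_aln$meta$group))
    names(rec) <- names(hyb_strs)
    truth$hybrids <- rec
    truth$maternal_group <- mat_grp
    list(alignment = comb, truth = truth)
  })
}

#' Simulate a full ITS dataset (parents plus hybrids)
#'
#' @param p A `synth_params`.
#' @param seed Base seed (default `p$seed`).
#' @return As [simulate_hybrids()].
#' @export
simulate_its_dataset <- function(p = synth_params(), seed = p$seed) {
  parents <- simulate_parental_pools(p, seed = seed)
  simulate_hybrids(parents, p, seed = seed + 1L)
}

#' Simulate a cpDNA spacer alignment with indels and repeat noise
#'
#' Haplotypes evolve on a simple bifurcating genealogy split into a diploid
#' and a tetraploid lineage: each new haplotype derives from a random earlier
#' haplotype of its lineage by 1-3 SNPs, occasionally an indel (length drawn
#' from `cp_indel_lengths`, realized as a gap run), and length jitter in a
#' planted mononucleotide repeat. Hexaploid individuals inherit a
#' tetraploid-lineage haplotype, emulating maternal plastid inheritance.
#'
#' @param p A `synth_params`.
#' @param seed RNG seed (default `p$seed + 2`).
#' @return List with `alignment` (one row per individual; groups diploid /
#'   tetraploid / hexaploid) and `truth` (haplotype assignment per
#'   individual, parent haplotype of each haplotype, event log, repeat
#'   columns).
#' @export
simulate_cpdna <- function(p, seed = p$seed + 2L) {
  .with_seed(seed, {
    L <- p$cp_length
    base <- .random_bases(L)
    rep_start <- floor(L * 0.4)
    rep_cols <- rep_start:(rep_start + 11L)
    base[rep_cols] <- "T"
    n <- p$cp_n_haplotypes
    n_tet <- ceiling(n / 2); n_dip <- n - n_tet
    seqs <- list(); parent <- integer(n); lineage <- character(n)
    events <- list()
    free_cols <- setdiff(seq_len(L), rep_cols)
    used <- rep(FALSE, L)
    place_indel <- function(len) {
      ## find a free internal interval not touching the repeat
      for (try in seq_len(200)) {
        st <- sample(2:(L - len - 1), 1)
        iv <- st:(st + len - 1)
        if (!any(used[iv]) && !any(iv %in% rep_cols) &&
            !used[st - 1] && !used[st + len]) {
          used[iv] <<- TRUE
          return(iv)
        }
      }
      NULL
    }
    seqs[[1]] <- base; parent[1] <- 0L; lineage[1] <- "tet"
    ## found the diploid lineage from a divergent derivative of hap 1
    for (k in 2:n) {
      lineage[k] <- if (k <= n_tet) "tet" else "dip"
      cand <- which(lineage[seq_len(k - 1)] == lineage[k])
      from <- if (lineage[k] == "dip" && !length(cand)) 1L
              else sample(cand, 1)
      s <- seqs[[from]]
      n_snp <- sample(1:3, 1) +
        if (lineage[k] == "dip" && !length(cand)) 4L else 0L
      snp_cols <- sample(free_cols[!used[free_cols]], n_snp)
      used[snp_cols] <- TRUE   # one substitution per column: no homoplasy
      s[snp_cols] <- .other_base(s[snp_cols])
      ev <- list(snps = sort(snp_cols), indel = NULL)
      if (stats::runif(1) < 0.6) {
        len <- sample(p$cp_indel_lengths, 1)
        iv <- place_indel(len)
        if (!is.null(iv)) { s[iv] <- .GAP; ev$indel <- range(iv) }
      }
      ## homopolymer length jitter: drop 0-2 repeat bases
      jit <- sample(0:2, 1)
      if (jit > 0) s[rep_cols[seq_len(jit)]] <- .GAP
      seqs[[k]] <- s
      parent[k] <- from
      events[[k]] <- ev
    }
    ## individuals: one per haplotype for parents; hexaploids reuse a
    ## tetraploid-lineage haplotype
    hap_of <- c(seq_len(n), rep(sample(which(lineage == "tet"), 1), 2))
    ids <- c(sprintf("%s_h%d", ifelse(lineage == "tet", "tet", "dip"),
                     seq_len(n)),
             sprintf("hex_i%d", 1:2))
    groups <- c(ifelse(lineage == "tet", "parentB_tetraploid",
                       "parentA_diploid"),
                rep("hybrid_hexaploid", 2))
    strs <- vapply(hap_of, function(k) paste(seqs[[k]], collapse = ""), "")
    names(strs) <- ids
    aln <- alignment(strs, group = groups)
    truth <- list(haplotype_of = stats::setNames(hap_of, ids),
                  parent_haplotype = parent, lineage = lineage,
                  events = events, repeat_columns = rep_cols)
    list(alignment = aln, truth = truth)
  })
}

#' Expected additivity outcome of a simulated hybrid
#'
#' Recomputes, from the generator truth alone, how many of the planted
#' diagnostic sites a hybrid kept additive, for parameter-recovery checks.
#'
#' @param truth Truth list from [simulate_hybrids()].
#' @param hybrid_id Hybrid sequence id.
#' @return List with `n_additive_expected` and `n_diagnostic` (the planted
#'   diagnostic sites at which this hybrid's parents actually differed).
#' @export
truth_expected_additivity <- function(truth, hybrid_id) {
  rec <- truth$hybrids[[hybrid_id]]
  if (is.null(rec)) stop("unknown hybrid id", call. = FALSE)
  on_diag <- rec$differing_columns %in% truth$diagnostic_columns
  list(n_additive_expected = sum(rec$outcome[on_diag] == "kept_additive"),
       n_diagnostic = sum(on_diag))
}
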