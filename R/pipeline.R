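## End-to-end orchestration: the nuclear (ITS) branch and the chloroplast
## branch, each returning a report bundle of machine-readable tables.

#' Run the ITS analysis branch
#'
#' collapse to ribotypes -> variable sites -> parental diagnostic profile ->
#' per-hybrid-ribotype additivity reports -> homogenization spectrum ->
#' ribotype-level nucleotide diversities.
#'
#' @param aln A `dna_alignment` with parental and hybrid groups assigned.
#' @param groupA,groupB Parental group labels.
#' @param hybrid_group Hybrid group label.
#' @param additive_threshold Passed to [score_ribotype()].
#' @param policy Ambiguity policy for distances, see [p_distance()].
#' @param outdir Optional directory; if given the bundle is written there
#'   via [write_report_bundle()].
#' @return Object of class `its_report`: list with `ribotypes`,
#'   `variable_sites`, `profile`, `scan`, `spectrum`, `distances`,
#'   `diversity` (within-A, within-B, between, in percent of sites).
#' @export
run_its_branch <- function(aln, groupA = "parentA_diploid",
                           groupB = "parentB_tetraploid",
                           hybrid_group = "hybrid_hexaploid",
                           additive_threshold = 0.9,
                           policy = "average", outdir = NULL) {
  if (!length(group_ids(aln, groupA)) || !length(group_ids(aln, groupB)))
    stop("configuration error: both parental groups must be present",
         call. = FALSE)
  rtab <- collapse_ribotypes(aln)
  variable <- find_variable_sites(aln)
  profile <- diagnostic_sites(aln, groupA, groupB)
  freq_col <- paste0("freq_", hybrid_group)
  hyb_reps <- if (freq_col %in% names(rtab$table))
    rtab$table$representative[rtab$table[[freq_col]] > 0] else character()
  scan <- additivity_scan(aln, profile, ids = hyb_reps,
                          additive_threshold = additive_threshold)
  spectrum <- if (length(scan$reports))
    homogenization_spectrum(scan, rtab, group = hybrid_group) else NULL
  dm <- distance_matrix(rtab$representatives, policy = policy)
  div_of <- function(a, b = NULL) tryCatch(
    100 * group_mean_diversity(dm, a, b), error = function(e) NA_real_)
  diversity <- c(within_A_pct = div_of(groupA),
                 within_B_pct = div_of(groupB),
                 between_pct = div_of(groupA, groupB))
  out <- structure(
    list(ribotypes = rtab, variable_sites = variable, profile = profile,
         scan = scan, spectrum = spectrum, distances = dm,
         diversity = diversity),
    class = "its_report")
  if (!is.null(outdir)) write_report_bundle(out, outdir)
  out
}

#' @export
print.its_report <- function(x, ...) {
  cat("ITS branch report\n")
  cat("  unique ribotypes:   ", nrow(x$ribotypes$table), "\n")
  cat("  variable sites:     ", length(x$variable_sites), "\n")
  cat("  diagnostic sites:   ", nrow(x$profile), "\n")
  cat("  hybrid ribotypes scored:", length(x$scan$reports), "\n")
  if (!is.null(x$spectrum)) {
    cat("  homogenization categories:\n")
    print(x$spectrum$categories)
  }
  cat("  diversity (% sites): within A ",
      sprintf("%.2f", x$diversity[["within_A_pct"]]), ", within B ",
      sprintf("%.2f", x$diversity[["within_B_pct"]]), ", between ",
      sprintf("%.2f", x$diversity[["between_pct"]]), "\n", sep = "")
  invisible(x)
}

#' Run the cpDNA analysis branch
#'
#' repeat masking -> haplotype collapsing -> simple indel coding -> A/T
#' recoding -> connection limit -> statistical-parsimony network ->
#' maternal-lineage call. The maternal call reports which parental group
#' shares a haplotype with the hybrids; it is shared-haplotype evidence,
#' not a statistical test.
#'
#' @param aln A `dna_alignment` (ingroup sequences).
#' @param min_run Mononucleotide-repeat masking threshold, see
#'   [mask_mononucleotide_repeats()].
#' @param alpha Parsimony confidence for the connection limit.
#' @param fixed_limit Optional integer overriding the computed limit.
#' @param hybrid_group Hybrid group label.
#' @param outdir Optional directory for [write_report_bundle()].
#' @return Object of class `cpdna_report`: list with `haplotypes`,
#'   `masked`, `indels`, `indel_summary`, `coding`, `network`,
#'   `connection_limit`, `maternal_call`.
#' @export
run_cpdna_branch <- function(aln, min_run = 8L, alpha = 0.95,
                             fixed_limit = NULL,
                             hybrid_group = "hybrid_hexaploid",
                             outdir = NULL) {
  masked <- mask_mononucleotide_repeats(aln, min_run = min_run)
  aln2 <- masked$alignment
  allgap <- which(apply(aln2$seq, 2, function(cc) all(cc == .GAP)))
  if (length(allgap)) {
    warning("dropping ", length(allgap), " all-gap column(s) after masking")
    aln2 <- subset_alignment(aln2, cols = setdiff(seq_len(ncol(aln2$seq)),
                                                  allgap))
  }
  htab <- collapse_ribotypes(aln2, label = "haplotype")
  reps <- htab$representatives
  coding <- simple_indel_coding(reps)
  recoded <- recode_indels_as_nucleotide(reps, coding)
  limit <- if (!is.null(fixed_limit)) as.integer(fixed_limit)
           else connection_limit(aln_length(recoded), alpha)
  freq <- stats::setNames(htab$table$frequency, htab$table$representative)
  net <- build_network(recoded, limit = limit, frequencies = freq)
  ## maternal call: parental group(s) sharing a haplotype with the hybrids
  fc <- function(g) paste0("freq_", g)
  tab <- htab$table
  hyb_here <- fc(hybrid_group) %in% names(tab) &&
    any(tab[[fc(hybrid_group)]] > 0)
  shared_with <- character()
  if (hyb_here) {
    for (g in c("parentA_diploid", "parentB_tetraploid")) {
      if (fc(g) %in% names(tab) &&
          any(tab[[fc(g)]] > 0 & tab[[fc(hybrid_group)]] > 0))
        shared_with <- c(shared_with, g)
    }
  }
  maternal_call <- if (!hyb_here || nrow(tab) < 2) "insufficient_signal"
                   else if (length(shared_with) == 1) shared_with
                   else if (length(shared_with) == 0) "none"
                   else "ambiguous"
  out <- structure(
    list(haplotypes = htab, masked = masked$masked,
         indels = coding$events, indel_summary = indel_summary(coding$events),
         coding = coding, network = net, connection_limit = limit,
         maternal_call = maternal_call),
    class = "cpdna_report")
  if (!is.null(outdir)) write_report_bundle(out, outdir)
  out
}

#' @export
print.cpdna_report <- function(x, ...) {
  cat("cpDNA branch report\n")
  cat("  haplotypes:        ", nrow(x$haplotypes$table), "\n")
  cat("  masked ranges:     ", nrow(x$masked), "\n")
  s <- x$indel_summary
  cat("  indels:            ", s$count,
      if (s$count > 0) sprintf(" (%d-%d bp)", s$min_length, s$max_length),
      "\n", sep = "")
  cat("  connection limit:  ", x$connection_limit, " steps\n", sep = "")
  cat("  network components:", length(unique(x$network$components)), "\n")
  cat("  maternal lineage call:", x$maternal_call,
      "(shared-haplotype evidence, not a test)\n")
  invisible(x)
}
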