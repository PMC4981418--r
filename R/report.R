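## Deterministic TSV serialization of every result table, plus the bundle
## writer with a provenance block.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a ribotype/haplotype table as TSV
#'
#' Rows sorted by type id; member ids joined with commas.
#'
#' @param rtab A `ribotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ribotype_table <- function(rtab, path) {
  df <- rtab$table
  df$members <- vapply(rtab$members, paste, "", collapse = ",")
  .write_tsv(df[order(df$type_id), ], path)
}

#' Write an indel inventory as TSV
#' @param events data.frame from [find_indels()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indel_inventory <- function(events, path) {
  df <- events
  df$members <- vapply(events$members, paste, "", collapse = ",")
  .write_tsv(df, path)
}

#' Write a diagnostic profile as TSV
#' @param profile A `diagnostic_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagnostic_profile <- function(profile, path) {
  df <- data.frame(
    column = profile$column,
    setA = vapply(profile$setA, paste, "", collapse = "/"),
    setB = vapply(profile$setB, paste, "", collapse = "/"))
  .write_tsv(df, path)
}

#' Write per-ribotype additivity reports as TSV
#'
#' One row per scored ribotype plus, in `calls_path` if given, the
#' site-by-site classification matrix (rows = ribotypes, columns =
#' diagnostic positions, cells = residue and category code).
#'
#' @param scan An `additivity_scan`.
#' @param path Output path for the summary table.
#' @param calls_path Optional output path for the per-site matrix.
#' @return `path`, invisibly.
#' @export
write_additivity_reports <- function(scan, path, calls_path = NULL) {
  df <- as.data.frame(scan)
  .write_tsv(df, path)
  if (!is.null(calls_path) && length(scan$reports)) {
    code <- c(parentA_like = "A", parentB_like = "B", additive = "+",
              inconclusive = ".")
    m <- t(vapply(scan$reports, function(r)
      paste0(r$calls$residue, code[r$calls$category]),
      character(nrow(scan$profile))))
    colnames(m) <- scan$profile$column
    out <- data.frame(ribotype = rownames(m), m, check.names = FALSE)
    .write_tsv(out, calls_path)
  }
  invisible(path)
}

#' Write a full report bundle
#'
#' Serializes every table of an `its_report` or `cpdna_report` into `dir`
#' with fixed file names and deterministic ordering, plus a provenance
#' table (package version, file checksums) so identical inputs yield an
#' identical bundle.
#'
#' @param report An `its_report` or `cpdna_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  written <- character()
  add <- function(path) written <<- c(written, path)
  if (inherits(report, "its_report")) {
    add(write_ribotype_table(report$ribotypes, p("ribotypes.tsv")))
    add(.write_tsv(data.frame(column = report$variable_sites),
                   p("variable_sites.tsv")))
    add(write_diagnostic_profile(report$profile,
                                 p("diagnostic_profile.tsv")))
    add(write_additivity_reports(report$scan, p("additivity.tsv"),
                                 p("additivity_calls.tsv")))
    if (!is.null(report$spectrum)) {
      add(.write_tsv(report$spectrum$categories,
                     p("spectrum_categories.tsv")))
      add(.write_tsv(report$spectrum$polymorphism,
                     p("spectrum_polymorphism.tsv")))
    }
    dmat <- report$distances$d
    long <- data.frame(
      id1 = rownames(dmat)[row(dmat)[upper.tri(dmat)]],
      id2 = colnames(dmat)[col(dmat)[upper.tri(dmat)]],
      distance = dmat[upper.tri(dmat)])
    add(.write_tsv(long[order(long$id1, long$id2), ], p("distances.tsv")))
    add(.write_tsv(data.frame(measure = names(report$diversity),
                              value_pct = unname(report$diversity)),
                   p("diversity.tsv")))
    add(write_alignment(report$ribotypes$representatives,
                        p("ribotype_representatives.fasta")))
  } else if (inherits(report, "cpdna_report")) {
    add(write_ribotype_table(report$haplotypes, p("haplotypes.tsv")))
    add(.write_tsv(report$masked, p("masked_ranges.tsv")))
    add(write_indel_inventory(report$indels, p("indel_inventory.tsv")))
    add(write_network_edges(report$network, p("network_edges.tsv")))
    add(write_network_graphml(report$network, p("network.graphml")))
    add(write_network_dot(report$network, p("network.dot")))
    add(.write_tsv(data.frame(
      measure = c("connection_limit", "n_components", "maternal_call"),
      value = c(report$connection_limit,
                length(unique(report$network$components)),
                report$maternal_call)),
      p("network_summary.tsv")))
  } else stop("unknown report type", call. = FALSE)
  prov <- data.frame(
    file = basename(written),
    md5 = unname(tools::md5sum(written)),
    package_version = as.character(utils::packageVersion("allohex")))
  .write_tsv(prov[order(prov$file), ], p("provenance.tsv"))
  invisible(written)
}
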