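## Diagnostic-site and additivity analysis: the evidence chain that detects a
## hybrid's two parental ITS copies (additive IUPAC codes at sites where the
## parental groups differ) and measures how far concerted evolution has
## homogenized them toward one parent.

.AMBIGUITY_CODES <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Variable alignment columns
#'
#' Columns where at least two distinct non-gap residues occur among the
#' scoped sequences. Ambiguity codes count as residues in their own right
#' (a 'C' vs 'Y' difference is variation); gap-only differences are not
#' variable sites (they belong to the indel inventory).
#'
#' @param aln A `dna_alignment`.
#' @param groups Optional group labels restricting the scope.
#' @return Increasing integer vector of 1-based columns.
#' @export
find_variable_sites <- function(aln, groups = NULL) {
  ids <- if (is.null(groups)) aln$meta$id else group_ids(aln, groups)
  if (length(ids) < 2) stop("need at least two sequences in scope",
                            call. = FALSE)
  m <- aln$seq[match(ids, rownames(aln$seq)), , drop = FALSE]
  which(apply(m, 2, function(col) length(unique(col[col != .GAP])) >= 2))
}

#' Intraindividual polymorphism positions of one sequence
#'
#' Superimposed peaks in a direct Sanger read are recorded as two- or
#' three-fold IUPAC ambiguity codes; this returns the columns carrying one
#' (N, the four-fold code, is missing data, not polymorphism).
#'
#' @param seq A residue string, or a `dna_alignment` (then `id` selects the
#'   sequence).
#' @param id Sequence id when `seq` is an alignment.
#' @return Increasing integer vector of 1-based columns.
#' @examples
#' intraindividual_polymorphism("ACYT")
#' @export
intraindividual_polymorphism <- function(seq, id = NULL) {
  v <- .as_residues(seq, id)
  which(v %in% .AMBIGUITY_CODES)
}

.as_residues <- function(seq, id = NULL) {
  if (inherits(seq, "dna_alignment")) {
    if (is.null(id)) stop("give an id to pick a sequence", call. = FALSE)
    seq$seq[match(id, rownames(seq$seq)), ]
  } else if (length(seq) == 1 && nchar(seq) > 1) {
    toupper(strsplit(seq, "")[[1]])
  } else {
    toupper(seq)
  }
}

#' Diagnostic sites between two parental groups
#'
#' A column is diagnostic when the IUPAC-expanded state sets of the two
#' parental groups are disjoint, so any state observed in a hybrid can be
#' attributed to one side. Group-wide set union (rather than consensus)
#' is used because parental ribotypes may themselves carry ambiguity codes.
#' Columns where any parental member shows a gap or N are skipped.
#'
#' @param aln A `dna_alignment` containing the parental sequences.
#' @param groupA,groupB Group labels (defaults: diploid vs tetraploid pool).
#' @param idsA,idsB Explicit sequence ids overriding the group labels.
#' @return Object of class `diagnostic_profile`: data.frame with `column`
#'   and list-columns `setA`, `setB`.
#' @export
diagnostic_sites <- function(aln, groupA = "parentA_diploid",
                             groupB = "parentB_tetraploid",
                             idsA = NULL, idsB = NULL) {
  if (is.null(idsA)) idsA <- group_ids(aln, groupA)
  if (is.null(idsB)) idsB <- group_ids(aln, groupB)
  if (!length(idsA) || !length(idsB))
    stop("both parental groups must be non-empty", call. = FALSE)
  mA <- aln$seq[match(idsA, rownames(aln$seq)), , drop = FALSE]
  mB <- aln$seq[match(idsB, rownames(aln$seq)), , drop = FALSE]
  cols <- integer(); setA <- list(); setB <- list()
  for (j in seq_len(ncol(mA))) {
    a <- mA[, j]; b <- mB[, j]
    if (any(c(a, b) %in% c(.GAP, "N"))) next
    sa <- sort(unique(unlist(lapply(unique(a), iupac_set))))
    sb <- sort(unique(unlist(lapply(unique(b), iupac_set))))
    if (!length(intersect(sa, sb))) {
      cols <- c(cols, j)
      setA <- c(setA, list(sa)); setB <- c(setB, list(sb))
    }
  }
  out <- data.frame(column = cols)
  out$setA <- I(setA); out$setB <- I(setB)
  structure(out, class = c("diagnostic_profile", "data.frame"),
            groupA = groupA, groupB = groupB)
}

#' @export
print.diagnostic_profile <- function(x, ...) {
  cat("diagnostic profile: ", nrow(x), " sites with disjoint parental state",
      " sets\n", sep = "")
  if (nrow(x)) {
    show <- data.frame(
      column = x$column,
      setA = vapply(x$setA, paste, "", collapse = "/"),
      setB = vapply(x$setB, paste, "", collapse = "/"))
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' Classify one observed state against the parental state sets
#'
#' `additive` when the observed set draws on both parental sides;
#' `parentA_like` / `parentB_like` when it is contained in one side;
#' `inconclusive` otherwise (third state, or missing data).
#'
#' @param observed A residue (IUPAC code) or a base set.
#' @param setA,setB Disjoint parental base sets.
#' @param strict If `TRUE`, additivity additionally requires the observed set
#'   to contain no base outside the two parental sets.
#' @return One of `"additive"`, `"parentA_like"`, `"parentB_like"`,
#'   `"inconclusive"`.
#' @examples
#' classify_site_state("Y", setA = "T", setB = "C")  # additive
#' @export
classify_site_state <- function(observed, setA, setB, strict = FALSE) {
  if (length(intersect(setA, setB)))
    stop("parental state sets must be disjoint", call. = FALSE)
  obs <- if (is.character(observed) && length(observed) == 1 &&
               nchar(observed) == 1) iupac_set(observed) else toupper(observed)
  if (isTRUE(attr(obs, "uninformative"))) return("inconclusive")
  inA <- length(intersect(obs, setA)) > 0
  inB <- length(intersect(obs, setB)) > 0
  if (inA && inB) {
    if (strict && length(setdiff(obs, union(setA, setB))))
      return("inconclusive")
    return("additive")
  }
  if (all(obs %in% setA)) return("parentA_like")
  if (all(obs %in% setB)) return("parentB_like")
  "inconclusive"
}

#' Score one sequence against a diagnostic profile
#'
#' Calls every diagnostic position, counts the site classes, infers the
#' homogenization direction (the parental side holding the majority of
#' non-additive parental calls; ties give `"none"`), and labels the
#' sequence:
#' \describe{
#'   \item{fully_additive}{additive at `additive_threshold` of the
#'     diagnostic sites or more — both parental copies essentially intact.}
#'   \item{fully_homogenized}{no additive site, all parental calls on one
#'     side — concerted evolution has erased one copy.}
#'   \item{chimeric}{no additive site but parental calls on both sides — a
#'     homogenized recombinant of the two parental sequences.}
#'   \item{partially_homogenized}{some but sub-threshold additivity.}
#'   \item{unclassified}{no interpretable parental signal.}
#' }
#'
#' @param seq Residue string, or a `dna_alignment` with `id`.
#' @param profile A `diagnostic_profile`.
#' @param additive_threshold Fraction of diagnostic sites that must be
#'   additive for `fully_additive` (default 0.9, separating complete or
#'   nearly complete additivity from partial homogenization).
#' @param strict Passed to [classify_site_state()].
#' @param id Sequence id when `seq` is an alignment.
#' @return Object of class `additivity_report`.
#' @export
score_ribotype <- function(seq, profile, additive_threshold = 0.9,
                           strict = FALSE, id = NULL) {
  v <- .as_residues(seq, id)
  nm <- if (!is.null(id)) id
        else if (inherits(seq, "dna_alignment")) rownames(seq$seq)[1]
        else if (!is.null(names(seq))) names(seq)[1] else "seq"
  if (nrow(profile) && max(profile$column) > length(v))
    stop("sequence shorter than profile's source alignment", call. = FALSE)
  cat_at <- character(nrow(profile))
  res_at <- character(nrow(profile))
  for (k in seq_len(nrow(profile))) {
    res_at[k] <- v[profile$column[k]]
    cat_at[k] <- classify_site_state(res_at[k], profile$setA[[k]],
                                     profile$setB[[k]], strict = strict)
  }
  n_add <- sum(cat_at == "additive")
  n_a   <- sum(cat_at == "parentA_like")
  n_b   <- sum(cat_at == "parentB_like")
  n_inc <- sum(cat_at == "inconclusive")
  D <- nrow(profile)
  direction <- if (n_a > n_b) "toward_A" else if (n_b > n_a) "toward_B"
               else "none"
  tie <- n_a == n_b && n_a > 0
  category <-
    if (D == 0) "unclassified"
    else if (n_add == 0 && n_a > 0 && n_b > 0) "chimeric"
    else if (n_add == 0 && xor(n_a > 0, n_b > 0)) "fully_homogenized"
    else if (n_add / D >= additive_threshold) "fully_additive"
    else if (n_add >= 1) "partially_homogenized"
    else "unclassified"
  structure(
    list(ribotype = nm,
         calls = data.frame(column = profile$column, residue = res_at,
                            category = cat_at),
         n_additive = n_add, n_parentA = n_a, n_parentB = n_b,
         n_inconclusive = n_inc,
         n_polymorphic_sites = length(intraindividual_polymorphism(v)),
         direction = direction, direction_tie = tie,
         category = category, n_diagnostic = D,
         additive_threshold = additive_threshold),
    class = "additivity_report")
}

#' @export
print.additivity_report <- function(x, ...) {
  cat("additivity report for '", x$ribotype, "': ", x$category, "\n",
      sep = "")
  cat(sprintf(
    "  diagnostic sites: %d (additive %d, parentA %d, parentB %d, inconclusive %d)\n",
    x$n_diagnostic, x$n_additive, x$n_parentA, x$n_parentB,
    x$n_inconclusive))
  cat("  homogenization direction:", x$direction,
      if (x$direction_tie) "(tied parental counts)" else "", "\n")
  cat("  intraindividual polymorphic sites:", x$n_polymorphic_sites, "\n")
  invisible(x)
}

#' Score a set of sequences against a diagnostic profile
#'
#' Applies [score_ribotype()] to each selected sequence (by default the
#' hybrid group) and assembles the per-ribotype reports.
#'
#' @param aln A `dna_alignment`.
#' @param profile A `diagnostic_profile`.
#' @param ids Sequence ids to score; default the `hybrid_hexaploid` group.
#' @param ... Passed to [score_ribotype()].
#' @return Object of class `additivity_scan`: list of `additivity_report`
#'   plus the profile.
#' @export
additivity_scan <- function(aln, profile, ids = NULL, ...) {
  if (is.null(ids)) ids <- group_ids(aln, "hybrid_hexaploid")
  reports <- lapply(ids, function(i)
    score_ribotype(aln, profile, id = i, ...))
  names(reports) <- ids
  structure(list(reports = reports, profile = profile),
            class = "additivity_scan")
}

#' Turn an additivity scan into a summary data frame
#' @param x An `additivity_scan`.
#' @param ... Unused.
#' @return data.frame, one row per scored sequence.
#' @export
as.data.frame.additivity_scan <- function(x, ...) {
  do.call(rbind, lapply(x$reports, function(r)
    data.frame(ribotype = r$ribotype, n_additive = r$n_additive,
               n_parentA = r$n_parentA, n_parentB = r$n_parentB,
               n_inconclusive = r$n_inconclusive,
               n_polymorphic_sites = r$n_polymorphic_sites,
               direction = r$direction, category = r$category,
               stringsAsFactors = FALSE)))
}

#' @export
print.additivity_scan <- function(x, ...) {
  cat("additivity scan: ", length(x$reports), " sequences against ",
      nrow(x$profile), " diagnostic sites\n", sep = "")
  df <- as.data.frame(x)
  rownames(df) <- NULL
  print(df)
  invisible(x)
}

#' @export
summary.additivity_scan <- function(object, ...) {
  df <- as.data.frame(object)
  cat("additivity scan over", nrow(df), "sequences\n")
  print(table(category = df$category))
  cat("additive sites per sequence: ")
  print(stats::quantile(df$n_additive))
  invisible(object)
}

#' Plot an additivity scan as a site-by-ribotype classification matrix
#'
#' Base-graphics image of the per-site calls, one row per scored sequence
#' and one column per diagnostic site, colour-coded by class.
#'
#' @param x An `additivity_scan`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.additivity_scan <- function(x, ...) {
  lv <- c("parentA_like", "parentB_like", "additive", "inconclusive")
  cols <- c("grey70", "steelblue", "black", "white")
  m <- vapply(x$reports, function(r)
    as.integer(factor(r$calls$category, levels = lv)),
    integer(nrow(x$profile)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(x$profile))
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  col = cols, zlim = c(1, 4),
                  xlab = "diagnostic site index", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_along(x$reports), labels = names(x$reports),
                 las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Tabulate homogenization categories and polymorphism levels
#'
#' Cross-tabulates the scan's category labels and intraindividual
#' polymorphism counts, both per ribotype and weighted by ribotype frequency
#' (individuals).
#'
#' @param scan An `additivity_scan` whose reports are named by ribotype
#'   representative ids.
#' @param rtab A `ribotype_table`; frequencies are matched via the
#'   representative id.
#' @param group Optional group label: weight individuals by that group's
#'   per-ribotype frequency (e.g. count only hexaploid carriers) instead of
#'   the total frequency.
#' @return List of two data.frames: `categories` (category, n_ribotypes,
#'   n_individuals) and `polymorphism` (n_polymorphic_sites, n_ribotypes,
#'   n_individuals), each sorted deterministically.
#' @export
homogenization_spectrum <- function(scan, rtab, group = NULL) {
  df <- as.data.frame(scan)
  i <- match(df$ribotype, rtab$table$representative)
  if (anyNA(i))
    stop("scan ids not found among ribotype representatives: ",
         paste(df$ribotype[is.na(i)], collapse = ", "), call. = FALSE)
  freq_col <- "frequency"
  if (!is.null(group)) {
    freq_col <- paste0("freq_", group)
    if (!freq_col %in% names(rtab$table))
      stop("no per-group frequencies for '", group, "'", call. = FALSE)
  }
  df$frequency <- rtab$table[[freq_col]][i]
  cat_lv <- c("fully_homogenized", "chimeric", "partially_homogenized",
              "fully_additive", "unclassified")
  categories <- do.call(rbind, lapply(cat_lv, function(cl) {
    sel <- df$category == cl
    data.frame(category = cl, n_ribotypes = sum(sel),
               n_individuals = sum(df$frequency[sel]))
  }))
  categories <- categories[categories$n_ribotypes > 0, , drop = FALSE]
  rownames(categories) <- NULL
  poly_lv <- sort(unique(df$n_polymorphic_sites))
  polymorphism <- do.call(rbind, lapply(poly_lv, function(p) {
    sel <- df$n_polymorphic_sites == p
    data.frame(n_polymorphic_sites = p, n_ribotypes = sum(sel),
               n_individuals = sum(df$frequency[sel]))
  }))
  rownames(polymorphism) <- NULL
  list(categories = categories, polymorphism = polymorphism)
}

#' Shared derived states private to a subgroup
#'
#' Columns at which every member of the focal set carries one identical
#' residue that occurs in no sequence of the background set (by default all
#' other parental sequences) — synapomorphies supporting the subgroup.
#'
#' @param aln A `dna_alignment`.
#' @param ids Focal sequence ids.
#' @param background_ids Background ids; default all parental-group
#'   sequences not in `ids`.
#' @return data.frame with columns `column` and `state`.
#' @export
synapomorphy_check <- function(aln, ids, background_ids = NULL) {
  if (is.null(background_ids))
    background_ids <- setdiff(
      group_ids(aln, c("parentA_diploid", "parentB_tetraploid")), ids)
  if (!length(ids) || !length(background_ids))
    stop("focal and background sets must be non-empty", call. = FALSE)
  mg <- aln$seq[match(ids, rownames(aln$seq)), , drop = FALSE]
  mb <- aln$seq[match(background_ids, rownames(aln$seq)), , drop = FALSE]
  cols <- integer(); states <- character()
  for (j in seq_len(ncol(mg))) {
    g <- unique(mg[, j])
    if (length(g) != 1 || g == .GAP) next
    if (!(g %in% mb[, j])) { cols <- c(cols, j); states <- c(states, g) }
  }
  data.frame(column = cols, state = states)
}
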