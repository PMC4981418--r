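## Deterministic synthetic reference-style datasets. These are stand-ins,
## built in code, that reproduce the documented structure of a published
## diploid/tetraploid/hexaploid ITS and cpDNA study system (column counts,
## diagnostic-site counts, ribotype inventory, indel inventory) without any
## real sequence data. They exist so the full pipeline can be exercised and
## its summary numbers checked end-to-end; they are synthetic and carry no
## information beyond the construction below.

## deterministic single-base substitution (A->C->G->T->A)
.next_base <- function(b) c(A = "C", C = "G", G = "T", T = "A")[b]

#' Synthetic reference-style ITS ribotype panel
#'
#' Builds a 624-column ITS alignment of 31 sequences collapsing to 29 unique
#' ribotypes in the classic allohexaploid configuration: 6 diploid ribotypes
#' (3 per diploid species, the second species marked by a synapomorphy at
#' column 529), 4 tetraploid ribotypes, and 21 hexaploid ribotypes (two of
#' them identical to tetraploid ribotypes). The parental clades differ at
#' exactly 37 diagnostic columns (including 443 and 576). Hexaploids span
#' the whole homogenization spectrum: a fully additive ribotype (ambiguity
#' codes at all 37 diagnostic sites), two nearly complete ones (36, 35),
#' fifteen partially homogenized ribotypes with 1-7 polymorphic sites, a
#' fully homogenized chimera carrying diploid states at columns 443 and 576
#' only, and ribotypes shared with the tetraploids. One 1-bp indel and
#' three hexaploid-only polymorphic columns bring the variable-site count
#' to 49. Entirely synthetic; deterministic.
#'
#' @return List with `alignment` (a `dna_alignment`) and `features` (the
#'   planted coordinates, for tests of the construction itself).
#' @export
synthetic_reference_its <- function() {
  L <- 624L
  diag_cols <- c(12L, 29L, 44L, 61L, 78L, 95L, 110L, 128L, 141L, 158L,
                 173L, 190L, 207L, 222L, 239L, 254L, 271L, 288L, 303L,
                 320L, 337L, 352L, 369L, 384L, 401L, 418L, 433L, 443L,
                 458L, 475L, 490L, 507L, 522L, 547L, 561L, 576L, 590L)
  syn_col <- 529L
  extra_poly <- c(200L, 215L, 230L)     # polymorphic only in hexaploids
  indel_col <- 300L
  backbone <- .with_seed(101L, .random_bases(L))
  consA <- backbone
  consB <- backbone
  consB[diag_cols] <- .next_base(consB[diag_cols])

  amb_both <- function(col, s) {
    s[col] <- iupac_code(c(consA[col], consB[col])); s
  }
  mut <- function(cols, s) { s[cols] <- .next_base(s[cols]); s }
  amb_self <- function(col, s) {
    s[col] <- iupac_code(c(s[col], .next_base(s[col]))); s
  }

  ## diploid ribotypes (clade A)
  r1 <- consA
  r2 <- mut(35L, consA)
  r3 <- amb_self(50L, consA)
  r4 <- mut(syn_col, consA)
  r5 <- mut(70L, r4)
  r6 <- mut(85L, r4)
  ## tetraploid ribotypes (clade B)
  r7  <- consB
  r14 <- mut(100L, consB)
  r28 <- mut(c(115L, 130L), consB)
  r29 <- mut(c(115L, 145L), consB); r29[indel_col] <- .GAP
  ## hexaploid ribotypes
  additive_at <- function(idx, base = consB) {
    s <- base
    for (k in idx) s <- amb_both(diag_cols[k], s)
    s
  }
  r12 <- additive_at(1:37)
  r18 <- additive_at(2:37)
  r20 <- additive_at(3:37)
  r15 <- consB; r15[c(443L, 576L)] <- consA[c(443L, 576L)]
  partial <- list(
    r8 = 3L, r9 = 3:4, r10 = 3:5, r11 = 3:6, r13 = 3:7,
    r16 = 10L, r17 = 10:11, r19 = 3:8,
    r21 = 15L, r22 = 15:16, r23 = 15:17, r24 = 15:18,
    r25 = 20:23, r26 = 20:24, r27 = 20:25)
  hex <- lapply(partial, additive_at)
  hex$r25 <- amb_self(extra_poly[1], hex$r25)
  hex$r26 <- amb_self(extra_poly[2], hex$r26)
  hex$r27 <- amb_self(extra_poly[3], hex$r27)

  rows <- c(
    fic_r1 = paste(r1, collapse = ""), fic_r2 = paste(r2, collapse = ""),
    fic_r3 = paste(r3, collapse = ""), sue_r4 = paste(r4, collapse = ""),
    sue_r5 = paste(r5, collapse = ""), sue_r6 = paste(r6, collapse = ""),
    stc_r7 = paste(r7, collapse = ""), stf_r14 = paste(r14, collapse = ""),
    stc_r28 = paste(r28, collapse = ""), stc_r29 = paste(r29, collapse = ""),
    alb_r7 = paste(r7, collapse = ""),
    alb_r8 = paste(hex$r8, collapse = ""),
    alb_r9 = paste(hex$r9, collapse = ""),
    alb_r10 = paste(hex$r10, collapse = ""),
    alb_r11 = paste(hex$r11, collapse = ""),
    alb_r12 = paste(r12, collapse = ""),
    alb_r13 = paste(hex$r13, collapse = ""),
    alb_r14 = paste(r14, collapse = ""),
    alb_r15 = paste(r15, collapse = ""),
    alb_r16 = paste(hex$r16, collapse = ""),
    alb_r17 = paste(hex$r17, collapse = ""),
    alb_r18 = paste(r18, collapse = ""),
    alb_r19 = paste(hex$r19, collapse = ""),
    alb_r20 = paste(r20, collapse = ""),
    alb_r21 = paste(hex$r21, collapse = ""),
    alb_r22 = paste(hex$r22, collapse = ""),
    alb_r23 = paste(hex$r23, collapse = ""),
    alb_r24 = paste(hex$r24, collapse = ""),
    alb_r25 = paste(hex$r25, collapse = ""),
    alb_r26 = paste(hex$r26, collapse = ""),
    alb_r27 = paste(hex$r27, collapse = ""))
  taxon <- c(rep("fic", 3), rep("sue", 3), "stc", "stf", "stc", "stc",
             rep("alb", 21))
  group <- c(rep("parentA_diploid", 6), rep("parentB_tetraploid", 4),
             rep("hybrid_hexaploid", 21))
  aln <- alignment(rows, taxon = taxon, group = group)
  list(alignment = aln,
       features = list(diagnostic_columns = diag_cols,
                       synapomorphy_column = syn_col,
                       chimera_columns = c(443L, 576L),
                       indel_column = indel_col,
                       extra_polymorphic_columns = extra_poly))
}

#' Synthetic reference-style cpDNA spacer panel
#'
#' Builds a 1254-column chloroplast spacer alignment: 9 ingroup individuals
#' carrying 7 haplotypes (a tetraploid-lineage cluster shared by the
#' tetraploids and all hexaploids, and a diverged diploid lineage) plus 4
#' outgroup sequences. The ingroup occupies 1184 columns (a 70-bp
#' outgroup-only insertion accounts for the rest). After masking a planted
#' 12-bp mononucleotide repeat whose length jitters between haplotypes, the
#' alignment contains exactly 25 internal indel events of 1-385 bp, 4 of
#' them segregating within the ingroup (1-150 bp). Entirely synthetic;
#' deterministic.
#'
#' @return List with `alignment` (full panel), `ingroup` (ingroup rows with
#'   outgroup-only columns dropped) and `features` (planted coordinates).
#' @export
synthetic_reference_cpdna <- function() {
  L <- 1254L
  block <- 1101:1170                       # outgroup-only insertion (70 bp)
  rep_cols <- 481:492                      # poly-T mononucleotide repeat
  ingroup_events <- data.frame(
    start = c(301L, 601L, 701L, 801L),
    end   = c(301L, 612L, 757L, 950L))    # lengths 1, 12, 57, 150
  og_events <- data.frame(
    row = c(rep("og1", 5), rep("og2", 5), rep("og3", 5), rep("og4", 5)),
    start = c(613L, 100L, 200L, 300L, 400L,
              150L, 250L, 350L, 450L, 550L,
              650L, 750L, 850L, 950L, 1050L,
              1180L, 1200L, 1220L, 1240L, 60L),
    len = c(385L, 40L, 35L, 30L, 28L,
            26L, 24L, 22L, 20L, 18L,
            16L, 14L, 12L, 10L, 8L,
            6L, 5L, 4L, 3L, 2L),
    stringsAsFactors = FALSE)
  og_events$end <- og_events$start + og_events$len - 1L

  master <- .with_seed(202L, .random_bases(L))
  master[rep_cols] <- "T"
  ## keep the planted repeat from fusing with neighbouring T's
  master[c(479L, 480L, 493L, 494L)] <- c("A", "C", "A", "C")
  ## deletions must not let identical flanking bases fuse into a maskable
  ## homopolymer run across the gap
  all_iv <- rbind(ingroup_events[c("start", "end")],
                  og_events[c("start", "end")],
                  data.frame(start = block[1], end = block[length(block)]))
  for (k in seq_len(nrow(all_iv))) {
    s <- all_iv$start[k]; e <- all_iv$end[k]
    if (master[s - 1L] == master[e + 1L])
      master[e + 1L] <- setdiff(.BASES, c(master[s - 1L],
                                          master[e + 2L]))[1]
  }

  snp <- function(cols, s) { s[cols] <- .next_base(s[cols]); s }
  del <- function(from, to, s) { s[from:to] <- .GAP; s }

  ing_base <- del(block[1], block[length(block)], master)
  hap1 <- ing_base
  hap2 <- snp(51L, hap1)
  hap3 <- del(301L, 301L, snp(71L, hap1))
  hap4 <- del(801L, 950L, snp(91L, hap1))
  dip_base <- del(701L, 757L, snp(c(111L, 131L, 151L, 171L, 191L), hap1))
  hap7 <- snp(211L, dip_base)
  hap5 <- del(601L, 612L, snp(231L, dip_base))
  hap6 <- del(601L, 612L, snp(251L, dip_base))
  ## homopolymer length jitter
  hap3[492L] <- .GAP
  hap5[491:492] <- .GAP

  og_base <- snp(seq(15L, 595L, by = 20L), master)
  og <- list(og1 = snp(c(1175L, 1177L), og_base),
             og2 = snp(c(1190L, 1192L), og_base),
             og3 = snp(c(1210L, 1212L), og_base),
             og4 = snp(c(1230L, 1232L), og_base))
  for (k in seq_len(nrow(og_events))) {
    r <- og_events$row[k]
    og[[r]] <- del(og_events$start[k], og_events$end[k], og[[r]])
  }

  haps <- list(hap1, hap2, hap3, hap4, hap5, hap6, hap7)
  rows <- c(stc_1 = 1L, stf_1 = 1L, alb_1 = 1L, alb_2 = 2L, alb_3 = 3L,
            stc_4 = 4L, sue_5 = 5L, sue_6 = 6L, fic_7 = 7L)
  strs <- vapply(rows, function(k) paste(haps[[k]], collapse = ""), "")
  strs <- c(strs, vapply(og, paste, "", collapse = ""))
  group <- c("parentB_tetraploid", "parentB_tetraploid",
             "hybrid_hexaploid", "hybrid_hexaploid", "hybrid_hexaploid",
             "parentB_tetraploid", "parentA_diploid", "parentA_diploid",
             "parentA_diploid", rep("outgroup", 4))
  taxon <- c("stc", "stf", "alb", "alb", "alb", "stc", "sue", "sue",
             "fic", paste0("og", 1:4))
  aln <- alignment(strs, taxon = taxon, group = group)
  ingroup <- subset_alignment(aln, ids = names(rows),
                              cols = setdiff(seq_len(L), block))
  list(alignment = aln, ingroup = ingroup,
       features = list(outgroup_block = range(block),
                       repeat_columns = range(rep_cols),
                       ingroup_events = ingroup_events,
                       og_events = og_events,
                       haplotype_of = rows))
}
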