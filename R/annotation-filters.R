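#' Apply annotation-based hard filters to a variant table
#'
#' Keeps variants with CADD strictly greater than `cfg$cadd_min`, population
#' allele frequency strictly less than `cfg$af_max` (missing frequency is
#' treated as 0, i.e. a novel allele), impact severity not in
#' `cfg$excluded_impacts`, and genotype quality at least `cfg$gq_min` in all
#' samples. A missing CADD score cannot reject a variant: the record is kept
#' and a warning is emitted. Input order is preserved; every rejected record
#' is logged with the first rule it failed.
#'
#' @param variants data.frame with at least `cadd`, `af`, `impact` and the
#'   three `gq_*` columns.
#' @param cfg A [filter_config()] object.
#' @return The retained rows, with a `rejections` attribute: a data.frame of
#'   `(row, gene, rule)` records for every dropped variant.
#' @export
#' @examples
#' v <- data.frame(gene = c("A", "B"), cadd = c(21.9, 9.9),
#'                 af = c(1.2e-5, 1.2e-5), impact = "MODERATE",
#'                 gq_proband = 60, gq_father = 60, gq_mother = 60)
#' kept <- apply_annotation_filters(v)
#' kept$gene
#' attr(kept, "rejections")
apply_annotation_filters <- function(variants, cfg = filter_config()) {
  if (nrow(variants) == 0) {
    attr(variants, "rejections") <-
      data.frame(row = integer(), gene = character(), rule = character(),
                 stringsAsFactors = FALSE)
    return(variants)
  }

  cadd <- variants$cadd
  if (any(is.na(cadd)))
    warning(sum(is.na(cadd)), " variant(s) without a CADD score were ",
            "retained: the deleteriousness filter cannot reject on absent ",
            "evidence.", call. = FALSE)
  cadd_fail <- !is.na(cadd) & cadd <= cfg$cadd_min

  af <- variants$af
  af[is.na(af)] <- 0
  af_fail <- af >= cfg$af_max

  impact_fail <- toupper(as.character(variants$impact)) %in%
    cfg$excluded_impacts
  impact_fail[is.na(variants$impact)] <- FALSE

  gq_fail <- !gq_pass(variants, cfg$gq_min)

  # first failing rule, in filter order, for the rejection log
  rule <- rep(NA_character_, nrow(variants))
  rule[gq_fail] <- "low_gq"
  rule[impact_fail & is.na(rule)] <- "excluded_impact"
  rule[af_fail & is.na(rule)] <- "common_af"
  rule[cadd_fail & is.na(rule)] <- "low_cadd"

  keep <- is.na(rule)
  rejections <- data.frame(
    row = which(!keep),
    gene = if (is.null(variants$gene)) NA_character_ else
      as.character(variants$gene[!keep]),
    rule = rule[!keep],
    stringsAsFactors = FALSE)

  out <- variants[keep, , drop = FALSE]
  attr(out, "rejections") <- rejections
  out
}

#' Assign ACMG-style evidence tags and a classification label
#'
#' Implements a deliberately narrow two-tag rule: PS2 (confirmed de novo, both
#' parents tested and confidently reference) is granted only to de novo calls
#' whose parental genotypes are homozygous reference at genotype quality
#' `gq_min` or better; PM2 (absent or rare in population controls) is granted
#' when the population frequency is missing, zero, or below `cfg$pm2_af_max`.
#' A variant is labelled `likely_pathogenic` exactly when it carries both
#' tags; everything else is `uncertain`. Records with mode `"none"` carry no
#' tags. This is not a full ACMG engine.
#'
#' @param variants data.frame of variant records (needs `af`; for PS2 also the
#'   parental genotype and `gq_*` columns).
#' @param mode Character vector of inheritance modes, as returned by
#'   [classify_inheritance()].
#' @param cfg A [filter_config()] object.
#' @return data.frame with columns `mode`, `ps2`, `pm2`, `evidence_tags`
#'   (comma-joined) and `classification`.
#' @export
assign_evidence <- function(variants, mode, cfg = filter_config()) {
  stopifnot(length(mode) == nrow(variants))
  parents_conf_ref <-
    gt_is_homref(variants$gt_father) & gt_is_homref(variants$gt_mother) &
    !is.na(variants$gq_father) & variants$gq_father >= cfg$gq_min &
    !is.na(variants$gq_mother) & variants$gq_mother >= cfg$gq_min

  ps2 <- !is.na(mode) & mode == "de_novo" & parents_conf_ref
  af <- variants$af
  pm2 <- is.na(af) | af == 0 | af < cfg$pm2_af_max
  pm2 <- pm2 & !is.na(mode) & mode != "none"

  tags <- character(nrow(variants))
  tags[ps2 & pm2] <- "PS2,PM2"
  tags[ps2 & !pm2] <- "PS2"
  tags[!ps2 & pm2] <- "PM2"

  data.frame(mode = mode,
             ps2 = ps2,
             pm2 = pm2,
             evidence_tags = tags,
             classification = ifelse(ps2 & pm2, "likely_pathogenic",
                                     "uncertain"),
             stringsAsFactors = FALSE)
}
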