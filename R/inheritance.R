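#' Call de novo variants from trio genotypes
#'
#' A variant is de novo when both parents are confidently homozygous reference
#' and the proband carries exactly one alternate allele (heterozygous on
#' autosomes and on X in females), with the proband allele balance inside the
#' configured window, proband depth at least `dn_min_depth`, and genotype
#' quality at least `gq_min` in all three samples. Hemizygous-alternate male-X
#' candidates are not called de novo under the default rule; a notice is
#' emitted for them because the heterozygous read-balance check does not apply.
#'
#' @param variants data.frame of trio variant records (see [read_trio_vcf()]);
#'   required columns: `chrom`, `pos`, `gt_proband`, `gt_father`, `gt_mother`,
#'   `gq_proband`, `gq_father`, `gq_mother`, `dp_proband`, `alt_proband`.
#' @param cfg A [filter_config()] object.
#' @param proband_sex `"male"` or `"female"`; defaults to the
#'   `proband_sex` column when present.
#' @return Logical vector, one element per row; `NA` marks uncallable records
#'   (any missing genotype), which is distinct from `FALSE`.
#' @export
call_de_novo <- function(variants, cfg = filter_config(),
                         proband_sex = NULL) {
  proband_sex <- resolve_sex(variants, proband_sex)
  miss <- gt_missing(variants$gt_proband) |
    gt_missing(variants$gt_father) |
    gt_missing(variants$gt_mother)

  parents_ref <- gt_is_homref(variants$gt_father) &
    gt_is_homref(variants$gt_mother)
  het <- gt_is_het(variants$gt_proband)

  male_x <- is_x(variants$chrom) &
    !in_par(variants$chrom, variants$pos, cfg$par_regions) &
    proband_sex == "male"
  hemi_alt_candidate <- male_x & gt_is_hemi_alt(variants$gt_proband) &
    gt_ploidy(variants$gt_proband) == 1L & parents_ref
  if (any(hemi_alt_candidate & !miss, na.rm = TRUE)) {
    message(sum(hemi_alt_candidate & !miss, na.rm = TRUE),
            " hemizygous-X alternate candidate(s) with reference parents were",
            " not called de novo (heterozygous pattern required); review",
            " separately.")
  }

  ab <- variants$alt_proband / variants$dp_proband
  ab_ok <- !is.na(ab) &
    ab >= cfg$dn_ab_window[1] & ab <= cfg$dn_ab_window[2]
  depth_ok <- !is.na(variants$dp_proband) &
    variants$dp_proband >= cfg$dn_min_depth
  gq_ok <- gq_pass(variants, cfg$gq_min)

  out <- parents_ref & het & ab_ok & depth_ok & gq_ok
  out[miss] <- NA
  out
}

#' Call autosomal recessive variants from trio genotypes
#'
#' True when the proband is homozygous alternate and both parents are
#' heterozygous carriers, with genotype quality at least `gq_min` in all three
#' samples. Only valid on autosomes; sex-chromosome input is an error and
#' should be routed to [call_x_linked_recessive()].
#'
#' @inheritParams call_de_novo
#' @return Logical vector; `NA` for records with any missing genotype.
#' @export
call_autosomal_recessive <- function(variants, cfg = filter_config()) {
  par_like <- in_par(variants$chrom, variants$pos, cfg$par_regions)
  if (any(!is_autosome(variants$chrom) & !par_like))
    stop("call_autosomal_recessive() requires autosomal records ",
         "(or pseudoautosomal X); use call_x_linked_recessive() for X.",
         call. = FALSE)
  miss <- gt_missing(variants$gt_proband) |
    gt_missing(variants$gt_father) |
    gt_missing(variants$gt_mother)
  out <- gt_is_homalt(variants$gt_proband) &
    gt_is_het(variants$gt_father) &
    gt_is_het(variants$gt_mother) &
    gq_pass(variants, cfg$gq_min)
  out[miss] <- NA
  out
}

#' Call X-linked recessive variants from trio genotypes
#'
#' For a male proband: hemizygous alternate proband, heterozygous carrier
#' mother, hemizygous-reference father. For a female proband (supported for
#' generality): homozygous alternate proband, carrier mother, hemizygous
#' alternate father. A homozygous-alternate mother is rejected under the
#' default configuration (`xlr_allow_hom_mother = FALSE`). Records inside a
#' pseudoautosomal region or on an autosome are errors.
#'
#' @inheritParams call_de_novo
#' @return Logical vector; `NA` for records with any missing genotype.
#' @export
call_x_linked_recessive <- function(variants, cfg = filter_config(),
                                    proband_sex = NULL) {
  proband_sex <- resolve_sex(variants, proband_sex)
  if (any(!is_x(variants$chrom)))
    stop("call_x_linked_recessive() requires X-chromosome records.",
         call. = FALSE)
  if (any(in_par(variants$chrom, variants$pos, cfg$par_regions)))
    stop("pseudoautosomal position(s) supplied to X-linked logic; ",
         "PAR records follow autosomal rules.", call. = FALSE)

  miss <- gt_missing(variants$gt_proband) |
    gt_missing(variants$gt_father) |
    gt_missing(variants$gt_mother)

  mother_ok <- gt_is_het(variants$gt_mother)
  if (cfg$xlr_allow_hom_mother)
    mother_ok <- mother_ok | gt_is_homalt(variants$gt_mother)

  out <- if (identical(proband_sex, "male")) {
    gt_is_hemi_alt(variants$gt_proband) &
      mother_ok &
      gt_is_hemi_ref(variants$gt_father)
  } else {
    gt_is_homalt(variants$gt_proband) &
      mother_ok &
      gt_is_hemi_alt(variants$gt_father)
  }
  out <- out & gq_pass(variants, cfg$gq_min)
  out[miss] <- NA
  out
}

#' Classify the inheritance mode of each trio variant record
#'
#' Routes autosomal (and pseudoautosomal) records to the de novo and autosomal
#' recessive predicates and non-PAR X records to the de novo and X-linked
#' recessive predicates. The three trio patterns are mutually exclusive, so at
#' most one predicate is true per record.
#'
#' @inheritParams call_de_novo
#' @return Character vector with values `"de_novo"`, `"autosomal_recessive"`,
#'   `"x_linked_recessive"` or `"none"` (`NA` when uncallable).
#' @export
classify_inheritance <- function(variants, cfg = filter_config(),
                                 proband_sex = NULL) {
  proband_sex <- resolve_sex(variants, proband_sex)
  n <- nrow(variants)
  mode <- rep("none", n)

  dn <- call_de_novo(variants, cfg, proband_sex)
  par_like <- in_par(variants$chrom, variants$pos, cfg$par_regions)
  auto <- is_autosome(variants$chrom) | par_like
  xnp <- is_x(variants$chrom) & !par_like

  ar <- rep(FALSE, n)
  if (any(auto))
    ar[auto] <- call_autosomal_recessive(variants[auto, , drop = FALSE], cfg)
  xlr <- rep(FALSE, n)
  if (any(xnp))
    xlr[xnp] <- call_x_linked_recessive(variants[xnp, , drop = FALSE], cfg,
                                        proband_sex)

  mode[which(ar)] <- "autosomal_recessive"
  mode[which(xlr)] <- "x_linked_recessive"
  mode[which(dn)] <- "de_novo"
  mode[is.na(dn) | (auto & is.na(ar)) | (xnp & is.na(xlr))] <- NA
  mode
}

resolve_sex <- function(variants, proband_sex) {
  if (is.null(proband_sex)) {
    if (!is.null(variants$proband_sex)) {
      proband_sex <- unique(variants$proband_sex)
      if (length(proband_sex) > 1)
        stop("mixed proband_sex values in variant table", call. = FALSE)
    } else {
      proband_sex <- "male"
    }
  }
  proband_sex <- match.arg(tolower(proband_sex), c("male", "female"))
  proband_sex
}

gq_pass <- function(variants, gq_min) {
  ok <- function(x) !is.na(x) & x >= gq_min
  ok(variants$gq_proband) & ok(variants$gq_father) & ok(variants$gq_mother)
}
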