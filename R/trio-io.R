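#' Read a trio VCF into a flat variant table
#'
#' Parses a three-sample VCF (via \pkg{vcfR}) and returns one row per variant
#' and alternate allele with trio genotypes, genotype qualities, depths and
#' alt-supporting read counts. Multi-allelic records are decomposed into
#' biallelic records: for alternate allele *k*, genotype allele indices equal
#' to *k* are recoded 1 and all other alleles 0; coordinates stay 1-based.
#' Chromosome names are accepted with or without a `chr` prefix and
#' normalized.
#'
#' @param vcf_path Path to a VCF (>= 4.2) with per-sample GT, AD, DP, GQ.
#' @param pedigree Named list with `proband`, `father`, `mother` (sample ids
#'   in the VCF) and `proband_sex` (`"male"`/`"female"`).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gt_proband`, `gt_father`, `gt_mother`, `gq_*`, `dp_*`, `alt_*` and
#'   `proband_sex`.
#' @export
read_trio_vcf <- function(vcf_path, pedigree) {
  check_pedigree(pedigree)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (!is.null(fix) && is.null(dim(fix)))  # single record comes back as a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (is.null(fix) || nrow(fix) == 0 || nrow(vcf@gt) == 0)
    return(empty_trio_table(pedigree$proband_sex))

  samples <- colnames(vcf@gt)[-1]
  roles <- c(proband = pedigree$proband, father = pedigree$father,
             mother = pedigree$mother)
  missing <- setdiff(unname(roles), samples)
  if (length(missing))
    stop("sample(s) not present in VCF: ", paste(missing, collapse = ", "),
         call. = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gq <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  ad <- vcfR::extract.gt(vcf, element = "AD")

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    lapply(seq_along(alts), function(k) {
      rec <- list(chrom = normalize_chrom(fix[i, "CHROM"]),
                  pos = as.integer(fix[i, "POS"]),
                  ref = fix[i, "REF"], alt = alts[k])
      for (role in names(roles)) {
        s <- roles[[role]]
        rec[[paste0("gt_", role)]] <- recode_gt(gt[i, s], k)
        rec[[paste0("gq_", role)]] <- gq[i, s]
        rec[[paste0("dp_", role)]] <- dp[i, s]
        rec[[paste0("alt_", role)]] <- ad_alt_reads(ad[i, s], k)
      }
      as.data.frame(rec, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out$proband_sex <- pedigree$proband_sex
  validate_trio_table(out)
  out
}

check_pedigree <- function(pedigree) {
  need <- c("proband", "father", "mother", "proband_sex")
  if (!all(need %in% names(pedigree)))
    stop("pedigree must name proband, father, mother and proband_sex",
         call. = FALSE)
  if (!pedigree$proband_sex %in% c("male", "female"))
    stop("proband_sex must be 'male' or 'female'", call. = FALSE)
  invisible(pedigree)
}

empty_trio_table <- function(proband_sex) {
  out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), gt_proband = character(),
                    gq_proband = numeric(), dp_proband = numeric(),
                    alt_proband = numeric(), gt_father = character(),
                    gq_father = numeric(), dp_father = numeric(),
                    alt_father = numeric(), gt_mother = character(),
                    gq_mother = numeric(), dp_mother = numeric(),
                    alt_mother = numeric(),
                    proband_sex = character(), stringsAsFactors = FALSE)
  out
}

# recode a raw GT string against alternate allele k (1-based among ALTs)
recode_gt <- function(g, k) {
  if (is.na(g)) return(NA_character_)
  sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
  parts <- strsplit(g, "[/|]")[[1]]
  parts[parts != "." & parts == as.character(k)] <- "ALT"
  parts[parts != "." & parts != "ALT"] <- "0"
  parts[parts == "ALT"] <- "1"
  paste(parts, collapse = sep)
}

ad_alt_reads <- function(ad, k) {
  if (is.na(ad) || ad == ".") return(NA_real_)
  counts <- suppressWarnings(as.numeric(strsplit(ad, ",", fixed = TRUE)[[1]]))
  if (length(counts) < k + 1) return(NA_real_)
  counts[k + 1]
}

validate_trio_table <- function(variants) {
  if (nrow(variants) == 0) return(invisible(variants))
  if (any(variants$pos < 1))
    stop("positions must be 1-based (pos >= 1)", call. = FALSE)
  for (role in c("proband", "father", "mother")) {
    a <- variants[[paste0("alt_", role)]]
    d <- variants[[paste0("dp_", role)]]
    bad <- !is.na(a) & !is.na(d) & a > d
    if (any(bad))
      stop("alt-supporting reads exceed depth for ", role, " at ",
           paste(sprintf("%s:%d", variants$chrom[bad], variants$pos[bad]),
                 collapse = ", "), call. = FALSE)
  }
  # hemizygous calls are only legal on non-PAR X/Y for a male proband
  hemi <- gt_ploidy(variants$gt_proband) == 1L
  sex <- unique(variants$proband_sex)
  onxy <- is_x(variants$chrom) | normalize_chrom(variants$chrom) %in% c("Y", "y")
  bad <- !is.na(hemi) & hemi & (!onxy | identical(sex, "female"))
  if (any(bad))
    stop("hemizygous proband genotype outside male X/Y at ",
         paste(sprintf("%s:%d", variants$chrom[bad], variants$pos[bad]),
               collapse = ", "),
         "; check pedigree sex assignment", call. = FALSE)
  invisible(variants)
}

#' Read a per-variant annotation table
#'
#' Tab-separated, one row per (variant, transcript); required columns `chrom`,
#' `pos`, `ref`, `alt`, `gene`, `effect`, `impact`, `freq`, `cadd`; optional
#' `pli`, `phylop`, `rsid`, `hgvs_c`, `hgvs_p`. Join key is
#' chrom:pos:ref:alt.
#'
#' @param path Path to the TSV file.
#' @return data.frame with normalized chromosome names and numeric `freq`,
#'   `cadd`, `pli`, `phylop` columns.
#' @export
read_annotation_table <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("chrom", "pos", "ref", "alt", "gene", "effect", "impact",
            "freq", "cadd")
  missing <- setdiff(need, names(ann))
  if (length(missing))
    stop("annotation table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ann$chrom <- normalize_chrom(ann$chrom)
  ann$pos <- as.integer(ann$pos)
  for (col in intersect(c("freq", "cadd", "pli", "phylop"), names(ann)))
    ann[[col]] <- as.numeric(ann[[col]])
  bad <- !is.na(ann$freq) & (ann$freq < 0 | ann$freq > 1)
  if (any(bad))
    stop("allele frequency outside [0,1] at row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  ann
}

#' Filter a trio exome and partition variants by inheritance mode
#'
#' End-to-end per-trio analysis: reads the VCF and the annotation table, joins
#' them on chrom:pos:ref:alt, applies the annotation hard filters, classifies
#' the Mendelian inheritance mode of each surviving variant, and assigns
#' evidence tags. Variants with no matching annotation row are rejected with
#' rule `"unannotated"`; every other rejection is logged with its failing
#' rule, so the report carries a machine-readable provenance of each decision.
#'
#' @param vcf_path Path to the trio VCF.
#' @param annotation_path Path to the annotation TSV
#'   (see [read_annotation_table()]).
#' @param cfg A [filter_config()] object.
#' @param pedigree Named list: `proband`, `father`, `mother` sample ids and
#'   `proband_sex`.
#' @return An object of class `trio_report`: lists `de_novo`,
#'   `autosomal_recessive`, `x_linked_recessive` (data.frames of surviving
#'   variants with annotations, tags and classification), `counts`,
#'   `rejections`, `uncallable`, and the configuration used.
#' @export
filter_trio <- function(vcf_path, annotation_path, cfg = filter_config(),
                        pedigree) {
  variants <- read_trio_vcf(vcf_path, pedigree)
  ann <- read_annotation_table(annotation_path)

  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  idx <- match(key(variants), key(ann))
  unannotated <- is.na(idx)
  ann_cols <- setdiff(names(ann), c("chrom", "pos", "ref", "alt"))
  merged <- cbind(variants,
                  ann[idx, ann_cols, drop = FALSE])
  rownames(merged) <- NULL
  names(merged)[names(merged) == "freq"] <- "af"
  names(merged)[names(merged) == "effect"] <- "consequence"

  unann_log <- data.frame(
    row = which(unannotated),
    gene = rep(NA_character_, sum(unannotated)),
    rule = rep("unannotated", sum(unannotated)),
    stringsAsFactors = FALSE)
  merged <- merged[!unannotated, , drop = FALSE]

  kept <- apply_annotation_filters(merged, cfg)
  rejections <- rbind(unann_log, attr(kept, "rejections"))

  mode <- if (nrow(kept)) {
    classify_inheritance(kept, cfg, pedigree$proband_sex)
  } else character(0)
  uncallable <- kept[is.na(mode), , drop = FALSE]
  callable <- kept[!is.na(mode), , drop = FALSE]
  mode <- mode[!is.na(mode)]
  ev <- assign_evidence(callable, mode, cfg)
  callable <- cbind(callable, ev[, c("evidence_tags", "classification")])
  callable$mode <- mode

  part <- function(m) {
    out <- callable[callable$mode == m, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  report <- list(
    de_novo = part("de_novo"),
    autosomal_recessive = part("autosomal_recessive"),
    x_linked_recessive = part("x_linked_recessive"),
    counts = c(de_novo = sum(mode == "de_novo"),
               autosomal_recessive = sum(mode == "autosomal_recessive"),
               x_linked_recessive = sum(mode == "x_linked_recessive"),
               none = sum(mode == "none")),
    rejections = rejections,
    uncallable = uncallable,
    config = cfg,
    pedigree = pedigree)
  class(report) <- "trio_report"
  report
}

#' @export
print.trio_report <- function(x, ...) {
  cat("Trio variant report\n")
  cat(sprintf("  de novo: %d | autosomal recessive: %d | X-linked recessive: %d\n",
              x$counts["de_novo"], x$counts["autosomal_recessive"],
              x$counts["x_linked_recessive"]))
  cat(sprintf("  passed filters without Mendelian pattern: %d\n",
              x$counts["none"]))
  cat(sprintf("  rejected by annotation filters: %d | uncallable: %d\n",
              nrow(x$rejections), nrow(x$uncallable)))
  lp <- sum(vapply(c("de_novo", "autosomal_recessive", "x_linked_recessive"),
                   function(m) sum(x[[m]]$classification == "likely_pathogenic"),
                   numeric(1)))
  cat(sprintf("  likely pathogenic: %d\n", lp))
  invisible(x)
}

#' Write a trio report to disk
#'
#' Emits a tab-separated variant table (all three mode partitions stacked), a
#' rejection log, and a JSON summary of counts.
#'
#' @param report A `trio_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_trio_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- rbind(report$de_novo, report$autosomal_recessive,
               report$x_linked_recessive)
  paths <- c(variants = file.path(dir, "variants.tsv"),
             rejections = file.path(dir, "rejections.tsv"),
             summary = file.path(dir, "summary.json"))
  utils::write.table(tab, paths["variants"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$rejections, paths["rejections"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(counts = as.list(report$counts)),
                       paths["summary"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
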