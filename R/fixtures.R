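#' Bundled variant table for the three-trio case study
#'
#' The 28 published exome variants (one row per variant) with patient,
#' inheritance label, coordinates and printed annotations (pLI, effect,
#' impact severity, population frequency, CADD, rsid, HGVS strings).
#'
#' @return data.frame with 28 rows.
#' @export
table2_variants <- function() {
  path <- system.file("extdata", "table2_variants.tsv",
                      package = "trioconnect", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Bundled developmental expression summaries for the 28 case-study genes
#'
#' Published per-gene RPKM means: early (< 12 postnatal months, prenatal
#' included) and late (1-40 years) windows, cerebellum versus the average of
#' all other brain structures. Means only; enrichment flags are derived with
#' [flag_enrichment()].
#'
#' @return data.frame with 28 rows and the four mean columns.
#' @export
table3_summaries <- function() {
  path <- system.file("extdata", "table3_expression.tsv",
                      package = "trioconnect", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Synthetic evidence-network fixtures for the case-study genes
#'
#' A constructed stand-in for the study's interaction network (the original
#' STRING/ChEA3/HiPPIP retrievals are external resources): a typed edge list
#' over the five high-confidence genes plus the CDK6 connector and decoy
#' neighbors, a TF-to-target map whose unique minimal connecting subset has
#' cardinality 4, and a rescue table of predicted interactions (plus the two
#' known support edges) for the three orphan genes. These fixtures reproduce
#' the *structure* of the published network (unique single connector, four
#' transcription factors, three rescued orphans), not its literal edge set.
#'
#' @return data.frame of edges, TF targets, or rescue edges.
#' @export
fig5_synthetic_edges <- function() {
  path <- system.file("extdata", "fig5_synthetic_edges.tsv",
                      package = "trioconnect", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname fig5_synthetic_edges
#' @export
fig5_synthetic_tf_targets <- function() {
  path <- system.file("extdata", "fig5_synthetic_tf_targets.tsv",
                      package = "trioconnect", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname fig5_synthetic_edges
#' @export
fig5_synthetic_rescue_edges <- function() {
  path <- system.file("extdata", "fig5_synthetic_rescue_edges.tsv",
                      package = "trioconnect", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' The five high-confidence genes of the case study
#' @return Character vector.
#' @export
high_confidence_genes <- function() {
  c("FOXN4", "LAMA5", "LAMB1", "LRRK2", "USP17L2")
}

#' Write trio VCF + annotation fixtures for a case-study patient
#'
#' Encodes the published variant rows for one patient as a three-sample VCF
#' whose genotypes realize each row's inheritance label (de novo:
#' heterozygous proband with balanced reads, reference parents; autosomal
#' recessive: homozygous proband, carrier parents; X-linked recessive:
#' hemizygous proband, carrier mother, reference father), together with the
#' printed annotations, plus one decoy variant per rejection rule
#' (inherited, low genotype quality, common allele, low CADD, LOW impact,
#' allele-balance outlier).
#'
#' @param dir Output directory.
#' @param patient Patient number (1, 2 or 3).
#' @param decoys Include the per-rule decoy block (default `TRUE`).
#' @return List with `vcf`, `annotations` (paths) and `pedigree`.
#' @export
table2_trio_fixture <- function(dir, patient = 1, decoys = TRUE) {
  stopifnot(patient %in% 1:3)
  tab <- table2_variants()
  tab <- tab[tab$patient == patient, , drop = FALSE]

  v <- data.frame(chrom = tab$chrom, pos = tab$pos, ref = tab$ref,
                  alt = tab$alt, stringsAsFactors = FALSE)
  n <- nrow(v)
  gt <- genotypes_for_modes(tab$inheritance)
  v <- cbind(v, gt)

  ann <- tab[, c("chrom", "pos", "ref", "alt", "gene", "pli", "effect",
                 "impact", "freq", "cadd", "rsid", "hgvs_c", "hgvs_p")]

  if (decoys) {
    dk <- decoy_block(start_pos = 500000L)
    v <- rbind(v, dk$variants)
    ann <- rbind(ann, dk$annotations)
  }

  ord <- order(chrom_rank(v$chrom), v$pos)
  v <- v[ord, , drop = FALSE]

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(dir, sprintf("patient%d.vcf", patient))
  ann_path <- file.path(dir, sprintf("patient%d_annotations.tsv", patient))
  write_trio_vcf(v, vcf_path,
                 samples = c("PROBAND", "FATHER", "MOTHER"),
                 contigs = unique(v$chrom))
  names(ann)[names(ann) == "freq"] <- "freq"
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  list(vcf = vcf_path, annotations = ann_path,
       pedigree = list(proband = "PROBAND", father = "FATHER",
                       mother = "MOTHER", proband_sex = "male"))
}

# canonical clean genotype blocks per inheritance label (male proband)
genotypes_for_modes <- function(modes) {
  n <- length(modes)
  out <- data.frame(
    gt_proband = character(n), ad_proband = character(n),
    dp_proband = integer(n), gq_proband = integer(n),
    gt_father = character(n), ad_father = character(n),
    dp_father = integer(n), gq_father = integer(n),
    gt_mother = character(n), ad_mother = character(n),
    dp_mother = integer(n), gq_mother = integer(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    out[i, ] <- switch(
      modes[i],
      de_novo = list("0/1", "20,20", 40L, 60L,
                     "0/0", "40,0", 40L, 60L,
                     "0/0", "40,0", 40L, 60L),
      autosomal_recessive = list("1/1", "0,40", 40L, 60L,
                                 "0/1", "20,20", 40L, 60L,
                                 "0/1", "20,20", 40L, 60L),
      x_linked_recessive = list("1", "0,40", 40L, 60L,
                                "0", "40,0", 40L, 60L,
                                "0/1", "20,20", 40L, 60L),
      inherited = list("0/1", "20,20", 40L, 60L,
                       "0/1", "20,20", 40L, 60L,
                       "0/0", "40,0", 40L, 60L),
      stop("unknown inheritance label: ", modes[i]))
  }
  out
}

# one decoy per rejection rule, on autosome 1 (AB outlier and low-GQ are
# de-novo-like; 'inherited' passes annotation filters but matches no trio
# pattern)
decoy_block <- function(start_pos = 500000L) {
  rules <- c("inherited", "low_gq", "common_af", "low_cadd",
             "low_impact", "ab_outlier")
  n <- length(rules)
  v <- data.frame(chrom = rep("1", n),
                  pos = start_pos + seq_len(n) * 1000L,
                  ref = rep("A", n), alt = rep("G", n),
                  stringsAsFactors = FALSE)
  modes <- c("inherited", "de_novo", "de_novo", "de_novo", "de_novo",
             "de_novo")
  gt <- genotypes_for_modes(modes)
  gt$gq_proband[rules == "low_gq"] <- 5L
  gt$ad_proband[rules == "ab_outlier"] <- "36,4"
  v <- cbind(v, gt)

  ann <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                    gene = paste0("DECOY_", toupper(rules)),
                    pli = 0, effect = "missense", impact = "MODERATE",
                    freq = 1e-4, cadd = 25, rsid = NA_character_,
                    hgvs_c = NA_character_, hgvs_p = NA_character_,
                    stringsAsFactors = FALSE)
  ann$freq[rules == "common_af"] <- 0.50
  ann$cadd[rules == "low_cadd"] <- 5.0
  ann$impact[rules == "low_impact"] <- "LOW"
  ann$effect[rules == "low_impact"] <- "synonymous"
  list(variants = v, annotations = ann)
}

chrom_rank <- function(chrom) {
  chrom <- normalize_chrom(chrom)
  r <- suppressWarnings(as.numeric(chrom))
  r[chrom == "X"] <- 23
  r[chrom == "Y"] <- 24
  r[is.na(r)] <- 25
  r
}

# minimal VCFv4.2 writer for simulated trio records; fields GT:AD:DP:GQ
write_trio_vcf <- function(v, path, samples, contigs) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  fmt <- function(role) {
    paste(v[[paste0("gt_", role)]], v[[paste0("ad_", role)]],
          v[[paste0("dp_", role)]], v[[paste0("gq_", role)]], sep = ":")
  }
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                "GT:AD:DP:GQ", fmt("proband"), fmt("father"), fmt("mother"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
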