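#' Parse a developmental age string to postnatal months
#'
#' Accepts the dialects used by developmental brain atlases: postconception
#' weeks (`"8 pcw"`), postnatal months (`"10 mos"`, `"4 m"`) and postnatal
#' years (`"40 yrs"`, `"2 y"`). All ages are mapped to a single totally
#' ordered axis in postnatal months, with birth at 40 postconception weeks:
#' `pcw` maps to `(weeks - 40) / 4.345` months (so prenatal ages are
#' negative), months map directly and years multiply by 12.
#'
#' @param age Character vector of age strings.
#' @return Numeric vector of ages in postnatal months.
#' @export
#' @examples
#' parse_age(c("8 pcw", "10 mos", "40 yrs"))
parse_age <- function(age) {
  age <- trimws(tolower(as.character(age)))
  m <- regmatches(age, regexec("^(-?[0-9.]+)\\s*([a-z]+)$", age))
  vapply(seq_along(age), function(i) {
    parts <- m[[i]]
    if (length(parts) != 3)
      stop("unparseable age string: '", age[i], "'", call. = FALSE)
    value <- as.numeric(parts[2])
    unit <- parts[3]
    if (unit %in% c("pcw", "wpc"))
      (value - 40) / 4.345
    else if (unit %in% c("mos", "mo", "m", "months", "month"))
      value
    else if (unit %in% c("yrs", "yr", "y", "years", "year"))
      value * 12
    else stop("unknown age unit: '", unit, "'", call. = FALSE)
  }, numeric(1))
}

#' Read an RPKM expression matrix with sample metadata
#'
#' The matrix is comma- or tab-separated with genes as rows and a header of
#' sample ids; the metadata table has columns `sample_id`, `structure_code`
#' and `age` (an age string accepted by [parse_age()]). Every matrix column
#' must have a metadata row.
#'
#' @param matrix_path Path to the expression matrix file.
#' @param metadata_path Path to the sample metadata file.
#' @param cerebellum_codes Structure codes counted as cerebellar cortex.
#' @return List with `rpkm` (numeric matrix, genes x samples) and `samples`
#'   (metadata data.frame with an added numeric `age_months` column and
#'   logical `cerebellum`).
#' @export
read_expression_matrix <- function(matrix_path, metadata_path,
                                   cerebellum_codes = c("CBC", "CB")) {
  sep <- if (grepl("\\.csv$", matrix_path)) "," else "\t"
  raw <- utils::read.table(matrix_path, sep = sep, header = TRUE,
                           row.names = 1, check.names = FALSE,
                           stringsAsFactors = FALSE)
  rpkm <- as.matrix(raw)
  storage.mode(rpkm) <- "numeric"
  if (any(rpkm < 0, na.rm = TRUE))
    stop("RPKM values must be non-negative", call. = FALSE)

  sep2 <- if (grepl("\\.csv$", metadata_path)) "," else "\t"
  samples <- utils::read.table(metadata_path, sep = sep2, header = TRUE,
                               stringsAsFactors = FALSE)
  need <- c("sample_id", "structure_code", "age")
  if (!all(need %in% names(samples)))
    stop("metadata needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(colnames(rpkm), samples$sample_id)
  if (length(missing))
    stop("matrix column(s) without metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  samples <- samples[match(colnames(rpkm), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  samples$age_months <- parse_age(samples$age)
  samples$cerebellum <- samples$structure_code %in% cerebellum_codes
  list(rpkm = rpkm, samples = samples)
}

#' Summarize one gene's expression by window and compartment
#'
#' Computes four unweighted arithmetic means of RPKM: early and late windows
#' crossed with cerebellum versus all other (non-cerebellar) brain structures.
#' The early window contains all samples with age strictly below `split_age`
#' (prenatal ages are always early); the late window is the remainder. A
#' (window, compartment) cell with no samples yields `NA` for that mean.
#'
#' @param expr A list as returned by [read_expression_matrix()].
#' @param gene Gene symbol (must be a row of the matrix).
#' @param split_age Early/late boundary in postnatal months (default 12).
#' @return One-row data.frame with columns `gene`, `early_other_mean`,
#'   `late_other_mean`, `early_cerebellum_mean`, `late_cerebellum_mean`.
#' @export
summarize_gene <- function(expr, gene, split_age = 12) {
  if (!gene %in% rownames(expr$rpkm))
    stop("gene not present in expression matrix: ", gene, call. = FALSE)
  x <- expr$rpkm[gene, ]
  early <- expr$samples$age_months < split_age
  cb <- expr$samples$cerebellum
  cell_mean <- function(sel) if (any(sel)) mean(x[sel]) else NA_real_
  data.frame(gene = gene,
             early_other_mean = cell_mean(early & !cb),
             late_other_mean = cell_mean(!early & !cb),
             early_cerebellum_mean = cell_mean(early & cb),
             late_cerebellum_mean = cell_mean(!early & cb),
             stringsAsFactors = FALSE)
}

#' Summarize a panel of genes
#'
#' Applies [summarize_gene()] to each gene and stacks the rows.
#'
#' @inheritParams summarize_gene
#' @param genes Character vector of gene symbols.
#' @return data.frame of per-gene summaries.
#' @export
summarize_expression <- function(expr, genes = rownames(expr$rpkm),
                                 split_age = 12) {
  out <- do.call(rbind, lapply(genes, summarize_gene, expr = expr,
                               split_age = split_age))
  rownames(out) <- NULL
  out
}

#' Flag cerebellar enrichment under an expression floor
#'
#' A gene is considered expressed in the earliest development when its early
#' other-structures mean is strictly above `floor` (default 1 RPKM). Genes at
#' or below the floor receive flag `"below_floor"` in both windows (the floor
#' gate is the earliest-development mean in both cases); expressed genes are
#' flagged `"plus"` when the cerebellar mean exceeds the other-structures
#' mean for that window, `"minus"` when lower, `"tie"` when equal. A window
#' whose means are unavailable gets flag `"no_data"`.
#'
#' @param summaries data.frame from [summarize_expression()] (or any table
#'   with the four mean columns).
#' @param floor RPKM floor; the comparison is strict (`> floor`).
#' @return The input with added `early_flag` and `late_flag` columns.
#' @export
#' @examples
#' s <- data.frame(gene = "LAMA5", early_other_mean = 2.30,
#'                 late_other_mean = 2.15, early_cerebellum_mean = 5.74,
#'                 late_cerebellum_mean = 7.17)
#' flag_enrichment(s)$early_flag
flag_enrichment <- function(summaries, floor = 1.0) {
  one_flag <- function(cb, other, gate) {
    ifelse(is.na(cb) | is.na(other) | is.na(gate), "no_data",
           ifelse(gate <= floor, "below_floor",
                  ifelse(cb > other, "plus",
                         ifelse(cb < other, "minus", "tie"))))
  }
  summaries$early_flag <- one_flag(summaries$early_cerebellum_mean,
                                   summaries$early_other_mean,
                                   summaries$early_other_mean)
  summaries$late_flag <- one_flag(summaries$late_cerebellum_mean,
                                  summaries$late_other_mean,
                                  summaries$early_other_mean)
  summaries
}

#' Count enrichment flags over a gene panel
#'
#' @param summaries A flagged summary table from [flag_enrichment()].
#' @return Named numeric vector: `n_above_floor` (genes whose early
#'   other-structures mean exceeds the floor, i.e. not `below_floor`/
#'   `no_data` in the early window), `n_plus_early`, `n_minus_early`,
#'   `n_plus_late`, `n_minus_late`.
#' @export
summarize_panel <- function(summaries) {
  if (nrow(summaries) == 0 || is.null(summaries$early_flag))
    return(c(n_above_floor = 0, n_plus_early = 0, n_minus_early = 0,
             n_plus_late = 0, n_minus_late = 0))
  c(n_above_floor = sum(summaries$early_flag %in% c("plus", "minus", "tie")),
    n_plus_early = sum(summaries$early_flag == "plus"),
    n_minus_early = sum(summaries$early_flag == "minus"),
    n_plus_late = sum(summaries$late_flag == "plus"),
    n_minus_late = sum(summaries$late_flag == "minus"))
}
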