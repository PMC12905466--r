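# Genotype string handling. Genotypes are VCF-style allele-index strings:
# diploid "0/1" (or phased "0|1"), hemizygous "1", missing "./." or ".".

parse_gt <- function(gt) {
  gt <- as.character(gt)
  out <- lapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.", ""))
      return(list(alleles = NA_integer_, missing = TRUE))
    parts <- strsplit(g, "[/|]")[[1]]
    if (any(parts == "."))
      return(list(alleles = NA_integer_, missing = TRUE))
    if (!all(grepl("^[0-9]+$", parts)))
      stop("malformed genotype string: ", g, call. = FALSE)
    list(alleles = as.integer(parts), missing = FALSE)
  })
  out
}

gt_missing <- function(gt) vapply(parse_gt(gt), `[[`, TRUE, "missing")

# number of alternate (non-zero) allele copies; NA when missing
gt_n_alt <- function(gt) {
  vapply(parse_gt(gt), function(p) {
    if (p$missing) return(NA_integer_)
    sum(p$alleles > 0L)
  }, integer(1))
}

gt_ploidy <- function(gt) {
  vapply(parse_gt(gt), function(p) {
    if (p$missing) return(NA_integer_)
    length(p$alleles)
  }, integer(1))
}

gt_is_homref <- function(gt) {
  p <- parse_gt(gt)
  vapply(p, function(x) !x$missing && all(x$alleles == 0L), logical(1))
}

gt_is_het <- function(gt) {
  p <- parse_gt(gt)
  vapply(p, function(x) {
    !x$missing && length(x$alleles) == 2L && sum(x$alleles > 0L) == 1L
  }, logical(1))
}

gt_is_homalt <- function(gt) {
  p <- parse_gt(gt)
  vapply(p, function(x) {
    !x$missing && length(x$alleles) == 2L && all(x$alleles > 0L)
  }, logical(1))
}

# hemizygous or fully-alternate call: on male X a caller may emit "1" or "1/1"
gt_is_hemi_alt <- function(gt) {
  p <- parse_gt(gt)
  vapply(p, function(x) !x$missing && all(x$alleles > 0L), logical(1))
}

gt_is_hemi_ref <- function(gt) {
  p <- parse_gt(gt)
  vapply(p, function(x) !x$missing && all(x$alleles == 0L), logical(1))
}
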