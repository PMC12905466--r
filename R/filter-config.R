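#' Filtering configuration for trio variant analysis
#'
#' Bundles every threshold used by the inheritance-mode and annotation filters.
#' Defaults follow common trio-exome practice: variants are kept when CADD is
#' strictly greater than `cadd_min`, population allele frequency strictly less
#' than `af_max`, impact severity not in `excluded_impacts`, and all three
#' genotype qualities at least `gq_min`. De novo candidates must additionally
#' show an allele balance inside `dn_ab_window` at depth `dn_min_depth`,
#' replacing manual read-level review with a numeric check.
#'
#' @param cadd_min Keep variants with CADD strictly greater than this
#'   (missing CADD is retained with a warning).
#' @param af_max Keep variants with population allele frequency strictly less
#'   than this; a missing frequency is treated as 0 (novel allele).
#' @param excluded_impacts Character vector of impact severity labels to drop.
#' @param gq_min Minimum phred-like genotype quality required in all samples.
#' @param dn_ab_window Length-2 numeric, closed allele-balance interval for a
#'   heterozygous de novo call in the proband.
#' @param dn_min_depth Minimum proband read depth for a de novo call.
#' @param pm2_af_max Frequency ceiling below which the rare-in-controls (PM2)
#'   evidence tag is granted; missing or zero frequency always qualifies.
#' @param par_regions data.frame with columns `chrom`, `start`, `end` giving
#'   half-open pseudoautosomal intervals excluded from X-linked logic.
#'   Defaults to the GRCh38 X PARs.
#' @param xlr_allow_hom_mother Accept a homozygous-alternate mother in the
#'   X-linked recessive pattern (default rejects; the expected pattern is a
#'   heterozygous carrier mother).
#'
#' @return An object of class `trio_filter_config`.
#' @export
#' @examples
#' cfg <- filter_config()
#' cfg$cadd_min
filter_config <- function(cadd_min = 10,
                          af_max = 0.05,
                          excluded_impacts = "LOW",
                          gq_min = 20,
                          dn_ab_window = c(0.30, 0.70),
                          dn_min_depth = 10,
                          pm2_af_max = 5e-3,
                          par_regions = grch38_x_pars(),
                          xlr_allow_hom_mother = FALSE) {
  stopifnot(af_max >= 0, af_max <= 1,
            length(dn_ab_window) == 2,
            dn_ab_window[1] >= 0, dn_ab_window[2] <= 1,
            dn_ab_window[1] <= dn_ab_window[2],
            gq_min >= 0, dn_min_depth >= 0,
            pm2_af_max >= 0, pm2_af_max <= 1)
  if (!is.null(par_regions)) {
    stopifnot(is.data.frame(par_regions),
              all(c("chrom", "start", "end") %in% names(par_regions)))
    par_regions$chrom <- normalize_chrom(par_regions$chrom)
  }
  structure(list(cadd_min = cadd_min,
                 af_max = af_max,
                 excluded_impacts = toupper(excluded_impacts),
                 gq_min = gq_min,
                 dn_ab_window = dn_ab_window,
                 dn_min_depth = dn_min_depth,
                 pm2_af_max = pm2_af_max,
                 par_regions = par_regions,
                 xlr_allow_hom_mother = isTRUE(xlr_allow_hom_mother)),
            class = "trio_filter_config")
}

#' @export
print.trio_filter_config <- function(x, ...) {
  cat("Trio filter configuration\n")
  cat(sprintf("  CADD > %g, AF < %g, exclude impacts {%s}, GQ >= %d\n",
              x$cadd_min, x$af_max, paste(x$excluded_impacts, collapse = ", "),
              as.integer(x$gq_min)))
  cat(sprintf("  de novo: AB in [%.2f, %.2f], depth >= %d\n",
              x$dn_ab_window[1], x$dn_ab_window[2], as.integer(x$dn_min_depth)))
  cat(sprintf("  PM2 ceiling: AF < %g\n", x$pm2_af_max))
  if (!is.null(x$par_regions) && nrow(x$par_regions))
    cat(sprintf("  PARs: %s\n",
                paste(sprintf("%s:%d-%d", x$par_regions$chrom,
                              x$par_regions$start, x$par_regions$end),
                      collapse = "; ")))
  invisible(x)
}

#' GRCh38 X-chromosome pseudoautosomal regions
#'
#' Half-open intervals on X treated autosomally by the inheritance logic.
#'
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
grch38_x_pars <- function() {
  data.frame(chrom = c("X", "X"),
             start = c(10001L, 155701383L),
             end   = c(2781480L, 156030896L),
             stringsAsFactors = FALSE)
}

# strip "chr" prefix; case-insensitive, keeps MT etc. as-is
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

is_autosome <- function(chrom) {
  grepl("^[0-9]+$", normalize_chrom(chrom))
}

is_x <- function(chrom) {
  normalize_chrom(chrom) %in% c("X", "x")
}

in_par <- function(chrom, pos, par_regions) {
  if (is.null(par_regions) || nrow(par_regions) == 0)
    return(rep(FALSE, length(chrom)))
  chrom <- normalize_chrom(chrom)
  hit <- rep(FALSE, length(chrom))
  for (i in seq_len(nrow(par_regions))) {
    hit <- hit | (chrom == par_regions$chrom[i] &
                    pos >= par_regions$start[i] &
                    pos < par_regions$end[i])
  }
  hit
}
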