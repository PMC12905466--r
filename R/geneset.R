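#' Exact hypergeometric overlap test for a gene list against a panel
#'
#' Tests whether `n_overlap` of `n_list` genes falling in a panel of
#' `n_panel` genes, out of a universe of `n_universe`, is more than expected
#' by chance. The computation is fully exact: hypergeometric point masses are
#' evaluated in log space (no normal approximation, stable at genome scale).
#' The two-sided p-value sums the probabilities of all achievable tables
#' whose probability does not exceed the observed table's (with a small
#' relative tolerance for ties); `greater` sums the upper tail. The odds
#' ratio is the sample odds ratio of the 2x2 table, reported as `Inf` when a
#' zero off-diagonal cell makes it undefined.
#'
#' @param n_overlap,n_list,n_panel,n_universe Non-negative integer counts;
#'   `n_overlap <= min(n_list, n_panel)` and both margins at most
#'   `n_universe`.
#' @param alternative `"two_sided"` or `"greater"`.
#' @return List with `odds_ratio`, `p_value`, `alternative`, and the input
#'   counts.
#' @export
#' @examples
#' fisher_overlap(3, 4, 4, 8)$p_value  # 34/70
fisher_overlap <- function(n_overlap, n_list, n_panel, n_universe,
                           alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  counts <- c(n_overlap, n_list, n_panel, n_universe)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (n_overlap > min(n_list, n_panel))
    stop("n_overlap exceeds min(n_list, n_panel)", call. = FALSE)
  if (n_list > n_universe || n_panel > n_universe)
    stop("margins exceed the universe size", call. = FALSE)
  if (n_list + n_panel - n_overlap > n_universe)
    stop("table cells are inconsistent with the universe size",
         call. = FALSE)

  # support of the overlap count given fixed margins
  k_min <- max(0, n_list + n_panel - n_universe)
  k_max <- min(n_list, n_panel)
  support <- k_min:k_max
  logp <- stats::dhyper(support, m = n_panel, n = n_universe - n_panel,
                        k = n_list, log = TRUE)

  obs <- logp[support == n_overlap]
  p_value <- if (alternative == "greater") {
    sum(exp(logp[support >= n_overlap]))
  } else {
    # relative tolerance on ties, as in the exact conditional test
    sum(exp(logp[logp <= obs + 1e-7]))
  }
  p_value <- min(1, p_value)

  a <- n_overlap
  b <- n_list - n_overlap
  c_ <- n_panel - n_overlap
  d <- n_universe - n_list - n_panel + n_overlap
  odds_ratio <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)

  list(odds_ratio = odds_ratio, p_value = p_value,
       alternative = alternative,
       n_overlap = n_overlap, n_list = n_list, n_panel = n_panel,
       n_universe = n_universe)
}

#' Overlap report for a gene list against named panels
#'
#' Computes the set intersection of `gene_list` with each panel (symbols are
#' matched case-insensitively after trimming whitespace; duplicates are
#' removed with a warning) and runs [fisher_overlap()] per panel.
#'
#' @param gene_list Character vector of gene symbols.
#' @param panels Named list of character vectors (curated panels).
#' @param n_universe Background universe size. There is no silent default in
#'   pipeline configuration; the documented library default is 20000
#'   protein-coding genes.
#' @param alternative Passed to [fisher_overlap()].
#' @return data.frame with one row per panel: `panel`, `n_overlap`,
#'   `n_list`, `n_panel`, `n_universe`, `odds_ratio`, `p_value` and the
#'   comma-joined `overlap_genes`.
#' @export
overlap_report <- function(gene_list, panels, n_universe = 20000,
                           alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  norm <- function(x, what) {
    x <- toupper(trimws(as.character(x)))
    if (anyDuplicated(x)) {
      warning("duplicate symbols removed from ", what, call. = FALSE)
      x <- unique(x)
    }
    x
  }
  gene_list <- norm(gene_list, "gene list")
  rows <- lapply(names(panels), function(nm) {
    panel <- norm(panels[[nm]], paste0("panel '", nm, "'"))
    hit <- intersect(gene_list, panel)
    ft <- fisher_overlap(length(hit), length(gene_list), length(panel),
                         n_universe, alternative)
    data.frame(panel = nm, n_overlap = length(hit),
               n_list = length(gene_list), n_panel = length(panel),
               n_universe = n_universe, odds_ratio = ft$odds_ratio,
               p_value = ft$p_value,
               overlap_genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read gene panels from disk
#'
#' Accepts either one-symbol-per-line text files (one file per panel, named
#' by file) or a single two-column `(panel, symbol)` table.
#'
#' @param paths Character vector of file paths.
#' @return Named list of character vectors.
#' @export
read_panels <- function(paths) {
  out <- list()
  for (p in paths) {
    first <- readLines(p, n = 1)
    if (grepl("\t", first)) {
      tab <- utils::read.delim(p, header = FALSE, stringsAsFactors = FALSE)
      if (tolower(tab[1, 1]) %in% c("panel", "set")) tab <- tab[-1, ]
      sp <- split(tab[[2]], tab[[1]])
      out[names(sp)] <- sp
    } else {
      nm <- tools::file_path_sans_ext(basename(p))
      out[[nm]] <- readLines(p)
    }
  }
  lapply(out, function(x) x[nzchar(trimws(x))])
}
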