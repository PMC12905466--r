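#' Permutation test for induced-edge enrichment of a gene set
#'
#' Counts the background edges with both endpoints inside `gene_set` and
#' compares that count with null draws of equally sized node sets from the
#' background universe. Under `node_resample` the null sets are uniform node
#' samples; under `degree_binned` they are matched to the observed set's
#' degree-decile composition, which guards against dense hubs inflating a
#' naive null. The p-value uses the add-one permutation estimator
#' `(n_ge + 1) / (n_perm + 1)`, so it can never be exactly zero.
#'
#' @param background_edges data.frame (or 2-column matrix) of undirected
#'   background edges; parallel records collapse to one edge per pair.
#' @param gene_set Character vector of genes (must be a subset of the node
#'   universe; must not exceed it in size).
#' @param n_perm Number of null draws (default 999).
#' @param null_model `"node_resample"` or `"degree_binned"`.
#' @param rng_seed Integer seed; results are reproducible given the seed.
#' @param universe Optional explicit node universe; defaults to all endpoint
#'   nodes of the background edges.
#' @return Object of class `enrichment_result`: `observed_edges`,
#'   `null_draws`, `n_ge`, `p_value`, `null_model`, `seed`.
#' @export
edge_enrichment <- function(background_edges, gene_set, n_perm = 999,
                            null_model = c("node_resample", "degree_binned"),
                            rng_seed = 1L, universe = NULL) {
  null_model <- match.arg(null_model)
  stopifnot(n_perm >= 1)
  ed <- as.data.frame(background_edges, stringsAsFactors = FALSE)
  a <- as.character(ed[[1]]); b <- as.character(ed[[2]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  pair <- paste(pmin(a, b), pmax(a, b))
  dup <- duplicated(pair)
  a <- a[!dup]; b <- b[!dup]

  if (is.null(universe)) universe <- sort(unique(c(a, b)))
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) > length(universe))
    stop("gene_set larger than the node universe", call. = FALSE)
  outside <- setdiff(gene_set, universe)
  if (length(outside))
    stop("gene_set member(s) outside the universe: ",
         paste(outside, collapse = ", "), call. = FALSE)

  ia <- match(a, universe); ib <- match(b, universe)
  n_nodes <- length(universe)
  member <- logical(n_nodes)
  member[match(gene_set, universe)] <- TRUE
  observed <- sum(member[ia] & member[ib])

  deg <- tabulate(c(ia, ib), nbins = n_nodes)
  set.seed(as.integer(rng_seed))
  k <- length(gene_set)

  if (null_model == "node_resample") {
    draw <- function() sample.int(n_nodes, k)
  } else {
    breaks <- unique(stats::quantile(deg, probs = seq(0, 1, 0.1)))
    bins <- cut(deg, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    set_bins <- bins[match(gene_set, universe)]
    need <- table(set_bins)
    by_bin <- split(seq_len(n_nodes), bins)
    draw <- function() {
      unlist(lapply(names(need), function(bn) {
        pool <- by_bin[[bn]]
        pool[sample.int(length(pool), need[[bn]])]
      }), use.names = FALSE)
    }
  }

  n_ge <- 0L
  memb <- logical(n_nodes)
  for (i in seq_len(n_perm)) {
    memb[] <- FALSE
    memb[draw()] <- TRUE
    if (sum(memb[ia] & memb[ib]) >= observed) n_ge <- n_ge + 1L
  }

  structure(list(observed_edges = observed,
                 null_draws = n_perm,
                 n_ge = n_ge,
                 p_value = (n_ge + 1) / (n_perm + 1),
                 null_model = null_model,
                 seed = as.integer(rng_seed)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Edge enrichment: %d observed edges; p = %.4g (%d of %d null draws >= observed; %s null, seed %d)\n",
    x$observed_edges, x$p_value, x$n_ge, x$null_draws, x$null_model, x$seed))
  invisible(x)
}
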