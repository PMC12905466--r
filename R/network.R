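#' Evidence channels recognized in gene-gene networks
#' @export
evidence_channels <- function() {
  c("experimental_ppi", "predicted_ppi", "curated", "cooccurrence",
    "fusion", "neighborhood", "textmining", "coexpression", "homology",
    "tf_target")
}

#' Build a typed gene-gene evidence network
#'
#' Constructs an evidence network from a typed edge list. Parallel edges
#' between the same gene pair (multiple evidence channels) count once for
#' connectivity but every provenance record is preserved. Only `tf_target`
#' edges are directed (regulator to target); connectivity is always evaluated
#' on the undirected view.
#'
#' @param edges data.frame with columns `a`, `b`, `channel` and optionally
#'   `directed` (logical; default `TRUE` only for `tf_target`).
#' @param seed_genes Genes guaranteed to appear as nodes (isolated if no edge
#'   touches them) and recorded with role `"seed"`.
#' @param nodes Additional genes to include as (possibly isolated) candidate
#'   nodes, e.g. the full gene panel when some members have no edges yet.
#' @return Object of class `evidence_network` with elements `nodes`, `edges`
#'   (provenance), `roles` (named character) and `graph` (collapsed
#'   undirected \pkg{igraph} graph).
#' @export
#' @examples
#' net <- build_network(data.frame(a = "LAMA5", b = "LAMB1",
#'                                 channel = "experimental_ppi"),
#'                      seed_genes = c("LAMA5", "LAMB1"))
#' network_summary(net)
build_network <- function(edges = NULL, seed_genes = character(),
                          nodes = character()) {
  if (is.null(edges))
    edges <- data.frame(a = character(), b = character(),
                        channel = character(), stringsAsFactors = FALSE)
  stopifnot(all(c("a", "b", "channel") %in% names(edges)))
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  edges$channel <- as.character(edges$channel)
  if (is.null(edges$directed))
    edges$directed <- edges$channel == "tf_target"
  edges$directed <- as.logical(edges$directed)

  bad <- !edges$channel %in% evidence_channels()
  if (any(bad))
    stop("unknown evidence channel(s): ",
         paste(unique(edges$channel[bad]), collapse = ", "), call. = FALSE)
  if (any(edges$a == edges$b))
    stop("self-loop edge(s) rejected: ",
         paste(unique(edges$a[edges$a == edges$b]), collapse = ", "),
         call. = FALSE)

  nodes <- sort(unique(c(edges$a, edges$b, seed_genes, nodes)))
  roles <- stats::setNames(rep("candidate", length(nodes)), nodes)
  roles[seed_genes] <- "seed"

  net <- structure(list(nodes = nodes, edges = edges, roles = roles),
                   class = "evidence_network")
  net$graph <- collapsed_graph(net)
  net
}

# simple undirected graph: one edge per unordered node pair
collapsed_graph <- function(net) {
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (nrow(net$edges)) {
    pair <- unique(t(apply(net$edges[, c("a", "b")], 1, sort)))
    g <- igraph::add_edges(g, t(matrix(match(pair, net$nodes),
                                       ncol = 2)))
  }
  igraph::simplify(g)
}

#' @export
print.evidence_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("Evidence network: %d nodes, %d collapsed edges (%d records), %d component(s)\n",
              s["n_nodes"], s["n_edges"], nrow(x$edges), s["n_components"]))
  tab <- table(x$edges$channel)
  if (length(tab))
    cat("  channels:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Summary counts for an evidence network
#'
#' Counts on the collapsed (one edge per gene pair) undirected view.
#'
#' @param net An `evidence_network`.
#' @return Named vector: `n_nodes`, `n_edges`, `n_components`, `density`
#'   (edges / choose(n, 2)).
#' @export
network_summary <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  c(n_nodes = n, n_edges = e,
    n_components = igraph::components(g)$no,
    density = if (n < 2) NA_real_ else e / choose(n, 2))
}

# adjacency (named logical matrix) of the collapsed view plus extra edges
adjacency_lookup <- function(net) {
  m <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE) > 0
  dimnames(m) <- list(net$nodes, net$nodes)
  m
}

# is the induced subgraph on `vids` (character names) connected?
induced_connected <- function(graph, vids) {
  if (length(vids) <= 1) return(TRUE)
  sub <- igraph::induced_subgraph(graph, vids)
  igraph::is_connected(sub)
}

#' Exhaustive minimal connector-node search
#'
#' Finds every minimum-cardinality set of additional nodes whose inclusion
#' makes the subgraph induced on the seed genes plus the added set connected
#' (undirected view, all evidence channels). The search enumerates candidate
#' subsets of size 0, 1, ... up to `k_max`, so returned solutions are
#' certified minimal: no smaller subset connects the seeds. Solutions are
#' ordered lexicographically by sorted gene symbols.
#'
#' @param net An `evidence_network`.
#' @param seeds Character vector of seed genes (must be network nodes).
#' @param candidate_pool Candidate connector nodes; defaults to all network
#'   neighbors of the seeds (excluding the seeds themselves).
#' @param k_max Maximum subset size to enumerate (default 3).
#' @return Object of class `connector_solution`: `added` (first minimal
#'   solution), `k`, `all_minimal` (list of all co-minimal solutions),
#'   `connected`, `status` (`"connected"`, `"already_connected"` or
#'   `"unconnectable_at_k_max"`).
#' @export
find_minimal_connectors <- function(net, seeds, candidate_pool = NULL,
                                    k_max = 3) {
  if (length(seeds) == 0)
    stop("empty seed set", call. = FALSE)
  missing <- setdiff(seeds, net$nodes)
  if (length(missing))
    stop("seed(s) not in network: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(candidate_pool)) {
    nb <- unique(unlist(lapply(seeds, function(s)
      igraph::neighbors(net$graph, s)$name)))
    candidate_pool <- setdiff(nb, seeds)
  } else {
    candidate_pool <- setdiff(intersect(candidate_pool, net$nodes), seeds)
  }
  candidate_pool <- sort(candidate_pool)

  for (k in 0:min(k_max, length(candidate_pool))) {
    subsets <- if (k == 0) list(character(0)) else
      utils::combn(candidate_pool, k, simplify = FALSE)
    hits <- Filter(function(s) induced_connected(net$graph, c(seeds, s)),
                   subsets)
    if (length(hits)) {
      hits <- hits[order(vapply(hits, paste, "", collapse = "|"))]
      return(structure(list(added = hits[[1]], k = k, all_minimal = hits,
                            connected = TRUE,
                            status = if (k == 0) "already_connected"
                                     else "connected"),
                       class = "connector_solution"))
    }
  }
  structure(list(added = character(0), k = NA_integer_,
                 all_minimal = list(), connected = FALSE,
                 status = "unconnectable_at_k_max"),
            class = "connector_solution")
}

#' @export
print.connector_solution <- function(x, ...) {
  if (identical(x$status, "partial")) {
    cat(sprintf(
      "Connector search: full connectivity unattainable; best achievable is %d component(s), reached with k = %d addition(s)\n",
      x$n_components, x$k))
    cat("  added:", paste(x$added, collapse = ", "), "\n")
  } else if (!x$connected) {
    cat("Connector search: no solution within k_max (", x$status, ")\n",
        sep = "")
  } else if (x$k == 0) {
    cat("Connector search: seeds already connected (k = 0)\n")
  } else {
    cat(sprintf("Connector search: k = %d; %d minimal solution(s)\n",
                x$k, length(x$all_minimal)))
    cat("  first:", paste(x$added, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Minimal transcription-factor augmentation
#'
#' Treats each transcription factor as a candidate node whose edges run from
#' the TF to each of its targets present in `genes`, and searches for the
#' smallest TF subset whose addition connects all of `genes` (undirected
#' view). The `exact` strategy enumerates TF subsets by increasing
#' cardinality up to `k_max`; when full connectivity is impossible even with
#' every TF, it returns the minimal subset achieving the best attainable
#' component count, with `status = "partial"`. The `greedy` strategy
#' repeatedly adds the TF that merges the most components (ties broken by
#' largest merge count, then lexicographically); greedy solutions are not
#' guaranteed minimal and a warning says so.
#'
#' @param net An `evidence_network` (edges among `genes` are used).
#' @param genes Genes to connect.
#' @param tf_targets data.frame with columns `tf`, `target`.
#' @param k_max Maximum exact subset size (default 5).
#' @param strategy `"exact"` or `"greedy"`.
#' @return A `connector_solution`; `status` is `"connected"`,
#'   `"already_connected"`, `"partial"` or `"unconnectable_at_k_max"`. For
#'   `"partial"` results `connected` is `FALSE` and the field
#'   `n_components` gives the component count achieved.
#' @export
augment_with_tfs <- function(net, genes, tf_targets, k_max = 5,
                             strategy = c("exact", "greedy")) {
  strategy <- match.arg(strategy)
  if (is.null(tf_targets) || nrow(tf_targets) == 0)
    stop("tf_targets is empty", call. = FALSE)
  if (length(genes) == 0)
    stop("empty gene set", call. = FALSE)
  tf_targets$tf <- as.character(tf_targets$tf)
  tf_targets$target <- as.character(tf_targets$target)
  tf_targets <- tf_targets[tf_targets$target %in% genes, , drop = FALSE]
  tfs <- sort(unique(tf_targets$tf))

  # base components of `genes` under the existing network
  base_graph <- base_gene_graph(net, genes)
  comp <- igraph::components(base_graph)$membership

  tf_comp_sets <- lapply(tfs, function(tf) {
    sort(unique(comp[unique(tf_targets$target[tf_targets$tf == tf])]))
  })
  names(tf_comp_sets) <- tfs
  n_comp <- max(comp)

  merged_count <- function(sets) {
    # union-find over components merged by the chosen TF stars
    parent <- seq_len(n_comp)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (s in sets) {
      if (length(s) > 1) {
        r <- find(s[1])
        for (j in s[-1]) {
          rj <- find(j)
          if (rj != r) parent[rj] <- r
        }
      }
    }
    length(unique(vapply(seq_len(n_comp), find, numeric(1))))
  }

  if (n_comp == 1)
    return(structure(list(added = character(0), k = 0,
                          all_minimal = list(character(0)), connected = TRUE,
                          status = "already_connected", n_components = 1),
                     class = "connector_solution"))

  if (strategy == "greedy") {
    added <- character(0)
    parent <- seq_len(n_comp)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    current <- n_comp
    remaining <- tfs
    repeat {
      gains <- vapply(remaining, function(tf) {
        roots <- unique(vapply(tf_comp_sets[[tf]], find, numeric(1)))
        length(roots) - 1L
      }, integer(1))
      if (!length(gains) || max(gains) == 0) break
      best <- remaining[gains == max(gains)]
      pick <- sort(best)[1]
      roots <- unique(vapply(tf_comp_sets[[pick]], find, numeric(1)))
      for (r in roots[-1]) parent[find(r)] <- find(roots[1])
      current <- current - (length(roots) - 1L)
      added <- c(added, pick)
      remaining <- setdiff(remaining, pick)
      if (current == 1) break
    }
    if (current > 1)
      warning("greedy TF augmentation could not fully connect the gene set",
              call. = FALSE)
    else
      warning("greedy strategy is not guaranteed minimal; use exact for a ",
              "certified minimum", call. = FALSE)
    return(structure(list(added = sort(added), k = length(added),
                          all_minimal = list(sort(added)),
                          connected = current == 1,
                          status = if (current == 1) "connected" else
                            "partial",
                          n_components = current),
                     class = "connector_solution"))
  }

  # exact: smallest subset achieving the best attainable component count
  best_possible <- merged_count(tf_comp_sets)
  target_comp <- 1L
  if (best_possible > 1) target_comp <- best_possible

  for (k in 0:min(k_max, length(tfs))) {
    subsets <- if (k == 0) list(character(0)) else
      utils::combn(tfs, k, simplify = FALSE)
    hits <- Filter(function(s) merged_count(tf_comp_sets[s]) <= target_comp,
                   subsets)
    if (length(hits)) {
      hits <- hits[order(vapply(hits, paste, "", collapse = "|"))]
      status <- if (best_possible == 1) "connected" else "partial"
      return(structure(list(added = hits[[1]], k = k, all_minimal = hits,
                            connected = best_possible == 1,
                            status = status,
                            n_components = target_comp),
                       class = "connector_solution"))
    }
  }
  structure(list(added = character(0), k = NA_integer_,
                 all_minimal = list(), connected = FALSE,
                 status = "unconnectable_at_k_max",
                 n_components = n_comp),
            class = "connector_solution")
}

base_gene_graph <- function(net, genes) {
  present <- intersect(genes, net$nodes)
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  if (length(present) > 1 && nrow(net$edges)) {
    keep <- net$edges$a %in% genes & net$edges$b %in% genes
    if (any(keep)) {
      pair <- unique(t(apply(net$edges[keep, c("a", "b"), drop = FALSE],
                             1, sort)))
      g <- igraph::add_edges(g, t(matrix(match(pair, genes), ncol = 2)))
    }
  }
  igraph::simplify(g)
}

#' Rescue orphan genes with predicted interactions
#'
#' A node outside the giant component of the network is rescued when a path
#' exists from it to the giant component through the union of the existing
#' network and the supplied support edges (typically predicted interactions,
#' possibly mixed with known edges for intermediate nodes). All edges and
#' intermediate "rescue" nodes along a shortest such path are added to the
#' network. Orphans with no path are listed in the report, never silently
#' dropped.
#'
#' @param net An `evidence_network`.
#' @param predicted_edges data.frame with columns `a`, `b` and optionally
#'   `channel` (default `"predicted_ppi"`).
#' @return List with `network` (augmented `evidence_network`) and `report`
#'   (data.frame with columns `orphan`, `rescued`, `via`).
#' @export
rescue_orphans <- function(net, predicted_edges) {
  if (is.null(predicted_edges$channel))
    predicted_edges$channel <- "predicted_ppi"
  comp <- igraph::components(net$graph)
  giant_id <- which.max(comp$csize)
  giant <- net$nodes[comp$membership == giant_id]
  orphans <- setdiff(net$nodes, giant)

  if (length(orphans) == 0)
    return(list(network = net,
                report = data.frame(orphan = character(),
                                    rescued = logical(), via = character(),
                                    stringsAsFactors = FALSE)))

  aug_edges <- rbind(net$edges[, c("a", "b", "channel")],
                     predicted_edges[, c("a", "b", "channel")])
  aug_nodes <- sort(unique(c(net$nodes, aug_edges$a, aug_edges$b)))
  aug_graph <- igraph::graph_from_data_frame(
    unique(aug_edges[, c("a", "b")]), directed = FALSE,
    vertices = aug_nodes)

  new_edges <- net$edges
  added_nodes <- character(0)
  report <- data.frame(orphan = orphans, rescued = FALSE,
                       via = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(orphans)) {
    o <- orphans[i]
    # unreachable targets are expected here (they define unrescued orphans)
    sp <- suppressWarnings(
      igraph::shortest_paths(aug_graph, from = o, to = giant,
                             output = "vpath"))
    lens <- vapply(sp$vpath, length, integer(1))
    reachable <- lens > 0
    if (!any(reachable)) next
    path <- sp$vpath[[which(reachable)[which.min(lens[reachable])]]]$name
    report$rescued[i] <- TRUE
    report$via[i] <- paste(path[-c(1, length(path))], collapse = ",")
    for (j in seq_len(length(path) - 1)) {
      a <- path[j]; b <- path[j + 1]
      src <- predicted_edges[(predicted_edges$a == a & predicted_edges$b == b) |
                               (predicted_edges$a == b & predicted_edges$b == a),
                             , drop = FALSE]
      channel <- if (nrow(src)) src$channel[1] else "predicted_ppi"
      already <- any((new_edges$a == a & new_edges$b == b) |
                       (new_edges$a == b & new_edges$b == a))
      if (!already)
        new_edges <- rbind(new_edges,
                           data.frame(a = a, b = b, channel = channel,
                                      directed = FALSE,
                                      stringsAsFactors = FALSE))
      added_nodes <- union(added_nodes, setdiff(c(a, b), net$nodes))
    }
  }

  out <- build_network(new_edges,
                       seed_genes = names(net$roles)[net$roles == "seed"],
                       nodes = net$nodes)
  out$roles[added_nodes] <- "rescue"
  list(network = out, report = report)
}
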