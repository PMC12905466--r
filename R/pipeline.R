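#' Assemble a run configuration
#'
#' Collects every input path, threshold and seed for an end-to-end run.
#' Stages execute only when their inputs are configured; a run's effective
#' configuration is persisted next to its outputs so reruns are exactly
#' reproducible.
#'
#' @param trios List of trio entries, each a list with `label`, `vcf`,
#'   `annotations`, `proband`, `father`, `mother`, `proband_sex`.
#' @param filter Arguments for [filter_config()] (list).
#' @param expression List: either `summary_table` (path to a table of
#'   per-gene window means) or `matrix` + `metadata` paths, plus optional
#'   `split_age` (months) and `floor` (RPKM).
#' @param network List: `edges` path, optional `seeds`, `tf_targets`,
#'   `rescue_edges` paths/vectors, `k_max`, `tf_k_max`, and `enrichment`
#'   options (`background_edges`, `gene_set`, `n_perm`, `null_model`,
#'   `rng_seed`).
#' @param stats List: `panels` (named list of symbol vectors or files) and
#'   `n_universe` (must be stated explicitly when panels are configured; the
#'   documented library default is 20000 protein-coding genes).
#' @param out_dir Output directory for reports.
#' @return Object of class `run_config`.
#' @export
run_config <- function(trios = list(), filter = list(),
                       expression = list(), network = list(),
                       stats = list(), out_dir = tempfile("trioconnect_")) {
  cfg <- list(trios = trios, filter = filter, expression = expression,
              network = network, stats = stats, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#' @param cfg A `run_config`.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full prioritization pipeline
#'
#' Executes, in order: per-trio variant filtering, expression
#' prioritization, network construction (minimal connector search, minimal
#' TF augmentation, orphan rescue, edge enrichment), and panel overlap
#' statistics. Each stage writes its own report under `out_dir`; a combined
#' machine-readable summary and the effective configuration are persisted as
#' `summary.json` and `config.yaml`. Reruns with the same configuration and
#' seeds produce identical summaries.
#'
#' @param cfg A [run_config()].
#' @return The summary list, invisibly. Stage failures abort with the stage
#'   name in the error message.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list()
  fcfg <- do.call(filter_config, cfg$filter)

  gene_pool <- character()
  if (length(cfg$trios)) {
    trio_summaries <- list()
    for (tr in cfg$trios) {
      label <- if (!is.null(tr$label)) tr$label else basename(tr$vcf)
      rep <- tryCatch(
        filter_trio(tr$vcf, tr$annotations, fcfg,
                    pedigree = tr[c("proband", "father", "mother",
                                    "proband_sex")]),
        error = function(e) stop("stage filter_trio (", label, "): ",
                                 conditionMessage(e), call. = FALSE))
      write_trio_report(rep, file.path(cfg$out_dir, paste0("trio_", label)))
      lp <- sum(c(rep$de_novo$classification,
                  rep$autosomal_recessive$classification,
                  rep$x_linked_recessive$classification) ==
                  "likely_pathogenic")
      trio_summaries[[label]] <- list(
        counts = as.list(rep$counts),
        likely_pathogenic = lp,
        de_novo_genes = rep$de_novo$gene,
        autosomal_recessive_genes = rep$autosomal_recessive$gene,
        x_linked_recessive_genes = rep$x_linked_recessive$gene)
      gene_pool <- union(gene_pool,
                         c(rep$de_novo$gene, rep$autosomal_recessive$gene,
                           rep$x_linked_recessive$gene))
    }
    summary$trios <- trio_summaries
  }

  if (length(cfg$expression)) {
    ex <- cfg$expression
    floor <- if (!is.null(ex$floor)) ex$floor else 1.0
    split_age <- if (!is.null(ex$split_age)) ex$split_age else 12
    summaries <- if (!is.null(ex$summary_table)) {
      utils::read.delim(ex$summary_table, stringsAsFactors = FALSE)
    } else {
      expr <- read_expression_matrix(ex$matrix, ex$metadata)
      genes <- if (!is.null(ex$genes)) ex$genes else
        intersect(gene_pool, rownames(expr$rpkm))
      summarize_expression(expr, genes, split_age = split_age)
    }
    flagged <- flag_enrichment(summaries, floor = floor)
    utils::write.table(flagged,
                       file.path(cfg$out_dir, "expression_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$expression <- as.list(summarize_panel(flagged))
  }

  if (length(cfg$network)) {
    nw <- cfg$network
    edges <- read_edge_list(nw$edges)
    seeds <- nw$seeds
    genes <- if (!is.null(nw$genes)) nw$genes else
      unique(c(gene_pool, seeds))
    net <- build_network(edges,
                         seed_genes = if (!is.null(seeds)) seeds else
                           character(),
                         nodes = genes)
    net_part <- list(summary = as.list(network_summary(net)))

    if (!is.null(seeds)) {
      k_max <- if (!is.null(nw$k_max)) nw$k_max else 3
      sol <- find_minimal_connectors(net, seeds, k_max = k_max)
      net_part$connectors <- list(k = sol$k, status = sol$status,
                                  added = sol$added,
                                  all_minimal = sol$all_minimal)
      if (sol$connected && sol$k > 0)
        net$roles[sol$added] <- "connector"
      genes <- union(genes, sol$added)
    }

    if (!is.null(nw$tf_targets)) {
      tf_targets <- read_tf_map(nw$tf_targets)
      tf_k_max <- if (!is.null(nw$tf_k_max)) nw$tf_k_max else 5
      tf_genes <- intersect(genes, c(net$nodes,
                                     unique(tf_targets$target)))
      tfsol <- augment_with_tfs(net, tf_genes, tf_targets,
                                k_max = tf_k_max, strategy = "exact")
      net_part$tf_augmentation <- list(k = tfsol$k, status = tfsol$status,
                                       added = tfsol$added)
      if (length(tfsol$added)) {
        tfe <- tf_targets[tf_targets$tf %in% tfsol$added &
                            tf_targets$target %in% tf_genes, , drop = FALSE]
        net <- build_network(rbind(net$edges,
                                   data.frame(a = tfe$tf, b = tfe$target,
                                              channel = "tf_target",
                                              directed = TRUE,
                                              stringsAsFactors = FALSE)),
                             seed_genes = names(net$roles)[net$roles ==
                                                             "seed"],
                             nodes = net$nodes)
        net$roles[unique(tfe$tf)] <- "tf"
      }
    }

    if (!is.null(nw$rescue_edges)) {
      rescue <- read_edge_list(nw$rescue_edges, default_channel =
                                 "predicted_ppi")
      res <- rescue_orphans(net, rescue)
      net <- res$network
      net_part$rescue <- list(
        rescued = res$report$orphan[res$report$rescued],
        unresolved = res$report$orphan[!res$report$rescued])
    }

    net_part$final_summary <- as.list(network_summary(net))
    utils::write.table(net$edges, file.path(cfg$out_dir, "network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    en <- nw$enrichment
    if (!is.null(en)) {
      background <- if (!is.null(en$background_edges))
        read_edge_list(en$background_edges) else net$edges
      gene_set <- if (!is.null(en$gene_set)) en$gene_set else
        intersect(genes, unique(c(background$a, background$b)))
      er <- edge_enrichment(background[, c("a", "b")], gene_set,
                            n_perm = if (!is.null(en$n_perm)) en$n_perm
                                     else 999,
                            null_model = if (!is.null(en$null_model))
                              en$null_model else "node_resample",
                            rng_seed = if (!is.null(en$rng_seed))
                              en$rng_seed else 1L)
      net_part$enrichment <- unclass(er)
    }
    summary$network <- net_part
  }

  if (length(cfg$stats) && !is.null(cfg$stats$panels)) {
    if (is.null(cfg$stats$n_universe))
      stop("stage geneset_stats: n_universe must be stated explicitly ",
           "in the configuration", call. = FALSE)
    panels <- cfg$stats$panels
    panels <- lapply(panels, function(p)
      if (length(p) == 1 && file.exists(p)) readLines(p) else p)
    gene_list <- if (!is.null(cfg$stats$gene_list)) cfg$stats$gene_list
                 else gene_pool
    ov <- overlap_report(gene_list, panels, cfg$stats$n_universe)
    utils::write.table(ov, file.path(cfg$out_dir, "overlap_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$overlap <- ov
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  write_run_config(cfg, file.path(cfg$out_dir, "config.yaml"))
  invisible(summary)
}

read_edge_list <- function(x, default_channel = "experimental_ppi") {
  if (is.data.frame(x)) return(x)
  first <- readLines(x, n = 1)
  header <- grepl("^a\\t|\\ta\\t|^tf\\t|channel", first)
  ed <- utils::read.delim(x, header = header, stringsAsFactors = FALSE)
  if (!header) {
    names(ed)[1:2] <- c("a", "b")
    if (ncol(ed) >= 3) names(ed)[3] <- "channel"
  }
  if (is.null(ed$channel)) ed$channel <- default_channel
  ed
}

read_tf_map <- function(x) {
  if (is.data.frame(x)) return(x)
  first <- readLines(x, n = 1)
  header <- grepl("^tf\\b", first)
  tf <- utils::read.delim(x, header = header, stringsAsFactors = FALSE)
  if (!header) names(tf)[1:2] <- c("tf", "target")
  tf
}
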