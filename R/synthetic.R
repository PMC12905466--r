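#' Miniature-genome pseudoautosomal region used by the simulator
#'
#' The simulated genome has two autosomes ("1", "2", 1 Mb each) and an X
#' chromosome whose first 10 kb are declared pseudoautosomal, keeping PAR
#' routing testable at small scale.
#'
#' @return data.frame of half-open PAR intervals.
#' @export
synthetic_par_regions <- function() {
  data.frame(chrom = "X", start = 1L, end = 10001L,
             stringsAsFactors = FALSE)
}

#' Simulate a trio exome with planted inheritance modes
#'
#' Generates a trio VCF, an annotation table and a ground-truth record on a
#' miniature genome (autosomes "1" and "2" plus "X" with a declared PAR).
#' Planted variants satisfy their mode's genotype pattern with clean
#' qualities (GQ 60, balanced de novo reads) and annotations inside every
#' filter bound; decoys each violate exactly one rule, cycling through a
#' fixed taxonomy: inherited, low-GQ, common allele, low CADD, LOW impact,
#' allele-balance outlier. Identical parameters and seed give byte-identical
#' output files.
#'
#' @param n_decoys Number of decoy variants.
#' @param planted Named counts, e.g.
#'   `c(de_novo = 2, autosomal_recessive = 3, x_linked_recessive = 1)`.
#' @param cfg [filter_config()]; planted annotations respect its bounds.
#'   PAR regions are overridden with [synthetic_par_regions()].
#' @param rng_seed Integer seed.
#' @param dir Output directory.
#' @param proband_sex `"male"` (default) so the X-linked pattern is
#'   exercisable; planting XLR with a female proband is an error.
#' @return List with `vcf`, `annotations`, `truth_json` paths, the
#'   `pedigree`, and `truth` (planted coordinates and modes).
#' @export
generate_trio <- function(n_decoys = 20,
                          planted = c(de_novo = 1, autosomal_recessive = 1,
                                      x_linked_recessive = 1),
                          cfg = filter_config(),
                          rng_seed = 1L, dir = tempfile("synthetic_trio_"),
                          proband_sex = "male") {
  stopifnot(all(planted >= 0))
  modes <- rep(names(planted), planted)
  if ("x_linked_recessive" %in% modes && proband_sex != "male")
    stop("X-linked recessive planting requires a male proband",
         call. = FALSE)
  set.seed(as.integer(rng_seed))

  n_planted <- length(modes)
  rules <- c("inherited", "low_gq", "common_af", "low_cadd", "low_impact",
             "ab_outlier")
  decoy_rules <- rep(rules, length.out = n_decoys)
  n <- n_planted + n_decoys

  chrom <- character(n)
  chrom[seq_len(n_planted)] <- ifelse(modes == "x_linked_recessive", "X",
                                      sample(c("1", "2"), n_planted,
                                             replace = TRUE))
  if (n_decoys > 0)
    chrom[n_planted + seq_len(n_decoys)] <-
      sample(c("1", "2"), n_decoys, replace = TRUE)
  # keep X positions outside the declared 10 kb PAR
  pos <- integer(n)
  pos[chrom != "X"] <- sample(1e4:1e6, sum(chrom != "X"))
  pos[chrom == "X"] <- sample(20001:1e6, sum(chrom == "X"))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")

  gt_modes <- c(modes,
                ifelse(decoy_rules == "inherited", "inherited", "de_novo"))
  gt <- genotypes_for_modes(gt_modes)
  gt$gq_proband[n_planted + which(decoy_rules == "low_gq")] <-
    max(0L, as.integer(cfg$gq_min) - 10L)
  gt$ad_proband[n_planted + which(decoy_rules == "ab_outlier")] <- "36,4"

  genes <- sprintf("SYNGENE%03d", seq_len(n))
  cadd <- round(stats::runif(n, cfg$cadd_min + 5, cfg$cadd_min + 25), 1)
  af <- signif(10^stats::runif(n, -6, log10(min(cfg$af_max,
                                                cfg$pm2_af_max) / 10)), 3)
  impact <- rep("MODERATE", n)
  effect <- rep("missense", n)
  di <- n_planted + seq_len(n_decoys)
  af[di[decoy_rules == "common_af"]] <- 0.5
  cadd[di[decoy_rules == "low_cadd"]] <- round(cfg$cadd_min / 2, 1)
  impact[di[decoy_rules == "low_impact"]] <- "LOW"
  effect[di[decoy_rules == "low_impact"]] <- "synonymous"

  v <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  stringsAsFactors = FALSE)
  v <- cbind(v, gt)
  ann <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    gene = genes, pli = 0, effect = effect, impact = impact,
                    freq = af, cadd = cadd, rsid = NA_character_,
                    hgvs_c = NA_character_, hgvs_p = NA_character_,
                    stringsAsFactors = FALSE)

  ord <- order(chrom_rank(v$chrom), v$pos)
  v <- v[ord, , drop = FALSE]
  ann <- ann[ord, , drop = FALSE]

  truth <- list(
    planted_variants = data.frame(
      coordinate = sprintf("%s:%d", chrom[seq_len(n_planted)],
                           pos[seq_len(n_planted)]),
      gene = genes[seq_len(n_planted)],
      mode = modes, stringsAsFactors = FALSE),
    decoys = data.frame(
      coordinate = sprintf("%s:%d", chrom[di], pos[di]),
      gene = genes[di], rule = decoy_rules, stringsAsFactors = FALSE),
    rng_seed = as.integer(rng_seed))

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(dir, "trio.vcf")
  ann_path <- file.path(dir, "annotations.tsv")
  truth_path <- file.path(dir, "truth.json")
  write_trio_vcf(v, vcf_path, samples = c("PROBAND", "FATHER", "MOTHER"),
                 contigs = c("1", "2", "X"))
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  jsonlite::write_json(truth, truth_path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  list(vcf = vcf_path, annotations = ann_path, truth_json = truth_path,
       pedigree = list(proband = "PROBAND", father = "FATHER",
                       mother = "MOTHER", proband_sex = proband_sex),
       truth = truth)
}

#' Simulate a developmental RPKM matrix with planted cerebellar enrichment
#'
#' Samples are a full crossing of brain structures (cerebellar cortex "CBC"
#' plus `n_structures - 1` others) with a default age ladder spanning 8
#' postconception weeks to 40 years. RPKM values are log-normal around
#' per-gene baselines; genes in `enriched` have their early-window
#' cerebellar samples multiplied by `multiplier`. With `noise_sd = 0` the
#' values equal the baselines exactly.
#'
#' @param genes Character vector of gene symbols.
#' @param n_structures Total structure count (>= 2; one is cerebellar).
#' @param ages Character age ladder (must cover both windows).
#' @param enriched Genes to plant as cerebellum-enriched.
#' @param multiplier Early cerebellar fold change for enriched genes (> 0).
#' @param noise_sd Standard deviation of log-normal noise.
#' @param rng_seed Integer seed.
#' @param baseline Optional named numeric baseline per gene; default drawn
#'   log-uniform in [2, 20].
#' @param split_age Early/late boundary in postnatal months.
#' @return List with `expr` (as from [read_expression_matrix()]) and
#'   `truth` (`planted_enriched_genes`, `rng_seed`).
#' @export
generate_expression_matrix <- function(genes,
                                       n_structures = 4,
                                       ages = c("8 pcw", "16 pcw", "24 pcw",
                                                "35 pcw", "4 mos", "10 mos",
                                                "4 yrs", "13 yrs", "23 yrs",
                                                "40 yrs"),
                                       enriched = character(),
                                       multiplier = 4,
                                       noise_sd = 0.2,
                                       rng_seed = 1L,
                                       baseline = NULL,
                                       split_age = 12) {
  stopifnot(multiplier > 0, n_structures >= 2)
  structures <- c("CBC", paste0("STR", seq_len(n_structures - 1)))
  age_months <- parse_age(ages)
  if (!any(age_months < split_age) || !any(age_months >= split_age))
    stop("ages must cover both the early and the late window",
         call. = FALSE)
  set.seed(as.integer(rng_seed))
  if (is.null(baseline))
    baseline <- stats::setNames(exp(stats::runif(length(genes),
                                                 log(2), log(20))), genes)

  grid <- expand.grid(structure_code = structures, age = ages,
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("S%02d_%s", seq_len(nrow(grid)),
                            grid$structure_code)
  grid$age_months <- parse_age(grid$age)
  grid$cerebellum <- grid$structure_code == "CBC"

  rpkm <- matrix(0, nrow = length(genes), ncol = nrow(grid),
                 dimnames = list(genes, grid$sample_id))
  for (g in genes) {
    mult <- ifelse(grid$cerebellum & grid$age_months < split_age &
                     g %in% enriched, multiplier, 1)
    noise <- if (noise_sd > 0) exp(stats::rnorm(nrow(grid), 0, noise_sd))
             else 1
    rpkm[g, ] <- baseline[[g]] * mult * noise
  }

  samples <- grid[, c("sample_id", "structure_code", "age", "age_months",
                      "cerebellum")]
  list(expr = list(rpkm = rpkm, samples = samples),
       truth = list(planted_enriched_genes = sort(enriched),
                    multiplier = multiplier, noise_sd = noise_sd,
                    rng_seed = as.integer(rng_seed)))
}

#' Simulate an evidence network with a planted unique connector
#'
#' Builds a random background graph over non-seed nodes (edge probability
#' `edge_prob`), keeps the seed genes mutually non-adjacent and detached
#' from the background, and attaches a single planted hub to every seed, so
#' the hub is the unique single-node connector. The guarantee is verified by
#' brute force over all nodes before anything is returned. Optionally
#' generates a transcription-factor layer in which a known minimal TF subset
#' connects extra orphan genes to the seed component; the planted TF
#' solution is verified with the exhaustive search.
#'
#' @param n_nodes Background node count (excluding seeds).
#' @param edge_prob Background edge probability in [0, 1].
#' @param seeds Character seed gene names (default 5 generated seeds).
#' @param planted_connector_unique Ensure a unique k = 1 connector.
#' @param tf_layer `NULL`, or a list with `n_tfs` (total TFs) and
#'   `solution_size` (cardinality of the planted minimal subset).
#' @param rng_seed Integer seed.
#' @return List with `edges` (data.frame), `tf_targets` (or `NULL`),
#'   `genes` (the gene set the TF layer connects), `seeds`, and `truth`
#'   (`planted_connector`, `planted_tf_solution`, `rng_seed`).
#' @export
generate_network <- function(n_nodes = 30, edge_prob = 0.08,
                             seeds = sprintf("SEED%d", 1:5),
                             planted_connector_unique = TRUE,
                             tf_layer = NULL,
                             rng_seed = 1L) {
  stopifnot(edge_prob >= 0, edge_prob <= 1, n_nodes >= 2)
  set.seed(as.integer(rng_seed))
  bg <- sprintf("NODE%03d", seq_len(n_nodes))
  hub <- bg[1]

  pairs <- utils::combn(bg, 2)
  keep <- stats::runif(ncol(pairs)) < edge_prob
  edges <- data.frame(a = pairs[1, keep], b = pairs[2, keep],
                      channel = rep("experimental_ppi", sum(keep)),
                      stringsAsFactors = FALSE)
  if (planted_connector_unique) {
    edges <- rbind(edges,
                   data.frame(a = hub, b = seeds,
                              channel = "experimental_ppi",
                              stringsAsFactors = FALSE))
    # no other node touches a seed, so the hub is the unique k = 1 solution
  }
  net <- build_network(edges, seed_genes = seeds)

  planted_connector <- NULL
  if (planted_connector_unique) {
    single <- Filter(function(x) induced_connected(net$graph,
                                                   c(seeds, x)),
                     setdiff(net$nodes, seeds))
    if (!identical(sort(unlist(single)), hub))
      stop("internal verification failed: planted connector not unique",
           call. = FALSE)
    planted_connector <- hub
  }

  tf_targets <- NULL
  tf_genes <- seeds
  planted_tf_solution <- NULL
  if (!is.null(tf_layer)) {
    n_tfs <- tf_layer$n_tfs
    s <- tf_layer$solution_size
    stopifnot(s >= 1, n_tfs >= s)
    orphan_genes <- sprintf("ORPH%02d", seq_len(2 * s))
    groups <- split(orphan_genes, rep(seq_len(s), each = 2))
    anchor <- if (planted_connector_unique) c(seeds[1], hub) else seeds[1]
    sol_tfs <- sprintf("TF%02d", seq_len(s))
    rows <- lapply(seq_len(s), function(i)
      data.frame(tf = sol_tfs[i], target = c(groups[[i]], anchor[1]),
                 stringsAsFactors = FALSE))
    decoy_tfs <- sprintf("TF%02d", s + seq_len(n_tfs - s))
    rows <- c(rows, lapply(decoy_tfs, function(tf)
      data.frame(tf = tf, target = sample(orphan_genes, 1),
                 stringsAsFactors = FALSE)))
    tf_targets <- do.call(rbind, rows)
    tf_genes <- c(seeds, if (planted_connector_unique) hub, orphan_genes)
    sol <- augment_with_tfs(net, tf_genes, tf_targets,
                            k_max = s, strategy = "exact")
    if (!sol$connected || !identical(sol$added, sol_tfs))
      stop("internal verification failed: planted TF solution not minimal",
           call. = FALSE)
    planted_tf_solution <- sol_tfs
  }

  list(edges = edges, tf_targets = tf_targets, genes = tf_genes,
       seeds = seeds,
       truth = list(planted_connector = planted_connector,
                    planted_tf_solution = planted_tf_solution,
                    rng_seed = as.integer(rng_seed)))
}
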