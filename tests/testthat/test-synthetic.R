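test_that("simulated trios are byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  t1 <- generate_trio(n_decoys = 12, rng_seed = 5, dir = d1)
  t2 <- generate_trio(n_decoys = 12, rng_seed = 5, dir = d2)
  expect_identical(readLines(t1$vcf), readLines(t2$vcf))
  expect_identical(readLines(t1$annotations), readLines(t2$annotations))
  t3 <- generate_trio(n_decoys = 12, rng_seed = 6,
                      dir = withr::local_tempdir())
  expect_false(identical(readLines(t1$vcf), readLines(t3$vcf)))
})

test_that("planted variants are recovered exactly with clean settings", {
  cfg <- filter_config(par_regions = synthetic_par_regions())
  tr <- generate_trio(n_decoys = 50,
                      planted = c(de_novo = 2, autosomal_recessive = 3,
                                  x_linked_recessive = 1),
                      cfg = cfg, rng_seed = 7)
  rep <- filter_trio(tr$vcf, tr$annotations, cfg, tr$pedigree)
  truth <- tr$truth$planted_variants
  expect_identical(sort(rep$de_novo$gene),
                   sort(truth$gene[truth$mode == "de_novo"]))
  expect_identical(sort(rep$autosomal_recessive$gene),
                   sort(truth$gene[truth$mode == "autosomal_recessive"]))
  expect_identical(sort(rep$x_linked_recessive$gene),
                   sort(truth$gene[truth$mode == "x_linked_recessive"]))
  # sensitivity and specificity both 1: nothing extra in the mode lists
  found <- c(rep$de_novo$gene, rep$autosomal_recessive$gene,
             rep$x_linked_recessive$gene)
  expect_setequal(found, truth$gene)
})

test_that("zero planting yields empty mode lists; female XLR planting errors", {
  cfg <- filter_config(par_regions = synthetic_par_regions())
  tr <- generate_trio(n_decoys = 10,
                      planted = c(de_novo = 0, autosomal_recessive = 0,
                                  x_linked_recessive = 0),
                      cfg = cfg, rng_seed = 3)
  rep <- filter_trio(tr$vcf, tr$annotations, cfg, tr$pedigree)
  expect_identical(unname(rep$counts[c("de_novo", "autosomal_recessive",
                                       "x_linked_recessive")]),
                   c(0L, 0L, 0L))
  expect_error(generate_trio(planted = c(x_linked_recessive = 1),
                             proband_sex = "female", rng_seed = 1),
               "male proband")
})

test_that("expression generator plants recoverable cerebellar enrichment", {
  genes <- sprintf("G%02d", 1:12)
  enriched <- c("G01", "G02", "G03")
  # noiseless: means are exactly baseline and baseline x multiplier
  ex0 <- generate_expression_matrix(genes, enriched = enriched,
                                    multiplier = 4, noise_sd = 0,
                                    rng_seed = 2,
                                    baseline = setNames(rep(5, 12), genes))
  s0 <- flag_enrichment(summarize_expression(ex0$expr))
  expect_equal(s0$early_other_mean, rep(5, 12))
  expect_equal(s0$early_cerebellum_mean[s0$gene %in% enriched],
               rep(20, 3))
  expect_identical(s0$early_flag[s0$gene %in% enriched],
                   rep("plus", 3))
  expect_identical(s0$early_flag[!s0$gene %in% enriched],
                   rep("tie", 9))
  # low noise: all planted genes flagged plus
  ex1 <- generate_expression_matrix(genes, enriched = enriched,
                                    multiplier = 4, noise_sd = 0.1,
                                    rng_seed = 4)
  s1 <- flag_enrichment(summarize_expression(ex1$expr))
  expect_identical(s1$early_flag[s1$gene %in% enriched], rep("plus", 3))
  # multiplier 1: plus rate for non-planted genes is near chance
  plus_rate <- mean(vapply(1:20, function(seed) {
    ex <- generate_expression_matrix(genes, enriched = character(),
                                     multiplier = 1, noise_sd = 0.3,
                                     rng_seed = seed)
    s <- flag_enrichment(summarize_expression(ex$expr))
    mean(s$early_flag == "plus")
  }, 0))
  expect_gt(plus_rate, 0.25)
  expect_lt(plus_rate, 0.75)
  # degenerate designs are rejected
  expect_error(generate_expression_matrix(genes, ages = c("8 pcw"),
                                          rng_seed = 1),
               "both the early and the late window")
})

test_that("network generator verifies its planted unique connector and TF set", {
  for (seed in c(1, 2, 3)) {
    gn <- generate_network(n_nodes = 25, edge_prob = 0.1,
                           tf_layer = list(n_tfs = 5, solution_size = 2),
                           rng_seed = seed)
    net <- build_network(gn$edges, seed_genes = gn$seeds)
    sol <- find_minimal_connectors(net, gn$seeds,
                                   candidate_pool = setdiff(net$nodes,
                                                            gn$seeds),
                                   k_max = 2)
    expect_identical(sol$k, 1L)
    expect_identical(sol$all_minimal, list(gn$truth$planted_connector))
    tfsol <- augment_with_tfs(net, gn$genes, gn$tf_targets, k_max = 3)
    expect_identical(tfsol$added, gn$truth$planted_tf_solution)
    expect_true(tfsol$connected)
  }
  # edge_prob 0 with no planted hub: isolated seeds are unconnectable
  gn0 <- generate_network(n_nodes = 10, edge_prob = 0,
                          planted_connector_unique = FALSE, rng_seed = 1)
  net0 <- build_network(gn0$edges, seed_genes = gn0$seeds,
                        nodes = sprintf("NODE%03d", 1:10))
  sol0 <- find_minimal_connectors(net0, gn0$seeds,
                                  candidate_pool = setdiff(net0$nodes,
                                                           gn0$seeds),
                                  k_max = 3)
  expect_identical(sol0$status, "unconnectable_at_k_max")
})
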