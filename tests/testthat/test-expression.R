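make_expr <- function(rpkm, structure, age) {
  samples <- data.frame(sample_id = colnames(rpkm),
                        structure_code = structure, age = age,
                        stringsAsFactors = FALSE)
  samples$age_months <- parse_age(samples$age)
  samples$cerebellum <- samples$structure_code == "CBC"
  list(rpkm = rpkm, samples = samples)
}

test_that("age strings map to a single ordered axis with birth at 40 pcw", {
  got <- parse_age(c("8 pcw", "40 pcw", "10 mos", "1 yrs", "40 yrs"))
  expect_equal(got[2], 0)                      # birth
  expect_lt(got[1], 0)                         # prenatal before birth
  expect_equal(got[3], 10)
  expect_equal(got[4], 12)
  expect_equal(got[5], 480)
  expect_true(all(diff(got) > 0))              # monotone ordering
  expect_error(parse_age("8 lightyears"), "unknown age unit")
  expect_error(parse_age("old"), "unparseable")
})

test_that("window/compartment means are plain arithmetic means", {
  rpkm <- matrix(c(4, 6, 1, 3), nrow = 1,
                 dimnames = list("G1", paste0("s", 1:4)))
  expr <- make_expr(rpkm, c("CBC", "CBC", "STR1", "STR2"),
                    rep("8 pcw", 4))
  s <- summarize_gene(expr, "G1")
  expect_equal(s$early_cerebellum_mean, 5.0)
  expect_equal(s$early_other_mean, 2.0)
  expect_true(is.na(s$late_other_mean))        # no late samples
  expect_error(summarize_gene(expr, "NOPE"), "not present")
})

test_that("means are invariant to sample order and match brute force", {
  set.seed(7)
  n <- 24
  rpkm <- matrix(rexp(3 * n, 0.2), nrow = 3,
                 dimnames = list(c("A", "B", "C"), paste0("s", 1:n)))
  structure <- sample(c("CBC", "STR1", "STR2"), n, replace = TRUE)
  age <- sample(c("8 pcw", "4 mos", "10 mos", "2 yrs", "30 yrs"), n,
                replace = TRUE)
  expr <- make_expr(rpkm, structure, age)
  s <- summarize_expression(expr)

  # brute-force recomputation
  am <- parse_age(age)
  for (g in c("A", "B", "C")) {
    expect_equal(s$early_other_mean[s$gene == g],
                 mean(rpkm[g, am < 12 & structure != "CBC"]))
    expect_equal(s$late_cerebellum_mean[s$gene == g],
                 mean(rpkm[g, am >= 12 & structure == "CBC"]))
  }

  # permutation invariance
  perm <- sample(n)
  expr2 <- make_expr(rpkm[, perm], structure[perm], age[perm])
  expect_equal(summarize_expression(expr2), s)
})

test_that("a fixture matrix reproduces the published LAMA5 window means", {
  # two samples per cell whose means equal the printed values
  vals <- c(5.70, 5.78,   # early cerebellum -> 5.74
            2.20, 2.40,   # early other -> 2.30
            7.00, 7.34,   # late cerebellum -> 7.17
            2.05, 2.25)   # late other -> 2.15
  rpkm <- matrix(vals, nrow = 1, dimnames = list("LAMA5", paste0("s", 1:8)))
  expr <- make_expr(rpkm,
                    c("CBC", "CBC", "STR1", "STR1", "CBC", "CBC", "STR1",
                      "STR1"),
                    c("8 pcw", "4 mos", "8 pcw", "4 mos", "2 yrs", "30 yrs",
                      "2 yrs", "30 yrs"))
  s <- flag_enrichment(summarize_gene(expr, "LAMA5"))
  expect_equal(s$early_cerebellum_mean, 5.74)
  expect_equal(s$early_other_mean, 2.30)
  expect_equal(s$late_cerebellum_mean, 7.17)
  expect_equal(s$late_other_mean, 2.15)
  expect_identical(s$early_flag, "plus")
  expect_identical(s$late_flag, "plus")
})

test_that("enrichment flags follow the floor-gated comparison rule", {
  s <- data.frame(gene = c("P", "M", "F", "T"),
                  early_other_mean = c(2.30, 7.47, 0.29, 2.0),
                  late_other_mean = c(2.15, 2.64, 0.88, 2.0),
                  early_cerebellum_mean = c(5.74, 5.84, 0.17, 2.0),
                  late_cerebellum_mean = c(7.17, 0.77, 0.14, 1.0))
  f <- flag_enrichment(s)
  expect_identical(f$early_flag, c("plus", "minus", "below_floor", "tie"))
  # the late window uses the earliest-development floor gate
  expect_identical(f$late_flag, c("plus", "minus", "below_floor", "minus"))
  # unavailable means give a distinct no-data outcome
  s$early_cerebellum_mean[1] <- NA
  expect_identical(flag_enrichment(s)$early_flag[1], "no_data")
})

test_that("flag counts are consistent and scale-invariant", {
  set.seed(11)
  s <- data.frame(gene = sprintf("G%02d", 1:40),
                  early_other_mean = 10^runif(40, -1, 1.5),
                  late_other_mean = 10^runif(40, -1, 1.5),
                  early_cerebellum_mean = 10^runif(40, -1, 1.5),
                  late_cerebellum_mean = 10^runif(40, -1, 1.5))
  f <- flag_enrichment(s)
  counts <- summarize_panel(f)
  # plus + minus + tie partitions the above-floor set per window
  expect_equal(counts[["n_above_floor"]],
               counts[["n_plus_early"]] + counts[["n_minus_early"]] +
                 sum(f$early_flag == "tie"))
  # brute-force recount
  expect_equal(counts[["n_plus_early"]],
               sum(s$early_other_mean > 1 &
                     s$early_cerebellum_mean > s$early_other_mean))
  # scaling the matrix and the floor together leaves flags unchanged
  c2 <- 3.7
  s2 <- s
  for (col in names(s)[-1]) s2[[col]] <- s2[[col]] * c2
  f2 <- flag_enrichment(s2, floor = c2)
  expect_identical(f2$early_flag, f$early_flag)
  expect_identical(f2$late_flag, f$late_flag)
  # empty panel
  expect_identical(unname(summarize_panel(s[0, ])), rep(0, 5))
})

test_that("published expression fixtures carry all 28 genes and exact means", {
  t3 <- table3_summaries()
  expect_identical(nrow(t3), 28L)
  expect_equal(t3$early_cerebellum_mean[t3$gene == "LAMB1"], 11.82)
  expect_equal(t3$early_other_mean[t3$gene == "GPI"], 35.96)
})
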