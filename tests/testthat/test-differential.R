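# Fold changes, Student's t-test, categories, three-criterion calling

test_that("student_t_test matches the closed-form pooled-variance oracle", {
  # hand-worked example: pooled sd = 1, t = 1/sqrt(2/3)
  r <- student_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(r$t, 1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$t, 1.2247, tolerance = 1e-4)
  expect_equal(r$p, 2 * pt(-1 / sqrt(2 / 3), df = 4), tolerance = 1e-12)
  expect_equal(r$p, 0.2879, tolerance = 5e-4)
  # identical groups
  expect_equal(student_t_test(c(5, 5, 5), c(5, 5, 5)), list(t = 0, p = 1))
  # swapping groups negates t, preserves p
  a <- student_t_test(c(1, 4, 2), c(8, 2, 3))
  b <- student_t_test(c(8, 2, 3), c(1, 4, 2))
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  # zero pooled variance with unequal means
  expect_warning(z <- student_t_test(c(1, 1), c(2, 2)), "zero pooled")
  expect_equal(z$p, .Machine$double.xmin)
})

test_that("student_t_test agrees with the oracle on 1000 random vectors", {
  set.seed(2024)
  worst <- 0
  for (i in 1:1000) {
    x <- rnorm(3); y <- rnorm(3)
    got <- student_t_test(x, y)
    want <- oracle_t(x, y)
    worst <- max(worst, abs(got$t - want$t), abs(got$p - want$p))
  }
  expect_lt(worst, 1e-10)
})

test_that("imputation_rule matches exhaustive enumeration of the criterion", {
  grid <- expand.grid(ctrl = 0:3, sil = 0:3)
  got <- imputation_rule(grid$ctrl, grid$sil, 3L)
  want <- with(grid, ctrl == 0 | sil == 0 | (ctrl <= 1 & sil <= 1))
  expect_equal(got, want)
  # admitted pairs: all with one fully observed condition (7) plus (1,1)
  expect_equal(sum(got), 8L)
  expect_true(imputation_rule(0L, 3L, 3L))
  expect_true(imputation_rule(1L, 1L, 3L))
  expect_false(imputation_rule(2L, 1L, 3L))
  expect_error(imputation_rule(4L, 0L, 3L), "n_reps")
})

test_that("compute_differential assigns categories with QC > DUB > direction", {
  # rows: strong up, strong down, below-fc, QC gene with big shift, the DUB
  lfq_log2 <- rbind(c(20, 20, 20, 22.33, 22.33, 22.33),
                    c(20, 20, 20, 18, 18, 18),
                    c(20.0, 20.1, 19.9, 20.5, 20.6, 20.4),
                    c(25, 25, 25, 28, 28, 28),
                    c(24, 24, 24, 22, 22, 22))
  lfq_log2 <- lfq_log2 + matrix(rnorm(30, 0, 0.01), 5, 6)  # break zero variance
  set.seed(1)
  res <- make_differential(lfq_log2,
                           gene = c("TTK", "DOWN1", "FLAT1", "PCCA", "USP9X"))
  expect_s3_class(res, "differential_result")
  expect_equal(res$category,
               c("up", "down", "not_significant", "qc_protein", "silenced_dub"))
  # log2_fc is exactly the difference of condition means
  expect_equal(res$log2_fc, res$mean_silenced - res$mean_control)
  # a large but sub-threshold fold change stays not significant
  expect_lt(abs(res$log2_fc[3]), 1)
  # missing DUB warns
  tab <- make_pg_table(2^lfq_log2[1:2, , drop = FALSE], gene = c("A", "B"))
  im <- impute(log2_transform(tab), seed = 1L)
  expect_warning(compute_differential(im, tab, dub_name = "USP9X"),
                 "not detected")
})

test_that("condition swap negates fold changes and preserves p-values", {
  syn <- generate_synthetic(synthetic_config(n_proteins = 120L,
                                             n_substrates = 8L, n_down = 3L,
                                             seed = 21L))
  flt <- filter_rows(syn$protein_groups)$table
  im <- impute(log2_transform(flt), seed = 21L)
  fwd <- suppressWarnings(compute_differential(im, flt, dub_name = "USP9X"))
  # swap the condition labels in the design
  des2 <- im$design
  des2$condition <- ifelse(des2$condition == "control", "silenced", "control")
  im2 <- im; im2$design <- des2
  attr(flt, "design") <- des2
  rev <- suppressWarnings(compute_differential(im2, flt, dub_name = "USP9X"))
  expect_equal(rev$log2_fc, -fwd$log2_fc)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
})

test_that("call_substrates applies the three criteria and sorts deterministically", {
  skel <- data.frame(
    row_key = sprintf("P%d", 1:5),
    gene_name = c("GOOD", "FEWPEP", "IMPUTED", "WEAKFC", "BIGP"),
    description = "",
    log2_fc = c(2.33, 2.33, 2.33, 0.5, 1.5),
    p_value = c(0.01, 0.01, 0.01, 0.001, 0.2),
    t_statistic = 3, mean_control = 20, mean_silenced = 22,
    n_imputed_control = c(0L, 0L, 2L, 0L, 0L),
    n_imputed_silenced = c(0L, 0L, 1L, 0L, 0L),
    unique_peptides = c(5L, 1L, 5L, 5L, 5L),
    category = c("up", "up", "up", "not_significant", "not_significant"),
    stringsAsFactors = FALSE)
  class(skel) <- c("differential_result", "data.frame")
  attr(skel, "n_reps") <- c(control = 3L, silenced = 3L)
  out <- call_substrates(skel)
  expect_equal(sort(out$initial_selection$gene_name),
               c("FEWPEP", "GOOD", "IMPUTED"))
  expect_equal(out$putative_substrates$gene_name, "GOOD")
  # empty input gives two empty frames
  empty <- skel[0, ]
  class(empty) <- class(skel)
  out0 <- call_substrates(empty)
  expect_equal(nrow(out0$initial_selection), 0L)
  expect_equal(nrow(out0$putative_substrates), 0L)
})

test_that("QC proteins and the silenced DUB are never callable", {
  lfq_log2 <- rbind(c(20, 20, 20, 23, 23, 23),
                    c(25, 25, 25, 28, 28, 28),
                    c(24, 24, 24, 27, 27, 27)) +
    matrix(rnorm(18, 0, 0.01), 3, 6)
  set.seed(2)
  res <- make_differential(lfq_log2, gene = c("SUB1", "PCCA", "USP9X"))
  out <- call_substrates(res)
  expect_equal(out$initial_selection$gene_name, "SUB1")
  expect_equal(res$category[2:3], c("qc_protein", "silenced_dub"))
})

test_that("tightening any threshold never adds a call", {
  syn <- generate_synthetic(synthetic_config(n_proteins = 250L,
                                             n_substrates = 20L, n_down = 5L,
                                             seed = 31L))
  flt <- filter_rows(syn$protein_groups)$table
  im <- impute(log2_transform(flt), seed = 31L)
  res <- suppressWarnings(compute_differential(im, flt, dub_name = "USP9X"))
  base <- call_substrates(res, default_thresholds())
  tighter <- list(default_thresholds(min_abs_log2_fc = 1.5),
                  default_thresholds(max_p = 0.01),
                  default_thresholds(min_unique_peptides = 6L))
  for (thr in tighter) {
    out <- call_substrates(res, thr)
    expect_true(all(out$initial_selection$row_key %in%
                      base$initial_selection$row_key))
    expect_true(all(out$putative_substrates$row_key %in%
                      base$putative_substrates$row_key))
    # putative is always a subset of the initial selection
    expect_true(all(out$putative_substrates$row_key %in%
                      out$initial_selection$row_key))
  }
  expect_true(all(base$putative_substrates$row_key %in%
                    base$initial_selection$row_key))
})

test_that("opt-in Benjamini-Hochberg correction only removes calls", {
  syn <- generate_synthetic(synthetic_config(n_proteins = 250L,
                                             n_substrates = 20L, n_down = 5L,
                                             seed = 32L))
  flt <- filter_rows(syn$protein_groups)$table
  im <- impute(log2_transform(flt), seed = 32L)
  raw <- suppressWarnings(compute_differential(im, flt, dub_name = "USP9X"))
  bh <- suppressWarnings(compute_differential(im, flt, dub_name = "USP9X",
                                              correction = "bh"))
  expect_true(all(bh$p_adjusted >= bh$p_value))
  expect_equal(bh$p_adjusted, p.adjust(raw$p_value, method = "BH"))
  raw_calls <- call_substrates(raw)$putative_substrates$row_key
  bh_calls <- call_substrates(bh)$putative_substrates$row_key
  expect_true(all(bh_calls %in% raw_calls))
})

test_that("volcano dataset conserves records and transforms p", {
  syn <- generate_synthetic(synthetic_config(n_proteins = 100L,
                                             n_substrates = 5L, n_down = 2L,
                                             seed = 41L))
  flt <- filter_rows(syn$protein_groups)$table
  im <- impute(log2_transform(flt), seed = 41L)
  res <- suppressWarnings(compute_differential(im, flt, dub_name = "USP9X"))
  v <- volcano_dataset(res)
  expect_equal(nrow(v), nrow(res))
  expect_equal(v$neg_log10_p, -log10(res$p_value))
  # categories partition the records
  expect_equal(sum(table(v$category)), nrow(v))
  expect_equal(-log10(0.05), 1.3010, tolerance = 1e-4)
})
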