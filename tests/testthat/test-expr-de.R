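test_that("quantile normalization equalizes column distributions", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- c("a", "b", "c")
  n <- normalize_quantile(m)
  expect_equal(unname(n[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(n[, 2]), c(2.5, 3.5, 4.5))

  # already-identical columns pass through
  m2 <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(normalize_quantile(m2), m2)

  # post-condition: all columns share the sorted value vector; ranks kept
  set.seed(3)
  m3 <- matrix(rnorm(500), ncol = 5)
  n3 <- normalize_quantile(m3)
  for (j in 2:5) {
    expect_equal(sort(n3[, j]), sort(n3[, 1]))
    expect_equal(order(n3[, j]), order(m3[, j]))
  }
  expect_error(normalize_quantile(m[, 1, drop = FALSE]), "2 samples")
  expect_error(normalize_quantile(cbind(c(1, NA), c(1, 2))), "finite")
})

test_that("BH adjustment matches examples and a brute-force oracle", {
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(19)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), bh_brute(p))
  }

  # permutation invariance: adjusted value follows its p-value
  p <- runif(30)
  o <- sample(30)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
})

test_that("signed fold change maps log2 to the signed linear convention", {
  expect_equal(signed_fold_change(1), 2)
  expect_equal(signed_fold_change(-1), -2)
  expect_equal(signed_fold_change(0), 1)
  x <- signed_fold_change(rnorm(200))
  expect_true(all(abs(x) >= 1))
})

test_that("de_test agrees gene-by-gene with compare_groups", {
  set.seed(23)
  m <- matrix(rnorm(50 * 6), nrow = 50,
              dimnames = list(paste0("g", 1:50), NULL))
  groups <- rep(c("case", "control"), each = 3)
  res <- de_test(m, groups)
  for (i in c(1, 17, 50)) {
    ref <- compare_groups(m[i, 1:3], m[i, 4:6])
    expect_equal(res$t_stat[i], ref$t_stat)
    expect_equal(res$p[i], ref$p_two_sided)
    expect_equal(res$log2fc[i], ref$mean_a - ref$mean_b)
  }
  expect_equal(res$fdr, bh_fdr(res$p))
  expect_true(all(res$fdr >= res$p))
  expect_equal(res$signed_fc, signed_fold_change(res$log2fc))
})

test_that("label swap negates fold changes and t, leaves p unchanged", {
  set.seed(29)
  m <- matrix(rnorm(40 * 8, 6), nrow = 40,
              dimnames = list(paste0("g", 1:40), NULL))
  g1 <- rep(c("case", "control"), each = 4)
  g2 <- rep(c("control", "case"), each = 4)
  r1 <- de_test(m, g1); r2 <- de_test(m, g2)
  expect_equal(r1$log2fc, -r2$log2fc)
  expect_equal(r1$t_stat, -r2$t_stat)
  expect_equal(r1$p, r2$p)
})

test_that("zero-variance genes yield t=0, p=1 rather than NaN", {
  m <- rbind(flat = rep(5, 6), normal = rnorm(6))
  res <- de_test(m, rep(c("case", "control"), each = 3))
  expect_equal(res$t_stat[1], 0)
  expect_equal(res$p[1], 1)
  expect_false(anyNA(res$p))
})

test_that("threshold filter applies FDR and fold-change rules inclusively", {
  rec <- data.frame(
    gene_id = c("up1", "dn1", "nsfc", "nsfdr", "edge_up", "edge_dn"),
    signed_fc = c(1.3, -1.25, 1.1, 3.0, 1.2, -1.2),
    fdr = c(0.04, 0.04, 0.01, 0.06, 0.049, 0.049))
  sets <- threshold_filter(rec)
  expect_setequal(sets$up, c("up1", "edge_up"))
  expect_setequal(sets$down, c("dn1", "edge_dn"))
  expect_length(intersect(sets$up, sets$down), 0)
  expect_equal(unname(sets$directions[c("up1", "dn1")]), c("up", "down"))
})

test_that("threshold filter is monotone in its thresholds", {
  set.seed(41)
  rec <- data.frame(gene_id = paste0("g", 1:500),
                    signed_fc = signed_fold_change(rnorm(500)),
                    fdr = runif(500))
  base <- threshold_filter(rec, 0.05, 1.2)
  looser_fc <- threshold_filter(rec, 0.05, 1.05)
  looser_fdr <- threshold_filter(rec, 0.2, 1.2)
  expect_true(all(base$up %in% looser_fc$up))
  expect_true(all(base$down %in% looser_fc$down))
  expect_true(all(base$up %in% looser_fdr$up))
  expect_true(all(base$down %in% looser_fdr$down))
})

test_that("planted deregulation is recovered with few false positives", {
  # strong effects, adequately powered groups
  p <- expr_pair_sim_params(n_genes_universe = 2000, n_dereg_a = 200,
                            n_dereg_b = 200, n_overlap = 100,
                            effect_log2 = 2, noise_sd = 0.5,
                            samples_per_group = 10, seed = 53)
  s <- sim_expression_pair(p)
  # samples are simulated on a common scale, so test the DE machinery
  # directly; false positives are judged against the FDR the BH procedure
  # actually guarantees (~5% of calls), not an absolute handful
  res <- de_test(s$study_a$values, s$study_a$groups)
  sets <- threshold_filter(res)
  called <- c(sets$up, sets$down)
  planted <- names(s$truth$dereg_a)
  expect_gte(length(intersect(called, planted)), 190)
  expect_lte(length(setdiff(called, planted)) / length(called), 0.1)
  # planted directions are called correctly
  hit_up <- intersect(sets$up, planted)
  expect_true(all(s$truth$dereg_a[hit_up] == "up"))
})

test_that("delta-delta-Ct quantification matches hand arithmetic", {
  expect_equal(delta_delta_ct(20, 18, 21, 19), 1.0)  # ddCt = 0
  expect_equal(delta_delta_ct(20, 18, 22, 19), 2.0)  # ddCt = -1
  expect_equal(delta_delta_ct(24, 18, 21, 19), 2^-4) # ddCt = 4
  expect_error(delta_delta_ct(-1, 18, 21, 19), "positive")
})
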