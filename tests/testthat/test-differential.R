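test_that("pooled t matches the closed form and stats::t.test", {
  tab <- tiny_table(matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, ncol = 6,
                           byrow = FALSE))
  # build one site with a = (1,2,3) in oa, b = (4,5,6) in ctrl
  tab1 <- tiny_table()[1, ]
  tab1[, c("oa_1", "oa_2", "oa_3")] <- as.list(c(1, 2, 3))
  tab1[, c("ctrl_1", "ctrl_2", "ctrl_3")] <- as.list(c(4, 5, 6))
  res <- ttest_contrast(tab1, "oa", "ctrl")
  expect_equal(res$log2fc, -3)
  expect_equal(res$t_stat, -3.674, tolerance = 1e-3)
  expect_equal(res$p_value, 0.0213, tolerance = 1e-2)
  expect_equal(res$df, 4)
  # independent oracle
  oracle <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$t_stat, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-12)
})

test_that("identical groups and zero-variance ties follow the conventions", {
  tab1 <- tiny_table()[1, ]
  tab1[, sample_columns(tab1)] <- as.list(rep(c(1, 2, 3), 2))
  res <- ttest_contrast(tab1, "oa", "ctrl")
  expect_equal(res$log2fc, 0)
  expect_equal(res$p_value, 1)

  tab2 <- tiny_table()[1, ]
  tab2[, sample_columns(tab2)] <- as.list(rep(10, 6))
  res2 <- ttest_contrast(tab2, "oa", "ctrl")
  expect_true(res2$degenerate)
  expect_equal(res2$p_value, 1)  # equal means

  tab3 <- tiny_table()[1, ]
  tab3[, c("oa_1", "oa_2", "oa_3")] <- as.list(rep(10, 3))
  tab3[, c("ctrl_1", "ctrl_2", "ctrl_3")] <- as.list(rep(12, 3))
  res3 <- ttest_contrast(tab3, "oa", "ctrl")
  expect_true(res3$degenerate)
  expect_lt(res3$p_value, 1e-300)  # p -> 0 convention, flagged
})

test_that("sites with < 2 observations per group are not testable", {
  tab <- tiny_table()
  tab$oa_1[1] <- NA
  tab$oa_2[1] <- NA
  res <- ttest_contrast(tab, "oa", "ctrl")
  expect_true(is.na(res$p_value[1]))
  calls <- call_sensitivity(
    dplyr::mutate(res, q_value = NA_real_),
    primary = res$contrast[1], mode = "in_vitro")
  expect_equal(calls$call[1], "not_testable")
})

test_that("BH q-values match hand step-up arithmetic, order-invariantly", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.004), 0.004)  # single p: q = p
  expect_equal(fdr_adjust(numeric()), numeric())
  p <- c(0.001, 0.008, 0.039, 0.041, 0.5)
  # by hand: step-up q_i = min_{j >= i}( p_(j) * m / j )
  hand <- c(0.005, 0.02, 0.05125, 0.05125, 0.5)
  expect_equal(fdr_adjust(p), hand)
  shuf <- c(4, 1, 5, 2, 3)
  expect_equal(fdr_adjust(p[shuf]), hand[shuf])
})

test_that("permutation FDR is near-nominal under the exchangeable null", {
  set.seed(8)
  n <- 1000
  vals <- matrix(rnorm(n * 6, 25, 1), n, 6)
  tab <- tibble::tibble(accession = sprintf("P%04d", 1:n), position = 1:n,
                        residue = "S", localization_prob = 1,
                        multiplicity = 1L)
  tab <- dplyr::bind_cols(tab, tibble::as_tibble(stats::setNames(
    as.data.frame(vals), c("a_1", "a_2", "a_3", "b_1", "b_2", "b_3"))))
  res <- phospho_difftest(tab, "a", "b", fdr_method = "permutation",
                          n_perm = 200, seed = 9)
  expect_lte(mean(res$q_value < 0.05), 0.07)
})

test_that("sensitivity and protection calls follow the threshold logic", {
  mk <- function(q1, fc1, q2, fc2) {
    tibble::tibble(
      accession = "P1", position = 1L, residue = "S", multiplicity = 1L,
      contrast = c("pp_vs_ctrl", "pp_vs_ppoa"),
      n_a = 3L, n_b = 3L, log2fc = c(fc1, fc2), t_stat = 0, df = 4,
      p_value = c(q1, q2) / 2, degenerate = FALSE, q_value = c(q1, q2))
  }
  pol <- call_policy()
  protected <- call_sensitivity(mk(0.01, -2, 0.004, -1.5),
                                primary = "pp_vs_ctrl",
                                protection = "pp_vs_ppoa", policy = pol)
  expect_equal(protected$call, "protected_candidate")
  sens_only <- call_sensitivity(mk(0.01, -2, 0.8, -1.5),
                                primary = "pp_vs_ctrl",
                                protection = "pp_vs_ppoa", policy = pol)
  expect_equal(sens_only$call, "sensitive")
  inert <- call_sensitivity(mk(0.9, 0.3, 0.9, 0), primary = "pp_vs_ctrl",
                            protection = "pp_vs_ppoa", policy = pol)
  expect_equal(inert$call, "insensitive")  # inside the -0.5..0.5 band
  expect_error(call_sensitivity(mk(0.9, 0.3, 0.9, 0), primary = "nope"),
               "nope")
  # strong flag uses the linear fold-change >= 3 threshold
  strong <- call_sensitivity(mk(0.01, -log2(3), 0.5, 0),
                             primary = "pp_vs_ctrl", policy = pol)
  expect_true(strong$strong)
  weakfc <- call_sensitivity(mk(0.01, -1.5, 0.5, 0),
                             primary = "pp_vs_ctrl", policy = pol)
  expect_false(weakfc$strong)
})

test_that("lowering the q threshold never adds a sensitive call", {
  set.seed(5)
  n <- 200
  res <- tibble::tibble(
    accession = sprintf("P%03d", 1:n), position = 1:n, residue = "S",
    multiplicity = 1L, contrast = "c", n_a = 3L, n_b = 3L,
    log2fc = rnorm(n), t_stat = 0, df = 4,
    p_value = runif(n), degenerate = FALSE, q_value = runif(n))
  sens_at <- function(thr) {
    calls <- call_sensitivity(res, primary = "c",
                              policy = call_policy(q_threshold = thr))
    site_keys(calls[calls$call == "sensitive", ])
  }
  loose <- sens_at(0.10)
  tight <- sens_at(0.02)
  expect_true(all(tight %in% loose))
})

test_that("in vivo mode calls preserved phosphorylation (positive log2fc)", {
  res <- tibble::tibble(
    accession = "P1", position = 1:2, residue = "S", multiplicity = 1L,
    contrast = "oa_vs_starved", n_a = 3L, n_b = 3L,
    log2fc = c(2, -2), t_stat = 0, df = 4, p_value = 0.001,
    degenerate = FALSE, q_value = 0.01)
  calls <- call_sensitivity(res, primary = "oa_vs_starved", mode = "in_vivo")
  expect_equal(calls$call, c("sensitive", "unchanged"))
})
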