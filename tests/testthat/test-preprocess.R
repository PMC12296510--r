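test_that("localization filter keeps the >= 0.75 boundary", {
  tab <- tiny_table()
  tab$localization_prob <- c(0.9, 0.75, 0.74)
  kept <- suppressMessages(filter_localization(tab))
  expect_equal(nrow(kept), 2)
  expect_equal(kept$localization_prob, c(0.9, 0.75))
  expect_equal(filter_localization(tab, min_prob = 0), tab)
  none <- suppressMessages(filter_localization(tab, min_prob = 1))
  expect_equal(nrow(none), 0)
  # downstream stages accept the empty table
  expect_equal(nrow(suppressMessages(floor_filter(none))), 0)
})

test_that("intensity floor is strict and cell-wise", {
  tab <- tiny_table(matrix(c(4.9, rep(21, 17)), nrow = 3))
  out <- suppressMessages(floor_filter(tab, floor_log2 = 5))
  m <- pptarget:::values_matrix(out)
  expect_true(is.na(m[1, 1]))
  expect_equal(sum(is.na(m)), 1)
  at_floor <- tiny_table(matrix(5, nrow = 3, ncol = 6))
  expect_equal(floor_filter(at_floor), at_floor)  # 5.0 kept, row-wise intact
  expect_equal(floor_filter(tab, floor_log2 = -Inf), tab)
})

test_that("SVD completion reconstructs masked low-rank entries", {
  # rank-1 oracle: outer product, masked cell (2,2) must come back as 10
  vals <- outer(c(1, 2, 3), c(4, 5, 6))
  truth <- vals[2, 2]
  vals[2, 2] <- NA
  tab <- tiny_table(cbind(vals, vals))  # two conditions, same structure
  names(tab)[6:11] <- c("a_1", "a_2", "a_3", "b_1", "b_2", "b_3")
  out <- impute_svd(tab, rank = 1)
  expect_equal(pptarget:::values_matrix(out)[2, 2], truth, tolerance = 1e-6)

  # noiseless rank-2 200 x 6 (one condition of 6 replicates), 5% masked;
  # the constant offset is itself a rank-1 component
  set.seed(4)
  big <- outer(rnorm(200), rnorm(6)) + 25
  mask <- matrix(runif(1200) < 0.05, 200, 6)
  # keep >= 2 observed per row so every cell is eligible
  mask[rowSums(mask) > 4, ] <- FALSE
  masked <- big
  masked[mask] <- NA
  tab2 <- tibble::tibble(accession = sprintf("P%03d", 1:200),
                         position = 1:200, residue = "S",
                         localization_prob = 1, multiplicity = 1L)
  tab2 <- dplyr::bind_cols(tab2, tibble::as_tibble(
    stats::setNames(as.data.frame(masked), paste0("g_", 1:6))))
  out2 <- impute_svd(tab2, rank = 2)
  err <- abs(pptarget:::values_matrix(out2)[mask] - big[mask])
  expect_lt(median(err), 1e-3)
})

test_that("imputation never alters observed values; no-missing is identity", {
  tab <- tiny_table()
  expect_identical(impute_svd(tab), tab)
  expect_identical(impute_downshift(tab, seed = 1), tab)
  holey <- tab
  holey$ctrl_2[1] <- NA
  obs_before <- pptarget:::values_matrix(holey)
  out <- impute_downshift(impute_svd(holey), seed = 1)
  m <- pptarget:::values_matrix(out)
  expect_identical(m[!is.na(obs_before)], obs_before[!is.na(obs_before)])
  expect_false(anyNA(m))
})

test_that("downshift draws match the shifted-normal closed form", {
  # one column with mean 25, sd 2 -> imputed ~ N(25 - 1.8*2, (0.3*2)^2)
  set.seed(2)
  n_obs <- 2000
  n_miss <- 10000
  obs <- rnorm(n_obs, 25, 2)
  obs <- (obs - mean(obs)) / sd(obs) * 2 + 25  # exact moments
  vals <- matrix(c(obs, rep(NA, n_miss)), ncol = 1)
  tab <- tibble::tibble(accession = sprintf("P%05d", seq_len(n_obs + n_miss)),
                        position = seq_len(n_obs + n_miss), residue = "S",
                        localization_prob = 1, multiplicity = 1L,
                        cond_1 = vals[, 1])
  out <- impute_downshift(tab, width = 0.3, shift = 1.8, seed = 11)
  imp <- out$cond_1[(n_obs + 1):(n_obs + n_miss)]
  expect_equal(mean(imp), 25 - 1.8 * 2, tolerance = 0.02 / (25 - 3.6))
  expect_equal(sd(imp), 0.6, tolerance = 0.05)
  # >= 96% of draws below the column mean (shift 1.8)
  expect_gte(mean(imp < 25), 0.96)
  # determinism
  out2 <- impute_downshift(tab, width = 0.3, shift = 1.8, seed = 11)
  expect_identical(out$cond_1, out2$cond_1)
})

test_that("downshift refuses columns without a stable mean/SD", {
  tab <- tiny_table()
  tab$ctrl_1 <- c(20, NA, NA)  # 1 observed, 2 missing
  expect_error(impute_downshift(tab, seed = 1), "fewer than 3")
})

test_that("protein normalization is a log-ratio and reports dropouts", {
  tab <- tiny_table(matrix(20, 3, 6))
  prot <- tibble::tibble(accession = "P12345",
                         ctrl_1 = 18, ctrl_2 = 18, ctrl_3 = 18,
                         oa_1 = 18, oa_2 = 18, oa_3 = 18)
  out <- suppressMessages(normalize_to_protein(tab, prot))
  expect_equal(nrow(out), 2)  # Q99999 dropped
  expect_true(all(pptarget:::values_matrix(out) == 2))
  expect_equal(attr(out, "not_normalizable"), "Q99999|7|S")
  # constant protein across samples leaves fold changes unchanged
  fc_raw <- rowMeans(pptarget:::values_matrix(tab)[1:2, 4:6]) -
    rowMeans(pptarget:::values_matrix(tab)[1:2, 1:3])
  fc_norm <- rowMeans(pptarget:::values_matrix(out)[, 4:6]) -
    rowMeans(pptarget:::values_matrix(out)[, 1:3])
  expect_equal(fc_norm, fc_raw)
  # sample mismatch errors
  expect_error(normalize_to_protein(tab, prot[, 1:5]), "oa_3")
})

test_that("re-running the filters on their own output is a no-op", {
  tab <- tiny_table()
  tab$localization_prob <- c(0.9, 0.74, 0.8)
  tab$ctrl_1[1] <- 3
  once <- suppressMessages(floor_filter(filter_localization(tab)))
  twice <- suppressMessages(floor_filter(filter_localization(once)))
  expect_identical(once, twice)
})

test_that("effect estimates survive imputation for lightly missing sites", {
  # parameter recovery: known effect, MNAR missingness, full chain
  pr <- simulate_proteome(n_proteins = 60, length_range = c(300, 700),
                          seed = 21)
  sim <- simulate_phospho_data(pr, n_sites = 500, seed = 22,
                               frac_low_localization = 0)
  pp <- suppressMessages(preprocess_phospho(sim$table, seed = 23))
  truth <- tidy(sim$truth)
  truth$key <- site_keys(truth)
  raw <- pptarget:::values_matrix(sim$table)
  light <- rowSums(is.na(raw[, 1:3])) <= 1 & rowSums(is.na(raw[, 4:6])) <= 1
  dt <- phospho_difftest(pp, "treated", "control")
  dt$key <- site_keys(dt)
  joined <- dplyr::inner_join(truth[light & truth$sensitive_treated, ],
                              dt, by = "key")
  expect_gt(nrow(joined), 10)
  expect_lt(abs(mean(joined$log2fc - joined$effect_treated)), 0.25)
})
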