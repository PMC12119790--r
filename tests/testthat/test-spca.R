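# Difference scores, standardization, sparse PCA and loading stability.

make_paired_table <- function(n = 12, effect = 0, seed = 1) {
  set.seed(seed)
  feats <- kinematic_features()
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    base <- rnorm(length(feats), 10, 1)
    on <- base + effect + rnorm(length(feats), 0, 0.1)
    rbind(
      data.frame(patient_id = sprintf("P%02d", i), visit_id = 1,
                 task = "finger_tapping", condition = "OFF",
                 age_at_visit = 60, as.list(setNames(base, feats))),
      data.frame(patient_id = sprintf("P%02d", i), visit_id = 1,
                 task = "finger_tapping", condition = "ON",
                 age_at_visit = 60, as.list(setNames(on, feats)))
    )
  }))
  rownames(rows) <- NULL
  rows
}

test_that("difference scores pair ON and OFF within patient-visit", {
  tab <- make_paired_table(8)
  dm <- compute_differences(tab, "finger_tapping")
  expect_equal(dim(dm), c(8L, 20L))
  # equal ON and OFF values give an all-zero matrix
  tab0 <- tab
  tab0[tab0$condition == "ON", kinematic_features()] <-
    tab0[tab0$condition == "OFF", kinematic_features()]
  expect_true(all(compute_differences(tab0, "finger_tapping") == 0))
  # a visit missing its ON recording is dropped
  tab2 <- tab[-2, ]  # drop P01's ON row
  expect_message(dm2 <- compute_differences(tab2, "finger_tapping"),
                 "unmatched")
  expect_equal(nrow(dm2), 7L)
})

test_that("a planted positive effect gives sign-consistent difference columns", {
  tab <- make_paired_table(100, effect = 0.4, seed = 3)
  dm <- compute_differences(tab, "finger_tapping")
  pos <- colSums(dm > 0)
  # sign test at n = 100 pairs: essentially all columns dominated by +
  expect_true(all(vapply(pos, function(k)
    binom.test(k, 100, 0.5)$p.value, numeric(1)) < 0.01))
})

test_that("standardization yields exact zero means and unit variances, idempotently", {
  set.seed(4)
  m <- matrix(rnorm(200, 5, 3), 20, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  z <- standardize(m)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 10), tolerance = 1e-12)
  z2 <- standardize(z)
  expect_equal(unclass(z2)[, ], unclass(z)[, ], tolerance = 1e-12)
  m[, 3] <- 7  # constant column is dropped with a warning
  expect_warning(z3 <- standardize(m), "f3")
  expect_equal(ncol(z3), 9L)
})

test_that("sparse PCA is deterministic and honours the penalty limit cases", {
  d <- planted_block_design()
  pf <- plant_factor_structure(200, d$blocks, noise_sd = 0.4, seed = 7)
  z <- standardize(pf$x)
  f1 <- fit_sparse_pca(z, 5)
  f2 <- fit_sparse_pca(z, 5)
  expect_identical(f1$loadings, f2$loadings)
  expect_true(any(f1$loadings == 0))               # penalty produces zeros
  # penalty -> 0 on noiseless rank-1 data: first component takes everything
  x1 <- outer(rnorm(60), c(3, 2, 1, rep(0, 7)))
  colnames(x1) <- paste0("f", 1:10)
  suppressWarnings(fr <- fit_sparse_pca(x1, 2, l1_penalty = 1e-9))
  expect_gte(fr$ev_fraction[1], 0.99)
  # a destructive penalty drops all-zero components with a warning
  expect_error(suppressWarnings(fit_sparse_pca(z, 2, l1_penalty = 1e6)),
               class = "kinemed_validation_error")
})

test_that("adjusted explained variance is ordered, bounded and sums below one", {
  d <- planted_block_design()
  pf <- plant_factor_structure(250, d$blocks, noise_sd = 0.5, seed = 9)
  fit <- fit_sparse_pca(standardize(pf$x), 6)
  expect_true(all(diff(fit$ev_fraction) <= 1e-8))
  expect_true(all(fit$ev_fraction >= 0 & fit$ev_fraction <= 1))
  expect_lte(sum(fit$ev_fraction), 1 + 1e-8)
  expect_true(!is.unsorted(fit$cum_var))
  # sign convention: each component's largest-magnitude loading is positive
  for (j in seq_len(ncol(fit$loadings))) {
    v <- fit$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("the elbow rule finds planted structure and degrades gracefully", {
  d <- planted_block_design()
  pf <- plant_factor_structure(300, d$blocks, block_strengths = c(1.2, 0.9, 0.7),
                               noise_sd = 0.4, seed = 21)
  fit <- fit_sparse_pca(standardize(pf$x), 8)
  expect_identical(select_n_components(fit), 3L)
  expect_identical(select_n_components(fit, override = 5), 5L)
  # isotropic noise: no elbow, fall back to the configured minimum
  set.seed(10)
  iso <- matrix(rnorm(300 * 20), 300, 20,
                dimnames = list(NULL, kinematic_features()))
  fit_iso <- fit_sparse_pca(standardize(iso), 8)
  expect_warning(k <- select_n_components(fit_iso), "elbow undefined")
  expect_identical(k, 1L)
})

test_that("support recovery matches the planted blocks", {
  d <- planted_block_design()
  pf <- plant_factor_structure(300, d$blocks, block_strengths = c(1.2, 0.9, 0.7),
                               noise_sd = 0.4, seed = 33)
  fit <- fit_sparse_pca(standardize(pf$x), 8)
  for (j in 1:3) expect_gte(support_jaccard(fit, j, d$blocks), 0.75)
})

test_that("loading stability obeys identity, antisymmetry and joint-zero exclusion", {
  d <- planted_block_design()
  pf <- plant_factor_structure(200, d$blocks, noise_sd = 0.4, seed = 13)
  fit <- fit_sparse_pca(standardize(pf$x), 3)
  st <- loading_stability(fit, fit, 1)
  expect_equal(st$r, 1, tolerance = 1e-12)
  expect_equal(st$n_features + length(st$excluded), 20L)
  neg <- fit
  neg$loadings[, 1] <- -neg$loadings[, 1]
  expect_equal(loading_stability(fit, neg, 1)$r, -1, tolerance = 1e-12)
  # jointly-zero features are excluded, features nonzero in one task are kept
  expect_true(all(fit$loadings[st$excluded, 1] == 0))
  mixed <- fit
  mixed$loadings[st$excluded[1], 1] <- 0.5
  st2 <- loading_stability(fit, mixed, 1)
  expect_equal(st2$n_features, st$n_features + 1L)
})

test_that("stability r is invariant to sign flips once loadings are renormalised", {
  d <- planted_block_design()
  pA <- plant_factor_structure(250, d$blocks, block_loadings = d$block_loadings,
                               noise_sd = 0.4, seed = 14, features = d$features)
  pB <- plant_factor_structure(250, d$blocks, block_loadings = d$block_loadings,
                               noise_sd = 0.4, seed = 15, features = d$features)
  fA <- fit_sparse_pca(standardize(pA$x), 3)
  # refitting the sign-flipped data yields the same normalised loadings
  fB1 <- fit_sparse_pca(standardize(pB$x), 3)
  fB2 <- fit_sparse_pca(-standardize(pB$x), 3)
  expect_equal(fB1$loadings, fB2$loadings, tolerance = 1e-4)
  expect_equal(loading_stability(fA, fB1, 1)$r,
               loading_stability(fA, fB2, 1)$r, tolerance = 1e-4)
})

test_that("top loadings are ranked by magnitude with canonical tie-breaks", {
  d <- planted_block_design()
  pf <- plant_factor_structure(300, d$blocks, block_strengths = c(1.2, 0.9, 0.7),
                               noise_sd = 0.3, seed = 17)
  fit <- fit_sparse_pca(standardize(pf$x), 3)
  tl <- top_loadings(fit, 1, k = 4)
  expect_equal(nrow(tl), 4L)
  expect_true(all(tl$feature %in% d$blocks$speed))
  expect_true(all(diff(abs(tl$loading)) <= 1e-12))
  # k beyond the nonzero count returns only nonzero loadings
  tl_all <- top_loadings(fit, 1, k = 100)
  expect_true(all(tl_all$loading != 0))
  # all-zero component: empty report with warning
  zfit <- fit
  zfit$loadings[, 2] <- 0
  expect_warning(tl0 <- top_loadings(zfit, 2), "no nonzero")
  expect_equal(nrow(tl0), 0L)
})
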