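# Mixed models: closed-form oracles, limits, and equivariances.

test_that("balanced one-way REML matches the closed-form ANOVA estimators", {
  d <- make_lmm_data(n_trees_per_trt = 5, n_leaves = 12, sd_tree = 2,
                     sd_resid = 1, effect = 1, seed = 51)
  fit <- fit_lmm(d, "value", include_date = FALSE)
  # ANOVA oracle: within-tree mean square and treatment-adjusted
  # between-tree mean square, computed directly
  n <- 12; g <- 10
  tree_means <- tapply(d$value, d$tree_id, mean)
  trt_of_tree <- tapply(as.character(d$treatment), d$tree_id, `[`, 1)
  trt_means <- tapply(tree_means, trt_of_tree, mean)
  ssw <- sum((d$value - tree_means[as.character(d$tree_id)])^2)
  msw <- ssw / (g * (n - 1))
  ssb <- n * sum((tree_means - trt_means[trt_of_tree])^2)
  msb <- ssb / (g - 2)
  sigma2_tree_oracle <- (msb - msw) / n
  vc <- fit$varcomp
  expect_equal(vc$variance[vc$term == "residual"], msw, tolerance = 1e-6)
  expect_equal(vc$variance[vc$term == "tree"], sigma2_tree_oracle,
               tolerance = 1e-6)
})

test_that("zero-variance grouping collapses to ordinary least squares", {
  d <- make_lmm_data(n_trees_per_trt = 6, n_leaves = 10, sd_tree = 0,
                     sd_resid = 0.3, effect = 0.5, seed = 52)
  fit <- fit_lmm(d, "value", include_date = FALSE)
  ols <- stats::lm(value ~ treatment, data = d)
  expect_lt(abs(treatment_effect(fit)$estimate - stats::coef(ols)[2]), 1e-6)
  expect_lt(fit$varcomp$variance[fit$varcomp$term == "tree"], 1e-4)
  expect_true(fit$singular)
})

test_that("Satterthwaite df reaches the classical n - 2 when tree variance is exactly zero", {
  # construct tree means exactly equal within treatment so the between-tree
  # variance estimate hits the boundary at 0
  resid_pattern <- c(-2, -1, 0, 1, 2)
  rows <- list()
  for (trt in c("aCO2", "eCO2")) for (tr in 1:4) {
    rows[[length(rows) + 1]] <- data.frame(
      treatment = trt, tree_id = sprintf("%s%d", trt, tr),
      date = "2023-07-25", array_id = trt,
      value = (trt == "eCO2") * 3 + resid_pattern)
  }
  d <- do.call(rbind, rows)
  fit <- fit_lmm(d, "value", include_date = FALSE)
  eff <- treatment_effect(fit)
  expect_equal(eff$df, nrow(d) - 2, tolerance = 0.1)
  # and the t test matches the classical two-sample equal-variance test
  tt <- stats::t.test(value ~ treatment, data = d, var.equal = TRUE)
  expect_equal(eff$t, -tt$statistic[[1]], tolerance = 1e-6)
})

test_that("Satterthwaite df is invariant to rescaling the response", {
  d <- make_lmm_data(n_trees_per_trt = 4, n_leaves = 6, sd_tree = 1,
                     sd_resid = 1, effect = 0.5, seed = 53,
                     dates = c("d1", "d2"), sd_date = 0.5)
  f1 <- fit_lmm(d, "value")
  d$value <- d$value * 1000
  f2 <- fit_lmm(d, "value")
  expect_equal(treatment_effect(f1)$df, treatment_effect(f2)$df,
               tolerance = 1e-4)
  expect_equal(treatment_effect(f2)$estimate,
               1000 * treatment_effect(f1)$estimate, tolerance = 1e-6)
})

test_that("adding a constant shifts only the intercept", {
  d <- make_lmm_data(n_trees_per_trt = 4, n_leaves = 6, sd_tree = 1,
                     sd_resid = 1, effect = 0.5, seed = 54,
                     dates = c("d1", "d2"), sd_date = 0.5)
  f1 <- fit_lmm(d, "value")
  d$value <- d$value + 100
  f2 <- fit_lmm(d, "value")
  ic <- function(f) f$coefficients$estimate[f$coefficients$term == "(Intercept)"]
  expect_equal(ic(f2), ic(f1) + 100, tolerance = 1e-6)
  expect_equal(treatment_effect(f2)$estimate, treatment_effect(f1)$estimate,
               tolerance = 1e-6)
})

test_that("the study-shaped design yields a small tree-limited treatment df near 6", {
  # tree SD raised so the tree variance component is clearly resolved; with
  # a boundary (zero) tree variance the df is no longer tree-limited
  set <- simulate_campaign(leaf_sim_config(seed = 55, sd_tree = 0.15))
  tab <- index_table(set, "PSRI")
  fit <- fit_lmm(tab, "value")
  df <- treatment_effect(fit)$df
  expect_gt(df, 4); expect_lt(df, 8)
})

test_that("a constant response is handled without numerical failure", {
  d <- make_lmm_data(n_trees_per_trt = 3, n_leaves = 4, seed = 56)
  d$value <- 5
  fit <- fit_lmm(d, "value")
  expect_equal(treatment_effect(fit)$estimate, 0)
  expect_true(all(fit$varcomp$variance == 0))
})

test_that("REML sits at a local optimum of the criterion", {
  d <- make_lmm_data(n_trees_per_trt = 4, n_leaves = 8, sd_tree = 1.5,
                     sd_resid = 1, effect = 1, seed = 57,
                     dates = c("d1", "d2"), sd_date = 0.8)
  fit <- fit_lmm(d, "value")
  m <- fit$model
  # perturb the variance parameters around the optimum
  theta <- lme4::getME(m, "theta")
  devf <- update(m, devFunOnly = TRUE)
  dev_opt <- devf(theta)
  for (i in seq_along(theta)) for (eps in c(-0.05, 0.05)) {
    th <- theta; th[i] <- max(th[i] + eps, 0)
    expect_gte(devf(th), dev_opt - 1e-6)
  }
})

test_that("misuse of the design is rejected", {
  d <- make_lmm_data(seed = 58)
  d$treatment[1] <- "eCO2"  # treatment varies within a tree
  expect_error(fit_lmm(d, "value"), "varies within")
  expect_error(fit_lmm(d[0, ], "value"), "usable|at least")
  expect_error(fit_lmm(d, "missing_col"), "lacks columns")
})

test_that("fit_all_indices produces one converged row per index with variance components", {
  set <- simulate_campaign(tiny_config(seed = 59,
                                       dates = c("2023-07-25", "2023-08-10")))
  tab <- index_table(set)
  fits <- fit_all_indices(tab[tab$index_name != "INTEGRATED", ])
  expect_equal(sort(fits$index), sort(setdiff(index_names(), "INTEGRATED")))
  expect_true(all(is.finite(fits$eco2_effect)))
  expect_true(all(fits$var_residual >= 0))
  expect_true(all(fits$n == n_spectra(set)))
})

test_that("satterthwaite_contrast on the treatment contrast matches the summary", {
  d <- make_lmm_data(n_trees_per_trt = 4, n_leaves = 6, sd_tree = 1,
                     sd_resid = 1, effect = 1, seed = 60,
                     dates = c("d1", "d2"), sd_date = 0.5)
  fit <- fit_lmm(d, "value")
  ct <- satterthwaite_contrast(fit, c(0, 1))
  eff <- treatment_effect(fit)
  expect_equal(ct$estimate, eff$estimate, tolerance = 1e-8)
  expect_equal(ct$df, eff$df, tolerance = 1e-6)
  expect_equal(ct$p, eff$p, tolerance = 1e-8)
})

test_that("PC score models report univariate and pooled treatment effects coherently", {
  set <- simulate_campaign(tiny_config(seed = 61,
                                       dates = c("2023-07-25", "2023-08-10")))
  pca <- suppressMessages(pca_fit(set, 4))
  fits <- fit_pcs(pca, 4)
  expect_named(fits$univariate, paste0("PC", 1:4))
  expect_s3_class(fits$pooled, "lmm_fit")
  expect_equal(fits$pooled$n, 4 * n_spectra(set))
  # identical scores across PCs make the pooled effect equal each univariate
  sc <- pca_scores(pca)
  for (pc in paste0("PC", 2:4)) sc[[pc]] <- sc$PC1
  same <- fit_pcs(sc, 4)
  expect_equal(treatment_effect(same$pooled)$estimate,
               treatment_effect(same$univariate$PC1)$estimate,
               tolerance = 1e-6)
})
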