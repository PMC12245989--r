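# Nested random-intercept linear mixed models.
#
# The study model is
#
#   response ~ CO2 + (1 | tree) + (1 | tree:date)
#
# estimated by REML, with Satterthwaite degrees of freedom for the fixed
# effects (lme4/lmerTest). The aCO2 treatment is the reference level, so the
# intercept is the aCO2 mean and the treatment coefficient the eCO2 effect.
# With one observation per tree:date cell the tree:date and residual
# variances are only weakly identified; boundary (zero-variance) fits are
# reported with a `singular` flag rather than errored.

lmm_data <- function(data, response) {
  need <- c(response, "treatment", "tree_id", "date")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stopf("data lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  d <- data.frame(y = data[[response]],
                  treatment = factor(data$treatment,
                                     levels = c("aCO2", "eCO2")),
                  tree_id = factor(data$tree_id),
                  date = factor(data$date),
                  array_id = factor(data$array_id %||%
                                      rep(NA_character_, nrow(data))))
  n_undef <- sum(!is.finite(d$y))
  d <- d[is.finite(d$y) & !is.na(d$treatment), , drop = FALSE]
  attr(d, "n_dropped") <- n_undef
  d
}

#' Fit the study's linear mixed model
#'
#' `response ~ treatment + (1 | tree_id) + (1 | tree_id:date)` by REML with
#' Satterthwaite degrees of freedom. `include_date = FALSE` drops the nested
#' tree-by-date intercept (one-way random-intercept model);
#' `include_array = TRUE` adds an array-level random intercept.
#'
#' A response with zero variance is returned as a degenerate fit (zero
#' effect, zero variance components) without invoking the optimizer.
#'
#' @param data Data frame with the response column plus `treatment`,
#'   `tree_id`, `date` (and `array_id` if `include_array`).
#' @param response Name of the response column.
#' @param include_date Include the nested `(1 | tree_id:date)` term.
#' @param include_array Also include `(1 | array_id)` (off by default; in
#'   the study design it explains no variance beyond tree identity).
#' @return Object of class `lmm_fit`: `coefficients` (estimate, SE, df, t, p
#'   per fixed effect), `varcomp` (variance and SD for tree, tree:date,
#'   residual), `n`, `reml_criterion`, `singular`, `model` (the underlying
#'   `lmerModLmerTest` or `lm` object).
#' @export
fit_lmm <- function(data, response, include_date = TRUE,
                    include_array = FALSE) {
  d <- lmm_data(data, response)
  if (nrow(d) == 0) stopf("no usable observations for response '%s'", response)
  if (nlevels(droplevels(d$tree_id)) < 2) stopf("need at least 2 trees")
  mix <- tapply(d$treatment, d$tree_id, function(x) length(unique(x)))
  if (any(mix > 1, na.rm = TRUE)) {
    stopf("treatment varies within a tree; the design must nest trees in treatments")
  }
  vc_names <- c("tree", if (include_date) "tree:date",
                if (include_array) "array", "residual")
  if (stats::var(d$y) == 0) {
    coefs <- data.frame(
      term = c("(Intercept)", "treatmenteCO2"),
      estimate = c(d$y[1], 0), se = c(0, 0), df = c(NA_real_, NA_real_),
      t = c(NA_real_, NA_real_), p = c(NA_real_, NA_real_))
    vc <- data.frame(term = vc_names, variance = 0, sd = 0)
    return(structure(list(coefficients = coefs, varcomp = vc, n = nrow(d),
                          n_dropped = attr(d, "n_dropped"),
                          reml_criterion = NA_real_, singular = TRUE,
                          response = response, model = NULL),
                     class = "lmm_fit"))
  }
  terms <- c("(1 | tree_id)",
             if (include_date) "(1 | tree_id:date)",
             if (include_array) "(1 | array_id)")
  form <- stats::as.formula(paste("y ~ treatment +",
                                  paste(terms, collapse = " + ")))
  diags <- character(0)
  m <- withCallingHandlers(
    lmerTest::lmer(form, data = d, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     calc.derivs = TRUE)),
    warning = function(w) {
      # boundary and near-boundary fits trip lme4's gradient/Hessian checks;
      # they are recorded on the fit as diagnostics, not raised
      diags <<- c(diags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(m, ddf = "Satterthwaite")
  co <- s$coefficients
  coefs <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], df = co[, "df"],
                      t = co[, "t value"], p = co[, "Pr(>|t|)"],
                      row.names = NULL)
  vc_raw <- as.data.frame(lme4::VarCorr(m))
  lookup <- c(tree_id = "tree", `tree_id:date` = "tree:date",
              array_id = "array", Residual = "residual")
  vc <- data.frame(term = unname(lookup[vc_raw$grp]),
                   variance = vc_raw$vcov, sd = vc_raw$sdcor)
  vc <- vc[match(vc_names, vc$term), ]
  rownames(vc) <- NULL
  structure(
    list(coefficients = coefs, varcomp = vc, n = nrow(d),
         n_dropped = attr(d, "n_dropped"),
         reml_criterion = stats::deviance(m, REML = TRUE),
         singular = lme4::isSingular(m), convergence_warnings = diags,
         response = response, model = m),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s, n = %d%s\n", x$response %||% "response", x$n,
              if (isTRUE(x$singular)) " [boundary fit]" else ""))
  print(x$coefficients, digits = 4)
  print(x$varcomp, digits = 4)
  invisible(x)
}

#' Treatment effect row of a fit
#' @param fit An `lmm_fit`.
#' @return One-row data frame (estimate, se, df, t, p) for the eCO2 effect.
#' @export
treatment_effect <- function(fit) {
  fit$coefficients[fit$coefficients$term == "treatmenteCO2", ]
}

#' Satterthwaite test of a fixed-effect contrast
#'
#' @param fit An `lmm_fit` from [fit_lmm()].
#' @param contrast Numeric contrast over the fixed effects (default: the
#'   treatment effect).
#' @return List with `estimate`, `se`, `df`, `t`, `p`. When the underlying
#'   information matrix is unusable the df is NA and p falls back to the
#'   normal approximation, with a warning.
#' @export
satterthwaite_contrast <- function(fit, contrast = c(0, 1)) {
  if (is.null(fit$model)) stopf("degenerate fit has no model to test")
  res <- tryCatch(
    lmerTest::contest1D(fit$model, contrast, ddf = "Satterthwaite"),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$df)) {
    warning("Satterthwaite information matrix unusable; normal approximation used")
    est <- sum(contrast * lme4::fixef(fit$model))
    se <- sqrt(as.numeric(t(contrast) %*% as.matrix(stats::vcov(fit$model))
                          %*% contrast))
    z <- est / se
    return(list(estimate = est, se = se, df = NA_real_, t = z,
                p = 2 * stats::pnorm(-abs(z))))
  }
  list(estimate = res$Estimate, se = res$`Std. Error`, df = res$df,
       t = res$`t value`, p = res$`Pr(>|t|)`)
}

#' Fit the study model to every vegetation index
#'
#' One mixed-model row per index in the long table from [index_table()].
#' Undefined index values are dropped listwise per index (count reported);
#' an index with no defined values is skipped with a message.
#'
#' @param index_tbl Long table from [index_table()].
#' @param alpha Significance level for the flag column.
#' @return Data frame of class `index_lmm_table`: one row per index with the
#'   aCO2 mean and SE, eCO2 effect and SE, t, Satterthwaite df and p,
#'   significance flag, and the three variance components with SDs.
#' @export
fit_all_indices <- function(index_tbl, alpha = 0.05) {
  rows <- list()
  for (nm in unique(index_tbl$index_name)) {
    sub <- index_tbl[index_tbl$index_name == nm, ]
    if (all(!is.finite(sub$value))) {
      message(sprintf("fit_all_indices: %s has no defined values; skipped", nm))
      next
    }
    fit <- fit_lmm(sub, "value")
    ic <- fit$coefficients[fit$coefficients$term == "(Intercept)", ]
    ef <- treatment_effect(fit)
    vc <- fit$varcomp
    rows[[nm]] <- data.frame(
      index = nm,
      aco2_mean = ic$estimate, aco2_se = ic$se,
      eco2_effect = ef$estimate, effect_se = ef$se,
      t = ef$t, df = ef$df, p = ef$p,
      significant = is.finite(ef$p) && ef$p < alpha,
      var_tree = vc$variance[vc$term == "tree"],
      sd_tree = vc$sd[vc$term == "tree"],
      var_tree_date = vc$variance[vc$term == "tree:date"],
      sd_tree_date = vc$sd[vc$term == "tree:date"],
      var_residual = vc$variance[vc$term == "residual"],
      sd_residual = vc$sd[vc$term == "residual"],
      n = fit$n, n_undefined = fit$n_dropped,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("index_lmm_table", "data.frame"))
}

#' Mixed models for principal component scores
#'
#' Standardizes each of the first `n_components` PC score columns, fits the
#' study model to each, and additionally fits one pooled model on the
#' stacked standardized scores with a single common treatment effect (the
#' "multivariate" summary: one intercept and one eCO2 effect across PCs).
#'
#' @param model A `pca_model` fitted on a `spectrum_set` (so scores carry
#'   metadata), or a data frame from [pca_scores()].
#' @param n_components How many leading PCs to model.
#' @return List with `univariate` (named list of `lmm_fit`) and `pooled`
#'   (a single `lmm_fit` on the stacked scores).
#' @export
fit_pcs <- function(model, n_components = 4) {
  scores <- if (inherits(model, "pca_model")) pca_scores(model) else model
  pcs <- paste0("PC", seq_len(n_components))
  missing_pcs <- setdiff(pcs, names(scores))
  if (length(missing_pcs)) {
    stopf("scores lack columns: %s", paste(missing_pcs, collapse = ", "))
  }
  for (pc in pcs) scores[[pc]] <- as.numeric(scale(scores[[pc]]))
  uni <- lapply(pcs, function(pc) fit_lmm(scores, pc))
  names(uni) <- pcs
  long <- do.call(rbind, lapply(pcs, function(pc) {
    data.frame(score = scores[[pc]], pc = pc,
               treatment = scores$treatment, tree_id = scores$tree_id,
               date = scores$date, array_id = scores$array_id,
               stringsAsFactors = FALSE)
  }))
  pooled <- fit_lmm(long, "score")
  list(univariate = uni, pooled = pooled)
}
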