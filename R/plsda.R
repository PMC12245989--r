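# Partial least squares discriminant analysis.
#
# PLS1 via NIPALS deflation: the centred/scaled spectra matrix is regressed
# on the 0/1 class code (aCO2 = 0, eCO2 = 1); class prediction thresholds the
# continuous prediction at 0.5. Cumulative wavelength importance over the
# retained components is sum_k |w_k| * v_k, where w_k is the k-th X-weight
# vector and v_k the fraction of class-code variance explained by component
# k, normalised to a maximum of 1. Raw weights are kept on the model so
# alternative importance definitions can be computed.

plsda_levels <- function(labels) {
  f <- if (is.factor(labels)) labels else {
    u <- unique(as.character(labels))
    lv <- if (all(u %in% c("aCO2", "eCO2"))) c("aCO2", "eCO2") else sort(u)
    factor(labels, levels = lv)
  }
  f <- droplevels(f)
  if (nlevels(f) != 2) {
    stopf("PLSDA needs exactly 2 classes, got %d (%s)", nlevels(f),
          paste(levels(f), collapse = ", "))
  }
  f
}

#' Fit a PLSDA model
#'
#' @param x A `spectrum_set` or numeric matrix (rows = spectra).
#' @param labels Class labels; `"aCO2"` is coded 0 and `"eCO2"` 1 (general
#'   two-level factors use the first level as 0).
#' @param n_components Number of PLS components (1..60, capped at the rank
#'   the data supports).
#' @return Object of class `plsda_model` with X-weights `W`, X-loadings `P`,
#'   y-loadings `q`, scores `T`, regression coefficients per component count,
#'   preprocessing parameters, and `v` (class-code variance fraction per
#'   component).
#' @export
plsda_fit <- function(x, labels, n_components) {
  sm <- spectra_matrix(x)
  X <- sm$x
  y_f <- plsda_levels(labels)
  if (length(y_f) != nrow(X)) stopf("labels length does not match spectra")
  y <- as.numeric(y_f) - 1
  if (n_components < 1 || n_components > 60) {
    stopf("n_components must be in [1, 60], got %d", n_components)
  }
  n <- nrow(X); p0 <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  kept <- which(sds > 0)
  ctr <- colMeans(X[, kept, drop = FALSE])
  scl <- sds[kept]
  Xs <- scale(X[, kept, drop = FALSE], center = ctr, scale = scl)
  ybar <- mean(y)
  yc <- y - ybar
  ssy <- sum(yc^2)
  k_max <- min(n_components, n - 1, length(kept))
  p <- length(kept)
  W <- matrix(0, p, k_max); P <- matrix(0, p, k_max)
  Tm <- matrix(0, n, k_max); q <- numeric(k_max); tt <- numeric(k_max)
  Xd <- Xs; yd <- yc
  for (k in seq_len(k_max)) {
    w <- crossprod(Xd, yd)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { k_max <- k - 1L; break }
    w <- w / nw
    t_k <- as.vector(Xd %*% w)
    tt[k] <- sum(t_k^2)
    p_k <- crossprod(Xd, t_k)[, 1] / tt[k]
    q[k] <- sum(yd * t_k) / tt[k]
    Xd <- Xd - tcrossprod(t_k, p_k)
    yd <- yd - t_k * q[k]
    W[, k] <- w; P[, k] <- p_k; Tm[, k] <- t_k
  }
  if (k_max < 1) stopf("no usable PLS component (X carries no class signal)")
  W <- W[, seq_len(k_max), drop = FALSE]
  P <- P[, seq_len(k_max), drop = FALSE]
  Tm <- Tm[, seq_len(k_max), drop = FALSE]
  q <- q[seq_len(k_max)]; tt <- tt[seq_len(k_max)]
  v <- q^2 * tt / ssy
  structure(
    list(n_components = k_max, W = W, P = P, q = q, scores = Tm,
         t_ss = tt, v = v, center = ctr, scale = scl, kept = kept,
         p_full = p0, y_mean = ybar, levels = levels(y_f),
         threshold = 0.5, n = n),
    class = "plsda_model"
  )
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d component(s), %d x %d matrix, classes %s\n",
              x$n_components, x$n, x$p_full,
              paste(x$levels, collapse = "/")))
  invisible(x)
}

# Continuous predictions for every component count 1..k on new data, by
# deflating the new matrix with the training loadings. Returns n x k matrix.
plsda_response_all <- function(model, newx) {
  sm <- spectra_matrix(newx)
  Xs <- scale(sm$x[, model$kept, drop = FALSE],
              center = model$center, scale = model$scale)
  k <- model$n_components
  out <- matrix(0, nrow(Xs), k)
  acc <- rep(model$y_mean, nrow(Xs))
  for (j in seq_len(k)) {
    t_new <- as.vector(Xs %*% model$W[, j])
    acc <- acc + t_new * model$q[j]
    out[, j] <- acc
    Xs <- Xs - tcrossprod(t_new, model$P[, j])
  }
  out
}

#' Predict from a PLSDA model
#'
#' @param object A `plsda_model`.
#' @param newx New spectra (`spectrum_set` or matrix).
#' @param type `"class"` (factor of predicted labels) or `"response"`
#'   (continuous 0/1-scale prediction).
#' @param n_components Component count to predict at (default: all fitted).
#' @param ... Unused.
#' @return Factor or numeric vector.
#' @export
predict.plsda_model <- function(object, newx, type = c("class", "response"),
                                n_components = NULL, ...) {
  type <- match.arg(type)
  k <- n_components %||% object$n_components
  stopifnot(k >= 1, k <= object$n_components)
  resp <- plsda_response_all(object, newx)[, k]
  if (type == "response") return(resp)
  factor(object$levels[1 + (resp >= object$threshold)],
         levels = object$levels)
}

#' Cumulative wavelength importance of a PLSDA model
#'
#' `importance(lambda) = sum_k |w_lambda,k| * v_k` over the retained
#' components, where `v_k` is the fraction of class-code variance explained
#' by component k; normalised so the maximum is 1. Wavelengths dropped as
#' zero-variance re-enter with importance 0.
#'
#' @param model A `plsda_model`.
#' @return Data frame of class `wavelength_importance`: `wavelength_nm`
#'   (when the model was fitted on the common grid) or column index, plus
#'   `importance`.
#' @export
wavelength_importance <- function(model) {
  imp_kept <- as.vector(abs(model$W) %*% model$v)
  imp <- numeric(model$p_full)
  imp[model$kept] <- imp_kept
  if (max(imp) > 0) imp <- imp / max(imp)
  wl <- if (model$p_full == GRID_N) spectrum_grid() else seq_len(model$p_full)
  structure(data.frame(wavelength_nm = wl, importance = imp),
            class = c("wavelength_importance", "data.frame"))
}

stratified_split <- function(y, fraction) {
  idx <- unlist(lapply(levels(y), function(l) {
    i <- which(y == l)
    sample(i, round(length(i) * fraction))
  }))
  sort(idx)
}

stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (l in levels(y)) {
    i <- which(y == l)
    fold[i] <- sample(rep(seq_len(folds), length.out = length(i)))
  }
  fold
}

#' Tune, train, and test a PLSDA model
#'
#' Stratified 70/30 train/test split, stratified k-fold cross-validation on
#' the training portion only, accuracy per component count, argmax selection
#' (ties broken towards fewer components), final refit on the full training
#' set, and evaluation on the untouched test set. The held-out 30% is never
#' seen before the final evaluation. All randomness (split and folds) is a
#' function of `seed`.
#'
#' @param x A `spectrum_set` or numeric matrix.
#' @param labels Class labels (see [plsda_fit()]).
#' @param max_components Largest component count examined (<= 60).
#' @param folds Number of CV folds.
#' @param train_fraction Fraction of spectra in the training split.
#' @param seed Integer seed.
#' @return Object of class `plsda_tuning`: `best_n_components`,
#'   `cv_accuracy` (data frame `n_components`, `accuracy`),
#'   `cv_best_accuracy`, `model` (final refit), `test_stats`
#'   ([evaluate()] on the held-out split), `train_idx`, `seed`.
#' @export
plsda_tune <- function(x, labels, max_components = 60, folds = 10,
                       train_fraction = 0.7, seed = 1L) {
  sm <- spectra_matrix(x)
  X <- sm$x
  y <- plsda_levels(labels)
  if (min(table(y)) < 2 * folds) {
    folds <- max(2, min(folds, floor(min(table(y)) / 2)))
  }
  train_idx <- local_seed(derive_seed(seed, 101L),
                          stratified_split(y, train_fraction))
  Xtr <- X[train_idx, , drop = FALSE]; ytr <- droplevels(y[train_idx])
  if (nlevels(ytr) != 2 || min(table(ytr)) < folds) {
    stopf("not enough samples per class for %d stratified folds", folds)
  }
  fold <- local_seed(derive_seed(seed, 202L), stratified_folds(ytr, folds))
  k_cap <- min(max_components,
               min(vapply(seq_len(folds), function(f) sum(fold != f),
                          numeric(1))) - 1)
  correct <- numeric(k_cap); total <- 0
  for (f in seq_len(folds)) {
    in_tr <- fold != f
    m <- plsda_fit(Xtr[in_tr, , drop = FALSE], ytr[in_tr], k_cap)
    resp <- plsda_response_all(m, Xtr[!in_tr, , drop = FALSE])
    truth01 <- as.numeric(ytr[!in_tr]) - 1
    kk <- m$n_components
    hits <- colSums((resp[, seq_len(kk), drop = FALSE] >= 0.5) == truth01)
    if (kk < k_cap) hits <- c(hits, rep(hits[kk], k_cap - kk))
    correct <- correct + hits
    total <- total + sum(!in_tr)
  }
  cv_acc <- correct / total
  best_k <- which.max(cv_acc)   # first maximum = fewest components on ties
  final <- plsda_fit(Xtr, ytr, best_k)
  test_idx <- setdiff(seq_len(nrow(X)), train_idx)
  pred <- predict(final, X[test_idx, , drop = FALSE])
  stats <- evaluate(pred, y[test_idx])
  structure(
    list(best_n_components = best_k,
         cv_accuracy = data.frame(n_components = seq_len(k_cap),
                                  accuracy = cv_acc),
         cv_best_accuracy = cv_acc[best_k],
         model = final, test_stats = stats,
         train_idx = train_idx, folds = folds, seed = seed),
    class = "plsda_tuning"
  )
}

#' @export
print.plsda_tuning <- function(x, ...) {
  cat(sprintf("<plsda_tuning> best = %d component(s), CV accuracy %.3f\n",
              x$best_n_components, x$cv_best_accuracy))
  cat(sprintf("  held-out accuracy %.3f (n = %d)\n",
              x$test_stats$accuracy, x$test_stats$n))
  invisible(x)
}
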