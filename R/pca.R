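# Principal component analysis of the spectra matrix.

# Coerce a spectrum_set or matrix to the n x p numeric matrix + metadata.
spectra_matrix <- function(x) {
  if (inherits(x, "spectrum_set")) {
    list(x = x$reflectance, meta = x$meta)
  } else {
    list(x = as.matrix(x), meta = NULL)
  }
}

#' Fit a PCA model to a spectra matrix
#'
#' Columns are centred and, by default, scaled to unit variance.
#' Zero-variance columns are dropped before scaling (reported via a message)
#' and carried as zero loadings. The sign of each component is fixed by
#' making its largest-magnitude loading positive, so results are reproducible
#' run to run.
#'
#' @param x A `spectrum_set` or numeric matrix (rows = spectra).
#' @param n_components Number of components to retain.
#' @param standardize Scale columns to unit variance (default TRUE).
#' @return Object of class `pca_model`: `loadings` (p x k), `scores`
#'   (n x k), `ev_fraction` (variance fractions for *all* components, summing
#'   to 1), `center`, `scale`, `kept` (column index of non-constant
#'   wavelengths), `meta`.
#' @export
pca_fit <- function(x, n_components = 10, standardize = TRUE) {
  sm <- spectra_matrix(x)
  X <- sm$x
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stopf("PCA needs at least 2 spectra")
  if (n_components > min(n, p)) {
    stopf("n_components = %d exceeds min(n, p) = %d", n_components, min(n, p))
  }
  sds <- apply(X, 2, stats::sd)
  kept <- which(sds > 0)
  if (length(kept) < p) {
    message(sprintf("pca_fit: dropping %d zero-variance column(s)",
                    p - length(kept)))
  }
  Xk <- X[, kept, drop = FALSE]
  pc <- stats::prcomp(Xk, center = TRUE, scale. = standardize)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  sco <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ev <- pc$sdev^2
  loadings <- matrix(0, p, k, dimnames = list(colnames(X), colnames(rot)))
  loadings[kept, ] <- rot
  structure(
    list(loadings = loadings, scores = sco, ev_fraction = ev / sum(ev),
         sdev = pc$sdev, center = pc$center,
         scale = if (standardize) pc$scale else NULL,
         standardize = standardize, kept = kept, n = n, p = p,
         n_components = k, meta = sm$meta),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components of %d x %d matrix (%s)\n",
              x$n_components, x$n, x$p,
              if (x$standardize) "centred + scaled" else "centred"))
  ev <- x$ev_fraction[seq_len(x$n_components)] * 100
  cat("  % variance:", paste(sprintf("%.2f", ev), collapse = ", "), "\n")
  invisible(x)
}

#' Explained-variance table of a PCA model
#' @param model A `pca_model`.
#' @return Data frame with `component`, `variance_pct`, `cumulative_pct`.
#' @export
pca_variance_table <- function(model) {
  k <- model$n_components
  pct <- model$ev_fraction[seq_len(k)] * 100
  data.frame(component = paste0("PC", seq_len(k)), variance_pct = pct,
             cumulative_pct = cumsum(pct))
}

#' PCA scores joined with campaign metadata
#' @param model A `pca_model` fitted on a `spectrum_set`.
#' @return Data frame: metadata columns plus `PC1..PCk`.
#' @export
pca_scores <- function(model) {
  sc <- as.data.frame(model$scores)
  if (!is.null(model$meta)) cbind(model$meta, sc) else sc
}
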