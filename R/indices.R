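# Vegetation indices and integrated reflectance.
#
# All indices are single-band formulas over the 1 nm grid; rho(lambda) is the
# fractional reflectance at the nearest integer nanometre. The
# log-reciprocal indices (NDNI, NDLI) use the natural log; their
# difference-over-sum structure makes them invariant to the log base.

# Each definition: the bands it reads and a vectorized formula over a named
# list of band vectors b[["670"]] etc. `bad` marks inputs whose result is
# flagged undefined (beyond non-finite arithmetic).
.index_defs <- list(
  NDVI = list(
    bands = c(800, 670),
    f = function(b) (b[["800"]] - b[["670"]]) / (b[["800"]] + b[["670"]])
  ),
  MCARI = list(
    bands = c(700, 670, 550),
    f = function(b) ((b[["700"]] - b[["670"]]) -
                       0.2 * (b[["700"]] - b[["550"]])) *
      (b[["700"]] / b[["670"]])
  ),
  PRI = list(
    bands = c(570, 530),
    f = function(b) (b[["570"]] - b[["530"]]) / (b[["570"]] + b[["530"]])
  ),
  PSRI = list(
    bands = c(680, 500, 750),
    f = function(b) (b[["680"]] - b[["500"]]) / b[["750"]]
  ),
  NDNI = list(
    bands = c(1510, 1680),
    f = function(b) (log(1 / b[["1510"]]) - log(1 / b[["1680"]])) /
      (log(1 / b[["1510"]]) + log(1 / b[["1680"]])),
    bad = function(b) b[["1510"]] <= 0 | b[["1680"]] <= 0
  ),
  NDLI = list(
    bands = c(1754, 1680),
    f = function(b) (log(1 / b[["1754"]]) - log(1 / b[["1680"]])) /
      (log(1 / b[["1754"]]) + log(1 / b[["1680"]])),
    bad = function(b) b[["1754"]] <= 0 | b[["1680"]] <= 0
  ),
  NDWI = list(
    bands = c(860, 1240),
    f = function(b) (b[["860"]] - b[["1240"]]) / (b[["860"]] + b[["1240"]])
  ),
  NPQI = list(
    bands = c(415, 435),
    f = function(b) (b[["415"]] - b[["435"]]) / (b[["415"]] + b[["435"]])
  )
)

#' Names of the available indices
#'
#' The eight vegetation indices plus `"INTEGRATED"` (trapezoidal integral of
#' fractional reflectance over 350-2500 nm, units fraction x nm).
#'
#' @return Character vector.
#' @export
index_names <- function() c(names(.index_defs), "INTEGRATED")

#' Reflectance at a single band
#'
#' Returns the grid value at the nearest integer nanometre.
#'
#' @param spectrum A `leaf_spectrum`.
#' @param lambda Wavelength in nm, within `[350, 2500]`.
#' @return Reflectance fraction.
#' @export
band <- function(spectrum, lambda) {
  if (lambda < 350 || lambda > 2500) {
    stopf("wavelength %.4g nm outside the 350-2500 nm range", lambda)
  }
  spectrum$reflectance[as.integer(round(lambda)) - 349L]
}

band_matrix <- function(set, lambdas) {
  cols <- as.integer(round(lambdas)) - 349L
  b <- lapply(cols, function(j) unname(set$reflectance[, j]))
  names(b) <- as.character(as.integer(round(lambdas)))
  b
}

index_values_matrix <- function(set, name) {
  if (name == "INTEGRATED") {
    R <- set$reflectance
    v <- unname(rowSums(R) - (R[, 1] + R[, ncol(R)]) / 2)
    return(list(value = v, undefined = rep(FALSE, length(v))))
  }
  def <- .index_defs[[name]]
  if (is.null(def)) {
    stopf("unknown index '%s'; available: %s", name,
          paste(index_names(), collapse = ", "))
  }
  b <- band_matrix(set, def$bands)
  bad <- if (!is.null(def$bad)) def$bad(b) else rep(FALSE, n_spectra(set))
  v <- suppressWarnings(def$f(b))
  undef <- bad | !is.finite(v)
  v[undef] <- NA_real_
  list(value = v, undefined = undef)
}

#' Compute one vegetation index for one spectrum
#'
#' A zero denominator, or a nonpositive band under a logarithm, yields a
#' flagged undefined result rather than an error or a silent drop.
#'
#' @param spectrum A `leaf_spectrum`.
#' @param name An [index_names()] entry.
#' @return List of class `index_result`: `index_name`, `value` (NA when
#'   undefined), `undefined` flag, `meta`.
#' @export
compute_index <- function(spectrum, name) {
  set <- new_spectrum_set(matrix(spectrum$reflectance, 1),
                          as.data.frame(spectrum$meta[meta_fields()],
                                        stringsAsFactors = FALSE))
  r <- index_values_matrix(set, name)
  structure(list(index_name = name, value = r$value[1],
                 undefined = r$undefined[1], meta = spectrum$meta),
            class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf("%s = %s%s\n", x$index_name,
              if (is.na(x$value)) "NA" else format(x$value, digits = 6),
              if (x$undefined) " [undefined]" else ""))
  invisible(x)
}

#' Integrated reflectance of a spectrum
#'
#' Trapezoidal integral of fractional reflectance over 350-2500 nm on the
#' 1 nm grid (units: fraction x nm; a constant 0.2 integrates to 430).
#'
#' @param spectrum A `leaf_spectrum`.
#' @return An `index_result` with name `"INTEGRATED"`.
#' @export
integrated_reflectance <- function(spectrum) {
  compute_index(spectrum, "INTEGRATED")
}

#' Long-format index table for a campaign
#'
#' One row per spectrum x index, ordered by (tree, date, leaf, index).
#' Undefined values are kept as NA rows with `undefined = TRUE` and their
#' count reported via a message.
#'
#' @param set A `spectrum_set`.
#' @param names Indices to compute (default: all of [index_names()]).
#' @return A data frame with the metadata columns plus `index_name`, `value`,
#'   `undefined`.
#' @export
index_table <- function(set, names = index_names()) {
  stopifnot(inherits(set, "spectrum_set"), n_spectra(set) > 0)
  unknown <- setdiff(names, index_names())
  if (length(unknown)) {
    stopf("unknown index '%s'; available: %s", unknown[1],
          paste(index_names(), collapse = ", "))
  }
  rows <- lapply(names, function(nm) {
    r <- index_values_matrix(set, nm)
    cbind(set$meta[c("treatment", "array_id", "tree_id", "date",
                     "leaf_index")],
          data.frame(index_name = nm, value = r$value,
                     undefined = r$undefined, stringsAsFactors = FALSE))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$tree_id, tab$date, tab$leaf_index,
                   match(tab$index_name, index_names())), ]
  rownames(tab) <- NULL
  n_undef <- sum(tab$undefined)
  if (n_undef > 0) {
    message(sprintf("index_table: %d undefined index value(s) flagged",
                    n_undef))
  }
  tab
}
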