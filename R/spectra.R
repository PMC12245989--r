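# Spectrum containers.
#
# A `leaf_spectrum` is a reflectance curve on the common integer-nanometre
# grid 350..2500 (2151 points) with per-spectrum metadata. A `spectrum_set`
# stores a whole campaign as an n x 2151 matrix plus a metadata table, the
# layout every downstream stage (indices, PCA, PLSDA, mixed models) consumes.

#' The common wavelength grid (nm)
#'
#' Integer nanometre grid from 350 to 2500 inclusive (2151 points) onto which
#' all spectra are resampled.
#'
#' @return Integer vector of wavelengths in nm.
#' @export
spectrum_grid <- function() 350:2500

GRID_N <- 2151L

#' Per-spectrum metadata record
#'
#' @param treatment `"aCO2"` or `"eCO2"`.
#' @param array_id Experimental array identifier.
#' @param tree_id Tree identifier (unique across arrays).
#' @param date Measurement date, ISO `YYYY-MM-DD`.
#' @param leaf_index Leaf number within tree and date.
#' @param source_file Originating file, if any.
#' @return A named list of class `spectrum_meta`.
#' @export
spectrum_meta <- function(treatment = NA_character_, array_id = NA_character_,
                          tree_id = NA_character_, date = NA_character_,
                          leaf_index = NA_integer_, source_file = NA_character_) {
  treatment <- as.character(treatment)
  if (!is.na(treatment) && !treatment %in% c("aCO2", "eCO2")) {
    stopf("treatment must be 'aCO2' or 'eCO2', got '%s'", treatment)
  }
  structure(
    list(treatment = treatment, array_id = as.character(array_id),
         tree_id = as.character(tree_id), date = as.character(date),
         leaf_index = as.integer(leaf_index),
         source_file = as.character(source_file)),
    class = "spectrum_meta"
  )
}

meta_fields <- function() {
  c("treatment", "array_id", "tree_id", "date", "leaf_index", "source_file")
}

#' Construct a spectrum on the common 1 nm grid
#'
#' Values are clipped to `[0, 1.5]`; reflectance can legitimately exceed 1
#' relative to the reference panel in leaf-clip geometry, so values above 1
#' are retained but the spectrum is flagged rather than truncated at 1.
#'
#' @param reflectance Numeric vector of length 2151 (fractional reflectance).
#' @param meta A [spectrum_meta()] record.
#' @return Object of class `leaf_spectrum` with elements `wavelength`,
#'   `reflectance`, `meta`, and `flag_over_one`.
#' @export
new_spectrum <- function(reflectance, meta = spectrum_meta()) {
  reflectance <- as.numeric(reflectance)
  if (length(reflectance) != GRID_N) {
    stopf("reflectance must have %d values (grid 350..2500 nm), got %d",
          GRID_N, length(reflectance))
  }
  if (any(!is.finite(reflectance))) {
    stopf("reflectance contains non-finite values (first at %d nm)",
          spectrum_grid()[which(!is.finite(reflectance))[1]])
  }
  flag <- any(reflectance > 1)
  reflectance <- pmin(pmax(reflectance, 0), 1.5)
  structure(
    list(wavelength = spectrum_grid(), reflectance = reflectance,
         meta = meta, flag_over_one = flag),
    class = "leaf_spectrum"
  )
}

#' @export
print.leaf_spectrum <- function(x, ...) {
  cat(sprintf("<leaf_spectrum> 350-2500 nm, %d points, mean reflectance %.3f%s\n",
              length(x$reflectance), mean(x$reflectance),
              if (isTRUE(x$flag_over_one)) " [values > 1 flagged]" else ""))
  m <- x$meta
  if (!is.na(m$tree_id)) {
    cat(sprintf("  %s  array %s  tree %s  %s  leaf %s\n", m$treatment,
                m$array_id, m$tree_id, m$date, m$leaf_index))
  }
  invisible(x)
}

#' Bundle spectra into a campaign set
#'
#' @param spectra List of [new_spectrum()] objects sharing the common grid.
#' @return Object of class `spectrum_set` with elements `wavelength`,
#'   `reflectance` (n x 2151 matrix), `meta` (data frame, one row per
#'   spectrum) and `flag_over_one` (logical per spectrum).
#' @export
spectrum_set <- function(spectra) {
  if (length(spectra) == 0) stopf("a spectrum_set cannot be empty")
  refl <- do.call(rbind, lapply(spectra, function(s) s$reflectance))
  meta <- do.call(rbind, lapply(spectra, function(s) {
    as.data.frame(s$meta[meta_fields()], stringsAsFactors = FALSE)
  }))
  flags <- vapply(spectra, function(s) isTRUE(s$flag_over_one), logical(1))
  new_spectrum_set(refl, meta, flags)
}

new_spectrum_set <- function(reflectance, meta, flag_over_one = NULL) {
  reflectance <- as.matrix(reflectance)
  if (ncol(reflectance) != GRID_N) {
    stopf("spectrum_set matrix must have %d columns, got %d", GRID_N,
          ncol(reflectance))
  }
  if (nrow(reflectance) == 0) stopf("a spectrum_set cannot be empty")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(reflectance)) {
    stopf("metadata rows (%d) do not match spectra (%d)", nrow(meta),
          nrow(reflectance))
  }
  for (f in meta_fields()) if (is.null(meta[[f]])) meta[[f]] <- NA
  key <- paste(meta$tree_id, meta$date, meta$leaf_index)
  if (!anyNA(meta$leaf_index) && anyDuplicated(key)) {
    stopf("duplicate (tree_id, date, leaf_index) in spectrum_set: %s",
          key[anyDuplicated(key)])
  }
  dimnames(reflectance) <- list(NULL, paste0("wl_", spectrum_grid()))
  structure(
    list(wavelength = spectrum_grid(), reflectance = reflectance,
         meta = meta[meta_fields()],
         flag_over_one = flag_over_one %||%
           apply(reflectance > 1, 1, any)),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d wavelengths (350-2500 nm)\n",
              nrow(x$reflectance), ncol(x$reflectance)))
  if (!all(is.na(x$meta$treatment))) {
    print(table(treatment = x$meta$treatment))
  }
  invisible(x)
}

#' @export
as.matrix.spectrum_set <- function(x, ...) x$reflectance

#' Number of spectra in a set
#' @param set A `spectrum_set`.
#' @return Integer count.
#' @export
n_spectra <- function(set) nrow(set$reflectance)

#' Extract one spectrum from a set
#' @param set A `spectrum_set`.
#' @param i Row index.
#' @return A `leaf_spectrum`.
#' @export
get_spectrum <- function(set, i) {
  stopifnot(i >= 1, i <= n_spectra(set))
  m <- set$meta[i, ]
  new_spectrum(set$reflectance[i, ],
               spectrum_meta(m$treatment, m$array_id, m$tree_id, m$date,
                             m$leaf_index, m$source_file))
}

#' Subset a spectrum set by row
#' @param set A `spectrum_set`.
#' @param idx Integer or logical row index.
#' @return A `spectrum_set`.
#' @export
subset_spectra <- function(set, idx) {
  new_spectrum_set(set$reflectance[idx, , drop = FALSE],
                   set$meta[idx, , drop = FALSE],
                   set$flag_over_one[idx])
}

#' Design summary of a spectrum set
#'
#' Counts of spectra per treatment, tree, and date.
#'
#' @param set A `spectrum_set`.
#' @return A list with `n_total`, `per_treatment`, and a `design` data frame
#'   (one row per treatment x array x tree x date with its leaf count).
#' @export
design_summary <- function(set) {
  m <- set$meta
  tab <- stats::aggregate(list(n_leaves = rep(1L, nrow(m))),
                          by = list(treatment = m$treatment,
                                    array_id = m$array_id,
                                    tree_id = m$tree_id, date = m$date),
                          FUN = sum)
  tab <- tab[order(tab$treatment, tab$array_id, tab$tree_id, tab$date), ]
  rownames(tab) <- NULL
  list(n_total = nrow(m),
       per_treatment = table(m$treatment),
       design = tab)
}
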