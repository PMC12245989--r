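# Raw-spectrum I/O and preprocessing.
#
# Field spectroradiometers of the class used for canopy leaf-clip work record
# each spectrum on three overlapping detectors (VNIR 350-1000 nm @ ~1.5 nm,
# SWIR1 1000-1890 nm @ ~3.8 nm, SWIR2 1890-2500 nm @ ~2.5 nm). Preprocessing
# stitches the detector segments into one continuous series, interpolates to
# the integer 1 nm grid, and multiplies by the laboratory-calibrated
# reflectance of the reference panel to convert relative to absolute
# reflectance.

DETECTOR_RANGES <- list(VNIR = c(350, 1000), SWIR1 = c(1000, 1890),
                        SWIR2 = c(1890, 2500))

# A detector segment may protrude this far past its nominal boundary:
# real instruments overlap their detectors around 1000 and 1890 nm.
BOUNDARY_SLACK <- 40

classify_segment <- function(wl) {
  cover <- vapply(DETECTOR_RANGES, function(r) {
    mean(wl >= r[1] & wl <= r[2])
  }, numeric(1))
  best <- names(DETECTOR_RANGES)[which.max(cover)]
  r <- DETECTOR_RANGES[[best]]
  # a sweep extending far past one detector's range is a merged full-range
  # series (e.g. an already-stitched export), kept as a single segment
  if (min(wl) < r[1] - BOUNDARY_SLACK || max(wl) > r[2] + BOUNDARY_SLACK) {
    return("FULL")
  }
  best
}

validate_segment <- function(seg, path = "<memory>") {
  if (seg$detector != "FULL") {
    r <- DETECTOR_RANGES[[seg$detector]]
    if (any(seg$wavelength < r[1] - BOUNDARY_SLACK) ||
        any(seg$wavelength > r[2] + BOUNDARY_SLACK)) {
      stopf("segment classified as %s has wavelengths far outside %g-%g nm in %s",
            seg$detector, r[1], r[2], path)
    }
  }
  if (any(diff(seg$wavelength) <= 0)) {
    stopf("wavelengths not strictly increasing within a %s segment in %s",
          seg$detector, path)
  }
  if (any(!is.finite(seg$value)) || any(seg$value < 0)) {
    stopf("non-finite or negative reflectance in %s segment of %s",
          seg$detector, path)
  }
  seg
}

new_raw_spectrum <- function(segments, meta = spectrum_meta()) {
  structure(list(segments = segments, meta = meta), class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("<raw_spectrum> %d segment(s)\n", length(x$segments)))
  for (s in x$segments) {
    cat(sprintf("  %-5s %7.1f-%7.1f nm  (%d points)\n", s$detector,
                min(s$wavelength), max(s$wavelength), length(s$wavelength)))
  }
  invisible(x)
}

#' Read a single raw spectrum file
#'
#' Two dialects are supported. `"svc"` is an SVC-style text file: an optional
#' header block of `key= value` lines (keys may include `treatment`,
#' `array_id`, `tree_id`, `date`, `leaf_index`), followed by two-column
#' numeric rows (wavelength in nm, relative reflectance fraction) separated
#' by whitespace or commas. `"csv"` is the package dialect: a CSV with
#' columns `wavelength_nm` and `reflectance`, one file per spectrum.
#'
#' Detector segments are recovered from the wavelength sequence: instruments
#' write segments one after another and the overlap at each detector boundary
#' forces the wavelength to step backwards, so a strict decrease starts a new
#' segment. An exactly repeated wavelength is a parse error.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"svc"`, or `"csv"`.
#' @param meta Optional [spectrum_meta()] overriding/completing header fields.
#' @return A `raw_spectrum` with one segment per detector sweep.
#' @export
read_spectrum_file <- function(path, dialect = c("auto", "svc", "csv"),
                               meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "svc"
  }
  header <- list()
  if (dialect == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("wavelength_nm", "reflectance") %in% names(tab))) {
      stopf("unsupported format: %s lacks wavelength_nm/reflectance columns (csv dialect)",
            path)
    }
    wl <- as.numeric(tab$wavelength_nm)
    val <- as.numeric(tab$reflectance)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    is_data <- grepl("^[0-9+.-]", lines) &
      !grepl("=", lines, fixed = TRUE)
    for (h in lines[!is_data]) {
      if (grepl("=", h, fixed = TRUE)) {
        kv <- strsplit(h, "=", fixed = TRUE)[[1]]
        header[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
      }
    }
    data_lines <- lines[is_data]
    if (length(data_lines) == 0) stopf("no data rows found in %s", path)
    fields <- strsplit(data_lines, "[,[:space:]]+")
    bad <- which(vapply(fields, length, integer(1)) < 2)
    if (length(bad)) {
      stopf("parse error in %s: line %d does not have two numeric columns",
            path, which(is_data)[bad[1]])
    }
    wl <- as.numeric(vapply(fields, `[[`, character(1), 1))
    val <- as.numeric(vapply(fields, `[[`, character(1), 2))
  }
  if (anyNA(wl) || anyNA(val)) {
    stopf("parse error in %s: non-numeric wavelength or reflectance", path)
  }
  dup <- which(diff(wl) == 0)
  if (length(dup)) {
    stopf("parse error in %s: duplicated wavelength %.4g nm", path, wl[dup[1]])
  }
  # strict decreases delimit detector sweeps
  breaks <- c(0, which(diff(wl) < 0), length(wl))
  segments <- lapply(seq_len(length(breaks) - 1), function(i) {
    idx <- (breaks[i] + 1):breaks[i + 1]
    seg <- list(detector = classify_segment(wl[idx]),
                wavelength = wl[idx], value = val[idx])
    validate_segment(seg, path)
  })
  ids <- vapply(segments, `[[`, character(1), "detector")
  if (anyDuplicated(ids)) {
    stopf("parse error in %s: two segments classified as the same detector (%s)",
          path, ids[anyDuplicated(ids)])
  }
  m <- meta %||% spectrum_meta(
    treatment = header$treatment %||% NA,
    array_id = header$array_id %||% NA,
    tree_id = header$tree_id %||% NA,
    date = header$date %||% NA,
    leaf_index = header$leaf_index %||% NA,
    source_file = path
  )
  if (is.na(m$source_file)) m$source_file <- path
  new_raw_spectrum(segments, m)
}

#' Stitch detector segments into one continuous series
#'
#' Under the default `"cut"` policy each wavelength is taken from the
#' detector that owns it: VNIR below 1000 nm, SWIR1 from 1000 to below
#' 1890 nm, SWIR2 from 1890 nm. The `"rescale"` policy additionally applies
#' a multiplicative jump correction before cutting: each later segment is
#' rescaled so that its mean over the overlap window matches the mean of the
#' (already corrected) earlier segment there.
#'
#' @param raw A `raw_spectrum`.
#' @param policy `"cut"` or `"rescale"`.
#' @return A `stitched_spectrum`: list with `wavelength` (strictly
#'   increasing), `value`, `meta`, and per-segment `scale` factors applied.
#' @export
stitch <- function(raw, policy = c("cut", "rescale")) {
  policy <- match.arg(policy)
  segs <- raw$segments
  ord <- order(vapply(segs, function(s) min(s$wavelength), numeric(1)))
  segs <- segs[ord]
  scales <- rep(1, length(segs))
  if (length(segs) > 1) {
    for (i in 2:length(segs)) {
      prev <- segs[[i - 1]]; cur <- segs[[i]]
      gap <- min(cur$wavelength) - max(prev$wavelength)
      if (gap > 5) {
        stopf("gap of %.2f nm between %s and %s segments exceeds 5 nm",
              gap, prev$detector, cur$detector)
      }
      if (policy == "rescale" && gap < 0) {
        lo <- min(cur$wavelength); hi <- max(prev$wavelength)
        pv <- prev$value[prev$wavelength >= lo & prev$wavelength <= hi]
        cv <- cur$value[cur$wavelength >= lo & cur$wavelength <= hi]
        if (any(!is.finite(pv)) || any(!is.finite(cv))) {
          stopf("non-finite values in the %s/%s overlap window",
                prev$detector, cur$detector)
        }
        if (length(pv) == 0 || length(cv) == 0 || mean(cv) <= 0) {
          stopf("cannot rescale %s segment: empty or nonpositive overlap",
                cur$detector)
        }
        f <- mean(pv) / mean(cv)
        segs[[i]]$value <- cur$value * f
        scales[i] <- f
      }
    }
  }
  # detector-priority cut
  pieces <- lapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    lo <- if (i == 1) -Inf else cut_point(segs[[i - 1]], s)
    hi <- if (i == length(segs)) Inf else cut_point(s, segs[[i + 1]])
    keep <- s$wavelength >= lo & s$wavelength < hi
    list(wavelength = s$wavelength[keep], value = s$value[keep])
  })
  wl <- unlist(lapply(pieces, `[[`, "wavelength"))
  val <- unlist(lapply(pieces, `[[`, "value"))
  if (any(diff(wl) <= 0)) stopf("stitched wavelengths are not strictly increasing")
  structure(list(wavelength = wl, value = val, meta = raw$meta,
                 policy = policy, scale = scales),
            class = "stitched_spectrum")
}

# Cut point between two adjacent segments: the nominal detector boundary when
# the pair spans one, otherwise the middle of their overlap (or gap).
cut_point <- function(a, b) {
  bnd <- c(VNIR.SWIR1 = 1000, SWIR1.SWIR2 = 1890)
  key <- paste(a$detector, b$detector, sep = ".")
  if (!is.na(bnd[key])) return(unname(bnd[key]))
  (max(a$wavelength) + min(b$wavelength)) / 2
}

#' Resample a stitched series onto the integer 1 nm grid
#'
#' Linear interpolation onto 350..2500 nm; beyond the data range the edge
#' value is held (no extrapolation). Errors if coverage starts more than 5 nm
#' above 350 or ends more than 5 nm below 2500.
#'
#' @param x A `stitched_spectrum`, a `leaf_spectrum`, or a list with
#'   `wavelength` and `value` elements.
#' @return A [new_spectrum()] on the common grid, metadata preserved.
#' @export
resample_1nm <- function(x) {
  if (inherits(x, "leaf_spectrum")) {
    wl <- x$wavelength; val <- x$reflectance; meta <- x$meta
  } else {
    wl <- x$wavelength; val <- x$value %||% x$reflectance
    meta <- x$meta %||% spectrum_meta()
  }
  if (min(wl) > 355 || max(wl) < 2495) {
    stopf("coverage %.1f-%.1f nm misses the 350-2500 nm grid by more than 5 nm",
          min(wl), max(wl))
  }
  out <- stats::approx(wl, val, xout = spectrum_grid(), method = "linear",
                       rule = 2, ties = "ordered")$y
  new_spectrum(out, meta)
}

#' Read a panel calibration curve
#'
#' CSV with columns `wavelength_nm` and `panel_reflectance` (fraction), the
#' laboratory-calibrated reflectance of the leaf clip's reference standard.
#'
#' @param path File path.
#' @return A data frame of class `panel_calibration`.
#' @export
read_panel <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("wavelength_nm", "panel_reflectance") %in% names(tab))) {
    stopf("panel file %s lacks wavelength_nm/panel_reflectance columns", path)
  }
  panel_calibration(tab$wavelength_nm, tab$panel_reflectance)
}

#' Construct a panel calibration
#' @param wavelength_nm Wavelengths (nm), ascending.
#' @param panel_reflectance Panel reflectance fraction, in (0, 1.05].
#' @return A data frame of class `panel_calibration`.
#' @export
panel_calibration <- function(wavelength_nm, panel_reflectance) {
  ord <- order(wavelength_nm)
  wl <- as.numeric(wavelength_nm)[ord]
  pr <- as.numeric(panel_reflectance)[ord]
  if (any(!is.finite(pr)) || any(pr <= 0)) {
    stopf("panel reflectance must be positive and finite")
  }
  if (any(pr > 1.05)) stopf("panel reflectance above 1.05 is not physical")
  if (min(wl) > 355 || max(wl) < 2495) {
    stopf("panel calibration must cover 350-2500 nm (got %.0f-%.0f)",
          min(wl), max(wl))
  }
  structure(data.frame(wavelength_nm = wl, panel_reflectance = pr),
            class = c("panel_calibration", "data.frame"))
}

#' Convert relative to absolute reflectance
#'
#' Multiplies relative reflectance by the panel's laboratory-calibrated
#' reflectance, linearly interpolated to the common grid.
#'
#' @param spectrum A `leaf_spectrum` of relative reflectance.
#' @param panel A [panel_calibration()].
#' @return A `leaf_spectrum` of absolute reflectance.
#' @export
to_absolute <- function(spectrum, panel) {
  stopifnot(inherits(spectrum, "leaf_spectrum"))
  if (!inherits(panel, "panel_calibration")) {
    panel <- panel_calibration(panel$wavelength_nm, panel$panel_reflectance)
  }
  p <- stats::approx(panel$wavelength_nm, panel$panel_reflectance,
                     xout = spectrum_grid(), rule = 2, ties = "ordered")$y
  new_spectrum(spectrum$reflectance * p, spectrum$meta)
}

#' Load and preprocess a campaign from a manifest
#'
#' The manifest is a CSV mapping files to metadata with columns `path`,
#' `treatment`, `array_id`, `tree_id`, `date`, `leaf_index`. Each file is
#' read, stitched, resampled to 1 nm, and (when a panel is given) converted
#' to absolute reflectance.
#'
#' @param manifest Path to the manifest CSV.
#' @param panel Optional [panel_calibration()] or path to a panel CSV.
#' @param dialect Spectrum-file dialect passed to [read_spectrum_file()].
#' @param policy Stitching policy passed to [stitch()].
#' @param base_dir Directory against which relative manifest paths resolve;
#'   defaults to the manifest's directory.
#' @return A `spectrum_set`.
#' @export
load_set <- function(manifest, panel = NULL, dialect = "auto",
                     policy = "cut", base_dir = NULL) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stopf("manifest %s is empty", manifest)
  need <- c("path", "treatment", "array_id", "tree_id", "date", "leaf_index")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stopf("manifest %s lacks columns: %s", manifest,
          paste(missing_cols, collapse = ", "))
  }
  incomplete <- !stats::complete.cases(tab[need])
  if (any(incomplete)) {
    stopf("metadata missing for files: %s",
          paste(tab$path[incomplete], collapse = ", "))
  }
  base_dir <- base_dir %||% dirname(manifest)
  if (is.character(panel)) panel <- read_panel(panel)
  spectra <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    p <- if (file.exists(r$path)) r$path else file.path(base_dir, r$path)
    m <- spectrum_meta(r$treatment, r$array_id, r$tree_id, r$date,
                       r$leaf_index, p)
    s <- resample_1nm(stitch(read_spectrum_file(p, dialect, meta = m),
                             policy = policy))
    if (!is.null(panel)) s <- to_absolute(s, panel) else s
  })
  spectrum_set(spectra)
}

#' Write a spectrum in the package CSV dialect
#' @param spectrum A `leaf_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(
    data.frame(wavelength_nm = spectrum$wavelength,
               reflectance = spectrum$reflectance),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write a spectrum set as a wide CSV
#'
#' One row per spectrum: the metadata columns followed by 2151 wavelength
#' columns `wl_350` .. `wl_2500`. Full double precision is retained so a
#' write/read round trip reproduces reflectance to better than 1e-9.
#'
#' @param set A `spectrum_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_set <- function(set, path) {
  wide <- cbind(set$meta, as.data.frame(set$reflectance))
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Read a wide-CSV spectrum set written by [write_spectrum_set()]
#' @param path File path.
#' @return A `spectrum_set`.
#' @export
read_spectrum_set <- function(path) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  wl_cols <- paste0("wl_", spectrum_grid())
  if (!all(wl_cols %in% names(wide))) {
    stopf("%s is not a wide spectrum_set CSV (missing wavelength columns)", path)
  }
  new_spectrum_set(as.matrix(wide[wl_cols]),
                   wide[intersect(meta_fields(), names(wide))])
}
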