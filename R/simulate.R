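# Synthetic leaf-reflectance campaigns.
#
# A deliberately simple leaf optical model -- not a physical radiative
# transfer model -- generates spectra with the qualitative shape and the
# hierarchical variance structure the analysis assumes:
#
#   R(lambda) = P(lambda) * exp(-sum_i c_i * A_i(lambda)) + eps(lambda)
#
# where P is a smooth envelope (high NIR plateau, declining SWIR), A_i is the
# absorbance profile of pigment/constituent i (a sum of Gaussian features:
# chlorophyll around 430/680 nm, carotenoids in the 450-500 nm band, water at
# 1450/1940 nm, dry matter at 1720/2100/2300 nm), c_i are abstract
# concentrations, and eps is white spectral noise. Concentrations vary on the
# log scale with independent tree, tree-by-date, and leaf effects, and the
# elevated-CO2 treatment acts multiplicatively on the pigment means (by
# default raising the carotenoid:chlorophyll ratio).

#' Gaussian absorption features of the leaf model
#'
#' Fixed package constants: one row per Gaussian feature with its pigment,
#' centre (nm), width (Gaussian sigma, nm) and strength per unit
#' concentration.
#'
#' @return A data frame with columns `pigment`, `center`, `sigma`, `strength`.
#' @export
absorption_features <- function() {
  data.frame(
    pigment = c("chl", "chl", "car", "car", "water", "water",
                "dm", "dm", "dm"),
    center  = c(430, 680, 460, 500, 1450, 1940, 1720, 2100, 2300),
    sigma   = c(60, 28, 40, 22, 55, 80, 75, 120, 85),
    strength = c(1.60, 1.90, 0.75, 0.55, 1.50, 1.30, 0.45, 0.55, 0.40),
    stringsAsFactors = FALSE
  )
}

pigment_names <- function() c("chl", "car", "water", "dm")

# 2151 x 4 absorbance-per-unit-concentration matrix, one column per pigment.
pigment_absorbance_matrix <- function(features = absorption_features()) {
  wl <- spectrum_grid()
  A <- matrix(0, length(wl), length(pigment_names()),
              dimnames = list(NULL, pigment_names()))
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    A[, f$pigment] <- A[, f$pigment] +
      f$strength * exp(-(wl - f$center)^2 / (2 * f$sigma^2))
  }
  A
}

#' Smooth reflectance envelope
#'
#' The absorption-free plateau: `level * (1 - curvature * ((lambda -
#' nir_center) / 1600)^2)`, floored at 0.02. High through the NIR, declining
#' into the SWIR and the near-UV.
#'
#' @param plateau List with `level`, `nir_center` (nm), `curvature`.
#' @return Numeric vector over the common grid.
#' @export
plateau_curve <- function(plateau = default_plateau()) {
  wl <- spectrum_grid()
  p <- plateau$level *
    (1 - plateau$curvature * ((wl - plateau$nir_center) / 1600)^2)
  pmax(p, 0.02)
}

#' @rdname plateau_curve
#' @export
default_plateau <- function() list(level = 0.384, nir_center = 950,
                                   curvature = 0.90)

#' Simulate one leaf spectrum
#'
#' @param c_chl,c_car,c_w,c_dm Nonnegative concentrations (abstract units;
#'   1 is a typical sunlit oak leaf under the package defaults).
#' @param plateau Envelope parameters, see [plateau_curve()].
#' @param noise_sd SD of white spectral noise (reflectance units).
#' @param meta A [spectrum_meta()] record.
#' @return A `leaf_spectrum`, clipped to `[0, 1]`.
#' @export
simulate_leaf_spectrum <- function(c_chl, c_car, c_w, c_dm,
                                   plateau = default_plateau(),
                                   noise_sd = 0, meta = spectrum_meta()) {
  conc <- c(chl = c_chl, car = c_car, water = c_w, dm = c_dm)
  if (any(conc < 0)) stopf("concentrations must be nonnegative")
  A <- pigment_absorbance_matrix()
  r <- plateau_curve(plateau) * exp(-as.vector(A %*% conc))
  if (noise_sd > 0) r <- r + stats::rnorm(length(r), 0, noise_sd)
  new_spectrum(pmin(pmax(r, 0), 1), meta)
}

#' Configuration of a simulated campaign
#'
#' Defaults reproduce the measured subset of the study design: 2 treatments
#' x 2 arrays per treatment x 2 trees per array x 4 dates x 30 leaves
#' (960 spectra; `n_total_per_treatment` can trim to realized totals).
#' Variance-component SDs act on log concentrations, independently per
#' pigment, at the tree, tree-by-date, and leaf levels; the defaults were
#' calibrated once so index-scale variances land in the magnitude bracket
#' reported for mature oak campaigns of this shape, with leaf-level variance
#' dominant.
#'
#' @param n_arrays_per_treatment Arrays per CO2 treatment.
#' @param n_trees_per_array Trees per array.
#' @param dates Character vector of measurement dates (ISO).
#' @param n_leaves_per_tree_per_date Leaves per tree per date.
#' @param seed Integer seed fixing the whole campaign.
#' @param pigment_means Named nonnegative means for `chl`, `car`, `water`, `dm`.
#' @param treatment_multipliers Multipliers applied to the pigment means
#'   under eCO2; the default raises carotenoid content, i.e. the
#'   carotenoid:chlorophyll ratio.
#' @param sd_tree,sd_tree_date,sd_leaf Log-scale SDs of the tree,
#'   tree-by-date, and leaf random effects.
#' @param noise_sd White spectral noise SD (reflectance units).
#' @param plateau Envelope parameters, see [plateau_curve()].
#' @param n_total_per_treatment Optional named vector (`aCO2`, `eCO2`);
#'   spectra beyond the target count are dropped from the end of each
#'   treatment to emulate realized (unbalanced) totals.
#' @return A validated list of class `leaf_sim_config`.
#' @export
leaf_sim_config <- function(n_arrays_per_treatment = 2,
                            n_trees_per_array = 2,
                            dates = c("2023-07-25", "2023-08-10",
                                      "2023-08-24", "2023-10-06"),
                            n_leaves_per_tree_per_date = 30,
                            seed = 1L,
                            pigment_means = c(chl = 1, car = 1,
                                              water = 1, dm = 1),
                            treatment_multipliers = c(chl = 1, car = 1.17,
                                                      water = 1, dm = 1),
                            sd_tree = 0.056,
                            sd_tree_date = 0.064,
                            sd_leaf = 0.17,
                            noise_sd = 0.004,
                            plateau = default_plateau(),
                            n_total_per_treatment = NULL) {
  cfg <- list(n_arrays_per_treatment = as.integer(n_arrays_per_treatment),
              n_trees_per_array = as.integer(n_trees_per_array),
              dates = as.character(dates),
              n_leaves_per_tree_per_date = as.integer(n_leaves_per_tree_per_date),
              seed = as.integer(seed),
              pigment_means = pigment_means[pigment_names()],
              treatment_multipliers = treatment_multipliers[pigment_names()],
              sd_tree = sd_tree, sd_tree_date = sd_tree_date,
              sd_leaf = sd_leaf, noise_sd = noise_sd, plateau = plateau,
              n_total_per_treatment = n_total_per_treatment)
  names(cfg$pigment_means) <- pigment_names()
  names(cfg$treatment_multipliers) <- pigment_names()
  if (anyNA(cfg$pigment_means) || any(cfg$pigment_means <= 0)) {
    stopf("pigment_means must be positive for all of: %s",
          paste(pigment_names(), collapse = ", "))
  }
  if (anyNA(cfg$treatment_multipliers) || any(cfg$treatment_multipliers <= 0)) {
    stopf("treatment_multipliers must be positive")
  }
  if (any(c(cfg$sd_tree, cfg$sd_tree_date, cfg$sd_leaf, cfg$noise_sd) < 0)) {
    stopf("SDs must be nonnegative")
  }
  if (length(cfg$dates) < 1) stopf("at least one date is required")
  if (cfg$n_leaves_per_tree_per_date < 1 || cfg$n_trees_per_array < 1 ||
      cfg$n_arrays_per_treatment < 1) {
    stopf("design counts must be at least 1")
  }
  if (is.na(cfg$seed)) stopf("seed is required")
  structure(cfg, class = "leaf_sim_config")
}

#' Read a campaign configuration from YAML
#' @param path YAML file whose keys mirror [leaf_sim_config()] arguments.
#' @return A `leaf_sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("pigment_means", "treatment_multipliers",
              "n_total_per_treatment")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$plateau)) raw$plateau <- as.list(raw$plateau)
  do.call(leaf_sim_config, raw)
}

#' Simulate a full leaf-reflectance campaign
#'
#' Draws tree, tree-by-date, and leaf random effects on log concentrations
#' (independently for each pigment), applies the treatment multipliers to the
#' pigment means, renders every leaf spectrum, and returns a fully labelled
#' `spectrum_set`. The campaign seed governs splittable per-tree substreams:
#' tree and date effects are drawn from a tree-level stream and leaf effects
#' from a separate per-tree stream, so adding leaves never perturbs tree
#' effects. Fully reproducible given `config$seed`.
#'
#' @param config A [leaf_sim_config()].
#' @return A `spectrum_set`.
#' @export
simulate_campaign <- function(config = leaf_sim_config()) {
  stopifnot(inherits(config, "leaf_sim_config"))
  A <- pigment_absorbance_matrix()
  P <- plateau_curve(config$plateau)
  np <- length(pigment_names())
  nd <- length(config$dates)
  nl <- config$n_leaves_per_tree_per_date
  treatments <- c("aCO2", "eCO2")
  blocks <- list(); metas <- list(); b <- 0L
  tree_counter <- 0L
  for (ti in seq_along(treatments)) {
    trt <- treatments[ti]
    mult <- if (trt == "eCO2") config$treatment_multipliers else rep(1, np)
    base_log <- log(config$pigment_means) + log(mult)
    for (ai in seq_len(config$n_arrays_per_treatment)) {
      array_id <- sprintf("%s%d", substr(trt, 1, 1), ai)
      for (wi in seq_len(config$n_trees_per_array)) {
        tree_counter <- tree_counter + 1L
        tree_id <- sprintf("%s_t%d", array_id, wi)
        # tree-level stream: tree effect + per-date effects, per pigment
        eff <- local_seed(derive_seed(config$seed, 1L, tree_counter), {
          list(tree = stats::rnorm(np, 0, config$sd_tree),
               date = matrix(stats::rnorm(np * nd, 0, config$sd_tree_date),
                             np, nd))
        })
        # leaf-level stream: leaf effects and spectral noise
        leafdraws <- local_seed(derive_seed(config$seed, 2L, tree_counter), {
          lapply(seq_len(nd), function(di) {
            list(leaf = matrix(stats::rnorm(np * nl, 0, config$sd_leaf),
                               np, nl),
                 noise = if (config$noise_sd > 0) {
                   matrix(stats::rnorm(GRID_N * nl, 0, config$noise_sd),
                          GRID_N, nl)
                 } else NULL)
          })
        })
        for (di in seq_len(nd)) {
          logc <- base_log + eff$tree + eff$date[, di] +
            leafdraws[[di]]$leaf           # np x nl
          conc <- exp(logc)
          refl <- P * exp(-A %*% conc)     # GRID_N x nl
          if (!is.null(leafdraws[[di]]$noise)) {
            refl <- refl + leafdraws[[di]]$noise
          }
          refl <- pmin(pmax(refl, 0), 1)
          b <- b + 1L
          blocks[[b]] <- t(refl)
          metas[[b]] <- data.frame(
            treatment = trt, array_id = array_id, tree_id = tree_id,
            date = config$dates[di], leaf_index = seq_len(nl),
            source_file = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  set <- new_spectrum_set(do.call(rbind, blocks), do.call(rbind, metas))
  if (!is.null(config$n_total_per_treatment)) {
    keep <- unlist(lapply(treatments, function(trt) {
      idx <- which(set$meta$treatment == trt)
      tgt <- config$n_total_per_treatment[[trt]] %||% length(idx)
      if (tgt > length(idx)) {
        stopf("n_total_per_treatment[%s] = %d exceeds generated count %d",
              trt, tgt, length(idx))
      }
      idx[seq_len(tgt)]
    }))
    set <- subset_spectra(set, sort(keep))
  }
  set
}

#' Noise-free index value implied by a configuration
#'
#' Evaluates the deterministic spectrum at the configured mean concentrations
#' (with treatment multipliers for eCO2) and computes an index from it: the
#' effect the simulator injects, before any hierarchy or noise.
#'
#' @param config A [leaf_sim_config()].
#' @param index Index name, see [index_names()].
#' @param treatment `"aCO2"` or `"eCO2"`.
#' @return Numeric index value.
#' @export
expected_index_value <- function(config, index, treatment = "aCO2") {
  mult <- if (treatment == "eCO2") config$treatment_multipliers else rep(1, 4)
  conc <- config$pigment_means * mult
  s <- simulate_leaf_spectrum(conc[["chl"]], conc[["car"]], conc[["water"]],
                              conc[["dm"]], plateau = config$plateau)
  compute_index(s, index)$value
}

#' @rdname expected_index_value
#' @return `expected_index_effect()`: the injected eCO2 minus aCO2 difference.
#' @export
expected_index_effect <- function(config, index) {
  expected_index_value(config, index, "eCO2") -
    expected_index_value(config, index, "aCO2")
}
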