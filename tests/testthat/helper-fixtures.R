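# Fixtures are built in code at test time; nothing binary is stored.

# Three-detector raw file emulating the instrument layout: VNIR 350-1000 nm
# @1.5 nm, SWIR1 (starting inside the VNIR overlap) @3.8 nm, SWIR2 @2.5 nm.
write_svc_fixture <- function(path, value_fun = function(wl) 0.2 + 0.1 * sin(wl / 300),
                              header = c("treatment= aCO2", "array_id= a1",
                                         "tree_id= a1_t1", "date= 2023-07-25",
                                         "leaf_index= 1")) {
  vnir <- seq(350, 1000, by = 1.5)
  swir1 <- seq(985, 1890, by = 3.8)
  swir2 <- seq(1880, 2500, by = 2.5)
  wl <- c(vnir, swir1, swir2)
  lines <- c(header, sprintf("%.2f %.8f", wl, value_fun(wl)))
  writeLines(lines, path)
  path
}

write_csv_spectrum <- function(path, wl, value) {
  utils::write.csv(data.frame(wavelength_nm = wl, reflectance = value),
                   path, row.names = FALSE, quote = FALSE)
  path
}

# A leaf_spectrum with smoothly varying positive reflectance; `jitter_seed`
# varies the curve between calls.
random_spectrum <- function(jitter_seed = 1) {
  wl <- spectrum_grid()
  r <- local_seed_helper(jitter_seed, {
    a <- runif(1, 0.1, 0.4); b <- runif(1, 0.05, 0.25)
    ph <- runif(2, 0, 2 * pi); f <- runif(2, 1 / 900, 1 / 150)
    a + b * (0.5 + 0.25 * sin(2 * pi * f[1] * wl + ph[1]) +
               0.25 * sin(2 * pi * f[2] * wl + ph[2]))
  })
  new_spectrum(r)
}

local_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

flat_spectrum <- function(c = 0.3) new_spectrum(rep(c, 2151))

# Spectrum with prescribed values at specific bands over a flat background.
banded_spectrum <- function(bands, background = 0.2) {
  r <- rep(background, 2151)
  for (nm in names(bands)) r[as.integer(nm) - 349L] <- bands[[nm]]
  new_spectrum(r)
}

# Small campaign configuration for fast tests.
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_arrays_per_treatment = 1, n_trees_per_array = 2,
         dates = "2023-07-25", n_leaves_per_tree_per_date = 5, seed = seed),
    list(...))
  do.call(leaf_sim_config, args)
}

# Balanced hierarchical index-style data frame for LMM tests.
make_lmm_data <- function(n_trees_per_trt = 4, n_leaves = 8, sd_tree = 1,
                          sd_resid = 1, effect = 0, seed = 1,
                          dates = "2023-07-25", sd_date = 0) {
  local_seed_helper(seed, {
    rows <- list()
    for (trt in c("aCO2", "eCO2")) {
      for (tr in seq_len(n_trees_per_trt)) {
        tree <- sprintf("%s_t%d", trt, tr)
        u <- rnorm(1, 0, sd_tree)
        for (d in dates) {
          v <- rnorm(1, 0, sd_date)
          rows[[length(rows) + 1]] <- data.frame(
            treatment = trt, tree_id = tree, date = d,
            array_id = substr(trt, 1, 1),
            value = (trt == "eCO2") * effect + u + v +
              rnorm(n_leaves, 0, sd_resid))
        }
      }
    }
    do.call(rbind, rows)
  })
}
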