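# small shared fixtures, generated in code

geom_iso <- function(n = 8, spacing = 3, origin = c(0, 0, 0)) {
  grid_geometry(rep(n, 3), rep(spacing, 3), origin)
}

uniform_dose <- function(value, geometry, label = "") {
  dose_grid(array(value, geometry$shape), geometry, label = label)
}

full_mask <- function(geometry, name = "all") {
  voi_mask(array(TRUE, geometry$shape), geometry, name = name)
}

# a small phantom used across suites: one lesion in a modest liver,
# mild correlated noise; everything inside the full-weight dose band
small_phantom <- function(seed = 3, noise_sigma = 0.05,
                          lesion_dose = 100, ntl_dose = 100) {
  generate_phantom(phantom_spec(
    geometry = grid_geometry(c(32, 32, 32), c(4, 4, 4),
                             origin = -c(62, 62, 62)),
    liver_semiaxes_mm = c(55, 50, 45),
    lesions = list(list(centre_mm = c(0, 0, 0), radius_mm = 15,
                        mean_dose_gy = lesion_dose)),
    ntl_mean_dose_gy = ntl_dose,
    noise_sigma = noise_sigma, noise_correlation_mm = 12, seed = seed))
}

# random in-band dose arrays for property sweeps
random_dose_pair <- function(geometry, lo = 0, hi = 250) {
  n <- prod(geometry$shape)
  list(pred = dose_grid(array(stats::runif(n, lo, hi), geometry$shape),
                        geometry),
       post = dose_grid(array(stats::runif(n, lo, hi), geometry$shape),
                        geometry))
}

# independent QF oracle: direct voxel summation from raw arrays,
# re-deriving Q and W from first principles (no package quality_map call)
qf_oracle <- function(pred_vals, post_vals, floor = 0.01,
                      zl = 10, fl = 40, fh = 120, zh = 200) {
  w1 <- function(d) {
    ifelse(d <= zl, 0,
      ifelse(d < fl, (d - zl) / (fl - zl),
        ifelse(d <= fh, 1,
          ifelse(d < zh, (zh - d) / (zh - fh), 0))))
  }
  w <- pmax(w1(pred_vals), w1(post_vals))
  strad <- (pred_vals < fl & post_vals > fh) | (post_vals < fl & pred_vals > fh)
  w[strad] <- 1
  q <- log10(pmax(post_vals, floor) / pmax(pred_vals, floor))
  sum(abs(q) * w) / sum(w)
}
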