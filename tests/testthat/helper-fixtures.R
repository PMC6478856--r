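# Shared fixtures, all built in code.

identity_curve <- function(range = c(4000, 6000), sigma = 0) {
  make_synthetic_curve("identity", range = range, sigma = sigma)
}

# minimal well-formed database rows
toy_dates <- function(n = 3, ...) {
  df <- data.frame(
    lab_id = sprintf("L%03d", seq_len(n)),
    site_id = "S001",
    site_name = "Toy site",
    region = "Mediterranean",
    latitude = 38.5, longitude = -0.5,
    site_type = "cave_rockshelter",
    material = "bone collagen",
    material_class = "short_lived",
    aggregate_consistent = TRUE,
    c14_age_bp = seq(9000, by = 150, length.out = n),
    c14_error = 50,
    d13c = -20,
    curve_class = "atmospheric",
    context_id = sprintf("ctx%03d", seq_len(n)),
    stringsAsFactors = FALSE)
  upd <- list(...)
  for (k in names(upd)) df[[k]] <- upd[[k]]
  df
}

# a density list -> bin structure for sum_probabilities
as_bins <- function(...) lapply(list(...), function(x)
  if (inherits(x, "cal_density")) list(x) else x)

# brute-force oracle: full-grid Gaussian evaluation of a calibrated density
oracle_calibrate <- function(age, err, curve) {
  w <- dnorm(age, curve$c14_mean, sqrt(err^2 + curve$c14_sigma^2))
  w / sum(w)
}
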