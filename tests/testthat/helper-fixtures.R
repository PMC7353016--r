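# Shared fixture builders for the suite. Everything is generated in code,
# deterministically where a seed is given.

# A tiny complete survey: `n` records in `n_eas` EAs on a small lattice.
make_survey <- function(n = 20, n_eas = 5, group = "WRA", serum = NULL) {
  ea_idx <- rep_len(seq_len(n_eas), n)
  tibble::tibble(
    person_id = sprintf("P%03d", seq_len(n)),
    ea_id = sprintf("EA%02d", ea_idx),
    region = rep_len(c("North", "South"), n),
    group = rep_len(group, n),
    sex = rep_len(c("F", "M"), n),
    residence = rep_len(c("urban", "rural"), n),
    weight = 1,
    lat = 8 + ea_idx * 0.5,
    lon = 38 + ea_idx * 0.7,
    serum_se_ugL = if (is.null(serum)) 60 + seq_len(n) else rep_len(serum, n)
  )
}

# EA sample table from a simulated Gaussian field at uniform locations.
make_ea_field <- function(n = 60, model = exp_variogram(2.51, 26.23, 132.8),
                          mean = 103.6, seed = 42) {
  loc <- simulate_ea_locations(n, seed = seed)
  z <- simulate_grf(model, loc$lat, loc$lon, mean = mean, seed = seed + 1L)
  tibble::tibble(ea_id = sprintf("EA%03d", seq_len(n)),
                 mean_lat = loc$lat, mean_lon = loc$lon,
                 mean_se = z, n = 1L)
}

# Wrap a bin table as an empirical_variogram without going through a cloud.
as_emp <- function(lag, gamma, n_pairs = 100L, estimator = "matheron") {
  structure(tibble::tibble(lag = lag, gamma = gamma, n_pairs = n_pairs),
            estimator = estimator, bins = NULL, bearing_class = NA_real_,
            class = c("empirical_variogram", "tbl_df", "tbl", "data.frame"))
}
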