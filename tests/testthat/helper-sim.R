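# Shared fixtures: small simulated experiments built in code at test time.

# a compact noiseless experiment with known thresholds
tiny_experiment <- function(ftswc = c(0.15, 0.3, 0.45), noise_sd_g = 0,
                            seed = 11, n_days = 19, ...) {
  profiles <- cultivar_profiles(sprintf("CV%02d", seq_along(ftswc)),
                                ftswc_true = ftswc)
  design <- drydown_design(n_days = n_days, noise_sd_g = noise_sd_g,
                           seed = seed, ...)
  simulate_experiment(profiles, design)
}

# exact two-segment response points on a regular FTSW grid
piecewise_points <- function(ftswc, plateau = 1, step = 0.05) {
  f <- seq(0, 1, by = step)
  data.frame(ftsw = f, ntr = plateau * pmin(1, f / ftswc))
}
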