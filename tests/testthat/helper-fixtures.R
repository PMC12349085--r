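# Shared fixtures: built in code, no binary data.

# A reduced version of the default scenario (16 specimens instead of 38)
# for tests that need a full dataset but not the full design.
small_scenario <- function(seed = 42L) {
  sc <- default_scenario(seed)
  n_small <- c(echinoderm = 2L, ammonoid = 3L, coleoid = 2L, arthropod = 2L,
               sponge = 2L, brachiopod = 2L, actinopterygian = 2L,
               sarcopterygian = 1L)
  for (cl in names(n_small)) sc$clades[[cl]]$n <- n_small[[cl]]
  sc$n_ppa <- 1L
  validate_scenario(sc)
}

# A random valid spectrum on an irregular grid.
random_spectrum <- function(n = 100L, seed = 1L, zone_id = "rnd") {
  set.seed(seed)
  energy <- sort(runif(n, 0.2, 20.6))
  while (any(diff(energy) <= 0)) energy <- sort(runif(n, 0.2, 20.6))
  xrf_spectrum(energy, rpois(n, 50), zone_id)
}

# A smooth random landmark-matrix row (for constructed alignment tests).
smooth_row <- function(seed) {
  set.seed(seed)
  g <- landmark_grid()
  as.numeric(sin(2 * pi * g / runif(1, 3, 9) + runif(1, 0, 2 * pi)) +
               0.3 * rnorm(831))
}

# Constructed multi-session landmark matrix: `n_zones` control zones present
# in every session plus `n_extra` session-specific zones, a per-session
# additive offset curve, and iid noise of sd `noise_sd`.
constructed_sessions <- function(offsets, n_zones = 10L, n_extra = 10L,
                                 noise_sd = 0, seed = 7L) {
  set.seed(seed)
  sessions <- names(offsets)
  base <- t(vapply(seq_len(n_zones + n_extra * length(sessions)),
                   function(i) smooth_row(seed + i), numeric(831)))
  rows <- list()
  meta <- list()
  r <- 0L
  for (si in seq_along(sessions)) {
    s <- sessions[si]
    zone_rows <- c(seq_len(n_zones),
                   n_zones + (si - 1L) * n_extra + seq_len(n_extra))
    for (z in zone_rows) {
      r <- r + 1L
      rows[[r]] <- base[z, ] + offsets[[s]] +
        if (noise_sd > 0) rnorm(831, 0, noise_sd) else 0
      meta[[r]] <- data.frame(
        zone_id = paste0("z", z), file = "", specimen_id = "spec",
        site = "Paris Canyon", clade = "echinoderm",
        zone_type = "fossil", session = s, mineralogy = "calcitic",
        stringsAsFactors = FALSE)
    }
  }
  landmark_matrix(do.call(rbind, rows), do.call(rbind, meta))
}
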