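# small-volume parameter sets used across tests: same physics, 16-um box,
# denser sites so a few are present
small_params <- function(...) {
  sim_params(edge_length = 16, site_density = 5e-3, ...)
}

# hand-built site sets for geometric oracles
manual_sites <- function(xyz, grid) {
  df <- tibble::tibble(site = seq_len(nrow(xyz)),
                       x = as.integer(xyz[, 1]), y = as.integer(xyz[, 2]),
                       z = as.integer(xyz[, 3]),
                       cohort = factor(rep("tonic", nrow(xyz)),
                                       levels = c("tonic", "phasic")))
  dopaflux:::new_release_sites(df, grid, NA_real_, NA_integer_)
}
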