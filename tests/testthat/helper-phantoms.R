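# Shared fixtures: small acquisitions (reduced matrix, full echo train) so
# simulation-heavy tests stay fast; the acquisition *parameters* other than
# matrix/slices are the package defaults (30 echoes at 9 ms, TR 4000 ms).

small_acq <- function(n = 48, slices = 2) {
  acq_params(matrix_size = c(n, n), n_slices = slices)
}

# Fit + summarize one phantom with its ground-truth mask.
phantom_metrics <- function(ph, method = "nls") {
  map <- fit_map(ph$stack, muscle_mask(ph$truth$mask_true), method = method)
  summarize_t2(map)
}

# Rician-corrupted decay matrix: nv voxels of S0*exp(-te/t2) with the
# noise channels scaled so the first-echo SNR equals `snr`.
rician_decays <- function(nv, t2, te, s0 = 500, snr = 50) {
  sigma <- s0 * exp(-te[1] / t2) / snr
  clean <- s0 * exp(outer(rep(-1 / t2, nv), te))
  g1 <- matrix(stats::rnorm(nv * length(te), 0, sigma), nv)
  g2 <- matrix(stats::rnorm(nv * length(te), 0, sigma), nv)
  sqrt((clean + g1)^2 + g2^2)
}
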