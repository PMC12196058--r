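# Shared fixtures: small simulated campaigns and hand-built batches.

tiny_campaign <- function(n_batches = 3L, rows = c(120L, 160L), seed = 1L,
                          ...) {
  simulate_campaign(sim_config(n_batches = n_batches,
                               rows_per_batch = rows, seed = seed,
                               ...))$campaign
}

# A hand-built batch with fully controlled fields (17 parameters, no
# spray-rate column so the phase/spray invariant does not apply).
manual_batch <- function(n = 30L, batch_id = "b1",
                         phase = rep(c("spray", "drying"),
                                     c(ceiling(0.7 * n),
                                       n - ceiling(0.7 * n))),
                         lod = NULL, seed = 1L) {
  set.seed(seed)
  spectra <- matrix(rnorm(n * 256, 1, 0.1), n, 256)
  colnames(spectra) <- sprintf("%.10g", as.numeric(spectral_grid()))
  params <- matrix(rnorm(n * 17, 10, 1), n, 17,
                   dimnames = list(NULL, process_parameters()))
  dv50 <- seq(150, 250, length.out = n)
  sizes <- outer(dv50, c(0.45, 0.7, 1, 1.4, 1.9))
  colnames(sizes) <- c("dv10", "dv25", "dv50", "dv75", "dv90")
  batch_record(batch_id, times = seq_len(n), spectra = spectra,
               params = params, sizes = sizes, lod = lod, phase = phase)
}
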