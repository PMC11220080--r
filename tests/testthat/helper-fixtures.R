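# shared fixtures, built in code

grid8x3 <- function() rep(seq(0, 21, by = 3), each = 3)

cosine_series <- function(times, mesor = 5, amplitude = 1, phase = 7,
                          noise_sd = 0, period = 24) {
  y <- mesor + amplitude * cos(2 * pi * (times - phase) / period)
  if (noise_sd > 0) y <- y + rnorm(length(times), 0, noise_sd)
  y
}

toy_matrix <- function(values, condition = "STD", compartment = "RNA",
                       times = NULL, prefix = "s") {
  n <- ncol(values)
  if (is.null(times)) times <- rep(seq(0, 21, by = 3), length.out = n)
  reps <- stats::ave(seq_len(n), times, FUN = seq_along)
  samples <- data.frame(
    sample_id = paste0(prefix, seq_len(n)), condition = condition,
    ct_hours = times, replicate = reps, compartment = compartment,
    stringsAsFactors = FALSE
  )
  colnames(values) <- samples$sample_id
  abundance_matrix(values, samples)
}

# a minimal rhythm_fits-like table for classifier tests
fake_calls <- function(ids, rhythmic, phase = NA_real_, amplitude = NA_real_) {
  data.frame(series_id = ids, consensus_rhythmic = rhythmic,
             acrophase = rep_len(phase, length(ids)),
             amplitude = rep_len(amplitude, length(ids)),
             stringsAsFactors = FALSE)
}

# benchmark design used in recovery tests: balanced classes, strong effects
benchmark_config <- function(n_genes = 1000, seed = 101, layers = c("RNA")) {
  cd <- rbind(c(LOR = 0.2, GOR = 0.2, ROR_stable = 0.2,
                ROR_advance = 0.1, NRB = 0.3))
  cd <- cd[rep(1, length(layers)), , drop = FALSE]
  rownames(cd) <- layers
  pd <- list(RNA = list(type = "uniform"),
             TE = list(type = "bimodal", centers = c(7, 17), sd = 1.5),
             NE = list(type = "unimodal", centers = 20, sd = 1.5))[layers]
  sim_config(n_genes = n_genes, layers = layers, change_design = cd,
             phase_dist = pd, amplitude_mean = 0.8, amplitude_sd = 0.2,
             amplitude_floor = 0.5, noise_sd = 0.2, dropout_rate = 0,
             advance_hours = 6, sampling = "quota", seed = seed)
}
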