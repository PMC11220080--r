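test_that("noiseless rhythmic series realize the exact cosine design", {
  cd <- rbind(RNA = c(LOR = 0, GOR = 0, ROR_stable = 1,
                      ROR_advance = 0, NRB = 0))
  cfg <- sim_config(n_genes = 3, layers = "RNA",
                    phase_dist = list(RNA = list(type = "unimodal",
                                                 centers = 6, sd = 0)),
                    change_design = cd, amplitude_mean = 1,
                    amplitude_sd = 0, amplitude_floor = 1,
                    noise_sd = 0, dropout_rate = 0,
                    baseline_mean = 10, baseline_sd = 0, seed = 3)
  sim <- generate_multiomics(cfg)
  m <- sim$matrices$RNA$STD
  y <- log2(m$values[1, ] + 1)
  at <- function(ct) mean(y[m$samples$ct_hours == ct])
  # peak at CT6 exceeds trough at CT18 by 2 log2 units (peak-to-trough = 2A)
  expect_equal(at(6) - at(18), 2, tolerance = 1e-3)
  expect_equal(sim$truth$phase_std, rep(6, 3))
  expect_equal(sim$truth$amplitude_std, rep(1, 3))
})

test_that("same config and seed give bitwise-identical output", {
  cfg <- sim_config(n_genes = 25, seed = 99)
  a <- generate_multiomics(cfg)
  b <- generate_multiomics(cfg)
  expect_identical(a$matrices, b$matrices)
  expect_identical(a$truth, b$truth)
})

test_that("quota sampling realizes the configured class counts exactly", {
  cfg <- benchmark_config(n_genes = 500, seed = 21)
  sim <- generate_multiomics(cfg)
  tab <- table(sim$truth$design_class)
  expect_equal(unname(tab[c("LOR", "GOR", "ROR_stable",
                            "ROR_advance", "NRB")]),
               c(100, 100, 100, 50, 150), ignore_attr = TRUE)
  # truth booleans consistent with the class
  with(sim$truth, {
    expect_true(all(rhythmic_std == (change_class %in% c("LOR", "ROR"))))
    expect_true(all(rhythmic_ecd == (change_class %in% c("GOR", "ROR"))))
    expect_true(all(abs(phase_shift) <= 12, na.rm = TRUE))
  })
})

test_that("binomial sampling lands in the binomial 99% CI of the target", {
  cd <- rbind(RNA = c(LOR = 0.13, GOR = 0, ROR_stable = 0.13,
                      ROR_advance = 0, NRB = 0.74))
  cfg <- sim_config(n_genes = 1000, layers = "RNA", change_design = cd,
                    phase_dist = list(RNA = list(type = "uniform")),
                    sampling = "binomial", seed = 8)
  sim <- generate_multiomics(cfg)
  n_rhy <- sum(sim$truth$rhythmic_std)
  margin <- qnorm(0.995) * sqrt(1000 * 0.26 * 0.74)
  expect_gt(n_rhy, 260 - margin)
  expect_lt(n_rhy, 260 + margin)
})

test_that("phase advance is applied toward earlier CT for shifted series", {
  cfg <- benchmark_config(n_genes = 200, seed = 4)
  sim <- generate_multiomics(cfg)
  adv <- sim$truth[sim$truth$design_class == "ROR_advance", ]
  expect_true(all(abs(wrap_shift <- ((adv$phase_std - adv$phase_ecd) %% 24) - 6)
                  < 1e-9))
  expect_true(all(adv$phase_shift == -6))
  stable <- sim$truth[sim$truth$design_class == "ROR_stable", ]
  expect_true(all(stable$phase_shift == 0))
})

test_that("noiseless cosinor recovers every designed phase and amplitude", {
  cd <- rbind(RNA = c(LOR = 0.5, GOR = 0, ROR_stable = 0.5,
                      ROR_advance = 0, NRB = 0))
  cfg <- sim_config(n_genes = 40, layers = "RNA", change_design = cd,
                    phase_dist = list(RNA = list(type = "uniform")),
                    noise_sd = 0, dropout_rate = 0, seed = 13)
  sim <- generate_multiomics(cfg)
  # protein-style layer would be exact; counts round, so test on TE instead
  cfgp <- sim_config(n_genes = 40, layers = "TE",
                     change_design = rbind(TE = cd[1, ]),
                     phase_dist = list(TE = list(type = "uniform")),
                     noise_sd = 0, dropout_rate = 0,
                     baseline_mean = 10, baseline_sd = 0.5, seed = 13)
  simp <- generate_multiomics(cfgp)
  m <- simp$matrices$TE$STD
  tr <- simp$truth
  Y <- log2(m$values + 1)
  for (i in seq_len(10)) {
    fit <- cosinor_fit(Y[i, ], m$samples$ct_hours)
    # log2(x+1) of a large-mesor series is log2(x) up to ~2^-mesor
    expect_equal(fit$acrophase, tr$phase_std[i], tolerance = 1e-2)
    expect_equal(fit$amplitude, tr$amplitude_std[i], tolerance = 1e-2)
  }
})

test_that("TMT plexing round-trips through bridge normalization", {
  set.seed(31)
  v <- matrix(rexp(40 * 32) * 50, 40, 32,
              dimnames = list(sprintf("p%02d", 1:40), NULL))
  tp <- rep(seq(0, 21, 3), each = 4)
  m <- toy_matrix(v, times = tp, compartment = "TE")
  # zero jitter: normalized values equal original / per-series grand mean
  plexes <- generate_tmt_plexes(m, plex_size = 18, bridge_count = 2,
                                plex_scale_jitter = 0, seed = 1)
  expect_length(plexes, 2)
  norm <- bridge_normalize(plexes)
  rel <- m$values / rowMeans(m$values)
  expect_equal(norm$values[, colnames(m$values)], rel)
  # unit-grand-mean input: exact identity round trip
  mu <- toy_matrix(rel, times = tp, compartment = "TE", prefix = "u")
  normu <- bridge_normalize(generate_tmt_plexes(mu, plex_scale_jitter = 0))
  expect_equal(normu$values[, colnames(mu$values)], mu$values)
  # with jitter, cross-plex disagreement vanishes after normalization
  pj <- generate_tmt_plexes(m, plex_scale_jitter = 0.3, seed = 2)
  nj <- bridge_normalize(pj)
  expect_equal(nj$values[, colnames(m$values)], rel, tolerance = 1e-12)
  # non-partitionable layouts rejected
  m2 <- subset_samples(m, 1:30)
  expect_error(generate_tmt_plexes(m2), "not partitionable")
})
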