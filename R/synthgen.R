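#' Configuration for the synthetic multi-omics generator
#'
#' Defines a two-condition (STD vs ECD), three-layer (RNA, TE, NE) circadian
#' study design with known ground truth. Defaults emulate the design the
#' package targets: 8 timepoints at 3-h spacing, triplicates, per-layer
#' rhythmic fractions and change-class mixtures derived from published
#' liver multi-omics counts, a 6-h phase advance for shifted series,
#' log-normal (Gaussian on log2) measurement noise, and transcript count
#' dropout.
#'
#' `change_design` is a layer x class matrix of probabilities over the five
#' design classes `LOR` (rhythmic under STD only), `GOR` (ECD only),
#' `ROR_stable` (both, same phase), `ROR_advance` (both, ECD phase advanced
#' by `advance_hours`), and `NRB` (neither); rows must sum to 1.
#'
#' @param n_genes number of genes (one series per gene per layer).
#' @param timepoints sampling grid in CT hours, strictly increasing within
#'   \[0, 24).
#' @param n_replicates replicates per timepoint.
#' @param layers molecular layers to simulate.
#' @param change_design layer x class probability matrix (rows `layers`,
#'   columns `LOR`, `GOR`, `ROR_stable`, `ROR_advance`, `NRB`).
#' @param amplitude_mean,amplitude_sd,amplitude_floor log2 half-amplitude
#'   distribution: `max(amplitude_floor, Normal(mean, sd))` draws.
#' @param phase_dist named list per layer; each entry has `type`
#'   (`"uniform"`, `"unimodal"` or `"bimodal"`), and for the modal types
#'   `centers` (CT hours) and `sd` (hours; wrapped-normal spread).
#' @param advance_hours ECD phase advance applied to `ROR_advance` series
#'   (ECD peak earlier: `phi_ECD = wrap(phi_STD - advance_hours)`).
#' @param noise_sd sd of additive Gaussian noise on the log2 scale.
#' @param baseline_mean,baseline_sd log2 mesor distribution.
#' @param dropout_rate probability a transcript count is zeroed, emulating
#'   detection failure. Off by default: at the default mesor scale
#'   (counts around 2^8) technical zeros are implausible, and a zeroed
#'   high-abundance count is an extreme log-scale outlier. Set it when
#'   simulating low-abundance series for the detection filter.
#' @param sampling `"quota"` (realized class counts equal the rounded
#'   quotas exactly; default) or `"binomial"` (independent draws).
#' @param seed integer root seed; all generator randomness derives from it.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_genes = 1000,
                       timepoints = seq(0, 21, by = 3),
                       n_replicates = 3,
                       layers = c("RNA", "TE", "NE"),
                       change_design = NULL,
                       amplitude_mean = 0.5,
                       amplitude_sd = 0.2,
                       amplitude_floor = 0.2,
                       phase_dist = NULL,
                       advance_hours = 6,
                       noise_sd = 0.2,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       dropout_rate = 0,
                       sampling = c("quota", "binomial"),
                       seed = 1L) {
  sampling <- match.arg(sampling)
  classes <- c("LOR", "GOR", "ROR_stable", "ROR_advance", "NRB")
  if (is.null(change_design)) {
    # mixtures matching published liver multi-omics counts: RNA 26% rhythmic STD / 16% ECD, TE 3.9%/12.4%,
    # NE 9.3%/4.9%; ~21% of retained transcript rhythms phase-advance
    change_design <- rbind(
      RNA = c(0.148, 0.050, 0.089, 0.024, 0.689),
      TE  = c(0.036, 0.121, 0.002, 0.001, 0.840),
      NE  = c(0.087, 0.043, 0.004, 0.002, 0.864)
    )
    colnames(change_design) <- classes
    change_design <- change_design[layers, , drop = FALSE]
  }
  change_design <- as.matrix(change_design)
  if (!all(layers %in% rownames(change_design)) ||
      !identical(colnames(change_design), classes)) {
    stop("change_design needs rows for each layer and columns ",
         paste(classes, collapse = ", "))
  }
  if (any(change_design < 0) || any(change_design > 1)) {
    stop("change_design probabilities must lie in [0, 1]")
  }
  if (any(abs(rowSums(change_design) - 1) > 1e-8)) {
    stop("change_design rows must sum to 1")
  }
  if (is.null(phase_dist)) {
    phase_dist <- list(
      RNA = list(type = "uniform"),
      TE  = list(type = "bimodal", centers = c(7, 17), sd = 1.5),
      NE  = list(type = "unimodal", centers = 20, sd = 1.5)
    )[layers]
  }
  if (!all(layers %in% names(phase_dist))) {
    stop("phase_dist must name every layer")
  }
  if (is.unsorted(timepoints, strictly = TRUE) ||
      any(timepoints < 0 | timepoints >= 24)) {
    stop("timepoints must be strictly increasing within [0, 24)")
  }
  if (amplitude_floor <= 0) stop("amplitude_floor must be > 0")
  if (dropout_rate < 0 || dropout_rate > 1) stop("dropout_rate in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(
    n_genes = as.integer(n_genes), timepoints = timepoints,
    n_replicates = as.integer(n_replicates), layers = layers,
    change_design = change_design, amplitude_mean = amplitude_mean,
    amplitude_sd = amplitude_sd, amplitude_floor = amplitude_floor,
    phase_dist = phase_dist, advance_hours = advance_hours,
    noise_sd = noise_sd, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, dropout_rate = dropout_rate,
    sampling = sampling, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes x ", length(x$layers),
      " layers; ", length(x$timepoints), " timepoints x ",
      x$n_replicates, " replicates x 2 conditions\n", sep = "")
  cat("  sampling: ", x$sampling, ", noise_sd ", x$noise_sd,
      ", dropout ", x$dropout_rate, ", advance ", x$advance_hours,
      " h, seed ", x$seed, "\n", sep = "")
  print(round(x$change_design, 3))
  invisible(x)
}

draw_phases <- function(n, spec) {
  if (n == 0L) return(numeric(0))
  switch(spec$type,
    uniform = stats::runif(n, 0, 24),
    unimodal = wrap_ct(stats::rnorm(n, spec$centers[1], spec$sd)),
    bimodal = {
      ctr <- sample(spec$centers, n, replace = TRUE)
      wrap_ct(stats::rnorm(n, ctr, spec$sd))
    },
    stop("unknown phase_dist type: ", spec$type)
  )
}

# integer quotas via largest remainder; remainder slack goes to NRB
quota_counts <- function(p, n) {
  k <- floor(p * n)
  rem <- p * n - k
  short <- n - sum(k)
  if (short > 0) {
    ord <- order(rem, decreasing = TRUE)
    k[ord[seq_len(short)]] <- k[ord[seq_len(short)]] + 1L
  }
  as.integer(k)
}

#' Generate a synthetic two-condition multi-omics dataset
#'
#' For each (gene, layer), a change class is drawn from the configured
#' mixture; rhythmic series follow
#' `mesor + A * cos(2 * pi * (t - phi) / 24)` on the log2 scale plus
#' `Normal(0, noise_sd)` per sample, non-rhythmic series are flat plus
#' noise. Transcripts are back-transformed to counts
#' (`round(2^x - 1)`, floored at 0) with Bernoulli dropout; protein layers
#' are linear intensities `2^x`. The returned truth table records the
#' realized design exactly.
#'
#' @param cfg a [sim_config()].
#' @return a `multiomics_sim` list: `matrices` (nested list
#'   `matrices[[layer]][[condition]]` of [abundance_matrix()]), `truth`
#'   (data.frame with gene, layer, change_class, per-condition rhythmicity,
#'   amplitude, phase, and signed phase shift), and `config`.
#' @export
generate_multiomics <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  classes <- colnames(cfg$change_design)
  tp <- cfg$timepoints
  nrep <- cfg$n_replicates
  tvec <- rep(tp, each = nrep)
  repv <- rep(seq_len(nrep), times = length(tp))

  truth_list <- list()
  matrices <- list()
  for (layer in cfg$layers) {
    p <- cfg$change_design[layer, ]
    cls <- if (cfg$sampling == "quota") {
      sample(rep(classes, quota_counts(p, cfg$n_genes)))
    } else {
      sample(classes, cfg$n_genes, replace = TRUE, prob = p)
    }
    rhy_std <- cls %in% c("LOR", "ROR_stable", "ROR_advance")
    rhy_ecd <- cls %in% c("GOR", "ROR_stable", "ROR_advance")
    amp_draw <- function(n) {
      pmax(cfg$amplitude_floor,
           stats::rnorm(n, cfg$amplitude_mean, cfg$amplitude_sd))
    }
    amp_std <- ifelse(rhy_std, amp_draw(cfg$n_genes), NA_real_)
    # retained rhythms keep their STD amplitude; gained rhythms draw fresh
    amp_ecd <- ifelse(cls %in% c("ROR_stable", "ROR_advance"), amp_std,
                      ifelse(rhy_ecd, amp_draw(cfg$n_genes), NA_real_))
    ph_std <- rep(NA_real_, cfg$n_genes)
    ph_std[rhy_std] <- draw_phases(sum(rhy_std), cfg$phase_dist[[layer]])
    ph_ecd <- rep(NA_real_, cfg$n_genes)
    ph_ecd[cls == "ROR_stable"] <- ph_std[cls == "ROR_stable"]
    ph_ecd[cls == "ROR_advance"] <-
      wrap_ct(ph_std[cls == "ROR_advance"] - cfg$advance_hours)
    ph_ecd[cls == "GOR"] <- draw_phases(sum(cls == "GOR"),
                                        cfg$phase_dist[[layer]])
    mesor <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)

    mk_cond <- function(cond) {
      rhy <- if (cond == "STD") rhy_std else rhy_ecd
      amp <- if (cond == "STD") amp_std else amp_ecd
      phi <- if (cond == "STD") ph_std else ph_ecd
      a <- ifelse(rhy, amp, 0)
      f <- ifelse(rhy, phi, 0)
      expected <- mesor + outer(a, tvec, function(A, t) A) *
        cos(2 * pi * sweep(matrix(tvec, cfg$n_genes, length(tvec),
                                  byrow = TRUE), 1, f, "-") / 24)
      x <- expected + matrix(stats::rnorm(length(expected), 0, cfg$noise_sd),
                             nrow = cfg$n_genes)
      if (layer == "RNA") {
        v <- pmax(round(2^x - 1), 0)
        if (cfg$dropout_rate > 0) {
          drop <- matrix(stats::runif(length(v)) < cfg$dropout_rate,
                         nrow = nrow(v))
          v[drop] <- 0
        }
      } else {
        v <- 2^x
      }
      dimnames(v) <- list(genes, sprintf("%s_%s_CT%02d_R%d", cond, layer,
                                         tvec, repv))
      samples <- data.frame(
        sample_id = colnames(v), condition = cond, ct_hours = tvec,
        replicate = repv, compartment = layer,
        stringsAsFactors = FALSE
      )
      abundance_matrix(v, samples)
    }
    matrices[[layer]] <- list(STD = mk_cond("STD"), ECD = mk_cond("ECD"))

    change_class <- ifelse(cls %in% c("ROR_stable", "ROR_advance"), "ROR", cls)
    truth_list[[layer]] <- data.frame(
      gene = genes, layer = layer, design_class = cls,
      change_class = change_class,
      rhythmic_std = rhy_std, rhythmic_ecd = rhy_ecd,
      amplitude_std = amp_std, amplitude_ecd = amp_ecd,
      phase_std = ph_std, phase_ecd = ph_ecd,
      phase_shift = ifelse(change_class == "ROR",
                           circ_diff(ph_std, ph_ecd), NA_real_),
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL
  structure(list(matrices = matrices, truth = truth, config = cfg),
            class = "multiomics_sim")
}

#' @export
print.multiomics_sim <- function(x, ...) {
  cat("<multiomics_sim> ", x$config$n_genes, " genes, layers: ",
      paste(x$config$layers, collapse = ", "), "\n", sep = "")
  print(table(x$truth$layer, x$truth$change_class))
  invisible(x)
}

#' Split an abundance matrix into TMT plexes with bridge channels
#'
#' Emulates multiplexed isobaric labelling: real sample columns are
#' partitioned into plexes of `plex_size - bridge_count` each, every plex's
#' columns (including its bridges) are multiplied by a shared log-normal
#' plex factor, and each bridge column carries the per-series grand mean
#' across all samples times the plex factor. [bridge_normalize()] then
#' removes the plex factors exactly, recovering each series' relative
#' abundance (value over per-series grand mean) in every plex.
#'
#' @param mat an [abundance_matrix()] of linear-scale intensities.
#' @param plex_size total channels per plex, bridges included (default 18).
#' @param bridge_count bridge (spike) channels per plex (default 2).
#' @param plex_scale_jitter sd of the log plex factor
#'   (`factor = exp(Normal(0, jitter))`); 0 gives unit factors.
#' @param seed optional seed for the plex factors.
#' @return a list of [abundance_matrix()] objects, one per plex, with
#'   bridge columns flagged `is_bridge` and carrying the plex id.
#' @export
generate_tmt_plexes <- function(mat, plex_size = 18, bridge_count = 2,
                                plex_scale_jitter = 0.1, seed = NULL) {
  stopifnot(inherits(mat, "abund_mat"))
  if (!is.null(seed)) set.seed(seed)
  real_per_plex <- plex_size - bridge_count
  n <- ncol(mat$values)
  if (real_per_plex <= 0) stop("plex_size must exceed bridge_count")
  if (n %% real_per_plex != 0) {
    stop(n, " samples are not partitionable into plexes of ",
         real_per_plex, " real channels (plex_size ", plex_size,
         " with ", bridge_count, " bridges)")
  }
  n_plexes <- n %/% real_per_plex
  gm <- rowMeans(mat$values)
  factors <- exp(stats::rnorm(n_plexes, 0, plex_scale_jitter))
  lapply(seq_len(n_plexes), function(p) {
    idx <- ((p - 1) * real_per_plex + 1):(p * real_per_plex)
    v <- mat$values[, idx, drop = FALSE] * factors[p]
    bridges <- matrix(rep(gm * factors[p], bridge_count),
                      ncol = bridge_count,
                      dimnames = list(rownames(mat$values),
                                      sprintf("plex%d_bridge%d", p,
                                              seq_len(bridge_count))))
    samples <- mat$samples[idx, , drop = FALSE]
    samples$plex <- p
    samples$is_bridge <- FALSE
    bs <- samples[rep(1, bridge_count), , drop = FALSE]
    bs$sample_id <- colnames(bridges)
    bs$is_bridge <- TRUE
    bs$condition <- samples$condition[1]
    bs$replicate <- seq_len(bridge_count) + max(mat$samples$replicate)
    abundance_matrix(cbind(v, bridges), rbind(samples, bs))
  })
}
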