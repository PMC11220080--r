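#' Pipeline configuration
#'
#' Bundles the thresholds, seeds and simulation design for a full
#' simulate -> filter -> detect -> compare -> overlap -> popstats run.
#' Mirrors the asymmetric transcript/protein thresholds by default:
#' transcripts are called on BH q-values, proteins on raw p-values, both
#' detectors below `alpha`.
#'
#' @param sim a [sim_config()] describing the synthetic study (or `NULL`
#'   when supplying `matrices` to [run_pipeline()] directly).
#' @param alpha consensus threshold, strictly inside (0, 1).
#' @param n_perm permutations for the rank-template detector.
#' @param seed integer root seed; every stochastic stage derives its seed
#'   from it.
#' @param resolution_hours sampling resolution for the phase-shift class.
#' @param use_q named logical per layer (defaults: RNA `TRUE`, TE/NE
#'   `FALSE`).
#' @param min_total,min_detected transcript detection filter (see
#'   [filter_transcript_series()]); `min_detected` applies to the combined
#'   two-condition sample count.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), alpha = 0.05, n_perm = 1000,
                            seed = 1L, resolution_hours = 3,
                            use_q = c(RNA = TRUE, TE = FALSE, NE = FALSE),
                            min_total = 50, min_detected = 32) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly inside (0, 1)")
  }
  if (is.null(seed)) stop("seed is required")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, alpha = alpha, n_perm = n_perm,
                 seed = as.integer(seed),
                 resolution_hours = resolution_hours, use_q = use_q,
                 min_total = min_total, min_detected = min_detected),
            class = "pipeline_config")
}

#' Run the full comparative circadian pipeline
#'
#' Orchestrates the stage sequence on a synthetic dataset (or supplied
#' matrices): transcript filtering on the combined two-condition sample
#' set, per-layer per-condition consensus rhythm detection, STD-vs-ECD
#' change classification with re-writing summaries, gene-level layer
#' joining with overlap percentages and the contribution chain, and
#' population statistics (cumulative daily abundance change, amplitude
#' comparison, phase histograms). Deterministic given the config seed.
#'
#' @param cfg a [pipeline_config()].
#' @param matrices optional nested list `matrices[[layer]][[condition]]` of
#'   [abundance_matrix()] objects to analyse instead of simulating; layer
#'   names must include `RNA`, `TE`, `NE`.
#' @param gene_map optional series-to-gene map; defaults to the identity
#'   map over series ids.
#' @return an `rr_report` list: `fits` (per layer/condition
#'   [detect_rhythms()] tables), `change` (per layer
#'   [classify_rhythm_change()] tables), `rewrite` (per layer
#'   [rewrite_summary()]), `join`, `overlap` (per condition), `popstats`,
#'   `filter_report`, `headline` (flat machine-readable list), `truth` (if
#'   simulated), and `config`.
#' @export
run_pipeline <- function(cfg, matrices = NULL, gene_map = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  truth <- NULL
  if (is.null(matrices)) {
    if (is.null(cfg$sim)) stop("either cfg$sim or matrices must be supplied")
    sim <- generate_multiomics(cfg$sim)
    matrices <- sim$matrices
    truth <- sim$truth
  }
  layers <- names(matrices)
  if (!all(c("STD", "ECD") %in% names(matrices[[1]]))) {
    stop("each layer needs STD and ECD matrices")
  }

  filter_report <- NULL
  if ("RNA" %in% layers) {
    combined <- abundance_matrix(
      cbind(matrices$RNA$STD$values, matrices$RNA$ECD$values),
      rbind(matrices$RNA$STD$samples, matrices$RNA$ECD$samples))
    fl <- filter_transcript_series(combined, min_total = cfg$min_total,
                                   min_detected = cfg$min_detected)
    filter_report <- fl$report
    keep <- rownames(fl$matrix$values)
    for (cond in c("STD", "ECD")) {
      m <- matrices$RNA[[cond]]
      matrices$RNA[[cond]] <- abundance_matrix(
        m$values[keep, , drop = FALSE], m$samples)
    }
  }

  fits <- list()
  change <- list()
  rewrite <- list()
  seed_k <- 0L
  for (layer in layers) {
    use_q <- isTRUE(cfg$use_q[[layer]])
    fits[[layer]] <- list()
    for (cond in c("STD", "ECD")) {
      seed_k <- seed_k + 1L
      fits[[layer]][[cond]] <- detect_rhythms(
        matrices[[layer]][[cond]], n_perm = cfg$n_perm,
        seed = cfg$seed + seed_k, alpha = cfg$alpha, use_q = use_q)
    }
    change[[layer]] <- classify_rhythm_change(
      fits[[layer]]$STD, fits[[layer]]$ECD,
      resolution = cfg$resolution_hours)
    rewrite[[layer]] <- rewrite_summary(change[[layer]])
  }

  join <- NULL; overlap <- NULL
  if (all(c("RNA", "TE", "NE") %in% layers)) {
    stack <- function(layer) {
      do.call(rbind, lapply(c("STD", "ECD"), function(cond) {
        f <- as.data.frame(fits[[layer]][[cond]])
        f$condition <- cond
        f
      }))
    }
    if (is.null(gene_map)) {
      ids <- unique(unlist(lapply(layers, function(l) {
        fits[[l]]$STD$series_id
      })))
      gene_map <- data.frame(series_id = ids, gene = ids,
                             stringsAsFactors = FALSE)
    }
    join <- join_layers(stack("RNA"), stack("TE"), stack("NE"), gene_map)
    overlap <- list(STD = overlap_percentages(join, "STD"),
                    ECD = overlap_percentages(join, "ECD"))
  }

  popstats <- list()
  for (layer in layers) {
    cc <- cumulative_change(matrices[[layer]]$STD, matrices[[layer]]$ECD)
    std_rhy <- fits[[layer]]$STD$series_id[fits[[layer]]$STD$consensus_rhythmic]
    ecd_rhy <- fits[[layer]]$ECD$series_id[fits[[layer]]$ECD$consensus_rhythmic]
    popstats[[layer]] <- list(
      cumulative_change = cc,
      cc_std_rhythmic_vs_all = if (length(std_rhy) >= 2) {
        compare_populations(cc[names(cc) %in% std_rhy], cc)
      },
      cc_ecd_rhythmic_vs_all = if (length(ecd_rhy) >= 2) {
        compare_populations(cc[names(cc) %in% ecd_rhy], cc)
      },
      amplitude_comparison = if (length(std_rhy) >= 2 &&
                                 length(ecd_rhy) >= 2) {
        compare_populations(
          fits[[layer]]$STD$amplitude[fits[[layer]]$STD$consensus_rhythmic],
          fits[[layer]]$ECD$amplitude[fits[[layer]]$ECD$consensus_rhythmic])
      },
      phase_hist = list(
        STD = phase_histogram(
          fits[[layer]]$STD$acrophase[fits[[layer]]$STD$consensus_rhythmic]),
        ECD = phase_histogram(
          fits[[layer]]$ECD$acrophase[fits[[layer]]$ECD$consensus_rhythmic]))
    )
  }

  headline <- list(seed = cfg$seed, alpha = cfg$alpha, n_perm = cfg$n_perm)
  for (layer in layers) {
    rw <- rewrite[[layer]]
    n <- nrow(fits[[layer]]$STD)
    headline[[paste0("pct_rhythmic_std_", tolower(layer))]] <-
      pct(rw$n_std, n, 1)
    headline[[paste0("pct_rhythmic_ecd_", tolower(layer))]] <-
      pct(rw$n_ecd, n, 1)
    headline[[paste0("pct_rewritten_", tolower(layer))]] <- rw$pct_rewritten
    headline[[paste0("pct_shifted_", tolower(layer))]] <- rw$pct_shifted
  }
  if (!is.null(overlap)) {
    for (cond in c("STD", "ECD")) {
      ov <- overlap[[cond]]
      headline[[paste0("pct_ne_with_rhythmic_te_", tolower(cond))]] <-
        ov$pct_rhythmic_ne_with_rhythmic_te
      headline[[paste0("pct_te_with_rhythmic_mrna_", tolower(cond))]] <-
        ov$pct_rhythmic_te_with_rhythmic_mrna
      headline[[paste0("contribution_chain_", tolower(cond))]] <-
        ov$pct_contribution_chain
    }
  }

  structure(list(fits = fits, change = change, rewrite = rewrite,
                 join = join, overlap = overlap, popstats = popstats,
                 filter_report = filter_report, headline = headline,
                 truth = truth, config = cfg),
            class = "rr_report")
}

#' @export
print.rr_report <- function(x, ...) {
  cat("== Comparative circadian rhythmicity report ==\n")
  if (!is.null(x$filter_report)) print(x$filter_report)
  for (layer in names(x$rewrite)) {
    cat("\n[", layer, "]\n", sep = "")
    print(x$rewrite[[layer]])
  }
  if (!is.null(x$overlap)) {
    cat("\n")
    print(x$overlap$STD)
    print(x$overlap$ECD)
  }
  invisible(x)
}

#' Write the machine-readable report headline as JSON
#'
#' @param report an `rr_report` from [run_pipeline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
report_json <- function(report, path) {
  stopifnot(inherits(report, "rr_report"))
  jsonlite::write_json(report$headline, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
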