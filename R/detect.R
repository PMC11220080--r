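#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`m * p_(i) / i` with a cumulative minimum,
#' capped at 1), applied within the analysis set at hand. Thin wrapper
#' around [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted q-values, same length and order as `pvals`.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Consensus rhythmicity call from two detectors
#'
#' A series is consensus-rhythmic only if BOTH detectors are significant at
#' `alpha`: the parametric cosinor F-test and the nonparametric
#' rank-template test. For transcript sets the comparison uses BH-adjusted
#' q-values computed within the set (`use_q = TRUE`); for protein sets it
#' uses raw p-values (`use_q = FALSE`), mirroring the asymmetric
#' transcript/protein thresholds of consensus rhythm calling.
#'
#' @param fits a data.frame with columns `p_param` and `p_rank` (one row per
#'   series), typically from [detect_rhythms()].
#' @param alpha significance threshold (default 0.05).
#' @param use_q compare BH q-values (`TRUE`) or raw p-values (`FALSE`).
#' @return `fits` with columns `q_param`, `q_rank` and the logical
#'   `consensus_rhythmic` added or refreshed.
#' @export
consensus_call <- function(fits, alpha = 0.05, use_q = TRUE) {
  if (!all(c("p_param", "p_rank") %in% names(fits))) {
    stop("fits must carry p_param and p_rank for every series")
  }
  if (anyNA(fits$p_param) || anyNA(fits$p_rank)) {
    stop("missing detector p-values; run both detectors on every series")
  }
  fits$q_param <- bh_adjust(fits$p_param)
  fits$q_rank <- bh_adjust(fits$p_rank)
  if (use_q) {
    fits$consensus_rhythmic <- fits$q_param < alpha & fits$q_rank < alpha
  } else {
    fits$consensus_rhythmic <- fits$p_param < alpha & fits$p_rank < alpha
  }
  attr(fits, "alpha") <- alpha
  attr(fits, "use_q") <- use_q
  fits
}

#' Detect rhythmic series by two-detector consensus
#'
#' Runs the cosinor F-test and the rank-template permutation test on every
#' series of an abundance matrix (one condition, one layer), BH-adjusts both
#' p-value sets within the matrix, and applies the consensus AND-rule. Raw
#' values are `log2(x + 1)`-transformed by default; the permutation draw is
#' shared across series (one draw per scan, derived from `seed`).
#'
#' @param mat an [abundance_matrix()] for a single condition.
#' @param period period in hours (default 24).
#' @param n_perm permutations for the rank test (default 1000).
#' @param seed integer seed for the permutation draw (required).
#' @param alpha consensus significance threshold.
#' @param use_q use BH q-values (transcripts) or raw p-values (proteins) in
#'   the consensus rule.
#' @param transform `"log2p1"` (default) or `"none"` if the matrix is
#'   already on a log scale.
#' @return a data.frame of class `rhythm_fits`, one row per series:
#'   `series_id`, `mesor`, `amplitude` (log2 half peak-to-trough),
#'   `acrophase` (CT hours in \[0, 24)), `p_param`, `p_rank`,
#'   `best_phase_rank`, `tau`, `q_param`, `q_rank`, `consensus_rhythmic`.
#' @export
detect_rhythms <- function(mat, period = 24, n_perm = 1000, seed,
                           alpha = 0.05, use_q = TRUE,
                           transform = c("log2p1", "none")) {
  stopifnot(inherits(mat, "abund_mat"))
  transform <- match.arg(transform)
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (length(unique(mat$samples$condition)) != 1L) {
    stop("detect_rhythms expects a single-condition matrix; subset first")
  }
  Y <- mat$values
  if (transform == "log2p1") Y <- log2(Y + 1)
  times <- mat$samples$ct_hours
  par_fit <- cosinor_scan(Y, times, period)
  rank_fit <- rank_scan(Y, times, period, n_perm = n_perm, seed = seed)
  fits <- merge(par_fit, rank_fit, by = "series_id", sort = FALSE)
  fits <- fits[match(rownames(Y), fits$series_id), , drop = FALSE]
  rownames(fits) <- NULL
  fits <- consensus_call(fits, alpha = alpha, use_q = use_q)
  attr(fits, "n_perm") <- n_perm
  attr(fits, "period") <- period
  attr(fits, "condition") <- mat$samples$condition[1]
  class(fits) <- c("rhythm_fits", "data.frame")
  fits
}

#' @export
print.rhythm_fits <- function(x, ...) {
  cat("<rhythm_fits> ", nrow(x), " series",
      if (!is.null(attr(x, "condition"))) paste0(" (", attr(x, "condition"), ")"),
      ": ", sum(x$consensus_rhythmic), " consensus-rhythmic (",
      pct(sum(x$consensus_rhythmic), nrow(x), 1), "%) at alpha ",
      attr(x, "alpha") %||% 0.05,
      if (isTRUE(attr(x, "use_q"))) " on q-values" else " on p-values",
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.rhythm_fits <- function(object, ...) {
  rhy <- object[object$consensus_rhythmic, , drop = FALSE]
  out <- list(
    n_series = nrow(object),
    n_rhythmic = nrow(rhy),
    pct_rhythmic = pct(nrow(rhy), nrow(object), 1),
    amplitude_mean = if (nrow(rhy)) mean(rhy$amplitude) else NA_real_,
    phase = circ_stats(rhy$acrophase)
  )
  class(out) <- "summary.rhythm_fits"
  out
}

#' @export
print.summary.rhythm_fits <- function(x, ...) {
  cat(x$n_rhythmic, "/", x$n_series, " rhythmic (", x$pct_rhythmic,
      "%); mean amplitude ", signif(x$amplitude_mean, 3),
      " log2 units; circular mean phase CT",
      signif(x$phase$mean, 3), " (R = ", signif(x$phase$R, 3), ")\n",
      sep = "")
  invisible(x)
}
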