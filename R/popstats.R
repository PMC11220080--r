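#' Per-series cumulative daily abundance change between conditions
#'
#' For each series, the cumulative daily abundance under a condition is the
#' sum over timepoints of the replicate mean on the linear scale
#' (abundance is cumulative material, so sums are taken before any log
#' transform). Returns the percent change
#' `100 * (S_ecd - S_std) / S_std` per series (`NA` where `S_std` is 0).
#' Invariant to replicate order and to adding replicates with the same
#' per-timepoint means.
#'
#' @param mat_std,mat_ecd [abundance_matrix()] objects on the linear scale
#'   for the two conditions, covering the same timepoint grid and sharing
#'   series ids.
#' @return named numeric vector of percent changes, one per shared series.
#' @export
cumulative_change <- function(mat_std, mat_ecd) {
  stopifnot(inherits(mat_std, "abund_mat"), inherits(mat_ecd, "abund_mat"))
  shared <- intersect(rownames(mat_std$values), rownames(mat_ecd$values))
  if (length(shared) == 0L) stop("no shared series between conditions")
  if (!setequal(mat_std$samples$ct_hours, mat_ecd$samples$ct_hours)) {
    stop("conditions must cover the same timepoint grid")
  }
  daily_sum <- function(m) {
    v <- m$values[shared, , drop = FALSE]
    tp <- m$samples$ct_hours
    means <- vapply(sort(unique(tp)), function(t) {
      rowMeans(v[, tp == t, drop = FALSE])
    }, numeric(length(shared)))
    rowSums(means)
  }
  s_std <- daily_sum(mat_std)
  s_ecd <- daily_sum(mat_ecd)
  out <- 100 * (s_ecd - s_std) / s_std
  out[s_std == 0] <- NA_real_
  names(out) <- shared
  out
}

#' Two-sample population comparison (Student's t)
#'
#' Classical pooled-variance unpaired two-tailed t-test, the default for
#' comparing amplitude profiles or cumulative-change distributions between
#' populations; Welch's unequal-variance form is available behind a flag.
#' Degenerate inputs (zero pooled variance) are handled explicitly: equal
#' means give `t = 0, p = 1`; unequal means give an infinite statistic and
#' a p-value at the double floor.
#'
#' @param values_a,values_b numeric vectors, each of length at least 2.
#' @param welch use Welch's t instead of the pooled-variance form.
#' @return a `population_comparison` list: `group_a_mean`, `group_b_mean`,
#'   `t_statistic`, `p_value`, `df`, `n_a`, `n_b`.
#' @export
compare_populations <- function(values_a, values_b, welch = FALSE) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  n_a <- length(values_a); n_b <- length(values_b)
  if (n_a < 2L || n_b < 2L) stop("each group needs at least 2 observations")
  pooled_var <- (sum((values_a - mean(values_a))^2) +
                   sum((values_b - mean(values_b))^2)) / (n_a + n_b - 2)
  if (pooled_var <= .Machine$double.eps *
        max(1, mean(values_a)^2, mean(values_b)^2)) {
    delta <- mean(values_a) - mean(values_b)
    if (abs(delta) <= .Machine$double.eps * max(1, abs(mean(values_a)))) {
      tt <- 0; p <- 1
    } else {
      tt <- sign(delta) * Inf; p <- .Machine$double.xmin
    }
    df <- n_a + n_b - 2
  } else {
    ht <- stats::t.test(values_a, values_b, var.equal = !welch,
                        alternative = "two.sided")
    tt <- unname(ht$statistic)
    p <- max(ht$p.value, .Machine$double.xmin)
    df <- unname(ht$parameter)
  }
  structure(list(
    group_a_mean = mean(values_a), group_b_mean = mean(values_b),
    t_statistic = tt, p_value = p, df = df, n_a = n_a, n_b = n_b
  ), class = "population_comparison")
}

#' @export
print.population_comparison <- function(x, ...) {
  cat(sprintf(
    "Unpaired two-tailed t: mean %.4g (n=%d) vs %.4g (n=%d); t = %.4g, df = %.4g, p = %.4g\n",
    x$group_a_mean, x$n_a, x$group_b_mean, x$n_b,
    x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Phase histogram with circular summary
#'
#' Bins acrophases into half-open intervals `[k*b, (k+1)*b)` over the cycle
#' and reports the circular mean and mean resultant length R (R = 1 for a
#' point mass, 0 for perfect dispersion).
#'
#' @param phases acrophases in CT hours, each in \[0, period).
#' @param bin_hours bin width in hours (must divide the period; default 3).
#' @param period period in hours.
#' @return a `phase_histogram` list: `breaks`, `counts` (named by bin
#'   start), `circular_mean` (CT hours), `resultant_length`, `n`.
#' @export
phase_histogram <- function(phases, bin_hours = 3, period = 24) {
  if (period %% bin_hours != 0) stop("bin_hours must divide the period")
  if (any(phases < 0 | phases >= period, na.rm = TRUE)) {
    stop("phases must lie in [0, ", period, ")")
  }
  phases <- phases[!is.na(phases)]
  breaks <- seq(0, period, by = bin_hours)
  idx <- floor(phases / bin_hours) + 1L
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  names(counts) <- paste0("CT", breaks[-length(breaks)])
  cs <- circ_stats(phases, period)
  structure(list(breaks = breaks, counts = counts,
                 circular_mean = cs$mean, resultant_length = cs$R,
                 n = length(phases)),
            class = "phase_histogram")
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat("Phase histogram (n = ", x$n, "):\n", sep = "")
  print(x$counts)
  cat(sprintf("  circular mean CT%.2f, resultant length R = %.3f\n",
              if (is.na(x$circular_mean)) NA else x$circular_mean,
              x$resultant_length))
  invisible(x)
}

#' @export
plot.phase_histogram <- function(x, ...) {
  graphics::barplot(x$counts, xlab = "acrophase bin (CT h)",
                    ylab = "series", ...)
  invisible(x)
}
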