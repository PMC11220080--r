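#' Round half away from zero
#'
#' Deterministic half-up rounding (unlike [round()], which rounds half to
#' even). Used for every headline percentage so printed summaries are
#' reproducible from printed counts.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Percentage of a count over a denominator
#'
#' `pct(285, 7314, 1)` gives `3.9`. Half-up rounding; `digits = 0` for
#' integer percentages.
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places kept.
#' @return percentage on the 0-100 scale.
#' @export
pct <- function(num, den, digits = 0) {
  round_half_up(100 * num / den, digits)
}

# wrap hours onto [0, period)
wrap_ct <- function(h, period = 24) {
  ((h %% period) + period) %% period
}

# circular mean (hours) and mean resultant length of phases on [0, period)
circ_stats <- function(phases, period = 24) {
  if (length(phases) == 0L) {
    return(list(mean = NA_real_, R = NA_real_))
  }
  ang <- 2 * pi * phases / period
  s <- mean(sin(ang))
  c <- mean(cos(ang))
  R <- sqrt(s^2 + c^2)
  m <- if (R < 1e-12) NA_real_ else wrap_ct(atan2(s, c) * period / (2 * pi), period)
  list(mean = m, R = R)
}

# signed circular difference b - a mapped to (-period/2, period/2]
circ_diff <- function(a, b, period = 24) {
  d <- ((b - a + period / 2) %% period) - period / 2
  d[d == -period / 2] <- period / 2
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
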