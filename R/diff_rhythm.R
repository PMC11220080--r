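#' Signed circadian phase shift and shift class
#'
#' The shift is the circular difference `phi_ecd - phi_std` mapped to
#' `(-period/2, period/2]`. A negative shift means the ECD peak occurs
#' earlier, i.e. a phase advance, matching the direction of the advancing
#' light schedule; positive is a delay. Shifts whose magnitude does not
#' exceed the sampling `resolution` (strictly greater than, per the 3-h
#' sampling rule) are classed `unshifted`.
#'
#' @param phi_std,phi_ecd acrophases in CT hours, each in \[0, period).
#' @param period period in hours (default 24).
#' @param resolution sampling resolution in hours (default 3).
#' @return a list with `delta_phi` (hours, in `(-12, 12]`) and
#'   `shift_class` (`"advance"`, `"delay"` or `"unshifted"`); vectorized.
#' @examples
#' phase_shift(6, 2)   # delta -4: advance
#' phase_shift(23, 1)  # delta +2 across the wrap: unshifted
#' @export
phase_shift <- function(phi_std, phi_ecd, period = 24, resolution = 3) {
  if (any(phi_std < 0 | phi_std >= period, na.rm = TRUE) ||
      any(phi_ecd < 0 | phi_ecd >= period, na.rm = TRUE)) {
    stop("phases must lie in [0, ", period, ")")
  }
  d <- circ_diff(phi_std, phi_ecd, period)
  cls <- rep(NA_character_, length(d))
  cls[abs(d) <= resolution] <- "unshifted"
  cls[d < -resolution] <- "advance"
  cls[d > resolution] <- "delay"
  list(delta_phi = d, shift_class = cls)
}

#' Classify per-series rhythmicity change between STD and ECD
#'
#' LOR: consensus-rhythmic under STD only; GOR: under ECD only; ROR: under
#' both (with phase shift and shift class); NRB: under neither. Both call
#' sets must cover the same series universe.
#'
#' @param std_calls,ecd_calls `rhythm_fits` data.frames (see
#'   [detect_rhythms()]) for the two conditions over identical series.
#' @param resolution sampling resolution (hours) for the shift class.
#' @param period period in hours.
#' @return a data.frame of class `rhythm_change_table`: `series_id`,
#'   `class` (LOR/GOR/ROR/NRB), `phase_std`, `phase_ecd`, `amplitude_std`,
#'   `amplitude_ecd` (phases/amplitudes present only where rhythmic in that
#'   condition), `delta_phi` and `shift_class` (ROR only).
#' @export
classify_rhythm_change <- function(std_calls, ecd_calls, resolution = 3,
                                   period = 24) {
  need <- c("series_id", "consensus_rhythmic", "acrophase", "amplitude")
  for (nm in list(std_calls, ecd_calls)) {
    if (!all(need %in% names(nm))) {
      stop("call tables need columns: ", paste(need, collapse = ", "))
    }
  }
  only_std <- setdiff(std_calls$series_id, ecd_calls$series_id)
  only_ecd <- setdiff(ecd_calls$series_id, std_calls$series_id)
  if (length(only_std) || length(only_ecd)) {
    stop("series present in one condition only: ",
         paste(utils::head(c(only_std, only_ecd), 10), collapse = ", "))
  }
  ecd_calls <- ecd_calls[match(std_calls$series_id, ecd_calls$series_id), ,
                         drop = FALSE]
  rs <- std_calls$consensus_rhythmic
  re <- ecd_calls$consensus_rhythmic
  cls <- ifelse(rs & re, "ROR",
                ifelse(rs, "LOR", ifelse(re, "GOR", "NRB")))
  out <- data.frame(
    series_id = std_calls$series_id,
    class = cls,
    phase_std = ifelse(rs, std_calls$acrophase, NA_real_),
    phase_ecd = ifelse(re, ecd_calls$acrophase, NA_real_),
    amplitude_std = ifelse(rs, std_calls$amplitude, NA_real_),
    amplitude_ecd = ifelse(re, ecd_calls$amplitude, NA_real_),
    delta_phi = NA_real_, shift_class = NA_character_,
    stringsAsFactors = FALSE
  )
  ror <- cls == "ROR"
  if (any(ror)) {
    ps <- phase_shift(out$phase_std[ror], out$phase_ecd[ror],
                      period = period, resolution = resolution)
    out$delta_phi[ror] <- ps$delta_phi
    out$shift_class[ror] <- ps$shift_class
  }
  attr(out, "resolution") <- resolution
  class(out) <- c("rhythm_change_table", "data.frame")
  out
}

#' @export
print.rhythm_change_table <- function(x, ...) {
  tab <- table(factor(x$class, levels = c("LOR", "GOR", "ROR", "NRB")))
  cat("<rhythm_change_table> ", nrow(x), " series: ",
      paste(names(tab), tab, sep = " ", collapse = ", "), "\n", sep = "")
  if (tab["ROR"] > 0) {
    st <- table(factor(x$shift_class[x$class == "ROR"],
                       levels = c("advance", "unshifted", "delay")))
    cat("  ROR shifts (resolution ", attr(x, "resolution") %||% 3, " h): ",
        paste(names(st), st, sep = " ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Union-level rhythm re-writing summary
#'
#' Over the union of series rhythmic in either condition
#' (`n_union = n_lor + n_gor + n_ror`), the re-written fraction is the part
#' whose rhythmicity status differs between conditions:
#' `pct_rewritten = 100 * (n_lor + n_gor) / n_union`. Headline percentages
#' use half-up rounding (integer by default) so printed counts reproduce
#' printed percentages.
#'
#' @param x a `rhythm_change_table`, or the LOR count for the count-based
#'   interface.
#' @param ... passed on; for the numeric method, `n_gor` and `n_ror`.
#' @return a `rewrite_summary` list: `n_std`, `n_ecd`, `n_lor`, `n_gor`,
#'   `n_ror`, `n_union`, `pct_rewritten` (rounded), `pct_rewritten_exact`,
#'   `pct_shifted` (share of the union with a shift beyond the sampling
#'   resolution; `NA` for the count interface), `n_shifted`.
#' @examples
#' rewrite_summary(261, n_gor = 885, n_ror = 24)  # whole-cell: 98%
#' @export
rewrite_summary <- function(x, ...) UseMethod("rewrite_summary")

#' @rdname rewrite_summary
#' @param n_gor,n_ror GOR and ROR counts (count interface).
#' @param n_shifted optional count of ROR series shifted beyond the
#'   sampling resolution.
#' @param digits decimal places for the headline percentage (default 0).
#' @export
rewrite_summary.numeric <- function(x, n_gor, n_ror, n_shifted = NA_integer_,
                                    digits = 0, ...) {
  n_lor <- x
  n_union <- n_lor + n_gor + n_ror
  out <- list(
    n_std = n_lor + n_ror, n_ecd = n_gor + n_ror,
    n_lor = n_lor, n_gor = n_gor, n_ror = n_ror, n_union = n_union,
    n_shifted = n_shifted,
    pct_rewritten = if (n_union > 0) {
      pct(n_lor + n_gor, n_union, digits)
    } else NA_real_,
    pct_rewritten_exact = if (n_union > 0) {
      100 * (n_lor + n_gor) / n_union
    } else NA_real_,
    pct_shifted = if (!is.na(n_shifted) && n_union > 0) {
      pct(n_shifted, n_union, digits)
    } else NA_real_
  )
  class(out) <- "rewrite_summary"
  out
}

#' @rdname rewrite_summary
#' @export
rewrite_summary.rhythm_change_table <- function(x, digits = 0, ...) {
  cls <- x$class
  n_shifted <- sum(x$class == "ROR" & x$shift_class != "unshifted",
                   na.rm = TRUE)
  rewrite_summary(sum(cls == "LOR"), n_gor = sum(cls == "GOR"),
                  n_ror = sum(cls == "ROR"), n_shifted = n_shifted,
                  digits = digits)
}

#' @export
print.rewrite_summary <- function(x, ...) {
  cat("Rhythm re-writing: LOR ", x$n_lor, " + GOR ", x$n_gor,
      " + ROR ", x$n_ror, " = ", x$n_union, " rhythmic in either condition\n",
      sep = "")
  cat("  re-written (LOR+GOR): ", x$pct_rewritten, "% of the union\n",
      sep = "")
  if (!is.na(x$pct_shifted)) {
    cat("  phase-shifted ROR beyond resolution: ", x$n_shifted, " (",
        x$pct_shifted, "% of the union)\n", sep = "")
  }
  invisible(x)
}
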