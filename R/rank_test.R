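# Rank-template permutation test internals.
#
# The statistic is the maximum, over one cosine template per distinct
# timepoint phase, of Kendall's tau-b between the series and the template.
# The null distribution permutes timepoint labels with replicate blocks
# kept intact, so only the B = #timepoints block labels are shuffled.
#
# Key identity used throughout: with C[s, t] = sum over (i in block s,
# j in block t) of sign(y_i - y_j), the tau numerator for template g under
# block permutation pi is sum_{s,t} sign(g[pi(s)] - g[pi(t)]) * C[s, t] / 2,
# and the tau-b denominator is permutation-invariant (tie structure of y and
# of each template is fixed). One C per series then serves every
# permutation and template.

# all permutations of 1..n (n! x n matrix); used for exact enumeration
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- nrow(sub)
  for (k in seq_len(n)) {
    rows <- ((k - 1L) * r + 1L):(k * r)
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow = r)
  }
  out
}

# per-series block comparison matrix C (B x B)
block_sign_matrix <- function(y, block) {
  S <- sign(outer(y, y, "-"))
  A <- rowsum(S, block, reorder = TRUE)
  t(rowsum(t(A), block, reorder = TRUE))
}

# tie correction term sum t*(t-1)/2 for a vector
tie_term <- function(x) {
  tab <- table(x)
  sum(tab * (tab - 1) / 2)
}

# template setup shared by single-series and scan versions
rank_templates <- function(times, period) {
  tp <- sort(unique(times))
  B <- length(tp)
  block <- match(times, tp)
  bsize <- tabulate(block, nbins = B)
  n <- length(times)
  n0 <- n * (n - 1) / 2
  Smat <- matrix(0, nrow = B * B, ncol = B)
  n2 <- numeric(B)
  for (k in seq_len(B)) {
    g <- cos(2 * pi * (tp - tp[k]) / period)
    d <- outer(g, g, "-")
    d[abs(d) < 1e-9] <- 0
    Smat[, k] <- as.vector(sign(d))
    gfull <- rep(signif(g, 9), times = bsize)
    n2[k] <- tie_term(gfull)
  }
  list(tp = tp, B = B, block = block, n0 = n0, Smat = Smat, n2 = n2)
}

# observed and permutation max-tau statistics for one series
# perms: matrix of block permutations (rows); returns list(stat, best, pstats)
rank_stat_series <- function(y, tmpl, perm_idx = NULL) {
  C <- block_sign_matrix(y, tmpl$block)
  n1 <- tie_term(y)
  denom <- sqrt((tmpl$n0 - n1) * (tmpl$n0 - tmpl$n2))
  Cv <- as.vector(C)
  numer <- as.vector(crossprod(Cv, tmpl$Smat)) / 2
  taus <- ifelse(denom > 0, numer / denom, 0)
  stat <- max(taus)
  best <- tmpl$tp[which(taus >= stat - 1e-9)[1L]]
  pstats <- NULL
  if (!is.null(perm_idx)) {
    Cperm <- matrix(Cv[perm_idx], nrow = tmpl$B^2)  # B^2 x n_perm
    numer_p <- crossprod(tmpl$Smat, Cperm) / 2      # B x n_perm
    taus_p <- numer_p / ifelse(denom > 0, denom, 1)
    taus_p[denom == 0, ] <- 0
    pstats <- do.call(pmax, lapply(seq_len(tmpl$B),
                                   function(k) taus_p[k, ]))
  }
  list(stat = stat, best = best, pstats = pstats, degenerate = all(denom == 0))
}

# flattened index matrix turning C into C[pi, pi] for each permutation
perm_index_matrix <- function(perms, B) {
  apply(perms, 1, function(p) {
    as.vector(outer(p, p, function(r, c) (c - 1L) * B + r))
  })
}

#' Rank-template permutation test for circadian rhythmicity
#'
#' Nonparametric detector: for each template phase on the sampling grid (one
#' per distinct timepoint), Kendall's tau-b is computed between the series
#' and a cosine of the given period peaking at that phase; the statistic is
#' the maximum tau. Significance comes from permuting timepoint labels with
#' replicate blocks kept intact, with the add-one estimate
#' `p = (1 + #permutation stats >= observed) / (1 + n_perm)`, which makes
#' the test valid but slightly conservative. `exact = TRUE` enumerates all
#' `B!` block orderings instead (feasible for the 8-point grid).
#'
#' @param series numeric abundance vector (any monotone scale; the test is
#'   rank-based).
#' @param times circadian times (hours) per observation.
#' @param period period in hours (default 24).
#' @param n_perm number of random permutations (at least 100).
#' @param seed seed for the permutation draw (required unless `exact`).
#' @param exact enumerate all block permutations instead of sampling.
#' @return a list with `p_rank`, `best_phase` (template phase maximizing
#'   tau; earliest CT on ties), `tau` (the observed maximum tau), and
#'   `n_perm_used`.
#' @export
rank_template_test <- function(series, times, period = 24, n_perm = 10000,
                               seed = NULL, exact = FALSE) {
  if (length(series) != length(times)) {
    stop("series and times must have equal length")
  }
  tmpl <- rank_templates(times, period)
  if (exact) {
    perms <- all_perms(tmpl$B)
  } else {
    if (n_perm < 100) stop("n_perm must be at least 100")
    if (is.null(seed)) stop("seed is required for random permutations")
    set.seed(seed)
    perms <- t(replicate(n_perm, sample.int(tmpl$B)))
  }
  idx <- perm_index_matrix(perms, tmpl$B)
  rs <- rank_stat_series(series, tmpl, idx)
  if (rs$degenerate) {
    return(list(p_rank = 1, best_phase = tmpl$tp[1L], tau = 0,
                n_perm_used = nrow(perms)))
  }
  m <- nrow(perms)
  if (exact) {
    p <- sum(rs$pstats >= rs$stat - 1e-9) / m
  } else {
    p <- (1 + sum(rs$pstats >= rs$stat - 1e-9)) / (1 + m)
  }
  list(p_rank = p, best_phase = rs$best, tau = rs$stat, n_perm_used = m)
}

# vectorized scan over matrix rows; one shared permutation draw
rank_scan <- function(Y, times, period = 24, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  tmpl <- rank_templates(times, period)
  set.seed(seed)
  perms <- t(replicate(n_perm, sample.int(tmpl$B)))
  idx <- perm_index_matrix(perms, tmpl$B)
  out <- vapply(seq_len(nrow(Y)), function(i) {
    rs <- rank_stat_series(Y[i, ], tmpl, idx)
    if (rs$degenerate) return(c(1, tmpl$tp[1L], 0))
    c((1 + sum(rs$pstats >= rs$stat - 1e-9)) / (1 + n_perm), rs$best, rs$stat)
  }, numeric(3))
  data.frame(series_id = rownames(Y), p_rank = out[1, ],
             best_phase_rank = out[2, ], tau = out[3, ],
             stringsAsFactors = FALSE)
}
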