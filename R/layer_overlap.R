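#' Join rhythmicity call sets across molecular layers at the gene level
#'
#' Builds one row per gene over the joined universe: genes with at least one
#' transcript series AND at least one protein series (whole-cell or nuclear)
#' quantified. A gene is "rhythmic at layer L in condition c" if ANY of its
#' series at that layer is consensus-rhythmic (transcript-to-gene maps may
#' be many-to-one). The representative phase/amplitude per (gene, layer,
#' condition) comes from the most significant rhythmic series (smallest
#' parametric p; falling back to largest amplitude).
#'
#' @param mrna_fits,te_fits,ne_fits data.frames of per-series calls with
#'   columns `series_id`, `condition`, `consensus_rhythmic`, `acrophase`,
#'   `amplitude` (optionally `p_param`), stacking both conditions. Obtain by
#'   `rbind`-ing two [detect_rhythms()] results with a `condition` column.
#' @param gene_map data.frame mapping `series_id` to `gene`, covering every
#'   series id in the three fit tables.
#' @return a data.frame of class `gene_join`, one row per gene: quantified
#'   flags `has_transcript`, `has_te`, `has_ne`; per layer x condition
#'   rhythmic flags (`rhythmic_mrna_std`, ...), phases (`phase_te_ecd`,
#'   ...), and amplitudes.
#' @export
join_layers <- function(mrna_fits, te_fits, ne_fits, gene_map) {
  if (!all(c("series_id", "gene") %in% names(gene_map))) {
    stop("gene_map needs columns series_id and gene")
  }
  layers <- list(mrna = mrna_fits, te = te_fits, ne = ne_fits)
  for (nm in names(layers)) {
    f <- layers[[nm]]
    need <- c("series_id", "condition", "consensus_rhythmic",
              "acrophase", "amplitude")
    if (!all(need %in% names(f))) {
      stop(nm, "_fits needs columns: ", paste(need, collapse = ", "))
    }
    unmapped <- setdiff(f$series_id, gene_map$series_id)
    if (length(unmapped)) {
      stop("unmapped series id(s) in ", nm, "_fits: ",
           paste(utils::head(unmapped, 10), collapse = ", "))
    }
  }
  gene_of <- function(ids) gene_map$gene[match(ids, gene_map$series_id)]
  genes_at <- function(f) unique(gene_of(f$series_id))
  universe <- intersect(genes_at(mrna_fits),
                        union(genes_at(te_fits), genes_at(ne_fits)))
  universe <- sort(universe)
  if (length(universe) == 0L) {
    out <- data.frame(gene = character(0))
    class(out) <- c("gene_join", "data.frame")
    return(out)
  }
  out <- data.frame(gene = universe, stringsAsFactors = FALSE)
  for (nm in names(layers)) {
    f <- layers[[nm]]
    f$gene <- gene_of(f$series_id)
    quant <- universe %in% f$gene
    if (nm == "mrna") out$has_transcript <- quant else {
      out[[paste0("has_", nm)]] <- quant
    }
    for (cond in c("STD", "ECD")) {
      fc <- f[f$condition == cond, , drop = FALSE]
      sub <- fc[fc$consensus_rhythmic, , drop = FALSE]
      suffix <- tolower(cond)
      rhy_col <- paste0("rhythmic_", nm, "_", suffix)
      out[[rhy_col]] <- universe %in% sub$gene
      ph <- rep(NA_real_, length(universe))
      am <- rep(NA_real_, length(universe))
      if (nrow(sub)) {
        ord <- if ("p_param" %in% names(sub)) {
          order(sub$gene, sub$p_param)
        } else {
          order(sub$gene, -sub$amplitude)
        }
        sub <- sub[ord, , drop = FALSE]
        rep_rows <- sub[!duplicated(sub$gene), , drop = FALSE]
        m <- match(universe, rep_rows$gene)
        ph <- rep_rows$acrophase[m]
        am <- rep_rows$amplitude[m]
      }
      out[[paste0("phase_", nm, "_", suffix)]] <- ph
      out[[paste0("amplitude_", nm, "_", suffix)]] <- am
    }
  }
  class(out) <- c("gene_join", "data.frame")
  out
}

#' @export
print.gene_join <- function(x, ...) {
  cat("<gene_join> ", nrow(x), " genes in the joined universe\n", sep = "")
  if (nrow(x)) {
    for (cond in c("std", "ecd")) {
      cat("  ", toupper(cond), ": rhythmic mRNA ",
          sum(x[[paste0("rhythmic_mrna_", cond)]]), ", TE ",
          sum(x[[paste0("rhythmic_te_", cond)]]), ", NE ",
          sum(x[[paste0("rhythmic_ne_", cond)]]), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Cross-layer overlap percentages and contribution chain
#'
#' Within the joined gene universe, computes the headline overlap
#' percentages for one condition, each within its stated denominator and
#' restricted to genes where both layers involved were quantified:
#' rhythmic transcripts with a rhythmic whole-cell protein (denominator:
#' rhythmic transcript genes), rhythmic whole-cell proteins with a rhythmic
#' transcript, rhythmic whole-cell proteins with a rhythmic nuclear
#' protein, and rhythmic nuclear proteins with a rhythmic whole-cell
#' protein. `n_gor_pta` counts genes rhythmic in the nucleus but not at the
#' whole-cell level — rhythmicity acquired post-translationally. The
#' contribution chain multiplies the two links from rhythmic transcript to
#' rhythmic nuclear protein (see [contribution_chain()]), using the
#' half-up-rounded integer percentages as published summaries do.
#'
#' @param j a [join_layers()] result.
#' @param condition `"STD"` or `"ECD"`.
#' @param digits decimal places for the reported percentages (default 0).
#' @return a `layer_overlap_summary` list of percentages (0-100 scale, `NA`
#'   on empty denominators), `n_gor_pta`, and `pct_contribution_chain`.
#' @export
overlap_percentages <- function(j, condition = c("STD", "ECD"), digits = 0) {
  condition <- match.arg(condition)
  if (nrow(j) == 0L) stop("empty gene universe")
  s <- tolower(condition)
  rm_ <- j[[paste0("rhythmic_mrna_", s)]]
  rt <- j[[paste0("rhythmic_te_", s)]]
  rn <- j[[paste0("rhythmic_ne_", s)]]
  mt <- j$has_transcript & j$has_te
  tn <- j$has_te & j$has_ne
  pc <- function(num, den) if (den > 0) pct(num, den, digits) else NA_real_
  pct_mrna_with_te <- pc(sum(rm_ & rt & mt), sum(rm_ & mt))
  pct_te_with_mrna <- pc(sum(rm_ & rt & mt), sum(rt & mt))
  pct_te_with_ne <- pc(sum(rt & rn & tn), sum(rt & tn))
  pct_ne_with_te <- pc(sum(rt & rn & tn), sum(rn & tn))
  n_gor_pta <- sum(rn & !rt & tn)
  out <- list(
    condition = condition,
    n_universe = nrow(j),
    pct_rhythmic_mrna_with_rhythmic_te = pct_mrna_with_te,
    pct_rhythmic_te_with_rhythmic_mrna = pct_te_with_mrna,
    pct_rhythmic_te_with_rhythmic_ne = pct_te_with_ne,
    pct_rhythmic_ne_with_rhythmic_te = pct_ne_with_te,
    n_gor_pta = n_gor_pta,
    pct_contribution_chain = if (!is.na(pct_ne_with_te) &&
                                 !is.na(pct_te_with_mrna)) {
      contribution_chain(pct_ne_with_te, pct_te_with_mrna)
    } else NA_real_
  )
  class(out) <- "layer_overlap_summary"
  out
}

#' @export
print.layer_overlap_summary <- function(x, ...) {
  cat("Layer overlaps (", x$condition, ", ", x$n_universe,
      " genes joined):\n", sep = "")
  cat("  rhythmic mRNA with rhythmic TE protein: ",
      x$pct_rhythmic_mrna_with_rhythmic_te, "%\n", sep = "")
  cat("  rhythmic TE protein with rhythmic mRNA: ",
      x$pct_rhythmic_te_with_rhythmic_mrna, "%\n", sep = "")
  cat("  rhythmic TE protein with rhythmic NE:   ",
      x$pct_rhythmic_te_with_rhythmic_ne, "%\n", sep = "")
  cat("  rhythmic NE protein with rhythmic TE:   ",
      x$pct_rhythmic_ne_with_rhythmic_te, "%\n", sep = "")
  cat("  post-translationally acquired (NE-only): ", x$n_gor_pta,
      " genes\n", sep = "")
  cat("  transcript-to-nuclear contribution chain: ",
      x$pct_contribution_chain, "%\n", sep = "")
  invisible(x)
}

#' Chained contribution of rhythmic transcripts to rhythmic nuclear proteins
#'
#' Multiplies two overlap links: the share of rhythmic nuclear proteins
#' that are also rhythmic at the whole-cell level, and the share of
#' rhythmic whole-cell proteins that have rhythmic transcripts. The result
#' is the estimated share of rhythmic nuclear proteins traceable to a
#' rhythmic transcript, reported to one decimal. Monotone non-decreasing in
#' each argument. Note that chaining rounded percentages can differ from
#' chaining the underlying counts in the last decimal (e.g. 6 x 48 gives
#' 2.9, where unrounded counts can give 2.8).
#'
#' @param pct_ne_also_te percent of rhythmic nuclear proteins also rhythmic
#'   at the whole-cell level, in \[0, 100\].
#' @param pct_te_with_rhythmic_mrna percent of rhythmic whole-cell proteins
#'   with rhythmic transcripts, in \[0, 100\].
#' @return the chained percentage, half-up rounded to one decimal.
#' @examples
#' contribution_chain(14, 27)  # 3.8
#' @export
contribution_chain <- function(pct_ne_also_te, pct_te_with_rhythmic_mrna) {
  if (pct_ne_also_te < 0 || pct_ne_also_te > 100 ||
      pct_te_with_rhythmic_mrna < 0 || pct_te_with_rhythmic_mrna > 100) {
    stop("percentages must lie in [0, 100]")
  }
  round_half_up(pct_ne_also_te * pct_te_with_rhythmic_mrna / 100, 1)
}

#' Transcript-vs-protein phase lead/lag counts
#'
#' Among genes rhythmic at both the transcript and whole-cell protein
#' layers in a condition, a gene counts as "lead" if the circular
#' difference (protein phase minus transcript phase) mod 24 lies strictly
#' inside (0, 12) — the transcript peaks first — and as "lag" otherwise
#' (boundaries at exactly 0 or 12 count as lag).
#'
#' @param j a [join_layers()] result.
#' @param condition `"STD"` or `"ECD"`.
#' @param period period in hours.
#' @return a list with `n_lead`, `n_lag` and `ratio = n_lead / n_lag`
#'   (`NA` when no gene is rhythmic at both layers).
#' @export
lead_lag_ratio <- function(j, condition = c("STD", "ECD"), period = 24) {
  condition <- match.arg(condition)
  s <- tolower(condition)
  both <- j[[paste0("rhythmic_mrna_", s)]] & j[[paste0("rhythmic_te_", s)]]
  if (!any(both)) {
    return(list(n_lead = NA_integer_, n_lag = NA_integer_, ratio = NA_real_))
  }
  d <- (j[[paste0("phase_te_", s)]][both] -
          j[[paste0("phase_mrna_", s)]][both]) %% period
  lead <- d > 0 & d < period / 2
  list(n_lead = sum(lead), n_lag = sum(!lead),
       ratio = sum(lead) / sum(!lead))
}

#' Whole-cell protein vs transcript amplitude comparison
#'
#' Among genes rhythmic at both layers in a condition, counts genes whose
#' whole-cell protein amplitude strictly exceeds the transcript amplitude
#' (ties count as protein-lower). Both amplitudes are cosinor log2
#' half-amplitudes from the same estimator, making the comparison
#' scale-consistent.
#'
#' @param j a [join_layers()] result.
#' @param condition `"STD"` or `"ECD"`.
#' @return a list with `n_protein_higher`, `n_protein_lower` and
#'   `ratio = n_protein_higher / n_protein_lower` (`NA` if no gene
#'   qualifies).
#' @export
amplitude_ratio_classification <- function(j, condition = c("STD", "ECD")) {
  condition <- match.arg(condition)
  s <- tolower(condition)
  both <- j[[paste0("rhythmic_mrna_", s)]] & j[[paste0("rhythmic_te_", s)]]
  if (!any(both)) {
    return(list(n_protein_higher = NA_integer_,
                n_protein_lower = NA_integer_, ratio = NA_real_))
  }
  higher <- j[[paste0("amplitude_te_", s)]][both] >
    j[[paste0("amplitude_mrna_", s)]][both]
  list(n_protein_higher = sum(higher), n_protein_lower = sum(!higher),
       ratio = sum(higher) / sum(!higher))
}
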