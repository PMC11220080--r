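#' Abundance matrix with sample metadata
#'
#' The universal carrier for all three molecular layers: a series x sample
#' matrix of non-negative abundances (raw transcript counts or reporter
#' intensities) together with one metadata record per sample column.
#'
#' Required metadata columns: `sample_id`, `condition` (`"STD"`/`"ECD"`),
#' `ct_hours` (circadian time, hours in \[0, 24)), `replicate` (positive
#' integer), `compartment` (`"RNA"`, `"TE"` or `"NE"`). Optional: `plex`,
#' `channel`, `is_bridge` (defaults to `FALSE`). Bridge (spike) samples must
#' carry a plex id; non-bridge samples must be unique in
#' (condition, ct_hours, replicate, compartment).
#'
#' @param values numeric matrix, series in rows, samples in columns. Row
#'   names are the series ids; column names must match `samples$sample_id`.
#' @param samples data.frame of per-sample metadata, one row per column of
#'   `values`, in column order.
#' @return an object of class `abund_mat`: a list with elements `values`
#'   (the matrix) and `samples` (the metadata data.frame).
#' @export
#' @examples
#' v <- matrix(rpois(8, 20), 2, 4,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' s <- data.frame(sample_id = paste0("s", 1:4), condition = "STD",
#'                 ct_hours = c(0, 6, 12, 18), replicate = 1L,
#'                 compartment = "RNA")
#' abundance_matrix(v, s)
abundance_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values))) {
    if (nrow(values) == 0L) {
      rownames(values) <- character(0)
    } else {
      stop("`values` must have row names (series ids)")
    }
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated series ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "ct_hours", "replicate", "compartment")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(samples) != ncol(values)) {
    stop("metadata has ", nrow(samples), " rows but matrix has ",
         ncol(values), " columns")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- samples$sample_id
  }
  if (!identical(as.character(colnames(values)),
                 as.character(samples$sample_id))) {
    bad <- setdiff(colnames(values), samples$sample_id)
    if (length(bad)) {
      stop("sample id(s) in matrix not found in metadata: ",
           paste(bad, collapse = ", "))
    }
    stop("matrix column order differs from metadata row order")
  }
  if (!"is_bridge" %in% names(samples)) samples$is_bridge <- FALSE
  samples$is_bridge[is.na(samples$is_bridge)] <- FALSE
  if (!"plex" %in% names(samples)) samples$plex <- NA
  if (!"channel" %in% names(samples)) samples$channel <- NA
  if (any(samples$is_bridge & is.na(samples$plex))) {
    stop("bridge samples must carry a plex id")
  }
  if (any(samples$ct_hours < 0 | samples$ct_hours >= 24)) {
    stop("ct_hours must lie in [0, 24)")
  }
  nb <- samples[!samples$is_bridge, , drop = FALSE]
  key <- paste(nb$condition, nb$ct_hours, nb$replicate, nb$compartment)
  if (anyDuplicated(key)) {
    stop("duplicate (condition, ct_hours, replicate, compartment): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  structure(list(values = values, samples = samples), class = "abund_mat")
}

#' @export
print.abund_mat <- function(x, ...) {
  s <- x$samples
  cat("<abund_mat> ", nrow(x$values), " series x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  conditions:  ", paste(unique(s$condition), collapse = ", "), "\n",
      sep = "")
  cat("  compartments:", paste(unique(s$compartment), collapse = ", "), "\n")
  cat("  CT grid:     ", paste(sort(unique(s$ct_hours)), collapse = ", "),
      " h\n", sep = "")
  if (any(s$is_bridge)) {
    cat("  bridge samples: ", sum(s$is_bridge), " across plexes ",
        paste(unique(s$plex[s$is_bridge]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.abund_mat <- function(x) dim(x$values)

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an abundance matrix and its sample metadata
#'
#' The matrix file is TSV or CSV (by extension) with the series id in the
#' first column and one column per sample; the metadata file has one row per
#' sample id. Samples are matched 1:1 to metadata rows, preserving the
#' matrix column order. Unmatched ids and non-numeric cells are hard errors.
#'
#' @param path matrix file.
#' @param metadata_path sample metadata file with at least the columns
#'   listed in [abundance_matrix()].
#' @return an [abundance_matrix()].
#' @seealso [write_matrix()] for the inverse.
#' @export
read_matrix <- function(path, metadata_path) {
  sep <- infer_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop("matrix file needs a series id column plus samples")
  ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(values) & !is.na(cells) &
                 !cells %in% c("NA", ""), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell at series '%s', sample '%s': '%s'",
                 ids[bad[1, 1]], colnames(cells)[bad[1, 2]],
                 cells[bad[1, 1], bad[1, 2]]))
  }
  dimnames(values) <- list(ids, colnames(cells))
  meta <- utils::read.table(metadata_path, header = TRUE,
                            sep = infer_sep(metadata_path),
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
  unmatched <- setdiff(colnames(values), meta$sample_id)
  if (length(unmatched)) {
    stop("sample id(s) missing from metadata: ",
         paste(unmatched, collapse = ", "))
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if ("is_bridge" %in% names(meta)) {
    meta$is_bridge <- as.logical(meta$is_bridge)
  }
  abundance_matrix(values, meta)
}

#' Write an abundance matrix and its sample metadata
#'
#' Values are written at 17 significant digits so that
#' `read_matrix(write_matrix(x))` is the identity to full double precision.
#'
#' @param x an [abundance_matrix()].
#' @param path matrix file to write (TSV unless the extension is `.csv`).
#' @param metadata_path metadata file to write.
#' @return `x`, invisibly.
#' @export
write_matrix <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "abund_mat"))
  sep <- infer_sep(path)
  chr <- apply(x$values, 2, function(col) sprintf("%.17g", col))
  if (!is.matrix(chr)) chr <- matrix(chr, nrow = nrow(x$values))
  out <- data.frame(series_id = rownames(x$values), chr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("series_id", colnames(x$values))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, metadata_path, sep = infer_sep(metadata_path),
                     quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Subset an abundance matrix by sample
#'
#' @param x an [abundance_matrix()].
#' @param keep logical or integer index over samples.
#' @return an [abundance_matrix()] with the selected samples.
#' @export
subset_samples <- function(x, keep) {
  stopifnot(inherits(x, "abund_mat"))
  abundance_matrix(x$values[, keep, drop = FALSE],
                   x$samples[keep, , drop = FALSE])
}

#' Filter transcript series by total abundance and detection
#'
#' A series is kept iff its summed raw count across all samples is at least
#' `min_total` AND it is detected (count strictly greater than zero) in at
#' least `min_detected` samples. Both boundaries keep: total exactly
#' `min_total` and detection in exactly `min_detected` samples survive. A
#' series failing both rules is counted once, under low abundance. Defaults
#' correspond to a 48-sample design (8 timepoints x 3 replicates x 2
#' conditions).
#'
#' @param m an [abundance_matrix()] of raw counts.
#' @param min_total minimum summed count across samples (default 50).
#' @param min_detected minimum number of samples with a nonzero count
#'   (default 32).
#' @return a list with `matrix` (the filtered [abundance_matrix()]) and
#'   `report`, a `filter_report` with fields `n_input`, `n_kept`,
#'   `n_dropped_low_abundance`, `n_dropped_low_detection`.
#' @export
filter_transcript_series <- function(m, min_total = 50, min_detected = 32) {
  stopifnot(inherits(m, "abund_mat"))
  if (min_detected > ncol(m$values)) {
    stop("min_detected (", min_detected, ") exceeds sample count (",
         ncol(m$values), ")")
  }
  totals <- rowSums(m$values)
  detected <- rowSums(m$values > 0)
  low_ab <- totals < min_total
  low_det <- detected < min_detected
  keep <- !low_ab & !low_det
  report <- structure(list(
    n_input = nrow(m$values),
    n_kept = sum(keep),
    n_dropped_low_abundance = sum(low_ab),
    n_dropped_low_detection = sum(!low_ab & low_det)
  ), class = "filter_report")
  out <- abundance_matrix(m$values[keep, , drop = FALSE], m$samples)
  list(matrix = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Series filter: ", x$n_kept, "/", x$n_input, " kept (",
      x$n_dropped_low_abundance, " low abundance, ",
      x$n_dropped_low_detection, " low detection)\n", sep = "")
  invisible(x)
}

#' TMT bridge-channel normalization across plexes
#'
#' Within each plex, every sample column is divided element-wise by the
#' per-series mean of that plex's bridge (spike) columns; bridge columns are
#' then dropped and the plexes concatenated on the series shared by all
#' plexes (intersection), ordered by series id. The result is relative
#' abundance, invariant to multiplying any whole plex by a positive
#' constant. Series whose bridge mean is zero in some plex are dropped with
#' a warning.
#'
#' @param plexes a list of [abundance_matrix()] objects, one per plex, each
#'   with its bridge samples flagged via `is_bridge`.
#' @param bridge_count minimum number of bridge samples required per plex
#'   (default 2).
#' @return an [abundance_matrix()] of bridge-normalized intensities with
#'   bridge columns removed; attribute `n_dropped_zero_bridge` counts series
#'   removed for a zero bridge mean.
#' @export
bridge_normalize <- function(plexes, bridge_count = 2) {
  if (inherits(plexes, "abund_mat")) plexes <- list(plexes)
  stopifnot(length(plexes) >= 1L, all(vapply(plexes, inherits, TRUE, "abund_mat")))
  shared <- Reduce(intersect, lapply(plexes, function(p) rownames(p$values)))
  shared <- sort(shared)
  if (length(shared) == 0L) stop("no series shared across plexes")
  n_zero <- 0L
  norm <- lapply(plexes, function(p) {
    br <- p$samples$is_bridge
    if (sum(br) == 0L) stop("plex without bridge samples")
    if (sum(br) < bridge_count) {
      stop("plex has ", sum(br), " bridge sample(s), need ", bridge_count)
    }
    v <- p$values[shared, , drop = FALSE]
    bm <- rowMeans(v[, br, drop = FALSE])
    list(values = v[, !br, drop = FALSE] / bm,
         samples = p$samples[!br, , drop = FALSE],
         zero = bm == 0)
  })
  zero_any <- Reduce(`|`, lapply(norm, `[[`, "zero"))
  if (any(zero_any)) {
    n_zero <- sum(zero_any)
    warning(n_zero, " series dropped (zero bridge mean in some plex)")
  }
  keep <- !zero_any
  values <- do.call(cbind, lapply(norm, function(p) p$values[keep, , drop = FALSE]))
  samples <- do.call(rbind, lapply(norm, `[[`, "samples"))
  rownames(samples) <- NULL
  out <- abundance_matrix(values, samples)
  attr(out, "n_dropped_zero_bridge") <- n_zero
  out
}

#' log2(x + 1) transform of an abundance matrix
#'
#' The scale on which all rhythm detection operates: raw transcript counts
#' and bridge-normalized reporter intensities are both taken to
#' `log2(x + 1)` before fitting.
#'
#' @param m an [abundance_matrix()].
#' @return an [abundance_matrix()] with transformed values.
#' @export
log2p1 <- function(m) {
  stopifnot(inherits(m, "abund_mat"))
  abundance_matrix(log2(m$values + 1), m$samples)
}
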