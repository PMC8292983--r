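#' Cytoplasmic/nuclear ratio of a translocation reporter
#'
#' Background-subtracts both channels and returns the per-timepoint
#' ratio (cyto - bg) / (nuc - bg), the standard readout of a kinase
#' translocation reporter. Points where the background-subtracted
#' nuclear signal is not positive are flagged as `NA` (never silently
#' clipped); a warning reports how many.
#'
#' @param cyto,nuc Numeric vectors of equal length: mean cytoplasmic and
#'   nuclear intensities on a matched time grid.
#' @param background Scalar or per-point background, applied to both
#'   channels (or a list with elements `cyto` and `nuc` for separate
#'   backgrounds).
#' @return Numeric ratio trace with `NA` at flagged points.
#' @examples
#' cn_ratio(c(30, 40), c(20, 20), background = 10)  # 2, 3
#' @export
cn_ratio <- function(cyto, nuc, background = 0) {
  if (length(cyto) != length(nuc))
    stop("cyto and nuc must share a time grid", call. = FALSE)
  if (is.list(background)) {
    bg_c <- background$cyto; bg_n <- background$nuc
  } else {
    bg_c <- background; bg_n <- background
  }
  if (any(c(bg_c, bg_n) < 0))
    stop("background must be >= 0", call. = FALSE)
  num <- cyto - bg_c
  den <- nuc - bg_n
  bad <- den <= 0
  if (any(bad)) {
    warning(sum(bad),
            " point(s) with non-positive nuclear signal flagged as NA")
    den[bad] <- NA_real_
  }
  num / den
}

#' Baselined-sum area under the curve
#'
#' Subtracts the initial value from every time point and sums the
#' differences over the whole grid -- a plain sum, not a trapezoidal
#' integral, matching how the biosensor AUCs are computed on the
#' standard 61-point, 15-s fibroblast grid. `NA` points (e.g. flagged
#' by [cn_ratio()]) are dropped from the sum when `na.rm = TRUE`.
#'
#' @param trace Numeric trace (ratio or normalized values), >= 2 points;
#'   the first point must be finite.
#' @param na.rm Drop `NA` points from the sum.
#' @return Scalar AUC in trace units (time-step free).
#' @examples
#' trace_auc(c(1, 2, 3))  # 0 + 1 + 2 = 3
#' @export
trace_auc <- function(trace, na.rm = FALSE) {
  if (length(trace) < 2L)
    stop("trace must have at least 2 points", call. = FALSE)
  if (!is.finite(trace[1L]))
    stop("initial trace value must be finite", call. = FALSE)
  sum(trace - trace[1L], na.rm = na.rm)
}

#' Min-normalize a calcium indicator trace
#'
#' Background-subtracts and divides by the minimum of the
#' background-subtracted trace, so the output minimum is exactly 1 and
#' the result is invariant to multiplicative rescaling of the raw
#' signal.
#'
#' @param trace Raw intensity trace.
#' @param background Scalar or per-point background (>= 0).
#' @param cell_id Optional identifier used in error messages.
#' @return Normalized trace with `min(out) == 1`.
#' @examples
#' normalize_gcamp(c(2, 4, 6))  # 1 2 3
#' @export
normalize_gcamp <- function(trace, background = 0, cell_id = NULL) {
  v <- trace - background
  m <- min(v)
  if (!is.finite(m) || m <= 0)
    stop("non-positive background-subtracted minimum",
         if (!is.null(cell_id)) paste0(" for cell ", cell_id),
         call. = FALSE)
  v / m
}

#' Classify a sustained calcium response
#'
#' A min-normalized trace counts as a sustained response when (i) its
#' maximum exceeds a noise threshold and (ii) a consecutive run of
#' samples, all at or above half the trace maximum (floored at the
#' noise threshold, so the episode itself clears noise), spans at least
#' `min_duration` seconds. A run of n samples spans (n - 1) * dt, so a
#' single 5-s "blink" never qualifies. Cumulative, non-consecutive time
#' above half-max is not counted.
#'
#' The default threshold is a fixed 1.5-fold change over the per-trace
#' minimum; pass `noise_threshold = NULL` to estimate it instead as
#' 1 + `noise_k` * MAD of the first `n_prestim` normalized samples.
#'
#' @param norm_trace Min-normalized trace (from [normalize_gcamp()]).
#' @param dt Sampling interval (s); default 5 s.
#' @param noise_threshold Absolute threshold on the normalized scale, or
#'   `NULL` for the adaptive pre-stimulus estimate.
#' @param min_duration Minimum sustained duration (s); default 30.
#' @param noise_k,n_prestim Adaptive-threshold settings (only used when
#'   `noise_threshold` is `NULL`).
#' @return Logical scalar.
#' @examples
#' v <- c(rep(1, 5), rep(3, 10), rep(1, 22))
#' sustained_response(v)       # plateau spans 45 s -> TRUE
#' w <- rep(1, 37); w[10] <- 3
#' sustained_response(w)       # single 5-s spike -> FALSE
#' @export
sustained_response <- function(norm_trace, dt = 5,
                               noise_threshold = 1.5,
                               min_duration = 30,
                               noise_k = 3, n_prestim = 3) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if ((length(norm_trace) - 1L) * dt < min_duration)
    stop("trace shorter than the minimum sustained duration (",
         min_duration, " s)", call. = FALSE)
  if (is.null(noise_threshold)) {
    pre <- norm_trace[seq_len(min(n_prestim, length(norm_trace)))]
    noise_threshold <- 1 + noise_k * stats::mad(pre)
  }
  peak <- max(norm_trace)
  if (peak <= noise_threshold) return(FALSE)
  ## the sustained episode must itself clear the noise threshold: when
  ## half-max falls below it (small responses), baseline samples would
  ## otherwise count toward the run
  level <- max(peak / 2, noise_threshold)
  runs <- rle(norm_trace >= level)
  any(runs$values & (runs$lengths - 1L) * dt >= min_duration)
}

#' Fraction of responding cells per field of view
#'
#' Applies [sustained_response()] to every trace of one field and
#' returns responders / total. Fields are the unit of replication, so
#' callers keep per-field results separate.
#'
#' @param traces List of min-normalized traces (one per cell), or a
#'   numeric matrix with one column per cell.
#' @param ... Passed to [sustained_response()].
#' @return Fraction in `[0, 1]`.
#' @examples
#' flat <- rep(1, 37)
#' resp <- c(rep(1, 5), rep(3, 32))
#' fraction_responding(list(resp, flat, flat, flat))  # 0.25
#' @export
fraction_responding <- function(traces, ...) {
  if (is.matrix(traces))
    traces <- lapply(seq_len(ncol(traces)), function(j) traces[, j])
  if (length(traces) == 0L)
    stop("empty field of view", call. = FALSE)
  mean(vapply(traces, sustained_response, logical(1), ...))
}

#' Membrane clustering metric: change in coefficient of variation
#'
#' For each frame, computes the CV (sd/mean) of the pixel intensities
#' inside a fixed membrane mask and reports the change relative to the
#' first frame, CV_t - CV_0. Spatial reorganization of a conserved
#' total intensity into puncta raises the CV, so the metric isolates
#' clustering from overall brightness changes (it is invariant to
#' multiplying a frame by a constant). Plain variance is available as an
#' alternative metric.
#'
#' @param frames A numeric 3-D array (rows x cols x time) or a list of
#'   2-D matrices.
#' @param mask Logical matrix matching the frame shape; fixed over time.
#' @param metric `"cv"` (default) or `"variance"`.
#' @return Numeric vector of per-frame changes (first element 0).
#' @examples
#' f0 <- matrix(1, 4, 4); f1 <- matrix(c(0, 2), 4, 4)
#' membrane_cv_timeseries(list(f0, f1), matrix(TRUE, 4, 4))  # 0, 1
#' @export
membrane_cv_timeseries <- function(frames, mask,
                                   metric = c("cv", "variance")) {
  metric <- match.arg(metric)
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3L]),
                     function(k) frames[, , k])
  if (length(frames) == 0L) stop("empty stack", call. = FALSE)
  if (!is.logical(mask) || !any(mask))
    stop("mask must be a non-empty logical matrix", call. = FALSE)
  vals <- vapply(frames, function(fr) {
    if (!identical(dim(fr), dim(mask)))
      stop("frame shape does not match mask", call. = FALSE)
    px <- fr[mask]
    if (metric == "variance") return(stats::var(px))
    m <- mean(px)
    if (m == 0) stop("zero mean intensity within mask", call. = FALSE)
    stats::sd(px) / m
  }, 0)
  vals - vals[1L]
}

#' Quantify a tidy table of biosensor traces
#'
#' Convenience wrapper over the per-trace statistics for the tidy CSV
#' layout (`cell_id`, `field_id`, `channel`, `time_s`, `value`,
#' `background`). The fibroblast protocol pairs `ktr_cyto`/`ktr_nuc`
#' channels into C/N ratios and reports their baselined AUC per cell;
#' `gcamp` channels are min-normalized and report AUC plus the
#' sustained-response call, and per-field responder fractions are
#' summarized separately.
#'
#' @param df Tidy data.frame of traces.
#' @param protocol `"fibroblast"` (KTR, 15-s grid) or `"jurkat"`
#'   (GCaMP, 5-s grid).
#' @param ... Passed to [sustained_response()] for GCaMP calls.
#' @return List with `per_cell` (cell_id, field_id, auc, and for GCaMP
#'   `responder`) and, for GCaMP, `per_field` (field_id, n_cells,
#'   fraction_responding).
#' @export
quantify_traces <- function(df, protocol = c("fibroblast", "jurkat"),
                            ...) {
  protocol <- match.arg(protocol)
  need <- c("cell_id", "field_id", "channel", "time_s", "value",
            "background")
  if (!all(need %in% names(df)))
    stop("trace table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  split_cell <- split(df, list(df$field_id, df$cell_id), drop = TRUE)
  if (protocol == "fibroblast") {
    rows <- lapply(split_cell, function(d) {
      cyto <- d[d$channel == "ktr_cyto", ]
      nuc <- d[d$channel == "ktr_nuc", ]
      cyto <- cyto[order(cyto$time_s), ]
      nuc <- nuc[order(nuc$time_s), ]
      if (nrow(cyto) == 0L || nrow(cyto) != nrow(nuc) ||
          any(cyto$time_s != nuc$time_s))
        stop("cell ", d$cell_id[1L],
             ": cytoplasmic and nuclear channels must share a grid",
             call. = FALSE)
      r <- cn_ratio(cyto$value, nuc$value,
                    list(cyto = cyto$background,
                         nuc = nuc$background))
      data.frame(cell_id = d$cell_id[1L], field_id = d$field_id[1L],
                 auc = trace_auc(r, na.rm = TRUE))
    })
    return(list(per_cell = do.call(rbind, c(rows,
                                            make.row.names = FALSE))))
  }
  rows <- lapply(split_cell, function(d) {
    g <- d[d$channel == "gcamp", ]
    g <- g[order(g$time_s), ]
    if (nrow(g) < 2L)
      stop("cell ", d$cell_id[1L], ": no gcamp trace", call. = FALSE)
    dts <- unique(round(diff(g$time_s), 9))
    if (length(dts) != 1L)
      stop("cell ", d$cell_id[1L], ": non-uniform sampling",
           call. = FALSE)
    nt <- normalize_gcamp(g$value, g$background,
                          cell_id = d$cell_id[1L])
    data.frame(cell_id = d$cell_id[1L], field_id = d$field_id[1L],
               auc = trace_auc(nt),
               responder = sustained_response(nt, dt = dts, ...))
  })
  per_cell <- do.call(rbind, c(rows, make.row.names = FALSE))
  per_field <- do.call(rbind, lapply(split(per_cell,
                                           per_cell$field_id),
    function(d) data.frame(field_id = d$field_id[1L],
                           n_cells = nrow(d),
                           fraction_responding = mean(d$responder))))
  rownames(per_field) <- NULL
  list(per_cell = per_cell, per_field = per_field)
}

#' Read or write tidy trace tables
#'
#' @param path CSV path with columns `cell_id`, `field_id`, `channel`,
#'   `time_s`, `value`, `background`.
#' @return `read_traces()` returns the data.frame.
#' @export
read_traces <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_traces
#' @param df Tidy trace data.frame.
#' @export
write_traces <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read or write an image stack as multi-page TIFF
#'
#' @param path TIFF path; masks are single-page logical images stored
#'   as 0/1.
#' @return `read_image_stack()` returns a list of matrices;
#'   `read_mask()` a logical matrix.
#' @export
read_image_stack <- function(path) {
  img <- tiff::readTIFF(path, all = TRUE)
  lapply(img, function(m) if (length(dim(m)) > 2L) m[, , 1L] else m)
}

#' @rdname read_image_stack
#' @param frames List of matrices (values scaled to `[0, 1]` on write).
#' @export
write_image_stack <- function(frames, path) {
  mx <- max(vapply(frames, max, 0), 1e-12)
  tiff::writeTIFF(lapply(frames, function(f) f / mx), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname read_image_stack
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) > 2L) m <- m[, , 1L]
  m > 0.5
}

#' @rdname read_image_stack
#' @param mask Logical matrix.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}
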