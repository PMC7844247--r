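#' Subtract a blank gradient trace from a sample trace
#'
#' In each centrifugation run a non-sample control gradient is recorded; its
#' trace is interpolated linearly onto the sample grid and subtracted, which
#' removes the sucrose/buffer baseline before peak integration.
#'
#' @param sample A `ribo_trace` with role `"sample"`.
#' @param blank A `ribo_trace` with role `"blank"` from the same run.
#' @param floor Optional numeric: clip the corrected absorbance at this value.
#'   Default `NULL` applies no clipping (integration clips negatives itself).
#' @return A background-corrected `ribo_trace` on the sample grid.
#' @export
subtract_blank <- function(sample, blank, floor = NULL) {
  stopifnot(inherits(sample, "ribo_trace"), inherits(blank, "ribo_trace"))
  lo <- max(min(sample$position), min(blank$position))
  hi <- min(max(sample$position), max(blank$position))
  if (lo >= hi) stop("sample and blank trace domains do not overlap")
  b <- stats::approx(blank$position, blank$absorbance, xout = sample$position,
                     rule = 2)$y
  y <- sample$absorbance - b
  if (!is.null(floor)) y <- pmax(y, floor)
  ribo_trace(sample$position, y, role = "sample",
             label = attr(sample, "label"))
}

#' Segment a corrected trace into ribosome complex regions
#'
#' Boundaries between adjacent complexes are placed at the absorbance minimum
#' between their expected (anchor) positions; when the trace is flat between
#' two anchors the midpoint is used. The outermost boundaries are the trace
#' ends (or configured limits). The polysome region is everything denser than
#' the 80S right boundary.
#'
#' @param trace A background-corrected `ribo_trace`.
#' @param anchors Named numeric vector of expected complex centres, in
#'   sedimentation order, e.g. `c("40S" = .22, "60S" = .33, "80S" = .47,
#'   "polysome" = .62)`. Must contain at least `40S`, `60S`, `80S` and one
#'   polysome anchor, strictly increasing and inside the trace domain.
#' @param limits Optional length-2 numeric giving the left edge of the 40S
#'   region and the right edge of the polysome region; defaults to the trace
#'   ends.
#' @return A `peak_segmentation`: data frame with columns `complex`, `left`,
#'   `right`, attribute `method = "valley"`.
#' @export
segment_peaks <- function(trace, anchors, limits = NULL) {
  stopifnot(inherits(trace, "ribo_trace"))
  req <- c("40S", "60S", "80S")
  if (!all(req %in% names(anchors))) {
    stop("anchors must name at least 40S, 60S and 80S")
  }
  if (length(anchors) < 4L) {
    stop("anchors must include a polysome anchor after 80S")
  }
  anchors <- anchors[order(anchors)]
  if (any(diff(anchors) <= 0)) stop("anchor positions must be strictly increasing")
  dom <- range(trace$position)
  if (any(anchors < dom[1] | anchors > dom[2])) {
    stop("anchors outside trace domain")
  }
  if (is.null(limits)) limits <- dom
  # valley between each adjacent anchor pair; ties resolved toward the midpoint
  valley <- function(a, b) {
    inside <- trace$position > a & trace$position < b
    if (!any(inside)) return((a + b) / 2)
    pos <- trace$position[inside]
    y <- trace$absorbance[inside]
    cand <- pos[y <= min(y) + .Machine$double.eps * max(1, abs(min(y)))]
    mid <- (a + b) / 2
    cand[which.min(abs(cand - mid))]
  }
  n <- length(anchors)
  cuts <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) cuts[i] <- valley(anchors[i], anchors[i + 1L])
  # regions for 40S, 60S, 80S; everything past the 80S right boundary is polysome
  i80 <- which(names(anchors) == "80S")
  bounds <- c(limits[1], cuts[seq_len(i80)], limits[2])
  labels <- c(names(anchors)[seq_len(i80)], "polysome")
  seg <- data.frame(complex = labels,
                    left = bounds[-length(bounds)],
                    right = bounds[-1L],
                    stringsAsFactors = FALSE)
  attr(seg, "method") <- "valley"
  class(seg) <- c("peak_segmentation", "data.frame")
  seg
}

#' Integrate complex peak areas from a segmented trace
#'
#' Trapezoidal integration of the corrected absorbance over each complex
#' interval. Negative absorbance (possible after blank subtraction) is
#' clipped to zero before integration, so areas are non-negative physical
#' quantities. The `total` row is the sum of the 40S, 60S, 80S and polysome
#' areas.
#'
#' @param trace A background-corrected `ribo_trace`.
#' @param seg A `peak_segmentation` for this trace.
#' @return A `complex_abundance` data frame with columns `sample`, `complex`
#'   and `area`, including a `total` row.
#' @export
integrate_complexes <- function(trace, seg) {
  stopifnot(inherits(trace, "ribo_trace"), inherits(seg, "peak_segmentation"))
  y <- pmax(trace$absorbance, 0)
  area1 <- function(l, r) {
    idx <- trace$position >= l & trace$position <= r
    if (sum(idx) < 2L) return(0)
    pracma::trapz(trace$position[idx], y[idx])
  }
  areas <- mapply(area1, seg$left, seg$right)
  out <- data.frame(sample = attr(trace, "label"),
                    complex = c(seg$complex, "total"),
                    area = c(areas, sum(areas)),
                    stringsAsFactors = FALSE)
  class(out) <- c("complex_abundance", "data.frame")
  out
}

#' Quantify a sample/blank trace pair in one call
#'
#' Convenience wrapper: blank subtraction, valley segmentation at the given
#' anchors, and integration.
#'
#' @inheritParams subtract_blank
#' @inheritParams segment_peaks
#' @return A `complex_abundance` table (see [integrate_complexes()]).
#' @export
quantify_trace <- function(sample, blank, anchors, limits = NULL) {
  corrected <- subtract_blank(sample, blank)
  integrate_complexes(corrected, segment_peaks(corrected, anchors, limits))
}

#' Log2 fold change of complex abundances relative to wild type
#'
#' @param mutant,wildtype `complex_abundance` tables with the same complexes.
#' @return A data frame with columns `complex`, `log2_fc` and `undefined`
#'   (TRUE where the wild-type area is zero, in which case `log2_fc` is NA
#'   rather than silently dropped).
#' @export
relative_abundance <- function(mutant, wildtype) {
  m <- stats::setNames(mutant$area, mutant$complex)
  w <- stats::setNames(wildtype$area, wildtype$complex)
  cx <- intersect(names(m), names(w))
  if (!setequal(names(m), names(w))) {
    stop("mutant and wild-type tables must cover the same complexes")
  }
  undef <- w[cx] <= 0
  fc <- ifelse(undef, NA_real_, log2(m[cx] / w[cx]))
  data.frame(complex = cx, log2_fc = unname(fc), undefined = unname(undef),
             stringsAsFactors = FALSE)
}

#' Pearson correlation between two complexes across measurements
#'
#' Correlates the log2 fold changes of two ribosome complexes over all
#' (mutant, timepoint) measurements, assuming a linear trend.
#'
#' @param fc Long-format data frame with columns `complex`, `log2_fc` and one
#'   or more id columns (e.g. `mutant`, `timepoint`) identifying each
#'   measurement.
#' @param a,b Complex labels to correlate.
#' @return List with elements `r` (Pearson coefficient, NA if undefined),
#'   `n` (number of paired observations) and `undefined` (TRUE when either
#'   vector has zero variance).
#' @export
correlate_complexes <- function(fc, a, b) {
  idcols <- setdiff(names(fc), c("complex", "log2_fc", "undefined"))
  xa <- fc[fc$complex == a, , drop = FALSE]
  xb <- fc[fc$complex == b, , drop = FALSE]
  key <- function(d) do.call(paste, c(d[idcols], sep = "\r"))
  ka <- key(xa); kb <- key(xb)
  common <- intersect(ka, kb)
  va <- xa$log2_fc[match(common, ka)]
  vb <- xb$log2_fc[match(common, kb)]
  ok <- is.finite(va) & is.finite(vb)
  va <- va[ok]; vb <- vb[ok]
  if (length(va) < 3L) stop("need at least 3 paired observations")
  if (stats::var(va) == 0 || stats::var(vb) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, n = length(va), undefined = TRUE))
  }
  list(r = stats::cor(va, vb), n = length(va), undefined = FALSE)
}

#' KCl sensitivity of the 80S monosome pool
#'
#' Non-translating 80S monosomes dissociate into 40S and 60S subunits at
#' elevated (400 mM) KCl while translating ribosomes resist. Given complex
#' abundance tables of the same sample extracted at regular (200 mM) and
#' elevated KCl, the KCl-sensitive share of the monosome pool is
#' `(area80S_normal - area80S_elevated) / area80S_normal`; the concomitant
#' relative gains of the 40S and 60S pools are reported alongside.
#'
#' @param normal,elevated `complex_abundance` tables of paired technical
#'   replicates at 200 mM and 400 mM KCl.
#' @return List with `sensitive_share_80s`, `gain_40s`, `gain_60s`,
#'   `consistent` (TRUE when the 80S loss is accompanied by 40S and 60S
#'   gains, the expected sign pattern of a KCl-sensitive pool) and
#'   `undefined` (TRUE when the 80S area at regular KCl is zero).
#' @export
kcl_sensitivity <- function(normal, elevated) {
  n <- stats::setNames(normal$area, normal$complex)
  e <- stats::setNames(elevated$area, elevated$complex)
  if (n[["80S"]] <= 0) {
    warning("80S area at regular KCl is zero: sensitivity undefined")
    return(list(sensitive_share_80s = NA_real_, gain_40s = NA_real_,
                gain_60s = NA_real_, consistent = NA, undefined = TRUE))
  }
  share <- (n[["80S"]] - e[["80S"]]) / n[["80S"]]
  gain <- function(cx) if (n[[cx]] > 0) (e[[cx]] - n[[cx]]) / n[[cx]] else NA_real_
  g40 <- gain("40S"); g60 <- gain("60S")
  list(sensitive_share_80s = unname(share),
       gain_40s = unname(g40), gain_60s = unname(g60),
       consistent = isTRUE(share > 0 && g40 > 0 && g60 > 0) ||
         isTRUE(share == 0 && g40 == 0 && g60 == 0),
       undefined = FALSE)
}

#' Flag a half-mer shoulder between the 80S peak and the first polysome peak
#'
#' Half-mers (polysomes carrying a stalled 40S preinitiation complex) appear
#' as shoulders between the 80S monosome and low-oligomer polysome peaks.
#' This is a qualitative flag only: TRUE when an interior local maximum is
#' found strictly between the 80S right boundary and the first polysome peak.
#'
#' @param trace A corrected `ribo_trace`.
#' @param seg A `peak_segmentation`.
#' @param min_prominence Minimum height of the local maximum above the lower
#'   of its flanking minima, as a fraction of the trace maximum (default 0.01).
#' @return Logical flag.
#' @export
flag_halfmer <- function(trace, seg, min_prominence = 0.01) {
  poly <- seg[seg$complex == "polysome", ]
  idx <- which(trace$position > poly$left & trace$position < poly$right)
  if (length(idx) < 5L) return(FALSE)
  y <- trace$absorbance[idx]
  # first polysome peak = first interior local max
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(locmax) < 2L) return(FALSE)
  # a shoulder is an extra local max before the main polysome peak
  main <- locmax[which.max(y[locmax])]
  shoulders <- locmax[locmax < main]
  if (length(shoulders) == 0L) return(FALSE)
  any(y[shoulders] - min(y[seq_len(main)]) > min_prominence * max(trace$absorbance))
}
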