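#' Absorbance trace from a sucrose density gradient
#'
#' A trace is an ordered series of (position, absorbance) pairs recorded at
#' 254 nm along one sucrose gradient. Positions are normalized gradient
#' coordinates in \[0, 1\] with 0 at the gradient top (low sucrose density)
#' and increasing toward the bottom, so complexes appear in sedimentation
#' order 40S < 60S < 80S < polysomes.
#'
#' @param position Numeric vector of strictly increasing gradient positions.
#' @param absorbance Numeric vector of A254 values (arbitrary units), same
#'   length as `position`, all finite.
#' @param role Either `"sample"` or `"blank"` (the non-sample control gradient
#'   run in the same centrifugation).
#' @param label Free-text label (genotype/timepoint/condition).
#'
#' @return An object of class `ribo_trace`: a data frame with columns
#'   `position` and `absorbance` and attributes `role` and `label`.
#' @export
#' @examples
#' tr <- ribo_trace(seq(0, 1, length.out = 11), rep(0.1, 11))
ribo_trace <- function(position, absorbance, role = c("sample", "blank"),
                       label = "") {
  role <- match.arg(role)
  if (length(position) != length(absorbance)) {
    stop("position and absorbance must have equal length")
  }
  if (length(position) < 2L) stop("a trace needs at least two points")
  if (any(!is.finite(position)) || any(!is.finite(absorbance))) {
    stop("trace values must be finite")
  }
  if (any(diff(position) <= 0)) {
    stop("positions must be strictly increasing")
  }
  out <- data.frame(position = as.numeric(position),
                    absorbance = as.numeric(absorbance))
  attr(out, "role") <- role
  attr(out, "label") <- label
  class(out) <- c("ribo_trace", "data.frame")
  out
}

#' @export
print.ribo_trace <- function(x, ...) {
  cat(sprintf("<ribo_trace> %s '%s': %d points, position [%g, %g], A254 [%g, %g]\n",
              attr(x, "role"), attr(x, "label"), nrow(x),
              min(x$position), max(x$position),
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' Read / write a trace as two-column CSV
#'
#' The on-disk format is a plain CSV with header `position,a254`.
#'
#' @param path File path.
#' @param role,label Passed to [ribo_trace()] on read.
#' @return `read_trace()` returns a `ribo_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path, role = "sample", label = "") {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("position", "a254") %in% names(df))) {
    stop("trace CSV must have columns 'position' and 'a254'")
  }
  ribo_trace(df$position, df$a254, role = role, label = label)
}

#' @rdname read_trace
#' @param trace A `ribo_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ribo_trace"))
  utils::write.csv(data.frame(position = trace$position, a254 = trace$absorbance),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
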