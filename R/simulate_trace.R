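#' Configuration for a synthetic sucrose-gradient trace
#'
#' Describes an A254 absorbance profile as a sum of Gaussian complex peaks
#' over a linearly drifting baseline with additive Gaussian recording noise.
#' Peak centres are normalized gradient positions in \[0, 1\] (0 = gradient
#' top) and must be strictly increasing in sedimentation order
#' 40S < 60S < 80S < polysome n-mers.
#'
#' Defaults emulate a wild-type root profile: a dominant 80S monosome peak,
#' smaller free 40S and 60S subunit peaks, and two low-oligomer polysome
#' peaks, with a mild baseline drift.
#'
#' @param n_points Grid size (>= 100).
#' @param peaks Data frame with columns `complex`, `center`, `amplitude`
#'   (absorbance units) and `width` (gradient-position SD, > 0).
#' @param baseline_slope Absorbance per unit position.
#' @param baseline_offset Absorbance at position 0.
#' @param noise_sd SD of additive recording noise (absorbance units).
#' @param seed Integer seed; identical seeds give bit-identical traces.
#' @return A `trace_config` list.
#' @export
trace_config <- function(n_points = 400,
                         peaks = data.frame(
                           complex = c("40S", "60S", "80S", "P2", "P3"),
                           center = c(0.20, 0.32, 0.47, 0.63, 0.74),
                           amplitude = c(0.35, 0.55, 1.00, 0.45, 0.25),
                           width = c(0.020, 0.022, 0.025, 0.022, 0.020),
                           stringsAsFactors = FALSE),
                         baseline_slope = 0.05,
                         baseline_offset = 0.08,
                         noise_sd = 0.002,
                         seed = 1L) {
  stopifnot(is.data.frame(peaks),
            all(c("complex", "center", "amplitude", "width") %in% names(peaks)))
  if (n_points < 100L) stop("n_points must be >= 100")
  if (any(diff(peaks$center) <= 0)) {
    stop("peak centers must be strictly increasing in sedimentation order")
  }
  if (any(peaks$width <= 0)) stop("peak widths must be > 0")
  structure(list(n_points = as.integer(n_points), peaks = peaks,
                 baseline_slope = baseline_slope,
                 baseline_offset = baseline_offset,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "trace_config")
}

#' Generate a synthetic sample/blank trace pair with known peak areas
#'
#' The sample trace is `baseline + sum of Gaussians + noise`; the blank trace
#' is the same baseline with independent noise, emulating the non-sample
#' control gradient of a centrifugation run. The ground-truth table holds the
#' closed-form area `amplitude * width * sqrt(2*pi)` of every peak. Peaks
#' whose centres are closer than the sum of their widths are flagged
#' (`overlap_warning`), since valley-based integration is ambiguous there.
#'
#' @param config A [trace_config()].
#' @param label Label stored on the sample trace.
#' @return List with elements `sample` and `blank` (`ribo_trace`) and `truth`
#'   (data frame `complex`, `center`, `area`, `overlap_warning`).
#' @export
generate_trace <- function(config = trace_config(), label = "synthetic") {
  stopifnot(inherits(config, "trace_config"))
  pos <- seq(0, 1, length.out = config$n_points)
  baseline <- config$baseline_offset + config$baseline_slope * pos
  signal <- rep(0, config$n_points)
  pk <- config$peaks
  for (i in seq_len(nrow(pk))) {
    signal <- signal +
      pk$amplitude[i] * exp(-(pos - pk$center[i])^2 / (2 * pk$width[i]^2))
  }
  noise <- withr::with_seed(config$seed, list(
    s = stats::rnorm(config$n_points, 0, config$noise_sd),
    b = stats::rnorm(config$n_points, 0, config$noise_sd)))
  overlap <- rep(FALSE, nrow(pk))
  if (nrow(pk) > 1L) {
    gap <- diff(pk$center)
    comb <- pk$width[-nrow(pk)] + pk$width[-1L]
    flag <- gap < comb
    overlap[-nrow(pk)] <- overlap[-nrow(pk)] | flag
    overlap[-1L] <- overlap[-1L] | flag
  }
  truth <- data.frame(complex = pk$complex, center = pk$center,
                      area = pk$amplitude * pk$width * sqrt(2 * pi),
                      overlap_warning = overlap, stringsAsFactors = FALSE)
  list(sample = ribo_trace(pos, baseline + signal + noise$s,
                           role = "sample", label = label),
       blank = ribo_trace(pos, baseline + noise$b, role = "blank",
                          label = paste0(label, "_blank")),
       truth = truth)
}

#' Simulate a full gradient-profiling study with planted complex effects
#'
#' Generates one sample/blank trace pair per genotype and timepoint. Complex
#' amplitudes are the wild-type defaults multiplied by per-genotype,
#' per-timepoint effect factors, emulating the study design in which mutant
#' gradients are compared against a wild-type gradient of the same
#' timepoint. Default effects emulate cold-acclimation behaviour of ribosome
#' biogenesis mutants: roughly two-fold 40S/60S subunit accumulation before
#' cold shift and strong 80S monosome depletion in double mutants after it,
#' with 40S and 60S moving together (so their fold changes correlate tightly)
#' and 80S following only loosely.
#'
#' @param genotypes Character vector of mutant labels.
#' @param timepoints Character vector of timepoint labels.
#' @param effects Data frame with columns `genotype`, `timepoint`, `complex`
#'   and `factor` (multiplicative amplitude effect vs wild type). Complexes
#'   absent from the table keep factor 1. `NULL` uses the built-in pattern.
#' @param effect_jitter_sd SD of multiplicative log2 jitter applied to each
#'   effect factor (biological variation between gradients); default 0.15.
#' @param base_config [trace_config()] used for the wild type.
#' @param seed Integer seed.
#' @return List with `traces` (named list, per genotype x timepoint, each a
#'   `generate_trace()` result; wild type under `"Col-0"`), `anchors` (the
#'   true peak centres usable as segmentation anchors) and `truth` (planted
#'   effect table including the realized jittered factors).
#' @export
simulate_profile_study <- function(genotypes = c("reil1-1", "reil2-1", "reil2-2",
                                                 "dko1", "dko2"),
                                   timepoints = c("0d", "1d", "3d", "7d", "21d"),
                                   effects = NULL,
                                   effect_jitter_sd = 0.15,
                                   base_config = trace_config(noise_sd = 0.002),
                                   seed = 1L) {
  if (is.null(effects)) effects <- default_profile_effects(genotypes, timepoints)
  pk <- base_config$peaks
  combos <- expand.grid(genotype = c("Col-0", genotypes),
                        timepoint = timepoints,
                        stringsAsFactors = FALSE)
  traces <- vector("list", nrow(combos))
  names(traces) <- paste(combos$genotype, combos$timepoint, sep = "_")
  truth_rows <- list()
  for (i in seq_len(nrow(combos))) {
    g <- combos$genotype[i]; tp <- combos$timepoint[i]
    sub_seed <- seed + 1000L * i
    fac <- stats::setNames(rep(1, nrow(pk)), pk$complex)
    if (g != "Col-0") {
      eff <- effects[effects$genotype == g & effects$timepoint == tp, ]
      fac[eff$complex] <- eff$factor
      # polysome n-mers share the polysome effect
      if ("polysome" %in% eff$complex) {
        fac[grepl("^P[0-9]", names(fac))] <-
          eff$factor[eff$complex == "polysome"]
      }
      jit <- withr::with_seed(sub_seed + 1L,
                              stats::rnorm(length(fac), 0, effect_jitter_sd))
      fac <- fac * 2^jit
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(genotype = g, timepoint = tp, complex = names(fac),
                   factor = unname(fac), stringsAsFactors = FALSE)
    }
    cfg <- base_config
    cfg$peaks$amplitude <- pk$amplitude * unname(fac[pk$complex])
    cfg$seed <- sub_seed
    traces[[i]] <- generate_trace(cfg, label = names(traces)[i])
  }
  anchors <- stats::setNames(pk$center, pk$complex)
  anchors <- anchors[c("40S", "60S", "80S", grep("^P", names(anchors), value = TRUE)[1])]
  names(anchors)[4] <- "polysome"
  list(traces = traces, anchors = anchors,
       truth = do.call(rbind, truth_rows), design = combos)
}

# Built-in planted effect pattern for the profile study: free subunits up
# ~2x before cold shift, relaxing toward 1 at day 1 and re-accumulating later;
# 80S unchanged before the shift and depleted in the cold (strongly in double
# mutants); polysomes mildly reduced in the cold.
default_profile_effects <- function(genotypes, timepoints) {
  sub40_60 <- c("0d" = 2.0, "1d" = 1.2, "3d" = 1.6, "7d" = 1.9, "21d" = 2.0)
  mono_dko <- c("0d" = 1.0, "1d" = 0.25, "3d" = 0.3, "7d" = 0.35, "21d" = 0.3)
  mono_single <- c("0d" = 1.0, "1d" = 0.6, "3d" = 0.65, "7d" = 0.7, "21d" = 0.6)
  poly <- c("0d" = 1.0, "1d" = 0.8, "3d" = 0.85, "7d" = 0.9, "21d" = 0.85)
  rows <- list()
  for (g in genotypes) {
    dbl <- grepl("^dko", g)
    for (tp in timepoints) {
      s <- if (g == "reil1-1" && tp == "1d") 1.8 else sub40_60[[tp]]
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, timepoint = tp,
        complex = c("40S", "60S", "80S", "polysome"),
        factor = c(s, s, if (dbl) mono_dko[[tp]] else mono_single[[tp]],
                   poly[[tp]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
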