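#' Build a synthetic protein annotation catalog
#'
#' Creates an in-silico catalog with cytosolic 40S and 60S RP families
#' (paralog pairs), organellar 30S/50S RPs, ribosome biogenesis factors
#' (including the pre-60S markers eIF6A and NMD3), eIF3 subunits and
#' unrelated co-purifying proteins. Identifiers are synthetic
#' (`sRPS*/sRPL*` etc. with `ATS*`-style gene models) so the catalog can
#' never be mistaken for a curated one.
#'
#' @param n_rp40,n_rp60 Number of cytosolic small/large subunit RP entries.
#' @param n_rp30_org,n_rp50_org Organelle RP entries.
#' @param n_biogenesis Biogenesis-factor entries beyond the two markers.
#' @param n_eif3,n_other eIF3 subunit and contaminant entries.
#' @return A `ribo_annotation`.
#' @export
synthetic_catalog <- function(n_rp40 = 20, n_rp60 = 30, n_rp30_org = 6,
                              n_rp50_org = 8, n_biogenesis = 8, n_eif3 = 5,
                              n_other = 12) {
  mk <- function(prefix, n, class, fam_prefix, gm_prefix) {
    if (n == 0L) return(NULL)
    i <- seq_len(n)
    # consecutive entries form paralog pairs within one family
    fam <- paste0(fam_prefix, (i + 1L) %/% 2L)
    data.frame(protein_id = sprintf("%s%02d", prefix, i),
               gene_model = sprintf("%sG%05d", gm_prefix, i * 10L),
               rp_class = class, family = fam,
               paralog = sprintf("%s%02d", prefix, i),
               marker_role = "none",
               paralog_specific = rep(c(TRUE, FALSE), length.out = n),
               stringsAsFactors = FALSE)
  }
  markers <- data.frame(
    protein_id = c("sEIF6A", "sNMD3"),
    gene_model = c("ATS3G55620", "ATS2G03820"),
    rp_class = "biogenesis", family = c("TIF6", "NMD3"),
    paralog = c("sEIF6A", "sNMD3"), marker_role = "pre60S_marker",
    paralog_specific = TRUE, stringsAsFactors = FALSE)
  df <- rbind(mk("sRPS", n_rp40, "RP40S", "S", "ATS1"),
              mk("sRPL", n_rp60, "RP60S", "L", "ATS2"),
              mk("sPRPS", n_rp30_org, "RP30S_org", "oS", "ATS3"),
              mk("sPRPL", n_rp50_org, "RP50S_org", "oL", "ATS4"),
              markers,
              mk("sBIO", n_biogenesis, "biogenesis", "BIO", "ATS5"),
              mk("sEIF3", n_eif3, "eIF3", "eIF3", "ATS6"),
              mk("sCONT", n_other, "other", "X", "ATS7"))
  as_annotation(df)
}

# Default relative abundance of each RP class across the six sampled
# fractions, in sedimentation order: 30S/40S, 50S, 60S, 60S/80S, 80S,
# low-oligomer polysome. Rows sum to 1.
DEFAULT_FRACTION_PROFILES <- rbind(
  RP40S      = c(0.58, 0.05, 0.02, 0.10, 0.10, 0.15),
  RP60S      = c(0.02, 0.05, 0.38, 0.30, 0.13, 0.12),
  RP30S_org  = c(0.60, 0.30, 0.05, 0.03, 0.01, 0.01),
  RP50S_org  = c(0.13, 0.65, 0.14, 0.05, 0.02, 0.01),
  biogenesis = c(0.02, 0.06, 0.47, 0.35, 0.07, 0.03),
  eIF3       = c(0.62, 0.16, 0.08, 0.06, 0.04, 0.04),
  other      = c(0.30, 0.25, 0.15, 0.12, 0.10, 0.08))
colnames(DEFAULT_FRACTION_PROFILES) <-
  c("F1", "F2", "F3", "F4", "F5", "F6")

#' Configuration for a synthetic fraction-wise LFQ experiment
#'
#' Describes two paired ribo-proteome experiments (`DS1`, `DS2`), each
#' comparing a wild type against one double mutant at an optimized (20C) and
#' a cold (10C) temperature. Each protein's abundance follows its RP-class
#' profile across six gradient fractions scaled by a per-protein base
#' abundance, multiplied by planted mutant effects, with multiplicative
#' log-normal noise and detection-limit censoring.
#'
#' @param catalog A `ribo_annotation`; default [synthetic_catalog()].
#' @param fraction_profiles Class x fraction matrix of relative abundances
#'   (rows named by rp_class, rows sum to 1).
#' @param planted_changes Data frame with columns `protein_id`, `experiment`
#'   (`"DS1"`, `"DS2"` or `"both"`), `temperature` (`"10C"`, `"20C"` or
#'   `"both"`) and `effect`: multiplicative factor applied to the mutant
#'   (`0` = absent in the mutant; `Inf` = present only in the mutant, i.e.
#'   absent from the wild type).
#' @param censor_threshold LFQ units below which values are reported as 0
#'   (not detected). Must be >= 0.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   noise; 0 disables noise.
#' @param base_meanlog,base_sdlog Log-normal parameters of per-protein base
#'   abundances (LFQ units).
#' @param seed Integer seed.
#' @return A `proteome_sim_config` list.
#' @export
proteome_sim_config <- function(catalog = synthetic_catalog(),
                                fraction_profiles = DEFAULT_FRACTION_PROFILES,
                                planted_changes = NULL,
                                censor_threshold = 0,
                                noise_cv = 0.2,
                                base_meanlog = log(1e7),
                                base_sdlog = 1,
                                seed = 1L) {
  stopifnot(inherits(catalog, "ribo_annotation"))
  if (nrow(catalog) == 0L) stop("catalog is empty")
  if (censor_threshold < 0) stop("censor_threshold must be >= 0")
  if (is.null(planted_changes)) {
    planted_changes <- data.frame(protein_id = character(),
                                  experiment = character(),
                                  temperature = character(),
                                  effect = numeric(),
                                  stringsAsFactors = FALSE)
  }
  unknown <- setdiff(planted_changes$protein_id, catalog$protein_id)
  if (length(unknown)) {
    stop("planted change names protein(s) not in catalog: ",
         paste(unknown, collapse = ", "))
  }
  missing_cls <- setdiff(unique(catalog$rp_class), rownames(fraction_profiles))
  if (length(missing_cls)) {
    stop("fraction_profiles missing class(es): ",
         paste(missing_cls, collapse = ", "))
  }
  structure(list(catalog = catalog, fraction_profiles = fraction_profiles,
                 planted_changes = planted_changes,
                 censor_threshold = censor_threshold, noise_cv = noise_cv,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 seed = as.integer(seed)),
            class = "proteome_sim_config")
}

#' Generate a synthetic fraction-wise LFQ experiment with planted truth
#'
#' Produces one `fraction_table` per experiment x genotype x temperature
#' (DS1/DS2, wild type `Col-0` vs `mutant`, `20C` vs `10C`) plus a complete
#' ground-truth ledger: one row per planted change per context it applies to,
#' with the expected downstream call (`"+"`, `"-"`, `"up"`, `"down"`) and
#' expected log2 fold change where numeric.
#'
#' @param config A [proteome_sim_config()].
#' @return List with `tables` (named list of `fraction_table`), `truth`
#'   (ledger data frame) and `catalog`.
#' @export
generate_lfq_experiment <- function(config = proteome_sim_config()) {
  stopifnot(inherits(config, "proteome_sim_config"))
  cat <- config$catalog
  prof <- config$fraction_profiles
  nf <- ncol(prof)
  expected <- function(base) {
    m <- base * prof[cat$rp_class, , drop = FALSE]
    rownames(m) <- cat$protein_id
    colnames(m) <- colnames(prof)
    m
  }
  sdlog <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0
  contexts <- expand.grid(experiment = c("DS1", "DS2"),
                          genotype = c("Col-0", "mutant"),
                          temperature = c("20C", "10C"),
                          stringsAsFactors = FALSE)
  pc <- config$planted_changes
  applies <- function(col, val) pc[[col]] == val | pc[[col]] == "both"
  tables <- withr::with_seed(config$seed, {
    base <- stats::setNames(
      stats::rlnorm(nrow(cat), config$base_meanlog, config$base_sdlog),
      cat$protein_id)
    out <- vector("list", nrow(contexts))
    names(out) <- paste(contexts$experiment, contexts$genotype,
                        contexts$temperature, sep = "_")
    for (i in seq_len(nrow(contexts))) {
      ex <- contexts$experiment[i]; g <- contexts$genotype[i]
      tp <- contexts$temperature[i]
      m <- expected(base)
      if (nrow(pc)) {
        hit <- applies("experiment", ex) & applies("temperature", tp)
        for (j in which(hit)) {
          p <- pc$protein_id[j]; eff <- pc$effect[j]
          if (g == "mutant") {
            if (is.finite(eff)) m[p, ] <- m[p, ] * eff
          } else {
            if (is.infinite(eff)) m[p, ] <- 0  # present only in the mutant
            if (eff == 0) m[p, ] <- m[p, ]     # absent in mutant: WT untouched
          }
          if (g == "mutant" && eff == 0) m[p, ] <- 0
        }
      }
      if (sdlog > 0) {
        m <- m * matrix(stats::rlnorm(length(m), -sdlog^2 / 2, sdlog),
                        nrow(m), ncol(m))
      }
      m[m < config$censor_threshold] <- 0
      out[[i]] <- fraction_table(m, cat, genotype = g, temperature = tp,
                                 experiment = ex)
    }
    out
  })
  truth <- if (nrow(pc)) {
    rows <- list()
    for (j in seq_len(nrow(pc))) {
      exs <- if (pc$experiment[j] == "both") c("DS1", "DS2") else pc$experiment[j]
      tps <- if (pc$temperature[j] == "both") c("20C", "10C") else pc$temperature[j]
      for (ex in exs) for (tp in tps) {
        eff <- pc$effect[j]
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = pc$protein_id[j], experiment = ex, temperature = tp,
          effect = eff,
          expected_call = if (is.infinite(eff)) "+" else if (eff == 0) "-"
                          else if (eff > 1) "up" else if (eff < 1) "down"
                          else "none",
          expected_log2fc = if (is.finite(eff) && eff > 0) log2(eff) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  } else {
    data.frame(protein_id = character(), experiment = character(),
               temperature = character(), effect = numeric(),
               expected_call = character(), expected_log2fc = numeric(),
               stringsAsFactors = FALSE)
  }
  list(tables = tables, truth = truth, catalog = cat)
}

#' Noise-free expectation of a synthetic LFQ table
#'
#' Deterministic expected table (before noise and censoring) for the wild
#' type of one experiment under a config; used to choose censoring thresholds
#' and as a construction oracle in tests.
#'
#' @param config A [proteome_sim_config()].
#' @return The wild-type DS1 expectation matrix at 20C.
#' @export
expected_lfq_table <- function(config) {
  cfg <- config
  cfg$noise_cv <- 0
  cfg$censor_threshold <- 0
  generate_lfq_experiment(cfg)$tables[["DS1_Col-0_20C"]]$lfq
}
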