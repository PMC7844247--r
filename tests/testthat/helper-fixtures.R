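# Shared fixtures built in code.

# minimal annotation catalog for toy fraction tables
toy_catalog <- function() {
  as_annotation(data.frame(
    protein_id = c("L1", "L2", "S1", "S2", "B1", "O1", "E6", "N3"),
    gene_model = c("AT1G00010", "AT1G00020", "AT1G00030", "AT1G00040",
                   "AT1G00050", "AT1G00060", "AT3G55620", "AT2G03820"),
    rp_class = c("RP60S", "RP60S", "RP40S", "RP40S", "biogenesis", "other",
                 "biogenesis", "biogenesis"),
    family = c("uL3", "uL3", "uS3", "uS3", "BIO", "X", "TIF6", "NMD3"),
    paralog = c("L1", "L2", "S1", "S2", "B1", "O1", "E6", "N3"),
    marker_role = c("none", "none", "none", "none", "none", "none",
                    "pre60S_marker", "pre60S_marker"),
    paralog_specific = TRUE, stringsAsFactors = FALSE))
}

# toy 6-fraction LFQ table following the default class layout
toy_fraction_table <- function(genotype = "Col-0", temperature = "10C",
                               experiment = "DS1") {
  m <- rbind(
    L1 = c(0, 1, 20, 15, 5, 3),
    L2 = c(0, 2, 60, 45, 12, 8),
    S1 = c(50, 3, 1, 6, 6, 8),
    S2 = c(30, 2, 1, 4, 4, 5),
    B1 = c(0, 1, 10, 8, 1, 0),
    O1 = c(5, 4, 4, 3, 2, 1),
    E6 = c(0, 0, 6, 4, 0, 0),
    N3 = c(0, 0, 5, 4, 0, 0))
  colnames(m) <- paste0("F", 1:6)
  fraction_table(m, toy_catalog(), genotype, temperature, experiment)
}

# single clean Gaussian trace on [0,1]
gaussian_trace <- function(center, amplitude, width, n = 1001, label = "g") {
  x <- seq(0, 1, length.out = n)
  ribo_trace(x, amplitude * exp(-(x - center)^2 / (2 * width^2)),
             label = label)
}

# planted proteome experiment for end-to-end tests: effects on
# non-reference-class proteins so zero-noise recovery is exact
planted_lfq_config <- function(noise_cv = 0, censor_threshold = 0, seed = 42) {
  planted <- data.frame(
    protein_id = c("sBIO01", "sBIO03", "sEIF301", "sCONT01"),
    experiment = "both",
    temperature = c("10C", "10C", "10C", "both"),
    effect = c(4, 0.25, 3, 0.3),
    stringsAsFactors = FALSE)
  proteome_sim_config(planted_changes = planted, noise_cv = noise_cv,
                      censor_threshold = censor_threshold, seed = seed)
}
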