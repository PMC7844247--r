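make_identity <- function(labels, fractions = paste0("F", seq_along(labels))) {
  out <- data.frame(fraction = fractions, label = labels,
                    stringsAsFactors = FALSE)
  class(out) <- c("fraction_identity", "data.frame")
  out
}

test_that("fraction identities follow RP-class sums and marker maxima", {
  tb <- toy_fraction_table()
  id <- assign_fractions(tb)
  expect_equal(id$label, c("30S/40S", "50S", "60S", "60S/80S",
                           "polysome", "polysome"))
  # the marker-bearing fraction carries the eIF6A/NMD3 maxima
  expect_true(id$marker_max[3])
  expect_true(id$label[3] %in% c("60S", "60S/80S"))
  # planted synthetic class profiles recover the planted sedimentation order
  sim <- generate_lfq_experiment(planted_lfq_config())
  for (nm in names(sim$tables)) {
    lab <- assign_fractions(sim$tables[[nm]])$label
    expect_equal(lab[1:4], c("30S/40S", "50S", "60S", "60S/80S"))
  }
})

test_that("a lone fraction of 40S RPs is forced to the 30S/40S label", {
  m <- matrix(c(10, 20), ncol = 1, dimnames = list(c("S1", "S2"), "F1"))
  tb <- fraction_table(m, toy_catalog())
  expect_equal(assign_fractions(tb)$label, "30S/40S")
  empty <- fraction_table(matrix(0, 2, 2, dimnames = list(c("O1", "B1"),
                                                          c("F1", "F2"))),
                          toy_catalog())
  expect_error(assign_fractions(empty), "no ribosomal proteins")
})

test_that("total RP summary gives exact per-class matrix sums", {
  tb <- toy_fraction_table()
  tot <- total_rp_summary(tb)
  get <- function(k) tot$total[tot$rp_class == k]
  expect_equal(get("RP60S"), sum(tb$lfq["L1", ]) + sum(tb$lfq["L2", ]))
  expect_equal(get("RP40S"), sum(tb$lfq["S1", ]) + sum(tb$lfq["S2", ]))
  expect_equal(get("biogenesis"),
               sum(tb$lfq[c("B1", "E6", "N3"), ]))
  zero <- fraction_table(matrix(0, 2, 2, dimnames = list(c("L1", "S1"),
                                                         c("F1", "F2"))),
                         toy_catalog())
  expect_true(all(total_rp_summary(zero)$total == 0))
})

test_that("normalized shares: reference sums to 1, hand case, scale invariance", {
  tb <- toy_fraction_table()
  sh <- normalize_shares(tb, "60S")
  cls <- classify_protein(tb$catalog, rownames(sh$shares))
  expect_equal(unname(colSums(sh$shares[cls == "RP60S", ])), c(1, 1))
  # 40S RPs excluded from the 60S compartment
  expect_false(any(c("S1", "S2") %in% rownames(sh$shares)))
  # hand-computed 3-protein toy: 60S RPs 2 and 6, non-RP protein 4
  m <- matrix(c(2, 6, 4), ncol = 1, dimnames = list(c("L1", "L2", "O1"), "F3"))
  mini <- fraction_table(m, toy_catalog())
  shm <- normalize_shares(mini, "60S", identity = make_identity("60S", "F3"))
  expect_equal(unname(shm$shares[, 1]), c(0.25, 0.75, 0.5))
  # multiplying a fraction by c > 0 leaves shares unchanged
  tb2 <- tb; tb2$lfq[, "F3"] <- tb$lfq[, "F3"] * 7.3
  expect_equal(normalize_shares(tb2, "60S")$shares, sh$shares)
  # zero reference sum excludes the fraction with a warning
  tb3 <- tb; tb3$lfq[c("L1", "L2"), "F4"] <- 0
  expect_warning(sh3 <- normalize_shares(tb3, "60S",
                                         identity = assign_fractions(tb)),
                 "zero")
  expect_equal(sh3$invalid_fractions, "F4")
})

test_that("40S-compartment shares normalize to the 40S RP sum", {
  tb <- toy_fraction_table()
  sh <- normalize_shares(tb, "40S")
  expect_equal(ncol(sh$shares), 1L)
  cls <- classify_protein(tb$catalog, rownames(sh$shares))
  expect_equal(unname(colSums(sh$shares[cls == "RP40S", , drop = FALSE])), 1)
  expect_false(any(c("L1", "L2") %in% rownames(sh$shares)))
  expect_equal(unname(sh$shares["S1", 1]), 50 / 80)
})

test_that("combining 60S and 60S/80S fractions averages with divisor 2", {
  m <- matrix(c(0.2, 0.4, 0.4, 0, 0.3, 0.3), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("F3", "F4")))
  sh <- structure(list(shares = m, compartment = "60S"),
                  class = "share_table")
  comb <- combine_60s_fractions(sh)
  expect_equal(unname(comb), c(0.3, 0.2, 0.3))
  # equal shares pass through unchanged
  expect_equal(unname(comb["c"]), 0.3)
})

test_that("abundance-maximum filter applies the conservative tie rule", {
  tb <- toy_fraction_table()
  id <- assign_fractions(tb)
  keep60 <- abundance_max_filter(tb, "60S", id)
  expect_true(keep60[["L1"]])
  expect_true(keep60[["B1"]])
  expect_false(keep60[["S1"]])  # peaks in 30S/40S
  expect_false(keep60[["O1"]])  # peaks outside 60S region
  # protein peaking in the 50S fraction is excluded from the 60S analysis
  tb2 <- tb
  tb2$lfq <- rbind(tb2$lfq, P50 = c(1, 30, 10, 5, 0, 0))
  expect_false(abundance_max_filter(tb2, "60S", id)[["P50"]])
  # tie between 50S and 60S maxima resolves against inclusion
  tb3 <- tb
  tb3$lfq <- rbind(tb3$lfq, TIE = c(0, 10, 10, 2, 0, 0))
  expect_false(abundance_max_filter(tb3, "60S", id)[["TIE"]])
  # protein detected only in the 60S fraction passes
  tb4 <- tb
  tb4$lfq <- rbind(tb4$lfq, ONLY = c(0, 0, 9, 0, 0, 0))
  expect_true(abundance_max_filter(tb4, "60S", id)[["ONLY"]])
  # 40S compartment: more abundant in 30S/40S than in 60S
  keep40 <- abundance_max_filter(tb, "40S", id)
  expect_true(keep40[["S1"]])
  expect_true(keep40[["O1"]])   # 5 > 4
  expect_false(keep40[["L1"]])
  # absent everywhere fails
  tb5 <- tb
  tb5$lfq <- rbind(tb5$lfq, GONE = rep(0, 6))
  expect_false(abundance_max_filter(tb5, "60S", id)[["GONE"]])
})

test_that("change calling codes presence, absence and |1| fold-change classes", {
  mut <- c(a = 0.4, b = 0, c = 0.2, d = 0.6, e = 0.1, f = 0.3)
  wt <- c(a = 0, b = 0.5, c = 0.2, d = 0.2, e = 0.4, f = 0.2)
  cc <- call_changes(mut, wt)
  row <- function(p) cc[cc$protein_id == p, ]
  expect_equal(row("a")$status, "+")
  expect_equal(row("b")$status, "-")
  expect_equal(row("c")$log2_fc, 0)
  expect_equal(row("c")$class, "weak_up")     # boundary convention
  expect_equal(row("d")$log2_fc, log2(3))
  expect_equal(row("d")$class, "strong_up")   # log2 FC ~ 1.585 > 1
  expect_equal(row("e")$class, "strong_down")
  expect_equal(row("f")$class, "weak_up")
  # antisymmetry of numeric calls under swapping mutant and wild type
  cc_rev <- call_changes(wt, mut)
  num <- cc$status == "numeric"
  m1 <- stats::setNames(cc$log2_fc, cc$protein_id)
  m2 <- stats::setNames(cc_rev$log2_fc, cc_rev$protein_id)
  expect_equal(m1[num], -m2[names(m1[num])])
  # proteins absent from both are dropped
  expect_equal(nrow(call_changes(c(g = 0), c(g = 0))), 0L)
})

test_that("shared-change selection agrees with its stated set rules", {
  mk <- function(ids, fcs, temp = "10C") {
    cc <- call_changes(stats::setNames(0.2 * 2^fcs, ids),
                       stats::setNames(rep(0.2, length(ids)), ids))
    cc$temperature <- temp
    cc
  }
  a <- mk(c("p", "q", "r"), c(1, -1, 0.5))
  # identity: every directional call shared; symmetric in arguments
  expect_equal(select_shared(a, a)$n_shared, 3L)
  b <- mk(c("p", "q", "r"), c(0.5, -2, -0.5))
  ab <- select_shared(a, b); ba <- select_shared(b, a)
  expect_equal(ab$table, ba$table)
  # r has opposite directions -> excluded; p, q agree
  expect_setequal(ab$increased, "p")
  expect_setequal(ab$decreased, "q")
  # stringent mode needs agreement at 20C matching the cold direction
  a2 <- rbind(a, mk(c("p", "q"), c(0.7, 1), "20C"))
  b2 <- rbind(b, mk(c("p", "q"), c(0.3, -1), "20C"))
  strict <- select_shared(a2, b2, "both_temperatures")
  expect_equal(strict$increased, "p")   # q flips at 20C in experiment A
  expect_equal(strict$n_decreased, 0L)
})

test_that("zero-noise end-to-end run recovers exactly the planted ledger", {
  sim <- generate_lfq_experiment(planted_lfq_config(noise_cv = 0))
  rep60 <- riboproteome_report(sim$tables, "60S", "cold_only")
  expect_equal(rep60$increased, "sBIO01")
  expect_equal(rep60$decreased, "sBIO03")
  rep40 <- riboproteome_report(sim$tables, "40S", "cold_only")
  expect_equal(rep40$increased, "sEIF301")
  expect_equal(rep40$decreased, "sCONT01")
  # stringent mode keeps only the change planted at both temperatures
  strict40 <- riboproteome_report(sim$tables, "40S", "both_temperatures")
  expect_equal(strict40$decreased, "sCONT01")
  expect_equal(strict40$n_increased, 0L)
})

test_that("organelle RPs are excluded from the 40S report, eIF3 retained", {
  planted <- data.frame(protein_id = c("sPRPS01", "sEIF302"),
                        experiment = "both", temperature = "10C",
                        effect = c(5, 3), stringsAsFactors = FALSE)
  sim <- generate_lfq_experiment(proteome_sim_config(
    planted_changes = planted, noise_cv = 0, seed = 13))
  rep40 <- riboproteome_report(sim$tables, "40S", "cold_only")
  expect_false("sPRPS01" %in% rep40$increased)
  expect_true("sEIF302" %in% rep40$increased)
  # configurable contaminant list
  rep40b <- riboproteome_report(sim$tables, "40S", "cold_only",
                                contaminants = "sEIF302")
  expect_false("sEIF302" %in% rep40b$increased)
})

test_that("transcript-protein association joins on gene model", {
  cat <- toy_catalog()
  calls <- call_changes(c(L1 = 0.1, B1 = 0.4, O1 = 0.2),
                        c(L1 = 0.4, B1 = 0.1, O1 = 0.2 * 2^-0.1))
  tx <- data.frame(gene_model = c("AT1G00010", "AT1G00050", "AT9G99999"),
                   log2_fc = c(-1.0, 0.8, 0.3),
                   p_value = c(0.01, 0.2, 0.5))
  out <- transcript_protein_association(calls, tx, cat)
  # RPL3B-style case: protein down, transcript down, significant -> concordant
  l1 <- out[!is.na(out$protein_id) & out$protein_id == "L1", ]
  expect_true(l1$concordant)
  # same direction but not significant -> not concordant
  b1 <- out[!is.na(out$protein_id) & out$protein_id == "B1", ]
  expect_false(b1$concordant)
  # protein with no transcript record keeps a null partner row
  o1 <- out[!is.na(out$protein_id) & out$protein_id == "O1", ]
  expect_true(is.na(o1$transcript_log2_fc))
  # unmatched transcript retained too; join size matches construction
  expect_true("AT9G99999" %in% out$gene_model)
  expect_equal(nrow(out), 4L)
})
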