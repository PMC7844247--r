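test_that("quantile normalization matches the order-statistic definition", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  expect_equal(unname(quantile_normalize(m)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  same <- cbind(x = c(5, 1, 3), y = c(5, 1, 3))
  expect_equal(quantile_normalize(same), same)
  one <- matrix(c(9, 2, 4), dimnames = list(NULL, "s"))
  expect_equal(quantile_normalize(one), one)
})

test_that("quantile normalization is idempotent", {
  set.seed(3)
  m <- matrix(stats::rnorm(200), 40, 5,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
  q1 <- quantile_normalize(m)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  # every column now has identical sorted values
  s <- apply(q1, 2, sort)
  expect_true(all(abs(s - s[, 1]) < 1e-12))
})

test_that("probe collapsing averages redundant probes", {
  m <- rbind(p1 = c(2, 10), p2 = c(4, 20), p3 = c(7, 7), px = c(0, 0))
  colnames(m) <- c("s1", "s2")
  map <- data.frame(probe = c("p1", "p2", "p3"),
                    gene = c("gA", "gA", "gB"))
  expect_warning(out <- collapse_probes(m, map), "unmapped")
  expect_equal(out["gA", ], c(s1 = 3, s2 = 15))
  expect_equal(out["gB", ], c(s1 = 7, s2 = 7))  # single probe passes through
  expect_false("px" %in% rownames(out))
  expect_error(collapse_probes(m, data.frame(probe = character(),
                                             gene = character())), "empty")
})

test_that("Welch test matches the closed-form formula and handles degeneracy", {
  a <- c(4.1, 5.2, 3.9, 4.8); b <- c(6.0, 6.4, 5.1)
  res <- welch_t(a, b)
  # independent closed-form evaluation
  se <- sqrt(stats::var(a) / 4 + stats::var(b) / 3)
  t_exp <- (mean(a) - mean(b)) / se
  df_exp <- se^4 / ((stats::var(a) / 4)^2 / 3 + (stats::var(b) / 3)^2 / 2)
  expect_equal(res$t, t_exp, tolerance = 1e-12)
  expect_equal(res$df, df_exp, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * stats::pt(-abs(t_exp), df_exp),
               tolerance = 1e-12)
  ident <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0); expect_equal(ident$p_value, 1)
  flat <- welch_t(c(2, 2), c(2, 2))
  expect_equal(flat$p_value, 1)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("log2fc recovers planted shifts and the self-contrast identity", {
  cfg <- expression_sim_config(n_genes = 40, residual_sd = 0,
                               cold_response_sd = 0,
                               planted_constitutive = data.frame(
                                 gene = "GENE00005", shift = 1),
                               seed = 2)
  sim <- generate_expression(cfg)
  fc <- log2fc(sim$matrix, sim$metadata, "DKO1", "0d")
  expect_equal(fc$log2_fc[fc$gene == "GENE00005"], 1)
  expect_equal(fc$log2_fc[fc$gene == "GENE00010"], 0)
  expect_equal(fc$p_value[fc$gene == "GENE00010"], 1)
  # reference against itself: FC 0, P 1 everywhere
  self <- log2fc(sim$matrix, sim$metadata, "Col-0", "0d")
  expect_true(all(self$log2_fc == 0))
  expect_true(all(self$p_value == 1))
  # linear-input flag applies log2 first
  lin <- log2fc(2^sim$matrix, sim$metadata, "DKO1", "0d", linear_input = TRUE)
  expect_equal(lin$log2_fc, fc$log2_fc, tolerance = 1e-9)
  expect_error(log2fc(sim$matrix, sim$metadata, "NOPE", "0d"), "replicates")
})

test_that("two-way ANOVA matches the brute-force SS oracle on balanced data", {
  set.seed(7)
  g <- rep(c("Col-0", "DKO1", "DKO2"), each = 9)
  t <- rep(rep(c("0d", "1d", "7d"), each = 3), 3)
  y <- stats::rnorm(27) + (g == "DKO1") * 0.8 + (t == "7d") * 0.5
  res <- two_way_anova(y, g, t)
  oracle <- bf_anova(y, g, t)
  expect_equal(c(res$f_genotype, res$f_time, res$f_interaction), oracle$f,
               tolerance = 1e-10)
  expect_equal(c(res$p_genotype, res$p_time, res$p_interaction), oracle$p,
               tolerance = 1e-10)
  # degenerate all-equal input
  flat <- two_way_anova(rep(1, 27), g, t)
  expect_equal(c(flat$f_genotype, flat$p_interaction), c(0, 1))
  expect_error(two_way_anova(y, rep("a", 27), t), "2 levels")
})

test_that("per-gene ANOVA flags a planted genotype effect without interaction", {
  cfg <- expression_sim_config(n_genes = 20, residual_sd = 0.1,
                               cold_response_sd = 0,
                               planted_constitutive = data.frame(
                                 gene = "GENE00003", shift = 2),
                               seed = 5)
  sim <- generate_expression(cfg)
  res <- anova_by_gene(sim$matrix, sim$metadata)
  hit <- res[res$gene == "GENE00003", ]
  expect_lt(hit$p_genotype, 1e-6)
  expect_gt(hit$p_interaction, 0.01)
})

test_that("PAGE z matches the worked case and its symmetries", {
  # engineered vector with global mean exactly 0 and SD exactly 1,
  # containing a 16-gene set with set mean 0.5
  n_bg <- 84
  bg_mean <- -8 / n_bg
  e2 <- 99 - 16 * 0.25 - n_bg * bg_mean^2
  e <- rep(c(1, -1), n_bg / 2) * sqrt(e2 / n_bg)
  fc <- c(rep(0.5, 16), bg_mean + e)
  names(fc) <- sprintf("g%03d", seq_along(fc))
  expect_equal(mean(fc), 0, tolerance = 1e-12)
  expect_equal(stats::sd(fc), 1, tolerance = 1e-12)
  sets <- list(worked = names(fc)[1:16])
  res <- page_enrichment(fc, sets)
  expect_equal(res$z, 2, tolerance = 1e-9)
  expect_equal(res$p_value, 2 * stats::pnorm(-2), tolerance = 1e-9)
  # one-sided variant
  res1 <- page_enrichment(fc, sets, sided = "one")
  expect_equal(res1$p_value, stats::pnorm(-2), tolerance = 1e-9)
  # a set whose mean equals the global mean scores z = 0
  res0 <- page_enrichment(fc, list(all = names(fc)))
  expect_equal(res0$z, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1, tolerance = 1e-12)
  # affine equivariance: fc -> a + b*fc gives z -> sign(b)*z
  resb <- page_enrichment(3 - 2 * fc, sets)
  expect_equal(resb$z, -res$z, tolerance = 1e-9)
})

test_that("PAGE skips small sets and validates its inputs", {
  set.seed(11)
  fc <- stats::setNames(stats::rnorm(100), sprintf("g%03d", 1:100))
  sets <- list(big = names(fc)[1:20], tiny = names(fc)[1:5])
  res <- page_enrichment(fc, sets)
  expect_equal(res$set, "big")
  expect_equal(attr(res, "skipped"), "tiny")
  expect_error(page_enrichment(stats::setNames(rep(1, 50), sprintf("g%03d", 1:50)),
                               sets), "zero")
  expect_error(page_enrichment(fc, list(tiny = names(fc)[1:5])), "min_size")
})

test_that("BH adjustment equals the hand-computed step-up", {
  p <- c(0.01, 0.04, 0.03, 0.20, 0.50)
  # hand step-up: sort, multiply by n/rank, cumulative min from the right
  o <- order(p)
  stepup <- p[o] * length(p) / seq_along(p)
  stepup <- rev(cummin(rev(stepup)))
  expected <- numeric(5); expected[o] <- pmin(stepup, 1)
  expect_equal(bh_fdr(p), expected)
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 4)), rep(0.07, 4))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("constitutive screen demands all six significant same-sign calls", {
  mk_fc <- function(fc, p) {
    out <- data.frame(gene = paste0("g", seq_along(fc)), log2_fc = fc,
                      p_value = p)
    class(out) <- c("fc_table", "data.frame"); out
  }
  # g1 constitutive up; g2 significant in only 5/6; g3 flips sign
  tabs <- lapply(1:6, function(i) {
    mk_fc(c(1, 1, if (i == 4) -1 else 1),
          c(0.001, if (i == 6) 0.2 else 0.001, 0.001))
  })
  out <- constitutive_screen(tabs)
  expect_equal(out$gene, "g1")
  expect_equal(out$direction, "up")
})

test_that("a planted constitutive gene survives the full screen", {
  sets <- split(sprintf("GENE%05d", 1:100),
                rep(sprintf("S%02d", 1:5), each = 20))
  cfg <- expression_sim_config(
    n_genes = 300, residual_sd = 0.15,
    planted_constitutive = data.frame(gene = c("GENE00250", "GENE00251"),
                                      shift = c(1.2, -1.1)),
    seed = 10)
  sim <- generate_expression(cfg)
  m <- quantile_normalize(sim$matrix)
  fcs <- list()
  for (g in c("DKO1", "DKO2")) for (tp in c("0d", "1d", "7d")) {
    fcs[[paste(g, tp)]] <- log2fc(m, sim$metadata, g, tp)
  }
  out <- constitutive_screen(fcs)
  expect_true(all(c("GENE00250", "GENE00251") %in% out$gene))
  expect_equal(out$direction[out$gene == "GENE00250"], "up")
  expect_equal(out$direction[out$gene == "GENE00251"], "down")
  # screen stays specific: few false positives among 298 null genes
  expect_lt(nrow(out), 8)
})

test_that("GMT gene sets round-trip through write and read", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
  tmp <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, tmp, description = c("first", "second"))
  back <- read_gmt(tmp)
  expect_equal(back, sets)
})
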