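#' Quantile normalize an expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution: rank r
#' in each column is replaced by the mean over columns of the r-th order
#' statistics; ties within a column receive the mean of the quantile means
#' they span. Delegates to `limma::normalizeQuantiles(ties = TRUE)`.
#' Idempotent: a second application changes nothing.
#'
#' @param matrix Numeric matrix, probes/genes x samples.
#' @return Matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(matrix) {
  m <- as.matrix(matrix)
  if (any(!is.finite(m))) stop("expression values must be finite")
  if (ncol(m) < 2L) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Collapse redundant probes to gene level by averaging
#'
#' @param matrix Probe x sample matrix.
#' @param probe_map Data frame with columns `probe` and `gene`. Probes absent
#'   from the map are dropped with a warning.
#' @return Gene x sample matrix of per-gene probe means.
#' @export
collapse_probes <- function(matrix, probe_map) {
  if (is.null(probe_map) || nrow(probe_map) == 0L) stop("probe map is empty")
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  m <- as.matrix(matrix)
  idx <- match(rownames(m), probe_map$probe)
  unmapped <- rownames(m)[is.na(idx)]
  if (length(unmapped)) {
    warning(length(unmapped), " unmapped probe(s) dropped")
    m <- m[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  gene <- probe_map$gene[idx]
  sums <- rowsum(m, gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  sums / counts
}

#' Welch's unequal-variance t test
#'
#' Heteroscedastic two-sample t test (Welch-Satterthwaite degrees of
#' freedom), two-sided. The degenerate case of zero variance in both groups
#' with equal means returns t = 0, P = 1; zero variance with different means
#' returns P = 0.
#'
#' @param a,b Numeric vectors of replicate values, each of length >= 2.
#' @return List with `t`, `df` and `p_value`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p_value = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p_value = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Differential expression of a condition versus a reference
#'
#' Per gene: difference of group means on the log2 scale, its standard error
#' sqrt(s1^2/n1 + s2^2/n2), and the Welch two-sided P value.
#'
#' @param matrix Gene x sample matrix (log2 scale unless `linear_input`).
#' @param metadata Data frame with columns `sample`, `genotype`, `timepoint`
#'   matching the matrix columns.
#' @param genotype,timepoint Condition of interest.
#' @param ref_genotype,ref_timepoint Reference condition; defaults compare a
#'   mutant against the wild type at the same timepoint.
#' @param linear_input If TRUE, log2-transform the values first.
#' @return An `fc_table` data frame: `gene`, `log2_fc`, `se`, `p_value`.
#' @export
log2fc <- function(matrix, metadata, genotype, timepoint,
                   ref_genotype = "Col-0", ref_timepoint = timepoint,
                   linear_input = FALSE) {
  m <- as.matrix(matrix)
  if (linear_input) {
    if (any(m <= 0)) stop("linear-scale input must be positive for log2")
    m <- log2(m)
  }
  pick <- function(g, tp) {
    s <- metadata$sample[metadata$genotype == g & metadata$timepoint == tp]
    if (length(s) < 2L) {
      stop("group ", g, "/", tp, " has fewer than 2 replicates")
    }
    m[, s, drop = FALSE]
  }
  x <- pick(genotype, timepoint)
  y <- pick(ref_genotype, ref_timepoint)
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se <- sqrt(v1 / n1 + v2 / n2)
  tt <- (m1 - m2) / se
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se == 0
  p[zero & m1 == m2] <- 1
  p[zero & m1 != m2] <- 0
  tt[zero] <- 0
  out <- data.frame(gene = rownames(m), log2_fc = unname(m1 - m2),
                    se = unname(se), p_value = unname(p),
                    stringsAsFactors = FALSE)
  class(out) <- c("fc_table", "data.frame")
  out
}

#' Two-factor fixed-effects analysis of variance per gene
#'
#' Tests differential effects of genotype, time (cold exposure) and their
#' interaction. Type-II sums of squares via `car::Anova`; for the balanced
#' designs used here type I/II/III coincide. The degenerate all-equal input
#' returns F = 0, P = 1 for all three terms.
#'
#' @param values Numeric vector of one gene's expression values.
#' @param genotype,time Factors (or coercible), one level pattern per value;
#'   each must have >= 2 levels.
#' @return List with `p_genotype`, `p_time`, `p_interaction` and the
#'   corresponding F statistics.
#' @export
two_way_anova <- function(values, genotype, time) {
  genotype <- as.factor(genotype); time <- as.factor(time)
  if (nlevels(genotype) < 2L || nlevels(time) < 2L) {
    stop("each factor needs at least 2 levels")
  }
  if (stats::var(values) == 0) {
    return(list(f_genotype = 0, f_time = 0, f_interaction = 0,
                p_genotype = 1, p_time = 1, p_interaction = 1))
  }
  fit <- stats::lm(values ~ genotype * time)
  an <- car::Anova(fit, type = 2)
  f <- an[["F value"]]; p <- an[["Pr(>F)"]]
  rn <- rownames(an)
  gi <- match("genotype", rn); ti <- match("time", rn)
  ii <- match("genotype:time", rn)
  list(f_genotype = f[gi], f_time = f[ti], f_interaction = f[ii],
       p_genotype = p[gi], p_time = p[ti], p_interaction = p[ii])
}

#' Per-gene two-factor ANOVA over an expression matrix
#'
#' @param matrix Gene x sample matrix.
#' @param metadata Data frame with `sample`, `genotype`, `timepoint`.
#' @return Data frame with one row per gene: P values and F statistics for
#'   genotype, time and interaction.
#' @export
anova_by_gene <- function(matrix, metadata) {
  m <- as.matrix(matrix)[, metadata$sample, drop = FALSE]
  g <- as.factor(metadata$genotype); tp <- as.factor(metadata$timepoint)
  res <- t(apply(m, 1, function(v) {
    a <- two_way_anova(v, g, tp)
    c(a$p_genotype, a$p_time, a$p_interaction,
      a$f_genotype, a$f_time, a$f_interaction)
  }))
  data.frame(gene = rownames(m),
             p_genotype = res[, 1], p_time = res[, 2],
             p_interaction = res[, 3],
             f_genotype = res[, 4], f_time = res[, 5],
             f_interaction = res[, 6],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement (delegates to
#' `stats::p.adjust(method = "BH")` after validating the input range).
#'
#' @param p Numeric vector of raw P values in \[0, 1\].
#' @return Adjusted P values, elementwise >= the input, order-preserving.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("P values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Parametric analysis of gene set enrichment (PAGE)
#'
#' For each gene set with at least `min_size` members present in the fold
#' change vector, the z statistic compares the set's mean log2 fold change
#' `Sm` to the global distribution: `z = (Sm - mu) * sqrt(m) / delta`, with
#' `mu` and `delta` the mean and SD of all fold changes and `m` the set
#' size. P values come from the standard normal (two-sided by default; the
#' one-sided variant of the original method is available), and are
#' BH-FDR-adjusted across all tested sets; significance at adjusted
#' P < `alpha`.
#'
#' @param fc Named numeric vector of gene-level log2 fold changes.
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param min_size Minimum number of set genes present in `fc` (default 10).
#' @param sided `"two"` or `"one"`.
#' @param alpha FDR significance threshold (default 0.05).
#' @return An `enrichment_result` data frame: `set`, `m`, `set_mean`,
#'   `global_mean`, `global_sd`, `z`, `p_value`, `fdr`, `significant`.
#'   Sets with fewer than `min_size` mapped genes are skipped (recorded in
#'   attribute `"skipped"`).
#' @export
page_enrichment <- function(fc, sets, min_size = 10,
                            sided = c("two", "one"), alpha = 0.05) {
  sided <- match.arg(sided)
  if (is.null(names(fc))) stop("fc must be a named gene-level vector")
  fc <- fc[is.finite(fc)]
  if (length(fc) < min_size) stop("fewer genes than min_size")
  mu <- mean(fc)
  delta <- stats::sd(fc)
  if (delta == 0) stop("global SD of fold changes is zero")
  rows <- lapply(names(sets), function(nm) {
    genes <- intersect(sets[[nm]], names(fc))
    m <- length(genes)
    if (m < min_size) return(NULL)
    sm <- mean(fc[genes])
    z <- (sm - mu) * sqrt(m) / delta
    p <- if (sided == "two") 2 * stats::pnorm(-abs(z)) else stats::pnorm(-z)
    data.frame(set = nm, m = m, set_mean = sm, z = z, p_value = p,
               stringsAsFactors = FALSE)
  })
  skipped <- names(sets)[vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no set has >= min_size genes in fc")
  out$global_mean <- mu
  out$global_sd <- delta
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < alpha
  out <- out[, c("set", "m", "set_mean", "global_mean", "global_sd",
                 "z", "p_value", "fdr", "significant")]
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Screen for constitutive transcriptional changes
#'
#' A gene changes constitutively when, relative to the wild type, it shows
#' the same fold-change direction with P < `alpha` in every pairwise Welch
#' comparison: both mutant genotypes at every timepoint (six comparisons in
#' the default design). Genes missing any comparison are excluded.
#'
#' @param fc_tables Named list of `fc_table`s (one per mutant x timepoint,
#'   from [log2fc()] against the wild type at the same timepoint).
#' @param alpha Per-comparison significance threshold (default 0.05).
#' @return Data frame `gene`, `direction` (`"up"`/`"down"`), `mean_log2_fc`
#'   of the genes passing the screen, sorted by gene.
#' @export
constitutive_screen <- function(fc_tables, alpha = 0.05) {
  stopifnot(length(fc_tables) >= 2L)
  genes <- Reduce(intersect, lapply(fc_tables, function(x) x$gene))
  fcm <- sapply(fc_tables, function(x) x$log2_fc[match(genes, x$gene)])
  pm <- sapply(fc_tables, function(x) x$p_value[match(genes, x$gene)])
  sig <- rowSums(pm < alpha) == ncol(pm)
  up <- rowSums(fcm > 0) == ncol(fcm)
  down <- rowSums(fcm < 0) == ncol(fcm)
  keep <- sig & (up | down)
  data.frame(gene = genes[keep],
             direction = ifelse(up[keep], "up", "down"),
             mean_log2_fc = rowMeans(fcm)[keep],
             stringsAsFactors = FALSE, row.names = NULL)[order(genes[keep]), ]
}

#' Read / write gene sets in GMT format
#'
#' Standard tab-delimited GMT: set name, description, member genes. Reading
#' delegates to `fgsea::gmtPathways`.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of gene-id vectors.
#' @param description Optional vector of set descriptions (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
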