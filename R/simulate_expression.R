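#' Configuration for a synthetic expression experiment
#'
#' Emulates the transcriptome design of a cold-shift study: genotypes
#' (wild type plus two allelic double mutants) x timepoints (non-acclimated
#' and cold-acclimating) x biological replicates, on the log2 scale.
#' Planted effects are (i) gene-set shifts in specific conditions, for
#' enrichment testing, and (ii) constitutive genes shifted in both mutant
#' genotypes at all timepoints, for the constitutive screen.
#'
#' @param n_genes Number of genes (beyond those implied by sets).
#' @param genotypes Character vector; first element is the reference
#'   (wild type).
#' @param timepoints Character vector; first element is the non-acclimated
#'   reference state.
#' @param n_replicates Replicates per genotype x timepoint (>= 2).
#' @param set_definitions Named list of gene-id vectors (gene sets); planted
#'   sets must have >= 10 members.
#' @param planted_set_shifts Data frame with columns `set`, `genotype`,
#'   `timepoint`, `shift` (mean log2 shift added to all member genes in that
#'   condition; `genotype`/`timepoint` may be `"all"`).
#' @param planted_constitutive Data frame with columns `gene`, `shift`
#'   (log2 effect present in every non-reference genotype at every
#'   timepoint).
#' @param cold_response_sd SD of gene-wise cold-response effects shared by
#'   all genotypes at non-reference timepoints (default 0.5), so that cold
#'   acclimation itself moves expression as it does on arrays.
#' @param residual_sd Residual replicate noise SD, log2 units.
#' @param baseline_mean,baseline_sd Gene baseline distribution (log2 units).
#' @param n_probes_per_gene Integer; when > 1, each gene is measured by this
#'   many redundant probes (probe values share the gene signal).
#' @param seed Integer seed.
#' @return An `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_genes = 2000,
                                  genotypes = c("Col-0", "DKO1", "DKO2"),
                                  timepoints = c("0d", "1d", "7d"),
                                  n_replicates = 3,
                                  set_definitions = NULL,
                                  planted_set_shifts = NULL,
                                  planted_constitutive = NULL,
                                  cold_response_sd = 0.5,
                                  residual_sd = 0.25,
                                  baseline_mean = 8, baseline_sd = 2,
                                  n_probes_per_gene = 1,
                                  seed = 1L) {
  if (n_replicates < 2) stop("need >= 2 replicates per condition")
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  if (!is.null(set_definitions)) {
    unknown <- setdiff(unlist(set_definitions), genes)
    if (length(unknown)) {
      stop("gene set references unknown gene(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  if (!is.null(planted_set_shifts)) {
    sz <- lengths(set_definitions[planted_set_shifts$set])
    if (any(sz < 10)) stop("planted sets must have >= 10 members")
  }
  if (!is.null(planted_constitutive)) {
    unknown <- setdiff(planted_constitutive$gene, genes)
    if (length(unknown)) {
      stop("planted constitutive gene(s) not in gene universe: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(n_genes = n_genes, genes = genes, genotypes = genotypes,
                 timepoints = timepoints, n_replicates = n_replicates,
                 set_definitions = set_definitions,
                 planted_set_shifts = planted_set_shifts,
                 planted_constitutive = planted_constitutive,
                 cold_response_sd = cold_response_sd,
                 residual_sd = residual_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 n_probes_per_gene = as.integer(n_probes_per_gene),
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Generate a synthetic expression matrix with planted truth
#'
#' log2 expression = gene baseline + shared cold response (non-reference
#' timepoints) + planted set shifts + planted constitutive effects +
#' N(0, residual_sd). Redundant probes (when configured) share the gene
#' signal and differ only in noise, so probe averaging recovers the gene
#' value.
#'
#' @param config An [expression_sim_config()].
#' @return List with `matrix` (probe-or-gene x sample), `metadata` (data
#'   frame `sample`, `genotype`, `timepoint`, `replicate`), `probe_map`
#'   (data frame `probe`, `gene`; NULL when one probe per gene) and `truth`
#'   (list with `set_shifts` and `constitutive` ledgers).
#' @export
generate_expression <- function(config = expression_sim_config()) {
  stopifnot(inherits(config, "expression_sim_config"))
  genes <- config$genes
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        timepoint = config$timepoints,
                        genotype = config$genotypes,
                        stringsAsFactors = FALSE)[, c(3, 2, 1)]
  design$sample <- sprintf("%s_%s_r%d", design$genotype, design$timepoint,
                           design$replicate)
  ng <- length(genes); ns <- nrow(design)
  out <- withr::with_seed(config$seed, {
    baseline <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
    cold <- matrix(0, ng, length(config$timepoints),
                   dimnames = list(genes, config$timepoints))
    for (tp in setdiff(config$timepoints, config$timepoints[1])) {
      cold[, tp] <- stats::rnorm(ng, 0, config$cold_response_sd)
    }
    mu <- matrix(baseline, ng, ns, dimnames = list(genes, design$sample))
    for (j in seq_len(ns)) mu[, j] <- mu[, j] + cold[, design$timepoint[j]]
    pss <- config$planted_set_shifts
    if (!is.null(pss)) {
      for (k in seq_len(nrow(pss))) {
        members <- config$set_definitions[[pss$set[k]]]
        hit <- (pss$genotype[k] == "all" | design$genotype == pss$genotype[k]) &
               (pss$timepoint[k] == "all" | design$timepoint == pss$timepoint[k])
        mu[members, hit] <- mu[members, hit] + pss$shift[k]
      }
    }
    pconst <- config$planted_constitutive
    if (!is.null(pconst)) {
      mut <- design$genotype != config$genotypes[1]
      for (k in seq_len(nrow(pconst))) {
        mu[pconst$gene[k], mut] <- mu[pconst$gene[k], mut] + pconst$shift[k]
      }
    }
    npp <- config$n_probes_per_gene
    if (npp > 1L) {
      probe_map <- data.frame(
        probe = sprintf("%s_p%d", rep(genes, each = npp),
                        rep(seq_len(npp), ng)),
        gene = rep(genes, each = npp), stringsAsFactors = FALSE)
      mu <- mu[probe_map$gene, , drop = FALSE]
      rownames(mu) <- probe_map$probe
    } else {
      probe_map <- NULL
    }
    noise <- if (config$residual_sd > 0) {
      matrix(stats::rnorm(length(mu), 0, config$residual_sd),
             nrow(mu), ncol(mu))
    } else 0
    list(matrix = mu + noise, probe_map = probe_map)
  })
  truth <- list(set_shifts = config$planted_set_shifts,
                constitutive = config$planted_constitutive)
  list(matrix = out$matrix,
       metadata = design[, c("sample", "genotype", "timepoint", "replicate")],
       probe_map = out$probe_map, truth = truth)
}

#' Write an expression matrix and metadata to TSV
#'
#' @param sim Result of [generate_expression()].
#' @param matrix_path,metadata_path Output paths.
#' @export
write_expression <- function(sim, matrix_path, metadata_path) {
  df <- data.frame(gene = rownames(sim$matrix), sim$matrix, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(sim$metadata, metadata_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(matrix_path)
}
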