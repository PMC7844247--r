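# write a TSV with a provenance header comment
.write_tsv_prov <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coldribo %s | seed=%d | stage output",
                     as.character(utils::packageVersion("coldribo")), seed),
             con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key=value run configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are parsed
#' as numbers where possible. Keys use `stage.option` dotted names.
#'
#' @param path File path.
#' @return Named list of options.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  stats::setNames(out, keys)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates the stages in dependency order from one configuration and a
#' single global seed (per-stage seeds are derived from it): synthetic data
#' generation, gradient-profile quantification (blank subtraction,
#' segmentation, integration, log2-FC, inter-complex correlations),
#' riboproteome compositional analysis (shared-change report), and
#' transcriptome statistics (quantile normalization, probe collapsing,
#' per-condition fold changes, PAGE enrichment, constitutive screen). All
#' tabular outputs are TSV with a provenance header recording the seed; a
#' JSON run report summarizes every stage. Identical seed and configuration
#' give byte-identical outputs.
#'
#' @param config Named list (or path to a flat key=value file readable by
#'   [read_run_config()]). Recognized keys: `seed` (default 1),
#'   `stages` (comma-separated subset of `profiles,riboproteome,transcriptome`;
#'   default all), `riboproteome.mode` (`cold_only`/`both_temperatures`),
#'   `transcriptome.page_sided` (`two`/`one`).
#' @param out_dir Output directory (created if needed).
#' @return The run report (list), invisibly written to
#'   `<out_dir>/run_report.json`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file does not exist: ", config)
    config <- read_run_config(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% "profiles,riboproteome,transcriptome"
  stages <- trimws(strsplit(stages, ",")[[1]])
  mode <- config$riboproteome.mode %||% "cold_only"
  sided <- config$transcriptome.page_sided %||% "two"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package = "coldribo",
                 version = as.character(utils::packageVersion("coldribo")),
                 seed = seed, stages = stages)

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    report$stage_summaries[[name]] <<- res
  }

  if ("profiles" %in% stages) run_stage("profiles", function() {
    study <- simulate_profile_study(seed = seed + 11L)
    fc_all <- list()
    for (tp in unique(study$design$timepoint)) {
      wt <- study$traces[[paste0("Col-0_", tp)]]
      awt <- quantify_trace(wt$sample, wt$blank, study$anchors)
      for (g in setdiff(unique(study$design$genotype), "Col-0")) {
        tr <- study$traces[[paste(g, tp, sep = "_")]]
        am <- quantify_trace(tr$sample, tr$blank, study$anchors)
        fc <- relative_abundance(am, awt)
        fc$mutant <- g; fc$timepoint <- tp
        fc_all[[paste(g, tp)]] <- fc
      }
    }
    fc_tab <- do.call(rbind, fc_all)
    rownames(fc_tab) <- NULL
    .write_tsv_prov(fc_tab, file.path(out_dir, "complex_log2fc.tsv"), seed)
    r1 <- correlate_complexes(fc_tab, "40S", "60S")
    r2 <- correlate_complexes(fc_tab, "60S", "80S")
    cors <- data.frame(pair = c("40S~60S", "60S~80S"),
                       r = c(r1$r, r2$r), n = c(r1$n, r2$n))
    .write_tsv_prov(cors, file.path(out_dir, "complex_correlations.tsv"), seed)
    list(n_traces = length(study$traces), r_40s_60s = r1$r, r_60s_80s = r2$r)
  })

  if ("riboproteome" %in% stages) run_stage("riboproteome", function() {
    planted <- data.frame(
      protein_id = c("sRPL01", "sRPL02", "sRPL03", "sBIO01", "sRPS01"),
      experiment = "both",
      temperature = c("10C", "10C", "both", "both", "10C"),
      effect = c(2.5, 0.35, 3, 4, 2.2),
      stringsAsFactors = FALSE)
    sim <- generate_lfq_experiment(proteome_sim_config(
      planted_changes = planted, seed = seed + 23L))
    rep60 <- riboproteome_report(sim$tables, "60S", mode)
    rep40 <- riboproteome_report(sim$tables, "40S", mode)
    .write_tsv_prov(rep60$table, file.path(out_dir, "shared_changes_60S.tsv"),
                    seed)
    .write_tsv_prov(rep40$table, file.path(out_dir, "shared_changes_40S.tsv"),
                    seed)
    list(n_shared_60s = rep60$n_shared, n_increased_60s = rep60$n_increased,
         n_decreased_60s = rep60$n_decreased, n_shared_40s = rep40$n_shared)
  })

  if ("transcriptome" %in% stages) run_stage("transcriptome", function() {
    sets <- split(sprintf("GENE%05d", 1:200),
                  rep(sprintf("SET%02d", 1:10), each = 20))
    cfg <- expression_sim_config(
      set_definitions = sets,
      planted_set_shifts = data.frame(set = "SET01", genotype = "DKO1",
                                      timepoint = "7d", shift = 0.5),
      planted_constitutive = data.frame(gene = "GENE01999", shift = 1.5),
      seed = seed + 37L)
    sim <- generate_expression(cfg)
    m <- quantile_normalize(sim$matrix)
    fc_tabs <- list()
    for (g in c("DKO1", "DKO2")) for (tp in c("0d", "1d", "7d")) {
      fc_tabs[[paste(g, tp, sep = "_")]] <- log2fc(m, sim$metadata, g, tp)
    }
    enr <- page_enrichment(stats::setNames(fc_tabs[["DKO1_7d"]]$log2_fc,
                                           fc_tabs[["DKO1_7d"]]$gene),
                           sets, sided = sided)
    screen <- constitutive_screen(fc_tabs)
    .write_tsv_prov(as.data.frame(enr), file.path(out_dir, "enrichment.tsv"),
                    seed)
    .write_tsv_prov(screen, file.path(out_dir, "constitutive_genes.tsv"), seed)
    list(n_sets_tested = nrow(enr),
         n_significant = sum(enr$significant),
         top_set = enr$set[which.max(abs(enr$z))],
         n_constitutive = nrow(screen),
         constitutive_genes = screen$gene)
  })

  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
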