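FRACTION_LABELS <- c("30S/40S", "50S", "60S", "60S/80S", "polysome")

#' Assign fraction identities from RP-class sums and pre-60S markers
#'
#' Gradient fraction positions vary between centrifugation runs, so sampled
#' fractions are aligned by content rather than position: each fraction is
#' scored by the summed LFQ abundances of detected 40S, 60S and organellar
#' 30S/50S RPs and by the presence of the pre-60S maturation markers (eIF6A
#' and NMD3 homologs), and labels are assigned to maximize the class-profile
#' match subject to sedimentation order (labels non-decreasing with fraction
#' index; each non-polysome label used at most once; everything beyond the
#' 60S/80S region is polysome). Fractions holding the abundance maximum of a
#' pre-60S marker are eligible only for the 60S or 60S/80S labels.
#'
#' @param table A [fraction_table()].
#' @return A `fraction_identity` data frame: one row per fraction with the
#'   assigned `label` and the evidence sums (`sum_rp40s`, `sum_rp60s`,
#'   `sum_rp30s_org`, `sum_rp50s_org`, `sum_marker`, `marker_max`).
#' @export
assign_fractions <- function(table) {
  stopifnot(inherits(table, "fraction_table"))
  m <- table$lfq
  cls <- .row_classes(table)
  csum <- function(klass) {
    rows <- cls %in% klass
    if (!any(rows)) return(rep(0, ncol(m)))
    colSums(m[rows, , drop = FALSE])
  }
  s40 <- csum("RP40S"); s60 <- csum("RP60S")
  s30o <- csum("RP30S_org"); s50o <- csum("RP50S_org")
  markers <- marker_proteins(table$catalog, "pre60S_marker")$protein_id
  mrows <- rownames(m) %in% markers
  smark <- if (any(mrows)) colSums(m[mrows, , drop = FALSE]) else rep(0, ncol(m))
  seif3 <- csum("eIF3")
  if (sum(s40) + sum(s60) + sum(s30o) + sum(s50o) == 0) {
    stop("no ribosomal proteins detected: cannot assign fraction identities")
  }
  share <- function(v) if (sum(v) > 0) v / sum(v) else rep(0, length(v))
  p40 <- share(s40); p60 <- share(s60); p30 <- share(s30o); p50 <- share(s50o)
  pmk <- share(smark); pe3 <- share(seif3)
  nf <- ncol(m)
  score <- cbind(
    `30S/40S` = p40 + 0.5 * p30 + 0.5 * pe3,
    `50S` = p50,
    `60S` = p60 + pmk,
    `60S/80S` = p60 + 0.5 * pmk + 0.3 * p40,
    polysome = 0.4 * p60 + 0.6 * p40)
  # fractions holding a marker-protein abundance maximum: 60S/60S-80S only
  marker_max <- rep(FALSE, nf)
  for (p in which(mrows)) {
    v <- m[p, ]
    if (any(v > 0)) marker_max[which.max(v)] <- TRUE
  }
  score[marker_max, setdiff(FRACTION_LABELS, c("60S", "60S/80S"))] <- -1e9
  # monotone dynamic program over fractions x labels
  nl <- length(FRACTION_LABELS)
  best <- matrix(-Inf, nf, nl)
  back <- matrix(NA_integer_, nf, nl)
  best[1, ] <- score[1, ]
  if (nf > 1L) {
    for (f in 2:nf) {
      for (l in seq_len(nl)) {
        # non-polysome labels at most once: predecessor strictly below l,
        # polysome may repeat
        pred <- if (l == nl) seq_len(nl) else seq_len(l - 1L)
        if (l < nl) pred <- pred  # strictly increasing for unique labels
        if (length(pred) == 0L) next
        prev <- best[f - 1L, pred]
        k <- which.max(prev)
        best[f, l] <- prev[k] + score[f, l]
        back[f, l] <- pred[k]
      }
    }
  }
  lab <- integer(nf)
  lab[nf] <- which.max(best[nf, ])
  if (nf > 1L) for (f in nf:2) lab[f - 1L] <- back[f, lab[f]]
  out <- data.frame(fraction = colnames(m),
                    label = FRACTION_LABELS[lab],
                    sum_rp40s = s40, sum_rp60s = s60,
                    sum_rp30s_org = s30o, sum_rp50s_org = s50o,
                    sum_marker = smark, marker_max = marker_max,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("fraction_identity", "data.frame")
  out
}

#' Total RP abundance per class, summed across all fractions
#'
#' @param table A [fraction_table()].
#' @return Data frame with columns `rp_class` and `total` (exact matrix
#'   sums), one row per class present in the catalog.
#' @export
total_rp_summary <- function(table) {
  stopifnot(inherits(table, "fraction_table"))
  cls <- .row_classes(table)
  tot <- rowsum(rowSums(table$lfq), cls)
  out <- data.frame(rp_class = rownames(tot), total = tot[, 1],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(match(out$rp_class, RP_CLASSES)), , drop = FALSE]
}

#' Normalize fraction-wise abundances to a reference RP sum
#'
#' Compositional normalization: within each relevant fraction every protein's
#' LFQ abundance is divided by the summed abundance of the reference RP class
#' detected in that fraction, so values become shares of the reference
#' complex. For the 60S compartment the fractions labeled `60S` and `60S/80S`
#' are used, 40S RPs are excluded from consideration and the reference is the
#' sum of all detected 60S RPs; for the 40S compartment the `30S/40S`
#' fraction is used, 60S RPs are excluded and the reference is the sum of all
#' detected 40S RPs. Fractions whose reference sum is zero are excluded with
#' a warning.
#'
#' @param table A [fraction_table()].
#' @param compartment `"60S"` or `"40S"`.
#' @param identity Optional precomputed [assign_fractions()] result.
#' @return A `share_table`: list with `shares` (protein x fraction matrix of
#'   shares), `compartment`, `reference_class`, `fractions` (labels used),
#'   `invalid_fractions`, and the sample metadata of `table`.
#' @export
normalize_shares <- function(table, compartment = c("60S", "40S"),
                             identity = NULL) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(table, "fraction_table"))
  if (is.null(identity)) identity <- assign_fractions(table)
  cls <- .row_classes(table)
  if (compartment == "60S") {
    use_labels <- c("60S", "60S/80S"); ref_class <- "RP60S"; drop_class <- "RP40S"
  } else {
    use_labels <- "30S/40S"; ref_class <- "RP40S"; drop_class <- "RP60S"
  }
  cols <- which(identity$label %in% use_labels)
  if (length(cols) == 0L) {
    stop("no fraction labeled ", paste(use_labels, collapse = "/"),
         " in this table")
  }
  m <- table$lfq[cls != drop_class, cols, drop = FALSE]
  refsum <- colSums(table$lfq[cls == ref_class, cols, drop = FALSE])
  invalid <- refsum <= 0
  if (any(invalid)) {
    warning("excluding fraction(s) with zero ", ref_class, " reference sum: ",
            paste(colnames(m)[invalid], collapse = ", "))
  }
  shares <- sweep(m[, !invalid, drop = FALSE], 2, refsum[!invalid], "/")
  structure(list(shares = shares, compartment = compartment,
                 reference_class = ref_class,
                 fractions = identity$label[cols][!invalid],
                 invalid_fractions = colnames(m)[invalid],
                 genotype = table$genotype, temperature = table$temperature,
                 experiment = table$experiment),
            class = "share_table")
}

#' Combine normalized shares across the 60S and 60S/80S fractions
#'
#' One combined share per protein: the mean of its normalized shares over the
#' 60S and the 60S/80S fraction, where absence from one fraction contributes
#' 0 with the divisor kept at 2. For the 40S compartment the single 30S/40S
#' fraction passes through.
#'
#' @param shares A `share_table` from [normalize_shares()].
#' @return Named numeric vector of combined shares per protein.
#' @export
combine_60s_fractions <- function(shares) {
  stopifnot(inherits(shares, "share_table"))
  m <- shares$shares
  if (shares$compartment == "60S") {
    rowSums(m) / 2
  } else {
    m[, 1]
  }
}

#' Abundance-maximum filter against co-purification artifacts
#'
#' Compositional normalization can create false positives from co-purified
#' proteins, so a change is only considered when the non-normalized LFQ
#' abundance peaks where the complex sediments. For the 60S compartment a
#' protein passes iff its raw-abundance maximum lies in the 60S or 60S/80S
#' fraction (strictly greater than every other fraction; ties resolve
#' against inclusion). For the 40S compartment a protein passes iff it is
#' strictly more abundant in the 30S/40S fraction than in the 60S fraction.
#' Proteins absent everywhere fail.
#'
#' @param table A [fraction_table()].
#' @param compartment `"60S"` or `"40S"`.
#' @param identity Optional precomputed [assign_fractions()] result.
#' @return Named logical vector over the table's proteins.
#' @export
abundance_max_filter <- function(table, compartment = c("60S", "40S"),
                                 identity = NULL) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(table, "fraction_table"))
  if (is.null(identity)) identity <- assign_fractions(table)
  m <- table$lfq
  if (compartment == "60S") {
    inside <- identity$label %in% c("60S", "60S/80S")
    if (!any(inside)) stop("no 60S/60S-80S fraction in this table")
    m_in <- apply(m[, inside, drop = FALSE], 1, max)
    m_out <- if (any(!inside)) apply(m[, !inside, drop = FALSE], 1, max) else 0
    out <- m_in > m_out & m_in > 0
  } else {
    c40 <- which(identity$label == "30S/40S")[1]
    c60 <- which(identity$label == "60S")[1]
    if (is.na(c40)) stop("no 30S/40S fraction in this table")
    v60 <- if (is.na(c60)) 0 else m[, c60]
    out <- m[, c40] > v60 & m[, c40] > 0
  }
  stats::setNames(as.logical(out), rownames(m))
}

#' Call compositional changes between mutant and wild type
#'
#' Presence of a protein in the mutant and absence from the corresponding
#' wild type is classified as accumulation (`"+"`); absence from the mutant
#' and presence in the wild type as decrease (`"-"`). When a protein is
#' detected in both, the log2 fold change of its combined share is reported
#' and classified at the |log2-FC| = 1 threshold: `strong_up` (> 1),
#' `weak_up` (\[0, 1\]; the 0 boundary is assigned up by convention),
#' `weak_down` (\[-1, 0)), `strong_down` (< -1).
#'
#' @param mutant,wildtype Named numeric vectors of combined shares
#'   (e.g. from [combine_60s_fractions()]), same compartment and context.
#' @param context Optional list/data.frame of context columns (experiment,
#'   temperature, compartment) replicated onto every call.
#' @return A `change_calls` data frame with columns `protein_id`, `status`
#'   (`"+"`, `"-"` or `"numeric"`), `log2_fc`, `class` and any context
#'   columns. Proteins absent from both samples are dropped.
#' @export
call_changes <- function(mutant, wildtype, context = NULL) {
  ids <- union(names(mutant), names(wildtype))
  mv <- ifelse(ids %in% names(mutant), mutant[ids], 0)
  wv <- ifelse(ids %in% names(wildtype), wildtype[ids], 0)
  mv[is.na(mv)] <- 0; wv[is.na(wv)] <- 0
  keep <- mv > 0 | wv > 0
  ids <- ids[keep]; mv <- mv[keep]; wv <- wv[keep]
  status <- ifelse(mv > 0 & wv == 0, "+",
                   ifelse(mv == 0 & wv > 0, "-", "numeric"))
  fc <- ifelse(status == "numeric", log2(mv / wv), NA_real_)
  cl <- rep(NA_character_, length(ids))
  num <- status == "numeric"
  cl[num & fc > 1] <- "strong_up"
  cl[num & fc <= 1 & fc >= 0] <- "weak_up"
  cl[num & fc < 0 & fc >= -1] <- "weak_down"
  cl[num & fc < -1] <- "strong_down"
  out <- data.frame(protein_id = ids, status = status, log2_fc = unname(fc),
                    class = cl, stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(context)) for (nm in names(context)) out[[nm]] <- context[[nm]]
  class(out) <- c("change_calls", "data.frame")
  out
}

#' Direction of a change call
#'
#' Maps categorical and numeric calls to a common direction so they can be
#' compared across experiments: `"+"`, `strong_up` and `weak_up` count as
#' increase; `"-"`, `strong_down` and `weak_down` as decrease. A numeric call
#' with log2-FC exactly 0 is no change at all and gets direction `"none"`
#' (such calls never enter shared-change selection).
#'
#' @param calls A `change_calls` data frame.
#' @return Character vector `"increase"`/`"decrease"`/`"none"`, one per call.
#' @export
call_direction <- function(calls) {
  ifelse(calls$status == "+" |
           (calls$status == "numeric" & calls$log2_fc > 0), "increase",
         ifelse(calls$status == "-" |
                  (calls$status == "numeric" & calls$log2_fc < 0),
                "decrease", "none"))
}

#' Select changes shared between the two paired experiments
#'
#' A change is shared when the calls of the two experiments (e.g. wild type
#' vs each allelic double mutant) agree in direction at 10 degC. In the more
#' stringent `both_temperatures` mode the protein must additionally be called
#' in the same direction at 20 degC in both experiments, and that direction
#' must match the cold direction.
#'
#' @param calls_ds1,calls_ds2 `change_calls` with a `temperature` column
#'   (`"10C"`, `"20C"`), one per experiment, same compartment.
#' @param mode `"cold_only"` or `"both_temperatures"`.
#' @return List with `increased`, `decreased` (protein id vectors sorted
#'   alphabetically), `n_increased`, `n_decreased`, `n_shared` and `table`
#'   (per-protein directions per experiment and temperature).
#' @export
select_shared <- function(calls_ds1, calls_ds2,
                          mode = c("cold_only", "both_temperatures")) {
  mode <- match.arg(mode)
  dir_at <- function(calls, temp) {
    sub <- calls[calls$temperature == temp, , drop = FALSE]
    d <- call_direction(sub)
    stats::setNames(d, sub$protein_id)[d != "none"]
  }
  d1c <- dir_at(calls_ds1, "10C"); d2c <- dir_at(calls_ds2, "10C")
  ids <- intersect(names(d1c), names(d2c))
  agree <- ids[d1c[ids] == d2c[ids]]
  direction <- d1c[agree]
  if (mode == "both_temperatures") {
    d1w <- dir_at(calls_ds1, "20C"); d2w <- dir_at(calls_ds2, "20C")
    ok <- agree %in% names(d1w) & agree %in% names(d2w)
    agree2 <- agree[ok]
    keep <- d1w[agree2] == d2w[agree2] & d1w[agree2] == direction[agree2]
    agree <- agree2[keep]
    direction <- direction[agree]
  }
  tab <- data.frame(protein_id = agree, direction = unname(direction),
                    stringsAsFactors = FALSE, row.names = NULL)
  inc <- sort(agree[direction == "increase"])
  dec <- sort(agree[direction == "decrease"])
  list(increased = inc, decreased = dec,
       n_increased = length(inc), n_decreased = length(dec),
       n_shared = length(agree), table = tab[order(tab$protein_id), ])
}

#' Compositional change calls for one paired experiment
#'
#' Runs the full per-experiment compositional pipeline for one compartment:
#' fraction identity assignment, reference normalization, combination across
#' the 60S/60S-80S fractions, the abundance-maximum filter (applied to the
#' mutant and the wild type: a protein is kept when it passes in at least one
#' of the two, so genuine appearance/disappearance calls survive), exclusion
#' rules, and mutant vs wild-type change calling at both temperatures.
#'
#' For the 40S compartment, organellar RPs and a configurable contaminant
#' list are excluded from the report (they co-purify without being part of
#' the complex), while eIF3 subunits are retained as genuine 43S
#' preinitiation components.
#'
#' @param tables Named list of [fraction_table()]s as produced by
#'   [generate_lfq_experiment()] (names `<exp>_<genotype>_<temp>`).
#' @param experiment `"DS1"` or `"DS2"`.
#' @param compartment `"60S"` or `"40S"`.
#' @param contaminants Character vector of protein ids to drop from the 40S
#'   report in addition to organellar RPs.
#' @return A `change_calls` data frame covering both temperatures.
#' @export
compositional_calls <- function(tables, experiment,
                                compartment = c("60S", "40S"),
                                contaminants = character()) {
  compartment <- match.arg(compartment)
  calls <- list()
  for (temp in c("10C", "20C")) {
    tw <- tables[[paste(experiment, "Col-0", temp, sep = "_")]]
    tm <- tables[[paste(experiment, "mutant", temp, sep = "_")]]
    if (is.null(tw) || is.null(tm)) next
    one <- function(tb) {
      id <- assign_fractions(tb)
      sh <- normalize_shares(tb, compartment, identity = id)
      keep <- abundance_max_filter(tb, compartment, identity = id)
      comb <- combine_60s_fractions(sh)
      comb[!keep[names(comb)]] <- 0
      comb
    }
    cw <- one(tw); cm <- one(tm)
    cc <- call_changes(cm, cw,
                       context = list(experiment = experiment,
                                      temperature = temp,
                                      compartment = compartment))
    if (compartment == "40S") {
      cls <- classify_quiet(tw$catalog, cc$protein_id)
      drop <- cls %in% c("RP30S_org", "RP50S_org") |
        cc$protein_id %in% contaminants
      cc <- cc[!drop, , drop = FALSE]
    }
    calls[[temp]] <- cc
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  class(out) <- c("change_calls", "data.frame")
  out
}

# classify without the unknown-id warning (internal)
classify_quiet <- function(catalog, protein_id) {
  idx <- match(protein_id, catalog$protein_id)
  out <- catalog$rp_class[idx]
  out[is.na(idx)] <- "other"
  out
}

#' Shared-change report across both experiments
#'
#' Convenience wrapper: [compositional_calls()] for DS1 and DS2, then
#' [select_shared()].
#'
#' @inheritParams compositional_calls
#' @param mode Passed to [select_shared()].
#' @return The [select_shared()] report, with the per-experiment calls
#'   attached as attribute `"calls"`.
#' @export
riboproteome_report <- function(tables, compartment = c("60S", "40S"),
                                mode = c("cold_only", "both_temperatures"),
                                contaminants = character()) {
  compartment <- match.arg(compartment)
  mode <- match.arg(mode)
  c1 <- compositional_calls(tables, "DS1", compartment, contaminants)
  c2 <- compositional_calls(tables, "DS2", compartment, contaminants)
  rep <- select_shared(c1, c2, mode)
  attr(rep, "calls") <- list(DS1 = c1, DS2 = c2)
  rep
}

#' Match protein change calls with transcript-level fold changes
#'
#' Joins compositional protein calls and gene-level differential expression
#' on the gene model, keeping unmatched entries from both sides with a null
#' partner, and flags concordance (same direction and transcript P < 0.05).
#'
#' @param calls A `change_calls` data frame.
#' @param transcript_fc Data frame with columns `gene_model`, `log2_fc` and
#'   `p_value`.
#' @param catalog A `ribo_annotation` mapping protein ids to gene models.
#' @param alpha Transcript significance threshold (default 0.05).
#' @return Data frame with one row per matched or unmatched entry:
#'   `gene_model`, `protein_id`, `protein_direction`, `transcript_log2_fc`,
#'   `transcript_p`, `transcript_direction`, `matched`, `concordant`.
#' @export
transcript_protein_association <- function(calls, transcript_fc, catalog,
                                           alpha = 0.05) {
  stopifnot(all(c("gene_model", "log2_fc", "p_value") %in% names(transcript_fc)))
  prot <- data.frame(
    protein_id = calls$protein_id,
    gene_model = catalog$gene_model[match(calls$protein_id,
                                          catalog$protein_id)],
    protein_direction = call_direction(calls),
    stringsAsFactors = FALSE)
  tx <- data.frame(gene_model = transcript_fc$gene_model,
                   transcript_log2_fc = transcript_fc$log2_fc,
                   transcript_p = transcript_fc$p_value,
                   stringsAsFactors = FALSE)
  out <- merge(prot, tx, by = "gene_model", all = TRUE)
  out$transcript_direction <- ifelse(is.na(out$transcript_log2_fc), NA,
                                     ifelse(out$transcript_log2_fc >= 0,
                                            "increase", "decrease"))
  out$matched <- !is.na(out$protein_id) & !is.na(out$transcript_log2_fc)
  out$concordant <- out$matched &
    out$protein_direction == out$transcript_direction &
    out$transcript_p < alpha
  out[order(out$gene_model), , drop = FALSE]
}
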