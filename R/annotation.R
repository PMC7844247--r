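RP_CLASSES <- c("RP40S", "RP60S", "RP30S_org", "RP50S_org",
                "biogenesis", "eIF3", "other")
MARKER_ROLES <- c("pre60S_marker", "preinit_marker", "none")

ANNOT_COLS <- c("protein_id", "gene_model", "rp_class", "family", "paralog",
                "marker_role", "paralog_specific")

#' Load a protein annotation catalog
#'
#' The catalog classifies every protein identifier into a ribosomal-protein
#' (RP) class, family and paralog, and flags marker roles. Classes are
#' cytosolic `RP40S`/`RP60S`, organellar `RP30S_org`/`RP50S_org` (plastid and
#' mitochondrial prokaryote-type RPs that co-purify), `biogenesis`
#' (ribosome biogenesis factors such as the eIF6A/TIF6 and NMD3 homologs that
#' mark immature pre-60S particles), `eIF3` (43S preinitiation subunits) and
#' `other`. Peptide groups that cannot distinguish paralogs are single
#' entries flagged `paralog_specific = FALSE` and are reported at family
#' level downstream.
#'
#' @param path Path to a tab-separated file with columns `protein_id`,
#'   `gene_model`, `rp_class`, `family`, `paralog`, `marker_role`,
#'   `paralog_specific`.
#' @return A `ribo_annotation` data frame indexed by `protein_id` (rownames);
#'   use [classify_protein()] for lookups.
#' @export
#' @examples
#' cat <- load_annotation(system.file("extdata", "annotation_catalog.tsv",
#'                                    package = "coldribo"))
load_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0L) stop("annotation file is empty: ", path)
  missing <- setdiff(ANNOT_COLS, names(df))
  if (length(missing)) {
    stop("annotation is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  as_annotation(df)
}

#' Construct an annotation catalog from a data frame
#'
#' @param df Data frame with the columns listed in [load_annotation()].
#' @return A validated `ribo_annotation`.
#' @export
as_annotation <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)[, ANNOT_COLS]
  if (anyDuplicated(df$protein_id)) {
    stop("duplicate protein_id in annotation: ",
         paste(unique(df$protein_id[duplicated(df$protein_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$rp_class), RP_CLASSES)
  if (length(bad)) stop("unknown rp_class value(s): ", paste(bad, collapse = ", "))
  df$marker_role[is.na(df$marker_role) | df$marker_role == ""] <- "none"
  badm <- setdiff(unique(df$marker_role), MARKER_ROLES)
  if (length(badm)) stop("unknown marker_role value(s): ", paste(badm, collapse = ", "))
  df$paralog_specific <- as.logical(df$paralog_specific)
  rownames(df) <- df$protein_id
  class(df) <- c("ribo_annotation", "data.frame")
  df
}

#' Write an annotation catalog to TSV
#'
#' @param catalog A `ribo_annotation`.
#' @param path Output path.
#' @export
write_annotation <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classify a protein identifier into its RP class
#'
#' Pure catalog lookup; identifiers not in the catalog return `"other"` with
#' a warning.
#'
#' @param catalog A `ribo_annotation`.
#' @param protein_id Character vector of identifiers.
#' @return Character vector of RP classes, one per identifier.
#' @export
classify_protein <- function(catalog, protein_id) {
  stopifnot(inherits(catalog, "ribo_annotation"))
  idx <- match(protein_id, catalog$protein_id)
  unknown <- protein_id[is.na(idx)]
  if (length(unknown)) {
    warning("unknown protein id(s) classified as 'other': ",
            paste(unique(unknown), collapse = ", "))
  }
  out <- catalog$rp_class[idx]
  out[is.na(idx)] <- "other"
  out
}

#' Query marker proteins from a catalog
#'
#' @param catalog A `ribo_annotation`.
#' @param role Marker role, e.g. `"pre60S_marker"` for the eIF6A and NMD3
#'   homologs bound to immature 60S particles.
#' @return Subset of the catalog with that marker role.
#' @export
marker_proteins <- function(catalog, role = "pre60S_marker") {
  role <- match.arg(role, MARKER_ROLES)
  catalog[catalog$marker_role == role, , drop = FALSE]
}

#' Lookup catalog rows by gene model
#'
#' @param catalog A `ribo_annotation`.
#' @param gene_model AGI-style locus identifiers.
#' @return Catalog subset (possibly zero rows).
#' @export
lookup_gene_model <- function(catalog, gene_model) {
  catalog[catalog$gene_model %in% gene_model, , drop = FALSE]
}
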