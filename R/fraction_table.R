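#' Protein x fraction LFQ abundance table
#'
#' Container for label-free quantification (LFQ) abundances of proteins across
#' the sampled sucrose-gradient fractions of one ribosome preparation. Values
#' are >= 0; 0 means not detected (presence downstream is defined as LFQ > 0).
#'
#' @param lfq Numeric matrix, proteins in rows (rownames = protein ids),
#'   fractions in columns ordered by sedimentation (top of gradient first).
#' @param catalog A `ribo_annotation` resolving the protein ids; ids absent
#'   from the catalog are treated as class `"other"`.
#' @param genotype,temperature,experiment Sample metadata; `experiment` is the
#'   paired-experiment tag (e.g. `"DS1"`, `"DS2"`).
#' @return A `fraction_table` object.
#' @export
fraction_table <- function(lfq, catalog, genotype = "", temperature = "",
                           experiment = "") {
  lfq <- as.matrix(lfq)
  if (is.null(rownames(lfq))) stop("lfq matrix needs protein ids as rownames")
  if (any(!is.finite(lfq)) || any(lfq < 0)) {
    stop("LFQ values must be finite and >= 0")
  }
  stopifnot(inherits(catalog, "ribo_annotation"))
  structure(list(lfq = lfq, catalog = catalog, genotype = genotype,
                 temperature = temperature, experiment = experiment),
            class = "fraction_table")
}

#' @export
print.fraction_table <- function(x, ...) {
  cat(sprintf("<fraction_table> %s %s %s: %d proteins x %d fractions\n",
              x$experiment, x$genotype, x$temperature,
              nrow(x$lfq), ncol(x$lfq)))
  invisible(x)
}

# rp_class of every row, resolving unknown ids to "other" without warning spam
.row_classes <- function(table) {
  idx <- match(rownames(table$lfq), table$catalog$protein_id)
  cls <- table$catalog$rp_class[idx]
  cls[is.na(cls)] <- "other"
  cls
}

#' Write / read an LFQ fraction table as wide TSV
#'
#' @param table A `fraction_table`.
#' @param path File path.
#' @export
write_fraction_table <- function(table, path) {
  df <- data.frame(protein_id = rownames(table$lfq), table$lfq,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fraction_table
#' @inheritParams fraction_table
#' @export
read_fraction_table <- function(path, catalog, genotype = "",
                                temperature = "", experiment = "") {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  fraction_table(m, catalog, genotype, temperature, experiment)
}
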