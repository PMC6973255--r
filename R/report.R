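#' Write the per-sample classification report
#'
#' One row per sample: id, log10-odds score, MSI call, mean molecular
#' barcodes per marker, QC status, and BRAF c.1799 results when the panel
#' carries the BRAF locus (`NA` otherwise). Samples failing QC keep their
#' call -- the QC column flags them. Alongside the TSV, a machine-readable
#' JSON twin with the same content is written next to it.
#'
#' @param predictions A data.frame from [predict.msi_classifier()].
#' @param path Output TSV path (the JSON twin replaces the extension with
#'   `.json`).
#' @param braf Optional named list of [braf_vaf()] results, keyed by sample
#'   id.
#' @return The report data.frame, invisibly.
#' @export
write_report <- function(predictions, path, braf = NULL) {
  if (!nrow(predictions)) stop("no results to report")
  get_braf <- function(id, field) {
    b <- braf[[id]]
    if (is.null(b)) NA else b[[field]]
  }
  rep_df <- data.frame(
    sample_id = predictions$sample_id,
    score = predictions$score,
    call = predictions$call,
    markers_used = predictions$markers_used,
    mean_umi_per_marker = predictions$mean_umi,
    qc = ifelse(is.na(predictions$qc_pass), "NA",
                ifelse(predictions$qc_pass, "PASS", "FAIL")),
    braf_vaf_raw = vapply(predictions$sample_id, get_braf, numeric(1),
                          field = "vaf_raw"),
    braf_vaf_consensus = vapply(predictions$sample_id, get_braf, numeric(1),
                                field = "vaf_consensus"),
    braf_call = vapply(predictions$sample_id, function(id) {
      v <- get_braf(id, "call")
      if (is.na(v[1L])) NA_character_ else as.character(v)
    }, character(1)),
    stringsAsFactors = FALSE)
  rownames(rep_df) <- NULL
  utils::write.table(rep_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(rep_df,
                       paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = FALSE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(rep_df)
}
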