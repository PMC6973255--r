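#' Molecular-barcode quality-control metrics
#'
#' Distinct molecular barcodes estimate the number of template molecules
#' sequenced per marker. A sample passes QC when its mean barcode count per
#' panel marker reaches `threshold` (default 75, the conservative empirical
#' operating point); in-silico resampling supports advisory minima of 10
#' barcodes per marker for a 24-marker panel and 15 for a 6-marker subset.
#' QC failure never suppresses a classification -- low-template samples are
#' flagged, not dropped.
#'
#' @param summaries Long-format summaries from [summarize_cohort()] /
#'   [summarize_sample()] (uses `umi_count` per marker; zero-coverage
#'   markers count as 0).
#' @param threshold Mean barcodes per marker required to pass (default 75).
#' @param advisory_min Advisory per-marker minima, named by panel flavour.
#' @return A data.frame with one row per sample: `sample_id`,
#'   `mean_umi_per_marker`, `qc_pass`; `threshold` and `advisory_min` are
#'   attached as attributes.
#' @export
qc_metrics <- function(summaries, threshold = 75,
                       advisory_min = c(panel24 = 10, panel6 = 15)) {
  sp <- split(summaries, summaries$sample_id)
  out <- do.call(rbind, lapply(sp, function(g)
    data.frame(sample_id = g$sample_id[1L],
               mean_umi_per_marker = mean(g$umi_count),
               stringsAsFactors = FALSE)))
  out <- out[match(unique(summaries$sample_id), out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out$qc_pass <- out$mean_umi_per_marker >= threshold
  attr(out, "threshold") <- threshold
  attr(out, "advisory_min") <- advisory_min
  out
}

#' BRAF c.1799 variant-allele frequency
#'
#' Computes the alternate-allele frequency at the BRAF c.1799 position from
#' the reads assigned to the panel's BRAF locus, in two modes: `raw` counts
#' reads directly; `consensus` first groups reads by exact molecular
#' barcode, keeps groups with at least `min_reads` allele-called reads, and
#' calls the majority base per barcode (ties dropped), thereby suppressing
#' independent sequencing errors. Both VAFs are always reported; `mode`
#' selects which one drives the positive/negative call (strictly above
#' `vaf_threshold`, default 5%, the conventional clinical cut).
#'
#' @param profiles An `"mnr_profiles"` object, or a data.frame of BRAF read
#'   records with columns `umi` and `allele` (ref/alt/other/uncalled).
#' @param mode `"raw"` (default) or `"consensus"`: which VAF drives the call.
#' @param vaf_threshold Call threshold on the chosen VAF (default 0.05).
#' @param min_reads Minimum allele-called reads per barcode for a consensus
#'   group (default 2).
#' @return An object of class `"braf_result"`: raw and consensus ref/alt
#'   counts, `vaf_raw`, `vaf_consensus`, and `call` in
#'   `{"positive", "negative", "no-coverage"}`.
#' @examples
#' braf_vaf(data.frame(umi = c("A","A","A","B","B","B","C","C","C"),
#'                     allele = c("ref","ref","ref","ref","ref","alt",
#'                                "alt","alt","alt")))
#' @export
braf_vaf <- function(profiles, mode = c("raw", "consensus"),
                     vaf_threshold = 0.05, min_reads = 2L) {
  mode <- match.arg(mode)
  rec <- if (inherits(profiles, "mnr_profiles")) profiles$braf_records
         else profiles
  rec <- rec[rec$allele %in% c("ref", "alt"), , drop = FALSE]
  raw_ref <- sum(rec$allele == "ref"); raw_alt <- sum(rec$allele == "alt")
  vaf_raw <- if (raw_ref + raw_alt > 0) raw_alt / (raw_ref + raw_alt) else NA_real_
  cons <- vapply(split(rec$allele, rec$umi), function(a) {
    if (length(a) < min_reads) return(NA_character_)
    n_alt <- sum(a == "alt"); n_ref <- length(a) - n_alt
    if (n_alt == n_ref) NA_character_ else if (n_alt > n_ref) "alt" else "ref"
  }, character(1))
  cons_ref <- sum(cons == "ref", na.rm = TRUE)
  cons_alt <- sum(cons == "alt", na.rm = TRUE)
  vaf_cons <- if (cons_ref + cons_alt > 0) cons_alt / (cons_ref + cons_alt)
              else NA_real_
  chosen <- if (mode == "raw") vaf_raw else vaf_cons
  call <- if (is.na(chosen)) "no-coverage"
          else if (chosen > vaf_threshold) "positive" else "negative"
  structure(list(raw_ref = raw_ref, raw_alt = raw_alt,
                 consensus_ref = cons_ref, consensus_alt = cons_alt,
                 vaf_raw = vaf_raw, vaf_consensus = vaf_cons,
                 mode = mode, vaf_threshold = vaf_threshold, call = call),
            class = "braf_result")
}

#' @export
print.braf_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("BRAF c.1799T>A: raw VAF %s (%d/%d), consensus VAF %s (%d/%d) -> %s (by %s VAF > %g%%)\n",
              fmt(x$vaf_raw), x$raw_alt, x$raw_ref + x$raw_alt,
              fmt(x$vaf_consensus), x$consensus_alt,
              x$consensus_ref + x$consensus_alt,
              x$call, x$mode, 100 * x$vaf_threshold))
  invisible(x)
}
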