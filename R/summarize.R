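#' Summarize extracted profiles into per-marker classifier traits
#'
#' Computes, for every marker of the panel, the sample's deletion frequency
#' (proportion of measurable reads with repeat length below the reference)
#' and -- when the sample is heterozygous at the linked SNP -- the two-sided
#' Fisher exact p-value for allelic bias of deletions, plus the distinct
#' molecular-barcode count used for quality control.
#'
#' Heterozygosity rule: a sample is treated as heterozygous at a marker when
#' both SNP alleles are seen in at least `het_min_reads` reads and the
#' minor-allele read fraction is at least `het_min_frac`. The defaults (5
#' reads, 20%) are robust both to the ~0.6% per-base sequencing error rate
#' (which puts a handful of reads on the wrong allele) and to allelic
#' dropout at low depth.
#'
#' @param profiles An `"mnr_profiles"` object from [profile_sample()] or
#'   [read_profiles()].
#' @param panel The [mnr_panel()] the profiles were extracted against.
#' @param het_min_frac Minimum minor-allele read fraction for
#'   heterozygosity (default 0.2).
#' @param het_min_reads Minimum reads per allele for heterozygosity
#'   (default 5).
#' @param umi_collapse If `TRUE`, reads are first collapsed to one
#'   observation per molecular barcode (majority repeat length and allele
#'   per barcode; ties dropped) before computing the traits. The default
#'   `FALSE` uses raw reads: barcode error-reduction was found not to
#'   improve sample separation for this trait pair, but the collapsed mode
#'   is retained for comparison.
#' @return A data.frame with one row per panel marker: `sample_id`,
#'   `marker`, `n_reads` (measurable reads), `del_freq`, `bias_p` (`NA`
#'   when the SNP is not heterozygous or the table is untestable),
#'   `heterozygous`, `umi_count`, and `mean_umi` (mean distinct barcodes per
#'   panel marker, repeated on every row; zero-coverage markers count 0).
#' @export
summarize_sample <- function(profiles, panel, het_min_frac = 0.2,
                             het_min_reads = 5L, umi_collapse = FALSE) {
  stopifnot(inherits(profiles, "mnr_profiles"), inherits(panel, "mnr_panel"))
  rows <- lapply(panel$markers, function(m) {
    mp <- marker_profile(profiles, m$name, m$reference_repeat_length)
    rec <- profiles$records[profiles$records$marker == m$name, , drop = FALSE]
    if (umi_collapse && nrow(rec)) rec <- collapse_by_umi(rec)
    meas <- rec[!is.na(rec$repeat_length), , drop = FALSE]
    d <- if (nrow(meas)) mean(meas$repeat_length < m$reference_repeat_length)
         else NA_real_
    called <- rec$snp_allele[rec$snp_allele %in% c("ref", "alt")]
    n_ref <- sum(called == "ref"); n_alt <- sum(called == "alt")
    het <- min(n_ref, n_alt) >= het_min_reads &&
      (n_ref + n_alt) > 0 && min(n_ref, n_alt) / (n_ref + n_alt) >= het_min_frac
    p <- NA_real_
    if (het) {
      hm <- meas[meas$snp_allele %in% c("ref", "alt"), , drop = FALSE]
      del <- hm$repeat_length < m$reference_repeat_length
      p <- fisher_exact2(c(sum(hm$snp_allele == "ref" & del),
                           sum(hm$snp_allele == "ref" & !del),
                           sum(hm$snp_allele == "alt" & del),
                           sum(hm$snp_allele == "alt" & !del)))
    }
    data.frame(sample_id = profiles$sample_id, marker = m$name,
               n_reads = nrow(meas), del_freq = d, bias_p = p,
               heterozygous = het, umi_count = mp$distinct_umi_count,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$mean_umi <- mean(out$umi_count)
  out
}

# Majority-rule collapse of read records to one row per molecular barcode.
# Barcodes with a length tie, or with no measurable read, yield NA length;
# allele likewise by majority over called reads.
collapse_by_umi <- function(rec) {
  sp <- split(rec, rec$umi)
  rows <- lapply(sp, function(g) {
    maj <- function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA)
      t <- sort(table(v), decreasing = TRUE)
      if (length(t) > 1L && t[1L] == t[2L]) return(NA)
      names(t)[1L]
    }
    len <- maj(g$repeat_length)
    al <- maj(g$snp_allele[g$snp_allele %in% c("ref", "alt")])
    data.frame(marker = g$marker[1L], umi = g$umi[1L],
               repeat_length = if (is.na(len)) NA_integer_ else as.integer(len),
               snp_allele = if (is.na(al)) "uncalled" else al,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Profile and summarize a whole cohort
#'
#' @param sheet A sample sheet data.frame from [read_sample_sheet()] or
#'   [generate_cohort()].
#' @param panel An [mnr_panel()].
#' @param keep_profiles Also return the per-sample `"mnr_profiles"` objects
#'   (needed for the in-silico mixture / resampling experiments).
#' @param ... Passed to [summarize_sample()].
#' @return A data.frame stacking [summarize_sample()] rows for every sample,
#'   with the sheet's `label` column joined on. When `keep_profiles = TRUE`,
#'   a list with elements `summaries` and `profiles` (named list).
#' @export
summarize_cohort <- function(sheet, panel, keep_profiles = FALSE, ...) {
  profs <- lapply(seq_len(nrow(sheet)), function(i)
    profile_sample(sheet$fastq1[i], sheet$fastq2[i], panel,
                   sample_id = sheet$sample_id[i]))
  names(profs) <- sheet$sample_id
  summaries <- do.call(rbind, lapply(profs, summarize_sample, panel = panel, ...))
  rownames(summaries) <- NULL
  if (!is.null(sheet$label))
    summaries$label <- sheet$label[match(summaries$sample_id, sheet$sample_id)]
  if (keep_profiles) list(summaries = summaries, profiles = profs) else summaries
}

#' Deletion frequency of a repeat-length histogram
#'
#' The proportion of reads whose measured repeat length is below the
#' reference length. Reads longer than the reference (insertions) are not
#' deletions but stay in the denominator.
#'
#' @param histogram Named numeric vector mapping repeat length to read count.
#' @param reference_length Reference repeat length in bp.
#' @return A proportion in `[0, 1]`, or `NA` for an empty histogram.
#' @examples
#' deletion_frequency(c(`8` = 5, `9` = 10, `10` = 85), 10)  # 0.15
#' @export
deletion_frequency <- function(histogram, reference_length) {
  total <- sum(histogram)
  if (!isTRUE(total > 0)) return(NA_real_)
  lens <- as.numeric(names(histogram))
  sum(histogram[lens < reference_length]) / total
}
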