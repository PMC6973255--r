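# Reference-free, arm-anchored read extraction.
#
# The captured molecule is UMI | extension_arm | insert | ligation_arm, read
# in both orientations: read 1 on the insert strand, read 2 its reverse
# complement. Pairs are assigned to markers by matching both probe arms with
# at most one substitution each (arms are primer-like; indels would corrupt
# the UMI frame, so none are tolerated). Only base calls supported by both
# reads of a pair are used: positions where the mates disagree are masked and
# any measurement touching a masked base is voided.

# Vectorized repeat/SNP measurement on consensus insert strings. Masked
# positions are "?" and can never match an ACGT anchor. Returns a
# data.frame(repeat_length, snp_allele).
measure_insert_vec <- function(ins, marker) {
  lf <- marker$left_flank; rf <- marker$right_flank
  unit <- marker$repeat_unit
  n <- length(ins)
  if (!n) return(data.frame(repeat_length = integer(0), snp_allele = character(0)))
  lfpos <- regexpr(lf, ins, fixed = TRUE)
  after <- substr(ins, lfpos + nchar(lf), nchar(ins))
  runlen <- attr(regexpr(paste0("^", unit, "*"), after), "match.length")
  rf_ok <- substr(after, runlen + 1L, runlen + nchar(rf)) == rf
  ok <- lfpos > 0L & rf_ok & runlen <= marker$reference_repeat_length + 10L
  repeat_length <- ifelse(ok, runlen, NA_integer_)
  base <- substr(ins, marker$snp_offset + 1L, marker$snp_offset + 1L)
  snp_allele <- rep("other", n)
  snp_allele[base == marker$snp_ref_allele] <- "ref"
  snp_allele[base == marker$snp_alt_allele] <- "alt"
  snp_allele[base == "?" | base == ""] <- "uncalled"
  data.frame(repeat_length = as.integer(repeat_length), snp_allele = snp_allele,
             stringsAsFactors = FALSE)
}

# Scalar convenience wrapper (also used to vet fixture panels).
measure_insert <- function(ins, marker) {
  as.list(measure_insert_vec(ins, marker)[1L, ])
}

# Per-marker arm distances for every read pair: edits of the extension arm in
# read 1 (after the UMI) plus edits of the reverse-complemented ligation arm
# at the start of read 2. Inf when either read is too short.
arm_distances <- function(r1, r2, rec, umi_len) {
  d1 <- Biostrings::neditStartingAt(Biostrings::DNAString(rec$extension_arm),
                                    r1, starting.at = umi_len + 1L)[1L, ]
  d2 <- Biostrings::neditStartingAt(
    Biostrings::DNAString(revcomp(rec$ligation_arm)), r2, starting.at = 1L)[1L, ]
  short <- Biostrings::width(r1) < umi_len + nchar(rec$extension_arm) |
           Biostrings::width(r2) < nchar(rec$ligation_arm)
  d <- d1 + d2
  d[short] <- Inf
  list(total = d, ok = d1 <= 1L & d2 <= 1L & !short)
}

#' Extract per-marker read evidence from a FASTQ pair
#'
#' Assigns every read pair to at most one panel marker by probe-arm matching
#' (tolerance: one substitution per arm; ties between markers are counted as
#' ambiguous and dropped), extracts the molecular barcode adjacent to the
#' extension arm, forms the pair consensus (disagreeing positions masked),
#' and measures the repeat-tract length between the exact flank anchors and
#' the linked-SNP allele of each assigned pair. Pairs whose mates cannot be
#' superimposed (different lengths after orientation) are discarded. Reads
#' whose measured tract exceeds the reference length by more than 10 bp are
#' treated as chimeric and excluded from the histogram.
#'
#' @param fastq1,fastq2 Paths to the paired FASTQ files (gzip ok).
#' @param panel An [mnr_panel()].
#' @param sample_id Sample identifier carried into downstream tables.
#' @return An object of class `"mnr_profiles"`: a list with `records` (one
#'   row per retained pair: `marker`, `umi`, `repeat_length` -- `NA` when
#'   unmeasurable -- and `snp_allele` in ref/alt/other/uncalled),
#'   `braf_records` (`umi`, `allele` at the variant offset), per-marker
#'   discard counts, and overall pair accounting (`total`, `assigned`,
#'   `unassigned`, `ambiguous`, `discarded`).
#' @seealso [marker_profile()] for the per-marker histogram / 2x2 view.
#' @export
profile_sample <- function(fastq1, fastq2, panel, sample_id = NULL) {
  stopifnot(inherits(panel, "mnr_panel"))
  if (is.null(sample_id))
    sample_id <- sub("(_R?1)?\\.(fastq|fq)(\\.gz)?$", "", basename(fastq1))
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq")
  if (length(r1) != length(r2))
    stop("paired FASTQ files differ in read count")
  umi_len <- panel$markers[[1L]]$umi_length
  recs <- c(unname(panel$markers), if (!is.null(panel$braf)) list(panel$braf))
  n <- length(r1)
  k <- length(recs)
  empty <- structure(list(
    sample_id = sample_id, markers = panel_markers(panel),
    records = data.frame(marker = character(0), umi = character(0),
                         repeat_length = integer(0), snp_allele = character(0),
                         stringsAsFactors = FALSE),
    braf_records = data.frame(umi = character(0), allele = character(0),
                              stringsAsFactors = FALSE),
    marker_discarded = stats::setNames(integer(length(recs)),
                                       vapply(recs, `[[`, character(1), "name")),
    counts = list(total = 0L, assigned = 0L, unassigned = 0L,
                  ambiguous = 0L, discarded = 0L)), class = "mnr_profiles")
  if (n == 0L) return(empty)
  dist <- matrix(Inf, nrow = k, ncol = n)
  okm <- matrix(FALSE, nrow = k, ncol = n)
  for (j in seq_len(k)) {
    a <- arm_distances(r1, r2, recs[[j]], umi_len)
    dist[j, ] <- a$total
    okm[j, ] <- a$ok
  }
  dist[!okm] <- Inf
  best <- apply(dist, 2L, min)
  nbest <- colSums(sweep(dist, 2L, best, "==") & is.finite(dist))
  assigned_to <- rep(NA_integer_, n)
  hit <- is.finite(best) & nbest == 1L
  assigned_to[hit] <- apply(dist[, hit, drop = FALSE], 2L, which.min)
  ambiguous <- sum(is.finite(best) & nbest > 1L)
  unassigned <- sum(!is.finite(best))
  rec_rows <- vector("list", k)
  braf_rows <- NULL
  marker_discarded <- stats::setNames(integer(k),
                                      vapply(recs, `[[`, character(1), "name"))
  for (j in seq_len(k)) {
    idx <- which(assigned_to == j)
    if (!length(idx)) next
    rec <- recs[[j]]
    a1 <- r1[idx]
    a2rc <- Biostrings::reverseComplement(r2[idx])
    same <- Biostrings::width(a1) == Biostrings::width(a2rc)
    marker_discarded[j] <- sum(!same)
    if (!any(same)) next
    cons <- Biostrings::compareStrings(a1[same], a2rc[same])
    # the molecular barcode is read from the extension-side mate; a mate
    # disagreement there must not fabricate a masked pseudo-barcode
    umi <- substr(as.character(a1[same]), 1L, umi_len)
    ins <- substr(cons, umi_len + nchar(rec$extension_arm) + 1L,
                  nchar(cons) - nchar(rec$ligation_arm))
    if (inherits(rec, "braf_marker")) {
      # variant calling keeps the two orientations as separate base calls
      # (one record per mate): the raw VAF then reflects the per-read
      # base-calling error rate, which barcode consensus is meant to
      # suppress -- pair-consensus masking would hide exactly that signal
      pos <- umi_len + nchar(rec$extension_arm) + rec$variant_offset + 1L
      call_base <- function(reads) {
        base <- substr(as.character(reads), pos, pos)
        allele <- rep("other", length(base))
        allele[base == rec$ref_allele] <- "ref"
        allele[base == rec$alt_allele] <- "alt"
        allele[!base %in% c("A", "C", "G", "T")] <- "uncalled"
        allele
      }
      braf_rows <- data.frame(umi = rep(umi, 2L),
                              allele = c(call_base(a1[same]),
                                         call_base(a2rc[same])),
                              stringsAsFactors = FALSE)
    } else {
      mm <- measure_insert_vec(ins, rec)
      rec_rows[[j]] <- data.frame(marker = rec$name, umi = umi,
                                  repeat_length = mm$repeat_length,
                                  snp_allele = mm$snp_allele,
                                  stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec_rows[!vapply(rec_rows, is.null, logical(1))])
  if (is.null(records)) records <- empty$records
  if (is.null(braf_rows)) braf_rows <- empty$braf_records
  rownames(records) <- NULL
  rownames(braf_rows) <- NULL
  structure(list(
    sample_id = sample_id, markers = panel_markers(panel),
    records = records, braf_records = braf_rows,
    marker_discarded = marker_discarded,
    counts = list(total = n, assigned = sum(!is.na(assigned_to)),
                  unassigned = unassigned, ambiguous = ambiguous,
                  discarded = sum(marker_discarded))), class = "mnr_profiles")
}

#' @export
print.mnr_profiles <- function(x, ...) {
  cat(sprintf("mnr_profiles '%s': %d pairs (%d assigned, %d unassigned, %d ambiguous, %d discarded)\n",
              x$sample_id, x$counts$total, x$counts$assigned,
              x$counts$unassigned, x$counts$ambiguous, x$counts$discarded))
  invisible(x)
}

#' Per-marker read profile
#'
#' Tabulates one marker's evidence from extracted records: the repeat-length
#' histogram, the SNP-allele x deletion 2x2 table (deleted = measured length
#' below the reference length; reads with an other/uncalled allele or an
#' unmeasurable length are excluded from the table), and the distinct
#' molecular-barcode count.
#'
#' @param profiles An `"mnr_profiles"` object from [profile_sample()].
#' @param marker Marker name.
#' @param reference_length The marker's reference repeat length in bp.
#' @return A list: `length_histogram` (named integer vector), `allele_deletion_table`
#'   (2x2 matrix, rows ref/alt, cols deleted/not_deleted), `distinct_umi_count`,
#'   `total_pairs_assigned`, `pairs_discarded`, `pairs_unmeasurable`.
#' @export
marker_profile <- function(profiles, marker, reference_length) {
  stopifnot(inherits(profiles, "mnr_profiles"))
  r <- profiles$records[profiles$records$marker == marker, , drop = FALSE]
  meas <- r[!is.na(r$repeat_length), , drop = FALSE]
  hist <- table(factor(meas$repeat_length))
  hist <- stats::setNames(as.integer(hist), names(hist))
  tab <- matrix(0L, 2L, 2L, dimnames = list(c("ref", "alt"),
                                            c("deleted", "not_deleted")))
  het <- meas[meas$snp_allele %in% c("ref", "alt"), , drop = FALSE]
  if (nrow(het)) {
    del <- het$repeat_length < reference_length
    tab["ref", "deleted"] <- sum(het$snp_allele == "ref" & del)
    tab["ref", "not_deleted"] <- sum(het$snp_allele == "ref" & !del)
    tab["alt", "deleted"] <- sum(het$snp_allele == "alt" & del)
    tab["alt", "not_deleted"] <- sum(het$snp_allele == "alt" & !del)
  }
  disc <- unname(profiles$marker_discarded[marker])
  if (is.na(disc)) disc <- 0L
  list(length_histogram = hist, allele_deletion_table = tab,
       distinct_umi_count = length(unique(r$umi)),
       total_pairs_assigned = nrow(r) + disc,
       pairs_discarded = disc,
       pairs_unmeasurable = nrow(r) - nrow(meas))
}

PROFILE_FORMAT <- "mnrmsi-profiles"
PROFILE_VERSION <- 1L

#' Read / write extracted profiles
#'
#' Profiles serialize to a self-describing TSV: `#`-prefixed header lines
#' carry the format tag, sample id and pair accounting; data rows hold one
#' retained read pair each (`type` record/braf, `marker`, `umi`,
#' `repeat_length`, `allele`). Round-trips losslessly.
#'
#' @param profiles An `"mnr_profiles"` object.
#' @param path Output path.
#' @return `read_profiles()` returns the `"mnr_profiles"` object;
#'   `write_profiles()` returns `path` invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "mnr_profiles"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    paste0("#", PROFILE_FORMAT, "\tv", PROFILE_VERSION),
    paste0("#sample_id\t", profiles$sample_id),
    paste0("#markers\t", paste(profiles$markers, collapse = ",")),
    paste0("#counts\t", paste(sprintf("%s=%d", names(profiles$counts),
                                      unlist(profiles$counts)), collapse = ",")),
    paste0("#marker_discarded\t",
           paste(sprintf("%s=%d", names(profiles$marker_discarded),
                         profiles$marker_discarded), collapse = ",")))
  writeLines(hdr, con)
  rec <- profiles$records
  out <- rbind(
    data.frame(type = rep("record", nrow(rec)), marker = rec$marker,
               umi = rec$umi, repeat_length = rec$repeat_length,
               allele = rec$snp_allele, stringsAsFactors = FALSE),
    data.frame(type = rep("braf", nrow(profiles$braf_records)),
               marker = rep("", nrow(profiles$braf_records)),
               umi = profiles$braf_records$umi,
               repeat_length = rep(NA_integer_, nrow(profiles$braf_records)),
               allele = profiles$braf_records$allele, stringsAsFactors = FALSE))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  lines <- readLines(path, n = 5L)
  if (!startsWith(lines[1L], paste0("#", PROFILE_FORMAT)))
    stop("not a profiles file: ", path)
  field <- function(i) strsplit(lines[i], "\t", fixed = TRUE)[[1L]][2L]
  parse_kv <- function(s) {
    kv <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    stats::setNames(as.integer(vapply(kv, `[`, character(1), 2L)),
                    vapply(kv, `[`, character(1), 1L))
  }
  counts <- as.list(parse_kv(field(4L)))
  tab <- utils::read.delim(path, skip = 5L, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character",
                                          "integer", "character"))
  rec <- tab[tab$type == "record", , drop = FALSE]
  braf <- tab[tab$type == "braf", , drop = FALSE]
  structure(list(
    sample_id = field(2L),
    markers = strsplit(field(3L), ",", fixed = TRUE)[[1L]],
    records = data.frame(marker = rec$marker, umi = rec$umi,
                         repeat_length = rec$repeat_length,
                         snp_allele = rec$allele, stringsAsFactors = FALSE),
    braf_records = data.frame(umi = braf$umi, allele = braf$allele,
                              stringsAsFactors = FALSE),
    marker_discarded = parse_kv(field(5L)),
    counts = counts), class = "mnr_profiles")
}
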