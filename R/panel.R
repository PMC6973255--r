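#' Define a single repeat marker of an smMIP panel
#'
#' A marker is a short mononucleotide repeat (MNR) captured by a molecular
#' inversion probe. The captured insert, written 5'->3' from the extension
#' arm, is `insert_5p | left_flank | repeat | right_flank | insert_3p`; the
#' probe arms and the molecular barcode (UMI, adjacent to the extension arm)
#' lie outside the insert. A common SNP linked to the repeat sits inside
#' `insert_5p`, i.e. 5' of the repeat tract, so that repeat deletions never
#' shift its offset. All coordinates are 0-based on the insert strand.
#'
#' @param name Unique marker identifier.
#' @param extension_arm,ligation_arm Probe arm sequences (uppercase ACGT) as
#'   they appear in the sequenced molecule: read 1 starts with the UMI
#'   followed by `extension_arm`; the molecule ends with `ligation_arm`.
#' @param insert_5p Insert sequence 5' of `left_flank`; contains the linked
#'   SNP (reference allele at `snp_offset`).
#' @param left_flank,right_flank Exact anchor sequences (>= 4 nt) immediately
#'   flanking the repeat tract. Neither may continue the repeat
#'   (`left_flank` must not end with `repeat_unit`, `right_flank` must not
#'   start with it), otherwise the repeat length is ill-defined.
#' @param repeat_unit Single repeated base (`"A"`, `"C"`, `"G"` or `"T"`).
#' @param reference_repeat_length Repeat tract length in the reference, in bp.
#'   Must lie in `[5, 20]`; the assay is designed for 7-12 bp monomorphic
#'   MNRs and values outside that range raise a warning.
#' @param insert_3p Insert sequence 3' of `right_flank` (may be `""`).
#' @param snp_offset 0-based position of the linked SNP within the captured
#'   insert; must fall inside `insert_5p`.
#' @param snp_ref_allele,snp_alt_allele The two SNP alleles (single bases);
#'   `insert_5p` carries the reference allele.
#' @param umi_length Molecular barcode length in bases (default 6).
#' @return An object of class `"mnr_marker"` (a validated list).
#' @export
mnr_marker <- function(name, extension_arm, ligation_arm, insert_5p,
                       left_flank, repeat_unit, reference_repeat_length,
                       right_flank, insert_3p = "", snp_offset,
                       snp_ref_allele, snp_alt_allele, umi_length = 6L) {
  m <- structure(list(
    name = as.character(name),
    extension_arm = toupper(extension_arm),
    ligation_arm = toupper(ligation_arm),
    insert_5p = toupper(insert_5p),
    left_flank = toupper(left_flank),
    repeat_unit = toupper(repeat_unit),
    reference_repeat_length = as.integer(reference_repeat_length),
    right_flank = toupper(right_flank),
    insert_3p = toupper(insert_3p),
    snp_offset = as.integer(snp_offset),
    snp_ref_allele = toupper(snp_ref_allele),
    snp_alt_allele = toupper(snp_alt_allele),
    umi_length = as.integer(umi_length)
  ), class = "mnr_marker")
  validate_marker(m)
  m
}

validate_marker <- function(m) {
  who <- function(msg) stop(sprintf("marker '%s': %s", m$name, msg), call. = FALSE)
  seq_fields <- c("extension_arm", "ligation_arm", "insert_5p", "left_flank",
                  "right_flank")
  for (f in c(seq_fields, "insert_3p")) {
    s <- m[[f]]
    if (f != "insert_3p" && !nzchar(s)) who(sprintf("field '%s' is empty", f))
    if (nzchar(s) && grepl("[^ACGT]", s))
      who(sprintf("field '%s' contains non-ACGT characters", f))
  }
  if (!m$repeat_unit %in% c("A", "C", "G", "T"))
    who("repeat_unit must be a single base A/C/G/T")
  if (is.na(m$reference_repeat_length) ||
      m$reference_repeat_length < 5L || m$reference_repeat_length > 20L)
    who("reference_repeat_length must be in [5, 20]")
  if (m$reference_repeat_length < 7L || m$reference_repeat_length > 12L)
    warning(sprintf("marker '%s': reference_repeat_length %d outside the 7-12 bp design range",
                    m$name, m$reference_repeat_length), call. = FALSE)
  if (nchar(m$left_flank) < 4L || nchar(m$right_flank) < 4L)
    who("flank anchors must be at least 4 nt")
  if (substr(m$left_flank, nchar(m$left_flank), nchar(m$left_flank)) == m$repeat_unit)
    who("left_flank ends with the repeat unit; repeat length would be ill-defined")
  if (substr(m$right_flank, 1L, 1L) == m$repeat_unit)
    who("right_flank starts with the repeat unit; repeat length would be ill-defined")
  if (!m$snp_ref_allele %in% c("A", "C", "G", "T") ||
      !m$snp_alt_allele %in% c("A", "C", "G", "T") ||
      m$snp_ref_allele == m$snp_alt_allele)
    who("snp alleles must be two distinct single bases")
  if (is.na(m$snp_offset) || m$snp_offset < 0L || m$snp_offset >= nchar(m$insert_5p))
    who("snp_offset must fall within insert_5p (5' of the repeat tract)")
  if (substr(m$insert_5p, m$snp_offset + 1L, m$snp_offset + 1L) != m$snp_ref_allele)
    who("insert_5p does not carry snp_ref_allele at snp_offset")
  if (is.na(m$umi_length) || m$umi_length < 1L)
    who("umi_length must be >= 1")
  invisible(m)
}

#' Reference captured-insert sequence of a marker
#'
#' @param marker An [mnr_marker()].
#' @return The insert sequence with the reference-length repeat tract and the
#'   reference SNP allele.
#' @export
reference_insert <- function(marker) {
  paste0(marker$insert_5p, marker$left_flank,
         strrep(marker$repeat_unit, marker$reference_repeat_length),
         marker$right_flank, marker$insert_3p)
}

#' Define the optional BRAF c.1799 variant marker
#'
#' A variant-calling locus carried on the same panel: instead of a repeat it
#' has a single variant position (c.1799, T>A in the classic p.V600E
#' orientation as captured here).
#'
#' @param name Marker name (default `"BRAF_c1799"`).
#' @param extension_arm,ligation_arm Probe arms (as for [mnr_marker()]).
#' @param insert Reference captured-insert sequence (carries `ref_allele` at
#'   `variant_offset`).
#' @param variant_offset 0-based offset of the variant within the insert.
#' @param ref_allele,alt_allele Reference and alternate bases (default T/A).
#' @param umi_length Molecular barcode length (default 6).
#' @return An object of class `"braf_marker"`.
#' @export
braf_marker <- function(name = "BRAF_c1799", extension_arm, ligation_arm,
                        insert, variant_offset, ref_allele = "T",
                        alt_allele = "A", umi_length = 6L) {
  b <- structure(list(
    name = as.character(name),
    extension_arm = toupper(extension_arm),
    ligation_arm = toupper(ligation_arm),
    insert = toupper(insert),
    variant_offset = as.integer(variant_offset),
    ref_allele = toupper(ref_allele),
    alt_allele = toupper(alt_allele),
    umi_length = as.integer(umi_length)
  ), class = "braf_marker")
  if (grepl("[^ACGT]", b$insert) || grepl("[^ACGT]", b$extension_arm) ||
      grepl("[^ACGT]", b$ligation_arm))
    stop("BRAF marker sequences must be uppercase ACGT")
  if (b$variant_offset < 0L || b$variant_offset >= nchar(b$insert))
    stop("BRAF variant_offset outside the insert")
  if (substr(b$insert, b$variant_offset + 1L, b$variant_offset + 1L) != b$ref_allele)
    stop("BRAF insert does not carry ref_allele at variant_offset")
  b
}

#' Assemble a marker panel
#'
#' @param markers List of [mnr_marker()] objects (order is preserved).
#' @param braf Optional [braf_marker()]; when absent, BRAF reporting is
#'   disabled.
#' @return An object of class `"mnr_panel"`.
#' @export
mnr_panel <- function(markers, braf = NULL) {
  if (length(markers) < 1L) stop("a panel needs at least one marker")
  stopifnot(all(vapply(markers, inherits, logical(1), "mnr_marker")))
  nm <- vapply(markers, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("marker names must be unique")
  if (!is.null(braf)) {
    stopifnot(inherits(braf, "braf_marker"))
    if (braf$name %in% nm) stop("BRAF marker name collides with a repeat marker")
  }
  names(markers) <- nm
  ul <- unique(vapply(markers, `[[`, integer(1), "umi_length"))
  if (length(ul) != 1L) stop("all markers must share one umi_length")
  structure(list(markers = markers, braf = braf), class = "mnr_panel")
}

#' @export
print.mnr_panel <- function(x, ...) {
  cat(sprintf("smMIP MNR panel: %d repeat marker(s)%s\n", length(x$markers),
              if (is.null(x$braf)) "" else " + BRAF c.1799"))
  rl <- vapply(x$markers, `[[`, integer(1), "reference_repeat_length")
  ru <- vapply(x$markers, `[[`, character(1), "repeat_unit")
  cat(sprintf("  %-12s %s(%d)\n", names(x$markers), ru, rl), sep = "")
  invisible(x)
}

#' Marker names of a panel
#' @param panel An [mnr_panel()].
#' @return Character vector of repeat-marker names (BRAF excluded).
#' @export
panel_markers <- function(panel) names(panel$markers)

PANEL_FORMAT <- "mnrmsi-panel"
PANEL_VERSION <- 1L

#' Read / write a panel definition file
#'
#' The panel file is versioned JSON (format tag `"mnrmsi-panel"`, version 1)
#' with a `markers` array holding every [mnr_marker()] field and an optional
#' `braf` record. Round-trips losslessly.
#'
#' @param path File path.
#' @return `read_panel()` returns an [mnr_panel()]; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$format) || j$format != PANEL_FORMAT)
    stop("not a panel file (missing format tag '", PANEL_FORMAT, "')")
  if (is.null(j$version) || j$version != PANEL_VERSION)
    stop("unsupported panel format version: ", j$version)
  markers <- lapply(j$markers, function(rec) do.call(mnr_marker, rec))
  braf <- if (!is.null(j$braf)) do.call(braf_marker, j$braf) else NULL
  mnr_panel(markers, braf = braf)
}

#' @rdname read_panel
#' @param panel An [mnr_panel()].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "mnr_panel"))
  j <- list(format = PANEL_FORMAT, version = PANEL_VERSION,
            markers = lapply(unname(panel$markers), unclass))
  if (!is.null(panel$braf)) j$braf <- unclass(panel$braf)
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated file with columns `sample_id`, `fastq1`, `fastq2` and an
#' optional `label` column (`MSI-H`, `MSS` or `unknown`). Relative FASTQ
#' paths are resolved against the sheet's directory. Reference labels follow
#' the usual clinical convention: samples with a single mutant reference
#' marker (MSI-low) are labelled MSS upstream.
#'
#' @param path Path to the TSV sheet.
#' @param require_labels If `TRUE`, every sample must carry an MSI-H/MSS
#'   label (needed for training).
#' @return A data.frame with columns `sample_id`, `fastq1`, `fastq2`, `label`.
#' @export
read_sample_sheet <- function(path, require_labels = FALSE) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "fastq1", "fastq2")
  if (!all(need %in% names(ss)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample ids in sample sheet")
  if (is.null(ss$label)) ss$label <- "unknown"
  ss$label[is.na(ss$label) | ss$label == ""] <- "unknown"
  bad <- setdiff(unique(ss$label), c("MSI-H", "MSS", "unknown"))
  if (length(bad)) stop("unknown labels in sample sheet: ", paste(bad, collapse = ", "))
  if (require_labels && any(ss$label == "unknown"))
    stop("training requires an MSI-H/MSS label for every sample")
  base <- dirname(path)
  for (f in c("fastq1", "fastq2")) {
    rel <- !grepl("^(/|[A-Za-z]:)", ss[[f]])
    ss[[f]][rel] <- file.path(base, ss[[f]][rel])
  }
  ss[c("sample_id", "fastq1", "fastq2", "label")]
}
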