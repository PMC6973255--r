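#' Build a synthetic fixture panel
#'
#' Generates a panel of `k` repeat markers with random, non-repetitive probe
#' arms and flanks, repeat lengths cycling over 7-12 bp, and one linked SNP
#' per marker 5' of the repeat. The panel is entirely synthetic -- it stands
#' in for a real assay design whose marker sequences are not distributed with
#' this package -- but satisfies every structural invariant of a real panel
#' (unique arms, unambiguous flank anchors, SNP outside the repeat tract).
#'
#' @param k Number of repeat markers (>= 1).
#' @param seed Integer seed; the same seed always yields the same panel.
#' @param with_braf Also attach a synthetic BRAF c.1799-like variant locus.
#' @param umi_length Molecular barcode length (default 6).
#' @param arm_length Probe arm length in nt (default 18).
#' @return An [mnr_panel()].
#' @examples
#' p <- make_fixture_panel(6, seed = 1)
#' panel_markers(p)
#' @export
make_fixture_panel <- function(k = 6L, seed = 1L, with_braf = TRUE,
                               umi_length = 6L, arm_length = 18L) {
  stopifnot(k >= 1L)
  with_seed(seed, {
    rep_lens <- rep(7:12, length.out = k)
    units <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    n_arms <- 2L * k + if (with_braf) 2L else 0L
    # draw arms until all pairwise edit distances exceed 4
    repeat {
      arms <- random_dna(n_arms, arm_length)
      d <- utils::adist(arms)
      if (min(d[upper.tri(d)]) > 4L) break
    }
    markers <- vector("list", k)
    for (i in seq_len(k)) {
      u <- units[i]
      repeat {
        ins5 <- random_dna(1L, 10L)
        lf <- random_dna(1L, 5L)
        rf <- random_dna(1L, 5L)
        ins3 <- random_dna(1L, 12L)
        if (substr(lf, 5L, 5L) == u || substr(rf, 1L, 1L) == u) next
        snp_off <- 3L
        ref_a <- substr(ins5, snp_off + 1L, snp_off + 1L)
        alt_a <- sample(setdiff(c("A", "C", "G", "T"), ref_a), 1L)
        m <- tryCatch(
          mnr_marker(name = sprintf("MNR%02d", i),
                     extension_arm = arms[2L * i - 1L],
                     ligation_arm = arms[2L * i],
                     insert_5p = ins5, left_flank = lf, repeat_unit = u,
                     reference_repeat_length = rep_lens[i], right_flank = rf,
                     insert_3p = ins3, snp_offset = snp_off,
                     snp_ref_allele = ref_a, snp_alt_allele = alt_a,
                     umi_length = umi_length),
          error = function(e) NULL)
        if (is.null(m)) next
        # the anchored measurement must recover the reference structure for
        # both SNP alleles, else redraw (anchor collision inside the insert)
        ok <- TRUE
        for (allele in c("ref", "alt")) {
          ins <- reference_insert(m)
          if (allele == "alt")
            substr(ins, m$snp_offset + 1L, m$snp_offset + 1L) <- m$snp_alt_allele
          mm <- measure_insert(ins, m)
          if (is.na(mm$repeat_length) ||
              mm$repeat_length != m$reference_repeat_length ||
              mm$snp_allele != allele) ok <- FALSE
        }
        if (ok) break
      }
      markers[[i]] <- m
    }
    braf <- NULL
    if (with_braf) {
      ins <- random_dna(1L, 40L)
      off <- 19L
      substr(ins, off + 1L, off + 1L) <- "T"
      braf <- braf_marker(extension_arm = arms[n_arms - 1L],
                          ligation_arm = arms[n_arms],
                          insert = ins, variant_offset = off,
                          ref_allele = "T", alt_allele = "A",
                          umi_length = umi_length)
    }
    mnr_panel(markers, braf = braf)
  })
}

#' Configure a synthetic smMIP cohort
#'
#' Collects the generative parameters of the simulated assay. Defaults
#' emulate the assay's operating point: a per-base substitution error of
#' 0.62% (the MiSeq base-calling error rate the assay was characterized at),
#' 6-base molecular barcodes, ~150 template molecules per marker, a Poisson
#' mean of 3 read pairs per template, per-marker somatic deletion rates of
#' 30-70% of tumor templates under MSI-H, and PCR stutter deletion rates of
#' 0.5-3% per read pair rising with repeat length. MSI-H deletions are placed
#' preferentially on one haplotype of the linked SNP (linkage 0.9) in
#' heterozygous samples, creating the allelic-bias signal; MSS stutter is
#' haplotype-blind.
#'
#' @param panel An [mnr_panel()].
#' @param n_msih,n_mss Cohort sizes per class.
#' @param mutant_fraction_range Range of per-marker mutant-template fractions
#'   under MSI-H (drawn once per cohort per marker).
#' @param stutter_range Per-pair stutter deletion probability at repeat
#'   lengths 7 and 12 bp; linear in between.
#' @param tumor_content_range Range of MSI-H tumor cell content (uniform per
#'   sample); somatic deletion rates scale with it.
#' @param het_prob Probability a sample is heterozygous at a marker's SNP.
#' @param linkage Probability a somatic deletion arises on the biased
#'   haplotype (0.5 = no allelic bias).
#' @param error_rate Per-base substitution error per read (default 0.0062).
#' @param templates_per_marker Template molecules per marker per sample.
#' @param reads_per_template Mean read pairs per template.
#' @param fixed_reads If `TRUE`, every template gets exactly
#'   `reads_per_template` pairs instead of a Poisson draw.
#' @param braf_alt_fraction Alternate-allele template fraction at the BRAF
#'   locus, per class: named vector `c("MSI-H" = ..., "MSS" = ...)` or a
#'   single number for both classes.
#' @param seed Integer seed (mandatory: every output byte is a function of
#'   the configuration and seed).
#' @return A validated configuration object of class `"msi_cohort_config"`.
#' @export
cohort_config <- function(panel, n_msih = 10L, n_mss = 10L,
                          mutant_fraction_range = c(0.3, 0.7),
                          stutter_range = c(0.005, 0.03),
                          tumor_content_range = c(0.5, 1),
                          het_prob = 0.3, linkage = 0.9,
                          error_rate = 0.0062,
                          templates_per_marker = 150L,
                          reads_per_template = 3,
                          fixed_reads = FALSE,
                          braf_alt_fraction = 0,
                          seed) {
  stopifnot(inherits(panel, "mnr_panel"))
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory for reproducibility")
  probs <- c(mutant_fraction_range, stutter_range, het_prob, linkage,
             error_rate, braf_alt_fraction)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (any(tumor_content_range <= 0 | tumor_content_range > 1))
    stop("tumor_content_range must lie in (0, 1]")
  if (length(braf_alt_fraction) == 1L)
    braf_alt_fraction <- c("MSI-H" = unname(braf_alt_fraction), "MSS" = unname(braf_alt_fraction))
  structure(list(panel = panel, n_msih = as.integer(n_msih),
                 n_mss = as.integer(n_mss),
                 mutant_fraction_range = mutant_fraction_range,
                 stutter_range = stutter_range,
                 tumor_content_range = tumor_content_range,
                 het_prob = het_prob, linkage = linkage,
                 error_rate = error_rate,
                 templates_per_marker = as.integer(templates_per_marker),
                 reads_per_template = reads_per_template,
                 fixed_reads = fixed_reads,
                 braf_alt_fraction = braf_alt_fraction,
                 seed = as.integer(seed)),
            class = "msi_cohort_config")
}

# Stutter probability per pair for a given repeat length, interpolating the
# configured range over the 7-12 bp design window.
stutter_rate <- function(ref_len, stutter_range) {
  w <- (pmin(pmax(ref_len, 7L), 12L) - 7) / 5
  stutter_range[1L] + w * (stutter_range[2L] - stutter_range[1L])
}

# Simulate read pairs for one sample. Returns r1/r2 character vectors and a
# per-marker truth data.frame. Consumes the ambient RNG stream.
simulate_sample_reads <- function(cfg, label, tumor_content, mutant_fraction,
                                  sample_id) {
  panel <- cfg$panel
  umi_len <- panel$markers[[1L]]$umi_length
  r1 <- character(0); r2 <- character(0)
  truth <- vector("list", length(panel$markers))
  geom_sizes <- function(n) 1L + pmin(stats::rgeom(n, 0.6), 2L)
  for (mi in seq_along(panel$markers)) {
    m <- panel$markers[[mi]]
    nt <- cfg$templates_per_marker
    umis <- random_umis(nt, umi_len)
    het <- stats::runif(1) < cfg$het_prob
    hap <- if (het) sample(c("ref", "alt"), nt, replace = TRUE)
           else rep(sample(c("ref", "alt"), 1L), nt)
    del <- integer(nt)
    if (label == "MSI-H") {
      f <- mutant_fraction[m$name] * tumor_content
      if (het) {
        biased <- sample(c("ref", "alt"), 1L)
        p_mut <- ifelse(hap == biased, pmin(1, 2 * f * cfg$linkage),
                        pmin(1, 2 * f * (1 - cfg$linkage)))
      } else p_mut <- rep(f, nt)
      mut <- stats::runif(nt) < p_mut
      del[mut] <- geom_sizes(sum(mut))
    }
    npairs_t <- if (cfg$fixed_reads) rep(as.integer(cfg$reads_per_template), nt)
                else stats::rpois(nt, cfg$reads_per_template)
    tpl <- rep(seq_len(nt), npairs_t)
    np <- length(tpl)
    st <- stats::runif(np) < stutter_rate(m$reference_repeat_length, cfg$stutter_range)
    st_size <- integer(np)
    st_size[st] <- sample(1:3, sum(st), replace = TRUE, prob = c(0.9, 0.08, 0.02))
    L <- pmax(m$reference_repeat_length - del[tpl] - st_size, 0L)
    ins5 <- m$insert_5p
    ins5_alt <- ins5
    substr(ins5_alt, m$snp_offset + 1L, m$snp_offset + 1L) <- m$snp_alt_allele
    mol <- paste0(umis[tpl], m$extension_arm,
                  ifelse(hap[tpl] == "alt", ins5_alt, ins5),
                  m$left_flank, strrep(m$repeat_unit, L), m$right_flank,
                  m$insert_3p, m$ligation_arm)
    r1 <- c(r1, inject_errors(mol, cfg$error_rate))
    r2 <- c(r2, revcomp(inject_errors(mol, cfg$error_rate)))
    emitted <- npairs_t > 0L
    truth[[mi]] <- data.frame(
      sample_id = sample_id, marker = m$name,
      n_templates = sum(emitted), n_pairs = np,
      n_mutant_templates = sum(del > 0L & emitted),
      mutant_fraction = if (label == "MSI-H")
        unname(mutant_fraction[m$name]) * tumor_content else 0,
      heterozygous = het,
      del_pair_fraction = mean(L < m$reference_repeat_length),
      stringsAsFactors = FALSE)
  }
  if (!is.null(panel$braf)) {
    b <- panel$braf
    nt <- cfg$templates_per_marker
    umis <- random_umis(nt, umi_len)
    alt <- stats::runif(nt) < cfg$braf_alt_fraction[[label]]
    npairs_t <- if (cfg$fixed_reads) rep(as.integer(cfg$reads_per_template), nt)
                else stats::rpois(nt, cfg$reads_per_template)
    tpl <- rep(seq_len(nt), npairs_t)
    ins_alt <- b$insert
    substr(ins_alt, b$variant_offset + 1L, b$variant_offset + 1L) <- b$alt_allele
    mol <- paste0(umis[tpl], b$extension_arm,
                  ifelse(alt[tpl], ins_alt, b$insert), b$ligation_arm)
    r1 <- c(r1, inject_errors(mol, cfg$error_rate))
    r2 <- c(r2, revcomp(inject_errors(mol, cfg$error_rate)))
  }
  # shuffle pairs jointly: output order must carry no information
  ord <- sample.int(length(r1))
  list(r1 = r1[ord], r2 = r2[ord], truth = do.call(rbind, truth))
}

#' Generate a synthetic paired-FASTQ cohort with ground truth
#'
#' Simulates every sample of the configured cohort and writes standard
#' 4-line paired FASTQ files, a sample sheet, and truth tables to `dir`.
#' Template molecules carry unique random barcodes; MSI-H samples draw
#' somatic 1-3 bp repeat deletions (geometric sizes) per template at rate
#' `mutant_fraction * tumor_content`, placed preferentially on one SNP
#' haplotype; every read pair is subject to PCR stutter (a shared deletion on
#' the sequenced amplicon) and independent per-base substitution errors on
#' the two mates.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @param compress Write gzip-compressed FASTQ (default plain).
#' @return A list with `sheet` (sample sheet data.frame, also written as
#'   `sample_sheet.tsv`), `truth_markers` (per-sample per-marker truth) and
#'   `truth_samples` (per-sample truth: label, tumor content, BRAF fraction),
#'   and `mutant_fraction` (the per-marker MSI-H deletion rates drawn for
#'   this cohort).
#' @export
generate_cohort <- function(config, dir, compress = FALSE) {
  stopifnot(inherits(config, "msi_cohort_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, {
    mk <- panel_markers(config$panel)
    mutant_fraction <- stats::setNames(
      stats::runif(length(mk), config$mutant_fraction_range[1L],
                   config$mutant_fraction_range[2L]), mk)
    labels <- c(rep("MSI-H", config$n_msih), rep("MSS", config$n_mss))
    n <- length(labels)
    ids <- sprintf("S%03d", seq_len(n))
    ext <- if (compress) ".fastq.gz" else ".fastq"
    sheet <- data.frame(sample_id = ids,
                        fastq1 = paste0(ids, "_R1", ext),
                        fastq2 = paste0(ids, "_R2", ext),
                        label = labels, stringsAsFactors = FALSE)
    tms <- vector("list", n)
    tss <- vector("list", n)
    for (i in seq_len(n)) {
      tc <- if (labels[i] == "MSI-H")
        stats::runif(1, config$tumor_content_range[1L], config$tumor_content_range[2L])
      else 1
      sim <- simulate_sample_reads(config, labels[i], tc, mutant_fraction, ids[i])
      nm <- sprintf("%s_%06d", ids[i], seq_along(sim$r1))
      write_fastq(sim$r1, nm, file.path(dir, sheet$fastq1[i]), compress)
      write_fastq(sim$r2, nm, file.path(dir, sheet$fastq2[i]), compress)
      tms[[i]] <- sim$truth
      tss[[i]] <- data.frame(sample_id = ids[i], label = labels[i],
                             tumor_content = tc,
                             braf_alt_fraction = unname(config$braf_alt_fraction[[labels[i]]]),
                             stringsAsFactors = FALSE)
    }
    truth_markers <- do.call(rbind, tms)
    truth_samples <- do.call(rbind, tss)
    utils::write.table(sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth_markers, file.path(dir, "truth_markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth_samples, file.path(dir, "truth_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(sheet = transform(sheet,
                           fastq1 = file.path(dir, fastq1),
                           fastq2 = file.path(dir, fastq2)),
         truth_markers = truth_markers, truth_samples = truth_samples,
         mutant_fraction = mutant_fraction)
  })
}

write_fastq <- function(seqs, ids, path, compress = FALSE) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              compress = isTRUE(compress))
  invisible(path)
}
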