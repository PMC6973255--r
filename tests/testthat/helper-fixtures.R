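# Shared fixtures, built once per test run and cached. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

fx_panel <- function() fx_memo("panel", function() make_fixture_panel(6, seed = 101))

# A small labelled cohort with profiles, used by classifier / QC / in-silico
# tests: 8 MSI-H + 8 MSS, 60 templates per marker.
fx_cohort <- function() fx_memo("cohort", function() {
  panel <- fx_panel()
  dir <- file.path(tempdir(), "fx_cohort")
  cfg <- cohort_config(panel, n_msih = 8, n_mss = 8,
                       templates_per_marker = 60, het_prob = 0.5,
                       braf_alt_fraction = c("MSI-H" = 0.2, "MSS" = 0),
                       seed = 2024)
  gen <- generate_cohort(cfg, dir)
  res <- summarize_cohort(gen$sheet, panel, keep_profiles = TRUE)
  list(panel = panel, gen = gen, summaries = res$summaries,
       profiles = res$profiles)
})

fx_model <- function() fx_memo("model", function() msi_train(fx_cohort()$summaries))

# Build an mnr_profiles object directly from read records (for tests that
# exercise record-level operations without FASTQ round-trips).
profiles_from_records <- function(records, markers, sample_id = "synth") {
  structure(list(
    sample_id = sample_id, markers = markers, records = records,
    braf_records = data.frame(umi = character(0), allele = character(0),
                              stringsAsFactors = FALSE),
    marker_discarded = stats::setNames(integer(length(markers)), markers),
    counts = list(total = nrow(records), assigned = nrow(records),
                  unassigned = 0L, ambiguous = 0L, discarded = 0L)),
    class = "mnr_profiles")
}

# Simulated long-format cohort summaries (classifier-level fixture): one
# informative marker structure controlled per marker via `spec`, a list of
# lists with fields msih (function(n) deletion freqs), mss (likewise), and
# optional bias (p-value generators per class).
simulate_summaries <- function(n_msih, n_mss, spec, seed) {
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed(seed, {
    ids <- sprintf("T%03d", seq_len(n_msih + n_mss))
    labels <- c(rep("MSI-H", n_msih), rep("MSS", n_mss))
    rows <- list()
    for (mk in names(spec)) {
      s <- spec[[mk]]
      d <- c(s$msih(n_msih), s$mss(n_mss))
      p <- if (!is.null(s$bias_msih))
        c(s$bias_msih(n_msih), s$bias_mss(n_mss)) else rep(NA_real_, length(ids))
      rows[[mk]] <- data.frame(sample_id = ids, marker = mk, n_reads = 300L,
                               del_freq = d, bias_p = p,
                               heterozygous = !is.na(p), umi_count = 100L,
                               label = labels, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[order(match(out$sample_id, ids)), ]
    out$mean_umi <- 100
    rownames(out) <- NULL
    out
  })
}

# Write a FASTQ pair from explicit read sequences (test helper).
write_pair_fastq <- function(r1, r2, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  ids <- sprintf("rd%04d", seq_along(r1))
  f1 <- file.path(dir, "t_R1.fastq"); f2 <- file.path(dir, "t_R2.fastq")
  fq_lines <- function(r) if (!length(r)) character(0) else
    as.vector(rbind(paste0("@", ids), r, "+", strrep("I", nchar(r))))
  writeLines(fq_lines(r1), f1)
  writeLines(fq_lines(r2), f2)
  list(f1 = f1, f2 = f2)
}

# Construct a perfect (error-free) read pair for a marker.
perfect_pair <- function(marker, umi = "ACGTTG", repeat_length = NULL,
                         allele = "ref") {
  ins <- reference_insert(marker)
  if (!is.null(repeat_length))
    ins <- paste0(marker$insert_5p, marker$left_flank,
                  strrep(marker$repeat_unit, repeat_length),
                  marker$right_flank, marker$insert_3p)
  if (allele == "alt")
    substr(ins, marker$snp_offset + 1, marker$snp_offset + 1) <- marker$snp_alt_allele
  mol <- paste0(umi, marker$extension_arm, ins, marker$ligation_arm)
  rc <- chartr("ACGT", "TGCA", mol)
  rc <- paste(rev(strsplit(rc, "")[[1]]), collapse = "")
  list(r1 = mol, r2 = rc, insert = ins)
}
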