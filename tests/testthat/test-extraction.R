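test_that("read pairs are assigned by exact and near-exact arm matches", {
  panel <- fx_panel()
  m3 <- panel$markers[[3]]
  pp <- perfect_pair(m3, umi = "ACGTTG")
  # a pair with one substitution in the ligation arm region of read 2
  mut <- pp$r2
  substr(mut, 4, 4) <- setdiff(c("A", "C", "G", "T"), substr(mut, 4, 4))[1]
  # a pair unrelated to any marker
  junk1 <- strrep("ACGT", 30); junk2 <- strrep("TTGA", 30)
  fq <- write_pair_fastq(c(pp$r1, pp$r1, junk1), c(pp$r2, mut, junk2))
  pr <- profile_sample(fq$f1, fq$f2, panel, "t")
  expect_equal(pr$counts$total, 3L)
  expect_equal(pr$counts$assigned, 2L)
  expect_equal(pr$counts$unassigned, 1L)
  expect_equal(unique(pr$records$marker), m3$name)
  expect_equal(pr$records$umi, c("ACGTTG", "ACGTTG"))
  # agreement with the exhaustive edit-distance oracle
  expect_equal(oracle_arm_scan(pp$r1, pp$r2, panel, 6), m3$name)
  expect_equal(oracle_arm_scan(pp$r1, mut, panel, 6), m3$name)
  expect_length(oracle_arm_scan(junk1, junk2, panel, 6), 0)
  # two substitutions in one arm exceed the tolerance
  mut2 <- pp$r2
  substr(mut2, 2, 3) <- chartr("ACGT", "GTAC", substr(mut2, 2, 3))
  fq <- write_pair_fastq(pp$r1, mut2)
  pr <- profile_sample(fq$f1, fq$f2, panel, "t")
  expect_equal(pr$counts$unassigned, 1L)
})

test_that("pair consensus masks disagreements and voids touched measurements", {
  panel <- fx_panel()
  m <- panel$markers[[1]]
  pp <- perfect_pair(m)
  ins_start <- 6 + nchar(m$extension_arm)
  flip_r1 <- function(pos_in_insert) {
    r <- pp$r1
    p <- ins_start + pos_in_insert + 1
    substr(r, p, p) <- setdiff(c("A", "C", "G", "T"), substr(r, p, p))[1]
    r
  }
  snp_r1 <- flip_r1(m$snp_offset)                      # disagreement at SNP
  rep_r1 <- flip_r1(nchar(m$insert_5p) + nchar(m$left_flank) + 2)  # in repeat
  fq <- write_pair_fastq(c(pp$r1, snp_r1, rep_r1),
                         c(pp$r2, pp$r2, pp$r2))
  pr <- profile_sample(fq$f1, fq$f2, panel, "t")
  rec <- pr$records
  expect_equal(nrow(rec), 3L)
  # clean pair: full measurement
  expect_equal(rec$repeat_length[1], m$reference_repeat_length)
  expect_equal(rec$snp_allele[1], "ref")
  # SNP position masked -> allele uncalled, repeat still measured
  expect_equal(rec$snp_allele[2], "uncalled")
  expect_equal(rec$repeat_length[2], m$reference_repeat_length)
  # masked base inside the repeat tract -> unmeasurable
  expect_true(is.na(rec$repeat_length[3]))
  expect_equal(rec$snp_allele[3], "ref")
})

test_that("repeat length is anchored between exact flank matches", {
  m <- fx_panel()$markers[[2]]
  mk_ins <- function(rep_seq) paste0(m$insert_5p, m$left_flank, rep_seq,
                                     m$right_flank, m$insert_3p)
  meas <- function(ins) mnrmsi:::measure_insert(ins, m)
  ref <- strrep(m$repeat_unit, m$reference_repeat_length)
  expect_equal(meas(mk_ins(ref))$repeat_length, m$reference_repeat_length)
  # 1 bp deletion
  del <- strrep(m$repeat_unit, m$reference_repeat_length - 1)
  expect_equal(meas(mk_ins(del))$repeat_length, m$reference_repeat_length - 1L)
  # interrupted tract is unmeasurable
  other <- setdiff(c("A", "C", "G", "T"), m$repeat_unit)[1]
  inter <- paste0(strrep(m$repeat_unit, 3), other, strrep(m$repeat_unit, 3))
  expect_true(is.na(meas(mk_ins(inter))$repeat_length))
  # absent left flank anchor is unmeasurable
  no_anchor <- sub(m$left_flank, strrep(other, nchar(m$left_flank)),
                   mk_ins(ref), fixed = TRUE)
  expect_true(is.na(meas(no_anchor)$repeat_length))
  # chimeric expansions beyond reference + 10 are excluded
  huge <- strrep(m$repeat_unit, m$reference_repeat_length + 11)
  expect_true(is.na(meas(mk_ins(huge))$repeat_length))
  # SNP allele is read at its offset
  alt_ins <- mk_ins(ref)
  substr(alt_ins, m$snp_offset + 1, m$snp_offset + 1) <- m$snp_alt_allele
  expect_equal(meas(alt_ins)$snp_allele, "alt")
})

test_that("pair accounting is conserved and order-invariant", {
  co <- fx_cohort()
  pr <- co$profiles[[2]]
  expect_equal(pr$counts$assigned + pr$counts$unassigned + pr$counts$ambiguous,
               pr$counts$total)
  for (m in co$panel$markers) {
    mp <- marker_profile(pr, m$name, m$reference_repeat_length)
    expect_equal(sum(mp$length_histogram) + mp$pairs_unmeasurable +
                   mp$pairs_discarded, mp$total_pairs_assigned)
    expect_lte(sum(mp$allele_deletion_table), sum(mp$length_histogram))
    expect_lte(mp$distinct_umi_count, mp$total_pairs_assigned)
  }
  # permuting the input reads changes no derived count
  r1 <- Biostrings::readDNAStringSet(co$gen$sheet$fastq1[2], format = "fastq")
  r2 <- Biostrings::readDNAStringSet(co$gen$sheet$fastq2[2], format = "fastq")
  set.seed(9); ord <- sample(length(r1))
  d <- tempfile(); dir.create(d)
  f1 <- file.path(d, "p_R1.fastq"); f2 <- file.path(d, "p_R2.fastq")
  Biostrings::writeXStringSet(r1[ord], f1, format = "fastq")
  Biostrings::writeXStringSet(r2[ord], f2, format = "fastq")
  pr2 <- profile_sample(f1, f2, co$panel, pr$sample_id)
  expect_equal(pr2$counts, pr$counts)
  s1 <- summarize_sample(pr, co$panel); s2 <- summarize_sample(pr2, co$panel)
  expect_equal(s2, s1)
})

test_that("error-free extraction recovers generator truth exactly", {
  panel <- fx_panel()
  cfg <- cohort_config(panel, n_msih = 1, n_mss = 1, templates_per_marker = 40,
                       error_rate = 0, reads_per_template = 3,
                       fixed_reads = TRUE, seed = 77)
  gen <- generate_cohort(cfg, file.path(tempdir(), "noerr"))
  for (i in 1:2) {
    pr <- profile_sample(gen$sheet$fastq1[i], gen$sheet$fastq2[i], panel,
                         gen$sheet$sample_id[i])
    tr <- gen$truth_markers[gen$truth_markers$sample_id == gen$sheet$sample_id[i], ]
    for (m in panel$markers) {
      mp <- marker_profile(pr, m$name, m$reference_repeat_length)
      row <- tr[tr$marker == m$name, ]
      expect_equal(mp$distinct_umi_count, row$n_templates)
      expect_equal(sum(mp$length_histogram), row$n_pairs)
      expect_equal(deletion_frequency(mp$length_histogram,
                                      m$reference_repeat_length),
                   row$del_pair_fraction)
    }
  }
})

test_that("empty input yields empty, QC-flaggable profiles", {
  fq <- write_pair_fastq(character(0), character(0))
  pr <- profile_sample(fq$f1, fq$f2, fx_panel(), "empty")
  expect_equal(pr$counts$total, 0L)
  sm <- summarize_sample(pr, fx_panel())
  expect_true(all(sm$umi_count == 0))
  expect_true(all(is.na(sm$del_freq)))
  expect_equal(sm$mean_umi[1], 0)
})
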