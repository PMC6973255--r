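test_that("twofold serial mixtures reach 0.78% after six steps", {
  fr <- serial_mixture_fractions()
  expect_length(fr, 7L)
  expect_equal(fr[1], 0.5)
  expect_equal(100 * fr[7], 0.78125)
  expect_equal(fr[-1] / fr[-7], rep(0.5, 6))
})

make_mix_sources <- function(dA = 0.4, dB = 0.02, depth = 2000, seed = 3) {
  set.seed(seed)
  markers <- c("M1", "M2")
  mk_rec <- function(d, ref_len) {
    lens <- ifelse(runif(depth * 2) < d, ref_len - 1L, ref_len)
    data.frame(marker = rep(markers, each = depth),
               umi = sprintf("u%05d", seq_len(depth * 2)),
               repeat_length = as.integer(lens),
               snp_allele = sample(c("ref", "alt"), depth * 2, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  list(a = profiles_from_records(mk_rec(dA, 10L), markers, "A"),
       b = profiles_from_records(mk_rec(dB, 10L), markers, "B"))
}

test_that("read mixing is exact at the degenerate fractions and unbiased in between", {
  src <- make_mix_sources()
  m0 <- mix_profiles(src$a, src$b, 0)
  expect_identical(m0$records, src$b$records)       # take-all at p = 0
  m1 <- mix_profiles(src$a, src$b, 1)
  expect_identical(m1$records, src$a$records)
  mhalf <- mix_profiles(src$a, src$b, 0.5, seed = 11)
  d_obs <- mean(mhalf$records$repeat_length < 10L)
  # expectation p*dA + (1-p)*dB = 0.21 at depth 2000 per marker
  expect_lt(abs(d_obs - 0.21), 3 * sqrt(0.21 * 0.79 / nrow(mhalf$records)) + 0.01)
  # depth matches the shallower source per marker
  expect_equal(nrow(mhalf$records), 2L * 2000L)
  # deterministic given the seed, without touching the caller's RNG
  set.seed(123); before <- runif(1)
  mrep <- mix_profiles(src$a, src$b, 0.5, seed = 11)
  expect_identical(mrep$records, mhalf$records)
  set.seed(123); expect_identical(runif(1), before)
})

test_that("empty mixture sources are rejected", {
  src <- make_mix_sources(depth = 50)
  empty <- profiles_from_records(src$a$records[0, ], src$a$markers, "E")
  expect_error(mix_profiles(src$a, empty, 0.5), "empty")
  expect_error(mix_profiles(src$a, src$b, 1.2), "\\[0, 1\\]")
})

test_that("mixture grids report per-fraction MSI-H call proportions on the grid", {
  co <- fx_cohort()
  model <- fx_model()
  lab <- co$gen$truth_samples
  ph <- co$profiles[lab$sample_id[lab$label == "MSI-H"][1:2]]
  ps <- co$profiles[lab$sample_id[lab$label == "MSS"][1:2]]
  mx <- mixture_grid(ph, ps, co$panel, model, fractions = c(0, 0.5, 1),
                     seed = 42)
  expect_equal(nrow(mx$by_fraction), 3L)
  expect_equal(mx$by_fraction$prop_msih[1], 0)   # pure MSS
  expect_equal(mx$by_fraction$prop_msih[3], 1)   # pure MSI-H
  expect_true(all(mx$by_fraction$prop_msih >= 0 & mx$by_fraction$prop_msih <= 1))
  # detection limit is reported on the evaluated grid only
  expect_true(is.na(mx$detection_limit) ||
                mx$detection_limit %in% c(0, 0.5, 1))
  mx2 <- mixture_grid(ph, ps, co$panel, model, fractions = c(0, 0.5, 1),
                      seed = 42)
  expect_identical(mx2$results, mx$results)
})

test_that("mixed deletion frequencies track their expectation linearly", {
  co <- fx_cohort()
  lab <- co$gen$truth_samples
  pa <- co$profiles[[lab$sample_id[lab$label == "MSI-H"][1]]]
  pb <- co$profiles[[lab$sample_id[lab$label == "MSS"][1]]]
  del_freq_by_marker <- function(pr) vapply(co$panel$markers, function(m) {
    mp <- marker_profile(pr, m$name, m$reference_repeat_length)
    deletion_frequency(mp$length_histogram, m$reference_repeat_length)
  }, numeric(1))
  dA <- del_freq_by_marker(pa); dB <- del_freq_by_marker(pb)
  obs <- NULL; expd <- NULL
  for (p in c(0, 0.25, 0.5, 0.75, 1)) {
    mx <- mix_profiles(pa, pb, p, seed = 100 + round(100 * p))
    obs <- c(obs, del_freq_by_marker(mx))
    expd <- c(expd, p * dA + (1 - p) * dB)
  }
  fit <- stats::lm(obs ~ expd)
  expect_lt(abs(coef(fit)[["expd"]] - 1), 0.1)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("barcode resampling at full depth reproduces the baseline score", {
  co <- fx_cohort()
  model <- fx_model()
  pr <- co$profiles[[1]]
  base <- predict(model, summarize_sample(pr, co$panel))
  full_mean <- summarize_sample(pr, co$panel)$mean_umi[1]
  dl <- resample_umis(pr, co$panel, model, targets = full_mean, reps = 3,
                      seed = 8)
  expect_equal(dl$baseline_call, base$call)
  expect_true(all(dl$results$match))
  expect_equal(unique(dl$results$score), base$score)
  # infeasible targets are skipped with a warning
  expect_warning(
    dl2 <- resample_umis(pr, co$panel, model, targets = c(5, 10 * full_mean),
                         reps = 2, seed = 8), "skipping")
  expect_equal(dl2$by_target$target, 5)
  # determinism under a fixed seed
  dl3 <- resample_umis(pr, co$panel, model, targets = 5, reps = 2, seed = 8)
  dl4 <- resample_umis(pr, co$panel, model, targets = 5, reps = 2, seed = 8)
  expect_identical(dl3$results, dl4$results)
})
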