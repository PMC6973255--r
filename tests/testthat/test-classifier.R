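test_that("deletion frequency counts only lengths below the reference", {
  expect_equal(deletion_frequency(c(`10` = 85, `9` = 10, `8` = 5), 10), 0.15)
  expect_equal(deletion_frequency(c(`10` = 100), 10), 0)
  # insertions stay in the denominator without counting as deletions
  expect_equal(deletion_frequency(c(`11` = 5, `10` = 80, `9` = 15), 10), 0.15)
  expect_true(is.na(deletion_frequency(integer(0), 10)))
})

test_that("training reproduces the Laplace estimator and percentile thresholds", {
  # one marker: 50 MSI-H of which 45 exceed the threshold, 20 MSS samples
  # with deletion frequencies 0.01..0.20
  mss_d <- seq(0.01, 0.20, by = 0.01)
  thr <- 0.1905                      # 95th percentile of the MSS values
  msih_d <- c(rep(0.30, 45), rep(0.10, 5))
  sm <- data.frame(
    sample_id = sprintf("s%02d", 1:70),
    marker = "M1",
    del_freq = c(msih_d, mss_d),
    bias_p = NA_real_,
    label = c(rep("MSI-H", 50), rep("MSS", 20)))
  fit <- msi_train(sm)
  expect_equal(fit$params$threshold, thr)
  expect_equal(fit$params$p_d_msih, 46 / 52)   # (45 + 1) / (50 + 2)
  expect_equal(fit$params$p_d_mss, (1 + 1) / (20 + 2))
  # no allelic-bias observations anywhere -> uninformative 0.5/0.5, flagged
  expect_true(fit$params$b_flagged)
  expect_equal(fit$params$p_b_msih, 0.5)
  expect_equal(fit$params$p_b_mss, 0.5)
  expect_equal(c(fit$n_msih, fit$n_mss), c(50L, 20L))
})

test_that("relabelling the classes swaps the probability tables exactly", {
  # both classes carry the same deletion-frequency multiset, so the MSS 95th
  # percentile threshold -- and hence every trait -- is invariant under
  # relabelling, and the conditional tables must swap exactly
  vals <- function(n) seq(0.01, by = 0.013, length.out = n)
  sm <- simulate_summaries(12, 12, list(
    M1 = list(msih = vals, mss = vals),
    M2 = list(msih = function(n) rev(vals(n)), mss = function(n) rev(vals(n)))),
    seed = 31)
  sm$del_freq <- sm$del_freq + ifelse(sm$label == "MSI-H", 0.2, 0)
  f1 <- msi_train(sm)
  # hand the MSI-H data to the MSS label and vice versa: the estimator must
  # be symmetric in the class roles, so every parameter reappears with the
  # class-conditional tables exchanged along with the data
  sm2 <- sm
  sm2$del_freq <- sm$del_freq - ifelse(sm$label == "MSI-H", 0.2, -0.2)
  sm2$label <- ifelse(sm$label == "MSI-H", "MSS", "MSI-H")
  f2 <- msi_train(sm2)
  expect_equal(f2$n_msih, f1$n_mss)
  expect_equal(f2$n_mss, f1$n_msih)
  expect_equal(f2$params$threshold, f1$params$threshold)
  expect_equal(f2$params$p_d_msih, f1$params$p_d_msih)
  expect_equal(f2$params$p_d_mss, f1$params$p_d_mss)
})

test_that("scores follow the additive log-odds arithmetic", {
  model <- structure(list(
    markers = c("M1", "M2"),
    params = data.frame(marker = c("M1", "M2"),
                        threshold = c(0.10, 0.10),
                        p_d_msih = c(0.9, 0.5), p_d_mss = c(0.05, 0.5),
                        p_b_msih = c(0.5, 0.5), p_b_mss = c(0.5, 0.5),
                        b_flagged = FALSE),
    prior_mss = 0.85, kappa = 1, p_cut = 0.05, qc_threshold = 75,
    n_msih = 10L, n_mss = 10L, version = 1L), class = "msi_classifier")
  new_sm <- function(d1, d2, p1 = NA, p2 = NA) data.frame(
    sample_id = "x", marker = c("M1", "M2"), del_freq = c(d1, d2),
    bias_p = c(p1, p2), mean_umi = 100)
  # prior only: a lone marker with equal class probabilities leaves the
  # prior odds untouched
  only_m2 <- data.frame(sample_id = "x", marker = "M2", del_freq = 0.5,
                        bias_p = NA_real_, mean_umi = 100)
  expect_warning(pr0 <- predict(model, only_m2), "1 of 2")
  expect_equal(pr0$score, log10(0.15 / 0.85))
  expect_equal(round(pr0$score, 3), -0.753)
  expect_equal(pr0$call, "MSS")
  pr <- predict(model, new_sm(0.05, NA))
  expect_equal(pr$score, log10(0.15 / 0.85) + log10((1 - 0.9) / (1 - 0.05)))
  expect_equal(pr$call, "MSS")
  # M2 carries no information: D=1 at equal probabilities shifts nothing
  pr2 <- predict(model, new_sm(0.05, 0.5))
  expect_equal(pr2$score, pr$score)
  # D=1 on the informative marker
  pr3 <- predict(model, new_sm(0.2, NA))
  expect_equal(pr3$score, log10(0.15 * 0.9 / (0.85 * 0.05)))
  expect_equal(round(pr3$score, 3), 0.502)
  expect_equal(pr3$call, "MSI-H")
  # marker order in the input is irrelevant
  rev_sm <- new_sm(0.2, 0.5)[2:1, ]
  expect_equal(predict(model, rev_sm)$score, predict(model, new_sm(0.2, 0.5))$score)
  # B trait adds its own term
  model$params$p_b_msih <- c(0.8, 0.5); model$params$p_b_mss <- c(0.1, 0.5)
  pr4 <- predict(model, new_sm(0.2, NA, p1 = 0.01))
  expect_equal(pr4$score, log10(0.15 * 0.9 * 0.8 / (0.85 * 0.05 * 0.1)))
  # all traits missing on every marker is unscorable
  expect_error(predict(model, new_sm(NA, NA)), "unscorable")
})

test_that("dichotomization uses strict boundaries", {
  model <- fx_model()
  mk <- model$markers[1]
  t1 <- model$params$threshold[1]
  sm <- data.frame(sample_id = c("a", "b", "c"), marker = mk,
                   del_freq = c(t1, t1 + 1e-9, t1 - 1e-9),
                   bias_p = c(0.05, 0.04999, 0.05001))
  tr <- dichotomize(sm, model)
  expect_equal(tr$D, c(0L, 1L, 0L))   # equality is NOT above the threshold
  expect_equal(tr$B, c(0L, 1L, 0L))   # p = .05 is NOT below the cut
})

test_that("changing the prior shifts every score by a constant", {
  co <- fx_cohort()
  f85 <- msi_train(co$summaries, prior_mss = 0.85)
  f50 <- msi_train(co$summaries, prior_mss = 0.50)
  s85 <- predict(f85, co$summaries)$score
  s50 <- predict(f50, co$summaries)$score
  expect_equal(s50 - s85, rep(-log10(0.15 / 0.85), length(s85)))
})

test_that("score is monotone in deletion frequency across the threshold", {
  model <- fx_model()
  mk <- model$markers[2]
  stopifnot(model$params$p_d_msih[2] > model$params$p_d_mss[2])
  base <- fx_cohort()$summaries
  one <- base[base$sample_id == base$sample_id[1], ]
  low <- one; low$del_freq[low$marker == mk] <- model$params$threshold[2] - 0.01
  high <- one; high$del_freq[high$marker == mk] <- model$params$threshold[2] + 0.01
  expect_gt(predict(model, high)$score, predict(model, low)$score)
})

test_that("evaluation reports exact confidence intervals", {
  preds <- data.frame(sample_id = sprintf("s%d", 1:98),
                      call = c(rep("MSI-H", 51), rep("MSS", 47)))
  labels <- stats::setNames(c(rep("MSI-H", 51), rep("MSS", 47)), preds$sample_id)
  ev <- evaluate_classifier(preds, labels)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(round(100 * ev$sensitivity_ci[["lower"]], 1), 93.0)
  expect_equal(round(100 * ev$specificity_ci[["lower"]], 1), 92.5)
  # 9 of 10 correct MSI-H
  preds2 <- data.frame(sample_id = sprintf("t%d", 1:10),
                       call = c(rep("MSI-H", 9), "MSS"))
  ev2 <- suppressWarnings(evaluate_classifier(preds2, rep("MSI-H", 10)))
  expect_equal(ev2$sensitivity, 0.9)
  expect_warning(evaluate_classifier(preds2, rep("MSI-H", 10)), "empty")
  # all wrong: symmetric bound
  preds3 <- data.frame(sample_id = preds$sample_id,
                       call = ifelse(preds$call == "MSI-H", "MSS", "MSI-H"))
  ev3 <- suppressWarnings(evaluate_classifier(preds3, labels))
  expect_equal(ev3$sensitivity, 0)
  expect_equal(ev3$sensitivity_ci[["upper"]], 1 - 0.025^(1 / 51), tolerance = 1e-10)
})

test_that("trained trait probabilities recover generator rates as n grows", {
  p_true <- 0.75
  sm <- simulate_summaries(200, 200, list(
    M1 = list(msih = function(n) ifelse(runif(n) < p_true, 0.4, 0.0),
              mss = function(n) rep(0.0, n))), seed = 13)
  fit <- msi_train(sm)
  # threshold sits at 0 (all MSS identical), so D=1 iff d > 0
  expect_equal(fit$params$threshold, 0)
  expect_lt(abs(fit$params$p_d_msih - p_true), 3 * sqrt(p_true * (1 - p_true) / 200))
})

test_that("barcode-collapsed summaries are available as an alternative mode", {
  co <- fx_cohort()
  sm <- summarize_sample(co$profiles[[1]], co$panel, umi_collapse = TRUE)
  expect_equal(nrow(sm), 6L)
  raw <- summarize_sample(co$profiles[[1]], co$panel)
  # collapsing can only reduce the number of observations per marker
  expect_true(all(sm$n_reads <= raw$n_reads))
})
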