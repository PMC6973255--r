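# Independent oracles, deliberately written from first principles and kept
# free of the package's own implementation paths.

# Two-sided Fisher p-value by direct enumeration of the hypergeometric
# support using binomial coefficients.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  denom <- choose(m + n, k)
  probs <- vapply(lo:hi, function(i) choose(m, i) * choose(n, k - i) / denom,
                  numeric(1))
  p_obs <- probs[a - lo + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Type-7 95th percentile, hand-coded (rank 0.95*(n-1)+1 interpolation).
oracle_pctl95 <- function(v) {
  v <- sort(v)
  h <- 0.95 * (length(v) - 1) + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
}

# Leave-one-out naive Bayes accuracy for a marker subset, via plain loops:
# retrains thresholds and Laplace-smoothed trait probabilities without each
# held-out sample and scores that sample on its own traits.
oracle_loo_accuracy <- function(d, p, labels, subset, prior_mss = 0.85,
                                kappa = 1, p_cut = 0.05) {
  n <- nrow(d)
  correct <- logical(n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    score <- log10((1 - prior_mss) / prior_mss)
    for (mk in subset) {
      thr <- oracle_pctl95(d[intersect(keep, which(labels == "MSS")), mk])
      D <- d[, mk] > thr
      B <- p[, mk] < p_cut
      prob <- function(tr, cls, val) {
        tr_k <- tr[intersect(keep, which(labels == cls))]
        tr_k <- tr_k[!is.na(tr_k)]
        pr1 <- (sum(tr_k) + kappa) / (length(tr_k) + 2 * kappa)
        if (val) pr1 else 1 - pr1
      }
      if (!is.na(D[i]))
        score <- score + log10(prob(D, "MSI-H", D[i]) / prob(D, "MSS", D[i]))
      if (!is.na(B[i])) {
        n_obs <- sum(!is.na(B[keep]))
        if (n_obs > 0)
          score <- score + log10(prob(B, "MSI-H", B[i]) / prob(B, "MSS", B[i]))
      }
    }
    call <- if (score > 0) "MSI-H" else if (score < 0) "MSS" else "none"
    correct[i] <- call == labels[i]
  }
  mean(correct)
}

# Exhaustive edit-distance scan of a read region against every probe arm
# (oracle for arm-anchored assignment).
oracle_arm_scan <- function(read1, read2, panel, umi_len, tol = 1) {
  hits <- character(0)
  for (m in panel$markers) {
    r1arm <- substr(read1, umi_len + 1, umi_len + nchar(m$extension_arm))
    rc <- function(s) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    r2arm <- substr(read2, 1, nchar(m$ligation_arm))
    d1 <- utils::adist(r1arm, m$extension_arm)
    d2 <- utils::adist(r2arm, rc(m$ligation_arm))
    if (d1 <= tol && d2 <= tol) hits <- c(hits, m$name)
  }
  hits
}
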