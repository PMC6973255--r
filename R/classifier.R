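#' Train the naive Bayes MSI classifier
#'
#' Estimates the classifier's parameters from a labelled training cohort.
#' For every marker, a sample contributes two binary traits: `D` -- its
#' deletion frequency exceeds the marker threshold (the 95th percentile of
#' the deletion frequencies of the MSS training samples, strict `>`) -- and
#' `B` -- its allelic-bias Fisher p-value is below `p_cut` (strict `<`,
#' default .05; only defined for samples heterozygous at the linked SNP).
#' Trait probabilities per class are estimated with Laplace smoothing:
#' `P(trait = 1 | class) = (count + kappa) / (n + 2 * kappa)`, where `n`
#' counts the samples in which the trait was observed (so `B` probabilities
#' are conditioned on heterozygosity). A new sample's score is the decadic
#' log odds of MSI-H versus MSS under a prior MSS probability of 0.85.
#'
#' @param summaries Long-format cohort summaries from [summarize_cohort()]
#'   (columns `sample_id`, `marker`, `del_freq`, `bias_p`, optionally
#'   `label`, `umi_count`, `mean_umi`).
#' @param labels Reference labels (`"MSI-H"`/`"MSS"`), either a vector named
#'   by sample id, or `NULL` to use the `label` column of `summaries`.
#'   MSI-low samples are labelled MSS upstream, per the reference-standard
#'   convention.
#' @param markers Markers to train on (default: all markers present).
#' @param prior_mss Prior probability that a sample is MSS (default .85).
#' @param kappa Laplace smoothing pseudocount (default 1).
#' @param p_cut Allelic-bias dichotomization cut (default .05).
#' @param qc_threshold Mean barcodes per marker required for QC pass
#'   (default 75); advisory, never suppresses a classification.
#' @return An object of class `"msi_classifier"` with `print()`,
#'   `summary()`, `coef()` and `predict()` methods.
#' @examples
#' \dontrun{
#' fit <- msi_train(train_summaries)
#' predict(fit, test_summaries)
#' }
#' @export
msi_train <- function(summaries, labels = NULL, markers = NULL,
                      prior_mss = 0.85, kappa = 1, p_cut = 0.05,
                      qc_threshold = 75) {
  if (prior_mss <= 0 || prior_mss >= 1) stop("prior_mss must be in (0, 1)")
  if (kappa <= 0) stop("kappa must be positive for smoothed probabilities")
  mats <- summaries_to_matrices(summaries, markers)
  labels <- resolve_labels(summaries, labels, rownames(mats$d))
  n_msih <- sum(labels == "MSI-H"); n_mss <- sum(labels == "MSS")
  if (n_msih < 2L || n_mss < 2L)
    stop("training requires at least 2 samples in each class")
  d <- mats$d; p <- mats$p
  mss <- labels == "MSS"
  if (anyNA(d[mss, , drop = FALSE])) {
    bad <- colnames(d)[colSums(is.na(d[mss, , drop = FALSE])) > 0]
    stop("every MSS training sample needs a defined deletion frequency; missing for marker(s): ",
         paste(bad, collapse = ", "))
  }
  thr <- apply(d[mss, , drop = FALSE], 2L, percentile_95)
  D <- sweep(d, 2L, thr, ">")
  B <- p < p_cut
  est <- function(tr, class) {
    obs <- colSums(!is.na(tr[labels == class, , drop = FALSE]))
    ones <- colSums(tr[labels == class, , drop = FALSE], na.rm = TRUE)
    (ones + kappa) / (obs + 2 * kappa)
  }
  p_d_msih <- est(D, "MSI-H"); p_d_mss <- est(D, "MSS")
  p_b_msih <- est(B, "MSI-H"); p_b_mss <- est(B, "MSS")
  b_obs <- colSums(!is.na(B))
  b_flagged <- b_obs == 0L
  p_b_msih[b_flagged] <- 0.5
  p_b_mss[b_flagged] <- 0.5
  params <- data.frame(marker = colnames(d), threshold = unname(thr),
                       p_d_msih = unname(p_d_msih), p_d_mss = unname(p_d_mss),
                       p_b_msih = unname(p_b_msih), p_b_mss = unname(p_b_mss),
                       b_flagged = unname(b_flagged), stringsAsFactors = FALSE)
  structure(list(markers = colnames(d), params = params,
                 prior_mss = prior_mss, kappa = kappa, p_cut = p_cut,
                 qc_threshold = qc_threshold, n_msih = n_msih, n_mss = n_mss,
                 version = MODEL_VERSION, call = match.call()),
            class = "msi_classifier")
}

# Long summaries -> samples x markers matrices of del_freq and bias_p,
# preserving first-seen order of samples and markers.
summaries_to_matrices <- function(summaries, markers = NULL) {
  need <- c("sample_id", "marker", "del_freq", "bias_p")
  if (!all(need %in% names(summaries)))
    stop("summaries must have columns: ", paste(need, collapse = ", "))
  samples <- unique(summaries$sample_id)
  mk <- if (is.null(markers)) unique(summaries$marker) else markers
  shape <- function(col) {
    m <- matrix(NA_real_, length(samples), length(mk),
                dimnames = list(samples, mk))
    keep <- summaries$marker %in% mk
    m[cbind(match(summaries$sample_id[keep], samples),
            match(summaries$marker[keep], mk))] <- summaries[[col]][keep]
    m
  }
  list(d = shape("del_freq"), p = shape("bias_p"))
}

resolve_labels <- function(summaries, labels, samples) {
  if (is.null(labels)) {
    if (is.null(summaries$label))
      stop("no labels: supply `labels` or a `label` column in summaries")
    labels <- stats::setNames(
      summaries$label[match(samples, summaries$sample_id)], samples)
  } else if (!is.null(names(labels))) {
    labels <- labels[samples]
  } else if (length(labels) != length(samples)) {
    stop("unnamed `labels` must have one entry per sample")
  }
  labels <- as.character(labels)
  if (anyNA(labels) || !all(labels %in% c("MSI-H", "MSS")))
    stop("labels must be 'MSI-H' or 'MSS' for every sample")
  stats::setNames(labels, samples)
}

MODEL_VERSION <- 1L

#' Dichotomize per-marker summaries into binary traits
#'
#' @param summaries Long-format summaries for one or more samples.
#' @param model A fitted [msi_train()] model supplying per-marker thresholds
#'   and the p-value cut.
#' @return A data.frame `sample_id`, `marker`, `D`, `B` (integer 0/1, `NA`
#'   when the underlying quantity is missing). `D = 1` iff the deletion
#'   frequency strictly exceeds the marker threshold; `B = 1` iff the
#'   allelic-bias p-value is strictly below the cut.
#' @export
dichotomize <- function(summaries, model) {
  stopifnot(inherits(model, "msi_classifier"))
  mk <- intersect(model$markers, unique(summaries$marker))
  mats <- summaries_to_matrices(summaries, mk)
  thr <- model$params$threshold[match(mk, model$params$marker)]
  D <- sweep(mats$d, 2L, thr, ">")
  B <- mats$p < model$p_cut
  out <- data.frame(
    sample_id = rep(rownames(D), times = ncol(D)),
    marker = rep(colnames(D), each = nrow(D)),
    D = as.integer(D), B = as.integer(B), stringsAsFactors = FALSE)
  out[order(match(out$sample_id, rownames(D))), , drop = FALSE]
}

#' Score samples with a fitted MSI classifier
#'
#' Computes each sample's decadic log-odds score
#' `log10((1 - prior) / prior) + sum_m log10 P(trait_m | MSI-H) / P(trait_m | MSS)`
#' over the markers shared between the model and the data; missing traits
#' contribute nothing. Scores above 0 call MSI-H, below 0 MSS; an exact 0 is
#' reported as `indeterminate`.
#'
#' @param object A fitted `"msi_classifier"`.
#' @param newdata Long-format summaries from [summarize_cohort()] /
#'   [summarize_sample()].
#' @param ... Unused.
#' @return A data.frame with one row per sample: `sample_id`, `score`,
#'   `call`, `markers_used`, `mean_umi`, `qc_pass`; per-marker traits are
#'   attached as attribute `"traits"`.
#' @export
predict.msi_classifier <- function(object, newdata, ...) {
  mk <- intersect(object$markers, unique(newdata$marker))
  if (!length(mk)) stop("no model markers present in the data")
  if (length(mk) < length(object$markers))
    warning(sprintf("scoring restricted to %d of %d model markers present in the data",
                    length(mk), length(object$markers)))
  mats <- summaries_to_matrices(newdata, mk)
  pp <- object$params[match(mk, object$params$marker), ]
  D <- sweep(mats$d, 2L, pp$threshold, ">")
  B <- mats$p < object$p_cut
  llr_d <- ifelse(is.na(D), 0,
                  ifelse(D, log10(pp$p_d_msih / pp$p_d_mss)[col(D)],
                         log10((1 - pp$p_d_msih) / (1 - pp$p_d_mss))[col(D)]))
  llr_b <- ifelse(is.na(B), 0,
                  ifelse(B, log10(pp$p_b_msih / pp$p_b_mss)[col(B)],
                         log10((1 - pp$p_b_msih) / (1 - pp$p_b_mss))[col(B)]))
  used <- rowSums(!is.na(D))
  if (any(used == 0L))
    stop("unscorable sample (no marker with a measurable deletion frequency): ",
         paste(rownames(D)[used == 0L], collapse = ", "))
  score <- log10((1 - object$prior_mss) / object$prior_mss) +
    rowSums(llr_d) + rowSums(llr_b)
  call <- ifelse(score > 0, "MSI-H", ifelse(score < 0, "MSS", "indeterminate"))
  mean_umi <- if (!is.null(newdata$mean_umi))
    newdata$mean_umi[match(rownames(D), newdata$sample_id)] else NA_real_
  out <- data.frame(sample_id = rownames(D), score = unname(score),
                    call = unname(call), markers_used = unname(used),
                    mean_umi = unname(mean_umi),
                    qc_pass = unname(mean_umi >= object$qc_threshold),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "traits") <- data.frame(
    sample_id = rep(rownames(D), ncol(D)), marker = rep(mk, each = nrow(D)),
    D = as.integer(D), B = as.integer(B), stringsAsFactors = FALSE)
  out
}

#' @export
print.msi_classifier <- function(x, ...) {
  cat(sprintf("MSI naive Bayes classifier (%d markers)\n", length(x$markers)))
  cat(sprintf("  trained on %d MSI-H / %d MSS samples\n", x$n_msih, x$n_mss))
  cat(sprintf("  prior P(MSS) = %.2f, smoothing kappa = %g, p cut = %.2f\n",
              x$prior_mss, x$kappa, x$p_cut))
  invisible(x)
}

#' @export
summary.msi_classifier <- function(object, ...) {
  structure(list(model = object), class = "summary.msi_classifier")
}

#' @export
print.summary.msi_classifier <- function(x, ...) {
  print(x$model)
  p <- x$model$params
  p$llr_d1 <- round(log10(p$p_d_msih / p$p_d_mss), 3)
  print(p, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.msi_classifier <- function(object, ...) object$params

#' Evaluate classifier calls against reference labels
#'
#' @param predictions A data.frame from [predict.msi_classifier()] (or any
#'   with `sample_id` and `call`).
#' @param labels Reference labels, named by sample id or aligned with
#'   `predictions`.
#' @param conf Confidence level for the exact binomial intervals.
#' @return A list of class `"msi_evaluation"`: `sensitivity`, `specificity`
#'   (proportions), their exact Clopper-Pearson `conf` intervals, and the
#'   class tallies.
#' @export
evaluate_classifier <- function(predictions, labels, conf = 0.95) {
  if (!is.null(names(labels))) labels <- labels[predictions$sample_id]
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(predictions))
  h <- labels == "MSI-H"; s <- labels == "MSS"
  if (!any(h) || !any(s))
    warning("a class is empty; the corresponding rate is undefined")
  x_sens <- sum(predictions$call[h] == "MSI-H"); n_sens <- sum(h)
  x_spec <- sum(predictions$call[s] == "MSS"); n_spec <- sum(s)
  structure(list(
    sensitivity = if (n_sens) x_sens / n_sens else NA_real_,
    specificity = if (n_spec) x_spec / n_spec else NA_real_,
    sensitivity_ci = if (n_sens) clopper_pearson(x_sens, n_sens, conf) else c(NA, NA),
    specificity_ci = if (n_spec) clopper_pearson(x_spec, n_spec, conf) else c(NA, NA),
    n_msih = n_sens, n_mss = n_spec, conf = conf), class = "msi_evaluation")
}

#' @export
print.msi_evaluation <- function(x, ...) {
  pct <- function(v) sprintf("%.1f%%", 100 * v)
  cat(sprintf("sensitivity %s (%d MSI-H; %d%% CI %s-%s)\n",
              pct(x$sensitivity), x$n_msih, round(100 * x$conf),
              pct(x$sensitivity_ci[1]), pct(x$sensitivity_ci[2])))
  cat(sprintf("specificity %s (%d MSS;   %d%% CI %s-%s)\n",
              pct(x$specificity), x$n_mss, round(100 * x$conf),
              pct(x$specificity_ci[1]), pct(x$specificity_ci[2])))
  invisible(x)
}

#' Save / load a fitted classifier
#'
#' The model file is versioned JSON carrying every parameter at full
#' precision plus the training-set sizes. Loading refuses files whose
#' format tag or version does not match.
#'
#' @param model A fitted `"msi_classifier"`.
#' @param path File path.
#' @return `load_model()` returns the `"msi_classifier"`; `save_model()`
#'   returns `path` invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "msi_classifier"))
  j <- list(format = "mnrmsi-model", version = model$version,
            markers = model$markers,
            params = model$params,
            prior_mss = model$prior_mss, kappa = model$kappa,
            p_cut = model$p_cut, qc_threshold = model$qc_threshold,
            n_msih = model$n_msih, n_mss = model$n_mss)
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("cannot parse model file: ",
                                         conditionMessage(e)))
  if (is.null(j$format) || j$format != "mnrmsi-model")
    stop("not a model file (missing format tag)")
  if (is.null(j$version) || j$version != MODEL_VERSION)
    stop("unsupported model version: ", j$version)
  need <- c("markers", "params", "prior_mss", "kappa", "p_cut",
            "qc_threshold", "n_msih", "n_mss")
  if (!all(need %in% names(j))) stop("truncated or invalid model file")
  structure(list(markers = j$markers,
                 params = as.data.frame(j$params, stringsAsFactors = FALSE),
                 prior_mss = j$prior_mss, kappa = j$kappa, p_cut = j$p_cut,
                 qc_threshold = j$qc_threshold, n_msih = j$n_msih,
                 n_mss = j$n_mss, version = j$version, call = NULL),
            class = "msi_classifier")
}
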