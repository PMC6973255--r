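# In-silico detection-limit experiments: read mixing (tumor-content limit)
# and molecular-barcode resampling (template-number limit). Both operate on
# extracted read records -- a read keeps its repeat length, SNP allele and
# barcode together -- because the allelic-bias trait depends on their joint
# distribution, not on marginal histograms.

#' Mix reads of an MSI-H and an MSS sample in a predetermined proportion
#'
#' Per marker, draws reads without replacement from the two source samples
#' so that the expected fraction originating from `a` is `p`, at a total
#' depth matched to the shallower source (the number from `a` is binomial
#' `(depth, p)`, the remainder from `b`). At `p = 0` or `p = 1` the
#' corresponding source is taken verbatim at full depth ("take-all").
#'
#' @param a,b `"mnr_profiles"` of the MSI-H and MSS source samples, profiled
#'   on the same panel.
#' @param p Fraction of reads from `a`, in `[0, 1]`.
#' @param seed Optional seed for a reproducible draw (the caller's RNG state
#'   is untouched).
#' @return A synthetic `"mnr_profiles"` object (BRAF records are not mixed).
#' @export
mix_profiles <- function(a, b, p, seed = NULL) {
  stopifnot(inherits(a, "mnr_profiles"), inherits(b, "mnr_profiles"))
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (!identical(a$markers, b$markers))
    stop("profiles must come from the same panel")
  if (!nrow(a$records) || !nrow(b$records)) stop("empty source profile")
  with_seed(seed, {
    rows <- lapply(a$markers, function(mk) {
      ra <- a$records[a$records$marker == mk, , drop = FALSE]
      rb <- b$records[b$records$marker == mk, , drop = FALSE]
      if (p == 1) return(ra)
      if (p == 0) return(rb)
      depth <- min(nrow(ra), nrow(rb))
      if (depth == 0L) return(ra[0L, ])
      ka <- stats::rbinom(1L, depth, p)
      rbind(ra[sample.int(nrow(ra), ka), , drop = FALSE],
            rb[sample.int(nrow(rb), depth - ka), , drop = FALSE])
    })
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    structure(list(
      sample_id = sprintf("%s:%s@%.4f", a$sample_id, b$sample_id, p),
      markers = a$markers, records = records,
      braf_records = a$braf_records[0L, , drop = FALSE],
      marker_discarded = stats::setNames(integer(length(a$markers)), a$markers),
      counts = list(total = nrow(records), assigned = nrow(records),
                    unassigned = 0L, ambiguous = 0L, discarded = 0L)),
      class = "mnr_profiles")
  })
}

#' Read-mixture detection-limit experiment
#'
#' Classifies in-silico read mixtures of every supplied MSI-H x MSS sample
#' pair over a grid of MSI-H read fractions, reporting the proportion of
#' mixtures called MSI-H at each fraction and the detection limit: the
#' smallest grid fraction at which that proportion exceeds `level`
#' (no interpolation -- limits are reported on the evaluated grid only).
#'
#' @param profiles_msih,profiles_mss Named lists of `"mnr_profiles"` for the
#'   two classes (e.g. from [summarize_cohort()] with
#'   `keep_profiles = TRUE`).
#' @param panel The [mnr_panel()].
#' @param model A fitted [msi_train()] classifier.
#' @param fractions Grid of MSI-H read fractions in `[0, 1]`.
#' @param reps Independent mixture draws per pair and fraction (default 1;
#'   the pairwise combinations already replicate each fraction).
#' @param seed Seed for the whole experiment (recorded in the result).
#' @param level Reliability level defining the detection limit
#'   (default 0.95).
#' @param ... Passed to [summarize_sample()].
#' @return An object of class `"mixture_result"`: `results` (one row per
#'   mixture: pair, fraction, rep, score, call), `by_fraction` (proportion
#'   called MSI-H per fraction), `detection_limit`, `seed`.
#' @export
mixture_grid <- function(profiles_msih, profiles_mss, panel, model,
                         fractions = seq(0, 1, by = 0.1), reps = 1L,
                         seed = 1L, level = 0.95, ...) {
  grid <- expand.grid(h = seq_along(profiles_msih),
                      s = seq_along(profiles_mss),
                      p = fractions, rep = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      mixed <- mix_profiles(profiles_msih[[g$h]], profiles_mss[[g$s]], g$p)
      sm <- summarize_sample(mixed, panel, ...)
      pr <- predict(model, sm)
      data.frame(msih = profiles_msih[[g$h]]$sample_id,
                 mss = profiles_mss[[g$s]]$sample_id,
                 fraction = g$p, rep = g$rep,
                 score = pr$score, call = pr$call, stringsAsFactors = FALSE)
    })
    results <- do.call(rbind, rows)
  })
  prop <- vapply(split(results$call == "MSI-H", results$fraction), mean,
                 numeric(1))
  by_fraction <- data.frame(fraction = as.numeric(names(prop)),
                            prop_msih = unname(prop))
  by_fraction <- by_fraction[order(by_fraction$fraction), , drop = FALSE]
  lim <- by_fraction$fraction[by_fraction$prop_msih > level]
  structure(list(results = results, by_fraction = by_fraction,
                 detection_limit = if (length(lim)) min(lim) else NA_real_,
                 level = level, seed = seed), class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  cat("read-mixture experiment (proportion called MSI-H by MSI-H read fraction):\n")
  print(x$by_fraction, row.names = FALSE, digits = 3)
  cat(sprintf("detection limit (> %.0f%% called MSI-H): %s\n", 100 * x$level,
              if (is.na(x$detection_limit)) "not reached on grid"
              else format(x$detection_limit)))
  invisible(x)
}

#' Molecular-barcode resampling (template-dilution) experiment
#'
#' Emulates sequencing fewer template molecules by subsampling distinct
#' molecular barcodes per marker (keeping all reads of a kept barcode) down
#' to a target mean barcode count per marker, then re-classifying. Per
#' target, reports the proportion of replicates whose call matches the
#' full-depth call, and the minimum adequate depth: the smallest target
#' whose proportion exceeds `level`.
#'
#' @param profiles An `"mnr_profiles"` object (one sample).
#' @param panel The [mnr_panel()].
#' @param model A fitted [msi_train()] classifier.
#' @param targets Target mean barcodes per marker (targets above the
#'   observed mean are skipped with a warning).
#' @param reps Replicates per target (default 25).
#' @param seed Seed for the experiment.
#' @param level Reliability level (default 0.95).
#' @param ... Passed to [summarize_sample()].
#' @return An object of class `"dilution_result"`: `results` (target, rep,
#'   score, call, match), `by_target` (proportion matching the baseline
#'   call), `baseline_call`, `min_adequate`, `seed`.
#' @export
resample_umis <- function(profiles, panel, model,
                          targets = c(5, 10, 15, 25, 50, 75), reps = 25L,
                          seed = 1L, level = 0.95, ...) {
  stopifnot(inherits(profiles, "mnr_profiles"))
  base_sm <- summarize_sample(profiles, panel, ...)
  baseline <- predict(model, base_sm)$call
  observed_mean <- base_sm$mean_umi[1L]
  feasible <- targets <= observed_mean
  if (any(!feasible))
    warning(sprintf("skipping target(s) above the observed mean of %.1f barcodes/marker: %s",
                    observed_mean, paste(targets[!feasible], collapse = ", ")))
  targets <- targets[feasible]
  umi_by_marker <- lapply(stats::setNames(profiles$markers, profiles$markers),
                          function(mk)
                            unique(profiles$records$umi[profiles$records$marker == mk]))
  n_umis <- vapply(umi_by_marker, length, integer(1))
  with_seed(seed, {
    rows <- lapply(targets, function(tg) {
      scale <- tg / mean(n_umis)
      keep_n <- pmin(n_umis, as.integer(round(n_umis * scale)))
      do.call(rbind, lapply(seq_len(reps), function(r) {
        kept <- unlist(lapply(profiles$markers, function(mk) {
          u <- umi_by_marker[[mk]]
          paste0(mk, ":", u[sample.int(length(u), keep_n[[mk]])])
        }))
        rec <- profiles$records[
          paste0(profiles$records$marker, ":", profiles$records$umi) %in% kept, ,
          drop = FALSE]
        sub <- profiles
        sub$records <- rec
        sub$counts$total <- sub$counts$assigned <- nrow(rec)
        sub$marker_discarded[] <- 0L
        sm <- summarize_sample(sub, panel, ...)
        pr <- predict(model, sm)
        data.frame(target = tg, rep = r, score = pr$score, call = pr$call,
                   match = pr$call == baseline, stringsAsFactors = FALSE)
      }))
    })
    results <- do.call(rbind, rows)
  })
  prop <- vapply(split(results$match, results$target), mean, numeric(1))
  by_target <- data.frame(target = as.numeric(names(prop)),
                          prop_match = unname(prop))
  by_target <- by_target[order(by_target$target), , drop = FALSE]
  ok <- by_target$target[by_target$prop_match > level]
  structure(list(results = results, by_target = by_target,
                 baseline_call = baseline,
                 min_adequate = if (length(ok)) min(ok) else NA_real_,
                 level = level, seed = seed), class = "dilution_result")
}

#' @export
print.dilution_result <- function(x, ...) {
  cat(sprintf("barcode-resampling experiment (baseline call %s):\n",
              x$baseline_call))
  print(x$by_target, row.names = FALSE, digits = 3)
  cat(sprintf("minimum adequate depth (> %.0f%% concordant): %s barcodes/marker\n",
              100 * x$level,
              if (is.na(x$min_adequate)) "not reached on grid"
              else format(x$min_adequate)))
  invisible(x)
}

#' Twofold serial-mixture fractions
#'
#' The MSI-H content of a twofold serial dilution of an MSI-H sample into a
#' normal diluent: starting from `initial` (a 1:1 mix gives 50%), each step
#' mixes equal volumes of the previous mixture and diluent, halving the
#' MSI-H fraction.
#'
#' @param initial Starting MSI-H fraction (default 0.5).
#' @param steps Number of further twofold steps (default 6, giving the
#'   series 50%, 25%, ..., 0.78%).
#' @return Numeric vector of length `steps + 1` of MSI-H fractions.
#' @examples
#' round(100 * serial_mixture_fractions(), 2)
#' @export
serial_mixture_fractions <- function(initial = 0.5, steps = 6L) {
  initial * 0.5^(0:steps)
}
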