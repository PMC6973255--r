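# Backward-forward stepwise marker selection.
#
# The search starts from the full panel (backward-first, since the goal is a
# small subset of an existing panel) and walks through subsets by single-
# marker moves: each backward step removes the marker whose removal
# maximizes the objective, accepted as long as the resulting accuracy stays
# at or above the full panel's (the full-panel accuracy is the floor the
# selected subset must meet, so the walk may cross flat or mildly lower
# stretches above that floor instead of halting at the first local optimum);
# after each removal, any previously removed marker whose re-addition
# strictly improves accuracy is added back. Already-visited subsets are
# never re-entered, which guarantees termination, and the reported subset is
# the best one visited: highest accuracy, then largest mean |score| margin,
# then fewest markers. Candidate moves are ranked by accuracy, then margin,
# then by removing the marker with the smallest |log10 P(D=1|MSI-H)/
# P(D=1|MSS)| (least informative first), then by name -- the walk is fully
# deterministic.
#
# The default objective is leave-one-out (LOO) cross-validated accuracy.
# Because the additive naive Bayes score decomposes over markers, each
# sample's per-marker log-likelihood-ratio contributions under LOO
# retraining can be precomputed once, making any subset's objective a
# row-sum -- the same machinery also supports exhaustive subset search in
# validation tests.

# Precompute, for every sample i and marker m, the log10 likelihood-ratio
# contribution of sample i's traits under a model trained without sample i
# (objective = "loo") or on the full cohort (objective = "training").
llr_contributions <- function(d, p, labels, kappa, p_cut, loo = TRUE) {
  n <- nrow(d); m <- ncol(d)
  is_h <- labels == "MSI-H"; is_s <- !is_h
  B <- p < p_cut            # fixed cut: traits don't depend on training fold
  llr_d <- matrix(0, n, m, dimnames = dimnames(d))
  llr_b <- matrix(0, n, m, dimnames = dimnames(d))
  smooth <- function(ones, obs) (ones + kappa) / (obs + 2 * kappa)
  for (i in seq_len(n)) {
    keep <- if (loo) seq_len(n) != i else rep(TRUE, n)
    thr <- apply(d[keep & is_s, , drop = FALSE], 2L, percentile_95)
    D <- sweep(d, 2L, thr, ">")
    cls_est <- function(tr, cls) {
      sub <- tr[keep & cls, , drop = FALSE]
      smooth(colSums(sub, na.rm = TRUE), colSums(!is.na(sub)))
    }
    pdh <- cls_est(D, is_h); pds <- cls_est(D, is_s)
    pbh <- cls_est(B, is_h); pbs <- cls_est(B, is_s)
    no_b <- colSums(!is.na(B[keep, , drop = FALSE])) == 0L
    pbh[no_b] <- 0.5; pbs[no_b] <- 0.5
    di <- D[i, ]; bi <- B[i, ]
    llr_d[i, ] <- ifelse(is.na(di), 0,
                         ifelse(di, log10(pdh / pds), log10((1 - pdh) / (1 - pds))))
    llr_b[i, ] <- ifelse(is.na(bi), 0,
                         ifelse(bi, log10(pbh / pbs), log10((1 - pbh) / (1 - pbs))))
  }
  list(llr_d = llr_d, llr_b = llr_b)
}

subset_objective <- function(contrib, subset, labels, prior_term) {
  sc <- prior_term +
    rowSums(contrib$llr_d[, subset, drop = FALSE]) +
    rowSums(contrib$llr_b[, subset, drop = FALSE])
  correct <- (sc > 0 & labels == "MSI-H") | (sc < 0 & labels == "MSS")
  c(n_correct = sum(correct), margin = mean(abs(sc)))
}

#' Backward-forward stepwise marker selection
#'
#' Searches for a minimal marker subset whose cross-validated classification
#' accuracy equals that of the full panel, mirroring the assay-design goal
#' of replacing a 24-marker panel by a handful of markers at no loss of
#' accuracy. The search walks from the full panel by single-marker removals
#' (with strict-improvement re-additions), never drops below the full
#' panel's accuracy, never revisits a subset, and returns the best subset
#' visited (accuracy, then score margin, then parsimony); see the file-level
#' notes for the exact move and tie-break rules.
#'
#' @param summaries Labelled long-format training summaries
#'   (see [msi_train()]).
#' @param labels Reference labels (as in [msi_train()]).
#' @param markers Initial marker set (default: all markers present).
#' @param objective `"loo"` (leave-one-out cross-validated accuracy, the
#'   default) or `"training"` (reclassification accuracy); both are
#'   tie-broken by the mean absolute score.
#' @param prior_mss,kappa,p_cut Classifier hyper-parameters
#'   (see [msi_train()]).
#' @return An object of class `"msi_selection"`: `selected` (marker names,
#'   panel order), `trace` (one row per move: action, marker, set size,
#'   accuracy, margin), `objective`, and the objective values of the full
#'   panel and the selected subset.
#' @export
stepwise_select <- function(summaries, labels = NULL, markers = NULL,
                            objective = c("loo", "training"),
                            prior_mss = 0.85, kappa = 1, p_cut = 0.05) {
  objective <- match.arg(objective)
  mats <- summaries_to_matrices(summaries, markers)
  labels <- resolve_labels(summaries, labels, rownames(mats$d))
  if (sum(labels == "MSI-H") < 2L || sum(labels == "MSS") < 2L)
    stop("selection requires at least 2 samples per class")
  d <- mats$d; p <- mats$p
  all_mk <- colnames(d)
  contrib <- llr_contributions(d, p, labels, kappa, p_cut,
                               loo = objective == "loo")
  prior_term <- log10((1 - prior_mss) / prior_mss)
  obj <- function(S) subset_objective(contrib, S, labels, prior_term)
  # full-data informativeness of the D trait, for tie-breaking
  full <- msi_train(summaries, labels = labels, markers = all_mk,
                    prior_mss = prior_mss, kappa = kappa, p_cut = p_cut)
  info <- abs(log10(full$params$p_d_msih / full$params$p_d_mss))
  names(info) <- full$params$marker
  current <- all_mk
  removed <- character(0)
  cur_obj <- obj(current)
  full_obj <- cur_obj
  floor_acc <- full_obj["n_correct"]
  n <- nrow(d)
  sig <- function(S) paste(sort(S), collapse = "|")
  visited <- sig(current)
  best <- list(set = current, obj = cur_obj)
  # final selection prefers accuracy, then parsimony (the design goal is the
  # smallest subset of equal accuracy), then score margin
  note_best <- function(S, o) {
    if (o["n_correct"] > best$obj["n_correct"] ||
        (o["n_correct"] == best$obj["n_correct"] &&
         (length(S) < length(best$set) ||
          (length(S) == length(best$set) &&
           o["margin"] > best$obj["margin"] + 1e-9))))
      best <<- list(set = S, obj = o)
  }
  trace <- list(data.frame(step = 0L, action = "start", marker = "",
                           n_markers = length(current),
                           accuracy = cur_obj["n_correct"] / n,
                           margin = cur_obj["margin"], stringsAsFactors = FALSE))
  step <- 0L
  log_move <- function(action, mk) {
    step <<- step + 1L
    trace[[length(trace) + 1L]] <<- data.frame(
      step = step, action = action, marker = mk, n_markers = length(current),
      accuracy = cur_obj["n_correct"] / n, margin = cur_obj["margin"],
      stringsAsFactors = FALSE)
  }
  rank_cand <- function(cand, tiebreak_info) {
    order(-vapply(cand, `[`, numeric(1), "n_correct"),
          -vapply(cand, `[`, numeric(1), "margin"),
          tiebreak_info, names(cand))
  }
  repeat {
    moved <- FALSE
    # backward: best acceptable removal (accuracy stays at or above the
    # full-panel floor; unvisited subset)
    if (length(current) > 1L) {
      pool <- current[!vapply(current, function(mk)
        sig(setdiff(current, mk)) %in% visited, logical(1))]
      if (length(pool)) {
        cand <- lapply(pool, function(mk) obj(setdiff(current, mk)))
        names(cand) <- pool
        bestmk <- pool[rank_cand(cand, info[pool])[1L]]
        if (cand[[bestmk]]["n_correct"] >= floor_acc) {
          current <- setdiff(current, bestmk)
          removed <- union(removed, bestmk)
          cur_obj <- cand[[bestmk]]
          visited <- c(visited, sig(current))
          note_best(current, cur_obj)
          log_move("remove", bestmk)
          moved <- TRUE
        }
      }
    }
    # forward: re-add a removed marker if it strictly improves accuracy
    if (length(removed)) {
      pool <- removed[!vapply(removed, function(mk)
        sig(c(current, mk)) %in% visited, logical(1))]
      if (length(pool)) {
        cand <- lapply(pool, function(mk)
          obj(all_mk[all_mk %in% c(current, mk)]))
        names(cand) <- pool
        gain <- vapply(cand, function(o)
          o["n_correct"] > cur_obj["n_correct"], logical(1))
        if (any(gain)) {
          pool <- pool[gain]
          bestmk <- pool[rank_cand(cand[pool], -info[pool])[1L]]
          current <- all_mk[all_mk %in% c(current, bestmk)]
          removed <- setdiff(removed, bestmk)
          cur_obj <- cand[[bestmk]]
          visited <- c(visited, sig(current))
          note_best(current, cur_obj)
          log_move("add", bestmk)
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  tr <- do.call(rbind, trace)
  rownames(tr) <- NULL
  selected <- all_mk[all_mk %in% best$set]
  structure(list(selected = selected, trace = tr,
                 objective = objective,
                 full_accuracy = unname(full_obj["n_correct"]) / n,
                 selected_accuracy = unname(best$obj["n_correct"]) / n,
                 selected_margin = unname(best$obj["margin"])),
            class = "msi_selection")
}

#' @export
print.msi_selection <- function(x, ...) {
  cat(sprintf("stepwise selection (%s objective): %d marker(s) retained\n",
              x$objective, length(x$selected)))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  accuracy %.3f (full panel %.3f), margin %.3f\n",
              x$selected_accuracy, x$full_accuracy, x$selected_margin))
  invisible(x)
}
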