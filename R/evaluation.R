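#' Rank-based AUC (concordance)
#'
#' Probability that a randomly chosen positive score outranks a randomly
#' chosen negative score, counting ties as one half. Mathematically equal to
#' the trapezoidal area under the ROC curve obtained by sweeping a rank
#' threshold.
#'
#' @param pos,neg Numeric score vectors for the positive and negative
#'   classes; both must be non-empty.
#' @return AUC in \[0, 1\].
#' @export
auc_scores <- function(pos, neg) {
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both score vectors must be non-empty")
  }
  r <- rank(c(pos, neg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

#' Case-study contrast score
#'
#' Summarizes how highly a method ranked its experimentally verified
#' candidates: `exp(sum_i 1/R_i - sum_i 1/i)` over the verified candidates'
#' ranks `R_1..R_m`. Equals 1 exactly when the verified candidates occupy
#' ranks 1..m, and decreases strictly as any rank worsens.
#'
#' @param ranks Vector of positive integer ranks, one per verified
#'   candidate, in the order the candidates are listed.
#' @return The contrast score (positive; 1 for a perfect top-m ranking).
#' @export
contrast_score <- function(ranks) {
  if (length(ranks) == 0) {
    abort("rank list must be non-empty")
  }
  ranks <- as.numeric(ranks)
  if (any(ranks < 1) || any(ranks != floor(ranks))) {
    abort("ranks must be positive integers")
  }
  exp(sum(1 / ranks) - sum(1 / seq_along(ranks)))
}

#' Rank candidate lncRNAs for one disease
#'
#' Candidates are the lncRNAs with no known association to the disease;
#' they are ordered by descending predicted score, ties broken by registry
#' (row) order so the ranking is deterministic.
#'
#' @param scores Predicted score matrix (lncRNAs x diseases).
#' @param disease Disease name or column index.
#' @param ld Binary lncRNA-disease incidence matrix defining which pairs are
#'   already known.
#' @return Tibble with columns `lncrna`, `score`, `rank`.
#' @export
rank_candidates <- function(scores, disease, ld) {
  stopifnot(all(dim(scores) == dim(ld)))
  candidates <- which(ld[, disease] == 0)
  s <- scores[candidates, disease]
  ord <- order(-s, seq_along(s))
  tibble::tibble(
    lncrna = (rownames(ld) %||% as.character(seq_len(nrow(ld))))[candidates][ord],
    score = unname(s[ord]),
    rank = seq_along(ord)
  )
}

cv_folds <- function(n_known, scheme, k) {
  if (scheme == "loocv") {
    as.list(seq_len(n_known))
  } else {
    if (k < 2 || k > n_known) {
      abort(sprintf("fold count k = %d must lie in [2, %d]", k, n_known))
    }
    split(sample.int(n_known), rep_len(seq_len(k), n_known)[order(runif(n_known))])
  }
}

#' Cross-validated evaluation of the full predictor
#'
#' Runs leave-one-out or k-fold cross-validation over the known
#' lncRNA-disease pairs. Pair features are built once (they never touch the
#' lncRNA-disease matrix); for each fold the held-out entries are masked to
#' 0, the lncRNA functional similarity and the smoothed targets are rebuilt
#' from the masked matrix, the scorer is refit on all non-held-out pairs,
#' and the held-out pairs are scored against every unknown pair. AUC is the
#' concordance between held-out-pair scores and their fold's unknown-pair
#' scores (ties one half).
#'
#' @param fit A [fvtlda_fit()] object (the model refit per fold reuses its
#'   features and parameters).
#' @param scheme `"loocv"` or `"kfold"`.
#' @param k Fold count for `"kfold"`; default 5.
#' @param repeats Number of repetitions of the random partition (k-fold) or
#'   of the whole run (LOOCV with the ANN, where initialization is random);
#'   default 1.
#' @param seed Optional RNG seed for fold assignment and ANN training.
#' @return An object of class `fvtlda_cv`: list with `summary` (per-repeat
#'   AUC tibble), `positives` (per-held-out-pair concordance tibble) and the
#'   plan fields.
#' @export
cv_associations <- function(fit, scheme = c("loocv", "kfold"), k = 5,
                            repeats = 1, seed = NULL) {
  stopifnot(inherits(fit, "fvtlda_fit"))
  scheme <- match.arg(scheme)
  known <- which(fit$ld == 1, arr.ind = TRUE)
  if (nrow(known) < 2) {
    abort("need at least 2 known associations for cross-validation")
  }
  run_all <- function() {
    purrr::map_dfr(seq_len(repeats), function(rep_id) {
      folds <- cv_folds(nrow(known), scheme, k)
      purrr::imap_dfr(folds, function(test_rows, fold_id) {
        res <- cv_score_fold(fit, known, test_rows)
        res$fold <- as.integer(fold_id)
        res$repeat_id <- rep_id
        res
      })
    })
  }
  positives <- if (is.null(seed)) run_all() else withr::with_seed(seed, run_all())
  summary <- positives |>
    dplyr::group_by(.data$repeat_id) |>
    dplyr::summarize(auc = mean(.data$concordance), .groups = "drop")
  structure(
    list(summary = summary, positives = positives, scheme = scheme,
         k = if (scheme == "kfold") k else nrow(known),
         repeats = repeats, model = fit$model_kind, seed = seed),
    class = "fvtlda_cv"
  )
}

# Score one CV fold: mask the test entries, rebuild targets, refit, and
# return per-positive concordance against the fold's unknown pairs.
cv_score_fold <- function(fit, known, test_rows) {
  ld_masked <- fit$ld
  ld_masked[known[test_rows, , drop = FALSE]] <- 0
  fl <- functional_similarity(ld_masked, fit$ds_ld)
  targets <- association_targets(ld_masked, fl, fit$ds_ld,
                                 rate = fit$params$rate,
                                 k1 = fit$params$k1, k2 = fit$params$k2)
  all_pairs <- fit$pair_index # (lncRNA row, disease col) for every cell
  test_cells <- known[test_rows, , drop = FALSE]
  test_flat <- (test_cells[, 2] - 1) * nrow(fit$ld) + test_cells[, 1]
  train_mask <- !(all_pairs$flat %in% test_flat)
  model <- refit_scorer(fit, fit$features[train_mask, , drop = FALSE],
                        targets[all_pairs$flat[train_mask]])
  neg_mask <- fit$ld[all_pairs$flat] == 0
  neg_scores <- predict(model, fit$features[neg_mask, , drop = FALSE])
  pos_scores <- predict(model, fit$features[!train_mask, , drop = FALSE])
  nn <- length(neg_scores)
  tibble::tibble(
    lncrna = rownames(fit$ld)[test_cells[, 1]],
    disease = colnames(fit$ld)[test_cells[, 2]],
    score = pos_scores,
    concordance = vapply(pos_scores, function(s) {
      (sum(neg_scores < s) + 0.5 * sum(neg_scores == s)) / nn
    }, numeric(1))
  )
}

refit_scorer <- function(fit, x, y) {
  if (fit$model_kind == "mlr") {
    fit_mlr(x, y)
  } else {
    do.call(fit_ann, c(list(x = x, y = y), fit$ann_args))
  }
}

#' @export
print.fvtlda_cv <- function(x, ...) {
  cat("<fvtlda_cv> ", x$scheme, " (", x$model, ", k = ", x$k, ", repeats = ",
      x$repeats, "): mean AUC = ", round(mean(x$summary$auc), 4), "\n",
      sep = "")
  invisible(x)
}

#' @method glance fvtlda_cv
#' @export
glance.fvtlda_cv <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme, model = x$model, k = x$k, repeats = x$repeats,
    auc_mean = mean(x$summary$auc),
    auc_sd = if (x$repeats > 1) stats::sd(x$summary$auc) else NA_real_,
    n_positives = nrow(x$positives)
  )
}

#' @method tidy fvtlda_cv
#' @export
tidy.fvtlda_cv <- function(x, ...) {
  x$positives
}

#' ROC points of a cross-validation run
#'
#' Builds the ROC curve from the per-positive concordances: each held-out
#' pair's concordance is its percentile among the unknown-pair scores, so
#' sweeping a percentile threshold traces (FPR, TPR) with trapezoidal area
#' equal to the cross-validated AUC.
#'
#' @param cv A [cv_associations()] result.
#' @return Tibble with columns `fpr`, `tpr`, monotone nondecreasing.
#' @export
roc_points <- function(cv) {
  stopifnot(inherits(cv, "fvtlda_cv"))
  p <- sort(cv$positives$concordance)
  tibble::tibble(
    fpr = c(0, 1 - rev(p), 1),
    tpr = c(0, seq_along(p) / length(p), 1)
  )
}

#' @method autoplot fvtlda_cv
#' @export
autoplot.fvtlda_cv <- function(object, ...) {
  pts <- roc_points(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s (%s): AUC = %.4f", toupper(object$scheme),
                      object$model, mean(object$summary$auc))
    )
}

#' Case-study report for one disease
#'
#' Ranks the unknown lncRNAs for a disease with the fitted scorer and, given
#' the set of externally verified lncRNAs, reports their ranks and the
#' contrast score.
#'
#' @param fit A [fvtlda_fit()] object.
#' @param disease Disease name.
#' @param top Number of top candidates to keep in the report; default 10.
#' @param verified Optional character vector of lncRNA names confirmed by
#'   independent evidence.
#' @return An object of class `fvtlda_case_study`: list with `disease`,
#'   `candidates` (tibble `lncrna`, `score`, `rank`, `verified`),
#'   `verified_ranks` and `contrast_score` (NA without verified input).
#' @export
case_study <- function(fit, disease, top = 10, verified = NULL) {
  stopifnot(inherits(fit, "fvtlda_fit"))
  disease <- canonicalize_name(disease)
  if (!disease %in% colnames(fit$ld)) {
    abort(paste0("disease not in the lncRNA-disease universe: ", disease))
  }
  ranked <- rank_candidates(fit$scores, disease, fit$ld)
  verified <- canonicalize_name(verified %||% character())
  ranked$verified <- ranked$lncrna %in% verified
  verified_ranks <- ranked$rank[ranked$verified]
  structure(
    list(
      disease = disease,
      candidates = head(ranked, top),
      verified_ranks = verified_ranks,
      contrast_score = if (length(verified_ranks) > 0) {
        contrast_score(verified_ranks)
      } else {
        NA_real_
      }
    ),
    class = "fvtlda_case_study"
  )
}

#' @export
print.fvtlda_case_study <- function(x, ...) {
  cat("<fvtlda_case_study> ", x$disease, "\n", sep = "")
  print(x$candidates)
  if (!is.na(x$contrast_score)) {
    cat("verified ranks:", paste(x$verified_ranks, collapse = ", "),
        "| contrast score:", round(x$contrast_score, 4), "\n")
  }
  invisible(x)
}

#' Published case-study benchmark ranks
#'
#' The verified-candidate rank lists reported for the gastric cancer,
#' leukemia and lung cancer case studies of the method's original benchmark
#' (three scoring methods per disease), shipped with the package so the
#' contrast scores can be recomputed without any download.
#'
#' @return Tibble with columns `disease`, `method`, `position`
#'   (listing order of the verified candidate) and `rank`.
#' @export
case_study_benchmark <- function() {
  path <- system.file("extdata", "case_study_ranks.tsv", package = "fvtlda",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    disease = readr::col_character(),
                    method = readr::col_character(),
                    position = readr::col_integer(),
                    rank = readr::col_integer()
                  ))
}

#' Contrast scores of the shipped case-study benchmark
#'
#' Applies [contrast_score()] to every (disease, method) rank list of
#' [case_study_benchmark()].
#'
#' @return Tibble with columns `disease`, `method`, `m` (number of verified
#'   candidates) and `contrast_score`.
#' @export
benchmark_contrast_scores <- function() {
  case_study_benchmark() |>
    dplyr::arrange(.data$disease, .data$method, .data$position) |>
    dplyr::group_by(.data$disease, .data$method) |>
    dplyr::summarize(m = dplyr::n(),
                     contrast_score = contrast_score(.data$rank),
                     .groups = "drop")
}
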