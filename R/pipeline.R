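#' Model parameters
#'
#' Bundles every tunable parameter of the predictor with its default:
#' `rate` (mixing factor between lncRNA-side and disease-side target
#' smoothing, 0.3), `r1`/`r2` (restart probabilities of the lncRNA-side and
#' disease-side walks, 0.001), `k1`/`k2` (smoothing attenuation factors,
#' 0.008 and 0.007), `gamma_prime` (GIP bandwidth parameter, 1), `delta`
#' (semantic contribution decay, 0.5), plus the walk convergence controls.
#'
#' @param rate Mixing factor in \[0, 1\].
#' @param r1,r2 Restart probabilities in (0, 1).
#' @param k1,k2 Attenuation factors in \[0, 1\].
#' @param gamma_prime GIP bandwidth parameter, > 0.
#' @param delta Semantic decay factor in (0, 1).
#' @param rwr_tol Walk convergence threshold (max-norm); default 1e-10.
#' @param rwr_max_iter Walk iteration cap; default 10000.
#' @return A named list of class `fvtlda_params`.
#' @export
fvtlda_params <- function(rate = 0.3, r1 = 0.001, r2 = 0.001,
                          k1 = 0.008, k2 = 0.007, gamma_prime = 1,
                          delta = 0.5, rwr_tol = 1e-10,
                          rwr_max_iter = 10000) {
  stopifnot(rate >= 0, rate <= 1, r1 > 0, r1 < 1, r2 > 0, r2 < 1,
            k1 >= 0, k1 <= 1, k2 >= 0, k2 <= 1, gamma_prime > 0,
            delta > 0, delta < 1, rwr_tol > 0, rwr_max_iter >= 1)
  structure(
    list(rate = rate, r1 = r1, r2 = r2, k1 = k1, k2 = k2,
         gamma_prime = gamma_prime, delta = delta, rwr_tol = rwr_tol,
         rwr_max_iter = rwr_max_iter),
    class = "fvtlda_params"
  )
}

#' Assemble the tripartite association data
#'
#' Combines the three association tables and the MeSH code table into the
#' aligned incidence matrices the predictor works on. The miRNA registry is
#' the union of the miRNAs seen in the miRNA-disease and miRNA-lncRNA
#' tables; the lncRNA-disease table is restricted to lncRNAs and diseases
#' present in those universes (see [filter_ld_associations()]), and its
#' surviving pairs define the prediction universe.
#'
#' @param md Tibble of (miRNA, disease) pairs.
#' @param ml Tibble of (miRNA, lncRNA) pairs.
#' @param ld Tibble of (lncRNA, disease) pairs.
#' @param mesh_codes Tibble of (`disease`, `code`) rows; see
#'   [read_mesh_codes()].
#' @return An object of class `fvtlda_data` with the incidence matrices
#'   `md`, `ml`, `ld` and the code table.
#' @export
fvtlda_data <- function(md, ml, ld, mesh_codes) {
  mirnas <- entity_registry(md[[1]], ml[[1]])
  diseases_md <- entity_registry(md[[2]])
  lncrnas_ml <- entity_registry(ml[[2]])
  ld_kept <- filter_ld_associations(ld, lncrnas_ml, diseases_md)
  if (nrow(ld_kept) == 0) {
    abort("no lncRNA-disease association survives the universe filter")
  }
  structure(
    list(
      md = build_incidence(md, mirnas, diseases_md),
      ml = build_incidence(ml, mirnas, lncrnas_ml),
      ld = build_incidence(ld_kept, attr(ld_kept, "lncrnas"),
                           attr(ld_kept, "diseases")),
      mesh_codes = mesh_codes
    ),
    class = "fvtlda_data"
  )
}

#' @export
print.fvtlda_data <- function(x, ...) {
  cat("<fvtlda_data>\n",
      sprintf("  %d miRNAs x %d diseases (miRNA-disease), %d associations\n",
              nrow(x$md), ncol(x$md), sum(x$md)),
      sprintf("  %d miRNAs x %d lncRNAs (miRNA-lncRNA), %d associations\n",
              nrow(x$ml), ncol(x$ml), sum(x$ml)),
      sprintf("  %d lncRNAs x %d diseases (lncRNA-disease), %d associations\n",
              nrow(x$ld), ncol(x$ld), sum(x$ld)), sep = "")
  invisible(x)
}

#' Fit the full lncRNA-disease association predictor
#'
#' Runs the whole pipeline: GIP kernel over miRNA interaction profiles and
#' its restart walk (lncRNA features); disease semantic similarity, miRNA
#' functional similarity and its restart walk (disease features); pair
#' feature vectors as elementwise products; smoothed association-probability
#' targets from the known lncRNA-disease links; and a scorer (linear
#' regression or neural network) fit on every pair. Predicted scores for
#' every (lncRNA, disease) pair are computed eagerly.
#'
#' @param data A [fvtlda_data()] object.
#' @param model `"mlr"` (default) or `"ann"`.
#' @param params A [fvtlda_params()] object.
#' @param seed Optional RNG seed (only the neural network is stochastic).
#' @param ... Further arguments to [fit_ann()] (`hidden`, `max_epochs`,
#'   `mse_goal`, `patience`, `learn_rate`).
#' @return An object of class `fvtlda_fit` holding the similarity matrices,
#'   walk profiles, features, targets, fitted scorer and the score matrix.
#' @export
fvtlda_fit <- function(data, model = c("mlr", "ann"),
                       params = fvtlda_params(), seed = NULL, ...) {
  stopifnot(inherits(data, "fvtlda_data"))
  model <- match.arg(model)
  ann_args <- c(list(...), list(seed = seed))

  km <- gip_kernel(data$ml, gamma_prime = params$gamma_prime)
  pl <- rwr(column_normalize_seeds(data$ml), row_normalize(km),
            restart = params$r1, tol = params$rwr_tol,
            max_iter = params$rwr_max_iter)

  ds_md <- semantic_similarity_matrix(colnames(data$md), data$mesh_codes,
                                      delta = params$delta)
  fm <- functional_similarity(data$md, ds_md)
  pd <- rwr(column_normalize_seeds(data$md), row_normalize(fm),
            restart = params$r2, tol = params$rwr_tol,
            max_iter = params$rwr_max_iter)

  ld <- data$ld
  ds_ld <- ds_md[colnames(ld), colnames(ld), drop = FALSE]
  fl <- functional_similarity(ld, ds_ld)
  targets <- association_targets(ld, fl, ds_ld, rate = params$rate,
                                 k1 = params$k1, k2 = params$k2)

  nl <- nrow(ld)
  nd <- ncol(ld)
  pair_index <- tibble::tibble(
    flat = seq_len(nl * nd),
    lnc = rep(seq_len(nl), times = nd),
    dis = rep(seq_len(nd), each = nl)
  )
  features <- pair_features(pl[, rownames(ld), drop = FALSE],
                            pd[, colnames(ld), drop = FALSE],
                            pair_index$lnc, pair_index$dis)
  colnames(features) <- rownames(data$ml)

  scorer <- if (model == "mlr") {
    fit_mlr(features, targets[pair_index$flat])
  } else {
    do.call(fit_ann,
            c(list(x = features, y = targets[pair_index$flat]), ann_args))
  }
  scores <- matrix(predict(scorer, features), nl, nd, dimnames = dimnames(ld))

  structure(
    list(data = data, params = params, model_kind = model,
         ann_args = ann_args, km = km, ds_md = ds_md, fm = fm,
         pl = pl, pd = pd, ld = ld, ds_ld = ds_ld, fl = fl,
         targets = targets, pair_index = pair_index, features = features,
         scorer = scorer, scores = scores),
    class = "fvtlda_fit"
  )
}

#' @export
print.fvtlda_fit <- function(x, ...) {
  cat("<fvtlda_fit> ", toupper(x$model_kind), " scorer over ",
      nrow(x$ld), " lncRNAs x ", ncol(x$ld), " diseases (",
      sum(x$ld), " known associations, ", ncol(x$features),
      " miRNA features)\n", sep = "")
  invisible(x)
}

#' @method tidy fvtlda_fit
#' @export
tidy.fvtlda_fit <- function(x, ...) {
  tibble::tibble(
    lncrna = rownames(x$ld)[x$pair_index$lnc],
    disease = colnames(x$ld)[x$pair_index$dis],
    known = x$ld[x$pair_index$flat] == 1,
    target = x$targets[x$pair_index$flat],
    score = x$scores[x$pair_index$flat]
  )
}

#' @method glance fvtlda_fit
#' @export
glance.fvtlda_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model_kind,
    n_mirna = nrow(x$data$ml),
    n_lncrna = nrow(x$ld),
    n_disease = ncol(x$ld),
    n_known = sum(x$ld),
    walk_converged = isTRUE(attr(x$pl, "converged")) &&
      isTRUE(attr(x$pd, "converged"))
  )
}

#' Predicted score heat map
#'
#' @param object A [fvtlda_fit()] object.
#' @param ... Unused.
#' @return A ggplot object: lncRNAs x diseases tile map of predicted
#'   scores, known associations outlined.
#' @method autoplot fvtlda_fit
#' @export
autoplot.fvtlda_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$disease, y = .data$lncrna,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$known),
                       fill = NA, colour = "black", linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score")
}
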