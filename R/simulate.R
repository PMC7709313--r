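#' Simulate a tripartite association dataset with planted block structure
#'
#' Generates miRNA-disease, miRNA-lncRNA and lncRNA-disease association
#' tables plus a toy MeSH-style code table, fully determined by `seed`.
#' Every entity is assigned to one of `n_groups` latent groups; an
#' association is drawn with probability `p_in` when the two endpoints share
#' a group and `p_out` otherwise, so lncRNA-disease links are predictable
#' from the miRNA-side evidence exactly to the extent `p_in` exceeds
#' `p_out` (with `p_in == p_out` there is no signal). Disease codes place
#' same-group diseases under a shared lineage of depth `ontology_depth`,
#' split into `branching` sibling sub-branches, so semantic similarity is
#' informative about group membership.
#'
#' @param n_mirna,n_lncrna,n_disease Entity counts; defaults 40, 30, 25.
#' @param n_groups Latent group count; default 4.
#' @param p_in,p_out Within/between-group association probabilities;
#'   defaults 0.5 and 0.03.
#' @param ontology_depth Depth of the shared per-group code lineage;
#'   default 3.
#' @param branching Sibling sub-branches per group at the leaf level;
#'   default 2.
#' @param seed Optional RNG seed; same seed, same dataset.
#' @return An object of class `fvtlda_sim`: list of tibbles `md`, `ml`,
#'   `ld`, `mesh_codes`, plus `groups` (per-entity latent labels) and the
#'   configuration.
#' @export
simulate_tripartite <- function(n_mirna = 40, n_lncrna = 30, n_disease = 25,
                                n_groups = 4, p_in = 0.5, p_out = 0.03,
                                ontology_depth = 3, branching = 2,
                                seed = NULL) {
  stopifnot(p_out >= 0, p_in <= 1, p_out < p_in || p_in == p_out,
            n_mirna >= n_groups, n_lncrna >= n_groups,
            n_disease >= n_groups, ontology_depth >= 1, branching >= 1)
  if (p_out > p_in) {
    abort("p_out must not exceed p_in")
  }
  run <- function() {
    mirnas <- sprintf("mir-%03d", seq_len(n_mirna))
    lncrnas <- sprintf("lnc-%03d", seq_len(n_lncrna))
    diseases <- sprintf("disease-%03d", seq_len(n_disease))
    groups <- list(
      mirna = setNames(rep_len(seq_len(n_groups), n_mirna), mirnas),
      lncrna = setNames(rep_len(seq_len(n_groups), n_lncrna), lncrnas),
      disease = setNames(rep_len(seq_len(n_groups), n_disease), diseases)
    )
    draw_edges <- function(left, right, g_left, g_right, names) {
      prob <- ifelse(outer(g_left, g_right, "=="), p_in, p_out)
      hit <- which(matrix(runif(length(prob)), nrow(prob)) < prob,
                   arr.ind = TRUE)
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      tibble::tibble(!!names[[1]] := left[hit[, 1]],
                     !!names[[2]] := right[hit[, 2]])
    }
    md <- draw_edges(mirnas, diseases, groups$mirna, groups$disease,
                     c("mirna", "disease"))
    ml <- draw_edges(mirnas, lncrnas, groups$mirna, groups$lncrna,
                     c("mirna", "lncrna"))
    ld <- draw_edges(lncrnas, diseases, groups$lncrna, groups$disease,
                     c("lncrna", "disease"))
    g <- groups$disease
    lineage <- vapply(seq_len(n_disease), function(i) {
      base <- c(sprintf("C%02d", g[i]),
                sprintf("%03d", 100 * g[i] + seq_len(max(0, ontology_depth - 1))))
      branch <- sprintf("%03d", 500 + (i %% branching))
      leaf <- sprintf("%03d", 700 + i)
      paste(c(base, branch, leaf), collapse = ".")
    }, character(1))
    mesh_codes <- tibble::tibble(disease = diseases, code = lineage)
    list(md = md, ml = ml, ld = ld, mesh_codes = mesh_codes,
         groups = groups)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    c(out, list(config = list(
      n_mirna = n_mirna, n_lncrna = n_lncrna, n_disease = n_disease,
      n_groups = n_groups, p_in = p_in, p_out = p_out,
      ontology_depth = ontology_depth, branching = branching, seed = seed
    ))),
    class = "fvtlda_sim"
  )
}

#' @export
print.fvtlda_sim <- function(x, ...) {
  cat("<fvtlda_sim> ", x$config$n_mirna, " miRNAs, ", x$config$n_lncrna,
      " lncRNAs, ", x$config$n_disease, " diseases in ", x$config$n_groups,
      " groups (p_in = ", x$config$p_in, ", p_out = ", x$config$p_out,
      "): ", nrow(x$md), "/", nrow(x$ml), "/", nrow(x$ld),
      " MD/ML/LD associations\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset as the four TSV inputs
#'
#' Emits `md.tsv`, `ml.tsv`, `ld.tsv` (two-column association tables) and
#' `mesh_codes.tsv` (disease, semicolon-joined codes) in the dialects read
#' by [read_association_table()] and [read_mesh_codes()].
#'
#' @param sim A [simulate_tripartite()] object.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_tripartite <- function(sim, dir) {
  stopifnot(inherits(sim, "fvtlda_sim"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  paths <- c(
    md = file.path(dir, "md.tsv"), ml = file.path(dir, "ml.tsv"),
    ld = file.path(dir, "ld.tsv"),
    mesh_codes = file.path(dir, "mesh_codes.tsv")
  )
  write_association_table(sim$md, paths[["md"]])
  write_association_table(sim$ml, paths[["ml"]])
  write_association_table(sim$ld, paths[["ld"]])
  codes <- sim$mesh_codes |>
    dplyr::group_by(.data$disease) |>
    dplyr::summarize(code = paste(.data$code, collapse = ";"),
                     .groups = "drop")
  readr::write_tsv(codes, paths[["mesh_codes"]])
  invisible(paths)
}

#' Load a simulated (or real) four-file dataset from a directory
#'
#' Counterpart of [write_tripartite()]: reads the four TSVs and assembles a
#' [fvtlda_data()] object.
#'
#' @param dir Directory containing `md.tsv`, `ml.tsv`, `ld.tsv` and
#'   `mesh_codes.tsv`.
#' @return A `fvtlda_data` object.
#' @export
read_tripartite <- function(dir) {
  fvtlda_data(
    md = read_association_table(file.path(dir, "md.tsv"),
                                c("mirna", "disease")),
    ml = read_association_table(file.path(dir, "ml.tsv"),
                                c("mirna", "lncrna")),
    ld = read_association_table(file.path(dir, "ld.tsv"),
                                c("lncrna", "disease")),
    mesh_codes = read_mesh_codes(file.path(dir, "mesh_codes.tsv"))
  )
}

#' Assemble a `fvtlda_data` object directly from a simulation
#'
#' @param sim A [simulate_tripartite()] object.
#' @return A [fvtlda_data()] object.
#' @export
as_fvtlda_data <- function(sim) {
  stopifnot(inherits(sim, "fvtlda_sim"))
  fvtlda_data(sim$md, sim$ml, sim$ld, sim$mesh_codes)
}

#' Degrade a dataset by shuffling the known lncRNA-disease links
#'
#' Redistributes the 1-entries of the lncRNA-disease matrix uniformly at
#' random (same count, same shape), destroying any real structure while
#' preserving sparsity. Used as the label-shuffled control in signal
#' detection checks: the features are untouched, so any AUC above chance on
#' the shuffled data would indicate leakage.
#'
#' @param data A [fvtlda_data()] object.
#' @param seed Optional RNG seed.
#' @return A `fvtlda_data` object with shuffled `ld`.
#' @export
shuffle_ld <- function(data, seed = NULL) {
  stopifnot(inherits(data, "fvtlda_data"))
  run <- function() {
    ld <- data$ld
    n_one <- sum(ld)
    ld[] <- 0
    ld[sample.int(length(ld), n_one)] <- 1
    ld
  }
  data$ld <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  data
}
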