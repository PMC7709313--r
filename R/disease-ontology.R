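#' Read a disease-to-MeSH-tree-code table
#'
#' Expects a two-column TSV: disease name, then a semicolon-separated list of
#' MeSH tree codes (dot-separated hierarchical identifiers such as
#' `C04.588.180`). Codes locate a disease in the Medical Subject Headings
#' hierarchy; every dot-prefix of a code is an ancestor.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `disease` (canonical name) and `code`
#'   (one row per code, upper-cased).
#' @export
read_mesh_codes <- function(path) {
  raw <- read_association_table(path, col_names = c("disease", "code"),
                                sep = "\t")
  out <- tidyr::separate_rows(raw, "code", sep = ";")
  out$code <- toupper(trimws(out$code))
  out <- dplyr::distinct(out, .data$disease, .data$code)
  bad <- out$code[!grepl("^[A-Z][0-9]+(\\.[0-9]+)*$", out$code)]
  if (length(bad) > 0) {
    abort(paste0("malformed MeSH tree code(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  out
}

code_prefixes <- function(code) {
  parts <- strsplit(code, ".", fixed = TRUE)[[1]]
  vapply(seq_along(parts), function(k) paste(parts[1:k], collapse = "."),
         character(1))
}

#' Build the ancestor DAG of a disease from its MeSH tree codes
#'
#' The DAG of a disease consists of the disease's own node(s) -- its full
#' tree codes -- plus every dot-prefix truncation (ancestor). Node identity
#' is the tree-code string, so two diseases share a node exactly when they
#' share a code prefix. Each node carries a semantic contribution: 1 for the
#' disease itself, and for an ancestor the maximum over its children (within
#' this DAG) of `delta` times the child's contribution, so a chain ancestor
#' `k` levels up contributes `delta^k`.
#'
#' @param disease Disease name (canonicalized internally).
#' @param codes Tibble as returned by [read_mesh_codes()] (columns `disease`,
#'   `code`), or a character vector of codes for this disease alone.
#' @param delta Semantic contribution decay factor, in (0, 1); default 0.5.
#' @return An object of class `disease_dag`: list with `disease`, `nodes`,
#'   `edges` (tibble `parent`, `child`), `contribution` (named numeric) and
#'   `delta`.
#' @export
build_disease_dag <- function(disease, codes, delta = 0.5) {
  stopifnot(delta > 0, delta < 1)
  disease <- canonicalize_name(disease)
  own <- if (is.character(codes)) {
    toupper(trimws(codes))
  } else {
    codes$code[canonicalize_name(codes$disease) == disease]
  }
  own <- unique(own)
  if (length(own) == 0) {
    abort(paste0("no MeSH tree codes for disease: ", disease))
  }
  nodes <- unique(unlist(lapply(own, code_prefixes)))
  depth <- lengths(strsplit(nodes, ".", fixed = TRUE))
  parent_of <- function(code) sub("\\.[0-9]+$", "", code)
  edges <- tibble::tibble(
    child = nodes[depth > 1],
    parent = vapply(nodes[depth > 1], parent_of, character(1))
  )[, c("parent", "child")]
  # contributions bottom-up: deepest nodes first
  contribution <- setNames(rep(NA_real_, length(nodes)), nodes)
  for (nd in nodes[order(depth, decreasing = TRUE)]) {
    if (nd %in% own) {
      contribution[[nd]] <- 1
    } else {
      children <- edges$child[edges$parent == nd]
      contribution[[nd]] <- delta * max(contribution[children])
    }
  }
  structure(
    list(disease = disease, nodes = nodes, edges = edges,
         contribution = contribution, delta = delta),
    class = "disease_dag"
  )
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("<disease_dag> ", x$disease, ": ", length(x$nodes), " nodes, delta = ",
      x$delta, "\n", sep = "")
  invisible(x)
}

#' Semantic contribution of a node to a disease
#'
#' Returns the contribution of node `node` to the semantic value of the
#' disease represented by `dag`: 1 for the disease's own node(s), decayed by
#' `delta` per level up for ancestors, and 0 for nodes outside the DAG.
#'
#' @param dag A [build_disease_dag()] object.
#' @param node Tree-code string.
#' @return A number in \[0, 1\].
#' @export
dag_contribution <- function(dag, node) {
  stopifnot(inherits(dag, "disease_dag"))
  unname(ifelse(node %in% dag$nodes, dag$contribution[node], 0))
}

#' Semantic value of a disease
#'
#' Sum of the semantic contributions of every node in the disease's DAG;
#' at least 1 (the disease's own node).
#'
#' @param dag A [build_disease_dag()] object.
#' @return A number >= 1.
#' @export
dag_semantic_value <- function(dag) {
  stopifnot(inherits(dag, "disease_dag"))
  sum(dag$contribution)
}

#' Semantic similarity between two diseases
#'
#' Diseases whose DAGs share more (and more specific) nodes are more
#' similar: the score is the sum over shared nodes of both diseases'
#' contributions, divided by the sum of the two semantic values. Symmetric,
#' in \[0, 1\], and 1 for identical DAGs.
#'
#' @param dag_i,dag_j [build_disease_dag()] objects built with the same
#'   `delta`.
#' @return A number in \[0, 1\].
#' @export
disease_semantic_similarity <- function(dag_i, dag_j) {
  stopifnot(inherits(dag_i, "disease_dag"), inherits(dag_j, "disease_dag"))
  shared <- intersect(dag_i$nodes, dag_j$nodes)
  if (length(shared) == 0) {
    return(0)
  }
  num <- sum(dag_i$contribution[shared]) + sum(dag_j$contribution[shared])
  num / (dag_semantic_value(dag_i) + dag_semantic_value(dag_j))
}

#' Pairwise disease semantic similarity matrix
#'
#' Builds the DAG of every disease in `diseases` and evaluates
#' [disease_semantic_similarity()] for every pair. The sub-matrix for any
#' subset of diseases (e.g. those carrying lncRNA links) is extracted by
#' plain row/column indexing.
#'
#' @param diseases Character registry of disease names.
#' @param codes Tibble of (`disease`, `code`) rows; see [read_mesh_codes()].
#' @param delta Decay factor, default 0.5.
#' @param on_missing `"error"` (default) aborts when a disease has no codes;
#'   `"zero"` gives it an all-zero off-diagonal row with a warning.
#' @return Symmetric matrix with unit diagonal, dimnames = diseases.
#' @export
semantic_similarity_matrix <- function(diseases, codes, delta = 0.5,
                                       on_missing = c("error", "zero")) {
  on_missing <- match.arg(on_missing)
  diseases <- entity_registry(diseases)
  have <- diseases %in% canonicalize_name(codes$disease)
  if (any(!have)) {
    if (on_missing == "error") {
      abort(paste0("diseases without MeSH codes: ",
                   paste(head(diseases[!have], 5), collapse = ", ")))
    }
    warn(sprintf("%d disease(s) without MeSH codes get zero similarity",
                 sum(!have)))
  }
  dags <- setNames(vector("list", length(diseases)), diseases)
  for (d in diseases[have]) dags[[d]] <- build_disease_dag(d, codes, delta)
  n <- length(diseases)
  sim <- diag(1, n)
  dimnames(sim) <- list(diseases, diseases)
  if (n >= 2) {
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        if (have[a] && have[b]) {
          s <- disease_semantic_similarity(dags[[a]], dags[[b]])
          sim[a, b] <- s
          sim[b, a] <- s
        }
      }
    }
  }
  sim
}
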