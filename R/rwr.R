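#' Row-normalize a similarity matrix into a transition matrix
#'
#' Divides each row by its sum so rows are probability vectors; all-zero
#' rows stay zero (with a warning), leaving isolated nodes absorbing no
#' probability mass.
#'
#' @param sim Square nonnegative matrix.
#' @return Matrix of the same shape with row sums 1 (or 0).
#' @export
row_normalize <- function(sim) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim), all(sim >= 0))
  rs <- rowSums(sim)
  zero <- rs == 0
  if (any(zero)) {
    warn(sprintf("%d all-zero row(s) left unnormalized", sum(zero)))
    rs[zero] <- 1
  }
  sim / rs
}

#' Column-normalize an incidence matrix into restart seed vectors
#'
#' Each column of the binary incidence matrix becomes the restart
#' distribution of one walker: uniform over the column's ones. Columns with
#' no ones (isolated entities) stay zero; which ones are recorded in the
#' `"zero_seed"` attribute so downstream feature vectors for those entities
#' are all-zero rather than an error.
#'
#' @param assoc Binary incidence matrix (miRNAs x entities).
#' @return Column-stochastic (up to zero columns) seed matrix with a
#'   `"zero_seed"` logical attribute.
#' @export
column_normalize_seeds <- function(assoc) {
  stopifnot(is.matrix(assoc))
  cs <- colSums(assoc)
  zero <- cs == 0
  cs[zero] <- 1
  seeds <- sweep(assoc, 2, cs, "/")
  attr(seeds, "zero_seed") <- zero
  seeds
}

#' Random walk with restart over a miRNA similarity network
#'
#' Iterates `P_{s+1} = (1 - restart) * t(transition) %*% P_s + restart * P_0`
#' from `P_0 = seeds` until the maximum absolute entrywise change between
#' successive iterates drops below `tol`. At convergence the result equals
#' the closed form `restart * solve(I - (1 - restart) * t(transition), seeds)`.
#' Each column is one walker; columns with a stochastic seed stay
#' stochastic at every iteration.
#'
#' @param seeds Seed matrix (miRNAs x walkers), e.g. from
#'   [column_normalize_seeds()].
#' @param transition Row-stochastic matrix (up to zero rows), e.g. from
#'   [row_normalize()].
#' @param restart Restart probability in (0, 1).
#' @param tol Convergence threshold on the max-norm difference; default 1e-10.
#' @param max_iter Iteration cap; default 10000.
#' @return The stationary matrix, with attributes `converged` (logical) and
#'   `iterations`.
#' @export
rwr <- function(seeds, transition, restart, tol = 1e-10, max_iter = 10000) {
  stopifnot(is.matrix(seeds), is.matrix(transition),
            nrow(transition) == ncol(transition),
            nrow(seeds) == nrow(transition),
            restart > 0, restart < 1, tol > 0, max_iter >= 1)
  w_t <- t(transition)
  p0 <- seeds
  p <- p0
  converged <- FALSE
  iter <- 0L
  for (s in seq_len(max_iter)) {
    p_next <- (1 - restart) * (w_t %*% p) + restart * p0
    delta <- max(abs(p_next - p))
    p <- p_next
    iter <- s
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("random walk not converged after %d iterations", max_iter))
  }
  attr(p, "converged") <- converged
  attr(p, "iterations") <- iter
  attr(p, "zero_seed") <- attr(seeds, "zero_seed")
  p
}

#' Closed-form stationary state of the restart walk
#'
#' Direct linear solve of the fixed-point equation; used as the independent
#' cross-check for [rwr()].
#'
#' @inheritParams rwr
#' @return The stationary matrix.
#' @export
rwr_closed_form <- function(seeds, transition, restart) {
  n <- nrow(transition)
  restart * solve(diag(n) - (1 - restart) * t(transition), seeds)
}

#' Feature vector of one lncRNA-disease pair
#'
#' The pair feature is the elementwise (Hadamard) product of the lncRNA's
#' walk profile (a column of `pl`) and the disease's walk profile (a column
#' of `pd`): a miRNA contributes to the pair exactly to the extent it is
#' close to both endpoints.
#'
#' @param pl Walk profile matrix over lncRNAs (miRNAs x lncRNAs).
#' @param pd Walk profile matrix over diseases (miRNAs x diseases).
#' @param i lncRNA column index or name.
#' @param j Disease column index or name.
#' @return Numeric vector of length `nrow(pl)`.
#' @export
pair_feature <- function(pl, pd, i, j) {
  a <- pl[, i]
  b <- pd[, j]
  if (length(a) != length(b)) {
    abort("walk profile lengths differ between the two endpoints")
  }
  a * b
}

#' Feature matrix for a set of lncRNA-disease pairs
#'
#' Vectorized [pair_feature()]: one row per requested pair.
#'
#' @inheritParams pair_feature
#' @param lnc_idx,dis_idx Parallel vectors of column indices (or names).
#' @return Matrix of shape `length(lnc_idx)` x `nrow(pl)`.
#' @export
pair_features <- function(pl, pd, lnc_idx, dis_idx) {
  stopifnot(length(lnc_idx) == length(dis_idx), nrow(pl) == nrow(pd))
  t(pl[, lnc_idx, drop = FALSE] * pd[, dis_idx, drop = FALSE])
}
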