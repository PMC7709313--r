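#' lncRNA-side smoothing of the association matrix
#'
#' For each (lncRNA i, disease j), sums the attenuated votes of the lncRNAs
#' known to be linked to disease j, weighted by their functional similarity
#' to lncRNA i: `k1 * sum_n LD(n, j) * FL(i, n)`. A known pair additionally
#' receives `1 - k1`, so (because `FL(i, i) = 1` contributes `k1` through the
#' self term) a known pair with no other support scores exactly 1.
#'
#' @param ld Binary lncRNA-disease incidence matrix.
#' @param fl lncRNA functional similarity matrix (unit diagonal).
#' @param k1 Attenuation factor in \[0, 1\].
#' @return Matrix of the same shape as `ld`.
#' @export
fout_matrix <- function(ld, fl, k1) {
  stopifnot(nrow(ld) == nrow(fl), nrow(fl) == ncol(fl),
            k1 >= 0, k1 <= 1)
  k1 * (fl %*% ld) + (1 - k1) * (ld == 1)
}

#' Disease-side smoothing of the association matrix
#'
#' Mirror of [fout_matrix()] on the disease axis: each (i, j) collects the
#' attenuated votes of the diseases known to be linked to lncRNA i, weighted
#' by their semantic similarity to disease j. The nonzero entries of a
#' disease's similarity row form its "clique" of semantically related
#' diseases; diseases outside it contribute zero to the sum, so no explicit
#' clique set is needed.
#'
#' @param ld Binary lncRNA-disease incidence matrix.
#' @param ds_ld Disease semantic similarity matrix over `ld`'s diseases.
#' @param k2 Attenuation factor in \[0, 1\].
#' @return Matrix of the same shape as `ld`.
#' @export
dout_matrix <- function(ld, ds_ld, k2) {
  stopifnot(ncol(ld) == nrow(ds_ld), nrow(ds_ld) == ncol(ds_ld),
            k2 >= 0, k2 <= 1)
  k2 * (ld %*% ds_ld) + (1 - k2) * (ld == 1)
}

#' Smoothed association-probability targets
#'
#' Converts the binary lncRNA-disease matrix into graded regression targets:
#' the convex combination `rate * FOUT + (1 - rate) * DOUT` of the two
#' similarity-smoothed matrices, then min-max normalized over the whole
#' matrix to \[0, 1\]. With a degenerate (constant) combination every target
#' is set to 0 with a warning.
#'
#' @param ld Binary lncRNA-disease incidence matrix.
#' @param fl lncRNA functional similarity matrix.
#' @param ds_ld Disease semantic similarity matrix.
#' @param rate Mixing factor in \[0, 1\] between the lncRNA-side and
#'   disease-side smoothing; default 0.3.
#' @param k1,k2 Attenuation factors; defaults 0.008 and 0.007.
#' @return Target matrix in \[0, 1\], same dimnames as `ld`.
#' @export
association_targets <- function(ld, fl, ds_ld, rate = 0.3,
                                k1 = 0.008, k2 = 0.007) {
  stopifnot(rate >= 0, rate <= 1)
  out <- rate * fout_matrix(ld, fl, k1) +
    (1 - rate) * dout_matrix(ld, ds_ld, k2)
  lo <- min(out)
  hi <- max(out)
  if (hi == lo) {
    warn("constant combined smoothing matrix: all targets set to 0")
    out[] <- 0
    return(out)
  }
  (out - lo) / (hi - lo)
}
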