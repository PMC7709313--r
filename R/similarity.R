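#' Gaussian interaction-profile (GIP) kernel similarity
#'
#' Similarity between two entities as a Gaussian of the Euclidean distance
#' between their binary interaction profiles (rows of an incidence matrix):
#' `K(i, j) = exp(-gamma * ||IP_i - IP_j||^2)` with the bandwidth
#' `gamma = gamma_prime / sum_k ||IP_k||^2`. The denominator is the plain
#' sum of squared profile norms; set `average = TRUE` for the variant that
#' divides by the mean squared norm instead.
#'
#' @param profiles Binary matrix, one interaction profile per row.
#' @param gamma_prime Bandwidth parameter, > 0; default 1.
#' @param average If `TRUE`, normalize the bandwidth by the mean (not the
#'   sum) of squared profile norms.
#' @return Symmetric similarity matrix with unit diagonal, entries in
#'   (0, 1\], row names preserved.
#' @export
gip_kernel <- function(profiles, gamma_prime = 1, average = FALSE) {
  stopifnot(is.matrix(profiles), gamma_prime > 0)
  sq <- rowSums(profiles^2)
  total <- sum(sq)
  if (total == 0) {
    abort("all interaction profiles are zero: GIP bandwidth undefined")
  }
  denom <- if (average) total / nrow(profiles) else total
  gamma <- gamma_prime / denom
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0 # numerical noise
  k <- exp(-gamma * d2)
  diag(k) <- 1
  k <- (k + t(k)) / 2
  dimnames(k) <- list(rownames(profiles), rownames(profiles))
  k
}

#' Best-match-average functional similarity
#'
#' Functional similarity of two entities (miRNAs or lncRNAs) from the
#' semantic similarity of their associated disease sets: each disease of one
#' entity is matched to its most similar disease of the other, and the
#' best-match scores from both directions are averaged over the total number
#' of diseases (p + q). Entities sharing a disease set score 1; an entity
#' without any associated disease scores 0 against every other entity
#' (diagonal stays 1 by convention).
#'
#' @param assoc Binary incidence matrix (entities x diseases).
#' @param disease_sim Square similarity matrix over the same diseases, unit
#'   diagonal, entries in \[0, 1\].
#' @return Symmetric similarity matrix (entities x entities) with unit
#'   diagonal, entries in \[0, 1\].
#' @export
functional_similarity <- function(assoc, disease_sim) {
  stopifnot(is.matrix(assoc), is.matrix(disease_sim),
            ncol(assoc) == nrow(disease_sim),
            nrow(disease_sim) == ncol(disease_sim))
  n <- nrow(assoc)
  sets <- lapply(seq_len(n), function(e) which(assoc[e, ] != 0))
  sizes <- lengths(sets)
  # best_match[e, d]: similarity of disease d to its best match in entity
  # e's disease set (0 for an empty set)
  best_match <- matrix(0, n, ncol(assoc))
  for (e in seq_len(n)) {
    if (sizes[e] == 1) {
      best_match[e, ] <- disease_sim[, sets[[e]]]
    } else if (sizes[e] > 1) {
      best_match[e, ] <- apply(disease_sim[, sets[[e]], drop = FALSE], 1, max)
    }
  }
  sim <- diag(1, n)
  if (n >= 2) {
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        p <- sizes[a]
        q <- sizes[b]
        if (p == 0 || q == 0) next
        s <- (sum(best_match[b, sets[[a]]]) + sum(best_match[a, sets[[b]]])) /
          (p + q)
        sim[a, b] <- s
        sim[b, a] <- s
      }
    }
  }
  dimnames(sim) <- list(rownames(assoc), rownames(assoc))
  sim
}
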