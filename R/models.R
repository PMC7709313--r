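#' Fit the multiple linear regression scorer
#'
#' Least-squares fit of the association-probability targets on the pair
#' feature vectors, with an intercept prepended to every feature vector. The
#' coefficients are the minimum-norm least-squares solution (Moore-Penrose
#' pseudo-inverse), so perfectly collinear feature columns yield finite
#' coefficients with unchanged predictions.
#'
#' @param x Feature matrix, one pair per row (no intercept column).
#' @param y Numeric target vector, `length(y) == nrow(x)`.
#' @return An object of class `fvtlda_mlr` with elements `coefficients`
#'   (intercept first), `fitted`, `residuals` and `nobs`.
#' @export
fit_mlr <- function(x, y) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) == 0) {
    abort("cannot fit regression on zero samples")
  }
  stopifnot(nrow(x) == length(y))
  design <- cbind(1, x)
  w <- as.numeric(MASS::ginv(design) %*% y)
  names(w) <- c("(Intercept)",
                colnames(x) %||% paste0("f", seq_len(ncol(x))))
  fitted <- as.numeric(design %*% w)
  structure(
    list(coefficients = w, fitted = fitted, residuals = y - fitted,
         nobs = nrow(x)),
    class = "fvtlda_mlr"
  )
}

#' @export
print.fvtlda_mlr <- function(x, ...) {
  cat("<fvtlda_mlr> linear scorer:", length(x$coefficients) - 1,
      "features,", x$nobs, "training pairs\n")
  invisible(x)
}

#' Predict association scores from a linear scorer
#'
#' @param object A [fit_mlr()] model.
#' @param newdata Feature matrix (pairs x features) or a single feature
#'   vector.
#' @param ... Unused.
#' @return Numeric score vector (unclamped; scores are used for ranking).
#' @export
predict.fvtlda_mlr <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1)
  }
  if (ncol(newdata) != length(object$coefficients) - 1) {
    abort(sprintf("feature dimension %d does not match model dimension %d",
                  ncol(newdata), length(object$coefficients) - 1))
  }
  as.numeric(cbind(1, newdata) %*% object$coefficients)
}

#' @method tidy fvtlda_mlr
#' @export
tidy.fvtlda_mlr <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @method glance fvtlda_mlr
#' @export
glance.fvtlda_mlr <- function(x, ...) {
  y <- x$fitted + x$residuals
  tss <- sum((y - mean(y))^2)
  rss <- sum(x$residuals^2)
  tibble::tibble(
    r.squared = if (tss > 0) 1 - rss / tss else NA_real_,
    sigma = sqrt(rss / max(1, x$nobs - length(x$coefficients))),
    nobs = x$nobs
  )
}

#' Hidden-layer activation function
#'
#' The sigmoid `2 / (1 + exp(-2 * x)) - 1`, mapping to (-1, 1); algebraically
#' identical to `tanh(x)`.
#'
#' @param x Numeric vector or matrix of pre-activations.
#' @return Activations of the same shape.
#' @export
hidden_activation <- function(x) {
  2 / (1 + exp(-2 * x)) - 1
}

ann_forward <- function(par, x) {
  h <- hidden_activation(sweep(x %*% par$w1, 2, par$b1, "+"))
  list(hidden = h, output = as.numeric(h %*% par$w2 + par$b2))
}

ann_mse <- function(par, x, y) {
  mean((ann_forward(par, x)$output - y)^2)
}

# Jacobian of the network outputs with respect to all parameters, one row
# per sample; column order matches ann_unflatten (vec(w1), b1, w2, b2).
ann_jacobian <- function(par, x) {
  h <- hidden_activation(sweep(x %*% par$w1, 2, par$b1, "+"))
  a <- sweep(1 - h^2, 2, par$w2, "*") # d(output)/d(pre-activation_j)
  p <- ncol(x)
  nh <- length(par$w2)
  j_w1 <- matrix(0, nrow(x), p * nh)
  for (k in seq_len(nh)) {
    j_w1[, (k - 1) * p + seq_len(p)] <- x * a[, k]
  }
  cbind(j_w1, a, h, 1)
}

ann_unflatten <- function(theta, p, nh) {
  list(
    w1 = matrix(theta[seq_len(p * nh)], p, nh),
    b1 = theta[p * nh + seq_len(nh)],
    w2 = theta[p * nh + nh + seq_len(nh)],
    b2 = theta[p * nh + 2 * nh + 1]
  )
}

ann_flatten <- function(par) {
  c(as.numeric(par$w1), par$b1, par$w2, par$b2)
}

#' Fit the neural-network scorer
#'
#' Trains a single-hidden-layer feed-forward network (sigmoid hidden layer,
#' see [hidden_activation()]; one linear output neuron) to map pair feature
#' vectors to association-probability targets. Samples are split at random
#' into training, validation and test portions in a 3:1:1 ratio. A damped
#' Gauss-Newton (Levenberg-Marquardt) iteration minimizes the training MSE:
#' each epoch solves `(J'J + mu I) step = J'e` and the damping `mu` is
#' decreased after an accepted step and increased until a step improves.
#' Training stops at `max_epochs`, when training MSE reaches `mse_goal`, or
#' when the validation MSE has not improved for `patience` consecutive
#' epochs -- in every case the best-validation-epoch weights are restored.
#' The test portion is only reported, never used for stopping. Inputs are
#' min-max mapped to \[-1, 1\] per feature (the standard preprocessing of
#' feed-forward toolchains; constant features map to 0); the mapping is
#' stored in the model and reapplied at prediction.
#'
#' @param x Feature matrix, one pair per row.
#' @param y Numeric target vector.
#' @param hidden Hidden-layer size; default 10.
#' @param max_epochs Maximum training epochs; default 100.
#' @param mse_goal Training-MSE stopping goal; default 0.001.
#' @param patience Consecutive non-improving validation epochs tolerated;
#'   default 15.
#' @param damping Initial Levenberg-Marquardt damping `mu`; multiplied by 10
#'   on a rejected step and by 0.1 on an accepted one.
#' @param seed Optional RNG seed making the split, the uniform
#'   \[-0.5, 0.5\] weight initialization, and hence the fit reproducible.
#' @return An object of class `fvtlda_ann` with the layer weights, the
#'   input scaling, the training `trace` (one row per epoch) and the split
#'   indices.
#' @export
fit_ann <- function(x, y, hidden = 10, max_epochs = 100, mse_goal = 0.001,
                    patience = 15, damping = 0.001, seed = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), hidden >= 1, max_epochs >= 1,
            mse_goal > 0, patience >= 1, damping > 0)
  n <- nrow(x)
  if (n < 5) {
    abort("need at least 5 samples for the 3:1:1 train/validation/test split")
  }
  run <- function() {
    # input scaling to [-1, 1]
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    span <- hi - lo
    span[span == 0] <- 1
    xs <- sweep(sweep(x, 2, lo), 2, span, "/") * 2 - 1
    xs[, hi == lo] <- 0

    idx <- sample.int(n)
    n_train <- max(1L, round(n * 3 / 5))
    n_val <- max(1L, round(n / 5))
    train_idx <- idx[seq_len(n_train)]
    val_idx <- idx[n_train + seq_len(min(n_val, n - n_train - 1))]
    test_idx <- setdiff(idx, c(train_idx, val_idx))

    p <- ncol(x)
    par <- list(
      w1 = matrix(runif(p * hidden, -0.5, 0.5), p, hidden),
      b1 = runif(hidden, -0.5, 0.5),
      w2 = runif(hidden, -0.5, 0.5),
      b2 = runif(1, -0.5, 0.5)
    )
    xt <- xs[train_idx, , drop = FALSE]
    yt <- y[train_idx]
    xv <- xs[val_idx, , drop = FALSE]
    yv <- y[val_idx]

    mu <- damping
    theta <- ann_flatten(par)
    n_par <- length(theta)
    train_mse <- ann_mse(par, xt, yt)
    best <- list(par = par, val = ann_mse(par, xv, yv), epoch = 0L)
    stall <- 0L
    trace <- vector("list", max_epochs)
    stopped <- "max_epochs"
    epoch_done <- 0L
    for (epoch in seq_len(max_epochs)) {
      jac <- ann_jacobian(par, xt)
      err <- ann_forward(par, xt)$output - yt
      jtj <- crossprod(jac)
      jte <- crossprod(jac, err)
      # increase damping until a step lowers the training MSE (or give up)
      for (try in 1:20) {
        step <- tryCatch(
          solve(jtj + mu * diag(n_par), jte),
          error = function(e) NULL
        )
        if (!is.null(step)) {
          cand_theta <- theta - as.numeric(step)
          cand <- ann_unflatten(cand_theta, ncol(x), hidden)
          cand_mse <- ann_mse(cand, xt, yt)
          if (cand_mse < train_mse) {
            theta <- cand_theta
            par <- cand
            train_mse <- cand_mse
            mu <- max(mu * 0.1, 1e-12)
            break
          }
        }
        mu <- mu * 10
        if (mu > 1e10) break
      }
      val_mse <- ann_mse(par, xv, yv)
      trace[[epoch]] <- tibble::tibble(
        epoch = epoch, train_mse = train_mse, val_mse = val_mse, mu = mu
      )
      if (val_mse < best$val) {
        best <- list(par = par, val = val_mse, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      epoch_done <- epoch
      if (train_mse <= mse_goal) {
        stopped <- "mse_goal"
        break
      }
      if (stall >= patience) {
        stopped <- "patience"
        break
      }
      if (mu > 1e10) {
        stopped <- "damping_limit"
        break
      }
    }
    par <- best$par
    list(
      par = par, scale_lo = lo, scale_span = span, constant = hi == lo,
      trace = dplyr::bind_rows(trace[seq_len(epoch_done)]),
      stopped = stopped,
      split = list(train = train_idx, validation = val_idx, test = test_idx),
      train_mse = ann_mse(par, xt, yt),
      val_mse = best$val,
      test_mse = if (length(test_idx) > 0) {
        ann_mse(par, xs[test_idx, , drop = FALSE], y[test_idx])
      } else {
        NA_real_
      }
    )
  }
  fit <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    c(fit, list(hidden = hidden, seed = seed, nobs = n,
                config = list(max_epochs = max_epochs, mse_goal = mse_goal,
                              patience = patience, damping = damping))),
    class = "fvtlda_ann"
  )
}

#' @export
print.fvtlda_ann <- function(x, ...) {
  cat("<fvtlda_ann> ", nrow(x$par$w1), "-", x$hidden, "-1 network, ",
      x$nobs, " pairs, stopped by ", x$stopped,
      " after ", nrow(x$trace), " epoch(s)\n", sep = "")
  invisible(x)
}

#' Predict association scores from the neural-network scorer
#'
#' @param object A [fit_ann()] model.
#' @param newdata Feature matrix or single feature vector.
#' @param ... Unused.
#' @return Numeric score vector.
#' @export
predict.fvtlda_ann <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1)
  }
  if (ncol(newdata) != nrow(object$par$w1)) {
    abort(sprintf("feature dimension %d does not match model dimension %d",
                  ncol(newdata), nrow(object$par$w1)))
  }
  xs <- sweep(sweep(newdata, 2, object$scale_lo), 2, object$scale_span,
              "/") * 2 - 1
  xs[, object$constant] <- 0
  ann_forward(object$par, xs)$output
}

#' @method tidy fvtlda_ann
#' @export
tidy.fvtlda_ann <- function(x, ...) {
  p <- nrow(x$par$w1)
  h <- x$hidden
  input_names <- rownames(x$par$w1) %||% paste0("f", seq_len(p))
  dplyr::bind_rows(
    tidyr::expand_grid(from = input_names, to = paste0("h", seq_len(h))) |>
      dplyr::mutate(layer = "hidden",
                    weight = as.numeric(t(x$par$w1))),
    tibble::tibble(layer = "hidden", from = "(bias)",
                   to = paste0("h", seq_len(h)), weight = x$par$b1),
    tibble::tibble(layer = "output", from = paste0("h", seq_len(h)),
                   to = "score", weight = x$par$w2),
    tibble::tibble(layer = "output", from = "(bias)", to = "score",
                   weight = x$par$b2)
  )[, c("layer", "from", "to", "weight")]
}

#' @method glance fvtlda_ann
#' @export
glance.fvtlda_ann <- function(x, ...) {
  tibble::tibble(
    hidden = x$hidden,
    epochs = nrow(x$trace),
    stopped = x$stopped,
    train_mse = x$train_mse,
    val_mse = x$val_mse,
    test_mse = x$test_mse,
    nobs = x$nobs
  )
}
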