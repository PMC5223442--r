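# NIPALS partial least squares on mean-centred data.
#
# Descriptors share units (kcal/mol), so columns are centred but not scaled
# to unit variance. At full rank (n_latent = ncol(X), X of full column rank)
# the PLS solution coincides with ordinary least squares, which the LOO fast
# path below exploits.

#' Fit a PLS regression model
#'
#' NIPALS with column mean-centring; the latent-variable solution is folded
#' back into one coefficient per descriptor plus an intercept, so prediction
#' is a plain affine map.
#'
#' @param X numeric matrix (rows = molecules, labelled columns).
#' @param y numeric response (pIC50), length `nrow(X)`.
#' @param n_latent number of latent variables (1 <= n_latent <= ncol(X)).
#' @return object of class `pls_fit`: list with `labels`, `coefficients`,
#'   `intercept`, `n_latent`.
#' @export
fit_pls <- function(X, y, n_latent = min(ncol(X), nrow(X) - 1L)) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), n_latent >= 1L)
  if (stats::var(y) == 0) stop("response has zero variance")
  n_latent <- min(n_latent, ncol(X))
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar); yc <- y - ybar
  p <- ncol(X)
  W <- P <- matrix(0, p, n_latent)
  qvec <- numeric(n_latent)
  used <- 0L
  for (a in seq_len(n_latent)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break # response deflated to noise; stop early
    w <- w / nw
    t_ <- Xc %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) break
    pvec <- crossprod(Xc, t_) / tt
    qa <- sum(t_ * yc) / tt
    Xc <- Xc - t_ %*% t(pvec)
    yc <- yc - qa * t_
    W[, a] <- w; P[, a] <- pvec; qvec[a] <- qa
    used <- a
  }
  if (used == 0L) {
    beta <- rep(0, p)
  } else {
    W <- W[, seq_len(used), drop = FALSE]
    P <- P[, seq_len(used), drop = FALSE]
    qvec <- qvec[seq_len(used)]
    # B = W (P'W)^-1 q ; P'W is upper triangular and well conditioned
    beta <- as.numeric(W %*% solve(crossprod(P, W), qvec))
  }
  structure(list(labels = colnames(X), coefficients = stats::setNames(beta, colnames(X)),
                 intercept = ybar - sum(xbar * beta), n_latent = used),
            class = "pls_fit")
}

#' @export
predict.pls_fit <- function(object, newdata, ...) {
  .predict_linear(object, newdata)
}

.predict_linear <- function(object, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
                                               dimnames = list(NULL, object$labels))
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$labels, colnames(newdata))
  if (length(missing))
    stop("descriptor label(s) missing from new data: ",
         paste(missing, collapse = ", "))
  drop(newdata[, object$labels, drop = FALSE] %*% object$coefficients) +
    object$intercept
}

# Leave-one-out predictions for a PLS spec. Fast path: when n_latent equals
# the column count and the centred design has full rank, PLS == OLS and the
# LOO residual is e_i / (1 - h_ii); otherwise each fold is refit. A
# rank-deficient fold falls back to that fold's training mean (logged).
.loo_predictions <- function(X, y, n_latent) {
  X <- as.matrix(X); n <- nrow(X)
  if (n_latent >= ncol(X)) {
    Z <- cbind(1, X)
    qz <- qr(Z)
    if (qz$rank == ncol(Z)) {
      e <- qr.resid(qz, y)
      Q <- qr.Q(qz)
      h <- rowSums(Q[, seq_len(qz$rank), drop = FALSE]^2)
      if (all(h < 1 - 1e-10)) return(y - e / (1 - h))
    }
  }
  yhat <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(fit_pls(X[-i, , drop = FALSE], y[-i], n_latent),
                    error = function(e) NULL)
    yhat[i] <- if (is.null(fit)) {
      message("degenerate LOO fold ", i, ": predicting fold training mean")
      mean(y[-i])
    } else .predict_linear(fit, X[i, , drop = FALSE])
  }
  yhat
}

#' Leave-one-out cross-validated q2
#'
#' `q2 = 1 - sum((y_i - yhat_i)^2) / sum((y_i - y_mean)^2)` where each
#' `yhat_i` comes from a model refit without row i and `y_mean` is the mean
#' over the full training set.
#'
#' @param X descriptor matrix restricted to the model columns.
#' @param y activities.
#' @param n_latent latent-variable count of the refit models.
#' @return numeric q2, with the LOO predictions in attribute
#'   `loo_predictions`.
#' @export
q_squared_loo <- function(X, y, n_latent = min(ncol(as.matrix(X)), 5L)) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("need at least 3 rows for leave-one-out validation")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("zero denominator: response is constant")
  yhat <- .loo_predictions(X, y, n_latent)
  structure(1 - sum((y - yhat)^2) / tss, loo_predictions = yhat)
}

#' Coefficient of determination on an external test set
#'
#' `pred_r2 = 1 - sum((y_i - yhat_i)^2) / sum((y_i - y_mean)^2)` with
#' `y_mean` the mean activity of the test set itself.
#'
#' @param model a fitted `pls_fit`/`qsar` object.
#' @param X_test,y_test external test descriptors and activities.
#' @return numeric pred_r2 with predictions in attribute `predictions`.
#' @export
pred_r_squared <- function(model, X_test, y_test) {
  yhat <- .predict_linear(model, X_test)
  tss <- sum((y_test - mean(y_test))^2)
  if (tss == 0) stop("zero denominator: test activities are constant")
  structure(1 - sum((y_test - yhat)^2) / tss, predictions = yhat)
}

#' Regression F statistic from r2
#'
#' `F = (r2 / k) / ((1 - r2) / (n - k - 1))` for n observations and k
#' regressors; n and k are explicit arguments because reported QSAR F values
#' are only interpretable alongside them.
#'
#' @param r2 coefficient of determination (0 <= r2 < 1).
#' @param n number of observations.
#' @param k number of regressors.
#' @export
f_statistic <- function(r2, n, k) {
  stopifnot(n > k + 1, k >= 1)
  if (r2 >= 1) stop("F undefined for r2 = 1")
  if (r2 < 0) return(0)
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Stepwise-forward descriptor selection by LOO q2
#'
#' Greedily adds the descriptor whose inclusion maximises the leave-one-out
#' q2 of the refitted model, stopping at `max_terms` terms or when the best
#' gain falls below `min_q2_gain`. Deterministic; ties are broken by the
#' lower column index.
#'
#' @param X full descriptor matrix (labelled columns).
#' @param y activities.
#' @param max_terms maximum number of descriptors.
#' @param min_q2_gain minimum q2 improvement to keep adding.
#' @param n_latent_max cap on latent variables during scoring.
#' @return character vector of selected labels, with the q2 path in
#'   attribute `q2_path`.
#' @export
stepwise_forward_select <- function(X, y, max_terms = 4L, min_q2_gain = 0.001,
                                    n_latent_max = 5L) {
  X <- as.matrix(X)
  if (nrow(X) < 6L) stop("need at least 6 training rows for stepwise selection")
  selected <- integer(0)
  q2_path <- numeric(0)
  best_q2 <- -Inf
  while (length(selected) < max_terms && length(selected) < ncol(X)) {
    cand <- setdiff(seq_len(ncol(X)), selected)
    q2s <- vapply(cand, function(j) {
      Xs <- X[, c(selected, j), drop = FALSE]
      as.numeric(q_squared_loo(Xs, y, min(ncol(Xs), n_latent_max)))
    }, numeric(1))
    j_best <- cand[which.max(q2s)] # which.max: first max, i.e. lowest index
    gain <- max(q2s) - if (length(selected)) best_q2 else -Inf
    if (length(selected) && gain < min_q2_gain) break
    selected <- c(selected, j_best)
    best_q2 <- max(q2s)
    q2_path <- c(q2_path, best_q2)
  }
  structure(colnames(X)[selected], q2_path = q2_path)
}

#' Y-randomization (response scrambling) test
#'
#' Refits the model on permuted activities `n_perm` times, collects the
#' permuted-model r2 and LOO q2 distributions, and summarises the true
#' model's separation from chance as `z = (h - mu) / sigma` where `h` is the
#' true q2 and `mu`, `sigma` are the mean and sd of the permuted q2 values.
#'
#' @param X descriptor matrix restricted to the selected columns.
#' @param y activities.
#' @param n_latent latent-variable count used for each refit.
#' @param n_perm number of permutations (>= 10).
#' @param seed RNG seed.
#' @param h the true model's q2; computed from `X`, `y` when `NULL`.
#' @return object of class `y_randomization`.
#' @export
y_randomization <- function(X, y, n_latent = min(ncol(as.matrix(X)), 5L),
                            n_perm = 100L, seed = 1L, h = NULL) {
  stopifnot(n_perm >= 10L)
  X <- as.matrix(X)
  if (is.null(h)) h <- as.numeric(q_squared_loo(X, y, n_latent))
  perms <- .with_seed(seed, replicate(n_perm, sample(y), simplify = FALSE))
  q2p <- r2p <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    yp <- perms[[i]]
    fit <- fit_pls(X, yp, n_latent)
    r2p[i] <- 1 - sum((yp - .predict_linear(fit, X))^2) / sum((yp - mean(yp))^2)
    q2p[i] <- as.numeric(q_squared_loo(X, yp, n_latent))
  }
  mu <- mean(q2p); sigma <- stats::sd(q2p)
  z <- if (sigma > 0) (h - mu) / sigma else NA_real_
  structure(list(q2_perm = q2p, r2_perm = r2p, mu = mu, sigma = sigma,
                 h = h, z = z, best_rand_r2 = max(r2p), best_rand_q2 = max(q2p),
                 n_perm = n_perm, seed = seed),
            class = "y_randomization")
}

#' @export
print.y_randomization <- function(x, ...) {
  cat(sprintf("Y-randomization (%d permutations): true q2 %.4f, permuted mu %.4f sd %.4f\n",
              x$n_perm, x$h, x$mu, x$sigma))
  cat(sprintf("  Z = %.3f   best random r2 %.4f   best random q2 %.4f\n",
              x$z, x$best_rand_r2, x$best_rand_q2))
  invisible(x)
}

#' Signed percentage contribution of each descriptor
#'
#' `sign(coef_j) * 100 * |coef_j * sd(x_j)| / sum_l |coef_l * sd(x_l)|`:
#' the share of the model's explained spread carried by each descriptor,
#' signed by the direction of its effect. Absolute values sum to 100.
#'
#' @param model fitted `pls_fit`/`qsar` object.
#' @param X training descriptor matrix.
#' @return named numeric vector of signed percentages.
#' @export
contribution_percentages <- function(model, X) {
  X <- as.matrix(X)[, model$labels, drop = FALSE]
  w <- model$coefficients * apply(X, 2L, stats::sd)
  tot <- sum(abs(w))
  if (tot == 0) stop("all contributions are zero (zero coefficients or constant columns)")
  sign(model$coefficients) * 100 * abs(w) / tot
}
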