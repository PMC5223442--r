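#' Fit a grid-field 3D-QSAR model
#'
#' The central fitting function: stepwise-forward descriptor selection by
#' leave-one-out q2, a NIPALS PLS fit with the latent-variable count chosen
#' to maximise LOO q2 (capped at `min(n_latent_max, n selected)`), and the
#' full validation block — r2, q2, their standard errors, external pred_r2,
#' the regression F statistic, per-descriptor signed contribution
#' percentages, and a seeded Y-randomization test with Z-scores.
#'
#' @param x training descriptor matrix (molecule rows, labelled columns),
#'   typically a `descriptor_matrix` after [drop_invariant_columns()].
#' @param y training activities (pIC50), in row order of `x` or named by
#'   molecule id.
#' @param x_test,y_test optional external test set for pred_r2.
#' @param max_terms maximum number of descriptors selected.
#' @param min_q2_gain stepwise stopping threshold on q2 improvement.
#' @param n_latent_max cap on PLS latent variables.
#' @param n_perm Y-randomization permutation count (0 disables the test).
#' @param seed RNG seed for the randomization test.
#' @return an object of class `qsar`; see [predict.qsar()], [summary.qsar()].
#' @examples
#' set.seed(7)
#' X <- matrix(rnorm(30 * 6), 30, dimnames = list(NULL, paste0("S_", 0:5)))
#' y <- 2 * X[, "S_2"] - X[, "S_5"] + 6 + rnorm(30, sd = 0.1)
#' fit <- qsar(X, y, n_perm = 20)
#' coef(fit)
#' @export
qsar <- function(x, y, x_test = NULL, y_test = NULL,
                 max_terms = 4L, min_q2_gain = 0.001, n_latent_max = 5L,
                 n_perm = 100L, seed = 1L) {
  x <- as.matrix(x)
  if (!is.null(names(y)) && !is.null(rownames(x)))
    y <- y[rownames(x)]
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))

  labels <- stepwise_forward_select(x, y, max_terms = max_terms,
                                    min_q2_gain = min_q2_gain,
                                    n_latent_max = n_latent_max)
  if (!length(labels)) stop("stepwise selection returned no descriptors")
  Xs <- x[, labels, drop = FALSE]

  # choose n_latent maximising LOO q2
  ncomp_max <- min(n_latent_max, ncol(Xs))
  q2_by_ncomp <- vapply(seq_len(ncomp_max), function(a)
    as.numeric(q_squared_loo(Xs, y, a)), numeric(1))
  n_latent <- which.max(q2_by_ncomp)

  fit <- fit_pls(Xs, y, n_latent)
  fitted <- .predict_linear(fit, Xs)
  resid <- y - fitted
  n <- length(y); k <- length(labels)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  q2 <- q_squared_loo(Xs, y, n_latent)
  loo_pred <- attr(q2, "loo_predictions")

  val <- list(
    n = n, k = k,
    r2 = r2,
    r2_se = sqrt(mean(resid^2)),
    q2 = as.numeric(q2),
    q2_se = sqrt(mean((y - loo_pred)^2)),
    f_stat = if (r2 < 1) f_statistic(r2, n, k) else Inf,
    contribution_pct = contribution_percentages(fit, Xs))

  pred <- NULL
  if (!is.null(x_test)) {
    if (!is.null(y_test) && !is.null(names(y_test)) && !is.null(rownames(x_test)))
      y_test <- y_test[rownames(x_test)]
    pr2 <- pred_r_squared(fit, as.matrix(x_test)[, labels, drop = FALSE], y_test)
    val$pred_r2 <- as.numeric(pr2)
    val$pred_r2_se <- sqrt(mean((y_test - attr(pr2, "predictions"))^2))
    pred <- attr(pr2, "predictions")
  }

  rand <- NULL
  if (n_perm > 0L) {
    rand <- y_randomization(Xs, y, n_latent, n_perm = n_perm, seed = seed,
                            h = val$q2)
    val$z_score_q2 <- rand$z
    mu_r <- mean(rand$r2_perm); sd_r <- stats::sd(rand$r2_perm)
    val$z_score_r2 <- if (sd_r > 0) (r2 - mu_r) / sd_r else NA_real_
    val$best_rand_r2 <- rand$best_rand_r2
    val$best_rand_q2 <- rand$best_rand_q2
  }

  structure(list(labels = labels, coefficients = fit$coefficients,
                 intercept = fit$intercept, n_latent = n_latent,
                 train_ids = rownames(x), y = y, fitted = fitted,
                 residuals = resid, loo_predictions = loo_pred,
                 test_ids = if (is.null(x_test)) NULL else rownames(x_test),
                 y_test = if (is.null(x_test)) NULL else as.numeric(y_test),
                 test_predictions = pred,
                 validation = val, randomization = rand,
                 q2_by_ncomp = q2_by_ncomp,
                 grid = attr(x, "grid"), call = match.call()),
            class = c("qsar", "pls_fit"))
}

#' Construct a QSAR model from known coefficients
#'
#' Builds a bare `qsar` object from a published or externally derived
#' field-descriptor equation so it can be evaluated with [predict.qsar()].
#'
#' @param labels descriptor labels.
#' @param coefficients numeric coefficients, one per label.
#' @param intercept model intercept (pIC50 units).
#' @param n_latent latent-variable count (metadata only).
#' @return object of class `qsar`.
#' @examples
#' eq <- qsar_model(c("E_1657", "S_1911", "S_1696"),
#'                  c(2.83451, 2.68845, -3.97667), 2.80171)
#' predict(eq, setNames(rep(0, 3), eq$labels))
#' @export
qsar_model <- function(labels, coefficients, intercept, n_latent = length(labels)) {
  stopifnot(length(labels) == length(coefficients))
  structure(list(labels = as.character(labels),
                 coefficients = stats::setNames(as.numeric(coefficients), labels),
                 intercept = as.numeric(intercept),
                 n_latent = as.integer(n_latent), validation = NULL),
            class = c("qsar", "pls_fit"))
}

#' Predict activities from a fitted QSAR model
#'
#' @param object a `qsar` model.
#' @param newdata matrix/data.frame of descriptor rows (must contain every
#'   selected label; a missing label is an error naming it), or a named
#'   vector for a single molecule.
#' @param ... unused.
#' @return numeric predicted pIC50 values.
#' @export
predict.qsar <- function(object, newdata, ...) {
  if (is.null(dim(newdata)) && !is.null(names(newdata)))
    newdata <- matrix(newdata, nrow = 1L, dimnames = list(NULL, names(newdata)))
  .predict_linear(object, newdata)
}

#' @export
coef.qsar <- function(object, ...) {
  c(object$coefficients, `(Intercept)` = object$intercept)
}

#' @export
residuals.qsar <- function(object, ...) object$residuals

#' @export
fitted.qsar <- function(object, ...) object$fitted

#' @export
print.qsar <- function(x, ...) {
  terms <- paste(sprintf("%+.5g (%s)", x$coefficients, x$labels), collapse = " ")
  cat("Grid-field 3D-QSAR model (PLS, ", x$n_latent, " latent variable",
      if (x$n_latent != 1L) "s", ")\n", sep = "")
  cat("  pIC50 =", terms, sprintf("%+.5g", x$intercept), "\n")
  v <- x$validation
  if (!is.null(v)) {
    cat(sprintf("  n = %d, k = %d: r2 %.4f (se %.4f), q2 %.4f (se %.4f), F %.4f\n",
                v$n, v$k, v$r2, v$r2_se, v$q2, v$q2_se, v$f_stat))
    if (!is.null(v$pred_r2))
      cat(sprintf("  external: pred_r2 %.4f (se %.4f)\n", v$pred_r2, v$pred_r2_se))
  }
  invisible(x)
}

#' @export
summary.qsar <- function(object, ...) {
  structure(object, class = c("summary.qsar", class(object)))
}

#' @export
print.summary.qsar <- function(x, ...) {
  print.qsar(x)
  v <- x$validation
  if (!is.null(v$contribution_pct)) {
    cat("  Contribution (%):\n")
    for (l in names(v$contribution_pct))
      cat(sprintf("    %-8s %+8.3f\n", l, v$contribution_pct[[l]]))
  }
  if (!is.null(x$randomization)) print(x$randomization)
  if (!is.null(v$z_score_r2))
    cat(sprintf("  Z-score r2 %.3f, Z-score q2 %.3f\n", v$z_score_r2, v$z_score_q2))
  invisible(x)
}

#' Actual-versus-predicted fitness plot
#'
#' @param x a fitted `qsar` with stored training (and optionally test) data.
#' @param ... passed to `plot`.
#' @method plot qsar
#' @export
plot.qsar <- function(x, ...) {
  if (is.null(x$y)) stop("model carries no training data to plot")
  rng <- range(c(x$y, x$fitted, x$y_test, x$test_predictions))
  graphics::plot(x$y, x$fitted, xlim = rng, ylim = rng,
                 xlab = "actual pIC50", ylab = "predicted pIC50",
                 main = "QSAR fitness plot", pch = 19, ...)
  if (!is.null(x$test_predictions))
    graphics::points(x$y_test, x$test_predictions, pch = 17, col = 2)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Export the actual/predicted table behind the fitness plot
#' @param fit a fitted `qsar`.
#' @param path CSV output path.
#' @export
write_fitness_table <- function(fit, path) {
  tr <- data.frame(molecule_id = fit$train_ids %||% seq_along(fit$y),
                   subset = "train", actual = fit$y, predicted = fit$fitted,
                   loo_predicted = fit$loo_predictions)
  if (!is.null(fit$test_predictions)) {
    te <- data.frame(molecule_id = fit$test_ids %||% seq_along(fit$y_test),
                     subset = "test", actual = fit$y_test,
                     predicted = fit$test_predictions, loo_predicted = NA_real_)
    tr <- rbind(tr, te)
  }
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a QSAR model as YAML
#' @param fit a `qsar` model.
#' @param path YAML file path.
#' @export
save_qsar <- function(fit, path) {
  yaml::write_yaml(list(labels = as.list(fit$labels),
                        coefficients = as.list(unname(fit$coefficients)),
                        intercept = fit$intercept, n_latent = fit$n_latent,
                        validation = fit$validation[
                          setdiff(names(fit$validation), "contribution_pct")],
                        contribution_pct = as.list(fit$validation$contribution_pct)),
                   path, precision = 15L)
  invisible(path)
}

#' @rdname save_qsar
#' @export
load_qsar <- function(path) {
  y <- yaml::read_yaml(path)
  m <- qsar_model(unlist(y$labels), unlist(y$coefficients), y$intercept,
                  y$n_latent %||% length(y$labels))
  m$validation <- y$validation
  m
}
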