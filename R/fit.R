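# Training of the nonlinear scorer: loss assembly and constrained
# minimization, plus the S3 modelling surface.

#' Loss of the nonlinear scorer
#'
#' Assembles the training loss
#' `L = (sum_j E_j) / N + lambda * R1 + beta * R2`, where `E_j` is the mean
#' absolute error of the continuous scores within clinician level `j`, `N`
#' the number of distinct levels present, `R1 = sum_k (w_k sd(x_k))^2` a
#' scale-aware L2 penalty, and
#' `R2 = 1/(bu-p4) + 1/(p4-p3) + 1/(p3-p2) + 1/(p2-p1) + 1/(p1-bl)` a
#' barrier keeping neighbouring hyperplanes apart.
#'
#' @param params a [scorer_params].
#' @param x feature matrix (rows = subjects, columns in `params` order).
#' @param y integer vector of clinician-rated levels.
#' @param lambda,beta penalty weights (study values 0.1 and 0.005).
#' @param std_x per-feature standard deviations of the *training* set; by
#'   default computed from `x` (sample sd, denominator n-1).
#' @param huber_delta optional smoothing half-width for the absolute error;
#'   `NULL` keeps the exact `|.|`.
#' @return list of class `loss_breakdown`: `E` (named by level), `R1`,
#'   `R2`, `N`, `std_x`, `total`.
#' @export
scorer_loss <- function(params, x, y, lambda = 0.1, beta = 0.005,
                        std_x = NULL, huber_delta = NULL) {
  x <- as.matrix(x)
  if (!nrow(x)) abort_gs("empty dataset", "gaitscore_model_error")
  if (nrow(x) != length(y))
    abort_gs("x and y disagree in length", "gaitscore_model_error")
  std_x <- std_x %||% apply(x, 2, stats::sd)
  std_x[!is.finite(std_x)] <- 0  # a single row carries no scale information
  gaps <- diff(c(params$bl, params$p, params$bu))
  if (any(gaps <= 0))
    abort_gs("zero or negative hyperplane gap: R2 undefined",
             "gaitscore_model_error")
  scores <- score_features(x, params)
  err <- abs(scores - y)
  if (!is.null(huber_delta)) {
    d <- huber_delta
    err <- ifelse(err <= d, err^2 / (2 * d), err - d / 2)
  }
  E <- tapply(err, factor(y), mean)
  E <- stats::setNames(as.numeric(E), names(E))
  N <- length(E)
  R1 <- sum((params$w * std_x)^2)
  R2 <- sum(1 / gaps)
  structure(list(E = E, R1 = R1, R2 = R2, N = N, std_x = std_x,
                 lambda = lambda, beta = beta,
                 total = sum(E) / N + lambda * R1 + beta * R2),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("L = %.6g  (mean level error %.6g over %d level(s); R1 = %.4g, R2 = %.4g)\n",
              x$total, sum(x$E) / x$N, x$N, x$R1, x$R2))
  invisible(x)
}

# objective over theta = c(w, c, p); Inf outside the feasible set so the
# barrier optimizer never evaluates an invalid R2
make_objective <- function(X, Y, nf, bl, bu, lambda, beta, std_x,
                           huber_delta, eps_gap) {
  function(theta) {
    w <- theta[seq_len(nf)]
    cc <- theta[nf + 1L]
    p <- theta[nf + 2L:5L]
    gaps <- diff(c(bl, p, bu))
    if (gaps[1] < 0 || any(gaps[2:4] < eps_gap) || gaps[5] < 0 ||
        any(gaps <= 0)) return(Inf)
    pr <- scorer_params(w, cc, p, bl, bu, validate = FALSE)
    scorer_loss(pr, X, Y, lambda, beta, std_x, huber_delta)$total
  }
}

#' Fit the nonlinear gait severity scorer
#'
#' Fits the bounded parallel-hyperplane model by constrained minimization
#' of [scorer_loss()]. The linear demarcation constraints are handled with
#' a logarithmic-barrier method (`stats::constrOptim`, BFGS inner
#' iterations with central-difference gradients) from the deterministic
#' initialization `w = 0`, `c = 0`, `p = (0.5, 1.5, 2.5, 3.5)`; the
#' returned parameters always satisfy the constraints and never have a
#' larger loss than the initialization.
#'
#' @param formula model formula, e.g. `rated_level ~ SL + MH + RSZ`. The
#'   response is the clinician-rated level (integers 0-4).
#' @param data data.frame holding the response and feature columns.
#' @param lambda,beta penalty weights (defaults 0.1 and 0.005).
#' @param eps_gap numerical floor on the gaps between successive
#'   demarcations.
#' @param bl,bu score bounds.
#' @param init optional [scorer_params] starting point.
#' @param huber_delta optional smoothing of the absolute error.
#' @param control list of optimizer settings: `maxit`, `outer_iterations`,
#'   `reltol`.
#' @return object of class `gait_scorer` with components `params`
#'   ([scorer_params]), `loss` and `init_loss` (`loss_breakdown`s),
#'   `fitted` (continuous scores), `levels` (rounded), `data`, `features`,
#'   `convergence`, `call`.
#' @examples
#' sim <- generate_features(feature_gen_spec(n_per_level = c(8, 8, 8)),
#'                          seed = 1)
#' fit <- gait_scorer(rated_level ~ F1 + F2 + F3, sim$table)
#' fit
#' predict(fit, sim$table[1:3, ])
#' @export
gait_scorer <- function(formula, data, lambda = 0.1, beta = 0.005,
                        eps_gap = 1e-3, bl = -0.5, bu = 4.5, init = NULL,
                        huber_delta = NULL, control = list()) {
  mf <- stats::model.frame(formula, data)
  Y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  features <- colnames(X)
  nf <- length(features)
  if (length(unique(Y)) < 2)
    abort_gs("need at least two distinct levels to train",
             "gaitscore_model_error")
  std_x <- apply(X, 2, stats::sd)

  init <- init %||% scorer_params(rep(0, nf), 0, c(0.5, 1.5, 2.5, 3.5),
                                  bl, bu, features)
  theta0 <- c(init$w, init$c, init$p)
  ctrl <- utils::modifyList(
    list(maxit = 200, outer_iterations = 12, reltol = 1e-9), control)

  obj <- make_objective(X, Y, nf, bl, bu, lambda, beta, std_x,
                        huber_delta, eps_gap)
  if (!is.finite(obj(theta0)))
    abort_gs("infeasible initialization", "gaitscore_model_error")

  # linear constraints ui %*% theta >= ci over theta = (w, c, p1..p4)
  np <- nf + 5L
  ui <- matrix(0, 5, np)
  ci <- numeric(5)
  ui[1, nf + 2L] <- 1;                 ci[1] <- bl            # p1 >= bl
  for (i in 1:3) {                                            # gaps >= eps
    ui[1 + i, nf + 1L + i] <- -1
    ui[1 + i, nf + 2L + i] <- 1
    ci[1 + i] <- eps_gap
  }
  ui[5, nf + 5L] <- -1;                ci[5] <- -bu           # p4 <= bu

  res <- stats::constrOptim(
    theta = theta0, f = obj, grad = function(th) num_grad(obj, th),
    ui = ui, ci = ci, method = "BFGS",
    outer.iterations = ctrl$outer_iterations,
    control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))

  theta <- res$par
  if (!is.finite(res$value) || res$value > obj(theta0)) theta <- theta0
  params <- scorer_params(theta[seq_len(nf)], theta[nf + 1L],
                          theta[nf + 2L:5L], bl, bu, features)
  loss <- scorer_loss(params, X, Y, lambda, beta, std_x, huber_delta)
  fitted <- score_features(X, params)

  structure(
    list(params = params, loss = loss,
         init_loss = scorer_loss(init, X, Y, lambda, beta, std_x,
                                 huber_delta),
         fitted = fitted, levels = round_to_level(fitted),
         observed = Y, data = data, x = X, features = features,
         lambda = lambda, beta = beta, eps_gap = eps_gap,
         convergence = res$convergence, formula = formula,
         call = match.call()),
    class = "gait_scorer")
}

#' @export
print.gait_scorer <- function(x, ...) {
  cat("Nonlinear UPDRS gait-task scorer\n")
  cat("Call: "); print(x$call)
  cat(sprintf("%d subjects, features: %s\n", length(x$observed),
              paste(x$features, collapse = ", ")))
  print(x$params)
  cat(sprintf("Training loss %.5g (from %.5g at initialization)\n",
              x$loss$total, x$init_loss$total))
  invisible(x)
}

#' @export
summary.gait_scorer <- function(object, ...) {
  e <- abs(object$levels - object$observed)
  out <- list(
    call = object$call, params = object$params, loss = object$loss,
    n = length(object$observed),
    exact = mean(e == 0), within_one = mean(e <= 1),
    mean_error = mean(e),
    by_level = table(observed = object$observed,
                     predicted = object$levels))
  class(out) <- "summary.gait_scorer"
  out
}

#' @export
print.summary.gait_scorer <- function(x, ...) {
  cat("Nonlinear UPDRS gait-task scorer\n")
  print(x$params)
  print(x$loss)
  cat(sprintf(
    "In-sample: %.1f%% exact, %.1f%% within one level, mean error %.3f (n = %d)\n",
    100 * x$exact, 100 * x$within_one, x$mean_error, x$n))
  cat("Confusion (rows = clinician level):\n")
  print(x$by_level)
  invisible(x)
}

#' @export
coef.gait_scorer <- function(object, ...) {
  p <- object$params
  stats::setNames(c(p$w, p$c, p$p),
                  c(paste0("w.", object$features), "c",
                    paste0("p", 1:4)))
}

#' Predict severity scores for new subjects
#'
#' @param object a fitted `gait_scorer`.
#' @param newdata data.frame containing the model's feature columns;
#'   defaults to the training data.
#' @param type `"score"` (continuous), `"level"` (rounded) or `"both"`.
#' @param ... unused.
#' @export
predict.gait_scorer <- function(object, newdata = NULL,
                                type = c("score", "level", "both"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$x else {
    miss <- setdiff(object$features, names(newdata))
    if (length(miss))
      abort_gs(paste0("newdata is missing feature(s): ",
                      paste(miss, collapse = ", ")),
               "gaitscore_model_error")
    as.matrix(newdata[object$features])
  }
  y <- score_features(X, object$params)
  switch(type,
         score = y,
         level = round_to_level(y),
         both = data.frame(score = y, level = round_to_level(y)))
}

#' @export
residuals.gait_scorer <- function(object, ...) {
  object$fitted - object$observed
}

#' @export
fitted.gait_scorer <- function(object, ...) object$fitted

#' Plot the score transfer curve of a fitted scorer
#'
#' Draws the continuous score as a function of the signed hyperplane
#' distance, with the four demarcation hyperplanes marked, and overlays the
#' training subjects.
#'
#' @param x a `gait_scorer`.
#' @param ... passed to `plot.default`.
#' @export
plot.gait_scorer <- function(x, ...) {
  p <- x$params
  xhp_obs <- signed_distance(x$x, p)
  rng <- range(c(xhp_obs, -4, 8))
  xs <- seq(rng[1], rng[2], length.out = 400)
  ys <- piecewise_score(bounded_distance(xs, p$bl, p$bu), p)
  plot(xs, ys, type = "l", xlab = "signed hyperplane distance",
       ylab = "continuous score", ylim = c(p$bl, p$bu), ...)
  d <- inverse_bounded_distance(p$p, p$bl, p$bu)
  graphics::abline(v = d, lty = 3, col = "grey40")
  graphics::abline(h = c(0.5, 1.5, 2.5, 3.5), lty = 3, col = "grey80")
  graphics::points(xhp_obs, x$fitted, pch = 19,
                   col = x$observed + 1)
  invisible(x)
}

#' Simulate feature tables from a fitted scorer
#'
#' Draws `nsim` synthetic feature tables whose ground-truth scoring
#' structure is the fitted model, using the feature-level generator.
#'
#' @param object a fitted `gait_scorer`.
#' @param nsim number of tables.
#' @param seed RNG seed.
#' @param n_per_level subjects per level; defaults to the training level
#'   counts.
#' @param noise isotropic feature noise sd.
#' @param ... unused.
#' @return list of `nsim` data.frames (a single data.frame when
#'   `nsim = 1`).
#' @export
simulate.gait_scorer <- function(object, nsim = 1, seed = NULL,
                                 n_per_level = NULL, noise = 0, ...) {
  if (!is.null(seed)) set.seed(seed)
  counts <- table(factor(object$observed, levels = 0:4))
  n_per_level <- n_per_level %||% as.integer(counts)
  spec <- feature_gen_spec(
    n_per_level = n_per_level, w = object$params$w, c = object$params$c,
    p = object$params$p, noise = noise,
    feature_names = object$features)
  out <- lapply(seq_len(nsim),
                function(i) generate_features(spec)$table)
  if (nsim == 1) out[[1]] else out
}
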