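.design_alpha <- c(0.5, 1, 1, 1)
.design_p <- c(2L, 20L, 58L, 20L)

#' Per-design treatment-effect surface
#'
#' Evaluates the treatment-effect function \eqn{\tau_k(x)} of the four
#' synthetic benchmark designs:
#' \describe{
#'   \item{1}{\eqn{\tau_1(x) = x_1/2} (two covariates).}
#'   \item{2, 3}{\eqn{\tau(x) = \sum_{k=1}^{4} 1\{x_k > 0\} x_k}; the two
#'     designs share the surface and differ only in how many pure noise
#'     covariates accompany it (12 vs 50).}
#'   \item{4}{\eqn{\tau_4(x) = \sum_{k=1}^{4}\sin(x_k) +
#'     \sum_{k=5}^{8} x_k^{k-3}} (non-linear).}
#' }
#' Note this is the surface entering the outcome model
#' \eqn{Y = m(x) + \alpha(2w-1)\tau_k(x) + \sigma}; the implied
#' individual-level effect is \eqn{Y^{(1)} - Y^{(0)} = 2\alpha\,\tau_k(x)}
#' (see [sim_design()]).
#'
#' @param design integer 1–4.
#' @param x a numeric vector (one sample) or matrix (one row per sample)
#'   with at least the design's active covariate count (2, 8, 8, 8).
#' @return Numeric vector of \eqn{\tau_k(x_i)} values.
#' @export
#' @examples
#' true_tau(2, rep(1, 8))   # 4
true_tau <- function(design, x) {
  design <- as.integer(design)
  stopifnot(design %in% 1:4)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  need <- if (design == 1L) 2L else 8L
  if (ncol(x) < need)
    stop("design ", design, " needs at least ", need, " covariates; got ",
         ncol(x))
  a <- if (design > 1L) x[, 1:4, drop = FALSE]
  switch(design,
    0.5 * x[, 1L],
    rowSums((a > 0) * a),
    rowSums((a > 0) * a),
    rowSums(sin(a)) + x[, 5L]^2 + x[, 6L]^3 + x[, 7L]^4 + x[, 8L]^5)
}

.design_m <- function(design, x) {
  if (design == 1L) 0.5 * x[, 1L] + x[, 2L]
  else 0.5 * rowSums(x[, 1:4, drop = FALSE]) +
    rowSums(x[, 5:8, drop = FALSE])
}

#' Generate a synthetic treatment-effect benchmark dataset
#'
#' Draws one dataset from one of four data-generating processes built for
#' benchmarking CATE estimators. Covariates are i.i.d. standard normal,
#' treatment is randomized with probability `propensity` (default 0.5),
#' and the outcome is
#' \deqn{Y = m_k(x) + \alpha\,(2w - 1)\,\tau_k(x) + \sigma,}
#' with \eqn{\sigma \sim N(0, \code{noise_sd}^2)}. The designs are:
#' 1. \eqn{p = 2}, \eqn{m_1 = x_1/2 + x_2}, \eqn{\tau_1 = x_1/2},
#'    \eqn{\alpha = 0.5};
#' 2. \eqn{p = 20} (12 noise covariates),
#'    \eqn{m = \sum_{1}^{4} x_k/2 + \sum_{5}^{8} x_k},
#'    \eqn{\tau = \sum_{1}^{4} 1\{x_k>0\} x_k}, \eqn{\alpha = 1};
#' 3. as design 2 with \eqn{p = 58} (50 noise covariates);
#' 4. \eqn{p = 20}, same \eqn{m}, non-linear
#'    \eqn{\tau_4 = \sum_{1}^{4}\sin x_k + \sum_{5}^{8} x_k^{k-3}},
#'    \eqn{\alpha = 1}.
#'
#' The returned `true_tau` element is the ground-truth conditional average
#' treatment effect of the generated data,
#' \eqn{E[Y^{(1)} - Y^{(0)} \mid x] = 2\alpha\,\tau_k(x)} — the quantity a
#' CATE estimator fitted to this data should recover and the reference for
#' [rmse()] / [wrmse()] evaluation. The unscaled surface \eqn{\tau_k(x)}
#' is kept in `tau_basis`.
#'
#' @param design integer 1–4.
#' @param n sample size.
#' @param seed optional integer seed; the draw is fully reproducible and
#'   the caller's RNG state is left untouched.
#' @param alpha treatment-effect magnitude; defaults to the design's value
#'   (0.5, 1, 1, 1).
#' @param noise_sd standard deviation of the outcome noise (default 1).
#' @param p number of covariates; defaults to the design's value
#'   (2, 20, 58, 20) and must be at least the active-covariate count.
#' @param propensity randomization probability in (0, 1).
#' @return An object of class `"het_sim"`: list with `data` (a data frame
#'   with covariates `x1..xp`, treatment `w`, outcome `y` and the known
#'   propensity `e`), `true_tau`, `tau_basis`, and the generating
#'   parameters.
#' @export
#' @examples
#' sim <- sim_design(2, n = 100, seed = 1)
#' sim
sim_design <- function(design, n, seed = NULL, alpha = NULL, noise_sd = 1,
                       p = NULL, propensity = 0.5) {
  design <- as.integer(design)
  stopifnot(design %in% 1:4, n >= 1, noise_sd >= 0,
            propensity > 0, propensity < 1)
  if (is.null(alpha)) alpha <- .design_alpha[design]
  if (is.null(p)) p <- .design_p[design]
  stopifnot(alpha > 0, p >= if (design == 1L) 2L else 8L)
  gen <- function() {
    x <- matrix(stats::rnorm(n * p), n, p)
    w <- stats::rbinom(n, 1L, propensity)
    tk <- true_tau(design, x)
    m <- .design_m(design, x)
    y <- m + alpha * (2 * w - 1) * tk +
      if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    list(x = x, w = w, y = y, tk = tk)
  }
  g <- if (is.null(seed)) gen() else .with_seed(as.integer(seed), gen())
  df <- as.data.frame(g$x)
  names(df) <- paste0("x", seq_len(p))
  df$w <- g$w
  df$y <- g$y
  df$e <- rep(propensity, n)
  structure(list(data = df, true_tau = 2 * alpha * g$tk,
                 tau_basis = g$tk, design = design, n = as.integer(n),
                 alpha = alpha, noise_sd = noise_sd, p = as.integer(p),
                 propensity = propensity,
                 seed = if (is.null(seed)) NA_integer_
                        else as.integer(seed)),
            class = "het_sim")
}

#' @export
print.het_sim <- function(x, ...) {
  cat("<het_sim> design ", x$design, ": n = ", x$n, ", p = ", x$p,
      ", alpha = ", x$alpha, ", noise_sd = ", x$noise_sd,
      ", P(W=1) = ", x$propensity, "\n", sep = "")
  invisible(x)
}

#' Convert a simulated dataset to a het_data container
#'
#' @param sim a [sim_design()] object.
#' @return A [het_data()] object with the constant randomization
#'   probability as known propensity.
#' @export
as_het_data <- function(sim) {
  stopifnot(inherits(sim, "het_sim"))
  covs <- paste0("x", seq_len(sim$p))
  het_data(as.matrix(sim$data[covs]), sim$data$y, sim$data$w,
           propensity = sim$data$e, feature_names = covs)
}

#' Error of estimated treatment effects
#'
#' `rmse()` is the root mean squared error
#' \eqn{\sqrt{n^{-1}\sum_i (\hat\tau_i - \tau_i)^2}}. `wrmse()` weights
#' each squared error by \eqn{\omega_i = 1} when the estimated and true
#' effects have opposite signs (\eqn{\tau_i \hat\tau_i < 0}) and
#' \eqn{\omega_i = 0.1} otherwise, so predicting the wrong direction of an
#' effect is penalized ten times as hard as a same-sign magnitude error; a
#' zero product carries no sign disagreement and takes the 0.1 weight.
#'
#' @param tau_hat,tau_true numeric vectors of equal length.
#' @return A non-negative scalar; always `wrmse(a, b) <= rmse(a, b)`.
#' @name effect-error
#' @examples
#' rmse(c(1, -1, 1, -1), rep(0, 4))  # 1
#' wrmse(-1, 1)                      # 2
#' wrmse(2, 1)                       # sqrt(0.1)
NULL

#' @rdname effect-error
#' @export
rmse <- function(tau_hat, tau_true) {
  if (length(tau_hat) != length(tau_true) || !length(tau_hat))
    stop("tau_hat and tau_true must be non-empty vectors of equal length")
  sqrt(mean((tau_hat - tau_true)^2))
}

#' @rdname effect-error
#' @export
wrmse <- function(tau_hat, tau_true) {
  if (length(tau_hat) != length(tau_true) || !length(tau_hat))
    stop("tau_hat and tau_true must be non-empty vectors of equal length")
  w <- ifelse(tau_hat * tau_true < 0, 1, 0.1)
  sqrt(mean(w * (tau_hat - tau_true)^2))
}

#' Write a simulated dataset (and its ground truth) to CSV
#'
#' @param sim a [sim_design()] object.
#' @param file path for the data CSV (covariates, `w`, `y`, `e`).
#' @param truth_file optional path for a one-column CSV of the true
#'   per-sample effects.
#' @return `file`, invisibly.
#' @export
write_het_sim <- function(sim, file, truth_file = NULL) {
  stopifnot(inherits(sim, "het_sim"))
  utils::write.csv(sim$data, file, row.names = FALSE)
  if (!is.null(truth_file))
    utils::write.csv(data.frame(true_tau = sim$true_tau), truth_file,
                     row.names = FALSE)
  invisible(file)
}
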