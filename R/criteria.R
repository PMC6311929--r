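#' Split-scoring criteria
#'
#' Scalar scores used to rank candidate splits of a node into a left child
#' (feature value at or below the threshold) and a right child. All scores
#' are "higher is better".
#'
#' * `fit_score()` — the fitness criterion
#'   \eqn{C^{fit} = n_L \hat\tau_L^2 + n_R \hat\tau_R^2}, the maximization
#'   surrogate for the (unobservable) mean squared error of the effect
#'   estimates; the causal-tree (CT) criterion ranks splits by this score.
#' * `hete_score()` — the maximizing-heterogeneity criterion
#'   \eqn{C^{hete} = (\hat\tau_L - \hat\tau_R)^2}.
#' * `ts_score()` — the squared t-statistic
#'   \eqn{n (\hat\tau_L - \hat\tau_R)^2 / (\sigma_L^2/n_L + \sigma_R^2/n_R)}
#'   for the null of equal effects in the two children, where a child's
#'   \eqn{\sigma^2} is the sum of the treated-arm and control-arm outcome
#'   variances within that child (see Details).
#' * `variance_reduction_score()` — the CART impurity decrease
#'   \eqn{SSE(parent) - SSE(left) - SSE(right)}; applied to the raw outcome
#'   it gives the plain regression-tree (RT) criterion, applied to the
#'   [transformed_outcome()] it gives the TOT criterion.
#'
#' @details The within-child variance entering `ts_score()` is computed as
#' `var(y[w==1]) + var(y[w==0])` (sample variances); this pooled-by-arm
#' form is one reading of "the variance of treated and untreated samples
#' within a node" and is kept simple and configurable by passing your own
#' variances. A floor of `1e-12` guards the denominator against
#' arm-constant outcomes.
#'
#' @param tau_l,tau_r effect estimates in the left/right child.
#' @param n_l,n_r child sample sizes.
#' @param var_l,var_r within-child variances \eqn{\sigma_L^2, \sigma_R^2}.
#' @param n parent sample size.
#' @param floor denominator floor for `ts_score`.
#' @param parent_y,left_y,right_y outcome vectors; the children must
#'   partition the parent.
#' @return A single non-negative numeric score.
#' @name criteria
#' @examples
#' fit_score(1, -1, 2, 3)    # 5
#' hete_score(1, -1)         # 4
#' ts_score(1, 0, 1, 1, 50, 50, 100)  # 2500
NULL

#' @rdname criteria
#' @export
fit_score <- function(tau_l, tau_r, n_l, n_r) {
  stopifnot(n_l >= 1, n_r >= 1)
  n_l * tau_l^2 + n_r * tau_r^2
}

#' @rdname criteria
#' @export
hete_score <- function(tau_l, tau_r) {
  (tau_l - tau_r)^2
}

#' @rdname criteria
#' @export
ts_score <- function(tau_l, tau_r, var_l, var_r, n_l, n_r, n,
                     floor = 1e-12) {
  denom <- var_l / n_l + var_r / n_r
  if (!is.finite(denom) || denom <= 0) {
    if (denom <= 0 && denom > -floor) denom <- floor
    else stop("ts_score: invalid variance denominator")
  }
  n * (tau_l - tau_r)^2 / max(denom, floor)
}

#' @rdname criteria
#' @export
variance_reduction_score <- function(parent_y, left_y, right_y) {
  if (length(left_y) + length(right_y) != length(parent_y))
    stop("children must partition the parent")
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  sse(parent_y) - sse(left_y) - sse(right_y)
}

#' Score one candidate split
#'
#' Estimates the child effects of a single candidate split by the
#' within-node IPW estimator and returns its fitness/heterogeneity score
#' pair — the \eqn{(C^{fit}, C^{hete})} point that the multi-objective
#' criterion feeds into the epsilon-dominance archive.
#'
#' @param data a [het_data()] object.
#' @param feature covariate column index (1-based).
#' @param threshold split threshold; rows with value `<= threshold` go left.
#' @param rows parent node rows (default: all).
#' @param propensity optional propensity vector (default:
#'   [estimate_propensity()]).
#' @return A list with `fit`, `hete`, `tau_l`, `tau_r`, `n_l`, `n_r`.
#'   A candidate leaving one child without both treatment arms is invalid
#'   and raises an error of class `"hettree_inestimable"`.
#' @export
score_split <- function(data, feature, threshold, rows = NULL,
                        propensity = NULL) {
  stopifnot(inherits(data, "het_data"))
  if (is.null(rows)) rows <- seq_along(data$y)
  if (is.null(propensity)) propensity <- estimate_propensity(data)
  v <- data$x[rows, feature]
  left <- rows[v <= threshold]
  right <- rows[v > threshold]
  if (!length(left) || !length(right))
    stop("threshold does not split the node")
  tau_l <- node_cate(data, left, propensity)
  tau_r <- node_cate(data, right, propensity)
  list(fit = fit_score(tau_l, tau_r, length(left), length(right)),
       hete = hete_score(tau_l, tau_r),
       tau_l = tau_l, tau_r = tau_r,
       n_l = length(left), n_r = length(right))
}

# Vectorized scan of every candidate split of a node.
#
# For each feature the node rows are sorted and thresholds placed at
# midpoints between consecutive distinct values; child statistics for all
# cut positions come from cumulative sums, so the scan is O(n log n) per
# feature. Returns one row per *valid* candidate (both children meet the
# minimum size and contain >= min_arm samples of each arm), in
# deterministic order (feature ascending, threshold ascending), with the
# child stats every criterion needs.
.node_scan <- function(x, y, w, e, rows, min_node, min_arm, yt = NULL) {
  out <- vector("list", ncol(x))
  n <- length(rows)
  want_tot <- !is.null(yt)
  for (j in seq_len(ncol(x))) {
    v <- x[rows, j]
    o <- order(v)
    vs <- v[o]
    cut <- which(vs[-n] < vs[-1L])
    if (!length(cut)) next
    ro <- rows[o]
    ys <- y[ro]; ws <- w[ro]; es <- e[ro]
    i <- cut
    cnt <- cumsum(ws)
    n_l <- i; n_r <- n - i
    nt_l <- cnt[i]; nt_r <- cnt[n] - nt_l
    nc_l <- n_l - nt_l; nc_r <- n_r - nt_r
    ok <- n_l >= min_node & n_r >= min_node &
      nt_l >= min_arm & nc_l >= min_arm &
      nt_r >= min_arm & nc_r >= min_arm
    if (!any(ok)) next
    i <- i[ok]
    n_l <- n_l[ok]; n_r <- n_r[ok]
    nt_l <- nt_l[ok]; nt_r <- nt_r[ok]
    nc_l <- nc_l[ok]; nc_r <- nc_r[ok]

    ctw <- cumsum(ws / es)
    ctwy <- cumsum(ws * ys / es)
    ccw <- cumsum((1 - ws) / (1 - es))
    ccwy <- cumsum((1 - ws) * ys / (1 - es))
    Tw <- ctw[n]; Twy <- ctwy[n]; Cw <- ccw[n]; Cwy <- ccwy[n]
    tau_l <- ctwy[i] / ctw[i] - ccwy[i] / ccw[i]
    tau_r <- (Twy - ctwy[i]) / (Tw - ctw[i]) -
      (Cwy - ccwy[i]) / (Cw - ccw[i])

    # per-arm outcome moments (squared t-statistic variances)
    cty <- cumsum(ws * ys); cty2 <- cumsum(ws * ys^2)
    ccy <- cumsum((1 - ws) * ys); ccy2 <- cumsum((1 - ws) * ys^2)
    svar <- function(s, s2, m) {
      v <- (s2 - s^2 / m) / pmax(m - 1, 1)
      pmax(v, 0)
    }
    var_l <- svar(cty[i], cty2[i], nt_l) + svar(ccy[i], ccy2[i], nc_l)
    var_r <- svar(cty[n] - cty[i], cty2[n] - cty2[i], nt_r) +
      svar(ccy[n] - ccy[i], ccy2[n] - ccy2[i], nc_r)

    # raw-outcome SSE decrease (regression-tree criterion)
    cy <- cumsum(ys); cy2 <- cumsum(ys^2)
    sse <- function(s, s2, m) s2 - s^2 / m
    dss_y <- sse(cy[n], cy2[n], n) - sse(cy[i], cy2[i], n_l) -
      sse(cy[n] - cy[i], cy2[n] - cy2[i], n_r)

    if (want_tot) {
      zs <- yt[ro]
      cz <- cumsum(zs); cz2 <- cumsum(zs^2)
      dss_t <- sse(cz[n], cz2[n], n) - sse(cz[i], cz2[i], n_l) -
        sse(cz[n] - cz[i], cz2[n] - cz2[i], n_r)
    } else dss_t <- rep(NA_real_, length(i))

    out[[j]] <- data.frame(
      feature = j,
      threshold = (vs[i] + vs[i + 1L]) / 2,
      n_l = n_l, n_r = n_r,
      nt_l = nt_l, nc_l = nc_l, nt_r = nt_r, nc_r = nc_r,
      tau_l = tau_l, tau_r = tau_r,
      var_l = var_l, var_r = var_r,
      dss_y = dss_y, dss_t = dss_t)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) {
    return(data.frame(feature = integer(), threshold = numeric(),
                      n_l = integer(), n_r = integer(), nt_l = integer(),
                      nc_l = integer(), nt_r = integer(), nc_r = integer(),
                      tau_l = numeric(), tau_r = numeric(),
                      var_l = numeric(), var_r = numeric(),
                      dss_y = numeric(), dss_t = numeric()))
  }
  do.call(rbind, out)
}

#' Enumerate valid candidate splits of a node
#'
#' Thresholds are placed at midpoints between consecutive distinct sorted
#' values of each feature within the node; candidates whose children would
#' violate the minimum child size, or leave a child without at least
#' `min_arm` treated and `min_arm` control samples, are dropped. The order
#' is deterministic: feature index ascending, threshold ascending.
#'
#' @param data a [het_data()] object.
#' @param rows parent node rows (default: all).
#' @param min_node minimum samples per child.
#' @param min_arm minimum samples per treatment arm per child.
#' @return A data frame with columns `feature` and `threshold` (possibly
#'   zero rows).
#' @export
enumerate_splits <- function(data, rows = NULL, min_node = 10L,
                             min_arm = 2L) {
  stopifnot(inherits(data, "het_data"))
  if (is.null(rows)) rows <- seq_along(data$y)
  e <- rep(0.5, length(data$y))  # validity does not depend on e
  sc <- .node_scan(data$x, data$y, data$w, e, rows, min_node, min_arm)
  sc[c("feature", "threshold")]
}
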