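#' Construct a validated treatment-effect dataset
#'
#' Bundles the ingredients of a two-arm study into a validated container:
#' an \eqn{n \times p} covariate matrix, a numeric outcome, a binary
#' treatment indicator, and (optionally) a known per-sample propensity
#' score \eqn{e(x) = \Pr(W = 1 \mid x)}. All downstream estimation in the
#' package runs on this container.
#'
#' Under the potential-outcomes model each sample carries two outcomes
#' \eqn{Y^{(0)}, Y^{(1)}} of which only \eqn{Y = W Y^{(1)} + (1-W) Y^{(0)}}
#' is observed; unconfoundedness (\eqn{Y^{(0)}, Y^{(1)} \perp W \mid x}) is
#' assumed whenever the data are not from a randomized experiment.
#'
#' @param x numeric matrix or data frame of covariates, one row per sample.
#' @param y numeric outcome vector.
#' @param w treatment indicator; every entry must be 0 or 1 (logical is
#'   coerced).
#' @param propensity optional numeric vector of known treatment
#'   probabilities, each strictly inside (0, 1).
#' @param feature_names optional character vector of column labels for `x`.
#'
#' @return An object of class `"het_data"`: a list with elements `x`
#'   (matrix), `y`, `w` and `propensity` (or `NULL`).
#' @seealso [read_het_csv()], [estimate_propensity()], [node_cate()]
#' @export
#' @examples
#' d <- het_data(matrix(rnorm(20), 10, 2), rnorm(10), rep(0:1, 5))
#' d$w
het_data <- function(x, y, w, propensity = NULL, feature_names = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (is.logical(w)) w <- as.integer(w)
  w <- as.numeric(w)
  n <- nrow(x)
  if (n < 1L) stop("dataset must contain at least one sample")
  if (length(y) != n || length(w) != n)
    stop("covariates, outcome and treatment must have the same length (n = ",
         n, ", length(y) = ", length(y), ", length(w) = ", length(w), ")")
  if (anyNA(x)) {
    bad <- which(rowSums(is.na(x)) > 0L)
    stop("missing covariate values in row(s) ", paste(utils::head(bad, 5L),
         collapse = ", "))
  }
  if (anyNA(y)) stop("missing outcome values in row(s) ",
                     paste(utils::head(which(is.na(y)), 5L), collapse = ", "))
  bad_w <- which(is.na(w) | !(w %in% c(0, 1)))
  if (length(bad_w))
    stop("treatment must be 0 or 1; offending row(s): ",
         paste(utils::head(bad_w, 5L), collapse = ", "))
  if (!is.null(propensity)) {
    propensity <- as.numeric(propensity)
    if (length(propensity) != n)
      stop("propensity vector has length ", length(propensity),
           " but n = ", n)
    bad_e <- which(is.na(propensity) | propensity <= 0 | propensity >= 1)
    if (length(bad_e))
      stop("propensity must lie strictly in (0, 1); offending row(s): ",
           paste(utils::head(bad_e, 5L), collapse = ", "))
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(x)
    if (is.null(feature_names))
      feature_names <- paste0("x", seq_len(ncol(x)))
  }
  if (length(feature_names) != ncol(x))
    stop("feature_names must have one entry per covariate column")
  colnames(x) <- feature_names
  structure(list(x = x, y = y, w = as.integer(w), propensity = propensity),
            class = "het_data")
}

#' @export
print.het_data <- function(x, ...) {
  cat("<het_data> n =", nrow(x$x), " p =", ncol(x$x),
      " treated =", sum(x$w),
      if (is.null(x$propensity)) " (no propensity column)\n"
      else " (known propensity)\n")
  invisible(x)
}

#' Read a treatment-effect dataset from CSV
#'
#' Reads a header-labelled CSV and assembles a [het_data()] object. All
#' numeric columns other than the designated outcome, treatment and
#' propensity columns become covariates.
#'
#' @param file path to a CSV file with a header row.
#' @param outcome,treatment column names of the outcome and the binary
#'   treatment indicator.
#' @param propensity optional column name of known propensity scores.
#' @return A `"het_data"` object.
#' @export
read_het_csv <- function(file, outcome = "y", treatment = "w",
                         propensity = NULL) {
  df <- utils::read.csv(file, header = TRUE)
  need <- c(outcome, treatment, propensity)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("column(s) not found in ", file, ": ", paste(miss, collapse = ", "))
  covs <- setdiff(names(df), need)
  covs <- covs[vapply(df[covs], is.numeric, logical(1L))]
  if (!length(covs)) stop("no numeric covariate columns found in ", file)
  het_data(as.matrix(df[covs]), df[[outcome]], df[[treatment]],
           propensity = if (!is.null(propensity)) df[[propensity]],
           feature_names = covs)
}

#' Estimate or retrieve propensity scores
#'
#' @param data a [het_data()] object.
#' @param method `"known"` returns the stored propensity column;
#'   `"constant"` returns the empirical treated fraction for every sample
#'   (appropriate for completely randomized designs); `"logistic"` fits a
#'   maximum-likelihood logistic regression of treatment on all covariates
#'   and returns fitted probabilities. `"auto"` (default) uses `"known"`
#'   when a propensity column is present and `"constant"` otherwise.
#' @param clip fitted/constant probabilities are clamped to
#'   `[clip, 1 - clip]` so inverse-propensity weights stay bounded.
#' @return Numeric length-\eqn{n} vector strictly inside (0, 1).
#' @export
estimate_propensity <- function(data,
                                method = c("auto", "known", "constant",
                                           "logistic"),
                                clip = 0.01) {
  stopifnot(inherits(data, "het_data"), clip > 0, clip < 0.5)
  method <- match.arg(method)
  if (method == "auto")
    method <- if (!is.null(data$propensity)) "known" else "constant"
  if (method == "known") {
    if (is.null(data$propensity))
      stop("method = \"known\" requires a propensity column")
    return(data$propensity)
  }
  pbar <- mean(data$w)
  if (pbar == 0 || pbar == 1)
    stop("propensity is degenerate: all samples are ",
         if (pbar == 1) "treated" else "control")
  if (method == "constant")
    return(rep(min(max(pbar, clip), 1 - clip), length(data$w)))
  fit <- stats::glm.fit(cbind(1, data$x), data$w,
                        family = stats::binomial())
  pmin(pmax(fit$fitted.values, clip), 1 - clip)
}

#' Within-node IPW treatment-effect estimate
#'
#' Estimates the (conditional) average treatment effect over a set of rows
#' by the inverse-propensity-weighted ratio-of-sums contrast
#' \deqn{\hat\tau = \frac{\sum W_i Y_i / e_i}{\sum W_i / e_i}
#'              - \frac{\sum (1-W_i) Y_i / (1-e_i)}{\sum (1-W_i) / (1-e_i)},}
#' the sums running over the node members. With a constant propensity this
#' reduces exactly to the difference of treated and control outcome means.
#'
#' @param data a [het_data()] object.
#' @param rows integer vector of member row indices (default: all rows).
#' @param propensity propensity vector aligned with `data` (default:
#'   [estimate_propensity()] with `method = "auto"`).
#' @return The scalar effect estimate \eqn{\hat\tau}.
#'   A node containing only one treatment arm is inestimable and raises an
#'   error of class `"hettree_inestimable"`.
#' @export
#' @examples
#' d <- het_data(matrix(0, 2, 1), c(1, 0), c(1, 0), propensity = c(.5, .5))
#' node_cate(d)  # 1
node_cate <- function(data, rows = NULL, propensity = NULL) {
  stopifnot(inherits(data, "het_data"))
  if (is.null(rows)) rows <- seq_along(data$y)
  if (!length(rows) || anyNA(rows) || any(rows < 1L) ||
      any(rows > length(data$y)) || anyDuplicated(rows))
    stop("rows must be unique valid row indices")
  if (is.null(propensity)) propensity <- estimate_propensity(data)
  w <- data$w[rows]
  if (all(w == 1L) || all(w == 0L))
    stop(structure(class = c("hettree_inestimable", "error", "condition"),
                   list(message = paste0(
                     "node is inestimable: contains only ",
                     if (all(w == 1L)) "treated" else "control",
                     " samples"), call = sys.call(-1))))
  .ipw_cate(data$y[rows], w, propensity[rows])
}

.ipw_cate <- function(y, w, e) {
  tw <- w / e
  cw <- (1 - w) / (1 - e)
  sum(tw * y) / sum(tw) - sum(cw * y) / sum(cw)
}

#' Transformed outcome
#'
#' Computes the transformed outcome
#' \eqn{Y^{TOT}_i = Y_i (W_i - \pi) / (\pi (1 - \pi))} for a constant
#' assignment probability \eqn{\pi}. Under randomization,
#' \eqn{E[Y^{TOT} \mid x] = \tau(x)}, so an ordinary regression tree fitted
#' to the transformed outcome estimates the treatment effect.
#'
#' @param data a [het_data()] object.
#' @param pi constant treatment probability in (0, 1); defaults to the
#'   mean stored propensity, or the empirical treated fraction.
#' @return Numeric length-\eqn{n} vector.
#' @export
transformed_outcome <- function(data, pi = NULL) {
  stopifnot(inherits(data, "het_data"))
  if (is.null(pi)) {
    pi <- if (!is.null(data$propensity)) mean(data$propensity)
          else mean(data$w)
  }
  if (!is.numeric(pi) || length(pi) != 1L || pi <= 0 || pi >= 1)
    stop("pi must be a single number strictly in (0, 1)")
  data$y * (data$w - pi) / (pi * (1 - pi))
}
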