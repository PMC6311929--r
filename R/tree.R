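#' Fit a treatment-effect tree
#'
#' Grows a binary recursive-partitioning model of the conditional average
#' treatment effect (CATE). Every node's effect is estimated by the
#' within-node inverse-propensity-weighted contrast ([node_cate()]);
#' candidate splits place thresholds at midpoints between distinct sorted
#' feature values ("value at or below the threshold goes left") and must
#' leave both treatment arms represented in both children.
#'
#' The splitting criterion decides which candidate becomes the split:
#' \describe{
#'   \item{`"mo"`}{multi-objective: every candidate's
#'     \eqn{(C^{fit}, C^{hete})} pair is streamed into a bounded
#'     epsilon-dominance archive ([build_archive()]) and the split is taken
#'     from the archived epsilon-optimal set by [select_split()]
#'     (largest \eqn{C^{hete}} by default).}
#'   \item{`"mh"`}{maximize heterogeneity \eqn{(\hat\tau_L-\hat\tau_R)^2}.}
#'   \item{`"ct"`}{maximize the fitness score
#'     \eqn{n_L\hat\tau_L^2 + n_R\hat\tau_R^2} (causal-tree criterion).}
#'   \item{`"ts"`}{maximize the squared t-statistic for equal child
#'     effects.}
#'   \item{`"tot"`}{CART variance reduction on the
#'     [transformed_outcome()].}
#'   \item{`"rt"`}{CART variance reduction on the raw outcome.}
#' }
#'
#' Growth is best-first: among all expandable nodes the one whose best
#' candidate has the highest criterion score is split next, so trees of
#' different criteria are comparable at the same number of splits. Growth
#' stops after `max_splits` internal nodes or when no node has a valid
#' candidate. Ties are broken deterministically (lowest feature index,
#' then lowest threshold, then earliest node).
#'
#' With `honest = TRUE` the rows are split 50/50 (seeded): one half drives
#' split selection, the other re-estimates the leaf effects, removing the
#' selection bias of reusing the same data twice. A leaf whose estimation
#' half lacks one arm inherits its parent's estimate.
#'
#' @param formula model formula `outcome ~ covariates` (covariates must be
#'   plain numeric columns of `data`; `.` expands to all columns except
#'   outcome, treatment and propensity).
#' @param data a data frame.
#' @param treatment name of the binary treatment column, or a 0/1 vector.
#' @param propensity optional name of a known propensity column, or a
#'   numeric vector in (0, 1).
#' @param criterion splitting criterion, see Details.
#' @param eps length-2 positive slack vector
#'   \eqn{(\varepsilon_1, \varepsilon_2)} of the multi-objective archive.
#' @param select_rule archive selection rule for `"mo"`.
#' @param max_splits maximum number of internal nodes (0 gives a single
#'   leaf carrying the overall ATE).
#' @param min_node minimum samples per child.
#' @param min_arm minimum treated and control samples per child.
#' @param honest logical; see Details.
#' @param propensity_method passed to [estimate_propensity()].
#' @param clip propensity clipping bound.
#' @param seed integer seed used for the honest sample split; stored in the
#'   model so the identical tree can be regrown.
#' @return An object of class `"hettree"` with `print`, `summary`,
#'   `predict`, `coef` and `plot` methods.
#' @seealso [hettree_fit()] for the matrix interface, [write_hettree()]
#'   for serialization, [sim_design()] for benchmark data.
#' @export
#' @examples
#' sim <- sim_design(1, n = 800, seed = 42)
#' df <- cbind(sim$data)
#' fit <- hettree(y ~ x1 + x2, df, treatment = "w", propensity = "e",
#'                criterion = "mo", max_splits = 3)
#' fit
#' head(predict(fit, df))
hettree <- function(formula, data, treatment, propensity = NULL,
                    criterion = c("mo", "mh", "ct", "ts", "tot", "rt"),
                    eps = c(0.1, 0.1),
                    select_rule = c("max_hete", "max_fit"),
                    max_splits = 10L, min_node = 10L, min_arm = 2L,
                    honest = FALSE,
                    propensity_method = c("auto", "known", "constant",
                                          "logistic"),
                    clip = 0.01, seed = NULL) {
  stopifnot(is.data.frame(data))
  criterion <- match.arg(criterion)
  select_rule <- match.arg(select_rule)
  propensity_method <- match.arg(propensity_method)

  special <- character()
  if (is.character(treatment)) {
    if (length(treatment) != 1L || !treatment %in% names(data))
      stop("treatment column not found: ", treatment)
    w <- data[[treatment]]
    special <- c(special, treatment)
  } else w <- treatment
  e_col <- NULL
  if (is.character(propensity)) {
    if (length(propensity) != 1L || !propensity %in% names(data))
      stop("propensity column not found: ", propensity)
    e_col <- data[[propensity]]
    special <- c(special, propensity)
  } else if (!is.null(propensity)) e_col <- propensity

  resp <- all.vars(formula[[2L]])
  if (length(resp) != 1L || !resp %in% names(data))
    stop("the formula response must be a single column of `data`")
  tt <- stats::terms(formula,
                     data = data[setdiff(names(data), c(special, resp))])
  covs <- attr(tt, "term.labels")
  if (!all(covs %in% names(data)))
    stop("covariate terms must be plain columns of `data`; not found: ",
         paste(setdiff(covs, names(data)), collapse = ", "))
  hd <- het_data(as.matrix(data[covs]), data[[resp]], w,
                 propensity = e_col, feature_names = covs)
  fit <- hettree_fit(hd, criterion = criterion, eps = eps,
                     select_rule = select_rule, max_splits = max_splits,
                     min_node = min_node, min_arm = min_arm,
                     honest = honest, propensity_method = propensity_method,
                     clip = clip, seed = seed)
  fit$call <- match.call()
  fit
}

#' Fit a treatment-effect tree from a validated dataset
#'
#' Lower-level interface to the same growth engine as [hettree()], taking
#' a [het_data()] container directly.
#'
#' @inheritParams hettree
#' @param data a [het_data()] object.
#' @return An object of class `"hettree"`.
#' @export
hettree_fit <- function(data,
                        criterion = c("mo", "mh", "ct", "ts", "tot", "rt"),
                        eps = c(0.1, 0.1),
                        select_rule = c("max_hete", "max_fit"),
                        max_splits = 10L, min_node = 10L, min_arm = 2L,
                        honest = FALSE,
                        propensity_method = c("auto", "known", "constant",
                                              "logistic"),
                        clip = 0.01, seed = NULL) {
  stopifnot(inherits(data, "het_data"))
  criterion <- match.arg(criterion)
  select_rule <- match.arg(select_rule)
  propensity_method <- match.arg(propensity_method)
  stopifnot(is.numeric(eps), length(eps) == 2L, all(eps > 0))
  max_splits <- as.integer(max_splits)
  if (is.na(max_splits) || max_splits < 0L)
    stop("max_splits must be a non-negative integer")
  min_node <- max(as.integer(min_node), 1L)
  min_arm <- max(as.integer(min_arm), 1L)

  n <- length(data$y)
  e <- estimate_propensity(data, propensity_method, clip)
  yt <- if (criterion == "tot") transformed_outcome(data, pi = mean(e))

  if (honest) {
    if (!is.null(seed)) {
      sel <- .with_seed(seed, sort(sample.int(n, n %/% 2L)))
    } else sel <- sort(sample.int(n, n %/% 2L))
    est <- setdiff(seq_len(n), sel)
  } else {
    sel <- est <- seq_len(n)
  }
  w_est <- data$w[est]
  if (all(w_est == 1L) || all(w_est == 0L) ||
      all(data$w[sel] == 1L) || all(data$w[sel] == 0L))
    stop("root node is inestimable: a sample half lacks one treatment arm")

  best_candidate <- function(rows) {
    sc <- .node_scan(data$x, data$y, data$w, e, rows, min_node, min_arm, yt)
    if (!nrow(sc)) return(NULL)
    fitv <- sc$n_l * sc$tau_l^2 + sc$n_r * sc$tau_r^2
    hetv <- (sc$tau_l - sc$tau_r)^2
    nn <- length(rows)
    if (criterion == "mo") {
      arch <- .archive_stream(fitv, hetv, eps, sc$feature, sc$threshold)
      asz <- length(arch$fit)
      a <- if (select_rule == "max_hete") arch$hete else arch$fit
      b <- if (select_rule == "max_hete") arch$fit else arch$hete
      o <- order(-a, -b, arch$feature, arch$threshold, arch$id)[1L]
      return(list(feature = arch$feature[o], threshold = arch$threshold[o],
                  score = a[o], fit = arch$fit[o], hete = arch$hete[o],
                  archive_size = asz))
    }
    score <- switch(criterion,
      ct = fitv,
      mh = hetv,
      ts = nn * hetv / pmax(sc$var_l / sc$n_l + sc$var_r / sc$n_r, 1e-12),
      rt = sc$dss_y,
      tot = sc$dss_t)
    i <- which.max(score)
    list(feature = sc$feature[i], threshold = sc$threshold[i],
         score = score[i], fit = fitv[i], hete = hetv[i],
         archive_size = NA_integer_)
  }

  node_tau <- function(rows_est, fallback) {
    wr <- data$w[rows_est]
    if (!length(rows_est) || all(wr == 1L) || all(wr == 0L)) return(fallback)
    .ipw_cate(data$y[rows_est], wr, e[rows_est])
  }

  nodes <- list()
  new_node <- function(rows_sel, rows_est, parent_tau) {
    id <- length(nodes) + 1L
    tau <- node_tau(rows_est, parent_tau)
    cand <- if (max_splits > 0L) best_candidate(rows_sel)
    nodes[[id]] <<- list(
      id = id, leaf = TRUE, tau = tau,
      n = length(rows_est), n_treated = sum(data$w[rows_est]),
      n_control = sum(1L - data$w[rows_est]),
      feature = NA_integer_, threshold = NA_real_,
      left = NA_integer_, right = NA_integer_,
      fit = NA_real_, hete = NA_real_, archive_size = NA_integer_,
      rows_sel = rows_sel, rows_est = rows_est, cand = cand)
    id
  }

  root <- new_node(sel, est, NA_real_)
  if (is.na(nodes[[root]]$tau))
    stop("root node is inestimable")
  frontier <- if (!is.null(nodes[[root]]$cand)) root else integer()
  n_splits <- 0L
  while (n_splits < max_splits && length(frontier)) {
    scores <- vapply(frontier, function(id) nodes[[id]]$cand$score,
                     numeric(1L))
    id <- frontier[order(-scores, frontier)][1L]
    frontier <- setdiff(frontier, id)
    nd <- nodes[[id]]
    cand <- nd$cand
    v_sel <- data$x[nd$rows_sel, cand$feature]
    v_est <- data$x[nd$rows_est, cand$feature]
    lsel <- nd$rows_sel[v_sel <= cand$threshold]
    rsel <- nd$rows_sel[v_sel > cand$threshold]
    lest <- nd$rows_est[v_est <= cand$threshold]
    rest <- nd$rows_est[v_est > cand$threshold]
    lid <- new_node(lsel, lest, nd$tau)
    rid <- new_node(rsel, rest, nd$tau)
    nodes[[id]]$leaf <- FALSE
    nodes[[id]]$feature <- cand$feature
    nodes[[id]]$threshold <- cand$threshold
    nodes[[id]]$left <- lid
    nodes[[id]]$right <- rid
    nodes[[id]]$fit <- cand$fit
    nodes[[id]]$hete <- cand$hete
    nodes[[id]]$archive_size <- cand$archive_size
    n_splits <- n_splits + 1L
    if (n_splits < max_splits) {
      for (cid in c(lid, rid))
        if (!is.null(nodes[[cid]]$cand)) frontier <- c(frontier, cid)
    }
  }
  nodes <- lapply(nodes, function(nd) {
    nd$rows_sel <- NULL; nd$rows_est <- NULL; nd$cand <- NULL; nd
  })
  structure(list(
    nodes = nodes, root = root, n_splits = n_splits,
    criterion = criterion, eps = as.numeric(eps),
    select_rule = select_rule,
    config = list(max_splits = max_splits, min_node = min_node,
                  min_arm = min_arm, honest = honest,
                  propensity_method = propensity_method, clip = clip,
                  seed = if (is.null(seed)) NA_integer_
                         else as.integer(seed)),
    feature_names = colnames(data$x),
    n = n, call = sys.call()), class = "hettree")
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.resolve_newdata <- function(object, newdata) {
  p <- length(object$feature_names)
  if (inherits(newdata, "het_data")) newdata <- newdata$x
  if (inherits(newdata, "het_sim")) newdata <- newdata$data
  if (is.data.frame(newdata)) {
    miss <- setdiff(object$feature_names, names(newdata))
    if (length(miss))
      stop("newdata is missing covariate column(s): ",
           paste(miss, collapse = ", "))
    newdata <- as.matrix(newdata[object$feature_names])
  }
  if (!is.matrix(newdata)) newdata <- matrix(newdata, ncol = p)
  if (ncol(newdata) != p)
    stop("newdata has ", ncol(newdata), " columns; model expects ", p)
  storage.mode(newdata) <- "double"
  newdata
}

# leaf id of every row of X
.route <- function(object, X) {
  out <- integer(nrow(X))
  recurse <- function(id, idx) {
    nd <- object$nodes[[id]]
    if (nd$leaf) {
      out[idx] <<- id
      return(invisible())
    }
    v <- X[idx, nd$feature]
    l <- idx[v <= nd$threshold]
    r <- idx[v > nd$threshold]
    if (length(l)) recurse(nd$left, l)
    if (length(r)) recurse(nd$right, r)
  }
  if (nrow(X)) recurse(object$root, seq_len(nrow(X)))
  out
}

#' Predict conditional treatment effects from a fitted tree
#'
#' Routes each row down the tree ("value at or below the threshold goes
#' left") and returns the effect estimate of the leaf it lands in.
#'
#' @param object a fitted `"hettree"`.
#' @param newdata data frame containing the training covariate columns, a
#'   numeric matrix with the training column count, a [het_data()] or a
#'   [sim_design()] object.
#' @param ... unused.
#' @return Numeric vector of per-row CATE estimates \eqn{\hat\tau(x)}.
#' @export
predict.hettree <- function(object, newdata, ...) {
  X <- .resolve_newdata(object, newdata)
  leaf <- .route(object, X)
  vapply(leaf, function(id) object$nodes[[id]]$tau, numeric(1L))
}

#' @export
print.hettree <- function(x, digits = 4L, ...) {
  cat("Treatment-effect tree (criterion = ", x$criterion,
      if (x$criterion == "mo")
        paste0(", eps = (", x$eps[1L], ", ", x$eps[2L], "), rule = ",
               x$select_rule),
      ")\n", sep = "")
  cat("n = ", x$n, ", splits = ", x$n_splits,
      if (isTRUE(x$config$honest)) ", honest", "\n\n", sep = "")
  recurse <- function(id, indent) {
    nd <- x$nodes[[id]]
    pad <- strrep("  ", indent)
    if (nd$leaf) {
      cat(pad, "* leaf [", id, "]: tau = ",
          format(nd$tau, digits = digits), "  (n = ", nd$n, ", treated = ",
          nd$n_treated, ", control = ", nd$n_control, ")\n", sep = "")
    } else {
      cat(pad, "o node [", id, "]: split ",
          x$feature_names[nd$feature], " <= ",
          format(nd$threshold, digits = digits),
          "  (fit = ", format(nd$fit, digits = digits),
          ", hete = ", format(nd$hete, digits = digits),
          if (!is.na(nd$archive_size))
            paste0(", archive = ", nd$archive_size),
          ")\n", sep = "")
      recurse(nd$left, indent + 1L)
      recurse(nd$right, indent + 1L)
    }
  }
  recurse(x$root, 0L)
  invisible(x)
}

#' Summarize a fitted treatment-effect tree
#'
#' @param object a fitted `"hettree"`.
#' @param ... unused.
#' @return A list of class `"summary.hettree"` with data frames `splits`
#'   (feature, threshold and score pair of every internal node) and
#'   `leaves` (effect estimate and arm counts of every leaf).
#' @export
summary.hettree <- function(object, ...) {
  nd <- object$nodes
  is_leaf <- vapply(nd, `[[`, logical(1L), "leaf")
  splits <- do.call(rbind, lapply(nd[!is_leaf], function(z)
    data.frame(node = z$id, feature = object$feature_names[z$feature],
               threshold = z$threshold, fit = z$fit, hete = z$hete,
               archive_size = z$archive_size)))
  leaves <- do.call(rbind, lapply(nd[is_leaf], function(z)
    data.frame(node = z$id, tau = z$tau, n = z$n,
               n_treated = z$n_treated, n_control = z$n_control)))
  structure(list(criterion = object$criterion, n = object$n,
                 n_splits = object$n_splits, splits = splits,
                 leaves = leaves),
            class = "summary.hettree")
}

#' @export
print.summary.hettree <- function(x, ...) {
  cat("Treatment-effect tree: criterion =", x$criterion, " n =", x$n,
      " splits =", x$n_splits, "\n\nSplits:\n")
  if (is.null(x$splits)) cat("  (none)\n") else print(x$splits,
                                                      row.names = FALSE)
  cat("\nLeaves:\n")
  print(x$leaves, row.names = FALSE)
  invisible(x)
}

#' @export
coef.hettree <- function(object, ...) {
  nd <- object$nodes
  is_leaf <- vapply(nd, `[[`, logical(1L), "leaf")
  out <- vapply(nd[is_leaf], `[[`, numeric(1L), "tau")
  names(out) <- paste0("leaf", vapply(nd[is_leaf], `[[`, integer(1L), "id"))
  out
}

#' Plot a fitted treatment-effect tree
#'
#' Draws the tree with base graphics: internal nodes show the split rule,
#' leaves show the estimated effect and sample count.
#'
#' @param x a fitted `"hettree"`.
#' @param digits significant digits for labels.
#' @param ... passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.hettree <- function(x, digits = 3L, ...) {
  depth <- function(id) {
    nd <- x$nodes[[id]]
    if (nd$leaf) 0L else 1L + max(depth(nd$left), depth(nd$right))
  }
  pos <- list(); counter <- 0
  place <- function(id, d) {
    nd <- x$nodes[[id]]
    if (nd$leaf) {
      counter <<- counter + 1
      pos[[as.character(id)]] <<- c(counter, -d)
      return(counter)
    }
    xl <- place(nd$left, d + 1)
    xr <- place(nd$right, d + 1)
    pos[[as.character(id)]] <<- c((xl + xr) / 2, -d)
    (xl + xr) / 2
  }
  place(x$root, 0)
  xy <- do.call(rbind, pos)
  graphics::plot(xy[, 1L], xy[, 2L], type = "n", axes = FALSE,
                 xlab = "", ylab = "",
                 xlim = range(xy[, 1L]) + c(-0.5, 0.5),
                 ylim = range(xy[, 2L]) + c(-0.5, 0.5), ...)
  for (id in seq_along(x$nodes)) {
    nd <- x$nodes[[id]]
    if (nd$leaf) next
    p <- pos[[as.character(id)]]
    for (ch in c(nd$left, nd$right)) {
      q <- pos[[as.character(ch)]]
      graphics::segments(p[1L], p[2L], q[1L], q[2L], col = "grey50")
    }
  }
  for (id in seq_along(x$nodes)) {
    nd <- x$nodes[[id]]
    p <- pos[[as.character(id)]]
    lab <- if (nd$leaf)
      paste0("tau = ", format(nd$tau, digits = digits), "\nn = ", nd$n)
    else paste0(x$feature_names[nd$feature], " <= ",
                format(nd$threshold, digits = digits))
    graphics::points(p[1L], p[2L], pch = if (nd$leaf) 22 else 21,
                     bg = if (nd$leaf) "lightyellow" else "lightblue",
                     cex = 3)
    graphics::text(p[1L], p[2L] - 0.25, lab, cex = 0.8)
  }
  invisible(x)
}
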