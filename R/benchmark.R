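#' Benchmark splitting criteria on the synthetic designs
#'
#' For every combination of design, sample size, criterion, split budget
#' and replicate: draws a fresh training set and an independent test set
#' of the same size from the design, fits a tree with the given criterion
#' and exactly that split budget, and evaluates [rmse()] and [wrmse()] of
#' the predicted effects against the test set's true effects. All
#' criteria see the identical train/test draws within a replicate, so
#' comparisons are paired, and every replicate's seeds derive
#' deterministically from `seed`.
#'
#' @param designs integer vector, subset of 1:4.
#' @param criteria character vector from
#'   `c("mo", "mh", "ct", "ts", "tot", "rt")`.
#' @param sizes training sample sizes.
#' @param splits split budgets (`max_splits` values).
#' @param reps replicates per cell.
#' @param seed master seed for the replicate seed schedule.
#' @param n_test test-set size; default: same as the training size.
#' @param noise_sd outcome noise standard deviation.
#' @param eps,select_rule,min_node,min_arm,honest passed to
#'   [hettree_fit()].
#' @return A long-format data frame with one row per
#'   (design, n, criterion, splits, rep) and columns `rmse`, `wrmse`;
#'   failed fits are recorded with `NA` metrics rather than aborting the
#'   run.
#' @export
#' @examples
#' run_benchmark(designs = 1, criteria = c("mo", "ct"), sizes = 300,
#'               splits = 2, reps = 2, seed = 1)
run_benchmark <- function(designs = 1:4,
                          criteria = c("mo", "mh", "ct", "ts", "tot", "rt"),
                          sizes = 1000L, splits = 5L, reps = 20L,
                          seed = 1L, n_test = NULL, noise_sd = 1,
                          eps = c(0.1, 0.1), select_rule = "max_hete",
                          min_node = 10L, min_arm = 2L, honest = FALSE) {
  stopifnot(all(designs %in% 1:4), reps >= 1)
  criteria <- match.arg(criteria, c("mo", "mh", "ct", "ts", "tot", "rt"),
                        several.ok = TRUE)
  seed <- as.integer(seed)
  cell_seed <- function(design, n, rep, role) {
    h <- (seed %% 100003) * 19543 + design * 7919 + (n %% 9973) * 131 +
      rep * 613 + role
    as.integer(h %% 2147483647L)
  }
  out <- list()
  for (design in designs) for (n in sizes) for (rep in seq_len(reps)) {
    train <- sim_design(design, n, seed = cell_seed(design, n, rep, 1L),
                        noise_sd = noise_sd)
    ntst <- if (is.null(n_test)) n else n_test
    test <- sim_design(design, ntst, seed = cell_seed(design, n, rep, 2L),
                       noise_sd = noise_sd)
    hd <- as_het_data(train)
    Xtest <- as.matrix(test$data[paste0("x", seq_len(test$p))])
    for (criterion in criteria) for (ms in splits) {
      res <- tryCatch({
        fit <- hettree_fit(hd, criterion = criterion, eps = eps,
                           select_rule = select_rule, max_splits = ms,
                           min_node = min_node, min_arm = min_arm,
                           honest = honest,
                           seed = cell_seed(design, n, rep, 3L))
        tau_hat <- predict(fit, Xtest)
        c(rmse(tau_hat, test$true_tau), wrmse(tau_hat, test$true_tau))
      }, error = function(e) c(NA_real_, NA_real_))
      out[[length(out) + 1L]] <- data.frame(
        design = design, n = n, criterion = criterion, splits = ms,
        rep = rep, rmse = res[1L], wrmse = res[2L])
    }
  }
  do.call(rbind, out)
}
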