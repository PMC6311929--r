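# Fixtures are generated in code; seeds are fixed so every run sees the
# same data.

# Randomized experiment with a constant additive effect tau:
# Y = tau * W + noise, W ~ Bernoulli(p).
make_constant_effect <- function(n, tau, seed, noise_sd = 1, p = 0.5) {
  set.seed(seed)
  x <- matrix(rnorm(n * 2L), n, 2L)
  w <- rbinom(n, 1L, p)
  y <- tau * w + rnorm(n, 0, noise_sd)
  het_data(x, y, w, propensity = rep(p, n))
}

# Noiseless, exactly separable fixture: Y = (2w - 1) * sign(x1), i.e.
# Y(1) = sign(x1), Y(0) = -sign(x1), so the true CATE is 2 * sign(x1).
# Both arms carry signal, so the pure split at zero is the unique optimum
# of every effect-based criterion.
make_sign_fixture <- function(n = 500L, seed = 21L, p_cov = 2L) {
  set.seed(seed)
  x <- matrix(rnorm(n * p_cov), n, p_cov)
  w <- rbinom(n, 1L, 0.5)
  y <- (2 * w - 1) * sign(x[, 1L])
  list(data = het_data(x, y, w, propensity = rep(0.5, n)),
       cate = 2 * sign(x[, 1L]),
       gap = c(max(x[x[, 1L] < 0, 1L]), min(x[x[, 1L] > 0, 1L])))
}

# Brute-force dominance oracles (vectorized over the first argument set).
.oracle_eps_dom <- function(f1, h1, f2, h2, eps) {
  (1 + eps[1L]) * f1 >= f2 & (1 + eps[2L]) * h1 >= h2
}
.oracle_par_dom <- function(f1, h1, f2, h2) {
  f1 >= f2 & h1 >= h2 & (f1 > f2 | h1 > h2)
}

# O(n^2) check of both clauses of the epsilon-optimal-set definition:
# every input must be eps-dominated by some archive entry, and no archive
# entry may be Pareto-dominated by any input.
check_eps_optimal <- function(archive_df, fit, hete, eps) {
  clause1 <- all(vapply(seq_along(fit), function(i)
    any(.oracle_eps_dom(archive_df$fit, archive_df$hete,
                        fit[i], hete[i], eps)), logical(1L)))
  clause2 <- !any(vapply(seq_len(nrow(archive_df)), function(j)
    any(.oracle_par_dom(fit, hete,
                        archive_df$fit[j], archive_df$hete[j])),
    logical(1L)))
  c(covers_all = clause1, none_dominated = clause2)
}

# Exact Pareto front indices by exhaustive enumeration.
pareto_front_idx <- function(fit, hete) {
  which(vapply(seq_along(fit), function(i)
    !any(.oracle_par_dom(fit, hete, fit[i], hete[i])), logical(1L)))
}
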