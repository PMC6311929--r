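test_that("epsilon-dominance follows its defining inequalities", {
  s <- c(3.2, 1.7)
  expect_true(eps_dominates(s, s, eps = c(0.1, 0.1)))
  expect_true(eps_dominates(s, s, eps = c(0, 0)))  # mutual at equality
  expect_true(eps_dominates(c(1, 1), c(1.2, 1.2), eps = c(0.2, 0.2)))
  expect_false(eps_dominates(c(1, 1), c(1.21, 1.2), eps = c(0.2, 0.2)))
  # eps = 0 reduces to weak Pareto dominance: incomparable pair
  expect_false(eps_dominates(c(2, 1), c(1, 2), eps = c(0, 0)))
  expect_false(eps_dominates(c(1, 2), c(2, 1), eps = c(0, 0)))
})

test_that("Pareto dominance requires one strict component", {
  expect_true(pareto_dominates(c(2, 2), c(1, 1)))
  expect_false(pareto_dominates(c(1, 1), c(1, 1)))
  expect_false(pareto_dominates(c(2, 0.5), c(1, 1)))
  expect_false(pareto_dominates(c(1, 1), c(2, 0.5)))
  expect_true(pareto_dominates(c(1, 2), c(1, 1)))
})

test_that("box indices discretize scores on the epsilon log grid", {
  expect_equal(box_index(1, 1, eps = c(0.2, 0.3))$bx, 0)
  expect_equal(box_index(1.2^3, 1, eps = c(0.2, 0.2))$bx, 3)
  expect_equal(box_index(5, 1, eps = c(0.2, 0.2))$bx, 8)  # floor(8.827)
  expect_equal(box_index(0, 5, eps = c(0.2, 0.2))$bx, -Inf)
  b <- box_index(c(1, 5), c(5, 1), eps = c(0.2, 0.2))
  expect_equal(b$bx, c(0, 8))
  expect_equal(b$by, c(8, 0))
})

test_that("archive insertion follows the maintenance rules", {
  a <- epsilon_archive(eps = c(0.2, 0.2))
  a <- archive_insert(a, 3, 4)
  expect_equal(as.data.frame(a)$fit, 3)

  # box-dominated newcomer leaves the archive unchanged
  a <- epsilon_archive(eps = c(0.2, 0.2))
  a <- archive_insert(a, 100, 100)
  a2 <- archive_insert(a, 1, 1)
  expect_equal(as.data.frame(a2)[1:5], as.data.frame(a)[1:5])

  # newcomer whose box dominates sweeps out the old entries
  a <- epsilon_archive(eps = c(0.2, 0.2))
  a <- archive_insert(a, 1, 100)
  a <- archive_insert(a, 100, 1)
  a <- archive_insert(a, 1000, 1000)
  d <- as.data.frame(a)
  expect_equal(nrow(d), 1L)
  expect_equal(d$fit, 1000)

  # same box: replacement only under Pareto dominance (first-wins ties)
  a <- epsilon_archive(eps = c(0.2, 0.2))
  a <- archive_insert(a, 10, 10)
  a <- archive_insert(a, 9.9, 10.5)       # incomparable: incumbent stays
  expect_equal(as.data.frame(a)$fit, 10)
  a <- archive_insert(a, 10.5, 10.5)      # dominates: replaced
  expect_equal(as.data.frame(a)$fit, 10.5)

  # zero-score pairs live in the sentinel box and never displace
  # positive-score entries
  a <- epsilon_archive(eps = c(0.2, 0.2))
  a <- archive_insert(a, 5, 5)
  a <- archive_insert(a, 0, 0)
  expect_equal(nrow(as.data.frame(a)), 1L)
  a0 <- archive_insert(epsilon_archive(c(0.2, 0.2)), 0, 0)
  a0 <- archive_insert(a0, 0.5, 0.5)
  expect_equal(as.data.frame(a0)$fit, 0.5)
})

test_that("incremental insertion matches the batch builder", {
  set.seed(31)
  f <- runif(300, 0.01, 100); h <- runif(300, 0.01, 100)
  a <- epsilon_archive(eps = c(0.1, 0.1))
  sizes <- integer(300)
  for (i in seq_along(f)) {
    a <- archive_insert(a, f[i], h[i])
    sizes[i] <- length(a$fit)
  }
  b <- build_archive(f, h, eps = c(0.1, 0.1))
  da <- as.data.frame(a); db <- as.data.frame(b)
  expect_equal(da[c("fit", "hete", "bx", "by")],
               db[c("fit", "hete", "bx", "by")])
  # size grows by at most one per insertion
  expect_true(all(diff(sizes) <= 1L))
  expect_equal(attr(b, "max_size"), max(sizes))
})

test_that("archive output is an epsilon-optimal set (brute-force oracle)", {
  set.seed(5)
  for (r in 1:100) {
    n <- sample(20:500, 1)
    e <- rep(sample(c(0.05, 0.1, 0.2), 1), 2)
    f <- runif(n, 0.01, 100); h <- runif(n, 0.01, 100)
    ok <- check_eps_optimal(as.data.frame(build_archive(f, h, eps = e)),
                            f, h, e)
    expect_true(all(ok), label = paste("instance", r))
  }
})

test_that("vanishing epsilon recovers the exact Pareto set", {
  set.seed(7)
  f <- as.numeric(sample(1:10000, 200))
  h <- as.numeric(sample(1:10000, 200))
  a <- as.data.frame(build_archive(f, h, eps = c(1e-9, 1e-9)))
  p <- pareto_front_idx(f, h)
  expect_setequal(paste(a$fit, a$hete), paste(f[p], h[p]))
})

test_that("occupied boxes do not depend on the stream order", {
  set.seed(9)
  f <- runif(400, 0.01, 100); h <- runif(400, 0.01, 100)
  ref <- as.data.frame(build_archive(f, h, eps = c(0.1, 0.1)))
  for (k in 1:5) {
    o <- sample(400)
    perm <- as.data.frame(build_archive(f[o], h[o], eps = c(0.1, 0.1)))
    expect_setequal(paste(ref$bx, ref$by), paste(perm$bx, perm$by))
  }
})

test_that("archive size respects the theoretical bound on [0.01,100]^2", {
  set.seed(13)
  for (r in 1:20) {
    a <- build_archive(runif(2000, 0.01, 100), runif(2000, 0.01, 100),
                       eps = c(0.2, 0.2))
    expect_lte(attr(a, "max_size"), 75)
  }
})

test_that("split selection applies the rule and its tie-breaks", {
  a <- build_archive(c(5, 1), c(1, 5), eps = c(0.1, 0.1),
                     feature = c(1L, 2L), threshold = c(0.5, 0.7))
  expect_equal(select_split(a, "max_hete")$hete, 5)
  expect_equal(select_split(a, "max_fit")$fit, 5)

  s1 <- build_archive(3, 3, eps = c(0.1, 0.1))
  expect_equal(select_split(s1, "max_hete")$fit, 3)
  expect_equal(select_split(s1, "max_fit")$fit, 3)

  # equal rule component: prefer the larger other component
  a2 <- build_archive(c(4, 5), c(3, 3), eps = c(1e-9, 1e-9),
                      feature = c(1L, 2L), threshold = c(0, 0))
  expect_equal(select_split(a2, "max_hete")$fit, 5)

  expect_error(select_split(epsilon_archive(), "max_hete"), "empty")
})

test_that("the printed size-bound formula evaluates and is monotone", {
  expect_equal(archive_size_bound(c(0.2, 0.2)), 0.48 / log10(1.2)^2)
  expect_equal(archive_size_bound(c(0.2, 0.2)), 76.559, tolerance = 1e-4)
  expect_equal(archive_size_bound(c(0.05, 0.05)), 0.48 / log10(1.05)^2)
  e <- c(0.05, 0.1, 0.2, 0.5, 1)
  b <- vapply(e, function(z) archive_size_bound(c(z, z)), numeric(1L))
  expect_true(all(diff(b) < 0))
  expect_error(archive_size_bound(c(0, 0.1)), "> 0")
})
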