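test_that("a zero-split tree is the full-sample ATE leaf", {
  d <- make_constant_effect(200L, tau = 1.1, seed = 3L)
  fit <- hettree_fit(d, criterion = "mo", max_splits = 0L)
  expect_equal(fit$n_splits, 0L)
  expect_length(fit$nodes, 1L)
  expect_equal(fit$nodes[[1L]]$tau, node_cate(d))
  expect_equal(unname(predict(fit, d$x)), rep(node_cate(d), 200L))
})

test_that("all effect-based criteria recover the separable split exactly", {
  fx <- make_sign_fixture(n = 500L, seed = 21L)
  for (cr in c("mh", "mo", "ct")) {
    fit <- hettree_fit(fx$data, criterion = cr, max_splits = 1L)
    nd <- fit$nodes[[1L]]
    expect_equal(nd$feature, 1L, label = cr)
    expect_gte(nd$threshold, fx$gap[1L])
    expect_lte(nd$threshold, fx$gap[2L])
  }
  # and the two leaves carry the exact effects -2 / +2
  fit <- hettree_fit(fx$data, criterion = "mo", max_splits = 1L)
  expect_equal(unname(predict(fit, matrix(c(-2, 0, 2, 0), 2, 2,
                                          byrow = TRUE))),
               c(-2, 2))
})

test_that("growth respects the split budget and partitions the sample", {
  set.seed(17)
  sim <- sim_design(2, 400L, seed = 17L)
  hd <- as_het_data(sim)
  for (ms in c(1L, 3L, 7L)) {
    fit <- hettree_fit(hd, criterion = "ct", max_splits = ms)
    expect_lte(fit$n_splits, ms)
    leaves <- Filter(function(z) z$leaf, fit$nodes)
    expect_equal(sum(vapply(leaves, `[[`, integer(1L), "n")), 400L)
    # routing training rows reproduces the stored leaf sizes
    leaf_id <- hettree:::.route(fit, hd$x)
    tab <- table(leaf_id)
    for (z in leaves)
      expect_equal(unname(tab[as.character(z$id)]), z$n)
  }
})

test_that("training RMSE on the noiseless fixture never worsens with depth", {
  fx <- make_sign_fixture(n = 400L, seed = 33L)
  truth <- fx$cate
  errs <- vapply(0:4, function(ms) {
    fit <- hettree_fit(fx$data, criterion = "ct", max_splits = ms)
    rmse(predict(fit, fx$data$x), truth)
  }, numeric(1L))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("prediction validates dimensions and routes by the left rule", {
  fx <- make_sign_fixture(n = 300L, seed = 9L)
  fit <- hettree_fit(fx$data, criterion = "ct", max_splits = 2L)
  expect_error(predict(fit, matrix(0, 5, 3)), "expects")
  # boundary rows: value equal to the threshold goes left
  nd <- fit$nodes[[fit$root]]
  in_subtree <- function(id, root_id) {
    z <- fit$nodes[[root_id]]
    if (root_id == id) return(TRUE)
    if (z$leaf) return(FALSE)
    in_subtree(id, z$left) || in_subtree(id, z$right)
  }
  at <- matrix(0, 1, 2); at[1, nd$feature] <- nd$threshold
  above <- at; above[1, nd$feature] <- nd$threshold + 1e-9
  expect_true(in_subtree(hettree:::.route(fit, at), nd$left))
  expect_true(in_subtree(hettree:::.route(fit, above), nd$right))
})

test_that("serialization round-trips predictions and is byte-stable", {
  set.seed(25)
  sim <- sim_design(2, 600L, seed = 25L)
  hd <- as_het_data(sim)
  fit <- hettree_fit(hd, criterion = "mo", max_splits = 15L)
  js1 <- write_hettree(fit)
  js2 <- write_hettree(hettree_fit(hd, criterion = "mo", max_splits = 15L))
  expect_identical(js1, js2)  # identical data + config => identical bytes

  back <- read_hettree(js1)
  Xnew <- matrix(rnorm(1000 * 20), 1000, 20)
  expect_identical(predict(fit, Xnew), predict(back, Xnew))
  expect_identical(write_hettree(back), js1)

  # a zero-split model round-trips too
  f0 <- hettree_fit(hd, criterion = "ct", max_splits = 0L)
  expect_identical(predict(read_hettree(write_hettree(f0)), Xnew),
                   predict(f0, Xnew))
})

test_that("malformed model documents are rejected with clear errors", {
  fx <- make_sign_fixture(n = 200L, seed = 2L)
  fit <- hettree_fit(fx$data, criterion = "ct", max_splits = 1L)
  js <- write_hettree(fit)
  expect_error(read_hettree(gsub('"format": "hettree"', '"format": "x"',
                                 js, fixed = TRUE)), "format")
  expect_error(read_hettree(gsub('"version": 1', '"version": 99',
                                 js, fixed = TRUE)), "version")
  doc <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  doc$root$right <- NULL
  expect_error(read_hettree(jsonlite::toJSON(doc, auto_unbox = TRUE)),
               "child")
  expect_error(read_hettree("{not json"), "valid")
})

test_that("honest fitting re-estimates leaves on the held-out half", {
  d <- make_constant_effect(600L, tau = 1, seed = 41L)
  f1 <- hettree_fit(d, criterion = "ct", max_splits = 2L, honest = TRUE,
                    seed = 7L)
  f2 <- hettree_fit(d, criterion = "ct", max_splits = 2L, honest = TRUE,
                    seed = 7L)
  expect_identical(write_hettree(f1), write_hettree(f2))
  # leaf sizes cover only the estimation half
  leaves <- Filter(function(z) z$leaf, f1$nodes)
  expect_equal(sum(vapply(leaves, `[[`, integer(1L), "n")), 300L)
  # a different honest seed may change the tree
  expect_s3_class(hettree_fit(d, criterion = "ct", max_splits = 2L,
                              honest = TRUE, seed = 8L), "hettree")
})

test_that("formula front end matches the matrix back end", {
  sim <- sim_design(1, 300L, seed = 19L)
  m1 <- hettree(y ~ x1 + x2, sim$data, treatment = "w", propensity = "e",
                criterion = "mo", max_splits = 3L)
  m2 <- hettree_fit(as_het_data(sim), criterion = "mo", max_splits = 3L)
  expect_identical(predict(m1, sim$data), predict(m2, sim$data))
  expect_error(hettree(y ~ x1 + x2, sim$data, treatment = "nope"),
               "nope")
  # dot formula excludes outcome, treatment and propensity columns
  m3 <- hettree(y ~ ., sim$data, treatment = "w", propensity = "e",
                criterion = "mo", max_splits = 3L)
  expect_equal(m3$feature_names, c("x1", "x2"))
})

test_that("ct coincides with mo under the max-fit rule on a clean fixture", {
  fx <- make_sign_fixture(n = 300L, seed = 4L)
  fct <- hettree_fit(fx$data, criterion = "ct", max_splits = 1L)
  fmo <- hettree_fit(fx$data, criterion = "mo", select_rule = "max_fit",
                     max_splits = 1L)
  expect_equal(fct$nodes[[1L]]$feature, fmo$nodes[[1L]]$feature)
  expect_equal(fct$nodes[[1L]]$threshold, fmo$nodes[[1L]]$threshold)
})

test_that("model methods expose structure without recomputation", {
  fx <- make_sign_fixture(n = 300L, seed = 14L)
  fit <- hettree_fit(fx$data, criterion = "mo", max_splits = 2L)
  s <- summary(fit)
  expect_equal(nrow(s$splits), fit$n_splits)
  expect_equal(sum(s$leaves$n), 300L)
  expect_equal(length(coef(fit)), nrow(s$leaves))
  expect_output(print(fit), "criterion = mo")
  expect_output(print(s), "Leaves")
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf); on.exit(grDevices::dev.off(), add = TRUE)
  expect_invisible(plot(fit))
})
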