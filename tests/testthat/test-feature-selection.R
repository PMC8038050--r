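test_that("OFS removes constants, near-constants and collinear columns as constructed", {
  d <- gen_descriptor_dataset(synthetic_spec(
    n_molecules = 100, n_descriptors = 12, n_constant = 3,
    n_near_constant = 2, n_collinear_pairs = 2,
    planted_subset = c(1, 5), beta = c(1, -1), seed = 21))
  f <- ofs_filter(d$X, y = d$y)
  expect_setequal(f$report$removed_constant, d$truth$constant)
  expect_setequal(f$report$removed_near_constant, d$truth$near_constant)
  expect_setequal(f$report$removed_correlated$dropped, d$truth$collinear)
  expect_setequal(f$report$surviving, sprintf("D%03d", 1:12))
  # full pairwise scan: nothing above the cutoff survives
  R <- abs(cor(as.matrix(f$X$values)))
  diag(R) <- 0
  expect_lte(max(R), 0.90)
})

test_that("near-constant threshold is inclusive at the modal fraction", {
  X <- cbind(a = rnorm(100), b = c(rep(0, 96), 1:4))
  f <- ofs_filter(X)
  expect_equal(f$report$removed_near_constant, "b")  # 0.96 >= 0.95
  X2 <- cbind(a = rnorm(100), b = c(rep(0, 94), 1:6))
  f2 <- ofs_filter(X2)
  expect_length(f2$report$removed_near_constant, 0L)  # 0.94 < 0.95
})

test_that("collinearity pruning keeps exactly one of a perfect pair", {
  set.seed(5)
  base <- rnorm(50)
  X <- cbind(u = base, v = 3 * base, w = rnorm(50))
  f <- ofs_filter(X)
  expect_equal(sort(colnames(f$X)), sort(c(setdiff(c("u", "v"),
                                                   f$report$removed_correlated$dropped),
                                           "w")))
  expect_equal(nrow(f$report$removed_correlated), 1L)
  expect_equal(f$report$removed_correlated$abs_r, 1.0, tolerance = 1e-12)
  # with a response, the less informative twin is dropped
  y <- base + rnorm(50, sd = 2)
  fy <- ofs_filter(cbind(u = base + rnorm(50, sd = 1e-8), v = base,
                         w = rnorm(50)), y = y)
  expect_equal(nrow(fy$report$removed_correlated), 1L)

  jit <- gen_descriptor_dataset(synthetic_spec(
    n_molecules = 200, n_descriptors = 4, n_collinear_pairs = 1,
    planted_subset = 1, beta = 1, collinear_jitter = 1.2, seed = 9))
  # heavy jitter keeps |R| below the cutoff: the pair survives
  fj <- ofs_filter(jit$X)
  expect_lt(abs(cor(jit$X$values[, "collin1"],
                    jit$X$values[, jit$truth$collinear_source])), 0.90)
  expect_true("collin1" %in% fj$report$surviving)

  expect_error(ofs_filter(cbind(a = rep(1, 10), b = rep(2, 10))),
               "empty descriptor pool")
})

test_that("GA subset search finds the planted model and matches the exhaustive oracle", {
  d <- gen_descriptor_dataset(synthetic_spec(
    n_molecules = 60, n_descriptors = 20, planted_subset = c(3, 7, 11),
    beta = c(1, -1, 0.5), noise_sigma = 0.1, seed = 31))
  ex <- exhaustive_mlr_search(d$X, d$y, 3)
  cfg <- ga_config(3, population = 40, generations = 150, patience = 40,
                   seed = 8)
  ga <- ga_mlr_search(d$X, d$y, cfg)
  expect_setequal(ga[[1]]$descriptor_names, d$truth$planted_names)
  expect_setequal(ex[[1]]$descriptor_names, d$truth$planted_names)
  expect_equal(ga[[1]]$fitness_q2loo, ex[[1]]$fitness_q2loo, tolerance = 1e-12)
  # the GA can never beat complete enumeration
  expect_lte(ga[[1]]$fitness_q2loo, ex[[1]]$fitness_q2loo + 1e-12)

  # determinism under a fixed seed
  ga2 <- ga_mlr_search(d$X, d$y, cfg)
  expect_identical(lapply(ga, `[[`, "descriptor_names"),
                   lapply(ga2, `[[`, "descriptor_names"))
  expect_equal(vapply(ga, `[[`, numeric(1), "fitness_q2loo"),
               vapply(ga2, `[[`, numeric(1), "fitness_q2loo"))
})

test_that("GA fitness agrees with an independent LOO recomputation", {
  d <- gen_descriptor_dataset(synthetic_spec(
    n_molecules = 40, n_descriptors = 8, planted_subset = c(2, 5),
    beta = c(1, 1), noise_sigma = 0.3, seed = 12))
  ga <- ga_mlr_search(d$X, d$y, ga_config(2, population = 20,
                                          generations = 30, seed = 1))
  top <- ga[[1]]
  expect_equal(top$fitness_q2loo,
               q2_loo(d$X$values[, top$descriptor_names], d$y)$q2,
               tolerance = 1e-12)
})

test_that("degenerate and boundary subset searches behave", {
  set.seed(2)
  X <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("d", 1:5)))
  y <- X[, 1] + rnorm(20, sd = 0.1)
  ex <- exhaustive_mlr_search(X, y, 2, n_keep = 100)
  expect_length(ex, choose(5, 2))
  # model_size equal to the pool returns the single full subset
  full <- ga_mlr_search(X, y, ga_config(5, population = 10, generations = 5))
  expect_length(full, 1L)
  expect_setequal(full[[1]]$descriptor_names, colnames(X))
  # a duplicated column makes every containing subset singular, never ranked
  Xs <- cbind(X, d6 = X[, 1])
  exs <- exhaustive_mlr_search(Xs, y, 2, n_keep = 15)
  fits <- vapply(exs, `[[`, numeric(1), "fitness_q2loo")
  sing <- vapply(exs, function(cc)
    setequal(cc$descriptor_names, c("d1", "d6")), logical(1))
  expect_true(all(fits[sing] == -Inf))
  expect_true(all(which(sing) > which(is.finite(fits))))
  expect_error(exhaustive_mlr_search(matrix(rnorm(2000), 10, 200), rnorm(10),
                                     5, max_subsets = 1e6),
               "budget")
})

test_that("breaking-point analysis finds the elbow in the Q2 curve", {
  bp <- breaking_point(c(0.30, 0.50, 0.68, 0.70))
  expect_equal(bp$size, 3L)
  expect_equal(bp$table$q2, c(0.30, 0.50, 0.68, 0.70))
  expect_warning(bp2 <- breaking_point(c(0.2, 0.3, 0.4, 0.5)), "no elbow")
  expect_equal(bp2$size, 4L)
  expect_warning(breaking_point(c(0.5, 0.7, 0.65, 0.66)), "decreases")
  expect_error(breaking_point(c(0.5, 0.6)), "at least 3")
})
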