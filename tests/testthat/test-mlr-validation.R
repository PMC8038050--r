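rand_design <- function(n, p, seed, beta = NULL, sigma = 0.2) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("d", 1:p)))
    if (is.null(beta)) beta <- rnorm(p)
    y <- drop(X %*% beta) + rnorm(n, sd = sigma)
    list(X = X, y = y, beta = beta)
  })
}

test_that("OLS coefficients solve the normal equations", {
  # 5x2 hand dataset, solved by hand via solve(t(Z) Z) t(Z) y
  X <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 1, 4, 3, 6))
  y <- c(1.2, 1.9, 3.1, 3.9, 5.2)
  Z <- cbind(1, X)
  beta_ref <- drop(solve(t(Z) %*% Z, t(Z) %*% y))
  m <- fit_ols(X, y)
  expect_equal(unname(c(m$intercept, m$coefficients)), unname(beta_ref),
               tolerance = 1e-12)
  # and agree with lm(), including the 95% half-widths
  lf <- lm(y ~ a + b, data = data.frame(X, y))
  expect_equal(unname(m$coefficients), unname(coef(lf)[-1]), tolerance = 1e-10)
  ci <- confint(lf)
  expect_equal(unname(m$coef_halfwidths), unname((ci[-1, 2] - ci[-1, 1]) / 2),
               tolerance = 1e-8)

  # constant response: zero slopes, intercept = constant
  mc <- fit_ols(X, rep(2.5, 5))
  expect_equal(mc$intercept, 2.5, tolerance = 1e-12)
  expect_equal(unname(mc$coefficients), c(0, 0), tolerance = 1e-12)

  # noiseless planted data recovered exactly
  d <- rand_design(30, 4, seed = 3, sigma = 0)
  mn <- fit_ols(d$X, d$y)
  expect_equal(unname(mn$coefficients), d$beta, tolerance = 1e-8)
  expect_equal(mn$intercept, 0, tolerance = 1e-8)

  expect_error(fit_ols(cbind(a = 1:10, b = 2 * (1:10)), rnorm(10)),
               "singular")
})

test_that("prediction is the published affine form", {
  zero <- c(C_AbSA = 0, all_HASA2 = 0, fNH4B = 0, fringNH2A = 0, flipoH3B = 0)
  expect_equal(predict(published_model("model1"), zero), 0.928)
  expect_equal(predict(published_model("model2"), zero), 1.574)
  x <- zero; x["C_AbSA"] <- 100; x["all_HASA2"] <- 100
  expect_equal(predict(published_model("model1"), x),
               0.928 + 2.8 + 0.9, tolerance = 1e-12)
  expect_error(predict(published_model("model1"), c(C_AbSA = 1)),
               "missing descriptor")
})

test_that("fit statistics obey their defining identities", {
  d <- rand_design(40, 3, seed = 7)
  m <- fit_ols(d$X, d$y)
  st <- basic_fit_stats(m, d$X, d$y)
  res <- d$y - predict(m, d$X)
  n <- 40; p <- 3
  rss <- sum(res^2); tss <- sum((d$y - mean(d$y))^2)
  expect_equal(st$r2tr, 1 - rss / tss, tolerance = 1e-12)
  expect_equal(st$rmse_tr, sqrt(rss / n), tolerance = 1e-12)
  expect_equal(st$s, sqrt(rss / (n - p - 1)), tolerance = 1e-12)
  expect_equal(st$mae_tr, mean(abs(res)), tolerance = 1e-12)
  expect_equal(st$r2adj, 1 - (1 - st$r2tr) * (n - 1) / (n - p - 1),
               tolerance = 1e-12)
  expect_equal(st$f_stat, (st$r2tr / p) / ((1 - st$r2tr) / (n - p - 1)),
               tolerance = 1e-12)
  expect_equal(st$rss_tr, n * st$rmse_tr^2, tolerance = 1e-10)
  # F matches the overall lm F statistic
  lf <- summary(lm(y ~ ., data = data.frame(d$X, y = d$y)))
  expect_equal(st$f_stat, unname(lf$fstatistic[1]), tolerance = 1e-9)
})

test_that("hat-matrix LOO equals the explicit refit loop", {
  for (seed in 1:3) {
    d <- rand_design(30, 3, seed = seed)
    got <- q2_loo(d$X, d$y)
    ref <- oracle_loo_press(d$X, d$y)
    expect_equal(got$pred, ref$pred, tolerance = 1e-10)
    expect_equal(got$press, ref$press, tolerance = 1e-10)
    expect_equal(got$q2, ref$q2, tolerance = 1e-10)
  }
  # PRESS > RSS, so Q2loo < R2tr strictly
  d <- rand_design(25, 4, seed = 11)
  m <- fit_ols(d$X, d$y)
  expect_lt(q2_loo(d$X, d$y)$q2, basic_fit_stats(m, d$X, d$y)$r2tr)
  # noiseless data interpolates perfectly
  dn <- rand_design(25, 3, seed = 5, sigma = 0)
  expect_equal(q2_loo(dn$X, dn$y)$q2, 1, tolerance = 1e-10)
  expect_equal(q2_loo(dn$X, dn$y)$press, 0, tolerance = 1e-12)
})

test_that("leave-many-out is seeded, bounded and sane", {
  dn <- rand_design(40, 3, seed = 6, sigma = 0)
  expect_equal(q2_lmo(dn$X, dn$y, reps = 50)$q2_lmo, 1, tolerance = 1e-10)
  d <- rand_design(80, 3, seed = 13, sigma = 0.3)
  a <- q2_lmo(d$X, d$y, reps = 100, seed = 42)
  b <- q2_lmo(d$X, d$y, reps = 100, seed = 42)
  expect_identical(a$per_rep, b$per_rep)
  # leaving 30% out cannot beat leave-one-out by more than noise
  expect_lte(a$q2_lmo, q2_loo(d$X, d$y)$q2 + 0.05)
  expect_error(q2_lmo(d$X, d$y, frac_out = 0), "frac_out")
})

test_that("y-scrambling destroys a planted signal reproducibly", {
  d <- rand_design(60, 4, seed = 17, sigma = 0.2)
  m <- fit_ols(d$X, d$y)
  true_r2 <- basic_fit_stats(m, d$X, d$y)$r2tr
  scr <- y_scramble(d$X, d$y, reps = 150, seed = 7)
  expect_lt(scr$r2_yscr, true_r2)
  expect_lt(scr$q2_yscr, q2_loo(d$X, d$y)$q2)
  scr2 <- y_scramble(d$X, d$y, reps = 150, seed = 7)
  expect_identical(scr$per_rep, scr2$per_rep)
  expect_error(y_scramble(d$X, d$y, reps = 50), "reps")
})

test_that("external statistics honour their definitions and ordering", {
  d <- rand_design(60, 3, seed = 23)
  tr <- 1:40; ex <- 41:60
  m <- fit_ols(d$X[tr, ], d$y[tr])
  st <- external_stats(m, d$X[ex, ], d$y[ex], mean(d$y[tr]),
                       sum((d$y[tr] - mean(d$y[tr]))^2) / 40)
  pred <- predict(m, d$X[ex, ])
  press <- sum((d$y[ex] - pred)^2)
  expect_equal(st$press_ext, press, tolerance = 1e-12)
  expect_equal(st$rmse_ex, sqrt(press / 20), tolerance = 1e-12)
  expect_equal(st$q2_f2,
               1 - press / sum((d$y[ex] - mean(d$y[ex]))^2), tolerance = 1e-12)
  # the external mean minimizes the centered reference: Q2F2 <= Q2F1
  expect_lte(st$q2_f2, st$q2_f1)
  # perfect predictions: every external statistic is 1
  mp <- mlr_model(0, c(d1 = 1, d2 = 0, d3 = 0))
  stp <- external_stats(mp, cbind(d1 = d$y[ex], d2 = 0, d3 = 0), d$y[ex],
                        mean(d$y[tr]), 1)
  expect_equal(unlist(stp[c("r2_ex", "q2_f1", "q2_f2", "q2_f3", "ccc_ex")]),
               c(r2_ex = 1, q2_f1 = 1, q2_f2 = 1, q2_f3 = 1, ccc_ex = 1),
               tolerance = 1e-12)
  expect_error(external_stats(m, d$X[integer(0), ], numeric(0), 0, 1),
               "empty external")
})

test_that("concordance correlation behaves at its bounds", {
  x <- rnorm(30)
  expect_equal(lins_ccc(x, x), 1, tolerance = 1e-12)
  expect_lt(lins_ccc(x, -x), 0)
  expect_lte(abs(lins_ccc(rnorm(100), rnorm(100))), 1)
})

test_that("Golbraikh-Tropsha block matches the origin-regression oracle", {
  y <- seq(1, 5, length.out = 20)
  expect_equal(golbraikh_tropsha(y, y)[c("k", "k_prime", "r2m")],
               list(k = 1, k_prime = 1, r2m = 1), tolerance = 1e-12)
  gt2 <- golbraikh_tropsha(y, 2 * y)
  expect_equal(gt2$k, 0.5, tolerance = 1e-12)
  expect_equal(gt2$k_prime, 2, tolerance = 1e-12)
  withr::with_seed(77, {
    yo <- rnorm(20, mean = 5)
    yp <- yo + rnorm(20, sd = 0.7)
  })
  got <- golbraikh_tropsha(yo, yp)
  ref <- oracle_gt(yo, yp)
  for (f in names(ref)) {
    expect_equal(got[[f]], ref[[f]], tolerance = 1e-10, label = f)
  }
})

test_that("multivariate K correlation spans its rank limits", {
  set.seed(9)
  base <- rnorm(40)
  X1 <- cbind(a = base, b = 2 * base + 1e-9 * rnorm(40))
  expect_equal(kxx_delta_k(X1, rnorm(40))$kxx, 1, tolerance = 1e-4)
  # mutually orthogonal centered columns (orthogonal to the constant too)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 4), 40, 4))))[, 2:5]
  colnames(q) <- paste0("o", 1:4)
  expect_equal(kxx_delta_k(q, rnorm(40))$kxx, 0, tolerance = 1e-10)
  # direct eigenvalue-formula oracle on a random 4-descriptor block
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y <- rnorm(50)
  got <- kxx_delta_k(X, y)
  kref <- function(M) {
    lam <- eigen(cor(M))$values
    m <- ncol(M)
    sum(abs(lam / sum(lam) - 1 / m)) / (2 * (m - 1) / m)
  }
  expect_equal(got$kxx, kref(X), tolerance = 1e-12)
  expect_equal(got$delta_k, kref(cbind(X, y)) - kref(X), tolerance = 1e-12)
  expect_error(kxx_delta_k(cbind(a = rep(1, 10), b = rnorm(10)), rnorm(10)),
               "constant")
})

test_that("Williams applicability domain follows the hat-matrix algebra", {
  d <- rand_design(155, 5, seed = 41)
  m <- fit_ols(d$X, d$y)
  ad <- williams_ad(m, d$X, d$y)
  lev <- ad$points$leverage
  expect_equal(sum(lev), 5 + 1, tolerance = 1e-10)      # trace identity
  expect_equal(mean(lev), 6 / 155, tolerance = 1e-10)
  expect_equal(ad$h_star, 3 * 6 / 155)                   # ~0.116
  # a far-outlying external point exceeds h*
  far <- matrix(50, 1, 5, dimnames = list("far", colnames(d$X)))
  ad2 <- williams_ad(m, d$X, d$y, far, 0)
  expect_gt(ad2$points$leverage[ad2$points$id == "far"], ad$h_star)
  expect_true("far" %in% ad2$influential)
})

test_that("coefficient recovery is calibrated against its standard errors", {
  # y = X beta + noise: the fitted coefficients should sit within 3 standard
  # errors of truth at the rate the t-distribution implies (>= 99%)
  hits <- 0L; total <- 0L
  for (rep in 1:100) {
    d <- rand_design(60, 3, seed = 1000 + rep, beta = c(1, -2, 0.5),
                     sigma = 0.5)
    m <- fit_ols(d$X, d$y)
    se <- m$coef_halfwidths / qt(0.975, 60 - 3 - 1)
    hits <- hits + sum(abs(m$coefficients - d$beta) <= 3 * se)
    total <- total + 3L
  }
  expect_gte(hits / total, 0.99)
})

test_that("acceptance rules pass on the published block and flag perturbations", {
  rep1 <- published_model_report("model1")
  chk <- acceptance_check(rep1)
  expect_true(chk$pass)
  expect_true(all(chk$rules$pass))
  expect_true(acceptance_check(published_model_report("model2"))$pass)

  bad <- rep1; bad$q2_loo <- 0.4
  chk2 <- acceptance_check(bad)
  expect_false(chk2$pass)
  expect_false(chk2$rules$pass[chk2$rules$rule == "Q2loo >= 0.5"])

  bad3 <- rep1; bad3$rmse_tr <- bad3$rmse_cv + 0.01
  chk3 <- acceptance_check(bad3)
  expect_false(chk3$rules$pass[chk3$rules$rule == "RMSEtr < RMSEcv"])
  expect_equal(sum(!chk3$rules$pass), 1L)

  miss <- rep1; miss$ccc_ex <- NULL
  expect_error(acceptance_check(miss), "ccc_ex")
})
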