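# (Z'Z)^{-1} via Cholesky; signals a singularity error on rank deficiency
xtx_inverse <- function(Z) {
  G <- crossprod(Z)
  R <- tryCatch(chol(G), error = function(e)
    stop("singular design: descriptors are collinear", call. = FALSE))
  if (min(diag(R))^2 < 1e-12 * max(diag(G))) {
    stop("singular design: descriptors are collinear", call. = FALSE)
  }
  chol2inv(R)
}

#' Ordinary least squares fit of a descriptor subset
#'
#' @param X Numeric matrix or `descriptor_matrix` (training rows only).
#' @param y Response vector (pIC50), aligned with the rows of `X`.
#' @param ids Optional molecule identifiers (defaults to rownames).
#' @return An `mlr_model`: intercept, named coefficients, 95% confidence
#'   half-widths of each coefficient (the "+/-" values), residual standard
#'   error `s`, training ids, `n_train` and `p`.
#' @export
fit_ols <- function(X, y, ids = NULL) {
  V <- as_descriptor_values(X)
  n <- nrow(V)
  p <- ncol(V)
  stopifnot(length(y) == n)
  if (n <= p + 1L) stop("need n > p + 1 observations")
  if (is.null(ids)) ids <- rownames(V)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  Z <- cbind(`(Intercept)` = 1, V)
  XtXinv <- xtx_inverse(Z)
  beta <- drop(XtXinv %*% crossprod(Z, y))
  names(beta) <- colnames(Z)
  res <- y - drop(Z %*% beta)
  rss <- sum(res^2)
  s2 <- rss / (n - p - 1L)
  se <- sqrt(s2 * diag(XtXinv))
  hw <- stats::qt(0.975, n - p - 1L) * se
  structure(
    list(intercept = unname(beta[1L]),
         coefficients = beta[-1L],
         intercept_halfwidth = unname(hw[1L]),
         coef_halfwidths = stats::setNames(hw[-1L], colnames(V)),
         s = sqrt(s2), training_ids = ids, n_train = n, p = p,
         fitted = drop(Z %*% beta), residuals = res, source = "fitted"),
    class = "mlr_model")
}

#' Build an MLR model from published coefficients
#'
#' @param intercept Intercept value.
#' @param coefficients Named numeric vector of coefficients.
#' @param coef_halfwidths Optional named 95% half-widths.
#' @param intercept_halfwidth Optional intercept half-width.
#' @param n_train,p Training size metadata, if known.
#' @return An `mlr_model` with `source = "published"`.
#' @export
mlr_model <- function(intercept, coefficients, coef_halfwidths = NULL,
                      intercept_halfwidth = NA_real_, n_train = NA_integer_,
                      p = length(coefficients)) {
  stopifnot(!is.null(names(coefficients)))
  structure(
    list(intercept = intercept, coefficients = coefficients,
         intercept_halfwidth = intercept_halfwidth,
         coef_halfwidths = coef_halfwidths, s = NA_real_,
         training_ids = NULL, n_train = n_train, p = p,
         source = "published"),
    class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, digits = 3, ...) {
  co <- c(x$intercept, x$coefficients)
  hw <- c(x$intercept_halfwidth, x$coef_halfwidths)
  terms <- c("", paste0(" * ", names(x$coefficients)))
  eq <- paste0(
    sprintf("%+.*f", digits, co),
    ifelse(is.na(hw), "", sprintf(" (+/- %.*f)", digits, hw)),
    terms, collapse = " ")
  cat("<mlr_model>", x$source, "\n  pIC50 =", sub("^\\+", "", eq), "\n")
  invisible(x)
}

#' Predict activity from descriptor values
#'
#' @param object An `mlr_model`.
#' @param newdata Named numeric vector, or data frame / matrix with one column
#'   per model descriptor.
#' @param ... Unused.
#' @return Predicted pIC50 value(s).
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  nm <- names(object$coefficients)
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L,
                      dimnames = list(NULL, names(newdata)))
  }
  newdata <- as.matrix(newdata)
  miss <- setdiff(nm, colnames(newdata))
  if (length(miss)) stop("missing descriptor(s): ", paste(miss, collapse = ", "))
  drop(object$intercept + newdata[, nm, drop = FALSE] %*% object$coefficients)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two continuous measurements around the identity line:
#' `2*cov(x,y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, with population
#' (1/n) moments.
#'
#' @param x,y Numeric vectors of equal length.
#' @return CCC in `[-1, 1]`.
#' @export
lins_ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  n <- length(x)
  vx <- stats::var(x) * (n - 1) / n
  vy <- stats::var(y) * (n - 1) / n
  cxy <- stats::cov(x, y) * (n - 1) / n
  2 * cxy / (vx + vy + (mean(x) - mean(y))^2)
}

# ---- closed-form identities shared by fit statistics and the reports ----

#' Fitting-statistic identities
#'
#' Closed-form relations between the sums of squares and the reported
#' statistics of an OLS model with `p` descriptors fitted to `n` observations:
#' `rmse_from_rss` (root-mean-square error, RSS/n under the root),
#' `sigma_from_rss` (residual standard error, denominator `n - p - 1`),
#' `adj_r2`, and `f_from_r2` (Fisher statistic). These are the exact
#' identities linking a model's R2/RSS/PRESS block; they are used internally
#' by [basic_fit_stats()] and exposed for auditing reported statistics.
#'
#' @param rss Residual sum of squares.
#' @param press Predictive residual sum of squares (cross-validated).
#' @param n Number of observations.
#' @param p Number of descriptors.
#' @param r2 Coefficient of determination.
#' @return A numeric value.
#' @name fit_identities
NULL

#' @rdname fit_identities
#' @export
rmse_from_rss <- function(rss, n) sqrt(rss / n)

#' @rdname fit_identities
#' @export
sigma_from_rss <- function(rss, n, p) sqrt(rss / (n - p - 1))

#' @rdname fit_identities
#' @export
adj_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' @rdname fit_identities
#' @export
f_from_r2 <- function(r2, n, p) (r2 / p) / ((1 - r2) / (n - p - 1))

#' @rdname fit_identities
#' @param d Friedman lack-of-fit smoothing parameter (default 0.5).
#' @export
friedman_lof <- function(rss, n, p, d = 0.5) {
  (rss / n) / (1 - (p + 1 + d * p) / n)^2
}

#' Training-set fitting statistics
#'
#' @param model A fitted `mlr_model`.
#' @param X Training descriptor matrix (columns matching the model).
#' @param y Training response.
#' @param lof_d Friedman lack-of-fit smoothing parameter.
#' @return List of fitting statistics: `r2tr`, `r2adj`, `lof`, `rmse_tr`,
#'   `mae_tr`, `rss_tr`, `ccc_tr`, `s`, `f_stat` (plus `n`, `p`).
#' @export
basic_fit_stats <- function(model, X, y, lof_d = 0.5) {
  V <- as_descriptor_values(X)
  n <- length(y)
  p <- model$p
  if (n <= p + 1L) stop("need n > p + 1 observations")
  yhat <- predict(model, V)
  res <- y - yhat
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  list(r2tr = r2, r2adj = adj_r2(r2, n, p),
       lof = friedman_lof(rss, n, p, lof_d),
       rmse_tr = rmse_from_rss(rss, n), mae_tr = mean(abs(res)),
       rss_tr = rss, ccc_tr = lins_ccc(y, yhat),
       s = sigma_from_rss(rss, n, p), f_stat = f_from_r2(r2, n, p),
       n = n, p = p)
}

#' Leave-one-out cross-validation
#'
#' LOO predictions through the hat-matrix identity
#' `e_loo = e / (1 - h)`; any observation with leverage numerically equal to 1
#' falls back to an explicit refit without that observation.
#'
#' @param X Descriptor matrix (training rows).
#' @param y Response vector.
#' @return List: `q2` (1 - PRESS/TSS), `press`, `rmse_cv`, `mae_cv`, `ccc_cv`,
#'   and the LOO predictions `pred`.
#' @export
q2_loo <- function(X, y) {
  V <- as_descriptor_values(X)
  n <- nrow(V)
  p <- ncol(V)
  stopifnot(length(y) == n)
  if (n <= p + 2L) stop("need n > p + 2 observations for LOO")
  Z <- cbind(1, V)
  XtXinv <- xtx_inverse(Z)
  beta <- drop(XtXinv %*% crossprod(Z, y))
  res <- y - drop(Z %*% beta)
  h <- rowSums((Z %*% XtXinv) * Z)
  loo_res <- res / (1 - h)
  deg <- which(h > 1 - 1e-10)
  for (i in deg) {
    fi <- fit_ols(V[-i, , drop = FALSE], y[-i])
    loo_res[i] <- y[i] - predict(fi, V[i, , drop = FALSE])
  }
  press <- sum(loo_res^2)
  tss <- sum((y - mean(y))^2)
  pred <- y - loo_res
  list(q2 = 1 - press / tss, press = press,
       rmse_cv = rmse_from_rss(press, n), mae_cv = mean(abs(loo_res)),
       ccc_cv = lins_ccc(y, pred), pred = pred)
}

#' Leave-many-out cross-validation
#'
#' Repeatedly excludes `frac_out` of the observations at random, refits, and
#' scores the excluded block with `1 - PRESS_out / sum((y_out - mean(y_kept))^2)`.
#' Returns the mean over repetitions (the conventional LMO summary; the
#' workflow default is 2000 repetitions at 30% out).
#'
#' @param X Descriptor matrix.
#' @param y Response.
#' @param frac_out Fraction excluded per repetition, in (0, 1).
#' @param reps Number of repetitions.
#' @param seed RNG seed.
#' @return List: `q2_lmo` (mean), `per_rep` (vector), `skipped` (repetitions
#'   dropped because the reduced design was singular).
#' @export
q2_lmo <- function(X, y, frac_out = 0.30, reps = 2000L, seed = 1L) {
  V <- as_descriptor_values(X)
  n <- nrow(V)
  p <- ncol(V)
  if (frac_out <= 0 || frac_out >= 1) stop("frac_out must be in (0, 1)")
  n_out <- max(1L, round(n * frac_out))
  if (n - n_out <= p + 1L) stop("too few observations retained per repetition")
  per <- rep(NA_real_, reps)
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      out <- sample.int(n, n_out)
      fit <- tryCatch(fit_ols(V[-out, , drop = FALSE], y[-out]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      pred <- predict(fit, V[out, , drop = FALSE])
      per[r] <- 1 - sum((y[out] - pred)^2) /
        sum((y[out] - mean(y[-out]))^2)
    }
  })
  skipped <- sum(is.na(per))
  if (skipped) message(skipped, " leave-many-out repetition(s) skipped")
  list(q2_lmo = mean(per, na.rm = TRUE), per_rep = per, skipped = skipped)
}

#' Y-randomization (response scrambling)
#'
#' Refits the model on randomly permuted responses to estimate the chance
#' correlation floor. Robust models show near-zero mean scrambled R2 and
#' negative mean scrambled Q2.
#'
#' @param X Descriptor matrix.
#' @param y Response.
#' @param reps Number of permutations (>= 100).
#' @param seed RNG seed.
#' @return List: `r2_yscr`, `q2_yscr` (means over repetitions), `per_rep`
#'   data frame.
#' @export
y_scramble <- function(X, y, reps = 2000L, seed = 1L) {
  stopifnot(reps >= 100L)
  V <- as_descriptor_values(X)
  r2s <- q2s <- numeric(reps)
  withr::with_seed(seed, {
    for (r in seq_len(reps)) {
      ys <- sample(y)
      fit <- fit_ols(V, ys)
      r2s[r] <- 1 - sum(fit$residuals^2) / sum((ys - mean(ys))^2)
      q2s[r] <- q2_loo(V, ys)$q2
    }
  })
  list(r2_yscr = mean(r2s), q2_yscr = mean(q2s),
       per_rep = data.frame(r2 = r2s, q2 = q2s))
}

#' External-set predictivity statistics
#'
#' Scores a fitted model on molecules never used in training. The three
#' external Q2 flavours differ in the reference variance: `Q2F1` centers the
#' external responses on the training mean, `Q2F2` on the external mean, and
#' `Q2F3` compares per-observation mean squared errors against the training
#' variance.
#'
#' @param model A fitted `mlr_model`.
#' @param X_ext External descriptor matrix.
#' @param y_ext External responses.
#' @param y_train_mean Mean of the training responses.
#' @param tss_train_per_n Training TSS divided by `n_train`.
#' @return List: `rmse_ex`, `mae_ex`, `press_ext`, `r2_ex` (squared Pearson
#'   correlation of observed and predicted), `q2_f1`, `q2_f2`, `q2_f3`,
#'   `ccc_ex`, and the predictions `pred`.
#' @export
external_stats <- function(model, X_ext, y_ext, y_train_mean,
                           tss_train_per_n) {
  V <- as_descriptor_values(X_ext)
  if (!nrow(V)) stop("empty external set")
  stopifnot(nrow(V) == length(y_ext))
  pred <- predict(model, V)
  n_ext <- length(y_ext)
  press <- sum((y_ext - pred)^2)
  list(rmse_ex = rmse_from_rss(press, n_ext),
       mae_ex = mean(abs(y_ext - pred)),
       press_ext = press,
       r2_ex = stats::cor(y_ext, pred)^2,
       q2_f1 = 1 - press / sum((y_ext - y_train_mean)^2),
       q2_f2 = 1 - press / sum((y_ext - mean(y_ext))^2),
       q2_f3 = 1 - (press / n_ext) / tss_train_per_n,
       ccc_ex = lins_ccc(y_ext, pred),
       pred = pred)
}

#' Golbraikh-Tropsha external criteria
#'
#' Slopes of the regressions through the origin between observed and predicted
#' values (`k`, `k'`), the corresponding origin-constrained determination
#' coefficients (`Ro2`, `R'o2`), and the `r2m` metrics.
#'
#' @param y_obs Observed values.
#' @param y_pred Predicted values.
#' @return List: `k`, `k_prime`, `ro2`, `r_prime_o2`, `r2m`, `r_prime_2m`,
#'   and the underlying squared correlation `r2`.
#' @export
golbraikh_tropsha <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3L)
  if (sum(y_pred^2) == 0 || sum(y_obs^2) == 0) stop("zero-variance input")
  r2 <- stats::cor(y_obs, y_pred)^2
  k <- sum(y_obs * y_pred) / sum(y_pred^2)
  k_prime <- sum(y_obs * y_pred) / sum(y_obs^2)
  ro2 <- 1 - sum((y_obs - k * y_pred)^2) / sum((y_obs - mean(y_obs))^2)
  r_prime_o2 <- 1 - sum((y_pred - k_prime * y_obs)^2) /
    sum((y_pred - mean(y_pred))^2)
  list(k = k, k_prime = k_prime, ro2 = ro2, r_prime_o2 = r_prime_o2,
       r2m = r2 * (1 - sqrt(abs(r2 - ro2))),
       r_prime_2m = r2 * (1 - sqrt(abs(r2 - r_prime_o2))),
       r2 = r2)
}

#' Multivariate K correlation of the descriptor block
#'
#' Todeschini's K index measures the total correlation among a set of
#' variables from the eigenvalues of their correlation matrix: 0 for mutually
#' orthogonal variables, 1 for a rank-one block. `Kxx` is computed on the
#' descriptors alone and `Kxy` on descriptors plus response;
#' `delta_k = Kxy - Kxx` should be positive for a model whose descriptors are
#' collectively correlated with the response more than with each other.
#'
#' @param X Descriptor matrix; a single-column block has `kxx = 0` by
#'   convention.
#' @param y Response vector.
#' @return List: `kxx`, `kxy`, `delta_k`.
#' @export
kxx_delta_k <- function(X, y) {
  V <- as_descriptor_values(X)
  stopifnot(ncol(V) >= 1L, nrow(V) == length(y))
  if (any(apply(V, 2L, stats::sd) == 0)) stop("constant descriptor column")
  kfun <- function(M) {
    lam <- eigen(stats::cor(M), symmetric = TRUE, only.values = TRUE)$values
    m <- ncol(M)
    sum(abs(lam / sum(lam) - 1 / m)) / (2 * (m - 1) / m)
  }
  # a single descriptor carries no inter-descriptor correlation
  kxx <- if (ncol(V) == 1L) 0 else kfun(V)
  kxy <- kfun(cbind(V, y))
  list(kxx = kxx, kxy = kxy, delta_k = kxy - kxx)
}

#' Williams-plot applicability domain
#'
#' Leverages of the training (and optionally external) molecules against the
#' training design, with the conventional cutoff `h* = 3(p+1)/n_train`, and
#' residuals standardized by the model's residual standard error `s`.
#'
#' @param model A fitted `mlr_model`.
#' @param X_train Training descriptor matrix.
#' @param y_train Training responses.
#' @param X_ext,y_ext Optional external set scored against the training
#'   design.
#' @return An `ad_report`: per-molecule data frame (`id`, `set`, `leverage`,
#'   `std_residual`), `h_star`, `outliers` (|standardized residual| > 3) and
#'   `influential` (leverage > h*).
#' @export
williams_ad <- function(model, X_train, y_train, X_ext = NULL, y_ext = NULL) {
  V <- as_descriptor_values(X_train)
  n <- nrow(V)
  Z <- cbind(1, V)
  XtXinv <- xtx_inverse(Z)
  lev_tr <- rowSums((Z %*% XtXinv) * Z)
  s <- model$s
  if (is.na(s)) s <- sigma_from_rss(sum((y_train - predict(model, V))^2),
                                    n, model$p)
  res_tr <- (y_train - predict(model, V)) / s
  ids_tr <- if (!is.null(rownames(V))) rownames(V) else
    as.character(seq_len(n))
  df <- data.frame(id = ids_tr, set = "training", leverage = lev_tr,
                   std_residual = res_tr, stringsAsFactors = FALSE)
  if (!is.null(X_ext)) {
    Ve <- as_descriptor_values(X_ext)
    Ze <- cbind(1, Ve)
    lev_ex <- rowSums((Ze %*% XtXinv) * Ze)
    res_ex <- if (!is.null(y_ext)) (y_ext - predict(model, Ve)) / s else
      NA_real_
    ids_ex <- if (!is.null(rownames(Ve))) rownames(Ve) else
      paste0("ext", seq_len(nrow(Ve)))
    df <- rbind(df, data.frame(id = ids_ex, set = "external",
                               leverage = lev_ex, std_residual = res_ex,
                               stringsAsFactors = FALSE))
  }
  h_star <- 3 * (model$p + 1) / n
  structure(
    list(points = df, h_star = h_star,
         outliers = df$id[!is.na(df$std_residual) &
                            abs(df$std_residual) > 3],
         influential = df$id[df$leverage > h_star]),
    class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("<ad_report>  %d points, h* = %.4f\n", nrow(x$points), x$h_star))
  cat("  response outliers:",
      if (length(x$outliers)) paste(x$outliers, collapse = ", ") else "none",
      "\n  high leverage:",
      if (length(x$influential)) paste(x$influential, collapse = ", ") else
        "none", "\n")
  invisible(x)
}
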