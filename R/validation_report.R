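#' Assemble a full validation report
#'
#' Runs every fitting, cross-validation, scrambling and external statistic for
#' one training/external split of a chosen descriptor subset, and returns them
#' under the conventional field names (`r2tr`, `q2_loo`, `q2_lmo`, `q2_f1`,
#' ...).
#'
#' @param X_train,y_train Training descriptor matrix (subset columns only) and
#'   response.
#' @param X_ext,y_ext Optional external set for the external block.
#' @param lmo_reps,lmo_frac Leave-many-out repetitions and excluded fraction.
#' @param yscr_reps Y-randomization repetitions.
#' @param seed RNG seed for LMO and scrambling.
#' @param lof_d Friedman lack-of-fit smoothing parameter.
#' @return A `validation_report` list; external and Golbraikh-Tropsha fields
#'   are `NA` when no external set is given. The fitted model is attached as
#'   attribute `"model"`.
#' @export
validation_report <- function(X_train, y_train, X_ext = NULL, y_ext = NULL,
                              lmo_reps = 2000L, lmo_frac = 0.30,
                              yscr_reps = 2000L, seed = 1L, lof_d = 0.5) {
  model <- fit_ols(X_train, y_train)
  fitb <- basic_fit_stats(model, X_train, y_train, lof_d = lof_d)
  loo <- q2_loo(X_train, y_train)
  lmo <- q2_lmo(X_train, y_train, frac_out = lmo_frac, reps = lmo_reps,
                seed = seed)
  scr <- y_scramble(X_train, y_train, reps = max(100L, yscr_reps), seed = seed)
  kk <- kxx_delta_k(X_train, y_train)

  rep_ <- list(
    r2tr = fitb$r2tr, r2adj = fitb$r2adj, lof = fitb$lof,
    kxx = kk$kxx, delta_k = kk$delta_k,
    rmse_tr = fitb$rmse_tr, mae_tr = fitb$mae_tr, rss_tr = fitb$rss_tr,
    ccc_tr = fitb$ccc_tr, s = fitb$s, f_stat = fitb$f_stat,
    q2_loo = loo$q2, rmse_cv = loo$rmse_cv, mae_cv = loo$mae_cv,
    press_cv = loo$press, ccc_cv = loo$ccc_cv,
    q2_lmo = lmo$q2_lmo,
    r2_yscr = scr$r2_yscr, q2_yscr = scr$q2_yscr,
    rmse_ex = NA_real_, mae_ex = NA_real_, press_ext = NA_real_,
    r2_ex = NA_real_, q2_f1 = NA_real_, q2_f2 = NA_real_, q2_f3 = NA_real_,
    ccc_ex = NA_real_,
    gt = list(k = NA_real_, k_prime = NA_real_, ro2 = NA_real_,
              r_prime_o2 = NA_real_, r2m = NA_real_, r_prime_2m = NA_real_),
    n_train = fitb$n, n_ext = 0L, p = fitb$p)

  if (!is.null(X_ext)) {
    ext <- external_stats(model, X_ext, y_ext,
                          y_train_mean = mean(y_train),
                          tss_train_per_n = sum((y_train - mean(y_train))^2) /
                            length(y_train))
    gt <- golbraikh_tropsha(y_ext, ext$pred)
    rep_[c("rmse_ex", "mae_ex", "press_ext", "r2_ex", "q2_f1", "q2_f2",
           "q2_f3", "ccc_ex")] <-
      ext[c("rmse_ex", "mae_ex", "press_ext", "r2_ex", "q2_f1", "q2_f2",
            "q2_f3", "ccc_ex")]
    rep_$gt <- gt[c("k", "k_prime", "ro2", "r_prime_o2", "r2m", "r_prime_2m")]
    rep_$n_ext <- length(y_ext)
  }
  structure(rep_, class = "validation_report", model = model)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf("  fit:  R2tr %.3f  R2adj %.3f  RMSEtr %.3f  s %.3f  F %.1f\n",
              x$r2tr, x$r2adj, x$rmse_tr, x$s, x$f_stat))
  cat(sprintf("  cv:   Q2loo %.3f  RMSEcv %.3f  Q2LMO %.3f  R2Yscr %.3f\n",
              x$q2_loo, x$rmse_cv, x$q2_lmo, x$r2_yscr))
  if (!is.na(x$r2_ex)) {
    cat(sprintf("  ext:  R2ex %.3f  Q2F1 %.3f  Q2F2 %.3f  Q2F3 %.3f  CCCex %.3f\n",
                x$r2_ex, x$q2_f1, x$q2_f2, x$q2_f3, x$ccc_ex))
  }
  invisible(x)
}

#' Published model statistic blocks
#'
#' The complete reported validation statistics of the two shipped
#' five-descriptor models, as `validation_report` objects. Useful as fixtures
#' for [acceptance_check()] and for auditing the statistic identities.
#'
#' @param which `"model1"` or `"model2"`.
#' @return A `validation_report` populated with the published values.
#' @export
published_model_report <- function(which = c("model1", "model2")) {
  which <- match.arg(which)
  v <- if (which == "model1") {
    list(r2tr = 0.788, r2adj = 0.781, lof = 0.831, kxx = 0.296,
         delta_k = 0.063, rmse_tr = 0.853, mae_tr = 0.699, rss_tr = 112.659,
         ccc_tr = 0.882, s = 0.87, f_stat = 110.953,
         q2_loo = 0.77, rmse_cv = 0.89, mae_cv = 0.729, press_cv = 122.628,
         ccc_cv = 0.871, q2_lmo = 0.764, r2_yscr = 0.033, q2_yscr = -0.047,
         rmse_ex = 0.907, mae_ex = 0.743, press_ext = 126.77, r2_ex = 0.757,
         q2_f1 = 0.755, q2_f2 = 0.755, q2_f3 = 0.76, ccc_ex = 0.867,
         gt = list(k = 0.998, k_prime = 0.973, ro2 = 0.755,
                   r_prime_o2 = 0.714, r2m = 0.723, r_prime_2m = 0.6),
         n_train = 155L, n_ext = 154L, p = 5L)
  } else {
    list(r2tr = 0.771, r2adj = 0.763, lof = 0.882, kxx = 0.258,
         delta_k = 0.081, rmse_tr = 0.878, mae_tr = 0.727, rss_tr = 118.695,
         ccc_tr = 0.87, s = 0.896, f_stat = 99.365,
         q2_loo = 0.75, rmse_cv = 0.917, mae_cv = 0.758, press_cv = 129.517,
         ccc_cv = 0.859, q2_lmo = 0.745, r2_yscr = 0.033, q2_yscr = -0.048,
         rmse_ex = 0.876, mae_ex = 0.725, press_ext = 118.967, r2_ex = 0.777,
         q2_f1 = 0.776, q2_f2 = 0.776, q2_f3 = 0.771, ccc_ex = 0.871,
         gt = list(k = 0.999, k_prime = 0.974, ro2 = 0.776,
                   r_prime_o2 = 0.705, r2m = 0.758, r_prime_2m = 0.568),
         n_train = 154L, n_ext = 155L, p = 5L)
  }
  structure(v, class = "validation_report")
}

#' Model acceptance rules
#'
#' Evaluates the full rule set used to accept a QSAR model: R2tr >= 0.6,
#' Q2loo >= 0.5, Q2LMO >= 0.6, R2 > Q2, R2ex >= 0.6, RMSEtr < RMSEcv,
#' delta K >= 0.05, CCCex >= 0.80, Q2F1/F2/F3 >= 0.60, r2m >= 0.5, the
#' Golbraikh-Tropsha origin-regression conditions
#' ((1 - r2/Ro2) < 0.1 with 0.9 <= k <= 1.1, or the primed variant), and
#' |Ro2 - R'o2| < 0.3.
#'
#' @param report A complete `validation_report` (external block included).
#' @return An `acceptance_check`: data frame of per-rule verdicts plus an
#'   overall `pass` flag. Missing report fields raise an error naming them.
#' @export
acceptance_check <- function(report) {
  need <- c("r2tr", "q2_loo", "q2_lmo", "r2_ex", "rmse_tr", "rmse_cv",
            "delta_k", "ccc_ex", "q2_f1", "q2_f2", "q2_f3", "gt")
  present <- vapply(need, function(f)
    !is.null(report[[f]]) && !anyNA(unlist(report[[f]])), logical(1))
  if (!all(present)) {
    stop("report is missing field(s): ", paste(need[!present], collapse = ", "))
  }
  gt <- report$gt
  gt_k <- (1 - report$r2_ex / gt$ro2) < 0.1 && gt$k >= 0.9 && gt$k <= 1.1
  gt_kp <- (1 - report$r2_ex / gt$r_prime_o2) < 0.1 &&
    gt$k_prime >= 0.9 && gt$k_prime <= 1.1
  rules <- data.frame(
    rule = c("R2tr >= 0.6", "Q2loo >= 0.5", "Q2LMO >= 0.6", "R2tr > Q2loo",
             "R2ex >= 0.6", "RMSEtr < RMSEcv", "deltaK >= 0.05",
             "CCCex >= 0.80", "Q2F1 >= 0.60", "Q2F2 >= 0.60", "Q2F3 >= 0.60",
             "r2m >= 0.5", "GT origin-regression (k or k')",
             "|Ro2 - R'o2| < 0.3"),
    value = c(report$r2tr, report$q2_loo, report$q2_lmo,
              report$r2tr - report$q2_loo, report$r2_ex,
              report$rmse_cv - report$rmse_tr, report$delta_k, report$ccc_ex,
              report$q2_f1, report$q2_f2, report$q2_f3, gt$r2m,
              NA_real_, abs(gt$ro2 - gt$r_prime_o2)),
    pass = c(report$r2tr >= 0.6, report$q2_loo >= 0.5, report$q2_lmo >= 0.6,
             report$r2tr > report$q2_loo, report$r2_ex >= 0.6,
             report$rmse_tr < report$rmse_cv, report$delta_k >= 0.05,
             report$ccc_ex >= 0.80, report$q2_f1 >= 0.60,
             report$q2_f2 >= 0.60, report$q2_f3 >= 0.60, gt$r2m >= 0.5,
             gt_k || gt_kp, abs(gt$ro2 - gt$r_prime_o2) < 0.3),
    stringsAsFactors = FALSE)
  structure(list(rules = rules, pass = all(rules$pass)),
            class = "acceptance_check")
}

#' @export
print.acceptance_check <- function(x, ...) {
  cat("<acceptance_check> overall:", if (x$pass) "PASS" else "FAIL", "\n")
  for (i in seq_len(nrow(x$rules))) {
    cat(sprintf("  [%s] %s\n", if (x$rules$pass[i]) "ok" else "XX",
                x$rules$rule[i]))
  }
  invisible(x)
}
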