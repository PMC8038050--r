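#' Split a dataset into two equal halves
#'
#' The default method sorts molecules by activity and assigns them
#' alternately, so both halves span the full activity range; a seeded random
#' split is also available. Half sizes differ by at most one.
#'
#' @param y Response vector (pIC50).
#' @param ids Molecule identifiers aligned with `y`.
#' @param method `"activity_sorted_alternating"` or `"random"`.
#' @param seed RNG seed for the random method.
#' @return A `split_scheme` with `set_a_ids` and `set_b_ids`.
#' @export
split_dataset <- function(y, ids = NULL,
                          method = c("activity_sorted_alternating", "random"),
                          seed = 1L) {
  method <- match.arg(method)
  if (is.null(ids)) ids <- as.character(seq_along(y))
  stopifnot(length(ids) == length(y), !anyDuplicated(ids))
  ord <- if (method == "activity_sorted_alternating") {
    order(y, decreasing = TRUE)
  } else {
    withr::with_seed(seed, sample.int(length(y)))
  }
  a <- ord[seq_along(ord) %% 2L == 1L]
  b <- ord[seq_along(ord) %% 2L == 0L]
  structure(list(set_a_ids = ids[a], set_b_ids = ids[b], method = method,
                 seed = as.integer(seed)),
            class = "split_scheme")
}

#' Run the exchange (50/50 swap) modeling strategy
#'
#' The workflow behind the shipped models: split the dataset into two equal
#' halves, run objective feature selection and the GA subset search on one
#' half, fit and internally validate the best model there, validate it
#' externally on the other half - then exchange the roles of the halves and
#' repeat. A model family is trusted when both arms select the same
#' descriptors and both pass the acceptance rules.
#'
#' @param X Descriptor matrix (`descriptor_matrix` or numeric matrix) for the
#'   full dataset.
#' @param y Response vector aligned with the rows of `X`.
#' @param model_size Number of descriptors per model.
#' @param split A [split_dataset()] scheme, or `NULL` to create one.
#' @param ga A [ga_config()] (its `model_size` is overridden).
#' @param near_const_frac,corr_cut OFS thresholds.
#' @param lmo_reps,yscr_reps Validation repetition counts.
#' @param seed Seed for splitting and validation resampling.
#' @return An `exchange_result` with one entry per arm (`ab`: selected on A,
#'   validated on B; `ba`: the swap), each holding the OFS report, ranked
#'   candidates, the fitted model, its `validation_report` and
#'   `acceptance_check`, and a Williams `ad_report`; plus `consensus`, the
#'   descriptors common to both arms' top models.
#' @export
run_exchange_workflow <- function(X, y, model_size, split = NULL,
                                  ga = NULL, near_const_frac = 0.95,
                                  corr_cut = 0.90, lmo_reps = 500L,
                                  yscr_reps = 200L, seed = 1L) {
  V <- as_descriptor_values(X)
  if (is.null(rownames(V))) rownames(V) <- as.character(seq_len(nrow(V)))
  ids <- rownames(V)
  stopifnot(length(y) == nrow(V))
  if (is.null(split)) split <- split_dataset(y, ids, seed = seed)
  if (is.null(ga)) ga <- ga_config(model_size, population = 50L,
                                   generations = 300L, patience = 50L,
                                   seed = seed)
  ga$model_size <- as.integer(model_size)

  arm <- function(train_ids, ext_ids) {
    tr <- match(train_ids, ids)
    ex <- match(ext_ids, ids)
    if (length(tr) <= model_size + 2L) {
      stop("training half too small for model_size = ", model_size)
    }
    ofs <- ofs_filter(V[tr, , drop = FALSE], near_const_frac, corr_cut,
                      y = y[tr])
    Vtr <- as_descriptor_values(ofs$X)
    cands <- ga_mlr_search(Vtr, y[tr], ga)
    top <- cands[[1L]]
    sel <- top$descriptor_names
    rep_ <- validation_report(V[tr, sel, drop = FALSE], y[tr],
                              V[ex, sel, drop = FALSE], y[ex],
                              lmo_reps = lmo_reps, yscr_reps = yscr_reps,
                              seed = seed)
    model <- attr(rep_, "model")
    list(ofs_report = ofs$report, candidates = cands, model = model,
         descriptors = sel, report = rep_,
         acceptance = acceptance_check(rep_),
         ad = williams_ad(model, V[tr, sel, drop = FALSE], y[tr],
                          V[ex, sel, drop = FALSE], y[ex]))
  }

  ab <- arm(split$set_a_ids, split$set_b_ids)
  ba <- arm(split$set_b_ids, split$set_a_ids)
  structure(list(ab = ab, ba = ba, split = split,
                 consensus = intersect(ab$descriptors, ba$descriptors)),
            class = "exchange_result")
}

#' @export
print.exchange_result <- function(x, ...) {
  cat("<exchange_result>\n")
  for (nm in c("ab", "ba")) {
    a <- x[[nm]]
    cat(sprintf("  arm %s: {%s}  Q2loo %.3f  %s\n", nm,
                paste(a$descriptors, collapse = ", "),
                a$report$q2_loo,
                if (a$acceptance$pass) "PASS" else "FAIL"))
  }
  cat("  consensus descriptors:",
      if (length(x$consensus)) paste(x$consensus, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

# published coefficient tables (intercept first), with 95% half-widths
.published <- list(
  model1 = list(
    coef = c(`(Intercept)` = 0.928, C_AbSA = 0.028, all_HASA2 = 0.009,
             fNH4B = -0.142, fringNH2A = 0.554, flipoH3B = -0.241),
    hw = c(`(Intercept)` = 0.703, C_AbSA = 0.008, all_HASA2 = 0.001,
           fNH4B = 0.069, fringNH2A = 0.311, flipoH3B = 0.133),
    n_train = 155L),
  model2 = list(
    coef = c(`(Intercept)` = 1.574, C_AbSA = 0.026, all_HASA2 = 0.008,
             fNH4B = -0.19, fringNH2A = 0.772, flipoH3B = -0.287),
    hw = c(`(Intercept)` = 0.618, C_AbSA = 0.008, all_HASA2 = 0.001,
           fNH4B = 0.068, fringNH2A = 0.336, flipoH3B = 0.139),
    n_train = 154L))

#' The shipped five-descriptor models
#'
#' Returns one of the two published GA-MLR models for Hs-NMT inhibition as an
#' `mlr_model` ready for [predict()]: five descriptors (`C_AbSA`,
#' `all_HASA2`, `fNH4B`, `fringNH2A`, `flipoH3B`) with their reported
#' coefficients and 95% half-widths.
#'
#' @param which `"model1"` or `"model2"`.
#' @return An `mlr_model`.
#' @examples
#' m <- published_model("model1")
#' predict(m, c(C_AbSA = 0, all_HASA2 = 0, fNH4B = 0, fringNH2A = 0,
#'              flipoH3B = 0))  # the intercept, 0.928
#' @export
published_model <- function(which = c("model1", "model2")) {
  which <- match.arg(which)
  pm <- .published[[which]]
  m <- mlr_model(intercept = unname(pm$coef[1L]),
                 coefficients = pm$coef[-1L],
                 coef_halfwidths = pm$hw[-1L],
                 intercept_halfwidth = unname(pm$hw[1L]),
                 n_train = pm$n_train)
  m
}

#' Predict with a shipped model, with applicability-domain flag
#'
#' @param x Named vector (or data frame/matrix) carrying the five model
#'   descriptors.
#' @param model `"model1"` or `"model2"`.
#' @param ad Optional applicability-domain context: a list with `X_train`
#'   (descriptor matrix of the training molecules, columns as the model) used
#'   to compute the query leverage against `h* = 3(p+1)/n`.
#' @return A list: `pic50` (prediction(s)) and `in_domain` (logical, `NA`
#'   when no AD context is supplied).
#' @export
predict_with_published <- function(x, model = c("model1", "model2"),
                                   ad = NULL) {
  m <- published_model(match.arg(model))
  pred <- predict(m, x)
  in_domain <- rep(NA, length(pred))
  if (!is.null(ad)) {
    Vt <- as_descriptor_values(ad$X_train)[, names(m$coefficients),
                                           drop = FALSE]
    Zt <- cbind(1, Vt)
    XtXinv <- xtx_inverse(Zt)
    xq <- if (is.null(dim(x))) {
      matrix(x[names(m$coefficients)], nrow = 1L)
    } else {
      as.matrix(x)[, names(m$coefficients), drop = FALSE]
    }
    Zq <- cbind(1, xq)
    lev <- rowSums((Zq %*% XtXinv) * Zq)
    in_domain <- lev <= 3 * (m$p + 1) / nrow(Vt)
  }
  list(pic50 = pred, in_domain = in_domain)
}

#' Write workflow reports to disk
#'
#' Serializes an exchange-workflow result to a machine-readable JSON report, a
#' Markdown summary mirroring the statistic block layout, and CSV plot data
#' (Williams plot and observed-vs-predicted). Regeneration with the same
#' result is byte-identical.
#'
#' @param result An `exchange_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
report_workflow <- function(result, dir = ".", prefix = "qsar") {
  stopifnot(inherits(result, "exchange_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strip <- function(rep_) {
    out <- unclass(rep_)
    attr(out, "model") <- NULL
    out
  }
  payload <- list(
    split = unclass(result$split),
    consensus = result$consensus,
    arms = lapply(result[c("ab", "ba")], function(a) list(
      descriptors = a$descriptors,
      model = list(intercept = a$model$intercept,
                   coefficients = as.list(a$model$coefficients),
                   halfwidths = as.list(a$model$coef_halfwidths)),
      statistics = strip(a$report),
      acceptance = a$acceptance$rules,
      overall_pass = a$acceptance$pass)))
  json_path <- file.path(dir, paste0(prefix, "_report.json"))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  md_path <- file.path(dir, paste0(prefix, "_report.md"))
  md <- c("# GA-MLR QSAR workflow report", "")
  for (nm in c("ab", "ba")) {
    a <- result[[nm]]
    r <- a$report
    md <- c(md,
            sprintf("## Arm %s", toupper(nm)),
            sprintf("Descriptors: %s", paste(a$descriptors, collapse = ", ")),
            sprintf(paste0("R2tr = %.3f, R2adj = %.3f, RMSEtr = %.3f, ",
                           "s = %.3f, F = %.3f, Q2loo = %.3f, RMSEcv = %.3f, ",
                           "Q2LMO = %.3f, R2Yscr = %.3f, Q2Yscr = %.3f"),
                    r$r2tr, r$r2adj, r$rmse_tr, r$s, r$f_stat, r$q2_loo,
                    r$rmse_cv, r$q2_lmo, r$r2_yscr, r$q2_yscr),
            sprintf(paste0("RMSEex = %.3f, R2ex = %.3f, Q2F1 = %.3f, ",
                           "Q2F2 = %.3f, Q2F3 = %.3f, CCCex = %.3f"),
                    r$rmse_ex, r$r2_ex, r$q2_f1, r$q2_f2, r$q2_f3, r$ccc_ex),
            sprintf("Acceptance: %s",
                    if (a$acceptance$pass) "PASS" else "FAIL"),
            "")
  }
  writeLines(md, md_path)
  csv_paths <- character(0)
  for (nm in c("ab", "ba")) {
    p <- file.path(dir, paste0(prefix, "_williams_", nm, ".csv"))
    utils::write.csv(result[[nm]]$ad$points, p, row.names = FALSE)
    csv_paths <- c(csv_paths, p)
  }
  invisible(c(json = json_path, md = md_path, csv_paths))
}
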