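#' Objective feature selection (OFS)
#'
#' Unsupervised pruning of a descriptor pool in three passes: (1) constant
#' columns (zero range); (2) near-constant columns whose modal value occurs in
#' at least `near_const_frac` of molecules; (3) greedy correlation pruning of
#' pairs with absolute Pearson correlation above `corr_cut`. When the response
#' `y` is supplied, the member of a correlated pair with the smaller absolute
#' correlation to the response is dropped; on exact ties, or without a
#' response, the later column of the pair. After filtering no surviving pair exceeds the cutoff.
#'
#' @param X A `descriptor_matrix`, matrix or data frame (>= 2 rows).
#' @param near_const_frac Modal-frequency threshold, default 0.95.
#' @param corr_cut Absolute-correlation cutoff, default 0.90 (pairs strictly
#'   above are pruned).
#' @param y Optional response vector used in the correlation tie-break.
#' @return A list with `X` (the filtered matrix, same class as the input
#'   values) and `report` (an `ofs_report`: `removed_constant`,
#'   `removed_near_constant`, `removed_correlated` with the kept partner and
#'   |R|, `surviving`).
#' @export
ofs_filter <- function(X, near_const_frac = 0.95, corr_cut = 0.90, y = NULL) {
  dm <- if (inherits(X, "descriptor_matrix")) X else NULL
  V <- as_descriptor_values(X)
  stopifnot(nrow(V) >= 2L)
  if (is.null(colnames(V))) colnames(V) <- paste0("D", seq_len(ncol(V)))

  rng <- apply(V, 2L, function(v) diff(range(v)))
  const <- colnames(V)[rng == 0]
  V <- V[, rng > 0, drop = FALSE]

  modal_frac <- apply(V, 2L, function(v) max(table(v)) / length(v))
  nearc <- colnames(V)[modal_frac >= near_const_frac]
  V <- V[, modal_frac < near_const_frac, drop = FALSE]

  removed_corr <- data.frame(dropped = character(), kept = character(),
                             abs_r = numeric(), stringsAsFactors = FALSE)
  if (ncol(V) >= 2L) {
    R <- abs(stats::cor(V))
    diag(R) <- 0
    yr <- if (!is.null(y)) abs(stats::cor(V, y)[, 1L])
    repeat {
      m <- max(R)
      if (m <= corr_cut) break
      idx <- which(R == m, arr.ind = TRUE)[1L, ]
      i <- idx[1L]; j <- idx[2L]
      # response correlations equal to numerical noise (exact duplicates)
      # fall through to the deterministic input-order rule: the later
      # column of the pair is dropped
      drop_i <- if (!is.null(y) && abs(yr[i] - yr[j]) > 1e-9) {
        yr[i] < yr[j]
      } else {
        i > j
      }
      d <- if (drop_i) i else j
      k <- if (drop_i) j else i
      removed_corr <- rbind(removed_corr, data.frame(
        dropped = colnames(V)[d], kept = colnames(V)[k], abs_r = m,
        stringsAsFactors = FALSE))
      V <- V[, -d, drop = FALSE]
      R <- R[-d, -d, drop = FALSE]
      if (!is.null(y)) yr <- yr[-d]
      if (ncol(V) < 2L) break
    }
  }
  if (!ncol(V)) stop("empty descriptor pool after objective feature selection")

  report <- structure(
    list(removed_constant = const, removed_near_constant = nearc,
         removed_correlated = removed_corr, surviving = colnames(V)),
    class = "ofs_report")
  if (!is.null(dm)) {
    keep <- match(colnames(V), dm$names)
    X <- descriptor_matrix(V, dm$provenance[keep, , drop = FALSE])
  } else {
    X <- V
  }
  list(X = X, report = report)
}

#' @export
print.ofs_report <- function(x, ...) {
  cat(sprintf(
    "<ofs_report>  removed: %d constant, %d near-constant, %d correlated; %d survive\n",
    length(x$removed_constant), length(x$removed_near_constant),
    nrow(x$removed_correlated), length(x$surviving)))
  invisible(x)
}

#' Genetic-algorithm settings for descriptor-subset search
#'
#' Fixed-cardinality subset GA: tournament selection (size 2), uniform
#' crossover on the membership mask repaired back to `model_size`, point
#' mutation swapping one member for a random non-member, elitism of 1, and
#' leave-one-out Q2 as the fitness. Fitness values are cached per subset, so
#' long runs on small pools converge to the exhaustive optimum.
#'
#' @param model_size Number of descriptors per model.
#' @param population Population size (default 200).
#' @param generations Maximum generations (default 10000).
#' @param mutation_rate Per-individual mutation probability.
#' @param crossover_rate Per-pair crossover probability.
#' @param seed RNG seed; fixed seed gives an identical ranking.
#' @param fitness Only `"q2_loo"` is implemented.
#' @param patience Stop after this many generations without improvement
#'   (default `Inf`).
#' @param n_keep Number of ranked candidates to return.
#' @return A `ga_config` list.
#' @export
ga_config <- function(model_size, population = 200L, generations = 10000L,
                      mutation_rate = 0.05, crossover_rate = 0.5, seed = 1L,
                      fitness = "q2_loo", patience = Inf, n_keep = 10L) {
  fitness <- match.arg(fitness, "q2_loo")
  stopifnot(model_size >= 1, population >= 2, generations >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1)
  structure(list(model_size = as.integer(model_size),
                 population = as.integer(population),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate, seed = as.integer(seed),
                 fitness = fitness, patience = patience,
                 n_keep = as.integer(n_keep)),
            class = "ga_config")
}

# Q2_LOO fitness of a column subset; -Inf on singular designs
subset_fitness <- function(V, y, idx) {
  out <- tryCatch(q2_loo(V[, idx, drop = FALSE], y)$q2,
                  error = function(e) -Inf)
  if (!is.finite(out)) -Inf else out
}

rank_candidates <- function(V, y, subsets, fits, n_keep) {
  ord <- order(fits, decreasing = TRUE)
  ord <- ord[seq_len(min(n_keep, length(ord)))]
  cands <- lapply(ord, function(i) {
    idx <- subsets[[i]]
    model <- if (is.finite(fits[i])) {
      fit_ols(V[, idx, drop = FALSE], y)
    }
    list(descriptor_names = colnames(V)[idx],
         fitness_q2loo = unname(fits[i]), model = model)
  })
  structure(cands, class = "model_candidates")
}

#' @export
print.model_candidates <- function(x, ...) {
  cat("<model_candidates>\n")
  for (i in seq_along(x)) {
    cat(sprintf("  %2d. Q2loo = %7.4f  {%s}\n", i, x[[i]]$fitness_q2loo,
                paste(x[[i]]$descriptor_names, collapse = ", ")))
  }
  invisible(x)
}

#' GA search for the best fixed-size descriptor subset
#'
#' @param X A `descriptor_matrix` or numeric matrix (rows aligned with `y`).
#' @param y Response vector (pIC50).
#' @param config A [ga_config()].
#' @return A ranked `model_candidates` list (best first); each candidate holds
#'   the descriptor names, its leave-one-out Q2 fitness and the OLS model
#'   refitted on all rows. Degenerate (singular) subsets get fitness `-Inf`
#'   and never outrank finite candidates.
#' @export
ga_mlr_search <- function(X, y, config) {
  stopifnot(inherits(config, "ga_config"))
  V <- as_descriptor_values(X)
  p <- ncol(V)
  k <- config$model_size
  if (k > p) stop("model_size exceeds the descriptor pool")
  stopifnot(nrow(V) == length(y))
  if (k == p) {
    f <- subset_fitness(V, y, seq_len(p))
    return(rank_candidates(V, y, list(seq_len(p)), f, 1L))
  }

  cache <- new.env(parent = emptyenv(), hash = TRUE)
  fit_of <- function(idx) {
    key <- paste(idx, collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    f <- subset_fitness(V, y, idx)
    cache[[key]] <- f
    f
  }

  withr::with_seed(config$seed, {
    pop <- replicate(config$population, sort(sample.int(p, k)),
                     simplify = FALSE)
    fits <- vapply(pop, fit_of, numeric(1))
    best <- max(fits)
    stale <- 0L
    for (gen in seq_len(config$generations)) {
      elite <- pop[[which.max(fits)]]
      nxt <- vector("list", config$population)
      nxt[[1L]] <- elite
      i <- 2L
      while (i <= config$population) {
        pa <- tournament(pop, fits, 2L)
        pb <- tournament(pop, fits, 2L)
        child <- if (stats::runif(1) < config$crossover_rate) {
          crossover_subset(pa, pb, k, p)
        } else pa
        if (stats::runif(1) < config$mutation_rate) {
          child <- mutate_subset(child, p)
        }
        nxt[[i]] <- sort(child)
        i <- i + 1L
      }
      pop <- nxt
      fits <- vapply(pop, fit_of, numeric(1))
      if (max(fits) > best + 1e-12) {
        best <- max(fits)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
    }
  })

  keys <- ls(cache)
  subsets <- lapply(strsplit(keys, ","), as.integer)
  fits <- vapply(keys, function(k2) cache[[k2]], numeric(1))
  rank_candidates(V, y, subsets, fits, config$n_keep)
}

tournament <- function(pop, fits, size) {
  idx <- sample.int(length(pop), size)
  pop[[idx[which.max(fits[idx])]]]
}

# uniform crossover on the union, repaired to cardinality k
crossover_subset <- function(a, b, k, p) {
  common <- intersect(a, b)
  rest <- setdiff(union(a, b), common)
  need <- k - length(common)
  if (need <= 0L) return(sample(union(a, b), k))
  if (length(rest) == 1L) return(c(common, rest))
  c(common, sample(rest, need))
}

mutate_subset <- function(idx, p) {
  out_pos <- sample.int(length(idx), 1L)
  pool <- setdiff(seq_len(p), idx)
  if (!length(pool)) return(idx)
  idx[out_pos] <- if (length(pool) == 1L) pool else sample(pool, 1L)
  idx
}

#' Exhaustive search over all fixed-size subsets
#'
#' Complete enumeration with the same ranking key as [ga_mlr_search()]; serves
#' as the optimality oracle for the GA on small pools.
#'
#' @inheritParams ga_mlr_search
#' @param model_size Subset size.
#' @param n_keep Number of ranked candidates to return.
#' @param max_subsets Enumeration budget (error above it).
#' @return A ranked `model_candidates` list.
#' @export
exhaustive_mlr_search <- function(X, y, model_size, n_keep = 10L,
                                  max_subsets = 1e6) {
  V <- as_descriptor_values(X)
  p <- ncol(V)
  stopifnot(model_size >= 1, model_size <= p, nrow(V) == length(y))
  if (choose(p, model_size) > max_subsets) {
    stop("combinatorial budget exceeded: choose(", p, ", ", model_size, ")")
  }
  combos <- utils::combn(p, model_size, simplify = FALSE)
  fits <- vapply(combos, function(idx) subset_fitness(V, y, idx), numeric(1))
  rank_candidates(V, y, combos, fits, n_keep)
}

#' Breaking-point analysis of model size
#'
#' Given the best Q2 achieved at each model size (consecutive sizes from 1),
#' finds the elbow: the smallest size after which the marginal Q2 gain drops
#' below `gain_ratio` times the preceding gain. If the curve never flattens the
#' maximum size is returned with a warning.
#'
#' @param q2_by_size Numeric vector of best Q2 values for sizes `1..K`
#'   (names, if present, must be the sizes).
#' @param gain_ratio Elbow threshold on the marginal-gain ratio, default 0.25.
#' @return A `breaking_point` list with `size` (the chosen model size) and
#'   `table` (size, q2, gain) for plotting.
#' @export
breaking_point <- function(q2_by_size, gain_ratio = 0.25) {
  q2 <- as.numeric(q2_by_size)
  K <- length(q2)
  if (K < 3L) stop("need at least 3 consecutive model sizes")
  if (!is.null(names(q2_by_size))) {
    sizes <- as.integer(names(q2_by_size))
    if (any(sizes != seq_len(K))) stop("sizes must be consecutive from 1")
  }
  gains <- diff(q2)
  if (any(gains < 0)) {
    warning("Q2 decreases between some sizes (gains: ",
            paste(sprintf("%.3f", gains), collapse = ", "), ")")
  }
  size <- NA_integer_
  for (j in 2:(K - 1L)) {
    if (gains[j] < gain_ratio * max(gains[j - 1L], 0)) {
      size <- j
      break
    }
  }
  if (is.na(size)) {
    warning("no elbow: Q2 keeps improving; returning the largest size")
    size <- K
  }
  structure(list(size = size,
                 table = data.frame(size = seq_len(K), q2 = q2,
                                    gain = c(NA, gains))),
            class = "breaking_point")
}

#' @export
print.breaking_point <- function(x, ...) {
  cat("<breaking_point>  optimal model size:", x$size, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
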