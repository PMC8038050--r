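# Independent oracle implementations used to cross-check the package:
# deliberately written with different algorithms/code paths than R/.

# --- dense-grid point-rejection SASA on a Saff-Kuijlaars spiral ---
# (independent of the package's Fibonacci lattice; own radii table)
oracle_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

spiral_points <- function(N) {
  k <- seq_len(N)
  h <- -1 + 2 * (k - 1) / (N - 1)
  theta <- acos(pmin(1, pmax(-1, h)))
  step <- 3.6 / sqrt(N * pmax(1e-12, 1 - h^2))
  step[c(1, N)] <- 0
  phi <- cumsum(step) %% (2 * pi)
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

dense_sasa <- function(record, probe = 1.4, n_pts = 100000L) {
  a <- record$atoms
  centers <- as.matrix(a[, c("x", "y", "z")])
  r <- unname(oracle_radii[a$element]) + probe
  n <- nrow(a)
  pts0 <- spiral_points(n_pts)
  sapply(seq_len(n), function(i) {
    pts <- sweep(pts0 * r[i], 2, centers[i, ], `+`)
    free <- rep(TRUE, n_pts)
    for (j in setdiff(seq_len(n), i)) {
      d2 <- (pts[, 1] - centers[j, 1])^2 + (pts[, 2] - centers[j, 2])^2 +
        (pts[, 3] - centers[j, 3])^2
      free <- free & d2 >= r[j]^2
    }
    4 * pi * r[i]^2 * mean(free)
  })
}

# --- brute-force frequency descriptors: explicit BFS / double loops ---
oracle_adjacency <- function(record) {
  n <- nrow(record$atoms)
  adj <- vector("list", n)
  for (b in seq_len(nrow(record$bonds))) {
    i <- record$bonds$from[b]; j <- record$bonds$to[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

oracle_bfs_dist <- function(adj, start) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[start] <- 0
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (d[w] == Inf) {
        d[w] <- d[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

# count H atoms at exactly k bonds from the nearest center atom
oracle_h_freq_bonds <- function(record, center_idx, k) {
  adj <- oracle_adjacency(record)
  hs <- which(record$atoms$element == "H")
  cnt <- 0L
  for (h in hs) {
    d <- oracle_bfs_dist(adj, h)
    dc <- d[center_idx]
    if (length(dc) && min(dc) == k) cnt <- cnt + 1L
  }
  cnt
}

# count H atoms whose nearest center lies in [lo, hi) Angstrom
oracle_h_freq_space <- function(record, center_idx, lo, hi) {
  a <- record$atoms
  hs <- which(a$element == "H")
  cnt <- 0L
  for (h in hs) {
    dmin <- Inf
    for (c in center_idx) {
      d <- sqrt((a$x[h] - a$x[c])^2 + (a$y[h] - a$y[c])^2 +
                  (a$z[h] - a$z[c])^2)
      dmin <- min(dmin, d)
    }
    if (dmin >= lo && dmin < hi) cnt <- cnt + 1L
  }
  cnt
}

# --- explicit leave-one-out refit via lm() ---
oracle_loo_press <- function(X, y) {
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    df <- as.data.frame(X[-i, , drop = FALSE])
    fit <- stats::lm(y[-i] ~ ., data = df)
    pred[i] <- stats::predict(fit, newdata = as.data.frame(X)[i, , drop = FALSE])
  }
  list(pred = pred, press = sum((y - pred)^2),
       q2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2))
}

# --- origin-regression external criteria via lm(y ~ 0 + x) ---
oracle_gt <- function(y_obs, y_pred) {
  k <- unname(stats::coef(stats::lm(y_obs ~ 0 + y_pred)))
  kp <- unname(stats::coef(stats::lm(y_pred ~ 0 + y_obs)))
  ro2 <- 1 - sum(stats::resid(stats::lm(y_obs ~ 0 + y_pred))^2) /
    sum((y_obs - mean(y_obs))^2)
  rpo2 <- 1 - sum(stats::resid(stats::lm(y_pred ~ 0 + y_obs))^2) /
    sum((y_pred - mean(y_pred))^2)
  r2 <- stats::cor(y_obs, y_pred)^2
  list(k = k, k_prime = kp, ro2 = ro2, r_prime_o2 = rpo2,
       r2m = r2 * (1 - sqrt(abs(r2 - ro2))))
}

# --- shared fixtures (prepared once per test run) ---
has_obabel <- nzchar(Sys.which("obabel")) &&
  (nzchar(Sys.which("python")) || nzchar(Sys.which("python3")))

toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- toy_molecules(prepare = has_obabel)
    cache
  }
})

# 3D-prepared published example compounds with their descriptor pool
table1_pool <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toys <- toy_fixture()
      mols <- suppressMessages(prepare_molecules(
        toys[grep("^mol", names(toys))]))
      cache <<- list(
        mols = mols,
        pool = generate_descriptor_pool(mols),
        y = vapply(mols, function(m) m$pic50, numeric(1)))
    }
    cache
  }
})

# rigid-body rotation + translation of a prepared record
rotate_record <- function(record, angle = 0.7, shift = c(1, -2, 3)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(record$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, `+`)
  record$atoms[, c("x", "y", "z")] <- xyz
  record
}

# permute atom order (and remap bonds) of a record
permute_record <- function(record, perm) {
  inv <- order(perm)
  rec <- record
  rec$atoms <- record$atoms[perm, , drop = FALSE]
  rownames(rec$atoms) <- NULL
  rec$bonds$from <- inv[record$bonds$from]
  rec$bonds$to <- inv[record$bonds$to]
  rec
}
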