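#' Specification for a synthetic descriptor dataset
#'
#' Describes a planted-signal descriptor matrix emulating the statistical
#' structure a pruned QSAR pool presents to model selection: informative
#' columns carrying a sparse linear signal, independent noise columns, plus
#' the degeneracies objective feature selection must remove (constant,
#' near-constant and collinear columns).
#'
#' @param n_molecules Number of rows.
#' @param n_descriptors Number of regular (non-degenerate) columns; the
#'   planted subset indexes into these.
#' @param n_constant,n_near_constant,n_collinear_pairs Degenerate columns
#'   appended after the regular block.
#' @param planted_subset Indices (within the regular block) of the columns
#'   that carry the signal.
#' @param beta Coefficients of the planted columns (same length).
#' @param noise_sigma Gaussian noise standard deviation on the response.
#' @param near_const_frac Modal fraction of the near-constant columns
#'   (default 0.96, i.e. removed at the 0.95 threshold).
#' @param collinear_jitter Noise added to collinear copies (0 gives exact
#'   scalar multiples, |R| = 1).
#' @param seed RNG seed; generation is reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_molecules = 100L, n_descriptors = 20L,
                           n_constant = 0L, n_near_constant = 0L,
                           n_collinear_pairs = 0L,
                           planted_subset = c(3L, 7L, 11L),
                           beta = c(1, -1, 0.5), noise_sigma = 0.1,
                           near_const_frac = 0.96, collinear_jitter = 0,
                           seed = 1L) {
  stopifnot(length(planted_subset) == length(beta),
            all(planted_subset >= 1),
            all(planted_subset <= n_descriptors),
            !anyDuplicated(planted_subset),
            noise_sigma >= 0, n_molecules >= 4)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_descriptors = as.integer(n_descriptors),
                 n_constant = as.integer(n_constant),
                 n_near_constant = as.integer(n_near_constant),
                 n_collinear_pairs = as.integer(n_collinear_pairs),
                 planted_subset = as.integer(planted_subset), beta = beta,
                 noise_sigma = noise_sigma,
                 near_const_frac = near_const_frac,
                 collinear_jitter = collinear_jitter,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a planted-signal descriptor dataset
#'
#' Regular columns are standard normal; the response is
#' `y = X[, planted] %*% beta + N(0, sigma^2)`. Degenerate columns are
#' appended after the regular block: constants (`const<i>`), near-constants
#' (`nearconst<i>`, modal value in `near_const_frac` of rows), and collinear
#' copies (`collin<i>`, a scalar multiple of a regular column plus optional
#' jitter). Ground truth is returned so selection accuracy and coefficient
#' recovery can be scored without re-derivation.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `X` (a `descriptor_matrix`), `y`, and `truth` (planted
#'   column names and indices, `beta`, names of each degenerate column and,
#'   for collinear copies, their source column).
#' @export
gen_descriptor_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_molecules
  m <- spec$n_descriptors
  withr::with_seed(spec$seed, {
    X <- matrix(stats::rnorm(n * m), n, m,
                dimnames = list(as.character(seq_len(n)),
                                sprintf("D%03d", seq_len(m))))
    fam <- rep("regular", m)
    if (spec$n_constant) {
      C <- matrix(3.0, n, spec$n_constant,
                  dimnames = list(NULL, paste0("const", seq_len(spec$n_constant))))
      X <- cbind(X, C)
      fam <- c(fam, rep("constant", spec$n_constant))
    }
    if (spec$n_near_constant) {
      n_flip <- max(1L, floor(n * (1 - spec$near_const_frac)))
      NC <- sapply(seq_len(spec$n_near_constant), function(j) {
        v <- rep(0, n)
        v[sample.int(n, n_flip)] <- 1
        v
      })
      colnames(NC) <- paste0("nearconst", seq_len(spec$n_near_constant))
      X <- cbind(X, NC)
      fam <- c(fam, rep("near_constant", spec$n_near_constant))
    }
    collin_src <- character(0)
    if (spec$n_collinear_pairs) {
      src <- sample.int(m, spec$n_collinear_pairs, replace = TRUE)
      CP <- sapply(seq_len(spec$n_collinear_pairs), function(j) {
        2 * X[, src[j]] + spec$collinear_jitter * stats::rnorm(n)
      })
      colnames(CP) <- paste0("collin", seq_len(spec$n_collinear_pairs))
      collin_src <- sprintf("D%03d", src)
      X <- cbind(X, CP)
      fam <- c(fam, rep("collinear", spec$n_collinear_pairs))
    }
    y <- drop(X[, spec$planted_subset, drop = FALSE] %*% spec$beta) +
      stats::rnorm(n, sd = spec$noise_sigma)
  })
  prov <- data.frame(name = colnames(X), family = fam,
                     params = "", stringsAsFactors = FALSE)
  prov$params[match(collin_src, prov$name)] <- ""
  truth <- list(planted_names = sprintf("D%03d", spec$planted_subset),
                planted_idx = spec$planted_subset, beta = spec$beta,
                noise_sigma = spec$noise_sigma,
                constant = grep("^const", colnames(X), value = TRUE),
                near_constant = grep("^nearconst", colnames(X), value = TRUE),
                collinear = grep("^collin", colnames(X), value = TRUE),
                collinear_source = collin_src)
  list(X = descriptor_matrix(X, prov), y = y, truth = truth)
}

#' Hand-enumerable toy molecules
#'
#' Builds the small fixture set used to pin descriptor semantics: 3D-prepared
#' micro-molecules (methane, water, ammonia, cyclohexane, pyrrole,
#' n-propylamine) with hand-derived expected frequency-descriptor counts
#' attached as the `expected` attribute of each record, a hand-built linear
#' chain Cl-C-C-H probing the three-bond lipophilic count, and the ten
#' published example compounds (five most and five least active) with their
#' IC50/pIC50 values, loaded 2D from the packaged table.
#'
#' @param prepare Prepare the micro-molecules in 3D via OpenBabel (default
#'   TRUE; requires `obabel` on the PATH).
#' @return Named list of `molecule_record`s; the published examples are under
#'   names `mol<id>`.
#' @export
toy_molecules <- function(prepare = TRUE) {
  micro <- list(
    methane = list(smiles = "C",
                   expected = list(f_nh_4b = 0L, f_ring_nh_2a = 0L,
                                   f_lipo_h_3b = 0L)),
    water = list(smiles = "O",
                 expected = list(f_nh_4b = 0L, f_ring_nh_2a = 0L,
                                 f_lipo_h_3b = 0L)),
    ammonia = list(smiles = "N",
                   expected = list(f_nh_4b = 0L, f_ring_nh_2a = 0L,
                                   f_lipo_h_3b = 0L)),
    cyclohexane = list(smiles = "C1CCCCC1",
                       expected = list(f_nh_4b = 0L, f_ring_nh_2a = 0L,
                                       f_lipo_h_3b = 0L)),
    pyrrole = list(smiles = "c1cc[nH]c1",
                   # the N-H hydrogen sits ~1.01 A from the ring nitrogen;
                   # ring C-H hydrogens are beyond 2 A
                   expected = list(f_ring_nh_2a = 1L, f_nh_4b = 0L)),
    n_propylamine = list(smiles = "CCCN",
                         # the three methyl hydrogens are exactly 4 bonds
                         # from the nitrogen (N-C1-C2-C3-H)
                         expected = list(f_nh_4b = 3L, f_ring_nh_2a = 0L)))
  out <- list()
  for (nm in names(micro)) {
    rec <- molecule_record(nm, smiles = micro[[nm]]$smiles)
    if (prepare) rec <- prepare_3d(rec)
    attr(rec, "expected") <- micro[[nm]]$expected
    out[[nm]] <- rec
  }

  # hand-built linear chain Cl-O-O-H: the H is exactly 3 bonds from the only
  # lipophilic atom (Cl), so flipoH3B = 1 by a single path of length 3
  chain <- molecule_record(
    "chain_LXYH",
    atoms = data.frame(element = c("Cl", "O", "O", "H"),
                       x = c(0, 1.8, 3.2, 4.2), y = 0, z = 0,
                       charge = c(-0.1, 0.05, 0.05, 0.0)),
    bonds = data.frame(from = 1:3, to = 2:4, order = 1))
  attr(chain, "expected") <- list(f_lipo_h_3b = 1L, f_nh_4b = 0L)
  out$chain_LXYH <- chain

  tab <- utils::read.csv(system.file("extdata", "nmt_table1.csv",
                                     package = "nmtqsar"),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    rec <- molecule_record(paste0("mol", tab$id[i]), smiles = tab$smiles[i],
                           ic50 = tab$ic50_um[i])
    attr(rec, "expected") <- list(pic50 = tab$pic50[i])
    out[[paste0("mol", tab$id[i])]] <- rec
  }
  out
}
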