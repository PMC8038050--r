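#' Charge-window solvent-accessible surface area (all_HASA2)
#'
#' Sum of per-atom SASA over all atoms whose MMFF94 partial charge lies in
#' `[charge_lo, charge_hi]`. With the default window `[+0.10, +0.20]` this is
#' the published descriptor `all_HASA2`, which tracks the exposed surface of
#' mildly positively charged (hydrophobic-facing) atoms.
#'
#' @param record A prepared `molecule_record` with partial charges.
#' @param sasa Per-atom SASA vector from [per_atom_sasa()].
#' @param charge_lo,charge_hi Inclusive charge window bounds (elementary
#'   charges).
#' @return Non-negative surface area in Angstrom^2.
#' @export
all_hasa2 <- function(record, sasa, charge_lo = 0.10, charge_hi = 0.20) {
  q <- record$atoms$charge
  stopifnot(length(sasa) == length(q))
  if (anyNA(q)) stop("record ", record$id, " has no partial charges")
  sum(sasa[q >= charge_lo & q <= charge_hi])
}

#' Carbon surface area (C_AbSA)
#'
#' Sum of per-atom SASA over carbon atoms: the surface area a molecule exposes
#' through its carbon skeleton. Always bounded above by the molecular SASA.
#'
#' @inheritParams all_hasa2
#' @param element Element symbol to sum over (default `"C"`).
#' @return Non-negative surface area in Angstrom^2.
#' @export
c_absa <- function(record, sasa, element = "C") {
  stopifnot(length(sasa) == nrow(record$atoms))
  sum(sasa[record$atoms$element == element])
}

#' Lipophilic atom typing
#'
#' Standard pharmacophoric lipophilic set: carbon atoms not bonded to nitrogen,
#' oxygen, or any formally charged atom; halogens (F, Cl, Br, I); and divalent
#' sulfur.
#'
#' @param record A `molecule_record` with a bond table.
#' @return Logical vector flagging lipophilic atoms.
#' @export
lipophilic_atoms <- function(record) {
  a <- record$atoms
  n <- nrow(a)
  lipo <- rep(FALSE, n)
  lipo[a$element %in% c("F", "Cl", "Br", "I")] <- TRUE
  deg <- integer(n)
  if (nrow(record$bonds)) {
    tab <- table(factor(c(record$bonds$from, record$bonds$to), levels = 1:n))
    deg <- as.integer(tab)
  }
  lipo[a$element == "S" & deg == 2L] <- TRUE
  carb <- which(a$element == "C")
  if (length(carb) && nrow(record$bonds)) {
    b <- record$bonds
    polar <- a$element %in% c("N", "O") | a$formal_charge != 0
    bad <- unique(c(b$from[polar[b$to]], b$to[polar[b$from]]))
    lipo[setdiff(carb, bad)] <- TRUE
  } else {
    lipo[carb] <- TRUE
  }
  lipo
}

# Frequency of H atoms whose minimum graph distance (bond count) to any center
# atom equals k. "Exactly k bonds, and not nearer to any other center" is
# equivalent to the minimum over centers being k.
h_freq_bonds <- function(record, centers, k) {
  hs <- which(record$atoms$element == "H")
  centers <- which(centers)
  if (!length(hs) || !length(centers)) return(0L)
  d <- bond_distances(record)
  mins <- apply(d[hs, centers, drop = FALSE], 1L, min)
  sum(is.finite(mins) & mins == k)
}

# Frequency of H atoms whose minimum Euclidean distance to any center atom
# falls in [lo, hi) Angstrom (half-open bins avoid double counting at edges).
h_freq_space <- function(record, centers, lo, hi) {
  hs <- which(record$atoms$element == "H")
  centers <- which(centers)
  if (!length(hs) || !length(centers)) return(0L)
  d <- space_distances(record)
  mins <- apply(d[hs, centers, drop = FALSE], 1L, min)
  sum(mins >= lo & mins < hi)
}

#' fringNH2A: hydrogens 1-2 Angstrom from ring nitrogens
#'
#' Counts hydrogen atoms whose nearest ring nitrogen lies in the spatial shell
#' `[1.0, 2.0)` Angstrom. A hydrogen with any ring nitrogen nearer than 1.0
#' Angstrom is excluded, which the minimum-distance formulation enforces
#' automatically. A ring N-H hydrogen (approx. 1.01 Angstrom) qualifies.
#'
#' @param record A prepared `molecule_record`.
#' @return Non-negative integer count.
#' @export
f_ring_nh_2a <- function(record) {
  ringn <- record$atoms$element == "N" & record$atoms$in_ring
  h_freq_space(record, ringn, 1.0, 2.0)
}

#' flipoH3B: hydrogens exactly three bonds from lipophilic atoms
#'
#' Counts hydrogen atoms whose shortest topological path to the nearest
#' lipophilic atom (see [lipophilic_atoms()]) is exactly 3 bonds; hydrogens at
#' 1 or 2 bonds from any lipophilic atom are thereby excluded.
#'
#' @inheritParams f_ring_nh_2a
#' @param lipo Optional logical vector overriding the lipophilic typing.
#' @return Non-negative integer count.
#' @export
f_lipo_h_3b <- function(record, lipo = NULL) {
  if (is.null(lipo)) lipo <- lipophilic_atoms(record)
  h_freq_bonds(record, lipo, 3L)
}

#' fNH4B: hydrogens exactly four bonds from nitrogen
#'
#' Counts hydrogen atoms whose shortest topological path to the nearest
#' nitrogen atom is exactly 4 bonds; hydrogens with any nitrogen at fewer than
#' 4 bonds are excluded.
#'
#' @inheritParams f_ring_nh_2a
#' @return Non-negative integer count.
#' @export
f_nh_4b <- function(record) {
  h_freq_bonds(record, record$atoms$element == "N", 4L)
}

#' Assemble a descriptor matrix
#'
#' @param values Numeric matrix, molecules x descriptors, with dimnames.
#' @param provenance Data frame with one row per column: `name`, `family`,
#'   `params`.
#' @return A `descriptor_matrix` object.
#' @export
descriptor_matrix <- function(values, provenance = NULL) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (anyNA(values)) stop("descriptor matrix contains missing values")
  if (is.null(provenance)) {
    provenance <- data.frame(name = colnames(values), family = "unknown",
                             params = "", stringsAsFactors = FALSE)
  }
  stopifnot(nrow(provenance) == ncol(values))
  structure(list(molecule_ids = rownames(values), names = colnames(values),
                 values = values, provenance = provenance),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix>  %d molecules x %d descriptors\n",
              nrow(x$values), ncol(x$values)))
  fams <- table(x$provenance$family)
  cat("  families:", paste(sprintf("%s(%d)", names(fams), fams),
                           collapse = ", "), "\n")
  invisible(x)
}

# accept a descriptor_matrix, matrix or data.frame wherever a plain numeric
# matrix is needed
as_descriptor_values <- function(X) {
  if (inherits(X, "descriptor_matrix")) return(X$values)
  if (is.data.frame(X)) return(as.matrix(X))
  stopifnot(is.matrix(X))
  X
}

#' Generate a descriptor pool
#'
#' Computes a configurable pool of 3D descriptors for prepared molecules. The
#' families and their column-name grammar:
#' \describe{
#'   \item{named}{the five published model descriptors `all_HASA2`, `C_AbSA`,
#'     `fNH4B`, `fringNH2A`, `flipoH3B`.}
#'   \item{chargebin}{`qSASA_<lo>_<hi>`: SASA summed over atoms with partial
#'     charge in `[lo, hi)`, windows of width 0.10 spanning `[-0.5, +0.5]`.}
#'   \item{bondfreq}{`f<class>H<k>B`: number of H atoms whose nearest atom of
#'     the class (element symbol or `lipo`) is exactly `k` bonds away.}
#'   \item{distfreq}{`f<class>H<d>A`: number of H atoms whose nearest atom of
#'     the class (`N`, `ringN`, `O`, `lipo`) lies in the spatial shell
#'     `[d-1, d)` Angstrom.}
#'   \item{elemsasa}{`<El>_AbSA`: SASA summed over atoms of one element, plus
#'     `total_SASA`.}
#'   \item{counts}{`n_<El>` atom counts, plus `n_atoms` and `n_heavy`.}
#' }
#' Duplicate column names across families (the named descriptors re-appear in
#' their parametric families) are kept once, first family wins.
#'
#' @param records List of prepared `molecule_record`s.
#' @param families Character vector of family names to include.
#' @param sasa_cfg A [sasa_config()].
#' @param bond_k Bond shells for `bondfreq` (default 1:8).
#' @param dist_shells Upper edges of 1-Angstrom spatial shells for `distfreq`
#'   (default 1:5).
#' @param elements Element symbols for element-parameterized families.
#' @return A `descriptor_matrix`. Molecules for which descriptor calculation
#'   fails (e.g. missing 3D) are dropped with a message.
#' @export
generate_descriptor_pool <- function(records,
                                     families = c("named", "chargebin",
                                                  "bondfreq", "distfreq",
                                                  "elemsasa", "counts"),
                                     sasa_cfg = sasa_config(),
                                     bond_k = 1:8,
                                     dist_shells = 1:5,
                                     elements = c("C", "N", "O", "S", "F",
                                                  "Cl", "Br", "H")) {
  families <- match.arg(families, several.ok = TRUE)
  rows <- lapply(records, function(r) {
    tryCatch(descriptor_row(r, families, sasa_cfg, bond_k, dist_shells,
                            elements),
             error = function(e) {
               message("dropping molecule ", r$id, ": ", conditionMessage(e))
               NULL
             })
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("descriptor calculation failed for every molecule")
  rows <- rows[keep]
  ids <- unname(vapply(records[keep], `[[`, character(1), "id"))
  nm <- names(rows[[1L]])
  vals <- do.call(rbind, lapply(rows, function(r) unname(r[nm])))
  dimnames(vals) <- list(ids, nm)
  fam <- attr(rows[[1L]], "family")[nm]
  par <- attr(rows[[1L]], "params")[nm]
  descriptor_matrix(vals, data.frame(name = nm, family = unname(fam),
                                     params = unname(par),
                                     stringsAsFactors = FALSE))
}

descriptor_row <- function(record, families, sasa_cfg, bond_k, dist_shells,
                           elements) {
  vals <- numeric(0)
  fam <- character(0)
  par <- character(0)
  add <- function(v, name, family, params = "") {
    if (name %in% names(vals)) return(invisible())
    vals[[name]] <<- v
    fam[[name]] <<- family
    par[[name]] <<- params
  }
  need_sasa <- any(c("named", "chargebin", "elemsasa") %in% families)
  sasa <- if (need_sasa) per_atom_sasa(record, sasa_cfg)
  lipo <- lipophilic_atoms(record)
  a <- record$atoms
  for (f in families) {
    switch(f,
      named = {
        add(all_hasa2(record, sasa), "all_HASA2", "named", "q in [0.10,0.20]")
        add(c_absa(record, sasa), "C_AbSA", "named", "element C")
        add(f_nh_4b(record), "fNH4B", "named", "N, 4 bonds")
        add(f_ring_nh_2a(record), "fringNH2A", "named", "ring N, [1,2) A")
        add(f_lipo_h_3b(record, lipo), "flipoH3B", "named", "lipo, 3 bonds")
      },
      chargebin = {
        edges <- seq(-0.5, 0.5, by = 0.1)
        for (i in seq_len(length(edges) - 1L)) {
          lo <- edges[i]; hi <- edges[i + 1L]
          v <- sum(sasa[!is.na(a$charge) & a$charge >= lo & a$charge < hi])
          add(v, sprintf("qSASA_%+.1f_%+.1f", lo, hi), "chargebin",
              sprintf("q in [%.1f,%.1f)", lo, hi))
        }
      },
      bondfreq = {
        classes <- c(stats::setNames(as.list(elements[elements != "H"]),
                                     elements[elements != "H"]),
                     list(lipo = NA))
        for (cl in names(classes)) {
          centers <- if (cl == "lipo") lipo else a$element == cl
          for (k in bond_k) {
            add(h_freq_bonds(record, centers, k),
                sprintf("f%sH%dB", cl, k), "bondfreq",
                sprintf("class %s, %d bonds", cl, k))
          }
        }
      },
      distfreq = {
        for (cl in c("N", "ringN", "O", "lipo")) {
          centers <- switch(cl,
                            N = a$element == "N",
                            ringN = a$element == "N" & a$in_ring,
                            O = a$element == "O",
                            lipo = lipo)
          for (d in dist_shells) {
            add(h_freq_space(record, centers, d - 1, d),
                sprintf("f%sH%dA", cl, d), "distfreq",
                sprintf("class %s, [%d,%d) A", cl, d - 1, d))
          }
        }
      },
      elemsasa = {
        for (el in elements) {
          add(c_absa(record, sasa, el), paste0(el, "_AbSA"), "elemsasa",
              paste("element", el))
        }
        add(sum(sasa), "total_SASA", "elemsasa", "all atoms")
      },
      counts = {
        for (el in elements) {
          add(sum(a$element == el), paste0("n_", el), "counts",
              paste("element", el))
        }
        add(nrow(a), "n_atoms", "counts", "")
        add(sum(a$element != "H"), "n_heavy", "counts", "")
      })
  }
  structure(vals, family = fam, params = par)
}
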