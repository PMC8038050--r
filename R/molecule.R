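#' Construct a molecule record
#'
#' The central container of the package: one compound with identifiers,
#' activity, and (once prepared) a charged 3D conformer. Atoms are stored as a
#' data frame with one row per atom (element symbol, Cartesian coordinates in
#' Angstrom, MMFF94 partial charge in elementary-charge units, ring-membership
#' flag, formal charge); bonds as a data frame of atom-index pairs with bond
#' order. Records can be built by hand (e.g. toy graphs for descriptor tests)
#' or by [read_molecules()] / [prepare_3d()].
#'
#' @param id Identifier string (unique within a dataset).
#' @param smiles SMILES string, or `NA` for hand-built records.
#' @param ic50 IC50 in micromolar, or `NA` when unknown (prediction-only).
#' @param atoms Data frame with columns `element`, `x`, `y`, `z`, `charge`
#'   (partial charge), and optionally `in_ring` (logical) and `formal_charge`.
#'   Coordinates and charges may be `NA` before 3D preparation.
#' @param bonds Data frame with columns `from`, `to` (1-based atom indices) and
#'   `order` (numeric; aromatic bonds may carry 1.5).
#' @param pic50 Optional pIC50; computed from `ic50` when omitted.
#'
#' @return An object of class `molecule_record`.
#' @details `in_ring` is derived from the bond graph when not supplied: an atom
#'   is in a ring iff it is incident to a bond that is not a bridge of the
#'   molecular graph. Partial charges, when present, must sum to the net formal
#'   charge within 1e-3; a violation raises an error since it indicates a
#'   corrupted charge assignment.
#' @export
molecule_record <- function(id, smiles = NA_character_, ic50 = NA_real_,
                            atoms = NULL, bonds = NULL, pic50 = NULL) {
  stopifnot(length(id) == 1L, nzchar(as.character(id)))
  if (!is.na(ic50) && ic50 <= 0) stop("ic50 must be positive (uM)")
  if (is.null(pic50)) {
    pic50 <- if (is.na(ic50)) NA_real_ else pic50_from_ic50(ic50)
  }
  if (is.null(atoms)) {
    atoms <- data.frame(element = character(), x = numeric(), y = numeric(),
                        z = numeric(), charge = numeric(),
                        in_ring = logical(), formal_charge = numeric())
  }
  atoms <- as.data.frame(atoms)
  need <- c("element", "x", "y", "z", "charge")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0
  if (is.null(bonds)) {
    bonds <- data.frame(from = integer(), to = integer(), order = numeric())
  }
  bonds <- as.data.frame(bonds)
  if (nrow(bonds)) {
    if (any(bonds$from < 1 | bonds$from > nrow(atoms) |
            bonds$to < 1 | bonds$to > nrow(atoms))) {
      stop("bond references an invalid atom index")
    }
  }
  if (is.null(atoms$in_ring)) atoms$in_ring <- ring_membership(atoms, bonds)
  chg <- atoms$charge
  if (nrow(atoms) && !anyNA(chg)) {
    net <- sum(atoms$formal_charge)
    if (abs(sum(chg) - net) > 1e-3) {
      stop(sprintf("partial charges sum to %.4f but net formal charge is %g",
                   sum(chg), net))
    }
  }
  structure(
    list(id = as.character(id), smiles = smiles, ic50 = ic50, pic50 = pic50,
         atoms = atoms, bonds = bonds, flags = list(prepared = n3d(atoms))),
    class = "molecule_record"
  )
}

n3d <- function(atoms) nrow(atoms) > 0 && !anyNA(atoms$x)

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record %s>  atoms: %d  bonds: %d  prepared: %s\n",
              x$id, nrow(x$atoms), nrow(x$bonds), x$flags$prepared))
  if (!is.na(x$ic50))
    cat(sprintf("  IC50 = %g uM   pIC50 = %.3f\n", x$ic50, x$pic50))
  if (!is.na(x$smiles)) cat("  SMILES:", x$smiles, "\n")
  invisible(x)
}

# molecular graph as igraph object (atoms as vertices 1..n)
mol_graph <- function(record) {
  n <- nrow(record$atoms)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(record$bonds)) {
    g <- igraph::add_edges(g, rbind(record$bonds$from, record$bonds$to))
  }
  g
}

# in-ring flag: atom incident to any non-bridge edge lies on a cycle
ring_membership <- function(atoms, bonds) {
  n <- nrow(atoms)
  if (!n || !nrow(bonds)) return(rep(FALSE, n))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(bonds$from, bonds$to))
  br <- igraph::bridges(g)
  cyc <- setdiff(seq_len(igraph::ecount(g)), as.integer(br))
  flag <- rep(FALSE, n)
  if (length(cyc)) {
    ends <- igraph::ends(g, cyc)
    flag[unique(as.integer(ends))] <- TRUE
  }
  flag
}

# shortest topological path lengths (bond counts) between all atoms
bond_distances <- function(record) {
  igraph::distances(mol_graph(record))
}

# Euclidean distance matrix between atoms, Angstrom
space_distances <- function(record) {
  if (!n3d(record$atoms)) stop("record ", record$id, " has no 3D coordinates")
  as.matrix(stats::dist(record$atoms[, c("x", "y", "z")]))
}
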