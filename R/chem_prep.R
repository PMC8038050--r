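#' Convert IC50 (micromolar) to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50, so an IC50 of
#' 1 uM maps to 6 and a 2 nM inhibitor to 8.699. Computed at full precision;
#' round only for display.
#'
#' @param ic50_um IC50 value(s) in micromolar; must be positive.
#' @return pIC50 value(s), numeric.
#' @examples
#' pic50_from_ic50(1)      # 6
#' pic50_from_ic50(0.002)  # 8.699 (most active compound of the dataset)
#' @export
pic50_from_ic50 <- function(ic50_um) {
  if (!is.numeric(ic50_um) || any(!is.finite(ic50_um)) || any(ic50_um <= 0)) {
    stop("ic50_um must be positive and finite (micromolar)")
  }
  -log10(ic50_um * 1e-6)
}

#' Inverse of [pic50_from_ic50()]
#' @param pic50 pIC50 value(s).
#' @return IC50 in micromolar.
#' @export
ic50_from_pic50 <- function(pic50) 10^(6 - pic50)

#' 3D preparation settings
#'
#' Settings for conformer generation: a distance-geometry embedding seeded by
#' `embed_seed`, then MMFF94 steepest-descent optimization with at most
#' `max_steps` steps (the workflow default is 1000) and MMFF94 partial
#' charges. The whole chain is deterministic for a fixed seed.
#'
#' @param force_field Only `"MMFF94"` is supported.
#' @param optimizer Only `"steepest_descent"` is supported.
#' @param max_steps Maximum optimization steps, >= 1.
#' @param embed_seed Integer recorded with the conformer.
#' @return A `prep_config` list.
#' @export
prep_config <- function(force_field = "MMFF94", optimizer = "steepest_descent",
                        max_steps = 1000L, embed_seed = 42L) {
  force_field <- match.arg(force_field, "MMFF94")
  optimizer <- match.arg(optimizer, "steepest_descent")
  stopifnot(is.numeric(max_steps), max_steps >= 1)
  structure(list(force_field = force_field, optimizer = optimizer,
                 max_steps = as.integer(max_steps),
                 embed_seed = as.integer(embed_seed)),
            class = "prep_config")
}

obabel_available <- function() nzchar(Sys.which("obabel"))

python_binary <- function() {
  for (cand in c("python", "python3")) {
    if (nzchar(Sys.which(cand))) return(cand)
  }
  stop("no python interpreter found on PATH (needed for 3D embedding)")
}

# run the shipped RDKit embedding helper; returns TRUE on success
run_embed <- function(smiles, out_sdf, seed) {
  script <- system.file("python", "embed3d.py", package = "nmtqsar")
  status <- suppressWarnings(system2(python_binary(),
                                     c(shQuote(script), shQuote(smiles),
                                       shQuote(out_sdf), seed),
                                     stdout = FALSE, stderr = FALSE))
  if (status == 3L) return(structure(FALSE, reason = "unparsable SMILES"))
  if (status != 0L || !file.exists(out_sdf)) {
    return(structure(FALSE, reason = "3D embedding failed"))
  }
  TRUE
}

run_obabel <- function(args) {
  if (!obabel_available()) stop("obabel not found on PATH")
  out <- suppressWarnings(system2("obabel", args, stdout = TRUE, stderr = TRUE))
  invisible(out)
}

# Parse a TRIPOS mol2 file (possibly multi-molecule) into a list of
# list(name, atoms, bonds). Atom element is the atom-type field up to the dot.
parse_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(starts)) return(list())
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(i) {
    blk <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    name <- trimws(blk[2L])
    a0 <- grep("^@<TRIPOS>ATOM", blk)[1L]
    b0 <- grep("^@<TRIPOS>BOND", blk)[1L]
    sec_ends <- c(grep("^@<TRIPOS>", blk), length(blk) + 1L)
    nxt <- function(s) min(sec_ends[sec_ends > s]) - 1L
    atom_lines <- blk[(a0 + 1L):nxt(a0)]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    af <- do.call(rbind, strsplit(trimws(atom_lines), "\\s+"))
    atoms <- data.frame(
      element = sub("\\..*$", "", af[, 6L]),
      x = as.numeric(af[, 3L]), y = as.numeric(af[, 4L]),
      z = as.numeric(af[, 5L]),
      charge = if (ncol(af) >= 9L) as.numeric(af[, 9L]) else NA_real_
    )
    bonds <- data.frame(from = integer(), to = integer(), order = numeric())
    if (!is.na(b0)) {
      bond_lines <- blk[(b0 + 1L):nxt(b0)]
      bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
      if (length(bond_lines)) {
        bf <- do.call(rbind, strsplit(trimws(bond_lines), "\\s+"))
        ord <- bf[, 4L]
        ordn <- suppressWarnings(as.numeric(ord))
        ordn[ord == "ar"] <- 1.5
        ordn[ord == "am"] <- 1
        ordn[is.na(ordn)] <- 1
        bonds <- data.frame(from = as.integer(bf[, 2L]),
                            to = as.integer(bf[, 3L]), order = ordn)
      }
    }
    list(name = name, atoms = atoms, bonds = bonds)
  })
}

#' Write a molecule record as a TRIPOS mol2 file
#'
#' @param record A prepared `molecule_record` (3D coordinates present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mol2 <- function(record, path) {
  stopifnot(inherits(record, "molecule_record"))
  if (!n3d(record$atoms)) stop("record has no 3D coordinates")
  a <- record$atoms
  b <- record$bonds
  chg <- ifelse(is.na(a$charge), 0, a$charge)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@<TRIPOS>MOLECULE", record$id,
               sprintf(" %d %d 0 0 0", nrow(a), nrow(b)),
               "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM"), con)
  writeLines(sprintf("%7d %-4s %10.4f %10.4f %10.4f %-5s %3d UNL1 %10.4f",
                     seq_len(nrow(a)), a$element, a$x, a$y, a$z, a$element,
                     1L, chg), con)
  writeLines("@<TRIPOS>BOND", con)
  if (nrow(b)) {
    ord <- ifelse(b$order == 1.5, "ar", format(b$order, trim = TRUE))
    writeLines(sprintf("%6d %5d %5d %4s", seq_len(nrow(b)), b$from, b$to, ord),
               con)
  }
  invisible(path)
}

ob_energy <- function(mol2_path, ff = "MMFF94") {
  out <- suppressWarnings(system2("obenergy", c("-ff", ff, mol2_path),
                                  stdout = TRUE, stderr = FALSE))
  ln <- grep("TOTAL ENERGY", out, value = TRUE)
  if (!length(ln)) return(NA_real_)
  as.numeric(sub(".*=\\s*([-0-9.eE+]+).*", "\\1", ln[length(ln)]))
}

#' Generate a charged, optimized 3D conformer
#'
#' Embeds a single conformer from the record's SMILES with explicit hydrogens
#' (seeded distance-geometry embedding), keeps the largest fragment of
#' multi-fragment (salt) inputs, optimizes with the MMFF94 force field by
#' steepest descent (up to `config$max_steps` steps), and assigns MMFF94
#' partial charges. Preparing the same SMILES twice with the same
#' `embed_seed` yields identical coordinates.
#'
#' @param record A `molecule_record` with a valid SMILES.
#' @param config A [prep_config()].
#' @return The record with `atoms` (coordinates, charges, ring flags) and
#'   `bonds` populated. On embedding failure the record is returned with
#'   `flags$failed` set and a message describing the failure; downstream
#'   helpers drop such records.
#' @export
prepare_3d <- function(record, config = prep_config()) {
  stopifnot(inherits(record, "molecule_record"), inherits(config, "prep_config"))
  if (is.na(record$smiles)) stop("record ", record$id, " has no SMILES")
  fail <- function(msg) {
    record$flags$failed <- msg
    record$flags$prepared <- FALSE
    record
  }
  if (grepl("\\.", record$smiles)) {
    message("record ", record$id,
            ": multi-fragment SMILES; keeping largest fragment")
  }
  raw <- tempfile(fileext = ".sdf")
  opt <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(raw, opt)))
  ok <- run_embed(record$smiles, raw, config$embed_seed)
  if (!isTRUE(ok)) return(fail(attr(ok, "reason")))
  run_obabel(c(shQuote(raw), "-omol2", "-O", shQuote(opt),
               "--minimize", "--sd", "--steps", config$max_steps,
               "--ff", config$force_field,
               "--partialcharge", "mmff94"))
  if (!file.exists(opt) || !length(parse_mol2(opt))) {
    return(fail("force-field optimization failed"))
  }
  parsed <- parse_mol2(opt)[[1L]]
  if (anyNA(parsed$atoms$charge)) return(fail("charge assignment failed"))
  record$atoms <- parsed$atoms
  record$atoms$formal_charge <- 0
  record$atoms$in_ring <- ring_membership(parsed$atoms, parsed$bonds)
  record$bonds <- parsed$bonds
  # MMFF94 charges must balance to the net formal charge
  if (abs(sum(record$atoms$charge) - round(sum(record$atoms$charge))) > 1e-3) {
    return(fail("partial charges do not sum to an integer net charge"))
  }
  record$atoms$formal_charge[1L] <- round(sum(record$atoms$charge))
  record$flags$failed <- NULL
  record$flags$prepared <- TRUE
  record
}

#' Prepare a list of molecule records, dropping failures
#'
#' @param records List of `molecule_record`.
#' @param config A [prep_config()].
#' @return List of prepared records; embedding failures are dropped with a
#'   message naming the record.
#' @export
prepare_molecules <- function(records, config = prep_config()) {
  out <- lapply(records, prepare_3d, config = config)
  bad <- vapply(out, function(r) !is.null(r$flags$failed), logical(1))
  for (r in out[bad]) {
    message("dropping record ", r$id, ": ", r$flags$failed)
  }
  out[!bad]
}

# which SMILES strings does OpenBabel parse? returns logical vector
validate_smiles <- function(smiles, ids) {
  inp <- tempfile(fileext = ".smi")
  outp <- tempfile(fileext = ".smi")
  on.exit(unlink(c(inp, outp)))
  writeLines(paste(smiles, ids), inp)
  run_obabel(c(shQuote(inp), "-ocan", "-O", shQuote(outp)))
  if (!file.exists(outp)) return(rep(FALSE, length(smiles)))
  got <- readLines(outp, warn = FALSE)
  okids <- vapply(strsplit(got, "\\s+"), function(t) t[length(t)], character(1))
  ids %in% okids
}

#' Read a molecule table
#'
#' Supported formats: `csv` (header `id,smiles,ic50_um`; the activity column is
#' optional), `smi` (lines of `id <whitespace> SMILES`; lines in the
#' conventional `SMILES id` order are detected and swapped), and `sdf`
#' (pre-computed 3D coordinates, optional `IC50_uM` property; requires the
#' ChemmineR package and obabel for MMFF94 charge assignment).
#'
#' @param path Input file.
#' @param format One of `"csv"`, `"smi"`, `"sdf"`; guessed from the file
#'   extension by default.
#' @return List of `molecule_record`. Rows whose SMILES cannot be parsed are
#'   skipped with a warning naming the row; records without an activity carry
#'   `NA` pIC50 (prediction-only mode).
#' @export
read_molecules <- function(path, format = c("guess", "csv", "smi", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "guess") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", smi = "smi", sdf = "sdf",
                     stop("cannot guess format from extension: ", path))
  }
  recs <- switch(format,
                 csv = read_molecules_csv(path),
                 smi = read_molecules_smi(path),
                 sdf = read_molecules_sdf(path))
  if (!length(recs)) stop("empty dataset: ", path)
  ids <- vapply(recs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  recs
}

read_molecules_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty dataset: ", path)
  need <- c("id", "smiles")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("csv lacks columns: ", paste(miss, collapse = ", "))
  ic <- if ("ic50_um" %in% names(df)) as.numeric(df$ic50_um) else
    rep(NA_real_, nrow(df))
  build_smiles_records(as.character(df$id), df$smiles, ic)
}

read_molecules_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty dataset: ", path)
  tok <- strsplit(trimws(lines), "\\s+")
  ids <- vapply(tok, `[[`, character(1), 1L)
  smi <- vapply(tok, function(t) if (length(t) >= 2L) t[2L] else NA_character_,
                character(1))
  # documented layout is "id SMILES"; if the second column mostly fails to
  # parse while the first parses, the file uses the conventional "SMILES id"
  # order and the columns are swapped
  ok_spec <- validate_smiles(smi, as.character(seq_along(smi)))
  if (mean(ok_spec) < 0.5) {
    ok_alt <- validate_smiles(ids, as.character(seq_along(ids)))
    if (sum(ok_alt) > sum(ok_spec)) {
      tmp <- ids
      ids <- smi
      smi <- tmp
    }
  }
  build_smiles_records(ids, smi, rep(NA_real_, length(ids)))
}

build_smiles_records <- function(ids, smiles, ic50) {
  bad_row <- is.na(smiles) | !nzchar(smiles)
  if (!all(bad_row)) {
    ok <- validate_smiles(smiles[!bad_row], ids[!bad_row])
    bad_row[!bad_row] <- !ok
  }
  if (any(bad_row)) {
    warning("skipping unparsable SMILES at row(s): ",
            paste(which(bad_row), collapse = ", "), call. = FALSE)
  }
  mapply(function(i, s, c) molecule_record(i, smiles = s, ic50 = c),
         ids[!bad_row], smiles[!bad_row], ic50[!bad_row],
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

read_molecules_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("reading SDF requires the ChemmineR package")
  }
  sdf <- ChemmineR::read.SDFset(path)
  if (!length(sdf)) stop("empty dataset: ", path)
  mol2 <- tempfile(fileext = ".mol2")
  on.exit(unlink(mol2))
  run_obabel(c(shQuote(path), "-omol2", "-O", shQuote(mol2),
               "--partialcharge", "mmff94"))
  blocks <- parse_mol2(mol2)
  if (length(blocks) != length(sdf)) {
    stop("obabel converted ", length(blocks), " of ", length(sdf),
         " SDF molecules")
  }
  lapply(seq_along(sdf), function(i) {
    m <- sdf[[i]]
    props <- ChemmineR::datablock(m)
    id <- ChemmineR::sdfid(sdf[i])
    ic <- if ("IC50_uM" %in% names(props)) as.numeric(props[["IC50_uM"]])
          else NA_real_
    b <- blocks[[i]]
    b$atoms$formal_charge <- 0
    b$atoms$in_ring <- ring_membership(b$atoms, b$bonds)
    nc <- sum(b$atoms$charge)
    b$atoms$formal_charge[1L] <- round(nc)
    molecule_record(id, smiles = NA_character_, ic50 = ic,
                    atoms = b$atoms, bonds = b$bonds)
  })
}
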