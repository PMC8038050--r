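test_that("pIC50 conversion matches the published activity table to 3 decimals", {
  tab <- read.csv(system.file("extdata", "nmt_table1.csv", package = "nmtqsar"))
  expect_equal(round(pic50_from_ic50(tab$ic50_um), 3), round(tab$pic50, 3),
               tolerance = 0)
  expect_equal(pic50_from_ic50(1), 6)
  expect_equal(round(pic50_from_ic50(0.002), 3), 8.699)
  expect_equal(round(pic50_from_ic50(107000), 3), 0.971)
})

test_that("pIC50 conversion is strictly decreasing and round-trips", {
  ic <- sort(10^runif(50, -3, 5))
  p <- pic50_from_ic50(ic)
  expect_true(all(diff(p) < 0))
  expect_equal(ic50_from_pic50(p) / ic, rep(1, 50), tolerance = 1e-7)
  expect_error(pic50_from_ic50(0), "positive")
  expect_error(pic50_from_ic50(-2), "positive")
})

test_that("csv loading returns one record per row with activities attached", {
  recs <- read_molecules(system.file("extdata", "nmt_table1.csv",
                                     package = "nmtqsar"))
  expect_length(recs, 10L)
  ids <- vapply(recs, `[[`, character(1), "id")
  expect_setequal(ids, c("20", "73", "2", "78", "95", "293", "82", "83",
                         "84", "111"))
  expect_equal(round(recs[[1]]$pic50, 3), 8.699)
})

test_that("degenerate molecule tables are rejected or repaired", {
  empty <- tempfile(fileext = ".csv")
  writeLines("id,smiles,ic50_um", empty)
  expect_error(read_molecules(empty), "empty dataset")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles,ic50_um", "a,CCO,1", "a,CCN,2"), dup)
  expect_error(read_molecules(dup), "duplicate")

  skip_if_not(has_obabel)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles,ic50_um", "a,CCO,1", "b,C1CC,2"), bad)
  expect_warning(recs <- read_molecules(bad), "unparsable")
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "a")
})

test_that("smi loading accepts both id-first and smiles-first layouts", {
  skip_if_not(has_obabel)
  f1 <- tempfile(fileext = ".smi")
  writeLines(c("m1 CCO", "m2 c1ccccc1"), f1)
  r1 <- read_molecules(f1)
  expect_equal(vapply(r1, `[[`, character(1), "id"), c("m1", "m2"))
  f2 <- tempfile(fileext = ".smi")
  writeLines(c("CCO m1", "c1ccccc1 m2"), f2)
  r2 <- read_molecules(f2)
  expect_equal(vapply(r2, `[[`, character(1), "id"), c("m1", "m2"))
})

test_that("3D preparation yields force-field geometries with balanced charges", {
  skip_if_not(has_obabel)
  toys <- toy_fixture()

  ch4 <- toys$methane
  expect_equal(nrow(ch4$atoms), 5L)
  ci <- which(ch4$atoms$element == "C")
  hd <- sqrt((ch4$atoms$x[-ci] - ch4$atoms$x[ci])^2 +
               (ch4$atoms$y[-ci] - ch4$atoms$y[ci])^2 +
               (ch4$atoms$z[-ci] - ch4$atoms$z[ci])^2)
  expect_true(all(abs(hd - 1.09) < 0.02))

  h2o <- toys$water
  expect_lt(h2o$atoms$charge[h2o$atoms$element == "O"], 0)
  expect_true(all(h2o$atoms$charge[h2o$atoms$element == "H"] > 0))
  expect_lt(abs(sum(h2o$atoms$charge)), 1e-6)
})

test_that("preparation is deterministic and energy-idempotent", {
  skip_if_not(has_obabel)
  a <- prepare_3d(molecule_record("x", smiles = "CCO"))
  b <- prepare_3d(molecule_record("x", smiles = "CCO"))
  expect_identical(a$atoms, b$atoms)
  # a different seed gives a validly different embedding
  c <- prepare_3d(molecule_record("x", smiles = "CCO"),
                  prep_config(embed_seed = 7))
  expect_false(identical(a$atoms$x, c$atoms$x))

  skip_if_not(nzchar(Sys.which("obenergy")))
  f1 <- tempfile(fileext = ".mol2")
  write_mol2(a, f1)
  e1 <- nmtqsar:::ob_energy(f1)
  f2 <- tempfile(fileext = ".mol2")
  nmtqsar:::run_obabel(c(shQuote(f1), "-omol2", "-O", shQuote(f2),
                         "--minimize", "--sd", "--steps", 1000,
                         "--ff", "MMFF94"))
  e2 <- nmtqsar:::ob_energy(f2)
  expect_lt(abs(e2 - e1), 1e-3)
})

test_that("embedding failures are flagged and dropped, not fatal", {
  skip_if_not(has_obabel)
  ok <- molecule_record("good", smiles = "CCO")
  # SMILES parse failure surfaces as a flagged record
  bad <- molecule_record("bad", smiles = "C1CC")
  out <- suppressMessages(prepare_molecules(list(ok, bad)))
  expect_length(out, 1L)
  expect_equal(out[[1]]$id, "good")
})

test_that("molecule records validate bonds and charge balance", {
  expect_error(molecule_record("x", atoms = data.frame(
    element = "C", x = 0, y = 0, z = 0, charge = 0),
    bonds = data.frame(from = 1, to = 2, order = 1)), "invalid atom index")
  expect_error(molecule_record("x", atoms = data.frame(
    element = c("C", "H"), x = c(0, 1), y = 0, z = 0,
    charge = c(0.5, 0.1))), "formal charge")
})
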