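# Library reading, standardization and curation.

test_that("read_library standardizes records and skips unparseable rows", {
  tab <- data.frame(
    molecule_id = c("m1", "m2", "m3"),
    smiles = c("OCC", "not_a_smiles(((", "CC(=O)O.[Na+]"),
    target_id = "T1",
    potency_type = c("Ki", "IC50", "IC50"),
    potency_value = c(100, 1, 0.5),
    potency_unit = c("nM", "uM", "uM")
  )
  lib <- read_library(write_smiles_table(tab), "smiles-table")
  expect_equal(nrow(lib), 2L)
  expect_equal(attr(lib, "n_skipped"), 1L)
  # SMILES are stored in the backend's canonical form
  expect_equal(lib$smiles[lib$molecule_id == "m1"],
               unname(canonical_smiles("CCO")))
  # salt stripped to the acid fragment before canonicalization
  expect_equal(lib$smiles[lib$molecule_id == "m3"],
               unname(canonical_smiles("CC(=O)O")))
  # 0.5 uM -> 500 nM
  expect_equal(lib$potency_nM[lib$molecule_id == "m3"], 500)
})

test_that("duplicate molecule ids merge to the most potent measurement", {
  tab <- data.frame(
    molecule_id = c("d1", "d1", "d1"),
    smiles = "NS(=O)(=O)c1ccc(C)cc1",
    potency_type = c("Ki", "IC50", "Ki"),
    potency_value = c(800, 120, 300),
    potency_unit = "nM"
  )
  lib <- read_library(write_smiles_table(tab), "smiles-table")
  expect_equal(nrow(lib), 1L)
  expect_equal(lib$potency_nM, 120)
  expect_equal(lib$potency_type, "IC50")
})

test_that("read_library validates its inputs", {
  expect_error(read_library(tempfile(), "smiles-table"), "not found")
  bad <- write_smiles_table(data.frame(id = "x", smi = "CCO"))
  expect_error(read_library(bad, "smiles-table"), "missing required column")
  allbad <- write_smiles_table(data.frame(molecule_id = "x",
                                          smiles = "((((("))
  expect_error(read_library(allbad, "smiles-table"), "zero parseable")
})

test_that("SDF input round-trips through the parser", {
  smis <- c(sulfonamide_pair(), unrelated_molecules())
  ps <- dualscreen:::parse_smiles_set(smis)
  sdf_path <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(ps$sdf, sdf_path, cid = TRUE)
  lib <- read_library(sdf_path, "sdf")
  expect_equal(nrow(lib), 5L)
  expect_setequal(lib$molecule_id, names(smis))
  # canonical SMILES from the SDF route match direct canonicalization
  expect_equal(lib$smiles[match(names(smis), lib$molecule_id)],
               unname(canonical_smiles(smis)))
})

test_that("potency unit conversion is exact and round-trips", {
  expect_equal(potency_to_nM(0.5, "uM"), 500)
  expect_equal(potency_to_nM(2e-9, "M"), 2)
  expect_error(potency_to_nM(1, "mM"), "unknown potency unit")
  x <- c(0.123, 45.6, 789)
  expect_equal(potency_to_nM(x / 1e3, "uM"), x, tolerance = 1e-12)
})

test_that("filter_library applies strict cutoffs and is idempotent", {
  tab <- data.frame(
    molecule_id = sprintf("f%d", 1:3),
    smiles = "NS(=O)(=O)c1ccc(C)cc1",
    potency_type = "Ki",
    potency_value = c(450, 500, 550),
    potency_unit = "nM"
  )
  lib <- read_library(write_smiles_table(tab), "smiles-table")
  out <- filter_library(lib, curation_config())
  expect_equal(out$molecule_id, "f1")   # only 450 survives strict < 500

  # MW boundary: exactly mw_max is excluded ("smaller than")
  lib2 <- lib
  lib2$mw <- c(499.9, 500.0, 500.1)
  lib2$potency_nM <- 100
  out2 <- filter_library(lib2, curation_config())
  expect_equal(out2$molecule_id, "f1")

  expect_identical(filter_library(out, curation_config()), out)
})

test_that("representative selection keeps the most potent per cluster", {
  # SA1/SA2 are close analogs (TC >= 0.6), NAP is unrelated
  smis <- c(sulfonamide_pair(), unrelated_molecules()["NAP"])
  fps <- fingerprint_matrix(smis, "ECFP4")
  tcs <- tanimoto_matrix(fps)
  expect_gte(tcs["SA1", "SA2"], 0.6)
  expect_lt(tcs["SA1", "NAP"], 0.6)

  tab <- data.frame(molecule_id = names(smis), smiles = unname(smis),
                    potency_type = "Ki", potency_value = c(100, 50, 200),
                    potency_unit = "nM")
  lib <- read_library(write_smiles_table(tab), "smiles-table")
  reps <- select_representative_actives(lib, curation_config())
  expect_setequal(reps$molecule_id, c("SA2", "NAP"))  # 50 nM beats 100 nM
  expect_true(all(reps$role == "active"))
  expect_true(all(reps$molecule_id %in% lib$molecule_id))

  # potency tie inside the cluster breaks to the smaller molecule_id
  lib$potency_nM <- c(50, 50, 200)
  reps2 <- select_representative_actives(lib, curation_config())
  expect_true("SA1" %in% reps2$molecule_id)
})

test_that("singleton input is its own representative", {
  tab <- data.frame(molecule_id = "only", smiles = "CCO",
                    potency_type = "Ki", potency_value = 10,
                    potency_unit = "nM")
  lib <- read_library(write_smiles_table(tab), "smiles-table")
  reps <- select_representative_actives(lib)
  expect_equal(reps$molecule_id, "only")
})
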