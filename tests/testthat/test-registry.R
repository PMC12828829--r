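# Shorthand grammar, elemental compositions and adduct m/z values.

test_that("shorthand parsing covers species, linkage, oxygens and labels", {
  p <- parse_lipid("PC 34:2")
  expect_equal(p$class, "PC")
  expect_equal(p$carbons, 34L)
  expect_equal(p$db, 2L)
  expect_equal(p$linkage, "ester")
  expect_equal(p$label_d, 0L)

  p <- parse_lipid("Cer 38:1;O2")
  expect_equal(p[, c("class", "carbons", "db", "oxygens")],
               tibble::tibble(class = "Cer", carbons = 38L, db = 1L, oxygens = 2L))

  p <- parse_lipid("PC P-36:1 d9")
  expect_equal(p$linkage, "P-")
  expect_equal(p$class_label, "PC O-")
  expect_equal(p$carbons, 36L)
  expect_equal(p$label_d, 9L)

  # sphingolipids default to the ;O2 backbone when the suffix is omitted
  expect_equal(parse_lipid("SM 42:1")$oxygens, 2L)

  # Table 1 alias names map to canonical shorthand
  expect_equal(parse_lipid("Cer C18 d7")$species, "Cer 36:1;O2 d7")
  expect_equal(parse_lipid("GlcCer 36:1 d5")$species, "HexCer 36:1;O2 d5")
  expect_equal(parse_lipid("Chol d7")$label_d, 7L)

  expect_error(parse_lipid("XYZ 34:2"), "unknown class")
  expect_error(parse_lipid("PC 34"), "parse")
})

test_that("parse/format round-trips the mix names and paper-style names", {
  names <- c("PC 34:2", "Cer 38:1;O2", "PC P-36:1 d9", "PE O-33:3",
             "LPC 18:1 d7", "SM 36:2;O2 d9", "Chol d7", "TG 48:1 d7",
             "HexCer 42:1;O2", "PI 38:4")
  for (nm in names) {
    p <- parse_lipid(nm)
    expect_identical(format_lipid(p), nm)
    expect_identical(parse_lipid(format_lipid(p)), p)
  }
  # names with an implicit sphingolipid ;O2 round-trip at the species level
  expect_identical(parse_lipid(format_lipid(parse_lipid("SM 42:1"))),
                   parse_lipid("SM 42:1"))
})

test_that("compositions match independently assembled structural formulas", {
  # published structural formulas, assembled by hand
  cases <- c(
    "PC 34:2"       = "C42H80NO8P",
    "PE 34:1"       = "C39H76NO8P",
    "LPC 18:1"      = "C26H52NO7P",
    "LPE 18:1"      = "C23H46NO7P",
    "PG 34:1"       = "C40H77O10P",
    "PI 38:4"       = "C47H83O13P",
    "PS 36:1"       = "C42H80NO10P",
    "SM 34:1;O2"    = "C39H79N2O6P",
    "Cer 34:1;O2"   = "C34H67NO3",
    "HexCer 34:1;O2" = "C40H77NO8",
    "CE 18:1"       = "C45H78O2",
    "TG 52:2"       = "C55H102O6",
    "DG 34:1"       = "C37H70O5",
    "MG 18:1"       = "C21H40O4",
    "Chol"          = "C27H46O",
    "PC O-34:1"     = "C42H84NO7P",
    "PC P-36:1"     = "C44H86NO7P"
  )
  for (nm in names(cases)) {
    expect_identical(format_formula(lipid_composition(nm)), unname(cases[nm]),
                     label = nm)
  }
})

test_that("composition arithmetic follows the carbon/double-bond grammar", {
  # one more double bond removes exactly H2
  c2 <- lipid_composition("PC 34:2")
  c3 <- lipid_composition("PC 34:3")
  expect_equal(c2 - c3, c(C = 0L, H = 2L, D = 0L, N = 0L, O = 0L, P = 0L, S = 0L))
  # deuterium label swaps H for D without changing total hydrogen count
  d0 <- lipid_composition("PC 33:1")
  d7 <- lipid_composition("PC 33:1 d7")
  expect_equal(d7[["D"]], 7L)
  expect_equal(d7[["H"]] + d7[["D"]], d0[["H"]])
  expect_equal(d7[["C"]], d0[["C"]])
})

test_that("adduct m/z values hit the hand-computed oracle masses", {
  # summation of monoisotopic atomic masses, done independently by hand:
  # C42H80NO8P + H+ = 758.5694
  expect_equal(lipid_mz("PC 34:2", "positive"), 758.5694, tolerance = 1e-4 / 758)
  # water-loss and ammonium spacings
  m <- lipid_composition("PC 34:2")
  expect_equal(adduct_mz(m, "[M+H]+") - adduct_mz(m, "[M+H-H2O]+"),
               18.0106, tolerance = 1e-4)
  expect_equal(adduct_mz(m, "[M+NH4]+") - adduct_mz(m, "[M+H]+"),
               17.0265, tolerance = 1e-4)
  # acetate adduct sits CH3COOH - 2H above [M-H]-
  expect_equal(adduct_mz(m, "[M+CH3COO]-") - adduct_mz(m, "[M-H]-"),
               60.0211, tolerance = 1e-4)
})

test_that("m/z increases by one CH2 per carbon within a class", {
  mzs <- vapply(c("PC 32:1", "PC 33:1", "PC 34:1", "PC 35:1", "PC 36:1"),
                lipid_mz, numeric(1), polarity = "positive")
  expect_true(all(diff(mzs) > 0))
  expect_equal(unname(diff(mzs)), rep(14.01565, 4), tolerance = 1e-4)
})

test_that("class adduct rules follow the observed ionization behavior", {
  expect_equal(class_adduct("PI", "positive"), "[M+NH4]+")
  expect_equal(class_adduct("Cer", "positive"), "[M+H-H2O]+")
  expect_equal(class_adduct(c("PC", "PE", "SM", "TG"), "positive"),
               rep("[M+H]+", 4))
  expect_equal(class_adduct(c("LPE", "PE", "PG", "PI", "PS"), "negative"),
               rep("[M-H]-", 5))
  expect_equal(class_adduct(c("Cer", "HexCer", "LPC", "PC", "SM"), "negative"),
               rep("[M+CH3COO]-", 5))
  # PG and PS ionize only in negative mode; CE/TG only in positive
  expect_true(all(is.na(class_adduct(c("PG", "PS"), "positive"))))
  expect_true(all(is.na(class_adduct(c("CE", "TG"), "negative"))))
  expect_error(lipid_mz("PG 34:1", "positive"), "no adduct")
})

test_that("every mix class resolves in the registry", {
  mix <- is_mix()
  for (nm in is_species_names(mix)) {
    expect_s3_class(parse_lipid(nm), "tbl_df")
    expect_true(sum(lipid_composition(nm)) > 0)
  }
})
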