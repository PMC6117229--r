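test_that("formula parsing handles single parts, mixtures and charges", {
  f <- parse_formula("C9H16ClN5")
  expect_length(f$parts, 1)
  expect_equal(f$parts[[1]]$counts[["C"]], 9)
  expect_equal(f$parts[[1]]$counts[["Cl"]], 1)
  expect_equal(formula_charge(f), 0)

  anion <- parse_formula("C8F17O3S-")
  expect_equal(formula_charge(anion), -1)
  expect_equal(format(anion), "C8F17O3S-")

  # Unicode minus accepted
  expect_equal(formula_charge(parse_formula("C8F17O3S−")), -1)

  salt <- parse_formula("C31H42N3.C2H3O2")
  expect_length(salt$parts, 2)
  expect_equal(vapply(salt$parts, function(p) p$charge, integer(1)),
               c(0L, 0L))
  signed <- parse_formula("C31H42N3+.C2H3O2-")
  expect_equal(vapply(signed$parts, function(p) p$charge, integer(1)),
               c(1L, -1L))

  # charge dialects
  expect_equal(formula_charge(parse_formula("O--")), -2)
  expect_equal(formula_charge(parse_formula("SO42-")), -2)
  expect_equal(formula_charge(parse_formula("Ca2+")), 2)
  expect_equal(formula_charge(parse_formula("Fe+3")), 3)
  expect_equal(formula_charge(parse_formula("NH4+")), 1)
  expect_equal(formula_counts(parse_formula("NH4+"))[["H"]], 4)

  # repeated element tokens accumulate
  expect_equal(format(parse_formula("CH3COOH")), "C2H4O2")
})

test_that("malformed formulas raise errors naming the problem", {
  expect_error(parse_formula(""), "empty")
  expect_error(parse_formula("C9Xx3"), "Xx")
  expect_error(parse_formula("C9H0"), "positive")
  expect_error(parse_formula("+"), "no elements")
  expect_error(parse_formula("C9..H4"), "empty part")
})

test_that("Hill display puts C then H then alphabetical, and round-trips", {
  expect_equal(format(parse_formula("ClC9N5H16")), "C9H16ClN5")
  expect_equal(format(parse_formula("O4S")), "O4S")
  expect_equal(format(parse_formula("BrH")), "BrH")
  for (txt in random_formulas(200, seed = 42)) {
    f <- parse_formula(txt)
    expect_true(f == parse_formula(format(f)), label = txt)
  }
})

test_that("monoisotopic mass matches printed values and the atom oracle", {
  expect_equal(display_mass(monoisotopic_mass("C9H16ClN5")), "229.1094")
  expect_equal(display_mass(monoisotopic_mass("C7H12ClN5")), "201.0781")
  expect_equal(display_mass(monoisotopic_mass("C10H14N2")), "162.1157")
  # empty formula weighs nothing
  expect_equal(monoisotopic_mass(msready:::new_ms_formula(list())), 0)
  # multi-part = sum of parts
  expect_equal(
    monoisotopic_mass("C14H19N3S.C4H4O4"),
    monoisotopic_mass("C14H19N3S") + monoisotopic_mass("C4H4O4")
  )
  for (txt in random_formulas(500, seed = 7)) {
    expect_equal(monoisotopic_mass(txt), atomwise_mass(txt),
                 tolerance = 1e-4, label = txt)
  }
})

test_that("adduct m/z applies proton and electron masses correctly", {
  # intrinsic butyl cation: printed value is 57.0698, convention gap
  # between rounding and truncation is below 1 mDa
  expect_lt(abs(adduct_mz("C4H9+", "M") - 57.0698), 1e-3)
  expect_equal(display_mass(adduct_mz("C14H19N3S", "M+H")), "262.1372")
  # charge accounting is exact
  for (txt in c("C9H16ClN5", "C10H14N2", "C8HF17O3S")) {
    expect_equal(adduct_mz(txt, "M+H") - monoisotopic_mass(txt),
                 proton_mass(), tolerance = 1e-12)
    expect_equal(monoisotopic_mass(txt) - adduct_mz(txt, "M-H"),
                 proton_mass(), tolerance = 1e-12)
    expect_identical(adduct_mz(txt, "M"), monoisotopic_mass(txt))
  }
  expect_error(adduct_mz("Ca2+", "M"), "multiply charged")
  expect_error(adduct_mz("C8F17O3S-", "M+H"), "neutral")
})

test_that("formula neutralization transfers protons per unit charge", {
  expect_equal(format(neutralize_formula("C8F17O3S-")), "C8HF17O3S")
  expect_equal(format(neutralize_formula("NH4+")), "H3N")
  expect_equal(format(neutralize_formula("C10H14N2")), "C10H14N2")
  expect_error(neutralize_formula("C2+"), "not enough hydrogens")
})

test_that("element mass table is physically consistent", {
  m <- element_masses()
  expect_true(all(c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
                    "Si", "B", "Na", "K", "Ca", "Mg", "Fe", "Sn", "Hg")
                  %in% names(m)))
  expect_true(all(m > 0))
  expect_lt(abs(proton_mass() - (m[["H"]] - electron_mass())), 1e-6)
})
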