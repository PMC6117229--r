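test_that("consistency checking accepts sane structures, rejects bad valence", {
  expect_identical(check_consistency("c1ccccc1"), "c1ccccc1")
  expect_error(check_consistency("CC(C)(C)(C)C"), "valence")
  # hypervalent nitro drawing passes and is fixed downstream
  expect_silent(check_consistency("CC[N](=O)=O"))
  expect_error(check_consistency("C1CC"), "unparseable")
})

test_that("component splitting is complete and deterministically ordered", {
  nicarbazin <- paste0(
    "O=C(Nc1ccc(cc1)[N+](=O)[O-])Nc1ccc(cc1)[N+](=O)[O-].",
    "Cc1cc(C)nc(O)n1")
  comps <- split_components(nicarbazin)
  expect_length(comps, 2)
  expect_length(split_components("CCO"), 1)
  # heavy-atom descending order: carbanilide part first
  expect_gt(nchar(comps[1]), nchar(comps[2]))
  # methapyrilene fumarate 3:2 splits into 5 graph components
  mf <- paste(c(rep("CN(C)CCN(Cc1cccs1)c1ccccn1", 3),
                rep("OC(=O)/C=C/C(=O)O", 2)), collapse = ".")
  expect_length(split_components(mf), 5)
})

test_that("classification separates organic, inorganic, organometallic", {
  expect_identical(classify_component("[Na+]")$class, "inorganic")
  expect_identical(classify_component("O=C=O")$class, "inorganic")
  expect_identical(classify_component("[C-]#N")$class, "inorganic")
  expect_identical(classify_component("C(=O)(O)[O-]")$class, "inorganic")
  expect_identical(classify_component("OC=O")$class, "organic")  # has C-H
  expect_identical(classify_component("CCO")$class, "organic")

  tbt <- "CCCC[Sn](CCCC)(CCCC)CCCC"
  ms <- classify_component(tbt, std_config("msready"))
  qs <- classify_component(tbt, std_config("qsarready"))
  expect_identical(ms$class, "organometallic")
  expect_true(ms$retained)
  expect_false(qs$retained)
})

test_that("exclusion desalts multi-component records only", {
  cfg <- std_config("msready")
  # HCl on the list, dropped from a pair
  res <- apply_exclusion(c("CN1CCCC1c1cccnc1", "Cl"), cfg)
  expect_identical(res$retained, "CN1CCCC1c1cccnc1")
  expect_match(res$dropped$reason, "hydrochloric")
  # a single-component substance that IS a listed counterion is kept
  res1 <- apply_exclusion("CC(=O)O", cfg, n_record = 1L)
  expect_identical(res1$retained, "CC(=O)O")
  # salicylate is not on the MS-Ready list: both retained
  res2 <- apply_exclusion(c("CN1CCCC1c1cccnc1", "OC(=O)c1ccccc1O"), cfg)
  expect_length(res2$retained, 2)
  # matching is on the neutralized form: chloride anion matches the
  # hydrochloric acid entry
  res3 <- apply_exclusion(c("CC[N+](CC)(CC)CC", "[Cl-]"), cfg)
  expect_identical(res3$retained, "CC[N+](CC)(CC)CC")
})

test_that("mesomer and tautomer rules reach the canonical forms", {
  cfg <- std_config()
  nitro <- normalize_tautomer("CC[N](=O)=O", cfg)
  expect_identical(nitro, msready:::canonical_smiles("CC[N+](=O)[O-]"))
  azide <- normalize_tautomer("CN=N#N", cfg)
  expect_identical(azide, msready:::canonical_smiles("CN=[N+]=[N-]"))
  expect_identical(normalize_tautomer("C(=C)O", cfg),
                   msready:::canonical_smiles("CC=O"))
  expect_identical(normalize_tautomer("CC(O)=CC", cfg),
                   msready:::canonical_smiles("CC(=O)CC"))
  expect_identical(normalize_tautomer("NC=C", cfg),
                   msready:::canonical_smiles("CC=N"))
  # fixpoints: aromatics and saturated molecules unchanged
  expect_identical(normalize_tautomer("c1ccccc1", cfg), "c1ccccc1")
  expect_identical(normalize_tautomer("Oc1ccccc1", cfg),
                   msready:::canonical_smiles("Oc1ccccc1"))
  expect_identical(normalize_tautomer("CCO", cfg), "CCO")
})

test_that("tautomer/mesomer normalization never changes the formula", {
  cfg <- std_config()
  cases <- c("CC[N](=O)=O", "CN=N#N", "C(=C)O", "CC(O)=CC", "NC=C",
             "OC#Cc1ccccc1", "CC(=CC)N", "Oc1ccccc1",
             derived_structures(40, seed = 11))
  for (smi in cases) {
    comps <- split_components(smi)
    for (comp in comps) {
      before <- format(msready:::formula_of_smiles(comp))
      after <- format(msready:::formula_of_smiles(
        normalize_tautomer(comp, cfg)))
      expect_identical(after, before, label = comp)
    }
  }
})

test_that("neutralization moves protons only, and flags permanent charge", {
  n <- neutralize("CC(=O)[O-]")
  expect_identical(n$smiles, msready:::canonical_smiles("CC(=O)O"))
  expect_false(n$permanent_charge)
  # PFOS sulfonate becomes the neutral acid
  pfos_anion <- paste0("[O-]S(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)",
                       "C(F)(F)C(F)(F)C(F)(F)C(F)(F)F")
  expect_identical(format(msready:::formula_of_smiles(
    neutralize(pfos_anion)$smiles)), "C8HF17O3S")
  # protonated amine loses one H
  n2 <- neutralize("CC[NH3+]")
  expect_identical(n2$smiles, msready:::canonical_smiles("CCN"))
  # quaternary N and stabilized carbenium stay charged, flagged
  n3 <- neutralize("CC[N+](CC)(CC)CC")
  expect_true(n3$permanent_charge)
  expect_equal(n3$net_charge, 1)
  methylium <- paste0("CCN(CC)c1ccc(cc1)[C+](c1ccc(N(CC)CC)cc1)",
                      "c1ccc(N(CC)CC)cc1")
  expect_true(neutralize(methylium)$permanent_charge)
  # charge-separated nitro untouched
  n4 <- neutralize("CC[N+](=O)[O-]")
  expect_identical(n4$smiles, msready:::canonical_smiles("CC[N+](=O)[O-]"))
  expect_false(n4$permanent_charge)
  # H count is the only formula change
  for (smi in c("CC(=O)[O-]", "CC[NH3+]", "[O-]c1ccccc1", "CC[S-]")) {
    before <- formula_counts(msready:::formula_of_smiles(smi))
    after <- formula_counts(msready:::formula_of_smiles(
      neutralize(smi)$smiles))
    expect_identical(before[names(before) != "H"],
                     after[names(after) != "H"], label = smi)
  }
})

test_that("stereo stripping keeps the InChIKey first block", {
  s <- strip_stereo("CN1CCC[C@H]1c1cccnc1")
  expect_identical(s, msready:::canonical_smiles("CN1CCCC1c1cccnc1"))
  expect_identical(strip_stereo("CN1CCC[C@@H]1c1cccnc1"), s)
  # achiral unchanged; E/Z removed
  expect_identical(strip_stereo("CCO"), "CCO")
  expect_false(grepl("/", strip_stereo("OC(=O)/C=C/C(=O)O")))
  # isotopes retained
  expect_match(strip_stereo("[13CH4]"), "13C", fixed = TRUE)
  stereo_cases <- c("CN1CCC[C@H]1c1cccnc1", "OC(=O)/C=C/C(=O)O",
                    "C[C@H](N)C(=O)O", "C/C=C/C=C",
                    "O[C@@H]1CC[C@H](C)CC1")
  for (smi in stereo_cases) {
    expect_identical(first_block(inchikey(strip_stereo(smi))),
                     first_block(inchikey(smi)), label = smi)
  }
})

test_that("finalized components carry aromatic SMILES, formula, key, mass", {
  fin <- finalize_component("C1=CC=CC=C1")
  expect_identical(fin$smiles, "c1ccccc1")
  expect_identical(fin$formula, "C6H6")
  expect_equal(fin$monoisotopic_mass, monoisotopic_mass("C6H6"))
  expect_match(fin$inchikey, "^[A-Z]{14}-")
  fin2 <- finalize_component("c1ccncc1")
  expect_identical(fin2$formula, "C5H5N")
})

test_that("the full pipeline reproduces the worked examples", {
  nicarbazin <- paste0(
    "O=C(Nc1ccc(cc1)[N+](=O)[O-])Nc1ccc(cc1)[N+](=O)[O-].",
    "Cc1cc(C)nc(O)n1")
  r <- standardize_substance(nicarbazin, "NCZ1")
  expect_identical(r$status, "ok")
  expect_identical(sort(r$components$formula),
                   c("C13H10N4O5", "C6H8N2O"))

  # hydrochloride: counterion stripped, one component left
  ral <- standardize_substance(
    paste0("OC1=CC2=C(C=C1)SC(=C2C(=O)c1ccc(OCCN2CCCCC2)cc1)",
           "c1ccc(O)cc1.Cl"), "RLX1")
  expect_identical(ral$status, "ok")
  expect_equal(nrow(ral$components), 1)
  expect_identical(ral$components$formula, "C28H27NO4S")

  # all-inorganic record comes back empty, not errored
  nacl <- standardize_substance("[Na+].[Cl-]", "NACL")
  expect_identical(nacl$status, "empty")
  expect_equal(nrow(nacl$dropped), 2)

  # unparseable record reports an error status and continues
  bad <- standardize_substance("xyzzy", "BAD")
  expect_identical(bad$status, "error")

  # permanent cation survives with its counterion desalted
  slt <- build_fixture("salt_errors")$substances$smiles[1]
  r2 <- standardize_substance(slt, "SLT1")
  expect_identical(r2$status, "ok")
  expect_equal(nrow(r2$components), 1)
  expect_true(r2$components$permanent_charge)
  expect_identical(r2$components$formula, "C31H42N3+")
})

test_that("mixtures survive MS-Ready mode and die in QSAR-Ready mode", {
  mf <- paste(c(rep("CN(C)CCN(Cc1cccs1)c1ccccn1", 3),
                rep("OC(=O)/C=C/C(=O)O", 2)), collapse = ".")
  ms <- standardize_substance(mf, "MTP2", std_config("msready"))
  expect_identical(ms$status, "ok")
  expect_identical(sort(ms$components$formula), c("C14H19N3S", "C4H4O4"))
  # in QSAR-Ready mode fumarate is desalted away, leaving the free base
  qs <- standardize_substance(mf, "MTP2", std_config("qsarready"))
  expect_identical(qs$components$formula, "C14H19N3S")
  # a genuine two-drug mixture is discarded entirely in QSAR-Ready mode
  mix <- "CN1CCCC1c1cccnc1.CC(C)C1CCC(C)CC1O"
  expect_identical(standardize_substance(mix, "MIX",
                                         std_config("qsarready"))$status,
                   "empty")
  expect_identical(standardize_substance(mix, "MIX")$status, "ok")
})

test_that("standardization is idempotent on its own outputs", {
  cfg <- std_config()
  structures <- derived_structures(200, seed = 99)
  n_checked <- 0
  for (smi in structures) {
    r <- standardize_substance(smi, config = cfg)
    expect_false(r$status == "error", label = smi)
    for (k in seq_len(nrow(r$components))) {
      r2 <- standardize_substance(r$components$smiles[k], config = cfg)
      expect_identical(sort(r2$components$inchikey),
                       r$components$inchikey[k], label = smi)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 150)
})

test_that("component count never grows and modes nest correctly", {
  for (smi in derived_structures(40, seed = 5)) {
    r <- standardize_substance(smi)
    expect_lte(nrow(r$components), length(split_components(smi)))
    q <- standardize_substance(smi, config = std_config("qsarready"))
    # QSAR-Ready keeps at most one component, drawn from the MS-Ready set
    expect_lte(nrow(q$components), 1)
    if (nrow(q$components) == 1) {
      expect_true(q$components$inchikey %in% r$components$inchikey)
    }
  }
})

test_that("the tidy table API mirrors the per-substance results", {
  tbl <- tibble::tibble(
    id = c("A", "B", "C"),
    smiles = c("CN1CCC[C@H]1c1cccnc1.Cl", "[Na+].[Cl-]", "badsmiles")
  )
  out <- standardize(tbl)
  expect_identical(out$status, c("ok", "empty", "error"))
  expect_identical(out$n_components, c(1L, 0L, 0L))
  comps <- tidyr::unnest(out[1, ], "components")
  expect_identical(comps$formula, "C10H14N2")
})
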