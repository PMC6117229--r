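# Shared generators for property-style tests. Everything is seeded by the
# caller; nothing here touches the network or disk.

# random single-part neutral formulas over the organic element set
random_formulas <- function(n, seed = 1) {
  set.seed(seed)
  elements <- c("C", "H", "N", "O", "S", "P", "F", "Cl", "Br", "I",
                "Si", "B", "Na", "K")
  lapply(seq_len(n), function(i) {
    k <- sample(1:6, 1)
    syms <- sample(elements, k)
    counts <- sample(1:30, k, replace = TRUE)
    paste0(syms, ifelse(counts > 1, counts, ""), collapse = "")
  })
}

# independent per-atom mass oracle: expand the formula to one atom per
# entry and add masses one by one (no vectorized shortcut shared with
# the implementation)
atomwise_mass <- function(formula_text) {
  f <- parse_formula(formula_text)
  masses <- element_masses()
  total <- 0
  for (part in f$parts) {
    for (sym in names(part$counts)) {
      for (k in seq_len(part$counts[[sym]])) {
        total <- total + masses[[sym]]
      }
    }
    total <- total - part$charge * electron_mass()
  }
  total
}

# deterministic library of fixture-derived structures: scaffolds
# decorated with substituents, plus salt/mixture combinations, mirroring
# the chemistry the worked examples cover
derived_structures <- function(n, seed = 1) {
  set.seed(seed)
  scaffolds <- c(
    "%sNc1nc(Cl)nc(N%s)n1",      # chlorotriazine with two amino R-groups
    "CN1CCCC1c1ccc(%s)nc1",      # nicotine-like
    "c1ccc(%s)cc1%s",            # disubstituted benzene
    "%sC(=O)O%s",                # ester
    "%sN(%s)CCO",                # amino alcohol
    "%sC(=O)N%s",                # amide
    "O=S(=O)(O)%s",              # sulfonic acid
    "%sOc1ccc(cc1)%s"            # aryl ether
  )
  # substituents are spliced into scaffold slots on either side, so both
  # their first and last written atom must tolerate one more bond:
  # heteroatoms and halogens only appear in branches or mid-chain
  subst <- c("C", "CC", "CCC", "CC(C)C", "CCCC", "C(C)(C)C", "CCOC",
             "CCNC", "c1ccccc1", "CC=C", "C(F)(F)C", "C(Cl)C", "CCSC")
  counter <- c("", ".Cl", ".[Na+].[O-]C(=O)C", ".OC(=O)/C=C/C(=O)O",
               ".O", ".OS(=O)(=O)O")
  out <- character(n)
  for (i in seq_len(n)) {
    sc <- sample(scaffolds, 1)
    nslot <- lengths(regmatches(sc, gregexpr("%s", sc)))
    smi <- do.call(sprintf, c(list(sc), as.list(sample(subst, nslot,
                                                       replace = TRUE))))
    out[i] <- paste0(smi, sample(counter, 1))
  }
  out
}

# small scored-candidate table used by scoring tests
toy_candidates <- function() {
  tibble::tibble(
    id = c("TRZ1", "TRZ2", "TRZ3"),
    inchikey = c("FZXISNSWEXTPMF-UHFFFAOYSA-N",
                 "WBPYTXDJUQJLPQ-VMXQISHHSA-N",
                 "MGNFYQILYYYUBS-UHFFFAOYSA-N"),
    fragmenter = c(1, 0.9, 0.95),
    spectral = c(1, 0.5774, 0.9),
    data_sources = c(3880, 1560, 182),
    pubmed_count = c(540, 900, 12),
    norman = c(1, 1, 0),
    stoffident = c(1, 1, 1),
    toxcast_pct_active = c(32, 45, NA)
  )
}
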