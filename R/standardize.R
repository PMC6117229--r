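#' Standardization configuration
#'
#' Controls the structure-preparation pipeline. `"msready"` mode keeps
#' mixture components (linked to the parent substance) and organometallics
#' with covalent metal-carbon bonds, and desalts against a small
#' counterion exclusion list. `"qsarready"` mode additionally discards
#' mixtures and organometallics and uses a larger exclusion list.
#'
#' @param mode `"msready"` or `"qsarready"`.
#' @param exclusion Exclusion list as returned by
#'   [default_exclusion_list()] or [read_exclusion_sdf()]: a tibble with
#'   at least `name` and `smiles` columns.
#' @param max_iter Maximum tautomer/mesomer transform passes (>= 1).
#' @return A `std_config` list.
#' @export
std_config <- function(mode = c("msready", "qsarready"),
                       exclusion = NULL,
                       max_iter = 20L) {
  mode <- match.arg(mode)
  if (is.null(exclusion)) exclusion <- default_exclusion_list(mode)
  stopifnot(max_iter >= 1L)
  structure(list(mode = mode, exclusion = exclusion,
                 max_iter = as.integer(max_iter)),
            class = "std_config")
}

#' Consistency check (pipeline step 1)
#'
#' Parses the structure, perceives aromaticity and implicit hydrogens, and
#' rejects chemically implausible valences (e.g. pentavalent neutral
#' carbon). Hypervalent nitrogen drawings such as `N(=O)=O` are accepted;
#' the mesomer rules convert them downstream.
#'
#' @param smiles SMILES of the raw record (may be multi-component).
#' @return Canonical SMILES of the validated record.
#' @export
check_consistency <- function(smiles) {
  mol <- smiles_to_mol(smiles)
  bs <- bond_order_sum(mol)
  for (i in seq_len(nrow(mol$atoms))) {
    cap <- max_valence(mol$atoms$symbol[i], mol$atoms$charge[i])
    if (!is.na(cap) && bs[i] > cap) {
      stop("valence error: atom ", i, " (", mol$atoms$symbol[i],
           ", charge ", mol$atoms$charge[i], ") has explicit valence ",
           bs[i], " > ", cap, " in '", smiles, "'", call. = FALSE)
    }
  }
  canonical_smiles(smiles)
}

#' Split a record into connected components (pipeline step 2)
#'
#' One SMILES per connected component of the molecular graph, in
#' deterministic order: descending heavy-atom count, ties broken by
#' canonical SMILES.
#'
#' @param smiles SMILES of a validated record.
#' @return Character vector of component SMILES.
#' @examples
#' \donttest{
#' split_components("CC(=O)O.[Na+]")
#' }
#' @export
split_components <- function(smiles) {
  mols <- mol_components(smiles_to_mol(smiles))
  smis <- vapply(mols, mol_to_smiles, character(1))
  heavy <- vapply(mols, function(m) sum(m$atoms$symbol != "H"), integer(1))
  smis[order(-heavy, smis)]
}

#' Classify a single component (pipeline step 2)
#'
#' A component is `organic` if it has at least one carbon bonded to H, C
#' or a non-metal heteroatom and no covalent metal-carbon bond;
#' `organometallic` if it has a covalent metal-carbon bond; `inorganic`
#' otherwise (no carbon, or carbon only in CO2/carbonate/cyanide-like
#' patterns). Organics are always retained; organometallics only in
#' `msready` mode.
#'
#' @param smiles Component SMILES.
#' @param config A [std_config()].
#' @return One-row tibble: `smiles`, `class`, `retained`, `reason`.
#' @export
classify_component <- function(smiles, config = std_config()) {
  mol <- smiles_to_mol(smiles)
  syms <- mol$atoms$symbol
  metal <- is_metal(syms)
  carbon <- syms == "C"
  mc_bond <- FALSE
  if (nrow(mol$bonds)) {
    mc_bond <- any(
      (metal[mol$bonds$a1] & carbon[mol$bonds$a2]) |
      (metal[mol$bonds$a2] & carbon[mol$bonds$a1])
    )
  }
  cls <- if (!any(carbon)) {
    "inorganic"
  } else if (mc_bond) {
    "organometallic"
  } else {
    imph <- implicit_h(mol)
    c_idx <- which(carbon)
    cc_bond <- nrow(mol$bonds) &&
      any(carbon[mol$bonds$a1] & carbon[mol$bonds$a2])
    ch <- any(imph[c_idx] > 0L) ||
      (nrow(mol$bonds) &&
       any((carbon[mol$bonds$a1] & syms[mol$bonds$a2] == "H") |
           (carbon[mol$bonds$a2] & syms[mol$bonds$a1] == "H")))
    if (length(c_idx) == 1L && !ch && !cc_bond) "inorganic" else "organic"
  }
  retained <- cls == "organic" ||
    (cls == "organometallic" && config$mode == "msready")
  reason <- switch(cls,
    organic = "organic component",
    organometallic = if (retained) {
      "organometallic (covalent metal-carbon bond), retained for MS-Ready"
    } else {
      "organometallic, discarded in QSAR-Ready mode"
    },
    inorganic = "inorganic component"
  )
  tibble::tibble(smiles = smiles, class = cls, retained = retained,
                 reason = reason)
}

# key under which a component is compared to the exclusion list:
# neutralized, stereochemistry-free InChIKey, so salt and parent forms
# (benzoate / benzoic acid) unify.
exclusion_key <- function(smiles) {
  inchikey(strip_stereo(neutralize(smiles)$smiles))
}

#' Desalting against the exclusion list (pipeline step 3)
#'
#' Drops components whose neutralized, stereo-stripped InChIKey is on the
#' exclusion list. The list only applies to multi-component records: a
#' substance that *is* a listed counterion (e.g. acetic acid registered on
#' its own) is retained.
#'
#' @param components Character vector of component SMILES (the components
#'   of one substance record).
#' @param config A [std_config()].
#' @param n_record Total component count of the original record (defaults
#'   to `length(components)`; pass the pre-classification count when some
#'   components were already removed as inorganic).
#' @return List with `retained` (character) and `dropped` (tibble with
#'   `smiles`, `class`, `retained`, `reason`).
#' @export
apply_exclusion <- function(components, config = std_config(),
                            n_record = length(components)) {
  dropped <- tibble::tibble(smiles = character(), class = character(),
                            retained = logical(), reason = character())
  if (n_record < 2L || length(components) == 0L) {
    return(list(retained = components, dropped = dropped))
  }
  keys <- exclusion_lookup(config$exclusion)
  comp_keys <- vapply(components, exclusion_key, character(1),
                      USE.NAMES = FALSE)
  hit <- comp_keys %in% keys$inchikey
  if (any(hit)) {
    labels <- keys$name[match(comp_keys[hit], keys$inchikey)]
    dropped <- tibble::tibble(
      smiles = components[hit],
      class = "excluded",
      retained = FALSE,
      reason = paste0("on exclusion list: ", labels)
    )
  }
  list(retained = components[!hit], dropped = dropped)
}

#' Tautomer and mesomer normalization (pipeline step 4)
#'
#' Applies a fixed, ordered rule set to a fixpoint (or `max_iter` passes):
#' nitro and azide mesomers to their charge-separated forms, acyclic
#' keto-enol and enamine-imine tautomers to the keto/imine forms, and
#' ynols to ketenes. Rules never touch ring double bonds (so phenols are
#' left alone) and never change the molecular formula; mesomer fixes move
#' formal charges only.
#'
#' @param smiles Component SMILES.
#' @param config A [std_config()].
#' @return Canonical SMILES of the normalized component. If the rule set
#'   has not converged after `max_iter` passes the last form is returned
#'   with a warning.
#' @export
normalize_tautomer <- function(smiles, config = std_config()) {
  mol <- smiles_to_mol(smiles)
  converged <- FALSE
  for (iter in seq_len(config$max_iter)) {
    out <- apply_first_transform(mol)
    if (is.null(out)) {
      converged <- TRUE
      break
    }
    mol <- out
  }
  if (!converged && !is.null(apply_first_transform(mol))) {
    warning("tautomer rules did not converge after ", config$max_iter,
            " passes for '", smiles, "'", call. = FALSE)
  }
  mol_to_smiles(mol)
}

# ordered rule set; returns modified mol or NULL when nothing matches
apply_first_transform <- function(mol) {
  for (rule in list(rule_nitro, rule_azide, rule_keto_enol,
                    rule_enamine_imine, rule_ynol_ketene)) {
    out <- rule(mol)
    if (!is.null(out)) return(out)
  }
  NULL
}

terminal_single_O <- function(mol, i) {
  # neighbors of atom i that are neutral OH oxygens (degree 1, single bond)
  deg <- atom_degree(mol)
  hits <- integer(0)
  for (k in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[k, ]
    j <- if (b$a1 == i) b$a2 else if (b$a2 == i) b$a1 else next
    if (b$order == 1L && mol$atoms$symbol[j] == "O" &&
        mol$atoms$charge[j] == 0L && deg[j] == 1L) {
      hits <- c(hits, k)
    }
  }
  hits
}

rule_nitro <- function(mol) {
  deg <- atom_degree(mol)
  for (i in which(mol$atoms$symbol == "N" & mol$atoms$charge == 0L)) {
    dbl_o <- which((mol$bonds$a1 == i | mol$bonds$a2 == i) &
                   mol$bonds$order == 2L)
    dbl_o <- dbl_o[vapply(dbl_o, function(k) {
      j <- if (mol$bonds$a1[k] == i) mol$bonds$a2[k] else mol$bonds$a1[k]
      mol$atoms$symbol[j] == "O" && mol$atoms$charge[j] == 0L && deg[j] == 1L
    }, logical(1))]
    if (length(dbl_o) >= 2L) {
      k <- dbl_o[1]
      j <- if (mol$bonds$a1[k] == i) mol$bonds$a2[k] else mol$bonds$a1[k]
      mol$bonds$order[k] <- 1L
      mol$atoms$charge[j] <- -1L
      mol$atoms$charge[i] <- 1L
      return(mol)
    }
  }
  NULL
}

rule_azide <- function(mol) {
  deg <- atom_degree(mol)
  imph <- implicit_h(mol)
  for (i in which(mol$atoms$symbol == "N" & mol$atoms$charge == 0L &
                  atom_degree(mol) == 2L)) {
    ks <- which(mol$bonds$a1 == i | mol$bonds$a2 == i)
    if (length(ks) != 2L) next
    js <- vapply(ks, function(k) {
      if (mol$bonds$a1[k] == i) mol$bonds$a2[k] else mol$bonds$a1[k]
    }, integer(1))
    if (!all(mol$atoms$symbol[js] == "N")) next
    if (sum(mol$bonds$order[ks]) < 4L) next
    # mesomer fix only: the terminal N must carry no hydrogen, or the
    # charge separation would change the composition
    term <- which(deg[js] == 1L & mol$atoms$charge[js] == 0L &
                  imph[js] == 0L)
    if (!length(term)) next
    t <- term[1]
    if (mol$bonds$order[ks[t]] == 3L) mol$bonds$order[ks[t]] <- 2L
    mol$atoms$charge[i] <- 1L
    mol$atoms$charge[js[t]] <- -1L
    return(mol)
  }
  NULL
}

rule_keto_enol <- function(mol) {
  inring <- ring_bonds(mol)
  for (k in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[k, ]
    if (b$order != 2L || inring[k]) next
    if (mol$atoms$symbol[b$a1] != "C" || mol$atoms$symbol[b$a2] != "C") next
    if (mol$atoms$charge[b$a1] != 0L || mol$atoms$charge[b$a2] != 0L) next
    for (enol_c in c(b$a1, b$a2)) {
      oh <- terminal_single_O(mol, enol_c)
      if (length(oh)) {
        mol$bonds$order[k] <- 1L
        mol$bonds$order[oh[1]] <- 2L
        return(mol)
      }
    }
  }
  NULL
}

rule_enamine_imine <- function(mol) {
  inring <- ring_bonds(mol)
  imph <- implicit_h(mol)
  for (k in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[k, ]
    if (b$order != 2L || inring[k]) next
    if (mol$atoms$symbol[b$a1] != "C" || mol$atoms$symbol[b$a2] != "C") next
    if (mol$atoms$charge[b$a1] != 0L || mol$atoms$charge[b$a2] != 0L) next
    for (en_c in c(b$a1, b$a2)) {
      for (kk in which((mol$bonds$a1 == en_c | mol$bonds$a2 == en_c) &
                       mol$bonds$order == 1L)) {
        j <- if (mol$bonds$a1[kk] == en_c) mol$bonds$a2[kk] else
          mol$bonds$a1[kk]
        if (mol$atoms$symbol[j] == "N" && mol$atoms$charge[j] == 0L &&
            imph[j] > 0L) {
          mol$bonds$order[k] <- 1L
          mol$bonds$order[kk] <- 2L
          return(mol)
        }
      }
    }
  }
  NULL
}

rule_ynol_ketene <- function(mol) {
  inring <- ring_bonds(mol)
  for (k in seq_len(nrow(mol$bonds))) {
    b <- mol$bonds[k, ]
    if (b$order != 3L || inring[k]) next
    if (mol$atoms$symbol[b$a1] != "C" || mol$atoms$symbol[b$a2] != "C") next
    for (yn_c in c(b$a1, b$a2)) {
      oh <- terminal_single_O(mol, yn_c)
      if (length(oh)) {
        mol$bonds$order[k] <- 2L
        mol$bonds$order[oh[1]] <- 2L
        return(mol)
      }
    }
  }
  NULL
}

#' Neutralization of charged structures (pipeline step 5)
#'
#' Protonatable anions (O-, S-, N-, P-) gain a hydrogen; deprotonatable
#' cations (N+, P+, O+, S+ carrying at least one H) lose one. Atoms
#' adjacent to an oppositely charged atom (the charge-separated nitro,
#' azide, N-oxide forms produced by the mesomer rules) are left alone.
#' Permanent charges (quaternary nitrogen, stabilized carbenium ions) are
#' retained and flagged.
#'
#' @param smiles Component SMILES.
#' @return List: `smiles` (canonical), `net_charge` (after
#'   neutralization), `permanent_charge` (TRUE when a nonzero net charge
#'   remains).
#' @examples
#' \donttest{
#' neutralize("[O-]S(=O)(=O)C(F)(F)F")$smiles
#' }
#' @export
neutralize <- function(smiles) {
  mol <- smiles_to_mol(smiles)
  bs <- bond_order_sum(mol)
  for (i in seq_len(nrow(mol$atoms))) {
    q <- mol$atoms$charge[i]
    if (q == 0L) next
    nb <- neighbors_of(mol, i)
    if (length(nb) && any(sign(mol$atoms$charge[nb]) == -sign(q))) next
    sym <- mol$atoms$symbol[i]
    if (q < 0L && sym %in% c("O", "S", "N", "P", "Se", "F", "Cl", "Br",
                             "I")) {
      mol$atoms$charge[i] <- q + 1L
    } else if (q > 0L && sym %in% c("N", "P", "O", "S")) {
      # only if there is a proton to remove under the charged valence
      cap <- switch(sym, N = 4L, P = 4L, O = 3L, S = 3L)
      if (cap - bs[i] > 0L) mol$atoms$charge[i] <- q - 1L
    }
  }
  net <- sum(mol$atoms$charge)
  list(smiles = mol_to_smiles(mol), net_charge = as.integer(net),
       permanent_charge = net != 0L)
}

#' Remove stereochemistry (pipeline step 5)
#'
#' Drops tetrahedral and double-bond stereo descriptors; isotopic labels
#' are retained (they change the monoisotopic mass, which matters for
#' MS). The InChIKey first block is unchanged by this operation.
#'
#' @param smiles Component SMILES.
#' @return Canonical stereochemistry-free SMILES.
#' @export
strip_stereo <- function(smiles) {
  smi <- canonical_smiles(smiles)
  smi <- gsub("[/\\\\@]", "", smi)
  canonical_smiles(smi)
}

#' Finalize a component (pipeline step 6)
#'
#' Perceives aromaticity, and attaches the Hill formula, standard
#' InChIKey and monoisotopic mass. SDF written from finalized components
#' (see [write_fixture()] and the CLI) carries explicit hydrogens.
#'
#' @param smiles Component SMILES.
#' @return One-row tibble: `smiles` (canonical aromatic form), `formula`,
#'   `inchikey`, `monoisotopic_mass`.
#' @export
finalize_component <- function(smiles) {
  smi <- canonical_smiles(smiles)
  f <- formula_of_smiles(smi)
  tibble::tibble(
    smiles = smi,
    formula = format(f),
    inchikey = inchikey(smi),
    monoisotopic_mass = monoisotopic_mass(f)
  )
}

#' Run the full MS-Ready preparation pipeline on one substance
#'
#' Pipeline order: consistency check, component split, classification,
#' exclusion-list desalting, then per component tautomer/mesomer
#' normalization, neutralization, stereo removal and finalization,
#' followed by within-substance InChIKey deduplication. In `qsarready`
#' mode organometallics are dropped and any record still holding more
#' than one distinct component is discarded as a mixture.
#'
#' @param smiles Raw substance SMILES (may be multi-component).
#' @param id Source identifier (used in statuses and error messages).
#' @param config A [std_config()].
#' @return An `msready_result`: list with `id`, `status`
#'   (`"ok"`/`"empty"`/`"error"`), `components` (tibble: `smiles`,
#'   `formula`, `inchikey`, `monoisotopic_mass`, `permanent_charge`) and
#'   `dropped` (tibble of component verdicts with reasons).
#' @examples
#' \donttest{
#' r <- standardize_substance("CN1CCC[C@@H]1c1cccnc1.Cl", id = "S1")
#' r$components$formula
#' }
#' @export
standardize_substance <- function(smiles, id = NA_character_,
                                  config = std_config()) {
  empty_components <- tibble::tibble(
    smiles = character(), formula = character(), inchikey = character(),
    monoisotopic_mass = numeric(), permanent_charge = logical()
  )
  res <- tryCatch({
    validated <- check_consistency(smiles)
    comps <- split_components(validated)
    verdicts <- dplyr::bind_rows(
      lapply(comps, classify_component, config = config)
    )
    dropped <- dplyr::filter(verdicts, !.data$retained)
    kept <- verdicts$smiles[verdicts$retained]
    excl <- apply_exclusion(kept, config, n_record = length(comps))
    dropped <- dplyr::bind_rows(dropped, excl$dropped)
    out <- empty_components
    for (s in excl$retained) {
      s1 <- normalize_tautomer(s, config)
      n1 <- neutralize(s1)
      s2 <- strip_stereo(n1$smiles)
      fin <- finalize_component(s2)
      fin$permanent_charge <- n1$permanent_charge
      out <- dplyr::bind_rows(out, fin)
    }
    out <- dplyr::distinct(out, .data$inchikey, .keep_all = TRUE)
    if (config$mode == "qsarready" && nrow(out) > 1L) {
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        smiles = out$smiles, class = "organic", retained = FALSE,
        reason = "mixture discarded in QSAR-Ready mode"
      ))
      out <- empty_components
    }
    status <- if (nrow(out) > 0L) "ok" else "empty"
    list(id = id, status = status, components = out, dropped = dropped,
         reason = NA_character_)
  }, error = function(e) {
    list(id = id, status = "error", components = empty_components,
         dropped = tibble::tibble(smiles = smiles, class = "error",
                                  retained = FALSE,
                                  reason = conditionMessage(e)),
         reason = conditionMessage(e))
  })
  structure(res, class = "msready_result")
}

#' @export
print.msready_result <- function(x, ...) {
  cat("<msready_result> id=", x$id, " status=", x$status, ", ",
      nrow(x$components), " component(s), ", nrow(x$dropped),
      " dropped\n", sep = "")
  invisible(x)
}

#' Standardize a table of substances
#'
#' Tidy, table-first entry point to [standardize_substance()]: one row in,
#' one row out, with the per-substance component and verdict tables as
#' list-columns ready for [tidyr::unnest()].
#'
#' @param data Data frame with at least a SMILES column.
#' @param config A [std_config()].
#' @param smiles_col,id_col Column names (strings) holding the structure
#'   and the substance identifier. When `id_col` is absent, row numbers
#'   are used.
#' @return A tibble: `id`, `status`, `n_components`, `components`
#'   (list-column of tibbles), `dropped` (list-column).
#' @examples
#' \donttest{
#' library(tibble)
#' tbl <- tibble(id = "nic", smiles = "CN1CCC[C@@H]1c1cccnc1.Cl")
#' standardize(tbl)
#' }
#' @export
standardize <- function(data, config = std_config(),
                        smiles_col = "smiles", id_col = "id") {
  stopifnot(is.data.frame(data), smiles_col %in% names(data))
  ids <- if (id_col %in% names(data)) {
    as.character(data[[id_col]])
  } else {
    as.character(seq_len(nrow(data)))
  }
  results <- purrr::map2(data[[smiles_col]], ids, standardize_substance,
                         config = config)
  tibble::tibble(
    id = ids,
    status = vapply(results, function(r) r$status, character(1)),
    n_components = vapply(results, function(r) nrow(r$components),
                          integer(1)),
    components = purrr::map(results, "components"),
    dropped = purrr::map(results, "dropped")
  )
}
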