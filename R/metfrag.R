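metfrag_default_fields <- c(
  "INPUT", "FOUND_BY", "DTXCID_INDIVIDUAL_COMPONENT",
  "FORMULA_INDIVIDUAL_COMPONENT", "SMILES_INDIVIDUAL_COMPONENT",
  "MAPPED_DTXSID", "PREFERRED_NAME_DTXSID", "CASRN_DTXSID",
  "FORMULA_MAPPED_DTXSID", "SMILES_MAPPED_DTXSID", "MS_READY_SMILES",
  "INCHI_STRING_DTXCID", "INCHIKEY_DTXCID", "MONOISOTOPIC_MASS_DTXCID"
)

#' Export search hits as a MetFrag-compatible candidate file
#'
#' One row per (query, component, substance) triple with the 14 default
#' columns in fixed order, then any selected numeric metadata columns.
#' The substance identifier column (`MAPPED_DTXSID`) is what MetFrag
#' treats as the candidate identifier, while the structural columns
#' (formula, SMILES, InChI, InChIKey, monoisotopic mass) describe the
#' individual MS-Ready component actually observed. Monoisotopic mass is
#' printed to 4 decimals. Output is byte-stable (UTF-8, LF endings,
#' RFC-4180 quoting); missing metadata is written as the empty string
#' (the "no data gives score 0" rule is applied at scoring time, not in
#' the file).
#'
#' @param hits Hit tibble from the search functions, or an already-built
#'   MetFrag row tibble (14 default columns present), which is written
#'   as-is.
#' @param registry The [msr_registry()] the hits came from (used for
#'   InChI strings, MS-Ready SMILES and metadata; not needed when `hits`
#'   is already in MetFrag form).
#' @param path Output file.
#' @param metadata Character vector of metadata field names to append
#'   (must exist in the registry's metadata table or as a hit/substance
#'   column; unknown names error, listing what is available).
#' @param delim `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
export_metfrag <- function(hits, registry = NULL, path,
                           metadata = character(), delim = ",") {
  rows <- if (all(metfrag_default_fields %in% names(hits))) {
    hits
  } else {
    metfrag_rows(hits, registry, metadata)
  }
  readr::write_delim(rows, path, delim = delim, na = "", quote = "needed",
                     escape = "double", eol = "\n")
  invisible(path)
}

metfrag_rows <- function(hits, registry, metadata = character()) {
  stopifnot(inherits(registry, "msr_registry"))
  chem <- registry$chemicals
  available <- setdiff(
    unique(c(names(registry$metadata), "data_sources")), "sid"
  )
  unknown <- setdiff(metadata, available)
  if (length(unknown)) {
    stop("unknown metadata field(s) ", paste(unknown, collapse = ", "),
         "; available: ", paste(available, collapse = ", "),
         call. = FALSE)
  }
  msready_smiles <- vapply(hits$sid, function(sid) {
    cids <- registry$mappings$from_id[
      registry$mappings$to_id == sid &
      registry$mappings$relation == "component_of"
    ]
    paste(chem$smiles[match(cids, chem$cid)], collapse = ".")
  }, character(1))
  idx <- match(hits$cid, chem$cid)
  rows <- tibble::tibble(
    INPUT = as.character(hits$input),
    FOUND_BY = hits$found_by,
    DTXCID_INDIVIDUAL_COMPONENT = hits$cid,
    FORMULA_INDIVIDUAL_COMPONENT = hits$component_formula,
    SMILES_INDIVIDUAL_COMPONENT = hits$component_smiles,
    MAPPED_DTXSID = hits$sid,
    PREFERRED_NAME_DTXSID = hits$name,
    CASRN_DTXSID = hits$cas,
    FORMULA_MAPPED_DTXSID = hits$substance_formula,
    SMILES_MAPPED_DTXSID = hits$substance_smiles,
    MS_READY_SMILES = msready_smiles,
    INCHI_STRING_DTXCID = {
      s <- hits$component_smiles
      out <- rep(NA_character_, length(s))
      if (any(!is.na(s))) out[!is.na(s)] <- inchi(s[!is.na(s)])
      out
    },
    INCHIKEY_DTXCID = chem$inchikey[idx],
    MONOISOTOPIC_MASS_DTXCID = ifelse(
      is.na(hits$component_mass), "",
      formatC(round(hits$component_mass, 4), format = "f", digits = 4))
  )
  for (field in metadata) {
    vals <- if (field %in% names(registry$metadata)) {
      registry$metadata[[field]][match(hits$sid, registry$metadata$sid)]
    } else {
      registry$substances[[field]][
        match(hits$sid, registry$substances$sid)]
    }
    rows[[field]] <- ifelse(is.na(vals), "", as.character(vals))
  }
  rows
}

#' Read a MetFrag candidate file back
#'
#' Parses a file written by [export_metfrag()] (or equivalent). All
#' columns come back as character so that an export/read/export round
#' trip is byte-identical; optional metadata columns may appear in any
#' order after the 14 defaults.
#'
#' @param path Candidate file.
#' @param delim `","` or `"\t"`.
#' @return Tibble of candidate rows.
#' @export
read_metfrag <- function(path, delim = ",") {
  rows <- readr::read_delim(path, delim = delim, na = character(),
                            col_types = readr::cols(
                              .default = readr::col_character()),
                            show_col_types = FALSE)
  missing <- setdiff(metfrag_default_fields, names(rows))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows
}
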