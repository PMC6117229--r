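# Bundled default exclusion (salt/solvent) lists. These are synthetic
# stand-ins curated from counterions and solvents commonly stripped
# during structure preparation; the originally published lists can be
# supplied verbatim via read_exclusion_sdf() and plugged into
# std_config(exclusion = ...). The MS-Ready list is deliberately small so
# that MS-observable secondary components (benzoate, fumarate, citrate,
# ...) survive desalting and stay linked to their substances; the
# QSAR-Ready list is a strict superset that also strips those.

.msready_exclusion <- tibble::tibble(
  name = c(
    "hydrochloric acid", "hydrobromic acid", "hydroiodic acid",
    "hydrofluoric acid", "sulfuric acid", "nitric acid",
    "phosphoric acid", "perchloric acid", "carbonic acid", "water",
    "hydrogen peroxide", "ammonia", "sodium", "potassium", "lithium",
    "calcium", "magnesium", "zinc", "acetic acid", "formic acid",
    "trifluoroacetic acid", "methanesulfonic acid",
    "p-toluenesulfonic acid", "benzenesulfonic acid", "methanol",
    "ethanol", "2-propanol", "acetonitrile", "dimethyl sulfoxide",
    "diethyl ether", "ethyl acetate", "dichloromethane"
  ),
  smiles = c(
    "Cl", "Br", "I", "F", "OS(=O)(=O)O", "O[N+]([O-])=O", "OP(=O)(O)O",
    "OCl(=O)(=O)=O", "OC(=O)O", "O", "OO", "N", "[Na+]", "[K+]", "[Li+]",
    "[Ca+2]", "[Mg+2]", "[Zn+2]", "CC(=O)O", "OC=O", "OC(=O)C(F)(F)F",
    "CS(=O)(=O)O", "Cc1ccc(cc1)S(=O)(=O)O", "OS(=O)(=O)c1ccccc1", "CO",
    "CCO", "CC(C)O", "CC#N", "CS(C)=O", "CCOCC", "CCOC(C)=O", "ClCCl"
  )
)

.qsarready_extra <- tibble::tibble(
  name = c(
    "benzoic acid", "fumaric acid", "maleic acid", "citric acid",
    "tartaric acid", "succinic acid", "salicylic acid", "lactic acid",
    "malic acid", "oxalic acid", "malonic acid", "glutaric acid",
    "adipic acid", "gluconic acid", "ascorbic acid", "stearic acid",
    "palmitic acid", "pamoic acid precursor (3-hydroxy-2-naphthoic acid)",
    "gentisic acid", "hippuric acid", "mandelic acid", "cinnamic acid",
    "camphorsulfonic acid", "ethanesulfonic acid",
    "1,2-ethanedisulfonic acid", "naphthalene-2-sulfonic acid",
    "saccharin", "triethylamine", "diethylamine", "ethanolamine",
    "diethanolamine", "triethanolamine", "tromethamine", "pyridine",
    "piperazine", "morpholine", "benzylamine", "tetrahydrofuran",
    "1,4-dioxane", "N,N-dimethylformamide", "acetone", "toluene",
    "benzene", "n-hexane", "chloroform", "ammonium chloride leftover",
    "hydrogen sulfide", "boric acid", "thiocyanic acid", "cyanide"
  ),
  smiles = c(
    "OC(=O)c1ccccc1", "OC(=O)/C=C/C(=O)O", "OC(=O)/C=C\\C(=O)O",
    "OC(=O)CC(O)(CC(=O)O)C(=O)O", "OC(C(O)C(=O)O)C(=O)O",
    "OC(=O)CCC(=O)O", "OC(=O)c1ccccc1O", "CC(O)C(=O)O",
    "OC(CC(=O)O)C(=O)O", "OC(=O)C(=O)O", "OC(=O)CC(=O)O",
    "OC(=O)CCCC(=O)O", "OC(=O)CCCCC(=O)O", "OCC(O)C(O)C(O)C(O)C(=O)O",
    "OCC(O)C1OC(=O)C(=C1O)O", "CCCCCCCCCCCCCCCCCC(=O)O",
    "CCCCCCCCCCCCCCCC(=O)O", "OC(=O)c1cc2ccccc2cc1O",
    "OC(=O)c1cc(O)ccc1O", "OC(=O)CNC(=O)c1ccccc1", "OC(C(=O)O)c1ccccc1",
    "OC(=O)/C=C/c1ccccc1", "CC1(C)C2CCC1(CS(=O)(=O)O)C(=O)C2",
    "CCS(=O)(=O)O", "OS(=O)(=O)CCS(=O)(=O)O", "OS(=O)(=O)c1ccc2ccccc2c1",
    "O=C1NS(=O)(=O)c2ccccc12", "CCN(CC)CC", "CCNCC", "NCCO",
    "OCCNCCO", "OCCN(CCO)CCO", "NC(CO)(CO)CO", "c1ccncc1", "C1CNCCN1",
    "C1COCCN1", "NCc1ccccc1", "C1CCOC1", "C1COCCO1", "CN(C)C=O",
    "CC(C)=O", "Cc1ccccc1", "c1ccccc1", "CCCCCC", "ClC(Cl)Cl", "[Cl-]",
    "S", "OB(O)O", "SC#N", "[C-]#N"
  )
)

.msr_cache <- new.env(parent = emptyenv())

#' Default exclusion lists
#'
#' The bundled desalting lists: a 32-entry MS-Ready list of counterions,
#' mineral acids and solvents, and a larger QSAR-Ready superset that also
#' strips organic-acid and amine counterions. Both are synthetic
#' stand-ins (see `inst/extdata/` for the SDF renditions); externally
#' supplied lists can be loaded with [read_exclusion_sdf()].
#'
#' @param mode `"msready"` or `"qsarready"`.
#' @return Tibble with `name`, `smiles`.
#' @examples
#' nrow(default_exclusion_list("msready"))
#' @export
default_exclusion_list <- function(mode = c("msready", "qsarready")) {
  mode <- match.arg(mode)
  if (mode == "msready") {
    .msready_exclusion
  } else {
    dplyr::bind_rows(.msready_exclusion, .qsarready_extra)
  }
}

# exclusion table with the matching InChIKey column attached (cached)
exclusion_lookup <- function(exclusion) {
  stopifnot(is.data.frame(exclusion), all(c("name", "smiles") %in%
                                          names(exclusion)))
  if ("inchikey" %in% names(exclusion)) return(exclusion)
  key <- rlang::hash(exclusion$smiles)
  hit <- .msr_cache[[key]]
  if (!is.null(hit)) return(hit)
  exclusion$inchikey <- vapply(exclusion$smiles, exclusion_key,
                               character(1), USE.NAMES = FALSE)
  .msr_cache[[key]] <- exclusion
  exclusion
}

#' Read an exclusion list from an SDF file
#'
#' Accepts an SDF whose records carry a label in a data field (any of
#' `name`, `NAME`, `Name`, `LABEL`, `label`; falling back to the molfile
#' title line, then to the canonical SMILES).
#'
#' @param path SDF file path.
#' @return Tibble with `name`, `smiles` usable in
#'   [std_config()]`$exclusion`.
#' @export
read_exclusion_sdf <- function(path) {
  recs <- read_sdf_records(path)
  tibble::tibble(
    name = vapply(recs, function(r) {
      lbl <- r$fields[["name"]] %||% r$fields[["NAME"]] %||%
        r$fields[["Name"]] %||% r$fields[["LABEL"]] %||%
        r$fields[["label"]] %||% r$title
      if (is.null(lbl) || !nzchar(lbl)) r$smiles else lbl
    }, character(1)),
    smiles = vapply(recs, function(r) r$smiles, character(1))
  )
}

#' Write an exclusion list to an SDF file
#'
#' @param exclusion Tibble with `name`, `smiles`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_sdf <- function(exclusion, path) {
  write_sdf_records(exclusion$smiles, path,
                    titles = exclusion$name,
                    fields = list(name = exclusion$name),
                    explicit_h = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
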