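# Thin wrappers around the OpenBabel toolkit (via ChemmineOB). All SMILES
# crossing a package boundary are canonicalized here; all InChI/InChIKey
# generation happens here.

ob_convert <- function(from, to, text, options = NULL) {
  if (is.null(options)) {
    out <- ChemmineOB::convertFormat(from, to, text)
  } else {
    out <- ChemmineOB::convertFormat(from, to, text, options = options)
  }
  out
}

strip_smiles_line <- function(x) {
  # OpenBabel SMILES output is "smiles\ttitle\n"
  x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  x <- x[nzchar(trimws(x))]
  vapply(x, function(line) trimws(strsplit(line, "\t", fixed = TRUE)[[1]][1]),
         character(1), USE.NAMES = FALSE)
}

#' Parse and canonicalize a SMILES string
#'
#' @param smiles Single SMILES string.
#' @return Canonical (aromatic, lowercase-ring) SMILES.
#' @keywords internal
canonical_smiles <- function(smiles) {
  out <- ob_convert("SMI", "CAN", paste0(smiles, "\n"))
  out <- strip_smiles_line(out)
  if (length(out) != 1L || !nzchar(out)) {
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  }
  out
}

# InChI/InChIKey generation goes through the OpenBabel executable in a
# single batched call per vector (titles carry the input index, so
# failed records are identified reliably). The in-process route does not
# return the stereo layers of the standard InChI correctly, and keys
# must be stereo-faithful: stereoisomer originals may never collapse to
# one chemical at registration.
ob_cli_inchi <- function(smiles, key = TRUE) {
  if (length(smiles) == 0L) return(character(0))
  exe <- Sys.which("obabel")
  if (!nzchar(exe)) {
    stop("the 'obabel' executable is required for InChI generation ",
         "but was not found on the PATH", call. = FALSE)
  }
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)))
  writeLines(paste(smiles, paste0("m", seq_along(smiles))), fin)
  args <- c(fin, "-oinchi", "-xt", if (key) "-xK", "-O", fout)
  suppressWarnings(system2(exe, args, stdout = FALSE, stderr = FALSE))
  out <- if (file.exists(fout)) readLines(fout, warn = FALSE) else
    character(0)
  res <- rep(NA_character_, length(smiles))
  if (length(out)) {
    sp <- regmatches(out, regexec("^(\\S+) m([0-9]+)$", out))
    for (s in sp) {
      if (length(s) == 3L) res[as.integer(s[3])] <- s[2]
    }
  }
  res
}

#' Standard InChI and InChIKey of a structure
#'
#' Generates the standard InChI v1 key (27 characters,
#' `XXXXXXXXXXXXXX-YYYYYYYYFV-P`). Deterministic for identical structures;
#' stereoisomers share the 14-character first block.
#'
#' @param structure SMILES string(s) (or a tibble with a `smiles` column,
#'   as produced by the standardizer).
#' @param id Optional source identifier(s) used in error messages.
#' @return `inchikey()`: the 27-character key(s); `inchi()`: the InChI
#'   string(s).
#' @examples
#' \donttest{
#' inchikey("c1ccccc1")
#' }
#' @export
inchikey <- function(structure, id = NULL) {
  smiles <- if (is.data.frame(structure)) structure$smiles else structure
  out <- ob_cli_inchi(smiles, key = TRUE)
  bad <- is.na(out) | !grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", out)
  if (any(bad)) {
    stop("could not generate InChIKey",
         if (!is.null(id)) paste0(" for record '", id[bad][1], "'"),
         ": '", smiles[bad][1], "'", call. = FALSE)
  }
  out
}

#' @rdname inchikey
#' @export
inchi <- function(structure, id = NULL) {
  smiles <- if (is.data.frame(structure)) structure$smiles else structure
  out <- ob_cli_inchi(smiles, key = FALSE)
  bad <- is.na(out) | !startsWith(out, "InChI=")
  if (any(bad)) {
    stop("could not generate InChI",
         if (!is.null(id)) paste0(" for record '", id[bad][1], "'"),
         ": '", smiles[bad][1], "'", call. = FALSE)
  }
  out
}

#' First block of an InChIKey
#'
#' The 14-character connectivity-skeleton hash preceding the first hyphen,
#' used to group candidates that share a skeleton (stereoisomers,
#' charge/protonation variants).
#'
#' @param key A 27-character standard InChIKey (vectorized).
#' @return 14-character first block(s).
#' @examples
#' first_block("UHOVQNZJYSORNB-UHFFFAOYSA-N")
#' @export
first_block <- function(key) {
  ok <- grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", key)
  if (any(!ok)) {
    stop("malformed InChIKey: '", key[!ok][1], "'", call. = FALSE)
  }
  substr(key, 1, 14)
}

#' Molecular formula of a structure
#'
#' @param smiles SMILES string.
#' @return An `ms_formula` (single part; trailing-sign charges from the
#'   toolkit's formula string are parsed).
#' @keywords internal
formula_of_smiles <- function(smiles) {
  mol <- suppressWarnings(
    ChemmineOB::forEachMol("SMILES", paste0(smiles, "\n"), identity)
  )
  props <- ChemmineOB::prop_OB(mol)
  f <- props$formula[1]
  if (is.null(f) || is.na(f) || !nzchar(f)) {
    stop("could not compute formula for '", smiles, "'", call. = FALSE)
  }
  parse_formula(f)
}
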