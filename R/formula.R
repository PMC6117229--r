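#' Molecular formula objects
#'
#' A molecular formula is one or more dot-separated parts (as in salt or
#' mixture formulas such as `C31H42N3.C2H3O2`), each part an element->count
#' map with an integer formal charge. Charges are written as trailing signs
#' (`C8F17O3S-`); both the `2-` and `--` dialects and the Unicode minus
#' are accepted on input.
#'
#' @param text Formula string, e.g. `"C9H16ClN5"`, `"C8F17O3S-"`,
#'   `"C31H42N3.C2H3O2"`.
#' @return An object of class `ms_formula`: a list with `parts` (each a
#'   list with integer vector `counts` and integer `charge`).
#' @examples
#' parse_formula("C9H16ClN5")
#' parse_formula("C8F17O3S-")
#' @export
parse_formula <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("empty formula string", call. = FALSE)
  }
  text <- trimws(text)
  # normalize unicode minus/middle-dot dialects
  text <- gsub("\u2212", "-", text)
  text <- gsub("\u00b7", ".", text)
  part_texts <- strsplit(text, ".", fixed = TRUE)[[1]]
  if (length(part_texts) == 0L || any(!nzchar(part_texts))) {
    stop("malformed formula (empty part): '", text, "'", call. = FALSE)
  }
  parts <- lapply(part_texts, parse_formula_part)
  new_ms_formula(parts)
}

new_ms_formula <- function(parts) {
  structure(list(parts = parts), class = "ms_formula")
}

# Trailing-charge dialects accepted: repeated signs ("--"), sign then
# digits ("-2"), superscript-style digit(s) then one sign ("2-", "^2-").
# A single digit directly before a lone sign is ambiguous in plain text
# (NH4+ vs Ca2+): it binds to the charge only for a monatomic metal ion,
# otherwise to the last element.
parse_formula_part <- function(txt) {
  txt <- gsub("^", "", txt, fixed = TRUE)
  charge <- 0L
  m2 <- regmatches(txt, regexec("^(.+?)([+-])([0-9]+)$", txt))[[1]]
  m <- regmatches(txt, regexec("^(.*?)([+-]+)$", txt))[[1]]
  if (length(m2) == 4L) {
    # sign-then-digit dialect, e.g. "Fe+3"
    charge <- (if (m2[3] == "+") 1L else -1L) * as.integer(m2[4])
    txt <- m2[2]
  } else if (length(m) == 3L) {
    signs <- strsplit(m[3], "")[[1]]
    if (length(unique(signs)) > 1L) {
      stop("malformed charge in formula part: '", txt, "'", call. = FALSE)
    }
    sgn <- if (signs[1] == "+") 1L else -1L
    body <- m[2]
    digits <- sub("^.*?([0-9]*)$", "\\1", body)
    stem <- substr(body, 1, nchar(body) - nchar(digits))
    if (length(signs) > 1L || !nzchar(digits)) {
      # "--" dialect, or no digit in play: digits (if any) are counts
      charge <- sgn * length(signs)
      txt <- body
    } else if (nchar(digits) >= 2L) {
      # e.g. "SO42-": last digit is the charge, the rest the count
      charge <- sgn * as.integer(substr(digits, nchar(digits),
                                        nchar(digits)))
      txt <- paste0(stem, substr(digits, 1, nchar(digits) - 1L))
    } else if (grepl("[A-Z][a-z]?$", stem) &&
               is_metal(sub("^.*?([A-Z][a-z]?)$", "\\1", stem)) &&
               grepl("^[A-Z][a-z]?$", stem)) {
      # monatomic metal ion, e.g. "Ca2+", "Fe3+"
      charge <- sgn * as.integer(digits)
      txt <- stem
    } else {
      # e.g. "NH4+": the digit binds to the element
      charge <- sgn
      txt <- body
    }
  }
  if (!nzchar(txt)) {
    stop("formula part has a charge but no elements", call. = FALSE)
  }
  pieces <- regmatches(txt, gregexpr("[A-Z][a-z]?[0-9]*", txt))[[1]]
  if (length(pieces) == 0L || sum(nchar(pieces)) != nchar(txt)) {
    stop("malformed formula token in '", txt, "'", call. = FALSE)
  }
  counts <- integer(0)
  for (p in pieces) {
    sym <- sub("[0-9]*$", "", p)
    num <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(.element_masses)) {
      stop("unknown element symbol '", sym, "' in formula '", txt, "'",
           call. = FALSE)
    }
    if (n <= 0L) {
      stop("element count must be positive: '", p, "'", call. = FALSE)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  list(counts = counts, charge = charge)
}

#' @rdname parse_formula
#' @param x Object to coerce/test.
#' @export
as_formula <- function(x) {
  if (inherits(x, "ms_formula")) return(x)
  parse_formula(as.character(x))
}

#' @rdname parse_formula
#' @export
is_formula <- function(x) inherits(x, "ms_formula")

hill_order <- function(counts) {
  syms <- names(counts)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms)
  }
  counts[ord]
}

format_part <- function(part) {
  counts <- hill_order(part$counts)
  body <- paste0(names(counts), ifelse(counts > 1L, counts, ""),
                 collapse = "")
  q <- part$charge
  suffix <- if (q == 0L) {
    ""
  } else if (abs(q) == 1L) {
    if (q > 0L) "+" else "-"
  } else {
    paste0(abs(q), if (q > 0L) "+" else "-")
  }
  paste0(body, suffix)
}

#' @export
format.ms_formula <- function(x, ...) {
  paste(vapply(x$parts, format_part, character(1)), collapse = ".")
}

#' @export
print.ms_formula <- function(x, ...) {
  cat("<formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.ms_formula` <- function(e1, e2) {
  identical(format(canonical_formula(as_formula(e1))),
            format(canonical_formula(as_formula(e2))))
}

# sort parts so equality/dedup ignores part order
canonical_formula <- function(f) {
  keys <- vapply(f$parts, format_part, character(1))
  new_ms_formula(f$parts[order(keys)])
}

#' Net charge and totals of a formula
#'
#' @param formula An `ms_formula` or formula string.
#' @return `formula_charge()` the net charge summed over parts;
#'   `formula_counts()` a single named integer vector summed over parts.
#' @export
formula_charge <- function(formula) {
  f <- as_formula(formula)
  sum(vapply(f$parts, function(p) p$charge, integer(1)))
}

#' @rdname formula_charge
#' @export
formula_counts <- function(formula) {
  f <- as_formula(formula)
  out <- integer(0)
  for (p in f$parts) {
    for (sym in names(p$counts)) {
      out[sym] <- (if (sym %in% names(out)) out[[sym]] else 0L) +
        p$counts[[sym]]
    }
  }
  hill_order(out)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum over all parts of count x most-abundant-isotope mass, minus
#' net charge x electron mass (an ion is lighter than its neutral form by
#' one electron mass per positive charge).
#'
#' @param formula An `ms_formula` object or formula string.
#' @return Mass in Da at full precision. Use [display_mass()] for the
#'   conventional 4-decimal display.
#' @examples
#' monoisotopic_mass("C9H16ClN5")  # 229.1094
#' @export
monoisotopic_mass <- function(formula) {
  f <- as_formula(formula)
  total <- 0
  for (p in f$parts) {
    if (length(p$counts)) {
      total <- total + sum(.element_masses[names(p$counts)] * p$counts)
    }
  }
  total - formula_charge(f) * .electron_mass
}

#' @rdname monoisotopic_mass
#' @param mass Numeric mass in Da.
#' @export
display_mass <- function(mass) {
  formatC(round(mass, 4), format = "f", digits = 4)
}

#' m/z of a pseudomolecular ion
#'
#' Computes the m/z observed for a neutral formula under an adduct, or for
#' an intrinsically charged formula (`kind = "M"`). The electron mass is
#' accounted for: `[M+H]+` adds a proton (not a hydrogen atom), and an
#' intrinsic ion of charge q weighs q electron masses less than the same
#' atom count at charge 0.
#'
#' @param formula `ms_formula` or string.
#' @param kind One of `"M"`, `"M+H"`, `"M-H"` (Unicode minus accepted).
#' @return m/z in Da (|z| = 1 throughout).
#' @examples
#' adduct_mz("C14H19N3S", "M+H")  # 262.1372
#' @export
adduct_mz <- function(formula, kind = c("M", "M+H", "M-H")) {
  f <- as_formula(formula)
  kind <- gsub("\u2212", "-", kind)
  kind <- match.arg(kind)
  q <- formula_charge(f)
  if (kind == "M+H") {
    if (q != 0L) stop("M+H applies to a neutral formula", call. = FALSE)
    monoisotopic_mass(f) + .proton_mass
  } else if (kind == "M-H") {
    if (q != 0L) stop("M-H applies to a neutral formula", call. = FALSE)
    monoisotopic_mass(f) - .proton_mass
  } else {
    if (abs(q) > 1L) {
      stop("multiply charged ions are not supported (|z| must be <= 1)",
           call. = FALSE)
    }
    # monoisotopic_mass is already electron-corrected for intrinsic ions
    monoisotopic_mass(f)
  }
}

#' Neutralize a formula by proton transfer
#'
#' Converts a charged formula to the neutral form an HRMS analyst would
#' search: one H is added per negative charge and removed per positive
#' charge (e.g. the PFOS sulfonate `C8F17O3S-` becomes the neutral acid
#' `C8HF17O3S`).
#'
#' @param formula `ms_formula` or string.
#' @return Neutral `ms_formula`.
#' @export
neutralize_formula <- function(formula) {
  f <- as_formula(formula)
  parts <- lapply(f$parts, function(p) {
    q <- p$charge
    if (q == 0L) return(p)
    h <- if ("H" %in% names(p$counts)) p$counts[["H"]] else 0L
    h2 <- h - q
    if (h2 < 0L) {
      stop("cannot neutralize part '", format_part(p),
           "': not enough hydrogens to remove", call. = FALSE)
    }
    counts <- p$counts
    if (h2 == 0L) {
      counts <- counts[names(counts) != "H"]
    } else {
      counts["H"] <- h2
    }
    list(counts = counts, charge = 0L)
  })
  new_ms_formula(parts)
}
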