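# Internal connection-table layer: a parsed V2000 molfile as a pair of
# tibbles that the standardization rules can edit in place (formal
# charges, bond orders) before handing the block back to OpenBabel.
# Coordinates and wedge/ring-bond stereo flags are carried through
# untouched so stereochemistry survives a round trip until the dedicated
# stereo-stripping step.

msr_mol <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "msr_mol")
}

#' @export
print.msr_mol <- function(x, ...) {
  cat("<mol> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds\n",
      sep = "")
  invisible(x)
}

parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("truncated molfile", call. = FALSE)
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || natoms < 1L) {
    stop("molfile has no atoms", call. = FALSE)
  }
  at <- lines[5:(4 + natoms)]
  atoms <- tibble::tibble(
    x = as.numeric(substr(at, 1, 10)),
    y = as.numeric(substr(at, 11, 20)),
    z = as.numeric(substr(at, 21, 30)),
    symbol = trimws(substr(at, 32, 34)),
    charge = 0L,
    iso = 0L
  )
  if (nbonds > 0L) {
    bd <- lines[(5 + natoms):(4 + natoms + nbonds)]
    bonds <- tibble::tibble(
      a1 = as.integer(substr(bd, 1, 3)),
      a2 = as.integer(substr(bd, 4, 6)),
      order = as.integer(substr(bd, 7, 9)),
      stereo = {
        s <- suppressWarnings(as.integer(substr(bd, 10, 12)))
        ifelse(is.na(s), 0L, s)
      }
    )
  } else {
    bonds <- tibble::tibble(a1 = integer(), a2 = integer(),
                            order = integer(), stereo = integer())
  }
  for (line in lines[-seq_len(4 + natoms + nbonds)]) {
    if (startsWith(line, "M  END")) break
    if (startsWith(line, "M  CHG") || startsWith(line, "M  ISO")) {
      kind <- substr(line, 4, 6)
      n <- as.integer(substr(line, 7, 9))
      for (k in seq_len(n)) {
        off <- 10 + (k - 1) * 8
        idx <- as.integer(substr(line, off, off + 3))
        val <- as.integer(substr(line, off + 4, off + 7))
        if (kind == "CHG") atoms$charge[idx] <- val
        if (kind == "ISO") atoms$iso[idx] <- val
      }
    }
  }
  msr_mol(atoms, bonds)
}

write_molblock <- function(mol, title = "") {
  atoms <- mol$atoms
  bonds <- mol$bonds
  out <- c(
    title,
    " msready           2D",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            nrow(atoms), nrow(bonds))
  )
  out <- c(out, sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    atoms$x, atoms$y, atoms$z, atoms$symbol
  ))
  if (nrow(bonds) > 0L) {
    out <- c(out, sprintf("%3d%3d%3d%3d  0  0  0",
                          bonds$a1, bonds$a2, bonds$order, bonds$stereo))
  }
  prop_line <- function(kind, idx, val) {
    pieces <- split(seq_along(idx), ceiling(seq_along(idx) / 8))
    vapply(pieces, function(p) {
      paste0(sprintf("M  %s%3d", kind, length(p)),
             paste0(sprintf("%4d%4d", idx[p], val[p]), collapse = ""))
    }, character(1))
  }
  chg <- which(atoms$charge != 0L)
  if (length(chg)) out <- c(out, prop_line("CHG", chg, atoms$charge[chg]))
  iso <- which(atoms$iso != 0L)
  if (length(iso)) out <- c(out, prop_line("ISO", iso, atoms$iso[iso]))
  out <- c(out, "M  END", "$$$$")
  paste0(paste(out, collapse = "\n"), "\n")
}

smiles_to_mol <- function(smiles) {
  sdf <- suppressWarnings(ob_convert("SMI", "SDF", paste0(smiles, "\n")))
  if (!nzchar(trimws(sdf)) || !grepl("V2000", sdf, fixed = TRUE)) {
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  }
  parse_molblock(sdf)
}

mol_to_smiles <- function(mol, canonical = TRUE) {
  out <- suppressWarnings(
    ob_convert("SDF", if (canonical) "CAN" else "SMI", write_molblock(mol))
  )
  out <- strip_smiles_line(out)
  if (length(out) != 1L || !nzchar(out)) {
    stop("could not regenerate SMILES from connection table", call. = FALSE)
  }
  out
}

# bond-order sum per atom (explicit bonds only)
bond_order_sum <- function(mol) {
  s <- numeric(nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      b <- mol$bonds[i, ]
      s[b$a1] <- s[b$a1] + b$order
      s[b$a2] <- s[b$a2] + b$order
    }
  }
  s
}

atom_degree <- function(mol) {
  d <- integer(nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    tab <- table(c(mol$bonds$a1, mol$bonds$a2))
    d[as.integer(names(tab))] <- as.integer(tab)
  }
  d
}

neighbors_of <- function(mol, i) {
  c(mol$bonds$a2[mol$bonds$a1 == i], mol$bonds$a1[mol$bonds$a2 == i])
}

# standard-valence implicit hydrogen count (organic subset; metals 0)
implicit_h <- function(mol) {
  bs <- bond_order_sum(mol)
  vapply(seq_len(nrow(mol$atoms)), function(i) {
    sym <- mol$atoms$symbol[i]
    q <- mol$atoms$charge[i]
    val <- switch(sym,
      C = 4L - abs(q),
      N = if (q > 0L) 4L else 3L + q,
      P = if (q > 0L) 4L else 3L + q,
      O = 2L + q,
      S = if (q > 0L) 3L else if (q < 0L) 1L else 2L,
      Se = if (q > 0L) 3L else if (q < 0L) 1L else 2L,
      B = 3L - q,
      F = , Cl = , Br = , I = max(0L, 1L + q),
      0L
    )
    max(0L, as.integer(val) - as.integer(bs[i]))
  }, integer(1))
}

# maximum plausible explicit valence; used by check_consistency.
# Hypervalent-nitrogen drawings (N(=O)=O) are allowed here because the
# mesomer rules convert them to charge-separated form downstream.
max_valence <- function(sym, q) {
  switch(sym,
    C = 4L - abs(q),
    N = if (q > 0L) 4L else 5L + q,
    P = 6L,
    O = 2L + q + (q < 0L) * 0L,
    S = 6L,
    Se = 6L,
    B = 4L - q,
    Si = 6L,
    F = max(0L, 1L + q),
    Cl = , Br = , I = 7L,
    H = 1L,
    NA_integer_  # metals and the rest: unchecked
  )
}

# which bonds are in rings (i.e., not bridges of the molecular graph)
ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(logical(0))
  g <- igraph::graph_from_edgelist(
    cbind(mol$bonds$a1, mol$bonds$a2), directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, nrow(mol$atoms) - igraph::vcount(g)))
  br <- igraph::bridges(g)
  in_ring <- rep(TRUE, nb)
  in_ring[as.integer(br)] <- FALSE
  in_ring
}

# connected components as separate mols, original atom indices attached
mol_components <- function(mol) {
  n <- nrow(mol$atoms)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(mol$bonds)) {
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  }
  memb <- igraph::components(g)$membership
  lapply(unique(memb), function(m) {
    idx <- which(memb == m)
    remap <- integer(n)
    remap[idx] <- seq_along(idx)
    keep <- mol$bonds$a1 %in% idx
    bonds <- mol$bonds[keep, , drop = FALSE]
    bonds$a1 <- remap[bonds$a1]
    bonds$a2 <- remap[bonds$a2]
    msr_mol(mol$atoms[idx, , drop = FALSE], bonds)
  })
}
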