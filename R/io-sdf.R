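# SDF record I/O. All connection-table chemistry goes through OpenBabel;
# writing pins the program/timestamp line so identical inputs give
# identical bytes.

# Records are split at the $$$$ terminators and each connection table is
# converted by OpenBabel; data fields are taken from the "> <name>"
# blocks. (ChemmineR's SDFset round trip rejects monoatomic, zero-bond
# records such as [Na+] or water, which are legitimate exclusion-list
# entries, so the record handling is done here.) Records whose
# connection table OpenBabel cannot convert are dropped.
read_sdf_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) return(list())
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- lapply(seq_along(ends), function(i) {
    rec <- lines[starts[i]:ends[i]]
    m_end <- which(startsWith(rec, "M  END"))[1]
    if (is.na(m_end)) return(NULL)
    block <- paste0(paste(c(rec[seq_len(m_end)], "$$$$"),
                          collapse = "\n"), "\n")
    smi <- tryCatch(
      strip_smiles_line(suppressWarnings(ob_convert("SDF", "CAN", block))),
      error = function(e) character(0))
    if (length(smi) != 1L || !nzchar(smi)) return(NULL)
    fields <- list()
    tail_lines <- rec[-seq_len(m_end)]
    tag_at <- grep("^>", tail_lines)
    for (t in tag_at) {
      nm <- sub("^>\\s*<([^>]*)>.*$", "\\1", tail_lines[t])
      val_end <- t
      while (val_end < length(tail_lines) &&
             nzchar(trimws(tail_lines[val_end + 1L])) &&
             !startsWith(tail_lines[val_end + 1L], ">")) {
        val_end <- val_end + 1L
      }
      if (val_end > t) {
        fields[[nm]] <- paste(tail_lines[(t + 1L):val_end],
                              collapse = "\n")
      }
    }
    list(title = trimws(rec[1]), smiles = smi, fields = fields)
  })
  Filter(Negate(is.null), out)
}

write_sdf_records <- function(smiles, path, titles = NULL, fields = NULL,
                              explicit_h = TRUE) {
  con <- file(path, open = "wb")  # binary: LF line endings everywhere
  on.exit(close(con))
  opts <- if (explicit_h) data.frame(names = "h", args = "") else NULL
  for (i in seq_along(smiles)) {
    block <- suppressWarnings(
      ob_convert("SMI", "SDF", paste0(smiles[i], "\n"), options = opts)
    )
    if (!nzchar(trimws(block))) {
      stop("could not write SDF record for '", smiles[i], "'",
           call. = FALSE)
    }
    lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
    lines[1] <- if (!is.null(titles)) titles[i] else ""
    lines[2] <- " msready           2D"
    end <- which(lines == "$$$$")[1]
    body <- lines[seq_len(end - 1L)]
    # drop any data fields OpenBabel may have added; we write our own
    m_end <- which(body == "M  END")[1]
    body <- body[seq_len(m_end)]
    if (!is.null(fields)) {
      for (fname in names(fields)) {
        val <- fields[[fname]][i]
        if (!is.na(val) && nzchar(val)) {
          body <- c(body, paste0(">  <", fname, ">"), val, "")
        }
      }
    }
    writeLines(c(body, "$$$$"), con, sep = "\n")
  }
  invisible(path)
}
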