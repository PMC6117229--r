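#' Substance/chemical registry
#'
#' The registry links substances (registered entities that may be salts,
#' mixtures or single compounds; `SID`-prefixed), unique chemical
#' structures keyed by standard InChIKey (`CID`-prefixed) and the typed
#' relationships between them (`has_structure`: substance to its original
#' full structure; `component_of`: MS-Ready component chemical to
#' substance; `msready_of`: MS-Ready chemical to the original chemical it
#' was derived from).
#'
#' @return An empty `msr_registry`.
#' @seealso [ingest_substances()], [attach_msready()], [build_registry()]
#' @export
msr_registry <- function() {
  structure(list(
    substances = tibble::tibble(
      sid = character(), name = character(), cas = character(),
      smiles = character(), formula = character(),
      monoisotopic_mass = numeric(), data_sources = integer()
    ),
    chemicals = tibble::tibble(
      cid = character(), smiles = character(), inchikey = character(),
      formula = character(), monoisotopic_mass = numeric(),
      kind = character()
    ),
    mappings = tibble::tibble(
      from_id = character(), to_id = character(), relation = character()
    ),
    unmapped = character(),
    metadata = tibble::tibble(sid = character())
  ), class = "msr_registry")
}

#' @export
print.msr_registry <- function(x, ...) {
  cat("<msr_registry> ", nrow(x$substances), " substances, ",
      nrow(x$chemicals), " chemicals (",
      sum(x$chemicals$kind == "msready"), " MS-Ready), ",
      nrow(x$mappings), " mappings\n", sep = "")
  invisible(x)
}

next_id <- function(existing, prefix) {
  sprintf("%s%07d", prefix, length(existing) + 1L)
}

register_chemical <- function(registry, smiles, kind) {
  fin <- finalize_component(smiles)
  hit <- which(registry$chemicals$inchikey == fin$inchikey)
  if (length(hit)) {
    cid <- registry$chemicals$cid[hit[1]]
    # an original structure later also produced as an MS-Ready form (or
    # vice versa) keeps one row; kind records the first registration
    return(list(registry = registry, cid = cid, new = FALSE))
  }
  cid <- next_id(registry$chemicals$cid, "CID")
  registry$chemicals <- dplyr::bind_rows(registry$chemicals, tibble::tibble(
    cid = cid, smiles = fin$smiles, inchikey = fin$inchikey,
    formula = fin$formula, monoisotopic_mass = fin$monoisotopic_mass,
    kind = kind
  ))
  list(registry = registry, cid = cid, new = TRUE)
}

#' Register substances from a table or file
#'
#' Substances and their original full structures are registered; original
#' structures are unified across substances by standard InChIKey, so the
#' same structure under two substance ids yields two substances sharing
#' one chemical. Records without a parseable structure or with a missing
#' identifier are skipped with a message.
#'
#' @param registry An [msr_registry()].
#' @param data Data frame with columns `smiles` and optionally `id`,
#'   `name`, `cas`, `data_sources` plus arbitrary metadata columns (kept
#'   and joinable by `sid`); or a path to an SDF or CSV file with those
#'   fields.
#' @return The updated registry.
#' @export
ingest_substances <- function(registry, data) {
  stopifnot(inherits(registry, "msr_registry"))
  if (is.character(data) && length(data) == 1L) {
    data <- read_substance_file(data)
  }
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) return(registry)
  if (!"smiles" %in% names(data)) stop("need a 'smiles' column",
                                       call. = FALSE)
  for (i in seq_len(nrow(data))) {
    row <- data[i, ]
    smi <- row$smiles
    if (is.na(smi) || !nzchar(smi)) {
      message("skipping record ", i, ": missing structure")
      next
    }
    full <- tryCatch(finalize_component(smi), error = function(e) NULL)
    if (is.null(full)) {
      message("skipping record ", i, ": unparseable structure '", smi, "'")
      next
    }
    sid <- next_id(registry$substances$sid, "SID")
    reg <- register_chemical(registry, full$smiles, kind = "original")
    registry <- reg$registry
    registry$substances <- dplyr::bind_rows(
      registry$substances,
      tibble::tibble(
        sid = sid,
        name = as.character(col_or(row, "name") %||na%
                              col_or(row, "id") %||na% sid),
        cas = as.character(col_or(row, "cas") %||na% NA_character_),
        smiles = full$smiles,
        formula = full$formula,
        monoisotopic_mass = full$monoisotopic_mass,
        data_sources = as.integer(col_or(row, "data_sources") %||na% 0L)
      )
    )
    registry$mappings <- dplyr::bind_rows(registry$mappings, tibble::tibble(
      from_id = sid, to_id = reg$cid, relation = "has_structure"
    ))
    meta_cols <- setdiff(names(data),
                         c("id", "name", "cas", "smiles", "data_sources"))
    if (length(meta_cols)) {
      registry$metadata <- dplyr::bind_rows(
        registry$metadata,
        dplyr::bind_cols(tibble::tibble(sid = sid),
                         tibble::as_tibble(row[meta_cols]))
      )
    }
  }
  registry
}

# NA-aware null-default: treat missing column (NULL) and NA alike
`%||na%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a
}

col_or <- function(row, name, default = NULL) {
  if (name %in% names(row)) row[[name]] else default
}

read_substance_file <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    recs <- read_sdf_records(path)
    tibble::tibble(
      id = vapply(recs, function(r) r$title, character(1)),
      name = vapply(recs, function(r)
        as.character(r$fields[["name"]] %||% r$title), character(1)),
      cas = vapply(recs, function(r)
        as.character(r$fields[["cas"]] %||% NA_character_), character(1)),
      smiles = vapply(recs, function(r) r$smiles, character(1)),
      data_sources = vapply(recs, function(r)
        as.integer(r$fields[["data_sources"]] %||% 0L), integer(1))
    )
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
}

#' Attach the MS-Ready forms of a substance
#'
#' Registers each component of an `msready_result` (unifying by InChIKey)
#' and links it `component_of` the substance and `msready_of` the
#' substance's original chemical. Substances whose result is `empty` are
#' recorded as unmapped.
#'
#' @param registry An [msr_registry()].
#' @param sid Registered substance id.
#' @param result An `msready_result` from [standardize_substance()] (or a
#'   components tibble from [standardize()]).
#' @return The updated registry.
#' @export
attach_msready <- function(registry, sid, result) {
  stopifnot(inherits(registry, "msr_registry"))
  if (!sid %in% registry$substances$sid) {
    stop("unknown substance id: ", sid, call. = FALSE)
  }
  comps <- if (inherits(result, "msready_result")) {
    if (result$status == "error") {
      stop("cannot attach an errored result for ", sid, call. = FALSE)
    }
    result$components
  } else {
    result
  }
  if (nrow(comps) == 0L) {
    registry$unmapped <- union(registry$unmapped, sid)
    return(registry)
  }
  orig_cid <- registry$mappings$to_id[
    registry$mappings$from_id == sid &
    registry$mappings$relation == "has_structure"
  ][1]
  for (i in seq_len(nrow(comps))) {
    reg <- register_chemical(registry, comps$smiles[i], kind = "msready")
    registry <- reg$registry
    add <- tibble::tibble(
      from_id = c(reg$cid, reg$cid),
      to_id = c(sid, orig_cid),
      relation = c("component_of", "msready_of")
    )
    # avoid duplicate mapping rows on repeated attaches
    add <- dplyr::anti_join(add, registry$mappings,
                            by = c("from_id", "to_id", "relation"))
    registry$mappings <- dplyr::bind_rows(registry$mappings, add)
  }
  registry
}

#' Build a registry from a substance table in one call
#'
#' Ingests the substances, runs the standardization pipeline on each and
#' attaches the MS-Ready forms.
#'
#' @param data Substance table or file (see [ingest_substances()]).
#' @param config A [std_config()].
#' @return A populated `msr_registry`.
#' @examples
#' \donttest{
#' reg <- build_registry(build_fixture("nicarbazin")$substances)
#' reg
#' }
#' @export
build_registry <- function(data, config = std_config()) {
  registry <- ingest_substances(msr_registry(), data)
  for (i in seq_len(nrow(registry$substances))) {
    sid <- registry$substances$sid[i]
    res <- standardize_substance(registry$substances$smiles[i], id = sid,
                                 config = config)
    if (res$status != "error") {
      registry <- attach_msready(registry, sid, res)
    } else {
      registry$unmapped <- union(registry$unmapped, sid)
    }
  }
  registry
}

#' Substances linked to a chemical
#'
#' All substances reachable from a chemical: for an MS-Ready chemical the
#' substances it is a `component_of`; for an original chemical the
#' substances holding it as their structure (`has_structure`). Ordered by
#' data-source count descending, then substance id.
#'
#' @param registry An [msr_registry()].
#' @param cid Chemical id.
#' @return Tibble of substance rows.
#' @export
substances_for_chemical <- function(registry, cid) {
  stopifnot(inherits(registry, "msr_registry"))
  if (!cid %in% registry$chemicals$cid) {
    stop("unknown chemical id: ", cid, call. = FALSE)
  }
  maps <- registry$mappings
  sids <- unique(c(
    maps$to_id[maps$from_id == cid & maps$relation == "component_of"],
    maps$from_id[maps$to_id == cid & maps$relation == "has_structure"]
  ))
  registry$substances |>
    dplyr::filter(.data$sid %in% sids) |>
    dplyr::arrange(dplyr::desc(.data$data_sources), .data$sid)
}

#' Export / re-import a registry as flat files
#'
#' Writes `substances.sdf` (structures with id/name/cas/data_sources
#' fields), `chemicals.sdf` and `mappings.tsv` (columns `from_id`,
#' `to_id`, `relation`) into a directory; `read_registry()` rebuilds an
#' equivalent registry (identical id-to-InChIKey assignments).
#'
#' @param registry An [msr_registry()].
#' @param dir Directory (created if needed).
#' @return `dir` (write) / an `msr_registry` (read), invisibly for write.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- registry$substances
  write_sdf_records(
    s$smiles, file.path(dir, "substances.sdf"), titles = s$sid,
    fields = list(sid = s$sid, name = s$name, cas = s$cas,
                  data_sources = as.character(s$data_sources))
  )
  ch <- registry$chemicals
  write_sdf_records(
    ch$smiles, file.path(dir, "chemicals.sdf"), titles = ch$cid,
    fields = list(cid = ch$cid, inchikey = ch$inchikey, kind = ch$kind)
  )
  readr::write_tsv(registry$mappings, file.path(dir, "mappings.tsv"))
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  subs <- read_sdf_records(file.path(dir, "substances.sdf"))
  data <- tibble::tibble(
    id = vapply(subs, function(r) as.character(r$fields[["sid"]]),
                character(1)),
    name = vapply(subs, function(r) as.character(r$fields[["name"]]),
                  character(1)),
    cas = vapply(subs, function(r)
      as.character(r$fields[["cas"]] %||% NA_character_), character(1)),
    smiles = vapply(subs, function(r) r$smiles, character(1)),
    data_sources = vapply(subs, function(r)
      as.integer(r$fields[["data_sources"]] %||% 0L), integer(1))
  )
  build_registry(data)
}
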