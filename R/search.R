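#' Exact and MS-Ready searching
#'
#' `exact_formula_search()` returns substances whose *overall* formula
#' equals the query (a mixture whose component matches is not returned).
#' `msready_formula_search()` returns every substance linked to an
#' MS-Ready component with the query formula, so salts and mixtures
#' containing the structure are found too; a charged query is first
#' neutralized by one H per unit charge (the PFOS sulfonate
#' `C8F17O3S-` and the neutral acid `C8HF17O3S` retrieve the same set).
#'
#' @param registry An [msr_registry()].
#' @param formula Formula string or `ms_formula`.
#' @return Tibble of search hits: `input`, `found_by`, `cid`, `sid`,
#'   `name`, `cas`, `substance_formula`, `component_formula`,
#'   `component_smiles`, `component_mass`, `data_sources`, ordered by
#'   data-source count descending.
#' @examples
#' \donttest{
#' reg <- build_registry(build_fixture("methapyrilene")$substances)
#' msready_formula_search(reg, "C14H19N3S")$name
#' }
#' @export
exact_formula_search <- function(registry, formula) {
  f <- as_formula(formula)
  if (formula_charge(f) != 0L) {
    stop("exact formula search takes a neutral formula", call. = FALSE)
  }
  target <- format(canonical_formula(f))
  subs <- registry$substances
  hits <- subs[vapply(subs$formula, function(x)
    format(canonical_formula(parse_formula(x))) == target,
    logical(1)), , drop = FALSE]
  hit_table(registry, hits, cid = NA_character_,
            input = format(f), found_by = "exact formula match")
}

#' @rdname exact_formula_search
#' @export
msready_formula_search <- function(registry, formula) {
  f <- neutralize_formula(as_formula(formula))
  if (length(f$parts) != 1L) {
    stop("MS-Ready formula search takes a single-component formula",
         call. = FALSE)
  }
  target <- format(f)
  chem <- registry$chemicals
  cids <- chem$cid[chem$formula == target & cid_is_msready(registry)]
  rows <- NULL
  for (cid in cids) {
    subs <- substances_for_chemical(registry, cid)
    if (nrow(subs)) {
      rows <- dplyr::bind_rows(rows, hit_table(
        registry, subs, cid = cid,
        input = format(as_formula(formula)),
        found_by = "MS-Ready formula match"
      ))
    }
  }
  if (is.null(rows)) return(hit_table(registry, registry$substances[0, ],
                                      NA_character_, format(f), ""))
  rows |>
    dplyr::distinct(.data$sid, .data$cid, .keep_all = TRUE) |>
    dplyr::arrange(dplyr::desc(.data$data_sources), .data$sid)
}

cid_is_msready <- function(registry) {
  # a chemical counts as MS-Ready if produced by the standardizer, even
  # when it was first registered as an original single-component structure
  msr <- unique(registry$mappings$from_id[
    registry$mappings$relation == "component_of"])
  registry$chemicals$kind == "msready" | registry$chemicals$cid %in% msr
}

hit_table <- function(registry, subs, cid, input, found_by) {
  chem <- registry$chemicals
  comp <- if (!is.na(cid)) chem[chem$cid == cid, ] else NULL
  tibble::tibble(
    input = rep(input, nrow(subs)),
    found_by = rep(found_by, nrow(subs)),
    cid = rep(if (is.null(comp)) NA_character_ else comp$cid, nrow(subs)),
    sid = subs$sid,
    name = subs$name,
    cas = subs$cas,
    substance_formula = subs$formula,
    substance_smiles = subs$smiles,
    component_formula = if (is.null(comp)) subs$formula else
      rep(comp$formula, nrow(subs)),
    component_smiles = rep(if (is.null(comp)) NA_character_ else
      comp$smiles, nrow(subs)),
    component_mass = rep(if (is.null(comp)) NA_real_ else
      comp$monoisotopic_mass, nrow(subs)),
    data_sources = subs$data_sources
  )
}

#' Monoisotopic-mass search
#'
#' Matches MS-Ready component masses (`semantics = "msready"`) or
#' substance overall masses (`"exact"`) within a tolerance. `found_by`
#' records the observed deviation in ppm.
#'
#' @param registry An [msr_registry()].
#' @param mass Neutral monoisotopic mass in Da (> 0).
#' @param tol_ppm Tolerance in ppm (default 5, the conventional
#'   high-resolution screening window).
#' @param tol_da Absolute tolerance in Da; overrides `tol_ppm`.
#' @param semantics `"msready"` or `"exact"`.
#' @return Hit tibble as in [msready_formula_search()].
#' @export
mass_search <- function(registry, mass, tol_ppm = 5, tol_da = NULL,
                        semantics = c("msready", "exact")) {
  semantics <- match.arg(semantics)
  if (!is.numeric(mass) || mass <= 0) stop("mass must be > 0",
                                           call. = FALSE)
  tol <- if (!is.null(tol_da)) {
    if (tol_da <= 0) stop("tolerance must be > 0", call. = FALSE)
    tol_da
  } else {
    if (tol_ppm <= 0) stop("tolerance must be > 0", call. = FALSE)
    mass * tol_ppm * 1e-6
  }
  input <- format(mass)
  if (semantics == "exact") {
    subs <- registry$substances
    sel <- abs(subs$monoisotopic_mass - mass) <= tol
    hits <- hit_table(registry, subs[sel, , drop = FALSE], NA_character_,
                      input, "exact mass match")
    dev <- (subs$monoisotopic_mass[sel] - mass) / mass * 1e6
    hits$found_by <- sprintf("exact mass match, %+0.2f ppm", dev)
    return(dplyr::arrange(hits, dplyr::desc(.data$data_sources),
                          .data$sid))
  }
  chem <- registry$chemicals
  sel <- which(abs(chem$monoisotopic_mass - mass) <= tol &
               cid_is_msready(registry))
  rows <- NULL
  for (i in sel) {
    subs <- substances_for_chemical(registry, chem$cid[i])
    if (nrow(subs)) {
      h <- hit_table(registry, subs, chem$cid[i], input, "")
      dev <- (chem$monoisotopic_mass[i] - mass) / mass * 1e6
      h$found_by <- sprintf("MS-Ready mass match, %+0.2f ppm", dev)
      rows <- dplyr::bind_rows(rows, h)
    }
  }
  if (is.null(rows)) {
    return(hit_table(registry, registry$substances[0, ], NA_character_,
                     input, ""))
  }
  rows |>
    dplyr::distinct(.data$sid, .data$cid, .keep_all = TRUE) |>
    dplyr::arrange(dplyr::desc(.data$data_sources), .data$sid)
}

#' Batch search over a query file or vector
#'
#' One query per line; a line that parses as a number is dispatched to
#' [mass_search()], anything else to [msready_formula_search()] (or
#' [exact_formula_search()] with `semantics = "exact"`). Unparseable
#' lines are reported per line and processing continues. The `input`
#' column echoes each query verbatim, in input order.
#'
#' @param registry An [msr_registry()].
#' @param queries Character vector of queries or a path to a text file.
#' @param semantics `"msready"` or `"exact"`.
#' @param tol_ppm Mass tolerance in ppm for mass queries.
#' @return Concatenated hit tibble with an `error` attribute-free
#'   `query_status` tibble attached as the `"status"` attribute.
#' @export
batch_search <- function(registry, queries, semantics = c("msready",
                                                          "exact"),
                         tol_ppm = 5) {
  semantics <- match.arg(semantics)
  if (length(queries) == 1L && file.exists(queries)) {
    queries <- readr::read_lines(queries)
  }
  queries <- queries[nzchar(trimws(queries))]
  out <- NULL
  status <- tibble::tibble(input = character(), ok = logical(),
                           message = character())
  for (q in queries) {
    qt <- trimws(q)
    res <- tryCatch({
      num <- suppressWarnings(as.numeric(qt))
      h <- if (!is.na(num)) {
        mass_search(registry, num, tol_ppm = tol_ppm,
                    semantics = semantics)
      } else if (semantics == "msready") {
        msready_formula_search(registry, qt)
      } else {
        exact_formula_search(registry, qt)
      }
      h$input <- q
      h
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status <- dplyr::bind_rows(status, tibble::tibble(
        input = q, ok = FALSE, message = conditionMessage(res)
      ))
    } else {
      status <- dplyr::bind_rows(status, tibble::tibble(
        input = q, ok = TRUE, message = NA_character_
      ))
      out <- dplyr::bind_rows(out, res)
    }
  }
  if (is.null(out)) {
    out <- hit_table(registry, registry$substances[0, ], NA_character_,
                     "", "")
  }
  attr(out, "status") <- status
  out
}
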