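#' Scale a metadata category to `[0, 1]`
#'
#' Metadata categories (data-source counts, reference counts, percent
#' active assays, list-membership flags) are scaled per category before
#' entering the additive score. Divide-by-max is the default; min-max is
#' available as an option. Missing values always score 0; an all-missing
#' category scores 0 throughout; a constant non-zero category scores 1
#' under divide-by-max.
#'
#' @param values Numeric vector of raw category values (counts or
#'   percentages; negative values error).
#' @param scaling `"max"` (x / max) or `"minmax"` ((x - min) / (max -
#'   min)).
#' @return Numeric vector in `[0, 1]`, same length.
#' @examples
#' scale_metadata(c(3880, 1560, 182))
#' @export
scale_metadata <- function(values, scaling = c("max", "minmax")) {
  scaling <- match.arg(scaling)
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE)) {
    stop("metadata categories are counts/percentages; negative values ",
         "are not allowed", call. = FALSE)
  }
  present <- !is.na(values)
  if (!any(present)) return(rep(0, length(values)))
  out <- rep(0, length(values))
  if (scaling == "max") {
    mx <- max(values[present])
    out[present] <- if (mx == 0) 0 else values[present] / mx
  } else {
    mn <- min(values[present])
    mx <- max(values[present])
    out[present] <- if (mx == mn) {
      if (mx > 0) 1 else 0
    } else {
      (values[present] - mn) / (mx - mn)
    }
  }
  out
}

#' Combine scaled score terms into the additive candidate score
#'
#' Weighted sum of the scaled terms: the MetFrag fragmenter score and the
#' spectral-similarity score (both already in `[0, 1]`) plus each scaled
#' metadata category. With unit weights the maximum achievable score
#' equals the number of active categories: 2 core terms + 5 metadata
#' categories give a maximum of 7.
#'
#' @param terms Named numeric vector of scaled terms in `[0, 1]`.
#' @param weights Named non-negative weights; defaults to 1 for every
#'   term. A weight for a name not among the terms errors.
#' @return The combined score (single number).
#' @examples
#' combined_score(c(fragmenter = 1, spectral = 1))
#' @export
combined_score <- function(terms, weights = NULL) {
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(terms)), names(terms))
  }
  extra <- setdiff(names(weights), names(terms))
  if (length(extra)) {
    stop("weight given for inactive category: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  w <- stats::setNames(rep(1, length(terms)), names(terms))
  w[names(weights)] <- weights
  sum(w * terms[names(w)])
}

#' Score a candidate table
#'
#' The additive scoring scheme applied to a whole candidate table: core
#' scores are taken as given (the in-silico fragmenter and spectral
#' library matching are upstream tools; absent core scores default to
#' 0), metadata categories are scaled to `[0, 1]` per category, and the
#' combined score is the weighted sum. Candidates sharing an InChIKey
#' first block can be grouped, reporting the highest-scoring member as
#' group representative while keeping all identifiers.
#'
#' @param data Candidate data frame: one row per candidate with an
#'   identifier column, an InChIKey column (required when `group =
#'   TRUE`), optional core-score columns and the metadata columns.
#' @param metadata Character vector of metadata column names to score.
#' @param core Character vector of core score column names (values in
#'   `[0, 1]`); missing columns/values count 0.
#' @param weights Named numeric weights (default 1 per active category).
#' @param scaling Passed to [scale_metadata()].
#' @param group Group candidates by InChIKey first block?
#' @param id_col,inchikey_col Column names.
#' @return An `msr_scores` object; see [tidy.msr_scores()],
#'   [glance.msr_scores()], [rank_candidates()], [autoplot.msr_scores()].
#' @examples
#' library(tibble)
#' cand <- tibble(
#'   id = c("A", "B"),
#'   inchikey = c("AAAAAAAAAAAAAA-UHFFFAOYSA-N",
#'                "BBBBBBBBBBBBBB-UHFFFAOYSA-N"),
#'   fragmenter = c(1, 0.8), spectral = c(1, 0.58),
#'   data_sources = c(3880, 182)
#' )
#' rank_candidates(score_candidates(cand, metadata = "data_sources"))
#' @export
score_candidates <- function(data, metadata = character(),
                             core = c("fragmenter", "spectral"),
                             weights = NULL,
                             scaling = c("max", "minmax"),
                             group = TRUE,
                             id_col = "id", inchikey_col = "inchikey") {
  scaling <- match.arg(scaling)
  stopifnot(is.data.frame(data), id_col %in% names(data))
  scores <- tibble::tibble(id = as.character(data[[id_col]]))
  if (inchikey_col %in% names(data)) {
    scores$inchikey <- data[[inchikey_col]]
  } else if (group) {
    stop("grouping needs an InChIKey column ('", inchikey_col, "')",
         call. = FALSE)
  }
  term_names <- c(core, metadata)
  for (col in core) {
    v <- if (col %in% names(data)) as.numeric(data[[col]]) else
      rep(0, nrow(data))
    v[is.na(v)] <- 0
    if (any(v < 0 | v > 1)) {
      stop("core score '", col, "' must lie in `[0, 1]`", call. = FALSE)
    }
    scores[[col]] <- v
  }
  for (col in metadata) {
    if (!col %in% names(data)) {
      stop("metadata column '", col, "' not found", call. = FALSE)
    }
    scores[[col]] <- scale_metadata(data[[col]], scaling)
  }
  w <- stats::setNames(rep(1, length(term_names)), term_names)
  if (!is.null(weights)) {
    extra <- setdiff(names(weights), term_names)
    if (length(extra)) {
      stop("weight given for inactive category: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    w[names(weights)] <- weights
  }
  scores$combined <- as.numeric(
    as.matrix(scores[, term_names, drop = FALSE]) %*% w
  )
  out <- structure(list(
    candidates = scores,
    config = list(core = core, metadata = metadata, weights = w,
                  scaling = scaling, group = group,
                  max_score = sum(w))
  ), class = "msr_scores")
  if (group) out$groups <- group_candidates(scores)
  out
}

#' Group candidates by InChIKey first block
#'
#' Partitions a scored candidate table by the 14-character InChIKey first
#' block. Each group's representative is its highest-scoring member
#' (ties broken by lexicographically smallest identifier); all member
#' identifiers stay attached.
#'
#' @param scores Tibble with `id`, `inchikey` and `combined` columns
#'   (e.g. `tidy()` of an `msr_scores`).
#' @return Tibble: `group_key`, `n`, `representative`, `combined`,
#'   `member_ids` (list-column).
#' @export
group_candidates <- function(scores) {
  if (!all(c("id", "inchikey", "combined") %in% names(scores))) {
    stop("need columns id, inchikey, combined", call. = FALSE)
  }
  bad <- is.na(scores$inchikey) | !nzchar(scores$inchikey)
  if (any(bad)) {
    stop("candidate without InChIKey: ",
         paste(scores$id[bad], collapse = ", "), call. = FALSE)
  }
  scores$group_key <- first_block(scores$inchikey)
  scores |>
    dplyr::group_by(.data$group_key) |>
    dplyr::arrange(dplyr::desc(.data$combined), .data$id,
                   .by_group = TRUE) |>
    dplyr::summarise(
      n = dplyr::n(),
      representative = dplyr::first(.data$id),
      combined = dplyr::first(.data$combined),
      member_ids = list(.data$id),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$combined), .data$representative)
}

#' Rank scored candidates (or groups)
#'
#' @param x An `msr_scores` object.
#' @param grouped Rank groups (default when grouping was requested) or
#'   individual candidates.
#' @return Tibble in descending combined-score order, ties broken by
#'   identifier.
#' @export
rank_candidates <- function(x, grouped = !is.null(x$groups)) {
  stopifnot(inherits(x, "msr_scores"))
  if (grouped) {
    if (is.null(x$groups)) stop("scores were not grouped", call. = FALSE)
    x$groups
  } else {
    dplyr::arrange(x$candidates, dplyr::desc(.data$combined), .data$id)
  }
}

#' @export
print.msr_scores <- function(x, ...) {
  cat("<msr_scores> ", nrow(x$candidates), " candidate(s), max possible ",
      format(x$config$max_score), "\n", sep = "")
  top <- rank_candidates(x, grouped = FALSE)
  print(utils::head(top, 5))
  invisible(x)
}

#' Tidy a scored candidate set
#'
#' @param x An `msr_scores` object.
#' @param ... Unused.
#' @return One row per candidate with scaled terms and the combined
#'   score, in rank order.
#' @importFrom generics tidy
#' @method tidy msr_scores
#' @export
tidy.msr_scores <- function(x, ...) {
  rank_candidates(x, grouped = FALSE)
}

#' One-line summary of a scored candidate set
#'
#' @param x An `msr_scores` object.
#' @param ... Unused.
#' @return One-row tibble: `n_candidates`, `n_groups`, `max_score`,
#'   `top_id`, `top_score`.
#' @importFrom generics glance
#' @method glance msr_scores
#' @export
glance.msr_scores <- function(x, ...) {
  ranked <- rank_candidates(x, grouped = FALSE)
  tibble::tibble(
    n_candidates = nrow(x$candidates),
    n_groups = if (is.null(x$groups)) NA_integer_ else nrow(x$groups),
    max_score = x$config$max_score,
    top_id = ranked$id[1],
    top_score = ranked$combined[1]
  )
}

#' Score-breakdown plot
#'
#' Stacked horizontal bars of the weighted contribution of every score
#' term per candidate, ordered by combined score.
#'
#' @param object An `msr_scores` object.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @method autoplot msr_scores
#' @export
autoplot.msr_scores <- function(object, ...) {
  terms <- c(object$config$core, object$config$metadata)
  w <- object$config$weights
  long <- object$candidates |>
    dplyr::mutate(dplyr::across(dplyr::all_of(terms),
                                ~ .x * w[dplyr::cur_column()])) |>
    tidyr::pivot_longer(dplyr::all_of(terms), names_to = "term",
                        values_to = "contribution")
  ord <- rank_candidates(object, grouped = FALSE)$id
  long$id <- factor(long$id, levels = rev(ord))
  long$term <- factor(long$term, levels = terms)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$contribution, y = .data$id,
                                     fill = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "weighted score contribution", y = NULL,
                  fill = "term") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.msr_scores
#' @param x An `msr_scores` object.
#' @export
plot_score_breakdown <- function(x, ...) autoplot.msr_scores(x, ...)
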