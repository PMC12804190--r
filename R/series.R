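# Yearly score series --------------------------------------------------------

#' Construct a yearly association-score series
#'
#' A cumulative per-year association score for one (target, disease) pair at
#' one scope -- either a single data source (`"datasource:<id>"`) or the
#' weighted `"overall"` aggregate. Because evidence only accumulates, the
#' series must be non-decreasing; scores lie in \[0,1\].
#'
#' @param target_id,disease_id association key.
#' @param scope `"overall"` or `"datasource:<id>"`.
#' @param years contiguous integer year grid.
#' @param score numeric vector, same length as `years`.
#' @param datasource_id,datatype_id optional source annotation carried along
#'   for per-category reporting.
#' @return an object of class `score_series`.
#' @export
score_series <- function(target_id, disease_id, scope, years, score,
                         datasource_id = NA_character_,
                         datatype_id = NA_character_) {
  years <- as.integer(years)
  score <- as.numeric(score)
  stopifnot(length(years) == length(score), length(years) > 0L)
  if (any(diff(years) != 1L)) stop("year grid must be contiguous")
  if (any(score < -1e-12 | score > 1 + 1e-12)) {
    stop("scores must lie in [0, 1]")
  }
  if (any(diff(score) < -1e-12)) {
    stop("score series must be non-decreasing: evidence only accumulates")
  }
  structure(list(target_id = target_id, disease_id = disease_id,
                 scope = scope, years = years,
                 score = pmin(pmax(score, 0), 1),
                 datasource_id = datasource_id, datatype_id = datatype_id),
            class = "score_series")
}

#' @export
print.score_series <- function(x, ...) {
  cat(sprintf("<score_series> %s / %s [%s], %d-%d\n", x$target_id,
              x$disease_id, x$scope, min(x$years), max(x$years)))
  print(stats::setNames(round(x$score, 4), x$years))
  invisible(x)
}

#' @export
as.data.frame.score_series <- function(x, ...) {
  data.frame(target_id = x$target_id, disease_id = x$disease_id,
             scope = x$scope, year = x$years, score = x$score,
             stringsAsFactors = FALSE)
}

#' Reconstruct the yearly score evolution for one source
#'
#' For each year of the grid, recomputes the source association score using
#' only evidence resolved to that year or earlier -- the retrospective
#' recalculation that turns a static association score into a temporal
#' profile. Evidence dated before `start_year` contributes from `start_year`
#' onward (left-censoring at the grid start).
#'
#' @param evidence resolved evidence (see [resolve_timestamps()]) for a
#'   single (target, disease, datasource) key; unresolved rows are dropped.
#' @param start_year first grid year; the profiles start at 1995.
#' @param end_year last grid year; defaults to the latest evidence year (or
#'   `start_year` for empty evidence).
#' @param cap passed to [harmonic_sum()].
#' @return a [score_series] at scope `"datasource:<id>"`.
#' @export
yearly_source_scores <- function(evidence, start_year = 1995L,
                                 end_year = NULL, cap = 1000L) {
  evidence <- evidence[!is.na(evidence$year), , drop = FALSE]
  if (nrow(evidence) > 0L) {
    key <- unique(evidence[c("target_id", "disease_id", "datasource_id")])
    if (nrow(key) != 1L) {
      stop("evidence mixes more than one (target, disease, datasource) key")
    }
  } else {
    key <- data.frame(target_id = NA_character_, disease_id = NA_character_,
                      datasource_id = NA_character_)
  }
  if (is.null(end_year)) {
    end_year <- if (nrow(evidence)) max(max(evidence$year), start_year) else start_year
  }
  stopifnot(end_year >= start_year)
  years <- seq.int(start_year, end_year)
  eff_year <- pmax(evidence$year, start_year)
  score <- vapply(years, function(y) {
    harmonic_sum(evidence$score[eff_year <= y], cap = cap)
  }, numeric(1))
  datatype <- if (nrow(evidence)) evidence$datatype_id[[1L]] else NA_character_
  score_series(key$target_id, key$disease_id,
               scope = paste0("datasource:", key$datasource_id),
               years = years, score = score,
               datasource_id = key$datasource_id, datatype_id = datatype)
}

#' Aggregate per-source series into the overall score series
#'
#' Applies [overall_association_score()] year by year to a set of per-source
#' series sharing one association key and year grid.
#'
#' @param series_list list of [score_series] objects, one per data source.
#' @param weights a [source_weights] object.
#' @param cap passed to [harmonic_sum()].
#' @return a [score_series] at scope `"overall"`.
#' @export
yearly_overall_scores <- function(series_list, weights = source_weights(),
                                  cap = 1000L) {
  stopifnot(length(series_list) > 0L)
  first <- series_list[[1L]]
  for (s in series_list) {
    if (!identical(s$years, first$years)) stop("year grids are misaligned")
    if (!identical(c(s$target_id, s$disease_id),
                   c(first$target_id, first$disease_id))) {
      stop("series mix association keys")
    }
  }
  sources <- vapply(series_list, function(s) s$datasource_id, character(1))
  mat <- vapply(series_list, function(s) s$score, numeric(length(first$years)))
  mat <- matrix(mat, nrow = length(first$years),
                dimnames = list(NULL, sources))
  score <- vapply(seq_along(first$years), function(i) {
    overall_association_score(mat[i, ], weights = weights, cap = cap)
  }, numeric(1))
  score_series(first$target_id, first$disease_id, scope = "overall",
               years = first$years, score = score)
}
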