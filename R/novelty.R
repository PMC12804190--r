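# Logistic-decay novelty metric ----------------------------------------------

#' Novelty metric parameters
#'
#' Parameters of the logistic-decay novelty metric
#' \eqn{N = S / (1 + e^{k(W - m)})}: `k` is the steepness of the decay,
#' `m` the sigmoid midpoint in years after the shift, and `cutoff` the
#' threshold above which a novelty peak is reported as a relevant signal.
#' The defaults (`k = 2`, `m = 3`, `cutoff = 0.1`) give a slow decay in the
#' first two years after a shift, a fast decay in years three and four, and
#' effectively zero novelty (at two-decimal display) from year six on.
#'
#' @param k steepness, > 0.
#' @param m midpoint in years, > 0.
#' @param cutoff novelty threshold in \[0,1\].
#' @return an object of class `novelty_params`.
#' @export
novelty_params <- function(k = 2, m = 3, cutoff = 0.1) {
  stopifnot(k > 0, m > 0, cutoff >= 0, cutoff <= 1)
  structure(list(k = as.numeric(k), m = as.numeric(m),
                 cutoff = as.numeric(cutoff)),
            class = "novelty_params")
}

#' @export
print.novelty_params <- function(x, ...) {
  cat(sprintf("<novelty_params> k = %g, m = %g, cutoff = %g\n",
              x$k, x$m, x$cutoff))
  invisible(x)
}

#' Logistic decay of a score shift
#'
#' Evaluates \eqn{N = S / (1 + e^{k(W - m)})} for a shift of magnitude `S`
#' observed `W` whole years ago. Strictly decreasing in `W`; equals exactly
#' `S/2` at `W = m`; bounded by `S`.
#'
#' @param S shift magnitude(s), in (0,1\].
#' @param W elapsed whole years since the shift, >= 0; recycled with `S`.
#' @param params a [novelty_params] object.
#' @return numeric vector of novelty values in (0, S).
#' @examples
#' logistic_novelty(0.17, 0)  # ~0.17: a fresh shift keeps its magnitude
#' logistic_novelty(0.53, 3)  # midpoint: exactly half
#' @export
logistic_novelty <- function(S, W, params = novelty_params()) {
  S <- as.numeric(S)
  W <- as.numeric(W)
  if (any(S <= 0) || any(S > 1)) stop("shift magnitude S must lie in (0, 1]")
  if (any(W < 0)) stop("window W must be non-negative")
  S / (1 + exp(params$k * (W - params$m)))
}

#' Extract score shifts from a yearly series
#'
#' A shift is a year in which the cumulative score strictly increases; its
#' magnitude is the consecutive-year difference. The first nonzero year
#' yields a shift from zero. A nonzero value already at the grid start is
#' recorded as a shift flagged `grid_start`: it reflects evidence censored by
#' the grid boundary, not a dated burst of novelty, and is excluded from peak
#' reports by default.
#'
#' @param series a [score_series].
#' @return data frame with columns `year`, `magnitude`, `grid_start`; zero
#'   rows for a constant series.
#' @export
extract_shifts <- function(series) {
  stopifnot(inherits(series, "score_series"))
  delta <- diff(c(0, series$score))
  if (any(delta < -1e-12)) {
    stop("score series decreases: violates the cumulative-evidence invariant")
  }
  up <- delta > 1e-12
  data.frame(year = series$years[up], magnitude = delta[up],
             grid_start = series$years[up] == series$years[[1L]])
}

#' Novelty series of a yearly score profile
#'
#' For each year `t`, the novelty is the maximum of the logistic decay over
#' every shift registered at or before `t`:
#' \eqn{N(t) = \max_{t_0 \le t} S(t_0) / (1 + e^{k(t - t_0 - m)})}.
#' When shifts occur in close succession, all candidate values are computed
#' and the maximum is selected; with the default decay, shifts older than
#' about six years contribute negligibly. Years before the first shift have
#' zero novelty.
#'
#' @param series a [score_series].
#' @param params a [novelty_params] object.
#' @return an object of class `novelty_series`: the key and grid of `series`
#'   plus per-year `novelty` values and the registered `shifts`.
#' @export
novelty_series <- function(series, params = novelty_params()) {
  shifts <- extract_shifts(series)
  novelty <- vapply(series$years, function(t) {
    active <- shifts$year <= t
    if (!any(active)) return(0)
    max(logistic_novelty(shifts$magnitude[active], t - shifts$year[active],
                         params))
  }, numeric(1))
  structure(list(target_id = series$target_id, disease_id = series$disease_id,
                 scope = series$scope, years = series$years,
                 novelty = novelty, shifts = shifts, params = params,
                 datasource_id = series$datasource_id,
                 datatype_id = series$datatype_id),
            class = "novelty_series")
}

#' @export
print.novelty_series <- function(x, ...) {
  cat(sprintf("<novelty_series> %s / %s [%s], %d shift(s)\n", x$target_id,
              x$disease_id, x$scope, nrow(x$shifts)))
  print(stats::setNames(round(x$novelty, 4), x$years))
  invisible(x)
}

#' @export
as.data.frame.novelty_series <- function(x, ...) {
  data.frame(target_id = x$target_id, disease_id = x$disease_id,
             scope = x$scope, year = x$years, novelty = x$novelty,
             is_peak = x$years %in% x$shifts$year,
             is_above_cutoff = x$novelty >= x$params$cutoff,
             stringsAsFactors = FALSE)
}

#' Detect novelty peaks
#'
#' A peak is the novelty value registered at a shift year. Peaks below the
#' cutoff are retained but flagged sub-threshold; shifts flagged
#' `grid_start` are excluded unless `include_grid_start = TRUE`, since they
#' mark the censoring boundary rather than dated novelty.
#'
#' @param nseries a [novelty_series].
#' @param params a [novelty_params] object; defaults to the parameters the
#'   series was built with.
#' @param include_grid_start keep grid-start shifts as peaks?
#' @return data frame with one row per peak: `target_id`, `disease_id`,
#'   `scope`, `datasource_id`, `datatype_id`, `year`, `value`,
#'   `above_cutoff`, `grid_start`.
#' @export
detect_peaks <- function(nseries, params = nseries$params,
                         include_grid_start = FALSE) {
  stopifnot(inherits(nseries, "novelty_series"))
  shifts <- nseries$shifts
  if (!include_grid_start) shifts <- shifts[!shifts$grid_start, , drop = FALSE]
  value <- nseries$novelty[match(shifts$year, nseries$years)]
  n <- nrow(shifts)
  data.frame(target_id = rep(nseries$target_id, n),
             disease_id = rep(nseries$disease_id, n),
             scope = rep(nseries$scope, n),
             datasource_id = rep(nseries$datasource_id, n),
             datatype_id = rep(nseries$datatype_id, n), year = shifts$year,
             value = value, above_cutoff = value >= params$cutoff,
             grid_start = shifts$grid_start, stringsAsFactors = FALSE)
}

#' Overall novelty across data sources
#'
#' Mirrors the overall association score: the normalized harmonic sum of the
#' weighted per-source novelty values at one year.
#'
#' @param source_novelties named numeric vector, datasource_id -> novelty in
#'   \[0,1\].
#' @param weights a [source_weights] object.
#' @param cap passed to [harmonic_sum()].
#' @return a number in \[0,1\].
#' @export
overall_novelty <- function(source_novelties, weights = source_weights(),
                            cap = 1000L) {
  overall_association_score(source_novelties, weights = weights, cap = cap)
}

#' Year-by-year overall novelty series
#'
#' Applies [overall_novelty()] at every grid year to a set of per-source
#' novelty series sharing one key and grid.
#'
#' @param nseries_list list of [novelty_series], one per source.
#' @param weights a [source_weights] object.
#' @return a `novelty_series` at scope `"overall"` with an empty shift table
#'   (shifts belong to the per-source series).
#' @export
yearly_overall_novelty <- function(nseries_list, weights = source_weights()) {
  stopifnot(length(nseries_list) > 0L)
  first <- nseries_list[[1L]]
  for (s in nseries_list) {
    if (!identical(s$years, first$years)) stop("year grids are misaligned")
  }
  sources <- vapply(nseries_list, function(s) s$datasource_id, character(1))
  novelty <- vapply(seq_along(first$years), function(i) {
    vals <- vapply(nseries_list, function(s) s$novelty[[i]], numeric(1))
    overall_novelty(stats::setNames(vals, sources), weights = weights)
  }, numeric(1))
  structure(list(target_id = first$target_id, disease_id = first$disease_id,
                 scope = "overall", years = first$years, novelty = novelty,
                 shifts = first$shifts[0, , drop = FALSE],
                 params = first$params, datasource_id = NA_character_,
                 datatype_id = NA_character_),
            class = "novelty_series")
}

#' Round novelty for display
#'
#' Reports use two decimals with banker's (half-even) rounding; internal
#' computation keeps full precision. Under the default decay a shift six or
#' more years old displays as 0.00.
#'
#' @param x numeric.
#' @return `x` rounded to two decimals.
#' @export
display_novelty <- function(x) round(x, 2)
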