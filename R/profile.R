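# The central temporal-profile object -----------------------------------------

#' Fit temporal association and novelty profiles to an evidence corpus
#'
#' The package's main entry point. From a corpus of timestamped evidence it
#' reconstructs, for every (target, disease) association present:
#'
#' 1. the per-source yearly association-score series (normalized harmonic
#'    sums over evidence accumulated up to each year);
#' 2. the weighted overall association-score series;
#' 3. the per-source and overall logistic-decay novelty series;
#' 4. the table of novelty peaks (one per score shift), flagged against the
#'    novelty cutoff.
#'
#' Records without a `year` column are first passed through
#' [resolve_timestamps()]; unresolved records are dropped (and counted).
#'
#' @param evidence evidence data frame (see [read_evidence()]), resolved or
#'   not.
#' @param weights a [source_weights] object.
#' @param params a [novelty_params] object.
#' @param start_year first year of the reconstruction grid.
#' @param end_year last grid year; defaults to the latest resolved evidence
#'   year.
#' @param curated_sources passed to [resolve_timestamps()] when resolution is
#'   needed.
#' @param include_grid_start_peaks report shifts at the grid boundary as
#'   peaks?
#' @return an object of class `novelty_profile`: a list with elements
#'   `associations` (per-pair series bundles), `peaks` (corpus-wide peak
#'   table), `years`, `params`, `weights`, `n_records`, `n_unresolved`.
#' @examples
#' prof <- novelty_profile(tslp_fixture()$evidence)
#' summary(prof)
#' novelty_peaks(prof)
#' @export
novelty_profile <- function(evidence, weights = source_weights(),
                            params = novelty_params(), start_year = 1995L,
                            end_year = NULL,
                            curated_sources = curated_source_defaults(),
                            include_grid_start_peaks = FALSE) {
  stopifnot(inherits(weights, "source_weights"),
            inherits(params, "novelty_params"))
  if (!"year" %in% names(evidence)) {
    evidence <- resolve_timestamps(evidence, curated_sources = curated_sources,
                                   quiet = TRUE)
  }
  n_records <- nrow(evidence)
  n_unresolved <- sum(!evidence$resolved)
  evidence <- evidence[evidence$resolved, , drop = FALSE]
  if (is.null(end_year)) {
    end_year <- if (nrow(evidence)) max(max(evidence$year), start_year) else start_year
  }

  assoc_key <- if (nrow(evidence)) {
    paste(evidence$target_id, evidence$disease_id, sep = "\r")
  } else character()
  associations <- lapply(split(evidence, assoc_key), function(ev) {
    src_series <- lapply(split(ev, ev$datasource_id), yearly_source_scores,
                         start_year = start_year, end_year = end_year)
    src_novelty <- lapply(src_series, novelty_series, params = params)
    list(target_id = ev$target_id[[1L]], disease_id = ev$disease_id[[1L]],
         source_series = src_series, source_novelty = src_novelty,
         overall_series = yearly_overall_scores(src_series, weights = weights),
         overall_novelty = yearly_overall_novelty(src_novelty,
                                                  weights = weights))
  })
  names(associations) <- vapply(associations, function(a) {
    paste(a$target_id, a$disease_id, sep = "/")
  }, character(1))

  peak_rows <- lapply(associations, function(a) {
    do.call(rbind, lapply(a$source_novelty, detect_peaks, params = params,
                          include_grid_start = include_grid_start_peaks))
  })
  peaks <- do.call(rbind, peak_rows)
  if (is.null(peaks)) {
    peaks <- detect_peaks(structure(list(
      target_id = character(), disease_id = character(), scope = character(),
      years = integer(), novelty = numeric(),
      shifts = data.frame(year = integer(), magnitude = numeric(),
                          grid_start = logical()),
      params = params, datasource_id = character(),
      datatype_id = character()), class = "novelty_series"))
  }
  rownames(peaks) <- NULL

  structure(list(associations = associations, peaks = peaks,
                 years = seq.int(start_year, end_year), params = params,
                 weights = weights, n_records = n_records,
                 n_unresolved = n_unresolved),
            class = "novelty_profile")
}

#' Peak table of a fitted profile
#'
#' @param object a [novelty_profile].
#' @param above_cutoff_only keep only peaks at or above the novelty cutoff?
#' @return data frame of peaks (see [detect_peaks()]).
#' @export
novelty_peaks <- function(object, above_cutoff_only = FALSE) {
  stopifnot(inherits(object, "novelty_profile"))
  p <- object$peaks
  if (above_cutoff_only) p <- p[p$above_cutoff, , drop = FALSE]
  p
}

#' Tidy score table of a fitted profile
#'
#' One row per (target, disease, scope, year); the layout written by the
#' command-line `score` subcommand.
#'
#' @param object a [novelty_profile].
#' @return data frame with columns `target_id`, `disease_id`, `scope`,
#'   `year`, `score`.
#' @export
score_table <- function(object) {
  stopifnot(inherits(object, "novelty_profile"))
  rows <- lapply(object$associations, function(a) {
    do.call(rbind, c(lapply(a$source_series, as.data.frame),
                     list(as.data.frame(a$overall_series))))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(target_id = character(), disease_id = character(),
                      scope = character(), year = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Tidy novelty table of a fitted profile
#'
#' One row per (target, disease, scope, year) with the novelty value, peak
#' flag, and cutoff flag.
#'
#' @param object a [novelty_profile].
#' @return data frame with columns `target_id`, `disease_id`, `scope`,
#'   `year`, `novelty`, `is_peak`, `is_above_cutoff`.
#' @export
novelty_table <- function(object) {
  stopifnot(inherits(object, "novelty_profile"))
  rows <- lapply(object$associations, function(a) {
    do.call(rbind, c(lapply(a$source_novelty, as.data.frame),
                     list(as.data.frame(a$overall_novelty))))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(target_id = character(), disease_id = character(),
                      scope = character(), year = integer(),
                      novelty = numeric(), is_peak = logical(),
                      is_above_cutoff = logical(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.novelty_profile <- function(x, ...) {
  cat("<novelty_profile>\n")
  cat(sprintf("  %d evidence record(s), %d unresolved (dropped)\n",
              x$n_records, x$n_unresolved))
  cat(sprintf("  %d association(s) over %d-%d\n", length(x$associations),
              min(x$years), max(x$years)))
  cat(sprintf("  %d novelty peak(s), %d at or above cutoff %.2f\n",
              nrow(x$peaks), sum(x$peaks$above_cutoff), x$params$cutoff))
  invisible(x)
}

#' @export
summary.novelty_profile <- function(object, ...) {
  tops <- top_peak_per_category(object$peaks)
  structure(list(n_records = object$n_records,
                 n_unresolved = object$n_unresolved,
                 n_associations = length(object$associations),
                 years = object$years, params = object$params,
                 top_peaks = tops,
                 peaks_per_association = if (nrow(object$peaks)) {
                   table(paste(object$peaks$target_id,
                               object$peaks$disease_id, sep = "/"))
                 } else table(character())),
            class = "summary.novelty_profile")
}

#' @export
print.summary.novelty_profile <- function(x, ...) {
  cat("Temporal novelty profile\n")
  cat(sprintf("  grid: %d-%d; k = %g, m = %g, cutoff = %g\n", min(x$years),
              max(x$years), x$params$k, x$params$m, x$params$cutoff))
  cat(sprintf("  %d association(s) from %d record(s) (%d unresolved)\n",
              x$n_associations, x$n_records, x$n_unresolved))
  if (length(x$peaks_per_association)) {
    cat(sprintf("  peaks per association: median %.1f, max %d\n",
                stats::median(x$peaks_per_association),
                max(x$peaks_per_association)))
  }
  if (nrow(x$top_peaks)) {
    cat("  top peaks per association and category:\n")
    shown <- x$top_peaks
    shown$top_peak_value <- display_novelty(shown$top_peak_value)
    print(utils::head(shown, 20), row.names = FALSE)
    if (nrow(shown) > 20) cat("  ...", nrow(shown) - 20, "more\n")
  } else cat("  no peaks detected\n")
  invisible(x)
}

#' Plot the temporal profile of one association
#'
#' Two stacked base-graphics panels for a single (target, disease) pair: the
#' per-source and overall association-score curves, and the corresponding
#' novelty curves with peak years marked and the cutoff shown as a dashed
#' line.
#'
#' @param x a [novelty_profile].
#' @param target_id,disease_id association to plot; default the first fitted
#'   pair.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.novelty_profile <- function(x, target_id = NULL, disease_id = NULL, ...) {
  if (length(x$associations) == 0L) stop("profile contains no associations")
  a <- if (is.null(target_id)) {
    x$associations[[1L]]
  } else {
    key <- paste(target_id, disease_id, sep = "/")
    if (!key %in% names(x$associations)) stop("no such association: ", key)
    x$associations[[key]]
  }
  sources <- names(a$source_series)
  cols <- grDevices::hcl.colors(max(3L, length(sources)), "Dark 3")
  old <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old))

  plot(a$overall_series$years, a$overall_series$score, type = "s", lwd = 2,
       ylim = c(0, 1), xlab = "", ylab = "association score",
       main = paste(a$target_id, "/", a$disease_id))
  for (i in seq_along(sources)) {
    graphics::lines(a$source_series[[i]]$years, a$source_series[[i]]$score,
                    type = "s", col = cols[i])
  }
  graphics::legend("topleft", legend = c("overall", sources), bty = "n",
                   lwd = c(2, rep(1, length(sources))),
                   col = c("black", cols[seq_along(sources)]))

  plot(a$overall_novelty$years, a$overall_novelty$novelty, type = "l",
       lwd = 2, ylim = c(0, 1), xlab = "year", ylab = "novelty")
  for (i in seq_along(sources)) {
    ns <- a$source_novelty[[i]]
    graphics::lines(ns$years, ns$novelty, col = cols[i])
    graphics::points(ns$shifts$year,
                     ns$novelty[match(ns$shifts$year, ns$years)],
                     col = cols[i], pch = 19)
  }
  graphics::abline(h = x$params$cutoff, lty = 2, col = "grey40")
  invisible(x)
}

#' Project novelty decay beyond the fitted grid
#'
#' With no new evidence, novelty is fully determined by the registered score
#' shifts: for any later year the metric is the maximum logistic decay over
#' the existing shifts. `predict` evaluates that projection on new years
#' (past grid years are returned from the fitted series unchanged).
#'
#' @param object a [novelty_profile].
#' @param years integer years to evaluate; defaults to the five years after
#'   the fitted grid.
#' @param ... ignored.
#' @return data frame with columns `target_id`, `disease_id`, `scope`,
#'   `year`, `novelty`.
#' @export
predict.novelty_profile <- function(object,
                                    years = max(object$years) + 1:5, ...) {
  years <- as.integer(years)
  params <- object$params
  rows <- lapply(object$associations, function(a) {
    per_source <- lapply(a$source_novelty, function(ns) {
      vapply(years, function(t) {
        fitted <- match(t, ns$years)
        if (!is.na(fitted)) return(ns$novelty[[fitted]])
        active <- ns$shifts$year <= t
        if (!any(active)) return(0)
        max(logistic_novelty(ns$shifts$magnitude[active],
                             t - ns$shifts$year[active], params))
      }, numeric(1))
    })
    src_df <- do.call(rbind, lapply(names(per_source), function(ds) {
      data.frame(target_id = a$target_id, disease_id = a$disease_id,
                 scope = paste0("datasource:", ds), year = years,
                 novelty = per_source[[ds]], stringsAsFactors = FALSE)
    }))
    overall <- vapply(seq_along(years), function(i) {
      vals <- vapply(per_source, `[[`, numeric(1), i)
      overall_novelty(stats::setNames(vals, names(per_source)),
                      weights = object$weights)
    }, numeric(1))
    rbind(src_df,
          data.frame(target_id = a$target_id, disease_id = a$disease_id,
                     scope = "overall", year = years, novelty = overall,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
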