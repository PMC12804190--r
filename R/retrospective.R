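# Retrospective peak-vs-approval analysis -------------------------------------

#' Default therapeutic areas excluded from novelty counting
#'
#' Disease annotations that are not disease entities proper and are dropped
#' from per-year counts when a disease-to-area map is supplied.
#'
#' @return character vector of area labels.
#' @export
excluded_area_defaults <- function() {
  c("biological process", "phenotype", "measurement", "animal disease",
    "medical procedure")
}

#' Top novelty peak per association and category
#'
#' Selects, for each (target, disease) association and data-type category,
#' the highest-valued novelty peak; ties are broken by the earliest year.
#'
#' @param peaks peak table as returned by [detect_peaks()] /
#'   [novelty_peaks()] (columns `target_id`, `disease_id`, `datatype_id`,
#'   `year`, `value`).
#' @param category optional single category to restrict to; `NULL` keeps all.
#' @param cutoff optional minimum peak value; `NULL` keeps every peak.
#' @return data frame with one row per (target, disease, category):
#'   `target_id`, `disease_id`, `category`, `top_peak_year`,
#'   `top_peak_value`.
#' @export
top_peak_per_category <- function(peaks, category = NULL, cutoff = NULL) {
  if (!is.null(category)) {
    peaks <- peaks[peaks$datatype_id %in% category, , drop = FALSE]
  }
  if (!is.null(cutoff)) peaks <- peaks[peaks$value >= cutoff, , drop = FALSE]
  peaks <- peaks[!is.na(peaks$datatype_id), , drop = FALSE]
  if (nrow(peaks) == 0L) {
    return(data.frame(target_id = character(), disease_id = character(),
                      category = character(), top_peak_year = integer(),
                      top_peak_value = numeric(), stringsAsFactors = FALSE))
  }
  key <- interaction(peaks$target_id, peaks$disease_id, peaks$datatype_id,
                     drop = TRUE)
  picked <- lapply(split(peaks, key), function(g) {
    g <- g[order(-g$value, g$year), , drop = FALSE]  # max value, earliest year
    data.frame(target_id = g$target_id[[1L]], disease_id = g$disease_id[[1L]],
               category = g$datatype_id[[1L]], top_peak_year = g$year[[1L]],
               top_peak_value = g$value[[1L]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, picked)
  out <- out[order(out$target_id, out$disease_id, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Years elapsed from top novelty peak to drug approval
#'
#' Joins per-category top-peak summaries with a first-approval table on the
#' approval's (target, indication) pair and computes
#' `delta_years = first_approval_year - top_peak_year`: positive when the
#' supporting novelty peak precedes the approval. Only the approval's own
#' indication is matched -- no ontology expansion. Targets with peaks but no
#' approval (or vice versa) are skipped with a message.
#'
#' @param summaries output of [top_peak_per_category()].
#' @param approvals approval table; collapsed to one row per target with
#'   [first_approvals()].
#' @param quiet suppress the skipped-target message?
#' @return data frame with columns `target_id`, `disease_id`, `category`,
#'   `first_approval_year`, `top_peak_year`, `delta_years`.
#' @export
approval_deltas <- function(summaries, approvals, quiet = FALSE) {
  approvals <- first_approvals(approvals)
  idx <- match(paste(summaries$target_id, summaries$disease_id),
               paste(approvals$target_id, approvals$disease_id))
  skipped <- unique(summaries$target_id[is.na(idx)])
  if (length(skipped) && !quiet) {
    message("skipping ", length(skipped),
            " target(s) without a matching approval: ",
            paste(skipped, collapse = ", "))
  }
  keep <- !is.na(idx)
  out <- data.frame(
    target_id = summaries$target_id[keep],
    disease_id = summaries$disease_id[keep],
    category = summaries$category[keep],
    first_approval_year = approvals$first_approval_year[idx[keep]],
    top_peak_year = summaries$top_peak_year[keep],
    stringsAsFactors = FALSE)
  out$delta_years <- out$first_approval_year - out$top_peak_year
  out
}

#' Clinical-phase deltas relative to first approval
#'
#' Clinical novelty is assessed independently of score-shift peaks: each
#' approval carrying earliest phase I/II and phase III trial years yields
#' deltas `first_approval_year - phase_year` under the categories
#' `clinical_I_II` and `clinical_III`. An absent phase year emits no delta.
#'
#' @param approvals approval table (see [read_approvals()]).
#' @return data frame in the same layout as [approval_deltas()], with the
#'   phase trial year in `top_peak_year`.
#' @export
clinical_phase_deltas <- function(approvals) {
  rows <- list()
  for (phase in c("phase_1_2_year", "phase_3_year")) {
    cat_lab <- if (phase == "phase_1_2_year") "clinical_I_II" else "clinical_III"
    has <- !is.na(approvals[[phase]])
    if (!any(has)) next
    rows[[phase]] <- data.frame(
      target_id = approvals$target_id[has],
      disease_id = approvals$disease_id[has],
      category = cat_lab,
      first_approval_year = approvals$first_approval_year[has],
      top_peak_year = approvals[[phase]][has],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(target_id = character(), disease_id = character(),
                      category = character(), first_approval_year = integer(),
                      top_peak_year = integer(), delta_years = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$delta_years <- out$first_approval_year - out$top_peak_year
  out
}

#' Per-year counts of novel associations and targets
#'
#' Counts, per calendar year and data-type category, how many associations
#' and unique targets carry a relevant novelty signal. Peaks below `cutoff`
#' are discarded; each association is then assigned to the year of its
#' highest remaining peak in the category (earliest year on value ties), and
#' each target to the first such year among its associations. Supplying a
#' disease-to-therapeutic-area map drops associations whose disease falls in
#' an excluded area; with no map, no area filtering occurs.
#'
#' @param peaks peak table (see [top_peak_per_category()] for the columns).
#' @param cutoff minimum peak value to count as a novelty signal.
#' @param area_map optional data frame with columns `disease_id`,
#'   `therapeutic_area`.
#' @param excluded_areas area labels removed when `area_map` is given.
#' @return data frame with columns `year`, `category`, `n_associations`,
#'   `n_targets`.
#' @export
yearly_novelty_counts <- function(peaks, cutoff = 0.1, area_map = NULL,
                                  excluded_areas = excluded_area_defaults()) {
  peaks <- peaks[peaks$value >= cutoff, , drop = FALSE]
  if (!is.null(area_map)) {
    area <- area_map$therapeutic_area[match(peaks$disease_id,
                                            area_map$disease_id)]
    peaks <- peaks[is.na(area) | !area %in% excluded_areas, , drop = FALSE]
  }
  tops <- top_peak_per_category(peaks)
  if (nrow(tops) == 0L) {
    return(data.frame(year = integer(), category = character(),
                      n_associations = integer(), n_targets = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- list()
  for (cat_lab in sort(unique(tops$category))) {
    g <- tops[tops$category == cat_lab, , drop = FALSE]
    assoc_years <- g$top_peak_year
    # a target's first novel year: earliest top-peak year among its pairs
    target_first <- vapply(split(g$top_peak_year, g$target_id), min,
                           numeric(1))
    years <- sort(unique(assoc_years))
    out[[cat_lab]] <- data.frame(
      year = years, category = cat_lab,
      n_associations = vapply(years, function(y) sum(assoc_years == y),
                              integer(1)),
      n_targets = vapply(years, function(y) sum(target_first == y),
                         integer(1)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
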