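#' Harmonic sum of evidence scores
#'
#' Aggregates a vector of scores in \[0,1\] with the rank-squared harmonic
#' kernel used by the Open Targets Platform association framework: scores are
#' sorted in descending order, truncated to `cap` elements, and summed as
#' \eqn{\sum_i s_{(i)} / i^2} over the 1-based rank \eqn{i}. With
#' `normalize = TRUE` the sum is divided by its theoretical maximum, the same
#' sum over a vector of `cap` ones (about 1.644 for `cap = 1000`), so the
#' result lies in \[0,1\].
#'
#' @param scores numeric vector of scores, each in \[0,1\].
#' @param cap maximum number of scores that contribute; defaults to 1000,
#'   the truncation at which the all-ones sum approximates \eqn{\pi^2/6}.
#' @param normalize divide by the all-ones harmonic sum of length `cap`?
#' @return a single number; in \[0,1\] when `normalize = TRUE`. An empty
#'   input yields 0.
#' @examples
#' harmonic_sum(rep(1, 1000), normalize = FALSE) # ~1.644
#' harmonic_sum(c(0.70, 0.20, 0.10))
#' @export
harmonic_sum <- function(scores, cap = 1000L, normalize = TRUE) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L) return(0)
  if (anyNA(scores)) stop("scores must not contain NA")
  if (any(scores < 0 | scores > 1)) {
    stop("all scores must lie in [0, 1]; offending value: ",
         format(scores[which(scores < 0 | scores > 1)[1L]]))
  }
  s <- sort(scores, decreasing = TRUE)
  if (length(s) > cap) s <- s[seq_len(cap)]
  raw <- sum(s / seq_along(s)^2)
  if (normalize) raw / harmonic_norm_constant(cap) else raw
}

#' Harmonic-sum normalization constant
#'
#' The harmonic sum of a vector of `cap` ones, \eqn{\sum_{i=1}^{cap} 1/i^2};
#' the maximum attainable raw harmonic sum and hence the normalizer that maps
#' scores onto \[0,1\]. Approaches \eqn{\pi^2/6 \approx 1.6449} as `cap`
#' grows; equals 1.64393 (5 d.p.) at the default `cap = 1000`.
#'
#' @param cap truncation length.
#' @return a positive number.
#' @export
harmonic_norm_constant <- function(cap = 1000L) {
  cap <- as.integer(cap)
  stopifnot(cap >= 1L)
  sum(1 / seq_len(cap)^2)
}

#' Per-source weight configuration
#'
#' Holds the data-source weights applied before the second (overall-level)
#' harmonic sum. Sources without an explicit weight fall back to
#' `default`. The Platform's production weights are not public, so the
#' package defaults to uniform weight 1 for every source.
#'
#' @param ... named weights, e.g. `gwas = 1, europepmc = 0.2`, or a single
#'   named numeric vector.
#' @param default weight returned for sources not named; in (0,1].
#' @return an object of class `source_weights`.
#' @examples
#' w <- source_weights(europepmc = 0.2)
#' weight_for(w, c("gwas", "europepmc"))
#' @export
source_weights <- function(..., default = 1) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && !is.null(names(dots[[1L]]))) {
    dots <- as.list(dots[[1L]])
  }
  w <- vapply(dots, as.numeric, numeric(1))
  if (length(w) > 0L && (is.null(names(w)) || any(!nzchar(names(w))))) {
    stop("all weights must be named by datasource_id")
  }
  if (any(w <= 0 | w > 1) || default <= 0 || default > 1) {
    stop("weights must lie in (0, 1]")
  }
  structure(list(weights = w, default = as.numeric(default)),
            class = "source_weights")
}

#' @export
print.source_weights <- function(x, ...) {
  cat("<source_weights> default =", x$default, "\n")
  if (length(x$weights)) {
    for (nm in names(x$weights)) cat(" ", nm, "=", x$weights[[nm]], "\n")
  }
  invisible(x)
}

#' Look up weights for data sources
#'
#' @param weights a [source_weights] object.
#' @param datasource_id character vector of source identifiers.
#' @return numeric vector of weights, the default where a source is unknown.
#' @export
weight_for <- function(weights, datasource_id) {
  stopifnot(inherits(weights, "source_weights"))
  out <- unname(weights$weights[datasource_id])
  out[is.na(out)] <- weights$default
  out
}

#' Read a weight configuration file
#'
#' Accepts either a two-column TSV (`datasource_id`, `weight`, header
#' required) or a JSON object mapping source id to weight. A
#' `default_weight` entry (TSV row or JSON key) overrides the fallback.
#'
#' @param path file path.
#' @param default fallback weight when the file carries no `default_weight`.
#' @return a [source_weights] object.
#' @export
read_weights <- function(path, default = 1) {
  stopifnot(file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    w <- unlist(raw)
  } else {
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("datasource_id", "weight") %in% names(tab))) {
      stop("weight TSV needs columns datasource_id, weight")
    }
    w <- stats::setNames(as.numeric(tab$weight), tab$datasource_id)
  }
  if ("default_weight" %in% names(w)) {
    default <- unname(w[["default_weight"]])
    w <- w[names(w) != "default_weight"]
  }
  source_weights(w, default = default)
}

#' Association score for one data source
#'
#' The normalized harmonic sum of all evidence scores one source contributes
#' to one target-disease association.
#'
#' @param evidence data frame of evidence rows sharing a single
#'   (target_id, disease_id, datasource_id) key, with a `score` column;
#'   or a bare numeric vector of scores.
#' @param cap passed to [harmonic_sum()].
#' @return a number in \[0,1\]; 0 for empty evidence.
#' @export
source_association_score <- function(evidence, cap = 1000L) {
  if (is.numeric(evidence)) return(harmonic_sum(evidence, cap = cap))
  if (nrow(evidence) == 0L) return(0)
  key <- unique(evidence[c("target_id", "disease_id", "datasource_id")])
  if (nrow(key) != 1L) {
    stop("evidence mixes more than one (target, disease, datasource) key")
  }
  harmonic_sum(evidence$score, cap = cap)
}

#' Overall association score across data sources
#'
#' The second-level harmonic sum: each source association score is multiplied
#' by its source weight, and the weighted vector is aggregated and normalized
#' exactly as the per-source evidence scores are.
#'
#' @param source_scores named numeric vector, datasource_id -> score in
#'   \[0,1\].
#' @param weights a [source_weights] object.
#' @param cap passed to [harmonic_sum()].
#' @return a number in \[0,1\].
#' @export
overall_association_score <- function(source_scores,
                                      weights = source_weights(),
                                      cap = 1000L) {
  if (length(source_scores) == 0L) return(0)
  if (is.null(names(source_scores))) {
    stop("source_scores must be named by datasource_id")
  }
  w <- weight_for(weights, names(source_scores))
  harmonic_sum(w * source_scores, cap = cap)
}
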