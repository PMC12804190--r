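# Independent brute-force oracles used to cross-check the implementation.
# Deliberately written as plain loops over the defining formulas, sharing no
# code with the package internals.

naive_harmonic <- function(scores, cap = 1000L, normalize = TRUE) {
  s <- sort(scores, decreasing = TRUE)
  if (length(s) > cap) s <- s[1:cap]
  total <- 0
  for (i in seq_along(s)) total <- total + s[i] / i^2
  if (!normalize) return(total)
  denom <- 0
  for (i in 1:cap) denom <- denom + 1 / i^2
  total / denom
}

# Full from-scratch recomputation of the yearly score profile: for every grid
# year, filter the evidence and redo the harmonic sum with the loop oracle.
naive_yearly_scores <- function(scores, evidence_years, grid_years,
                                cap = 1000L) {
  start <- grid_years[1]
  out <- numeric(length(grid_years))
  for (j in seq_along(grid_years)) {
    eff <- pmax(evidence_years, start)
    out[j] <- naive_harmonic(scores[eff <= grid_years[j]], cap = cap)
  }
  out
}

# Enumerates every (shift, year) pair and takes the pointwise maximum of the
# logistic decay, straight from the closed form.
brute_novelty <- function(shift_years, magnitudes, grid_years, k = 2, m = 3) {
  out <- numeric(length(grid_years))
  for (j in seq_along(grid_years)) {
    t <- grid_years[j]
    best <- 0
    for (i in seq_along(shift_years)) {
      if (shift_years[i] <= t) {
        W <- t - shift_years[i]
        cand <- magnitudes[i] / (1 + exp(k * (W - m)))
        if (cand > best) best <- cand
      }
    }
    out[j] <- best
  }
  out
}

# A small random evidence set for one (target, disease, datasource) key.
random_key_evidence <- function(seed, years = 2000:2010, max_n = 12L) {
  set.seed(seed)
  n <- sample.int(max_n, 1L)
  data.frame(record_id = sprintf("r%03d", seq_len(n)),
             target_id = "TG0001", disease_id = "DS0001",
             datasource_id = "europepmc", datatype_id = "literature",
             score = round(stats::runif(n, 0.01, 1), 3),
             primary_year = sample(years, n, replace = TRUE),
             curation_year = NA_integer_, clinical_phase = NA_character_,
             stringsAsFactors = FALSE)
}

quiet_profile <- function(...) suppressMessages(novelty_profile(...))
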