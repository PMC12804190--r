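#' @keywords internal
"_PACKAGE"

# Evidence schema ------------------------------------------------------------

EVIDENCE_COLUMNS <- c("record_id", "target_id", "disease_id", "datasource_id",
                      "datatype_id", "score", "primary_year", "curation_year",
                      "clinical_phase")

#' Recognized data-type categories
#'
#' The seven evidence categories used by the Open Targets Platform: literature
#' mining, curated or statistical genetic associations, somatic mutations,
#' differential RNA expression, animal models, affected pathways, and clinical
#' ("known drug") evidence.
#'
#' @return character vector of valid `datatype_id` values.
#' @export
datatype_levels <- function() {
  c("literature", "genetic_association", "somatic_mutation", "rna_expression",
    "animal_model", "affected_pathway", "known_drug")
}

CLINICAL_PHASES <- c("I", "II", "III", "IV")

#' Default expert-curated genetic sources
#'
#' Sources for which a curation submission date, when present, takes
#' precedence over the primary publication date: curated genetic repositories
#' record the moment the resource became aware of the evidence, while the
#' primary date is the fallback.
#'
#' @return character vector of datasource identifiers.
#' @export
curated_source_defaults <- function() {
  c("eva", "clingen", "gene2phenotype", "genomics_england", "orphanet",
    "uniprot_literature", "gene_burden", "gwas")
}

validate_evidence <- function(df, strict = FALSE, source = "evidence") {
  required <- c("record_id", "target_id", "disease_id", "datasource_id",
                "datatype_id", "score")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", source, ": ",
         paste(missing, collapse = ", "))
  }
  for (col in c("primary_year", "curation_year")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_integer_, nrow(df))
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  if (!"clinical_phase" %in% names(df)) {
    df$clinical_phase <- rep(NA_character_, nrow(df))
  }
  df$clinical_phase <- as.character(df$clinical_phase)
  df$clinical_phase[!nzchar(trimws(as.character(df$clinical_phase))) |
                      df$clinical_phase == "."] <- NA_character_
  df$score <- suppressWarnings(as.numeric(df$score))

  bad <- rep(FALSE, nrow(df))
  why <- character(nrow(df))
  flag <- function(idx, msg) {
    why[idx & !bad] <<- msg
    bad <<- bad | idx
  }
  flag(is.na(df$score) | df$score <= 0 | df$score > 1, "score outside (0,1]")
  flag(!df$datatype_id %in% datatype_levels(), "unknown datatype_id")
  flag(!is.na(df$clinical_phase) & !df$clinical_phase %in% CLINICAL_PHASES,
       "unknown clinical_phase")
  year_ok <- function(y) is.na(y) | (y >= 1900L & y <= 2100L)
  flag(!year_ok(df$primary_year) | !year_ok(df$curation_year),
       "year outside [1900, 2100]")
  flag(is.na(df$record_id) | !nzchar(df$record_id) | duplicated(df$record_id),
       "missing or duplicated record_id")

  if (any(bad)) {
    detail <- paste0("row ", which(bad), " (record_id=", df$record_id[bad],
                     "): ", why[bad], collapse = "; ")
    if (strict) stop("invalid evidence in ", source, ": ", detail)
    warning("skipping ", sum(bad), " invalid evidence row(s) in ", source,
            ": ", detail, call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[EVIDENCE_COLUMNS]
}

#' Read timestamped evidence records
#'
#' Reads one scored, dated piece of target-disease evidence per row, from
#' JSON-lines (one object per line) or tab-delimited text (header required;
#' `"."` or an empty cell means absent). Rows that fail validation -- score
#' outside (0,1], unknown datatype, years outside \[1900,2100\], duplicated
#' record ids -- are skipped with a warning naming the row, or abort the run
#' when `strict = TRUE`. Sub-year date precision is out of scope: all
#' timestamps are calendar years.
#'
#' @param path path to the evidence file.
#' @param format `"jsonl"`, `"tsv"`, or `"auto"` (by file extension;
#'   `.jsonl`/`.json` vs anything else).
#' @param strict abort on the first invalid row instead of skipping?
#' @return a data frame of validated evidence records with columns
#'   `record_id`, `target_id`, `disease_id`, `datasource_id`, `datatype_id`,
#'   `score`, `primary_year`, `curation_year`, `clinical_phase`.
#' @seealso [resolve_timestamps()] to collapse the candidate dates to the
#'   single year used downstream; [write_evidence()] for the inverse.
#' @export
read_evidence <- function(path, format = c("auto", "jsonl", "tsv"),
                          strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("evidence file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) return(empty_evidence())
    rows <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) stop("malformed JSON on line ", i,
                                               ": ", conditionMessage(e)))
      obj[vapply(obj, is.null, logical(1))] <- NA
      as.data.frame(obj, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind_fill, rows)
  } else {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            na.strings = c("", "."), quote = "")
    if (nrow(df) == 0L) return(empty_evidence())
  }
  validate_evidence(df, strict = strict, source = path)
}

empty_evidence <- function() {
  validate_evidence(data.frame(record_id = character(), target_id = character(),
                               disease_id = character(),
                               datasource_id = character(),
                               datatype_id = character(), score = numeric(),
                               stringsAsFactors = FALSE))
}

# rbind data frames whose columns may differ; absent columns become NA
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  filled <- lapply(dfs, function(d) {
    for (col in setdiff(cols, names(d))) d[[col]] <- NA
    d[cols]
  })
  do.call(rbind, filled)
}

#' Write evidence records
#'
#' Inverse of [read_evidence()]: writes JSON-lines (absent fields omitted) or
#' TSV (absent fields as `"."`). A write followed by a read reproduces the
#' records field for field.
#'
#' @param records evidence data frame.
#' @param path output path.
#' @param format `"jsonl"`, `"tsv"`, or `"auto"` by extension.
#' @export
write_evidence <- function(records, path, format = c("auto", "jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  records <- records[intersect(EVIDENCE_COLUMNS, names(records))]
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      row <- as.list(records[i, , drop = FALSE])
      row <- row[!vapply(row, function(v) is.na(v), logical(1))]
      jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path)
  } else {
    write_tsv(records, path)
  }
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

# Timestamp resolution --------------------------------------------------------

#' Resolve each evidence record to a single calendar year
#'
#' Applies the timestamp precedence rules that turn the candidate dates of an
#' evidence record into the one year used by the yearly scoring grid:
#'
#' * `known_drug` (clinical) evidence: `primary_year` carries the clinical
#'   trial start year (`timestamp_kind = "trial_start"`);
#' * sources listed in `curated_sources` with a curation submission year:
#'   the curation year wins over the primary publication year
#'   (`timestamp_kind = "curation"`);
#' * `affected_pathway` evidence: `primary_year` is the project release or
#'   associated publication year (`timestamp_kind = "project_release"`);
#' * everything else: the primary publication year
#'   (`timestamp_kind = "primary"`).
#'
#' Records with no usable year are flagged `resolved = FALSE`, never imputed,
#' and the count is reported; downstream functions drop them.
#'
#' @param records validated evidence data frame (see [read_evidence()]).
#' @param curated_sources datasource ids treated as expert-curated.
#' @param quiet suppress the unresolved-count message?
#' @return the input with columns `year` (integer), `timestamp_kind`, and
#'   `resolved` (logical) appended; attribute `n_unresolved` carries the
#'   count of dropped-eligible records.
#' @export
resolve_timestamps <- function(records,
                               curated_sources = curated_source_defaults(),
                               quiet = FALSE) {
  n <- nrow(records)
  year <- rep(NA_integer_, n)
  kind <- rep(NA_character_, n)

  curated <- records$datasource_id %in% curated_sources &
    !is.na(records$curation_year)
  trial <- records$datatype_id == "known_drug" & !is.na(records$primary_year)
  pathway <- records$datatype_id == "affected_pathway" &
    !is.na(records$primary_year)

  year[trial] <- records$primary_year[trial]
  kind[trial] <- "trial_start"
  use_cur <- curated & !trial
  year[use_cur] <- records$curation_year[use_cur]
  kind[use_cur] <- "curation"
  use_rel <- pathway & !trial & !use_cur
  year[use_rel] <- records$primary_year[use_rel]
  kind[use_rel] <- "project_release"
  rest <- is.na(kind) & !is.na(records$primary_year)
  year[rest] <- records$primary_year[rest]
  kind[rest] <- "primary"

  records$year <- year
  records$timestamp_kind <- kind
  records$resolved <- !is.na(year)
  n_unresolved <- sum(!records$resolved)
  if (!quiet && n > 0L) {
    message(sprintf("resolved %d/%d evidence records to a year (%.1f%%); %d unresolved",
                    n - n_unresolved, n, 100 * (n - n_unresolved) / n,
                    n_unresolved))
  }
  attr(records, "n_unresolved") <- n_unresolved
  records
}

#' Fraction of evidence records with a resolved year
#'
#' @param resolved output of [resolve_timestamps()].
#' @return a number in \[0,1\]; `NaN` for an empty corpus.
#' @export
resolution_rate <- function(resolved) {
  mean(resolved$resolved)
}

#' Median lag between curation and primary dates
#'
#' For records carrying both a primary publication year and a curation
#' submission year, the median of `curation_year - primary_year` in years
#' (positive when curation postdates the primary source).
#'
#' @param records evidence data frame.
#' @return median lag in years; `NA` when no record carries both dates.
#' @export
curation_lag <- function(records) {
  both <- !is.na(records$primary_year) & !is.na(records$curation_year)
  if (!any(both)) return(NA_real_)
  stats::median(records$curation_year[both] - records$primary_year[both])
}

# Approvals -------------------------------------------------------------------

#' Read a drug-approval table
#'
#' Tab-delimited, header required, columns `target_id`, `disease_id`,
#' `drug_id`, `first_approval_year`, `phase_1_2_year`, `phase_3_year`
#' (the last two optional; `"."` or empty = absent). Duplicate
#' (target, drug) rows are collapsed to the earliest approval year, taking
#' the earliest recorded phase years across duplicates. Phase years may
#' postdate the first approval: trials continue for other indications.
#'
#' @param path file path.
#' @return a data frame of approval records.
#' @export
read_approvals <- function(path) {
  if (!file.exists(path)) stop("approvals file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("", "."), quote = "")
  required <- c("target_id", "disease_id", "drug_id", "first_approval_year")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  for (col in c("phase_1_2_year", "phase_3_year")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_integer_, nrow(df))
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  df$first_approval_year <- suppressWarnings(as.integer(df$first_approval_year))
  if (nrow(df) > 0L && anyNA(df$first_approval_year)) {
    stop("missing first_approval_year in row(s) ",
         paste(which(is.na(df$first_approval_year)), collapse = ", "),
         " of ", path)
  }
  if (nrow(df) > 0L && any(df$first_approval_year < 1900L)) {
    stop("first_approval_year before 1900 in ", path)
  }
  if (nrow(df) == 0L) return(df)
  key <- interaction(df$target_id, df$drug_id, drop = TRUE)
  collapsed <- lapply(split(df, key), function(g) {
    g <- g[order(g$first_approval_year), , drop = FALSE]
    out <- g[1L, , drop = FALSE]
    for (col in c("phase_1_2_year", "phase_3_year")) {
      m <- suppressWarnings(min(g[[col]], na.rm = TRUE))
      out[[col]] <- if (is.finite(m)) as.integer(m) else NA_integer_
    }
    out
  })
  out <- do.call(rbind, collapsed)
  out <- out[order(out$target_id, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' First approval per target
#'
#' Collapses an approval table to one row per target: the earliest approval
#' across that target's drugs, with the indication of that earliest approval.
#'
#' @param approvals output of [read_approvals()].
#' @return one row per `target_id`.
#' @export
first_approvals <- function(approvals) {
  if (nrow(approvals) == 0L) return(approvals)
  picked <- lapply(split(approvals, approvals$target_id), function(g) {
    g[order(g$first_approval_year, g$drug_id), , drop = FALSE][1L, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}
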