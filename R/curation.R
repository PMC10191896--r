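# Cohort curation ------------------------------------------------------------
#
# A cohort is a tibble with one row per patient: a `patient_id` column plus
# one column per schema item. Ternary items hold the character codes
# present/absent/unknown (manifestations) or positive/negative/unknown
# (autoantibody results and the qualitative urine-protein test); continuous
# items hold numbers. NA means the cell is missing, which is distinct from
# the explicit "unknown" answer.

new_curation_report <- function(n_input) {
  structure(
    list(
      n_input = n_input,
      n_duplicates_removed = 0L,
      n_imputed_values = 0L,
      n_incomplete_removed = 0L,
      n_output = n_input,
      imputation_log = tibble::tibble(
        patient_id = character(), item_id = character(),
        old_value = numeric(), new_value = numeric()
      )
    ),
    class = "curation_report"
  )
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Cohort curation report\n")
  cat(sprintf("  records in:            %d\n", x$n_input))
  cat(sprintf("  duplicates removed:    %d\n", x$n_duplicates_removed))
  cat(sprintf("  values imputed:        %d\n", x$n_imputed_values))
  cat(sprintf("  incomplete removed:    %d\n", x$n_incomplete_removed))
  cat(sprintf("  records out:           %d\n", x$n_output))
  invisible(x)
}

#' Tidy a curation report
#'
#' @param x A `curation_report`.
#' @param ... Unused.
#' @return One-row tibble of curation counts.
#' @method tidy curation_report
#' @export
tidy.curation_report <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_duplicates_removed = x$n_duplicates_removed,
    n_imputed_values = x$n_imputed_values,
    n_incomplete_removed = x$n_incomplete_removed,
    n_output = x$n_output
  )
}

#' Load a cohort CSV
#'
#' Reads a comma-separated cohort file (UTF-8, mandatory header) into a
#' cohort tibble. Columns are typed from the schema: continuous items are
#' parsed as numbers, ternary items as their three-level character codes.
#' Unparseable cells — non-numeric text in a lab column, or a code outside
#' the item's allowed set — become missing (`NA`) with a warning. Empty
#' cells and the literal string `"NA"` are missing.
#'
#' @param path Path to the CSV file.
#' @param schema Schema tibble (see [sle_schema()]).
#' @return A cohort tibble: `patient_id` plus one column per schema item,
#'   in schema order.
#' @export
load_cohort <- function(path, schema = sle_schema()) {
  validate_schema(schema, strict = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE)
  if (nrow(raw) == 0L) abort(paste0("cohort file is empty: ", path))
  if (!"patient_id" %in% names(raw)) abort("cohort CSV must have a patient_id column")
  extra <- setdiff(names(raw), c("patient_id", schema$item_id))
  if (length(extra) > 0) {
    abort(paste0("cohort column(s) not in schema: ", paste(extra, collapse = ", ")))
  }
  missing_items <- setdiff(schema$item_id, names(raw))
  if (length(missing_items) > 0) {
    abort(paste0("cohort CSV lacks schema column(s): ",
                 paste(missing_items, collapse = ", ")))
  }

  cohort <- tibble::tibble(patient_id = as.character(raw$patient_id))
  n_bad <- 0L
  for (i in seq_len(nrow(schema))) {
    id <- schema$item_id[i]
    col <- raw[[id]]
    if (schema$kind[i] %in% CONTINUOUS_KINDS) {
      parsed <- suppressWarnings(as.numeric(col))
      n_bad <- n_bad + sum(is.na(parsed) & !is.na(col))
      cohort[[id]] <- parsed
    } else {
      codes <- ternary_codes(schema$kind[i])
      val <- ifelse(col %in% codes, col, NA_character_)
      n_bad <- n_bad + sum(is.na(val) & !is.na(col))
      cohort[[id]] <- val
    }
  }
  if (n_bad > 0) {
    warn(sprintf("%d unparseable cell(s) set to missing while loading %s", n_bad, path))
  }
  cohort
}

#' Write a cohort tibble as CSV
#'
#' Inverse of [load_cohort()]: missing cells are written as empty strings.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Remove duplicate patient records
#'
#' Records whose item values are identical in every column — the patient id
#' is excluded from the comparison — are collapsed to the first occurrence
#' in input order; one patient's data are kept and the duplicates excluded.
#' Missingness patterns count as part of the data, so two records are
#' duplicates only if they also miss the same cells.
#'
#' @param cohort Cohort tibble.
#' @param report An existing `curation_report` to update, or `NULL`.
#' @return A list with `cohort` (deduplicated) and `report`.
#' @export
deduplicate <- function(cohort, report = NULL) {
  report <- report %||% new_curation_report(nrow(cohort))
  values <- cohort[setdiff(names(cohort), "patient_id")]
  dup <- duplicated(values)
  report$n_duplicates_removed <- report$n_duplicates_removed + sum(dup)
  report$n_output <- report$n_output - sum(dup)
  list(cohort = cohort[!dup, , drop = FALSE], report = report)
}

#' Repair erroneous continuous values
#'
#' A continuous value outside its item's plausible range (for example a
#' negative leukocyte count, typically a data-entry artifact where a value
#' was recorded although no test was performed) is replaced by a likely
#' value estimated from the cohort's basic statistics: the median of the
#' in-range values of that item. Every replacement is logged in the report.
#' If an item has no in-range values at all the offending cells are set to
#' missing with a warning, since no statistic can be estimated.
#'
#' @param cohort Cohort tibble.
#' @param schema Schema tibble.
#' @param report Optional `curation_report` to update.
#' @return A list with `cohort` (repaired) and `report`.
#' @export
repair_erroneous <- function(cohort, schema = sle_schema(), report = NULL) {
  validate_schema(schema, strict = FALSE)
  report <- report %||% new_curation_report(nrow(cohort))
  cont <- schema[schema$kind %in% CONTINUOUS_KINDS, ]
  logs <- list()
  for (i in seq_len(nrow(cont))) {
    id <- cont$item_id[i]
    x <- cohort[[id]]
    in_range <- !is.na(x) & x >= cont$range_low[i] & x <= cont$range_high[i]
    bad <- !is.na(x) & !in_range
    if (!any(bad)) next
    if (!any(in_range)) {
      warn(sprintf("item %s has no in-range values; erroneous cells set to missing", id))
      logs[[id]] <- tibble::tibble(
        patient_id = cohort$patient_id[bad], item_id = id,
        old_value = x[bad], new_value = NA_real_
      )
      x[bad] <- NA_real_
    } else {
      med <- median(x[in_range])
      logs[[id]] <- tibble::tibble(
        patient_id = cohort$patient_id[bad], item_id = id,
        old_value = x[bad], new_value = med
      )
      x[bad] <- med
    }
    cohort[[id]] <- x
  }
  log_tbl <- dplyr::bind_rows(logs)
  if (nrow(log_tbl) > 0) {
    report$imputation_log <- dplyr::bind_rows(report$imputation_log, log_tbl)
    report$n_imputed_values <- report$n_imputed_values + nrow(log_tbl)
  }
  list(cohort = cohort, report = report)
}

#' Classify kidney involvement from the urinary/renal items
#'
#' Kidney involvement is considered absent only if all four criteria hold:
#' \enumerate{
#'   \item qualitative urine-protein test negative;
#'   \item urine protein per day below 0.5 g, or no data;
#'   \item granular casts not observed;
#'   \item none of rapidly progressive glomerulonephritis, nephrotic
#'     syndrome, acute renal failure or chronic renal failure observed.
#' }
#' Otherwise it is present. A daily urine protein of exactly 0.5 g fails
#' criterion 2 (strict "< 0.5 g"). An unknown or missing qualitative test
#' cannot confirm criterion 1 and therefore classifies as present; an
#' unknown cast or renal-manifestation answer counts as "not observed".
#'
#' @param cohort Cohort tibble containing the kidney-rule items.
#' @return Integer vector (1 = involvement present, 0 = absent), one per row.
#' @export
classify_kidney_involvement <- function(cohort) {
  miss <- setdiff(KIDNEY_RULE_ITEMS, names(cohort))
  if (length(miss) > 0) {
    abort(paste0("cohort lacks kidney-rule item(s): ", paste(miss, collapse = ", ")))
  }
  qual_neg <- !is.na(cohort$urine_protein_qual) & cohort$urine_protein_qual == "negative"
  upd <- cohort$urine_protein_day
  protein_ok <- is.na(upd) | upd < 0.5
  casts_ok <- is.na(cohort$granular_casts) | cohort$granular_casts != "present"
  renal_ok <- rep(TRUE, nrow(cohort))
  for (id in RENAL_MANIFESTATION_ITEMS) {
    renal_ok <- renal_ok & (is.na(cohort[[id]]) | cohort[[id]] != "present")
  }
  absent <- qual_neg & protein_ok & casts_ok & renal_ok
  as.integer(!absent)
}

#' Drop records with missing data
#'
#' Complete-case filtering: a record is removed if any schema item is
#' missing, except items whose absence the kidney rule explicitly tolerates
#' (urine protein per day may be "no data"). The explicit answer "unknown"
#' is data, not missingness, and never causes removal.
#'
#' @param cohort Cohort tibble.
#' @param schema Schema tibble.
#' @param report Optional `curation_report` to update.
#' @param tolerate Item ids whose missingness is tolerated.
#' @return A list with `cohort` (complete cases) and `report`.
#' @export
drop_incomplete <- function(cohort, schema = sle_schema(), report = NULL,
                            tolerate = TOLERATED_MISSING_ITEMS) {
  validate_schema(schema, strict = FALSE)
  report <- report %||% new_curation_report(nrow(cohort))
  check_items <- setdiff(intersect(schema$item_id, names(cohort)), tolerate)
  incomplete <- rowSums(is.na(cohort[check_items])) > 0
  report$n_incomplete_removed <- report$n_incomplete_removed + sum(incomplete)
  report$n_output <- report$n_output - sum(incomplete)
  list(cohort = cohort[!incomplete, , drop = FALSE], report = report)
}

# Feature encoding ------------------------------------------------------------

# Scaling parameters: per continuous item the (transformed) cohort min and
# range, reused to encode new data identically.
fit_feature_scaling <- function(cohort, schema) {
  cont <- schema[schema$kind %in% CONTINUOUS_KINDS, ]
  purrr::pmap_dfr(cont, function(item_id, label, kind, range_low, range_high) {
    x <- cohort[[item_id]]
    if (kind == "titer-continuous") x <- log2(pmax(x, 1))
    x <- x[!is.na(x)]
    lo <- if (length(x) > 0) min(x) else 0
    hi <- if (length(x) > 0) max(x) else 0
    tibble::tibble(item_id = item_id, kind = kind, center = lo, range = hi - lo)
  })
}

#' Encode a cohort into the numeric feature matrix
#'
#' Deterministically maps each record to a numeric vector with one
#' coordinate per schema item, every coordinate in \[0, 1\]:
#' \itemize{
#'   \item ternary items: absent/negative = 0, unknown = 0.5,
#'     present/positive = 1 ("unknown" sits equidistant from both definite
#'     answers);
#'   \item laboratory values: min–max scaled to \[0, 1\] with cohort-wide
#'     parameters;
#'   \item antibody titers: min–max scaled on the log2 scale, since titers
#'     live on a geometric doubling-dilution ladder.
#' }
#' A missing tolerated item (urine protein per day with "no data") encodes
#' as 0 g/day, consistent with its role in the kidney rule. A degenerate
#' item (cohort max equals min) encodes as 0 with a warning.
#'
#' @param cohort Curated, complete-case cohort tibble.
#' @param schema Schema tibble.
#' @param scaling Optional scaling tibble from a previous call (attribute
#'   `scaling` of the result); fitted from `cohort` when `NULL`.
#' @return Numeric matrix, patients x items (schema order), with attributes
#'   `scaling` (tibble) and `patient_ids`.
#' @export
encode_features <- function(cohort, schema = sle_schema(), scaling = NULL) {
  validate_schema(schema, strict = FALSE)
  if (is.null(scaling)) scaling <- fit_feature_scaling(cohort, schema)
  n <- nrow(cohort)
  mat <- matrix(0, nrow = n, ncol = nrow(schema),
                dimnames = list(cohort$patient_id, schema$item_id))
  degenerate <- character()
  for (i in seq_len(nrow(schema))) {
    id <- schema$item_id[i]
    kind <- schema$kind[i]
    if (kind %in% TERNARY_KINDS) {
      x <- cohort[[id]]
      v <- dplyr::case_when(
        x %in% c("present", "positive") ~ 1,
        x %in% c("absent", "negative") ~ 0,
        x == "unknown" ~ 0.5,
        TRUE ~ NA_real_
      )
      mat[, i] <- v
    } else {
      x <- cohort[[id]]
      if (id %in% TOLERATED_MISSING_ITEMS) x[is.na(x)] <- 0
      if (kind == "titer-continuous") x <- log2(pmax(x, 1))
      sc <- scaling[scaling$item_id == id, ]
      if (nrow(sc) != 1L) abort(paste0("no scaling parameters for item ", id))
      if (sc$range <= 0) {
        degenerate <- c(degenerate, id)
        mat[, i] <- 0
      } else {
        mat[, i] <- pmin(pmax((x - sc$center) / sc$range, 0), 1)
      }
    }
  }
  if (length(degenerate) > 0) {
    warn(paste0("degenerate scaling (max = min); coordinate set to 0 for: ",
                paste(degenerate, collapse = ", ")))
  }
  if (anyNA(mat)) abort("encode_features requires a complete cohort (run drop_incomplete first)")
  attr(mat, "scaling") <- scaling
  attr(mat, "patient_ids") <- cohort$patient_id
  mat
}

#' Decode a feature matrix back to item values
#'
#' Inverts [encode_features()] given the stored scaling parameters: ternary
#' coordinates map back to their codes, continuous coordinates back to raw
#' units (titers through the inverse log2). Used to verify that encoding is
#' lossless up to the scaling resolution.
#'
#' @param features Encoded matrix with a `scaling` attribute (or pass
#'   `scaling` explicitly).
#' @param schema Schema tibble.
#' @param scaling Scaling tibble.
#' @return A cohort tibble (without missingness: tolerated missing cells
#'   come back as their encoded stand-in).
#' @export
decode_features <- function(features, schema = sle_schema(),
                            scaling = attr(features, "scaling")) {
  if (is.null(scaling)) abort("decode_features needs scaling parameters")
  out <- tibble::tibble(patient_id = attr(features, "patient_ids") %||%
                          as.character(seq_len(nrow(features))))
  for (i in seq_len(nrow(schema))) {
    id <- schema$item_id[i]
    kind <- schema$kind[i]
    v <- features[, i]
    if (kind %in% TERNARY_KINDS) {
      codes <- ternary_codes(kind)
      out[[id]] <- dplyr::case_when(
        v == 1 ~ codes[1], v == 0 ~ codes[2], TRUE ~ codes[3]
      )
    } else {
      sc <- scaling[scaling$item_id == id, ]
      x <- v * sc$range + sc$center
      if (kind == "titer-continuous") x <- 2^x
      out[[id]] <- x
    }
  }
  out
}

# Cohort matrix ---------------------------------------------------------------

#' Run the full curation chain and build the model-ready cohort matrix
#'
#' Chains [deduplicate()], [repair_erroneous()] and [drop_incomplete()],
#' classifies kidney involvement, dichotomizes every ternary manifestation,
#' and encodes the features. The chain is idempotent: curating an already
#' curated cohort changes nothing.
#'
#' @param cohort Raw cohort tibble (e.g. from [load_cohort()]).
#' @param schema Schema tibble.
#' @param unknown_as Dichotomization of an "unknown" manifestation answer
#'   when used as a binary label: `"absent"` (default) scores it 0;
#'   `"exclude"` scores it `NA` so downstream scans drop the patient for
#'   that manifestation only.
#' @return An object of class `cohort_matrix`: a list with `patient_ids`,
#'   `features` (n x items numeric matrix in \[0,1\]), `kidney_involvement`
#'   (0/1), `labels` (tibble of binary manifestation flags), `cohort`
#'   (curated records), `scaling`, `schema` and `report`
#'   (a `curation_report`).
#' @export
curate_cohort <- function(cohort, schema = sle_schema(),
                          unknown_as = c("absent", "exclude")) {
  unknown_as <- match.arg(unknown_as)
  validate_schema(schema, strict = FALSE)
  step1 <- deduplicate(cohort)
  step2 <- repair_erroneous(step1$cohort, schema, step1$report)
  step3 <- drop_incomplete(step2$cohort, schema, step2$report)
  curated <- step3$cohort
  report <- step3$report
  stopifnot(report$n_output == nrow(curated))

  features <- encode_features(curated, schema)
  kidney <- classify_kidney_involvement(curated)
  labels <- dichotomize_manifestations(curated, schema, unknown_as)

  structure(
    list(
      patient_ids = curated$patient_id,
      features = features,
      kidney_involvement = kidney,
      labels = labels,
      cohort = curated,
      scaling = attr(features, "scaling"),
      schema = schema,
      report = report
    ),
    class = "cohort_matrix"
  )
}

# Binary 0/1 flags for each ternary manifestation; "unknown" handled per
# the dichotomization mode.
dichotomize_manifestations <- function(cohort, schema, unknown_as = "absent") {
  ids <- schema_items(schema, "manifestation-ternary")
  out <- purrr::map(setNames(ids, ids), function(id) {
    x <- cohort[[id]]
    flag <- as.integer(!is.na(x) & x == "present")
    if (unknown_as == "exclude") flag[!is.na(x) & x == "unknown"] <- NA_integer_
    flag
  })
  tibble::as_tibble(out)
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d patients x %d items; %d (%.1f%%) with kidney involvement\n",
              nrow(x$features), ncol(x$features),
              sum(x$kidney_involvement),
              100 * mean(x$kidney_involvement)))
  invisible(x)
}

#' Tidy a cohort matrix
#'
#' @param x A `cohort_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per patient: id, kidney flag and encoded
#'   features as columns.
#' @method tidy cohort_matrix
#' @export
tidy.cohort_matrix <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(patient_id = x$patient_ids,
                   kidney_involvement = x$kidney_involvement),
    tibble::as_tibble(x$features)
  )
}
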