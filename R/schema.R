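# Survey-item schema ---------------------------------------------------------
#
# The feature space is a fixed set of survey items of four kinds:
#   manifestation-ternary  present / absent / unknown
#   lab-continuous         numeric, with a per-item plausible range
#   titer-continuous       antibody dilution titers (ANA, anti-dsDNA)
#   autoantibody-ternary   positive / negative / unknown
# The reference schema has exactly 75 items, mirroring the registry survey
# form ("Personal Clinical Record") for new SLE registrations.

SCHEMA_KINDS <- c(
  "manifestation-ternary", "lab-continuous",
  "titer-continuous", "autoantibody-ternary"
)

TERNARY_KINDS <- c("manifestation-ternary", "autoantibody-ternary")
CONTINUOUS_KINDS <- c("lab-continuous", "titer-continuous")

# codes a ternary cell may hold (besides NA = missing)
MANIFESTATION_CODES <- c("present", "absent", "unknown")
AUTOANTIBODY_CODES <- c("positive", "negative", "unknown")

# item ids with fixed semantics used by the kidney rule and the scans
RENAL_MANIFESTATION_ITEMS <- c(
  "rpgn", "nephrotic_syndrome", "acute_renal_failure", "chronic_renal_failure"
)
KIDNEY_RULE_ITEMS <- c(
  "urine_protein_qual", "urine_protein_day", "granular_casts",
  RENAL_MANIFESTATION_ITEMS
)
# items whose missingness is tolerated by the kidney rule ("< 0.5 g or no data")
TOLERATED_MISSING_ITEMS <- "urine_protein_day"

REQUIRED_ITEM_IDS <- c(
  "ana_titer", "dsdna_titer", "wbc", "lymphocytes", "complement",
  KIDNEY_RULE_ITEMS, "hemolytic_anemia", "arthritis", "myalgia", "pleurisy"
)

#' Reference 75-item survey schema
#'
#' Builds the package's reference schema: one row per survey item with a
#' stable `item_id`, a human-readable `label`, the item `kind` (ternary
#' clinical manifestation, continuous laboratory value, antibody titer, or
#' ternary autoantibody result) and, for continuous kinds, a plausible range
#' used to flag erroneous entries. The schema contains exactly 75 items and
#' includes all items with fixed semantics: the two antibody titers
#' (antinuclear and anti-dsDNA), the urinary/renal items that define the
#' kidney-involvement rule, and the manifestations analysed by the
#' association scans (hemolytic anemia, non-destructive arthritis,
#' myalgia/myositis, pleurisy). Remaining slots are filled with common SLE
#' manifestations plus generic filler items, standing in for the full
#' registry item list, which is not reproduced here.
#'
#' @return A tibble with columns `item_id`, `label`, `kind`, `range_low`,
#'   `range_high` (range columns are `NA` for ternary kinds).
#' @examples
#' sch <- sle_schema()
#' nrow(sch) # 75
#' @export
sle_schema <- function() {
  lab <- function(id, label, lo, hi) {
    tibble::tibble(
      item_id = id, label = label, kind = "lab-continuous",
      range_low = lo, range_high = hi
    )
  }
  man <- function(id, label) {
    tibble::tibble(
      item_id = id, label = label, kind = "manifestation-ternary",
      range_low = NA_real_, range_high = NA_real_
    )
  }
  ab <- function(id, label) {
    tibble::tibble(
      item_id = id, label = label, kind = "autoantibody-ternary",
      range_low = NA_real_, range_high = NA_real_
    )
  }
  titer <- function(id, label) {
    tibble::tibble(
      item_id = id, label = label, kind = "titer-continuous",
      range_low = 0, range_high = 40960
    )
  }

  named_manifestations <- c(
    granular_casts = "Granular casts",
    rpgn = "Rapidly progressive glomerulonephritis",
    nephrotic_syndrome = "Nephrotic syndrome",
    acute_renal_failure = "Acute renal failure",
    chronic_renal_failure = "Chronic renal failure",
    hemolytic_anemia = "Hemolytic anemia",
    arthritis = "Non-destructive arthritis (two or more lesions)",
    myalgia = "Myalgia (myositis)",
    pleurisy = "Pleurisy",
    malar_rash = "Malar rash",
    discoid_rash = "Discoid rash",
    photosensitivity = "Photosensitivity",
    oral_ulcers = "Oral ulcers",
    alopecia = "Alopecia",
    raynaud = "Raynaud phenomenon",
    purpura = "Purpura",
    fever = "Fever",
    lymphadenopathy = "Lymphadenopathy",
    pericarditis = "Pericarditis",
    seizure = "Seizure",
    psychosis = "Psychosis",
    peripheral_neuropathy = "Peripheral neuropathy",
    interstitial_pneumonia = "Interstitial pneumonia",
    pulmonary_hypertension = "Pulmonary hypertension",
    leukopenia = "Leukopenia",
    thrombocytopenia = "Thrombocytopenia"
  )
  n_filler <- 55L - length(named_manifestations)
  filler_ids <- sprintf("manifestation_%02d", seq_len(n_filler))
  filler_labels <- sprintf("Clinical manifestation item %02d", seq_len(n_filler))

  schema <- dplyr::bind_rows(
    titer("ana_titer", "Antinuclear antibody titer"),
    titer("dsdna_titer", "Anti-dsDNA antibody titer"),
    lab("wbc", "White blood cells (cells/uL)", 0, 50000),
    lab("lymphocytes", "Lymphocytes (cells/uL)", 0, 20000),
    lab("complement", "Complement CH50 (U/mL)", 0, 300),
    lab("urine_protein_day", "Urine protein per day (g)", 0, 30),
    lab("hemoglobin", "Hemoglobin (g/dL)", 0, 25),
    lab("platelets", "Platelets (10^3/uL)", 0, 1500),
    lab("creatinine", "Serum creatinine (mg/dL)", 0, 20),
    lab("crp", "C-reactive protein (mg/dL)", 0, 50),
    lab("esr", "Erythrocyte sedimentation rate (mm/h)", 0, 200),
    lab("albumin", "Serum albumin (g/dL)", 0, 10),
    ab("urine_protein_qual", "Urine protein qualitative test"),
    ab("anti_sm", "Anti-Sm antibody"),
    ab("anti_rnp", "Anti-RNP antibody"),
    ab("anti_ssa", "Anti-SS-A antibody"),
    ab("anti_ssb", "Anti-SS-B antibody"),
    ab("lupus_anticoagulant", "Lupus anticoagulant"),
    ab("anti_cardiolipin", "Anti-cardiolipin antibody"),
    ab("direct_coombs", "Direct Coombs test"),
    man(names(named_manifestations), unname(named_manifestations)),
    man(filler_ids, filler_labels)
  )
  validate_schema(schema)
  schema
}

#' Validate a survey-item schema
#'
#' Checks structural invariants: unique item ids, known kinds, finite ordered
#' plausible ranges for continuous items. With `strict = TRUE` (the default
#' used by the pipeline) additionally requires exactly 75 items and the
#' presence of every item with fixed semantics (titers, kidney-rule items,
#' scanned manifestations).
#'
#' @param schema A schema tibble as returned by [sle_schema()].
#' @param strict Enforce the 75-item reference contract?
#' @return `schema`, invisibly, after validation.
#' @export
validate_schema <- function(schema, strict = TRUE) {
  stopifnot(is.data.frame(schema))
  need <- c("item_id", "label", "kind", "range_low", "range_high")
  missing_cols <- setdiff(need, names(schema))
  if (length(missing_cols) > 0) {
    abort(paste0("schema lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(schema$item_id)) {
    abort("schema item_id values must be unique")
  }
  bad_kind <- setdiff(unique(schema$kind), SCHEMA_KINDS)
  if (length(bad_kind) > 0) {
    abort(paste0("unknown schema kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  cont <- schema[schema$kind %in% CONTINUOUS_KINDS, ]
  if (nrow(cont) > 0 &&
      (anyNA(cont$range_low) || anyNA(cont$range_high) ||
       any(cont$range_low >= cont$range_high))) {
    abort("continuous items need finite plausible ranges with range_low < range_high")
  }
  if (strict) {
    if (nrow(schema) != 75L) {
      abort(sprintf("reference schema must have exactly 75 items, got %d", nrow(schema)))
    }
    miss <- setdiff(REQUIRED_ITEM_IDS, schema$item_id)
    if (length(miss) > 0) {
      abort(paste0("schema lacks required item(s): ", paste(miss, collapse = ", ")))
    }
  }
  invisible(schema)
}

#' Read / write a schema as YAML
#'
#' The on-disk schema format is a YAML list of items, each with `item_id`,
#' `label`, `kind` and (continuous kinds only) `plausible_range: [low, high]`.
#'
#' @param path File path.
#' @param schema Schema tibble.
#' @param strict Passed to [validate_schema()].
#' @return `read_schema_yaml()` returns a schema tibble; `write_schema_yaml()`
#'   returns `path` invisibly.
#' @export
read_schema_yaml <- function(path, strict = TRUE) {
  raw <- yaml::read_yaml(path)
  schema <- purrr::map_dfr(raw, function(it) {
    rng <- it$plausible_range %||% c(NA_real_, NA_real_)
    tibble::tibble(
      item_id = it$item_id, label = it$label, kind = it$kind,
      range_low = as.numeric(rng[[1]]), range_high = as.numeric(rng[[2]])
    )
  })
  validate_schema(schema, strict = strict)
  schema
}

#' @rdname read_schema_yaml
#' @export
write_schema_yaml <- function(schema, path, strict = TRUE) {
  validate_schema(schema, strict = strict)
  items <- purrr::pmap(schema, function(item_id, label, kind, range_low, range_high) {
    it <- list(item_id = item_id, label = label, kind = kind)
    if (kind %in% CONTINUOUS_KINDS) {
      it$plausible_range <- c(range_low, range_high)
    }
    it
  })
  yaml::write_yaml(items, path)
  invisible(path)
}

# codes legal for a ternary item of the given kind
ternary_codes <- function(kind) {
  if (kind == "manifestation-ternary") MANIFESTATION_CODES else AUTOANTIBODY_CODES
}

schema_items <- function(schema, kinds) schema$item_id[schema$kind %in% kinds]
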