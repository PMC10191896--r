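# Synthetic cohort generation -------------------------------------------------
#
# The real registry is access-restricted, so the pipeline is exercised on
# synthetic cohorts with known ground truth. The generator emulates the
# survey-form schema and plants the structure the analysis is meant to
# find: a subgroup with high anti-dsDNA and low antinuclear-antibody titers
# inside which hemolytic anemia is positively, and the inflammatory
# manifestations (arthritis, myalgia, pleurisy) negatively, associated with
# kidney involvement. Duplicates, out-of-range errors and missingness are
# injected separately so curation can be tested against a known manifest.

#' Synthetic cohort configuration
#'
#' Parameters of the generative model. Effects are differences in
#' manifestation probability between kidney-involved and non-involved
#' patients, applied symmetrically around the base rate
#' (`p(kidney+) = base + effect/2`, `p(kidney-) = base - effect/2`), then
#' clipped into \[0.01, 0.99\] (clipping is logged on the result). Titers are
#' drawn log-normally per stratum and quantized to the doubling-dilution
#' ladder 40, 80, 160, 320, 640, ...
#'
#' @param n_patients Number of patients to generate.
#' @param seed Master seed; every patient draws from a counter-based stream
#'   derived from it, so earlier patients are unchanged when more are added.
#' @param p_kidney Baseline kidney-involvement prevalence (default 0.54,
#'   the prevalence reported for the analysable registry cohort).
#' @param subgroup_fraction Fraction of patients in the planted
#'   high-dsDNA / low-ANA subgroup.
#' @param effect_hemolytic Signed kidney-association effect for hemolytic
#'   anemia inside the subgroup.
#' @param effect_inflammatory Signed effect shared by arthritis, myalgia and
#'   pleurisy inside the subgroup.
#' @param background_effect Signed effect for every other manifestation,
#'   and for all manifestations outside the subgroup.
#' @param base_rate_scanned Base prevalence of the four scanned
#'   manifestations (anemia + inflammatory).
#' @param base_rate_other Base prevalence of the remaining manifestations.
#' @param titer_params Named list with `subgroup` and `background` entries,
#'   each holding `dsdna_meanlog`, `dsdna_sdlog`, `ana_meanlog`,
#'   `ana_sdlog` (log-normal on the dilution scale).
#' @param lab_params Tibble (`item_id`, `mean`, `sd`) of Gaussian parameters
#'   for laboratory items; items not listed default to mid-range with
#'   range/8 spread. Draws are truncated to the schema's plausible range.
#' @param severity_slope Strength (logit units per SD) of the latent
#'   disease-activity factor on the non-scanned manifestations. The factor
#'   is drawn per patient, independent of the kidney flag and the planted
#'   effects, and also shifts the laboratory means (via the
#'   `severity` column of `lab_params`), emulating the correlation of
#'   registry items with overall disease activity.
#' @param subgroup_lab_shift Named numeric vector of additive mean shifts
#'   applied to laboratory items inside the planted subgroup; the default
#'   lowers complement, the classic hypocomplementemia accompanying high
#'   anti-dsDNA titers.
#' @param dsdna_kidney_shift,dsdna_severity_shift Shifts (log-dilution
#'   units) of the anti-dsDNA titer mean per kidney-involvement flag and
#'   per SD of disease activity, reflecting the titer's established role
#'   as a nephritis/activity marker.
#' @param p_autoantibody_positive Background positivity probability of the
#'   ternary autoantibody items.
#' @param subgroup_ab_positive Named vector of positivity probabilities
#'   overriding `p_autoantibody_positive` inside the planted subgroup. The
#'   default enriches anti-Sm, direct Coombs, anti-cardiolipin and lupus
#'   anticoagulant: the subgroup is a coherent serological phenotype, not a
#'   two-titer shift, which is both clinically realistic and what makes it
#'   discoverable by a low-rank embedding.
#' @param subgroup_manifestation_shift Named additive shifts of
#'   manifestation base rates inside the subgroup (default: enriched
#'   leukopenia and thrombocytopenia, the cytopenias accompanying active
#'   serology).
#' @param unknown_rate Probability that a non-renal ternary answer is
#'   recorded as the explicit code "unknown".
#' @param p_protein_no_data Probability that urine protein per day is
#'   "no data" for a patient satisfying the kidney-absence criteria.
#' @param dup_rate Fraction of records duplicated by [inject_artifacts()].
#' @param error_rate Fraction of continuous cells overwritten with
#'   out-of-range values by [inject_artifacts()].
#' @param missing_rate Fraction of cells blanked by [inject_artifacts()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 2000,
                             seed = 1L,
                             p_kidney = 0.54,
                             subgroup_fraction = 0.15,
                             effect_hemolytic = 0.3,
                             effect_inflammatory = -0.3,
                             background_effect = 0.05,
                             base_rate_scanned = 0.3,
                             base_rate_other = 0.15,
                             titer_params = NULL,
                             lab_params = NULL,
                             severity_slope = 1,
                             subgroup_lab_shift = c(complement = -12),
                             dsdna_kidney_shift = 0.3,
                             dsdna_severity_shift = 0.3,
                             p_autoantibody_positive = 0.12,
                             subgroup_ab_positive = c(
                               anti_sm = 0.7, direct_coombs = 0.7,
                               anti_cardiolipin = 0.7, lupus_anticoagulant = 0.7
                             ),
                             subgroup_manifestation_shift = c(
                               leukopenia = 0.4, thrombocytopenia = 0.4
                             ),
                             unknown_rate = 0.03,
                             p_protein_no_data = 0.1,
                             dup_rate = 0.02,
                             error_rate = 0.005,
                             missing_rate = 0.01) {
  titer_params <- titer_params %||% list(
    subgroup = list(dsdna_meanlog = log(200), dsdna_sdlog = 0.6,
                    ana_meanlog = log(50), ana_sdlog = 0.5),
    background = list(dsdna_meanlog = log(50), dsdna_sdlog = 0.5,
                      ana_meanlog = log(640), ana_sdlog = 0.7)
  )
  # `severity` = additive mean shift per SD of the disease-activity factor:
  # acute-phase markers rise, complement / blood counts / albumin fall
  lab_params <- lab_params %||% tibble::tribble(
    ~item_id, ~mean, ~sd, ~severity,
    "wbc", 6000, 2500, -500,
    "lymphocytes", 1500, 700, -300,
    "complement", 35, 12, -8,
    "hemoglobin", 12, 2, -1,
    "platelets", 220, 80, -30,
    "creatinine", 0.9, 0.5, 0.1,
    "crp", 1.5, 2, 1.5,
    "esr", 30, 20, 15,
    "albumin", 3.8, 0.6, -0.3
  )
  if (!"severity" %in% names(lab_params)) lab_params$severity <- 0
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    p_kidney = p_kidney, subgroup_fraction = subgroup_fraction,
    effect_hemolytic = effect_hemolytic,
    effect_inflammatory = effect_inflammatory,
    background_effect = background_effect,
    base_rate_scanned = base_rate_scanned,
    base_rate_other = base_rate_other,
    titer_params = titer_params, lab_params = lab_params,
    severity_slope = severity_slope,
    subgroup_lab_shift = subgroup_lab_shift,
    dsdna_kidney_shift = dsdna_kidney_shift,
    dsdna_severity_shift = dsdna_severity_shift,
    p_autoantibody_positive = p_autoantibody_positive,
    subgroup_ab_positive = subgroup_ab_positive,
    subgroup_manifestation_shift = subgroup_manifestation_shift,
    unknown_rate = unknown_rate,
    p_protein_no_data = p_protein_no_data,
    dup_rate = dup_rate, error_rate = error_rate, missing_rate = missing_rate
  )
  probs <- c(p_kidney, subgroup_fraction, p_autoantibody_positive,
             unknown_rate, p_protein_no_data, dup_rate, error_rate,
             missing_rate, base_rate_scanned, base_rate_other)
  if (any(probs < 0 | probs > 1)) abort("probabilities and rates must lie in [0, 1]")
  if (cfg$n_patients < 0) abort("n_patients must be non-negative")
  structure(cfg, class = "synthetic_config")
}

INFLAMMATORY_ITEMS <- c("arthritis", "myalgia", "pleurisy")
SCANNED_ITEMS <- c("hemolytic_anemia", INFLAMMATORY_ITEMS)

# quantize a raw titer to the doubling-dilution ladder 40 * 2^k, censored
# at the form's top dilution 1280 (k = 0..5); rounding happens on the log2
# scale, the natural metric for dilutions
quantize_titer <- function(x) {
  k <- pmin(pmax(round(log2(x / 40)), 0), 5)
  40 * 2^k
}

# conditional manifestation probabilities implied by a config, with the
# [0.01, 0.99] clipping applied; one row per (item, subgroup, kidney) cell
realized_probabilities <- function(config, schema) {
  man_ids <- setdiff(schema_items(schema, "manifestation-ternary"),
                     c("granular_casts", RENAL_MANIFESTATION_ITEMS))
  grid <- tidyr::expand_grid(
    item_id = man_ids, subgroup = c(0L, 1L), kidney = c(0L, 1L)
  )
  grid$base <- ifelse(grid$item_id %in% SCANNED_ITEMS,
                      config$base_rate_scanned, config$base_rate_other)
  shift <- config$subgroup_manifestation_shift %||% numeric(0)
  hit <- grid$subgroup == 1L & grid$item_id %in% names(shift)
  grid$base[hit] <- grid$base[hit] + unname(shift[grid$item_id[hit]])
  grid$effect <- dplyr::case_when(
    grid$subgroup == 1L & grid$item_id == "hemolytic_anemia" ~ config$effect_hemolytic,
    grid$subgroup == 1L & grid$item_id %in% INFLAMMATORY_ITEMS ~ config$effect_inflammatory,
    TRUE ~ config$background_effect
  )
  raw <- grid$base + ifelse(grid$kidney == 1L, grid$effect / 2, -grid$effect / 2)
  grid$p <- pmin(pmax(raw, 0.01), 0.99)
  grid$clipped <- grid$p != raw
  grid
}

#' Generate a synthetic cohort with known ground truth
#'
#' Per patient, in order: draw subgroup membership; draw kidney involvement;
#' set the urinary/renal items so that [classify_kidney_involvement()]
#' reproduces the drawn flag exactly (kidney-involved patients receive at
#' least one absence-criterion violation chosen uniformly, non-involved
#' patients satisfy all four); draw ANA and anti-dsDNA titers from the
#' stratum's log-normal quantized to the doubling-dilution ladder; draw the
#' remaining manifestations Bernoulli with the configured signed effects;
#' draw the laboratory values from truncated Gaussians. The whole cohort is
#' deterministic given `config$seed` and each patient has an independent
#' counter-based stream.
#'
#' @param config A [synthetic_config()].
#' @param schema Schema tibble; must contain the required reference items.
#' @return A list with `cohort` (tibble, uncorrupted) and `truth` (tibble:
#'   `patient_id`, `subgroup`, `kidney_involvement`), the latter carrying
#'   the realized conditional probability table as attribute
#'   `probabilities` (column `clipped` flags cells hit by the \[0.01, 0.99\]
#'   clip).
#' @export
generate_cohort <- function(config = synthetic_config(), schema = sle_schema()) {
  validate_schema(schema, strict = FALSE)
  miss <- setdiff(REQUIRED_ITEM_IDS, schema$item_id)
  if (length(miss) > 0) {
    abort(paste0("schema lacks required item(s) for generation: ",
                 paste(miss, collapse = ", ")))
  }
  n <- config$n_patients
  probs <- realized_probabilities(config, schema)
  if (any(probs$clipped)) {
    inform(sprintf("%d conditional probabilities clipped into [0.01, 0.99]",
                   sum(probs$clipped)))
  }
  man_ids <- unique(probs$item_id)
  ab_ids <- setdiff(schema_items(schema, "autoantibody-ternary"), "urine_protein_qual")
  lab_ids <- setdiff(schema_items(schema, "lab-continuous"), "urine_protein_day")
  lp <- config$lab_params
  lab_mean <- setNames(rep(NA_real_, length(lab_ids)), lab_ids)
  lab_sd <- lab_mean
  lab_sev <- lab_mean
  for (id in lab_ids) {
    row <- schema[schema$item_id == id, ]
    if (id %in% lp$item_id) {
      lab_mean[id] <- lp$mean[lp$item_id == id]
      lab_sd[id] <- lp$sd[lp$item_id == id]
      lab_sev[id] <- lp$severity[lp$item_id == id]
    } else {
      lab_mean[id] <- (row$range_low + row$range_high) / 2
      lab_sd[id] <- (row$range_high - row$range_low) / 8
      lab_sev[id] <- 0
    }
  }
  sub_shift <- config$subgroup_lab_shift %||% numeric(0)
  lab_lo <- setNames(schema$range_low[match(lab_ids, schema$item_id)], lab_ids)
  lab_hi <- setNames(schema$range_high[match(lab_ids, schema$item_id)], lab_ids)

  # probability lookup: item x (subgroup, kidney)
  pkey <- paste(probs$item_id, probs$subgroup, probs$kidney)
  plook <- setNames(probs$p, pkey)

  rows <- vector("list", n)
  truth_sub <- integer(n)
  truth_kid <- integer(n)
  for (i in seq_len(n)) {
    rows[[i]] <- local_seed(derive_seed(config$seed, "patient", i), {
      subgroup <- rbinom(1, 1, config$subgroup_fraction)
      kidney <- rbinom(1, 1, config$p_kidney)
      severity <- rnorm(1) # disease-activity factor, independent of kidney
      rec <- list(patient_id = sprintf("SYN%05d", i))

      # urinary / renal items consistent with the kidney flag
      if (kidney == 0L) {
        rec$urine_protein_qual <- "negative"
        rec$urine_protein_day <- if (runif(1) < config$p_protein_no_data) NA_real_ else runif(1, 0, 0.49)
        rec$granular_casts <- "absent"
        for (id in RENAL_MANIFESTATION_ITEMS) rec[[id]] <- "absent"
      } else {
        violation <- sample.int(4L, 1L)
        extra <- runif(4) < 0.3
        viol <- extra
        viol[violation] <- TRUE
        rec$urine_protein_qual <- if (viol[1]) "positive" else "negative"
        rec$urine_protein_day <- if (viol[2]) {
          runif(1, 0.5, 8)
        } else if (runif(1) < config$p_protein_no_data) NA_real_ else runif(1, 0, 0.49)
        rec$granular_casts <- if (viol[3]) "present" else "absent"
        renal <- rep("absent", 4)
        if (viol[4]) {
          renal[sample.int(4L, 1L)] <- "present"
          renal[renal == "absent"][runif(sum(renal == "absent")) < 0.2] <- "present"
        }
        for (j in seq_along(RENAL_MANIFESTATION_ITEMS)) {
          rec[[RENAL_MANIFESTATION_ITEMS[j]]] <- renal[j]
        }
      }

      # antibody titers by stratum, on the dilution ladder; anti-dsDNA also
      # tracks kidney involvement and disease activity (its textbook role)
      tp <- if (subgroup == 1L) config$titer_params$subgroup else config$titer_params$background
      dsdna_mu <- tp$dsdna_meanlog +
        config$dsdna_kidney_shift * kidney + config$dsdna_severity_shift * severity
      rec$dsdna_titer <- quantize_titer(rlnorm(1, dsdna_mu, tp$dsdna_sdlog))
      rec$ana_titer <- quantize_titer(rlnorm(1, tp$ana_meanlog, tp$ana_sdlog))

      # manifestations with planted effects; non-scanned ones additionally
      # ride the severity factor (kept off the scanned items so their
      # kidney-association differences stay exactly as configured)
      for (id in man_ids) {
        p <- plook[[paste(id, subgroup, kidney)]]
        if (!(id %in% SCANNED_ITEMS)) {
          p <- stats::plogis(stats::qlogis(p) + config$severity_slope * severity)
        }
        x <- if (rbinom(1, 1, p) == 1L) "present" else "absent"
        if (runif(1) < config$unknown_rate) x <- "unknown"
        rec[[id]] <- x
      }

      # other autoantibodies; the subgroup carries its serological profile
      for (id in ab_ids) {
        p_pos <- config$p_autoantibody_positive
        if (subgroup == 1L && id %in% names(config$subgroup_ab_positive)) {
          p_pos <- config$subgroup_ab_positive[[id]]
        }
        x <- if (rbinom(1, 1, p_pos) == 1L) "positive" else "negative"
        if (runif(1) < config$unknown_rate) x <- "unknown"
        rec[[id]] <- x
      }

      # laboratory values, truncated to the plausible range
      for (id in lab_ids) {
        mu <- lab_mean[id] + lab_sev[id] * severity
        if (subgroup == 1L && id %in% names(sub_shift)) mu <- mu + sub_shift[[id]]
        rec[[id]] <- pmin(pmax(rnorm(1, mu, lab_sd[id]), lab_lo[id]), lab_hi[id])
      }
      list(rec = rec, subgroup = subgroup, kidney = kidney)
    })
    truth_sub[i] <- rows[[i]]$subgroup
    truth_kid[i] <- rows[[i]]$kidney
  }

  cohort <- if (n == 0) {
    empty <- c(list(patient_id = character()),
               purrr::map(setNames(schema$item_id, schema$item_id), function(id) {
                 if (schema$kind[schema$item_id == id] %in% CONTINUOUS_KINDS) numeric() else character()
               }))
    tibble::as_tibble(empty)
  } else {
    dplyr::bind_rows(purrr::map(rows, ~tibble::as_tibble(.x$rec)))[, c("patient_id", schema$item_id)]
  }
  truth <- tibble::tibble(
    patient_id = cohort$patient_id,
    subgroup = truth_sub,
    kidney_involvement = truth_kid
  )
  attr(truth, "probabilities") <- probs
  list(cohort = cohort, truth = truth)
}

#' Inject curation artifacts into a clean cohort
#'
#' Corrupts a cohort the way real registry extracts are corrupted, driven by
#' `config$seed`: overwrites randomly chosen continuous cells with
#' out-of-range values (`error_rate` of continuous cells), blanks randomly
#' chosen cells (`missing_rate` of all cells; chosen disjoint from the error
#' cells so each injected error remains repairable), and finally appends
#' exact duplicates of randomly chosen corrupted records (`dup_rate` of
#' records, fresh patient ids). Duplication happens last so each duplicate
#' is exactly identical to its source record and deduplication removes
#' precisely the injected copies.
#'
#' @param cohort Uncorrupted cohort tibble.
#' @param config A [synthetic_config()].
#' @param schema Schema tibble.
#' @return A list with `cohort` (corrupted) and `manifest`, a list of
#'   tibbles `errors` (`patient_id`, `item_id`, `bad_value`,
#'   `original_value`), `missing` (`patient_id`, `item_id`,
#'   `original_value`) and `duplicates` (`source_patient_id`,
#'   `new_patient_id`).
#' @export
inject_artifacts <- function(cohort, config, schema = sle_schema()) {
  n <- nrow(cohort)
  cont_ids <- intersect(schema_items(schema, CONTINUOUS_KINDS), names(cohort))
  all_ids <- intersect(schema$item_id, names(cohort))
  local_seed(derive_seed(config$seed, "artifacts"), {
    # out-of-range errors in continuous cells
    n_err <- round(config$error_rate * n * length(cont_ids))
    err_cells <- tibble::tibble(patient_id = character(), item_id = character(),
                                bad_value = numeric(), original_value = numeric())
    if (n_err > 0) {
      idx <- sample.int(n * length(cont_ids), n_err)
      row_i <- ((idx - 1L) %% n) + 1L
      col_i <- ((idx - 1L) %/% n) + 1L
      ids <- cont_ids[col_i]
      hi <- schema$range_high[match(ids, schema$item_id)]
      lo <- schema$range_low[match(ids, schema$item_id)]
      above <- runif(n_err) < 0.5
      bad <- ifelse(above, hi + runif(n_err, 1, 100), lo - runif(n_err, 1, 100))
      orig <- vapply(seq_len(n_err), function(k) cohort[[ids[k]]][row_i[k]], numeric(1))
      err_cells <- tibble::tibble(
        patient_id = cohort$patient_id[row_i], item_id = ids,
        bad_value = bad, original_value = orig
      )
      for (k in seq_len(n_err)) cohort[[ids[k]]][row_i[k]] <- bad[k]
    }

    # missingness, disjoint from the error cells
    n_miss <- round(config$missing_rate * n * length(all_ids))
    miss_cells <- tibble::tibble(patient_id = character(), item_id = character(),
                                 original_value = character())
    if (n_miss > 0) {
      taken <- paste(err_cells$patient_id, err_cells$item_id)
      pool <- seq_len(n * length(all_ids))
      pool_row <- ((pool - 1L) %% n) + 1L
      pool_col <- ((pool - 1L) %/% n) + 1L
      pool_key <- paste(cohort$patient_id[pool_row], all_ids[pool_col])
      pool <- pool[!(pool_key %in% taken)]
      idx <- sample(pool, min(n_miss, length(pool)))
      row_i <- ((idx - 1L) %% n) + 1L
      col_i <- ((idx - 1L) %/% n) + 1L
      ids <- all_ids[col_i]
      orig <- vapply(seq_along(idx), function(k) as.character(cohort[[ids[k]]][row_i[k]]),
                     character(1))
      miss_cells <- tibble::tibble(
        patient_id = cohort$patient_id[row_i], item_id = ids, original_value = orig
      )
      for (id in unique(ids)) {
        cohort[[id]][row_i[ids == id]] <- if (is.numeric(cohort[[id]])) NA_real_ else NA_character_
      }
    }

    # exact duplicates of corrupted records, appended last
    n_dup <- round(config$dup_rate * n)
    dup_tbl <- tibble::tibble(source_patient_id = character(), new_patient_id = character())
    if (n_dup > 0 && n > 0) {
      src <- sample.int(n, min(n_dup, n))
      dups <- cohort[src, , drop = FALSE]
      new_ids <- sprintf("DUP%05d", seq_along(src))
      dup_tbl <- tibble::tibble(source_patient_id = dups$patient_id,
                                new_patient_id = new_ids)
      dups$patient_id <- new_ids
      cohort <- dplyr::bind_rows(cohort, dups)
    }
    list(cohort = cohort,
         manifest = list(errors = err_cells, missing = miss_cells, duplicates = dup_tbl))
  })
}
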