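# End-to-end pipeline ---------------------------------------------------------
#
# One configuration drives curation -> training -> embedding ->
# attribution -> association scans -> subgroup extraction, writing every
# intermediate as a plain-text artifact. A single master seed fans out to
# per-stage seeds through a fixed derivation, so any stage can be rerun in
# isolation and two runs with the same configuration are bit-identical.

#' Pipeline configuration
#'
#' Exactly one of `cohort_path` (a cohort CSV on disk) or `synthetic`
#' (a [synthetic_config()]) must be supplied as the data source.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param synthetic A [synthetic_config()], or `NULL` when reading a CSV.
#' @param cohort_path Path to a cohort CSV, or `NULL` when simulating.
#' @param schema Schema tibble (validated strictly).
#' @param network An [ae_config()]. The pipeline default raises `epochs` to
#'   50 so the embedding is converged enough for the scans.
#' @param scan A [scan_config()].
#' @param attribution_subset `"kidney"` (patients with kidney involvement,
#'   the default) or `"all"`.
#' @param dsdna_cutoff Anti-dsDNA exclusion cutoff for plane analyses.
#' @param adapt_regions When `TRUE` (default), scan windows and thresholds
#'   are re-anchored on quantiles of the fitted embedding rather than the
#'   published absolute coordinates, which are specific to the original
#'   model fit and have no meaning for a freshly trained network.
#' @param corrupt When simulating, pass the cohort through
#'   [inject_artifacts()] first so curation has work to do (default TRUE).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            synthetic = synthetic_config(),
                            cohort_path = NULL,
                            schema = sle_schema(),
                            network = ae_config(epochs = 50),
                            scan = scan_config(),
                            attribution_subset = c("kidney", "all"),
                            dsdna_cutoff = 500,
                            adapt_regions = TRUE,
                            corrupt = TRUE) {
  if (is.null(synthetic) == is.null(cohort_path)) {
    abort("supply exactly one of synthetic config or cohort_path")
  }
  validate_schema(schema, strict = TRUE)
  structure(list(
    out_dir = out_dir, seed = as.integer(seed),
    synthetic = synthetic, cohort_path = cohort_path,
    schema = schema, network = network, scan = scan,
    attribution_subset = match.arg(attribution_subset),
    dsdna_cutoff = dsdna_cutoff,
    adapt_regions = adapt_regions,
    corrupt = corrupt
  ), class = "pipeline_config")
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full profiling pipeline
#'
#' Executes every stage behind one seed and writes plain-text artifacts to
#' `config$out_dir`: the schema (`schema.yaml`), raw and curated cohort
#' CSVs, the curation report and ground truth (JSON), scaling parameters
#' (`scaling.csv`), the training loss history, the latent embedding
#' (`latent.csv`: patient_id, x, y, z), contribution-rate and signed-mean
#' tables, the high-titer exclusion mask, Pattern-1 and Pattern-2
#' association-curve CSVs for the scanned manifestations, the subgroup
#' mask, and a reproducibility manifest (`manifest.json` with the
#' configuration hash, seed, versions and stage counts). Reruns with the
#' same configuration produce byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and
#'   `artifacts`, the named vector of file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  emit <- function(name, path) paths[[name]] <<- path
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  schema <- config$schema
  write_schema_yaml(schema, file.path(config$out_dir, "schema.yaml"))
  emit("schema", file.path(config$out_dir, "schema.yaml"))

  # -- data source ----------------------------------------------------------
  src <- stage("data", {
    if (!is.null(config$cohort_path)) {
      list(cohort = load_cohort(config$cohort_path, schema),
           truth = NULL, manifest = NULL)
    } else {
      syn_cfg <- config$synthetic
      syn_cfg$seed <- derive_seed(config$seed, "synthetic")
      gen <- generate_cohort(syn_cfg, schema)
      out <- list(cohort = gen$cohort, truth = gen$truth, manifest = NULL)
      if (config$corrupt) {
        corr <- inject_artifacts(gen$cohort, syn_cfg, schema)
        out$cohort <- corr$cohort
        out$manifest <- corr$manifest
      }
      out
    }
  })
  raw <- src$cohort
  truth <- src$truth
  manifest_artifacts <- src$manifest
  write_cohort_csv(raw, file.path(config$out_dir, "cohort_raw.csv"))
  emit("cohort_raw", file.path(config$out_dir, "cohort_raw.csv"))
  if (!is.null(truth)) {
    readr::write_csv(truth, file.path(config$out_dir, "ground_truth.csv"))
    emit("ground_truth", file.path(config$out_dir, "ground_truth.csv"))
  }

  # -- curation -------------------------------------------------------------
  cm <- stage("curation", curate_cohort(raw, schema))
  write_cohort_csv(cm$cohort, file.path(config$out_dir, "curated_cohort.csv"))
  emit("curated_cohort", file.path(config$out_dir, "curated_cohort.csv"))
  write_json_artifact(tidy(cm$report), file.path(config$out_dir, "curation_report.json"))
  emit("curation_report", file.path(config$out_dir, "curation_report.json"))
  readr::write_csv(cm$scaling, file.path(config$out_dir, "scaling.csv"))
  emit("scaling", file.path(config$out_dir, "scaling.csv"))

  # -- training -------------------------------------------------------------
  net_cfg <- config$network
  net_cfg$seed <- derive_seed(config$seed, "network")
  model <- stage("training", ae_train(build_autoencoder(net_cfg), cm))
  readr::write_csv(
    tibble::tibble(iteration = seq_along(model$loss_history),
                   loss = model$loss_history),
    file.path(config$out_dir, "loss_history.csv")
  )
  emit("loss_history", file.path(config$out_dir, "loss_history.csv"))

  # -- embedding ------------------------------------------------------------
  embedding <- stage("embedding", ae_encode(model, cm))
  readr::write_csv(embedding, file.path(config$out_dir, "latent.csv"))
  emit("latent", file.path(config$out_dir, "latent.csv"))

  # -- attribution ----------------------------------------------------------
  contrib <- stage("attribution", {
    subset <- if (config$attribution_subset == "kidney") "kidney" else NULL
    contribution_rates(model, cm, subset = subset)
  })
  readr::write_csv(contrib, file.path(config$out_dir, "contribution.csv"))
  emit("contribution", file.path(config$out_dir, "contribution.csv"))
  readr::write_csv(attr(contrib, "signed_means"),
                   file.path(config$out_dir, "signed_means.csv"))
  emit("signed_means", file.path(config$out_dir, "signed_means.csv"))

  excl <- stage("exclusion", exclude_high_dsdna(embedding, cm, config$dsdna_cutoff))
  readr::write_csv(
    tibble::tibble(patient_id = embedding$patient_id, excluded = excl$excluded),
    file.path(config$out_dir, "exclusion_mask.csv")
  )
  emit("exclusion_mask", file.path(config$out_dir, "exclusion_mask.csv"))

  # -- association scans ----------------------------------------------------
  keep <- !excl$excluded
  kid2 <- cm$kidney_involvement[keep]
  plane_sel <- stage("plane", select_feature_plane(excl$embedding, cm$cohort[keep, ]))
  emb2 <- plane_sel$plane
  readr::write_csv(
    tibble::tibble(plane_axis = c("x", "z"),
                   latent_axis = c(plane_sel$x_axis, plane_sel$z_axis)),
    file.path(config$out_dir, "feature_plane.csv")
  )
  emit("feature_plane", file.path(config$out_dir, "feature_plane.csv"))
  scan_cfg <- config$scan
  if (config$adapt_regions) {
    qx <- quantile(emb2$x, c(0.55, 0.90), names = FALSE)
    qz <- quantile(emb2$z, c(0.05, 0.30, 0.40, 0.50, 0.60, 0.70, 0.95), names = FALSE)
    scan_cfg$x_range_pattern2 <- c(qx[1], qx[2])
    scan_cfg$z_thresholds <- sort(unique(qz[2:6]))
    pattern2_thresholds <- seq(qz[1], qz[7], length.out = 101)
    pattern1_thresholds <- scan_cfg$z_thresholds
  } else {
    pattern2_thresholds <- NULL
    pattern1_thresholds <- scan_cfg$z_thresholds
  }

  scanned <- intersect(SCANNED_ITEMS, names(cm$labels))
  scans <- stage("scans", {
    p1 <- purrr::map_dfr(pattern1_thresholds, function(th) {
      cur <- scan_pattern1(emb2, kid2, cm$labels$hemolytic_anemia[keep],
                           z_threshold = th, config = scan_cfg,
                           manifestation = "hemolytic_anemia")
      dplyr::mutate(cur, z_threshold = th, .before = 1)
    })
    readr::write_csv(p1, file.path(config$out_dir, "scan_pattern1_hemolytic_anemia.csv"))
    emit("scan_pattern1", file.path(config$out_dir, "scan_pattern1_hemolytic_anemia.csv"))
    p2 <- purrr::map(setNames(scanned, scanned), function(item) {
      cur <- scan_pattern2(emb2, kid2, cm$labels[[item]][keep],
                           config = scan_cfg, thresholds = pattern2_thresholds,
                           manifestation = item)
      f <- file.path(config$out_dir, sprintf("scan_pattern2_%s.csv", item))
      readr::write_csv(cur, f)
      emit(paste0("scan_pattern2_", item), f)
      cur
    })
    list(pattern1 = p1, pattern2 = p2)
  })

  # -- subgroup -------------------------------------------------------------
  sub_region <- if (config$adapt_regions) {
    region(x_lo = scan_cfg$x_range_pattern2[1],
           z_lo = min(scan_cfg$z_thresholds), z_hi = max(scan_cfg$z_thresholds))
  } else {
    region(x_lo = 0.530, z_lo = 0.490, z_hi = 0.495)
  }
  sub_mask <- stage("subgroup", extract_subgroup(emb2, sub_region))
  readr::write_csv(
    tibble::tibble(patient_id = emb2$patient_id, in_subgroup = as.logical(sub_mask)),
    file.path(config$out_dir, "subgroup_mask.csv")
  )
  emit("subgroup_mask", file.path(config$out_dir, "subgroup_mask.csv"))

  # -- manifest -------------------------------------------------------------
  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    package_version = as.character(utils::packageVersion("nephroscape")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_raw = nrow(raw),
    n_curated = nrow(cm$cohort),
    n_kidney_involved = sum(cm$kidney_involvement),
    n_high_dsdna_excluded = excl$n_excluded,
    n_subgroup = sum(sub_mask),
    final_loss = tail_loss(model)
  )
  write_json_artifact(manifest, file.path(config$out_dir, "manifest.json"))
  emit("manifest", file.path(config$out_dir, "manifest.json"))

  invisible(list(
    raw = raw, truth = truth, corruption_manifest = manifest_artifacts,
    cohort_matrix = cm, model = model, embedding = embedding,
    contribution = contrib, exclusion = excl, scans = scans,
    subgroup_mask = sub_mask, manifest = manifest,
    artifacts = unlist(paths)
  ))
}
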