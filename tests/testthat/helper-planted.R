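# End-to-end planted-structure runs, shared by the acceptance suite.
# Each run: generate the default synthetic cohort -> curate -> train the
# autoencoder (epochs raised to 50 for a converged embedding) -> exclude
# high anti-dsDNA titers -> select the titer feature plane -> Pattern-2
# scan at thresholds bounding the planted subgroup region. Cached so the
# 20 seeded runs are computed once per test session.

.planted_cache <- new.env(parent = emptyenv())

planted_run <- function(seed) {
  cfg <- synthetic_config(n_patients = 2000, seed = seed)
  gen <- generate_cohort(cfg)
  cm <- curate_cohort(gen$cohort)
  truth <- gen$truth[match(cm$patient_ids, gen$truth$patient_id), ]
  model <- ae_train(build_autoencoder(ae_config(seed = seed)), cm, epochs = 50)
  emb <- ae_encode(model, cm)
  ex <- exclude_high_dsdna(emb, cm)
  keep <- !ex$excluded
  plane <- select_feature_plane(ex$embedding, cm$cohort[keep, ])$plane
  sub <- truth$subgroup[keep] == 1
  kid <- cm$kidney_involvement[keep]

  # x-strip and z-thresholds bounding the planted subgroup region
  x_rng <- quantile(plane$x[sub], c(0.1, 0.9), names = FALSE)
  thr <- quantile(plane$z[sub], c(0.80, 0.85, 0.90, 0.95), names = FALSE)
  stat_below <- function(item) {
    cur <- scan_pattern2(plane, kid, cm$labels[[item]][keep],
                         config = scan_config(), thresholds = thr,
                         x_range = x_rng, manifestation = item)
    stats::median(cur$stat_below, na.rm = TRUE)
  }
  list(
    seed = seed,
    anemia_below = stat_below("hemolytic_anemia"),
    arthritis_below = stat_below("arthritis"),
    top3 = top_contributors(contribution_rates(model, cm, subset = "kidney"), 3),
    n_curated = nrow(cm$cohort),
    subgroup_fraction = mean(sub)
  )
}

planted_runs <- function(seeds = 1:20) {
  key <- paste(seeds, collapse = ",")
  if (is.null(.planted_cache[[key]])) {
    .planted_cache[[key]] <- lapply(seeds, planted_run)
  }
  .planted_cache[[key]]
}
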