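# Shared fixtures, built in code.

# A minimal 8-item schema for fast unit tests: covers every kind and the
# full kidney rule.
tiny_schema <- function() {
  tibble::tibble(
    item_id = c("urine_protein_qual", "urine_protein_day", "granular_casts",
                "rpgn", "nephrotic_syndrome", "acute_renal_failure",
                "chronic_renal_failure", "wbc"),
    label = c("Urine protein qualitative", "Urine protein per day (g)",
              "Granular casts", "RPGN", "Nephrotic syndrome",
              "Acute renal failure", "Chronic renal failure",
              "White blood cells"),
    kind = c("autoantibody-ternary", "lab-continuous", "manifestation-ternary",
             rep("manifestation-ternary", 4), "lab-continuous"),
    range_low = c(NA, 0, NA, NA, NA, NA, NA, 0),
    range_high = c(NA, 30, NA, NA, NA, NA, NA, 50000)
  )
}

# One kidney-absent record on the tiny schema; override fields to build cases.
tiny_record <- function(patient_id = "p1", ...) {
  rec <- tibble::tibble(
    patient_id = patient_id,
    urine_protein_qual = "negative",
    urine_protein_day = 0.2,
    granular_casts = "absent",
    rpgn = "absent",
    nephrotic_syndrome = "absent",
    acute_renal_failure = "absent",
    chronic_renal_failure = "absent",
    wbc = 6000
  )
  overrides <- list(...)
  for (nm in names(overrides)) rec[[nm]] <- overrides[[nm]]
  rec
}

# A tiny trained-shape autoencoder over d inputs with bottleneck 3,
# weights random but reproducible.
tiny_model <- function(d = 6, sizes = c(d, 5, 3), seed = 42,
                       hidden = "relu", bottleneck = "sigmoid") {
  cfg <- ae_config(layer_sizes_encoder = sizes,
                   hidden_activation = hidden,
                   bottleneck_activation = bottleneck,
                   seed = seed)
  build_autoencoder(cfg)
}

# hand-placed embedding for region-membership tests
toy_embedding <- function(x, z, y = 0.5) {
  out <- tibble::tibble(patient_id = as.character(seq_along(x)),
                        x = x, y = rep(y, length(x)), z = z)
  class(out) <- c("latent_embedding", class(out))
  out
}

# brute-force reference for the pooled two-proportion z statistic
oracle_pooled_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
}
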