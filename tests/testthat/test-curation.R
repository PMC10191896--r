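# Curation: loading, dedup, repair, kidney rule, completeness, encoding.

test_that("load_cohort preserves rows, maps codes, and flags bad cells", {
  sch <- tiny_schema()
  cohort <- dplyr::bind_rows(
    tiny_record("a"),
    tiny_record("b", granular_casts = "unknown"),
    tiny_record("c", wbc = 7000)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cohort, path, na = "")
  loaded <- load_cohort(path, sch)
  expect_equal(nrow(loaded), 3L)
  expect_equal(loaded$granular_casts, c("absent", "unknown", "absent"))
  expect_equal(loaded$wbc, c(6000, 6000, 7000))

  # non-numeric text in a lab column becomes missing, with a warning
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  raw$wbc[2] <- "not-a-number"
  raw$granular_casts[3] <- "presentish"
  readr::write_csv(raw, path, na = "")
  expect_warning(reloaded <- load_cohort(path, sch), "unparseable")
  expect_true(is.na(reloaded$wbc[2]))
  expect_true(is.na(reloaded$granular_casts[3]))
})

test_that("load_cohort errors on unknown columns and empty files", {
  sch <- tiny_schema()
  path <- withr::local_tempfile(fileext = ".csv")
  bad <- tiny_record("a")
  bad$mystery_item <- 1
  readr::write_csv(bad, path, na = "")
  expect_error(load_cohort(path, sch), "mystery_item")
  writeLines("patient_id", path)
  expect_error(load_cohort(path, sch), "empty|lacks")
})

test_that("deduplicate keeps the first of identical records, ignoring patient_id", {
  a <- tiny_record("a")
  b <- tiny_record("b") # same values, different id
  c <- tiny_record("c", wbc = 9000)
  res <- deduplicate(dplyr::bind_rows(a, b, c))
  expect_equal(res$cohort$patient_id, c("a", "c"))
  expect_equal(res$report$n_duplicates_removed, 1L)

  res2 <- deduplicate(dplyr::bind_rows(a, c))
  expect_equal(res2$report$n_duplicates_removed, 0L)
  expect_equal(nrow(res2$cohort), 2L)
})

test_that("deduplicate matches a brute-force pairwise oracle on random cohorts", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      m <- 20L
      k <- sample(2:6, 1)
      base <- purrr::map_dfr(seq_len(m - k + 1L), function(i) {
        tiny_record(sprintf("p%02d", i), wbc = sample(3000:9000, 1),
                    urine_protein_day = round(runif(1, 0, 0.4), 3))
      })
      # k identical copies of record 1 inserted at random positions
      copies <- base[rep(1, k - 1L), ]
      copies$patient_id <- sprintf("copy%d", seq_len(k - 1L))
      cohort <- dplyr::bind_rows(base, copies)
      cohort <- cohort[sample(nrow(cohort)), ]

      res <- deduplicate(cohort)

      # oracle: quadratic pairwise comparison over value maps
      vals <- cohort[setdiff(names(cohort), "patient_id")]
      keep <- rep(TRUE, nrow(vals))
      for (i in seq_len(nrow(vals))) {
        if (!keep[i]) next
        for (j in seq_len(i - 1L)) {
          if (keep[j] && isTRUE(all.equal(vals[i, ], vals[j, ], check.attributes = FALSE))) {
            keep[i] <- FALSE
            break
          }
        }
      }
      expect_equal(res$cohort$patient_id, cohort$patient_id[keep])
      expect_equal(nrow(res$cohort), m - k + 1L)
    }
  })
})

test_that("repair_erroneous replaces out-of-range values by the in-range median", {
  sch <- tiny_schema()
  wbcs <- c(-5, 4000, 5000, 6000, 7000, 8000, 9000, 10000, 11000, 12000)
  cohort <- purrr::map_dfr(seq_along(wbcs), function(i) {
    tiny_record(sprintf("p%d", i), wbc = wbcs[i])
  })
  res <- repair_erroneous(cohort, sch)
  # independent median by sorting the 9 in-range values
  expected <- sort(wbcs[-1])[5]
  expect_equal(res$cohort$wbc[1], expected)
  expect_equal(res$report$n_imputed_values, 1L)
  expect_equal(res$report$imputation_log$old_value, -5)

  clean <- repair_erroneous(res$cohort, sch)
  expect_equal(clean$report$n_imputed_values, 0L)
  expect_equal(clean$cohort, res$cohort)
})

test_that("repair_erroneous blanks items with no in-range values at all", {
  sch <- tiny_schema()
  cohort <- dplyr::bind_rows(
    tiny_record("a", wbc = -1),
    tiny_record("b", wbc = -2)
  )
  expect_warning(res <- repair_erroneous(cohort, sch), "no in-range")
  expect_true(all(is.na(res$cohort$wbc)))
})

test_that("kidney rule follows the stated criteria on key cases", {
  # all four absence criteria met
  expect_equal(classify_kidney_involvement(tiny_record()), 0L)
  # urine protein per day missing ("no data") still absent
  expect_equal(classify_kidney_involvement(tiny_record(urine_protein_day = NA_real_)), 0L)
  # nephrotic syndrome observed -> present despite clean urine
  expect_equal(classify_kidney_involvement(tiny_record(nephrotic_syndrome = "present")), 1L)
  # exact 0.5 g boundary counts as not "< 0.5 g"
  expect_equal(classify_kidney_involvement(tiny_record(urine_protein_day = 0.5)), 1L)
  expect_equal(classify_kidney_involvement(tiny_record(urine_protein_day = 0.499)), 0L)
  # qualitative test unknown cannot confirm absence
  expect_equal(classify_kidney_involvement(tiny_record(urine_protein_qual = "unknown")), 1L)
})

test_that("kidney rule equals the 4-clause conjunction on the full truth table", {
  grid <- tidyr::expand_grid(
    qual = c("negative", "positive", "unknown"),
    protein = c(0.2, 0.5, 0.8, NA_real_),
    casts = c("absent", "present", "unknown"),
    renal = c("none", "rpgn", "nephrotic_syndrome",
              "acute_renal_failure", "chronic_renal_failure")
  )
  cohort <- purrr::pmap_dfr(grid, function(qual, protein, casts, renal) {
    rec <- tiny_record(urine_protein_qual = qual, urine_protein_day = protein,
                       granular_casts = casts)
    if (renal != "none") rec[[renal]] <- "present"
    rec
  })
  got <- classify_kidney_involvement(cohort)
  # independently coded conjunction, written directly from the four criteria
  expected <- purrr::pmap_int(grid, function(qual, protein, casts, renal) {
    c1 <- identical(qual, "negative")
    c2 <- is.na(protein) || protein < 0.5
    c3 <- !identical(casts, "present")
    c4 <- renal == "none"
    as.integer(!(c1 && c2 && c3 && c4))
  })
  expect_equal(got, expected)
})

test_that("drop_incomplete removes missing records but tolerates absent urine protein", {
  sch <- tiny_schema()
  cohort <- dplyr::bind_rows(
    tiny_record("complete"),
    tiny_record("lab_missing", wbc = NA_real_),
    tiny_record("protein_missing", urine_protein_day = NA_real_),
    tiny_record("unknown_answer", granular_casts = "unknown")
  )
  res <- drop_incomplete(cohort, sch)
  expect_setequal(res$cohort$patient_id, c("complete", "protein_missing", "unknown_answer"))
  expect_equal(res$report$n_incomplete_removed, 1L)

  full <- drop_incomplete(res$cohort, sch)
  expect_equal(full$report$n_incomplete_removed, 0L)
})

test_that("encode_features maps ternary codes and scales continuous items into [0,1]", {
  sch <- tiny_schema()
  cohort <- dplyr::bind_rows(
    tiny_record("a", granular_casts = "present", wbc = 3000, urine_protein_day = 0.1),
    tiny_record("b", granular_casts = "unknown", wbc = 6000, urine_protein_day = 0.2),
    tiny_record("c", granular_casts = "absent", wbc = 9000, urine_protein_day = 0.3)
  )
  f <- encode_features(cohort, sch)
  expect_equal(unname(f[, "granular_casts"]), c(1, 0.5, 0))
  expect_equal(unname(f[, "wbc"]), c(0, 0.5, 1)) # min-max identity
  expect_true(all(f >= 0 & f <= 1))
})

test_that("degenerate scaling (max = min) encodes as zero with a warning", {
  sch <- tiny_schema()
  cohort <- dplyr::bind_rows(tiny_record("a"), tiny_record("b", granular_casts = "present"))
  expect_warning(f <- encode_features(cohort, sch), "degenerate")
  expect_equal(unname(f[, "wbc"]), c(0, 0))
})

test_that("encoding round-trips through decode_features on random cohorts", {
  sch <- tiny_schema()
  withr::with_seed(5, {
    for (rep in 1:5) {
      cohort <- purrr::map_dfr(1:12, function(i) {
        tiny_record(
          sprintf("p%02d", i),
          urine_protein_qual = sample(c("positive", "negative", "unknown"), 1),
          granular_casts = sample(c("present", "absent", "unknown"), 1),
          urine_protein_day = round(runif(1, 0, 5), 4),
          wbc = round(runif(1, 2000, 15000))
        )
      })
      f1 <- encode_features(cohort, sch)
      decoded <- decode_features(f1, sch)
      f2 <- encode_features(decoded, sch, scaling = attr(f1, "scaling"))
      expect_equal(unname(f2), unname(f1), tolerance = 1e-12)
    }
  })
})

test_that("full curation chain is idempotent and its counts balance", {
  cfg <- synthetic_config(n_patients = 150, seed = 21)
  gen <- generate_cohort(cfg)
  corr <- inject_artifacts(gen$cohort, cfg)

  cm1 <- suppressWarnings(curate_cohort(corr$cohort))
  rep1 <- tidy(cm1$report)
  expect_equal(rep1$n_output,
               rep1$n_input - rep1$n_duplicates_removed - rep1$n_incomplete_removed)

  cm2 <- suppressWarnings(curate_cohort(cm1$cohort))
  expect_equal(cm2$cohort, cm1$cohort)
  expect_equal(cm2$report$n_duplicates_removed, 0L)
  expect_equal(cm2$report$n_imputed_values, 0L)
  expect_equal(cm2$report$n_incomplete_removed, 0L)
})

test_that("unknown manifestations dichotomize per the configured mode", {
  cfg <- synthetic_config(n_patients = 60, seed = 3)
  gen <- generate_cohort(cfg)
  cm_abs <- curate_cohort(gen$cohort)
  cm_exc <- curate_cohort(gen$cohort, unknown_as = "exclude")
  unknown_cells <- cm_abs$cohort$hemolytic_anemia == "unknown"
  expect_equal(cm_abs$labels$hemolytic_anemia[unknown_cells],
               rep(0L, sum(unknown_cells)))
  expect_equal(is.na(cm_exc$labels$hemolytic_anemia), unknown_cells)
})
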