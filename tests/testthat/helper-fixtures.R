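# In-code fixtures: metadata-only cohorts for split/noise/evaluation logic,
# and a cached small rendered cohort for tests that need real pixels.

# Cohort tibble without images (image_path points nowhere); fine for all
# patient/split/label bookkeeping.
meta_cohort <- function(n_patients_per_site = c(A = 6L),
                        tiles_per_patient = 8L,
                        classes_per_patient = NULL,
                        grades = NULL,
                        seed = 1L) {
  rows <- list()
  pat_i <- 0L
  for (site in names(n_patients_per_site)) {
    for (p in seq_len(n_patients_per_site[[site]])) {
      pat_i <- pat_i + 1L
      pid <- sprintf("%s_P%02d", site, p)
      grade <- if (is.null(grades)) 1L + (pat_i %% 3L) else grades[[pat_i]]
      cls <- if (is.null(classes_per_patient)) {
        rep_len(c(0L, 1L), tiles_per_patient)
      } else {
        rep_len(classes_per_patient[[pat_i]], tiles_per_patient)
      }
      rows[[pat_i]] <- tibble::tibble(
        tile_id = sprintf("%s_T%02d", pid, seq_len(tiles_per_patient)),
        patient_id = pid, site_id = site, quality_grade = grade,
        class_label = cls,
        image_path = sprintf("/nonexistent/%s.png", sprintf("%s_T%02d", pid, seq_len(tiles_per_patient))))
    }
  }
  new_tile_cohort(dplyr::bind_rows(rows))
}

# A small rendered, undegraded, losslessly stored cohort; built once per
# test run.
.fixture_env <- new.env(parent = emptyenv())
rendered_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    site <- site_profile("U", 20L, c("1" = 1, "2" = 0, "3" = 0))
    .fixture_env$dir <- tempfile("fixture_cohort_")
    .fixture_env$cohort <- generate_cohort(list(site), tiles_per_patient = 6L,
                                           tile_size = 32L, seed = 99L,
                                           out_dir = .fixture_env$dir)
  }
  .fixture_env$cohort
}

# Random vote matrix with named tiles.
random_votes <- function(n_tiles, n_members, seed = 1L) {
  withr::with_seed(seed, {
    v <- matrix(rbinom(n_tiles * n_members, 1, runif(1, 0.2, 0.8)),
                n_tiles, n_members)
    rownames(v) <- sprintf("t%03d", seq_len(n_tiles))
    vote_matrix(v)
  })
}

# Stub backend: training only advances an epoch counter; prediction
# follows a preset schedule. With all-1 validation labels, the realized
# validation accuracy at epoch e is exactly val_schedule[e] (the first
# round(acc * n) tiles get p = 0.9, the rest p = 0.1), so checkpoint
# logic can be tested without touching pixels.
stub_backend <- function(val_schedule, const_prob = NULL) {
  noisytile:::new_tile_backend(
    "stub", list(),
    featurize = function(img) c(mean(img)),
    init = function(d, seed) list(epoch = 0L),
    train_epoch = function(state, X, y, seed) {
      state$epoch <- state$epoch + 1L
      state
    },
    predict = function(state, X) {
      n <- nrow(X)
      if (!is.null(const_prob)) return(rep(const_prob, n))
      k <- round(val_schedule[[max(1L, state$epoch)]] * n)
      c(rep(0.9, k), rep(0.1, n - k))
    })
}
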