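#' Configure the packaged benchmark experiment
#'
#' Desk-scale defaults: three sites of 30 patients, 8 tiles per patient
#' at 64 px, 7-member ensembles trained for 10 epochs, noise levels 0
#' and 0.15, 3 repeats. The reference design's full scale (15 members,
#' 10 repeats, noise sweep 0-0.30, 512-px tiles, 40 tiles/patient) is
#' reachable by overriding these fields.
#'
#' @param sites List of [site_profile()]s (default [default_sites()]).
#' @param tiles_per_patient,tile_size,class_balance Cohort geometry, see
#'   [generate_cohort()].
#' @param train_sites Site ids to train site-restricted ensembles on
#'   (each also gets `"all"`-style shared test pools).
#' @param n_test_per_site Held-out patients per site per repeat.
#' @param n_repeats Number of repeated splits.
#' @param n_members Odd ensemble size.
#' @param val_fraction Member validation fraction.
#' @param epochs Training epochs.
#' @param noise_levels Numeric vector of label-flip fractions, all
#'   `< 0.5`.
#' @param backend_params Parameter list for [pooled_mlp_backend()].
#' @param seed Global experiment seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(sites = default_sites(30L),
                              tiles_per_patient = 8L,
                              tile_size = 64L,
                              class_balance = 0.5,
                              train_sites = c("A", "B"),
                              n_test_per_site = 7L,
                              n_repeats = 3L,
                              n_members = 7L,
                              val_fraction = 0.2,
                              epochs = 10L,
                              noise_levels = c(0, 0.15),
                              backend_params = list(),
                              seed = 1L) {
  if (any(noise_levels < 0 | noise_levels >= 0.5)) {
    abort_bad("noise levels must lie in [0, 0.5)")
  }
  if (n_members %% 2 == 0 || n_members < 3) abort_bad("n_members must be odd and >= 3")
  structure(list(sites = sites, tiles_per_patient = as.integer(tiles_per_patient),
                 tile_size = as.integer(tile_size), class_balance = class_balance,
                 train_sites = train_sites,
                 n_test_per_site = as.integer(n_test_per_site),
                 n_repeats = as.integer(n_repeats),
                 n_members = as.integer(n_members),
                 val_fraction = val_fraction, epochs = as.integer(epochs),
                 noise_levels = noise_levels,
                 backend_params = backend_params, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Serialize / restore an experiment config (JSON or YAML)
#' @param config An `experiment_config`.
#' @param path File path ending in `.json` or `.yaml`/`.yml`.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$sites <- lapply(config$sites, function(s) {
    list(site_id = s$site_id, n_patients = s$n_patients,
         quality_mix = as.list(s$quality_mix),
         jpeg_quality = s$jpeg_quality,
         degradation_by_grade = lapply(s$degradation_by_grade, unclass))
  })
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_bad("YAML configs require the yaml package")
    }
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_bad("YAML configs require the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  sites <- lapply(x$sites, function(s) {
    degr <- lapply(s$degradation_by_grade, function(d) {
      degradation_profile(blur_sigma = d$blur_sigma,
                          contrast_factor = d$contrast_factor,
                          brightness_shift = d$brightness_shift,
                          stain_gain = unlist(d$stain_gain),
                          jpeg_quality = if (identical(d$jpeg_quality, "none"))
                            "none" else as.integer(d$jpeg_quality))
    })
    site_profile(s$site_id, s$n_patients,
                 unlist(s$quality_mix),
                 degradation_by_grade = degr,
                 jpeg_quality = if (identical(s$jpeg_quality, "none"))
                   "none" else as.integer(s$jpeg_quality))
  })
  experiment_config(sites = sites, tiles_per_patient = x$tiles_per_patient,
                    tile_size = x$tile_size, class_balance = x$class_balance,
                    train_sites = unlist(x$train_sites),
                    n_test_per_site = x$n_test_per_site,
                    n_repeats = x$n_repeats, n_members = x$n_members,
                    val_fraction = x$val_fraction, epochs = x$epochs,
                    noise_levels = unlist(x$noise_levels),
                    backend_params = x$backend_params %||% list(),
                    seed = x$seed)
}

bench_log <- function(quiet, ...) {
  if (!quiet) message(sprintf("[noisytile] %s", sprintf(...)))
}

#' Run the packaged noisy-ensemble benchmark
#'
#' End to end: generate the synthetic cohort, build site-restricted
#' patient splits with a shared cross-site test pool, sweep the noise
#' levels (per-patient single-class selection plus exact-fraction label
#' flipping), train the member ensembles with best-epoch checkpointing,
#' collect votes on the held-out test tiles, and evaluate accuracy by
#' test site / quality grade, agreement curves, and quality-grade
#' statistics.
#'
#' The single-class selection is drawn once per repeat, so runs at
#' different noise levels share identical member partitions and differ
#' only in training labels.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional output directory; when given, plans, vote
#'   matrices, curves and aggregate tables are written beneath it.
#' @param quiet Suppress progress messages?
#' @return A `benchmark_result` list of tibbles: `accuracy` (per
#'   train-site/noise/repeat/test-site ensemble and group accuracy),
#'   `curves` (agreement curves), `agreement_by_correctness`,
#'   `by_quality` (per-patient accuracy with quality grade, clean
#'   models), `quality_stats` (ANOVA + Holm pairs when estimable), and
#'   `cohort`.
#' @export
run_benchmark <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  bench_log(quiet, "stage simulate: seed %d", config$seed)
  cohort_dir <- if (is.null(out_dir)) tempfile("bench_cohort_") else
    file.path(out_dir, "cohort")
  cohort <- generate_cohort(config$sites, config$tiles_per_patient,
                            config$tile_size, config$class_balance,
                            seed = config$seed, out_dir = cohort_dir)
  backend <- do.call(pooled_mlp_backend, config$backend_params)
  bench_log(quiet, "stage featurize: %d tiles", nrow(cohort))
  features <- tile_features(cohort, backend)

  acc_rows <- list(); curve_rows <- list(); agree_rows <- list()
  quality_rows <- list()

  for (train_site in config$train_sites) {
    plans <- make_site_splits(cohort, train_site, config$n_test_per_site,
                              config$n_repeats, seed = config$seed)
    for (plan in plans) {
      r <- plan$repeat_index
      plan <- make_member_splits(plan, config$n_members, config$val_fraction,
                                 seed = derive_seed(config$seed, 50L + r))
      test_tiles <- tiles_of(cohort, plan$test_patients)
      sel_seed <- derive_seed(config$seed, 100L + r)
      for (ri in seq_along(config$noise_levels)) {
        rho <- config$noise_levels[ri]
        sel <- select_single_class(cohort, plan$train_pool, seed = sel_seed)
        np <- inject_label_noise(sel, rho,
                                 seed = derive_seed(config$seed, 200L + r, ri))
        cfg <- train_config(config$n_members, config$epochs, backend,
                            seed = derive_seed(config$seed, 300L + r))
        bench_log(quiet, "stage train: site %s repeat %d rho %.2f", train_site, r, rho)
        ens <- train_ensemble(cohort, plan, np, cfg, features = features)
        votes <- predict_members(ens, test_tiles, features = features)
        mv <- majority_vote(votes)
        truth <- stats::setNames(test_tiles$class_label, test_tiles$tile_id)

        per_site <- stratified_performance(votes, cohort, by = "site")
        grp <- vapply(sort(unique(test_tiles$site_id)), function(sid) {
          idx <- test_tiles$site_id == sid
          sub <- vote_matrix(unclass(votes)[idx, , drop = FALSE])
          group_accuracy(sub, truth[idx])
        }, numeric(1))
        acc_rows[[length(acc_rows) + 1L]] <- per_site |>
          dplyr::transmute(train_site = train_site, rho = rho, repeat_index = r,
                           test_site = .data$group, n_tiles = .data$n_tiles,
                           ensemble_accuracy = .data$accuracy,
                           group_accuracy = grp[as.character(.data$group)])

        curve <- accuracy_by_agreement(votes, truth)
        curve_rows[[length(curve_rows) + 1L]] <- dplyr::mutate(
          curve, train_site = train_site, rho = rho, repeat_index = r,
          .before = 1)

        correct <- mv$ensemble_label == truth[mv$tile_id]
        agree_rows[[length(agree_rows) + 1L]] <- tibble::tibble(
          train_site = train_site, rho = rho, repeat_index = r,
          mean_agreement = mean(mv$agreement),
          mean_agreement_correct = mean(mv$agreement[correct]),
          mean_agreement_incorrect = if (any(!correct))
            mean(mv$agreement[!correct]) else NA_real_)

        if (rho == 0) {
          pp <- stratified_performance(votes, cohort, by = "patient")
          pats <- cohort_patients(cohort)
          quality_rows[[length(quality_rows) + 1L]] <- pp |>
            dplyr::inner_join(pats, by = c(group = "patient_id")) |>
            dplyr::transmute(train_site = train_site, repeat_index = r,
                             patient_id = .data$group,
                             quality_grade = .data$quality_grade,
                             accuracy = .data$accuracy)
        }

        if (!is.null(out_dir)) {
          d <- file.path(out_dir, sprintf("train%s_rho%03d_rep%d",
                                          train_site, round(rho * 100), r))
          dir.create(d, recursive = TRUE, showWarnings = FALSE)
          write_split_plans(list(plan), file.path(d, "split_plan.json"))
          write_noise_plan(np, file.path(d, "noise_plan.json"))
          write_vote_matrix(votes, file.path(d, "votes.csv"))
          write_report(curve, file.path(d, "agreement_curve.csv"))
        }
      }
    }
  }

  by_quality <- dplyr::bind_rows(quality_rows)
  quality_stats <- NULL
  gs <- split(by_quality$accuracy, by_quality$quality_grade)
  gs <- gs[lengths(gs) >= 2]
  if (length(gs) >= 2 && !all(vapply(gs, stats::var, numeric(1)) == 0)) {
    quality_stats <- tryCatch(pairwise_t_holm(gs), error = function(e) NULL)
  }

  res <- structure(
    list(accuracy = dplyr::bind_rows(acc_rows),
         curves = dplyr::bind_rows(curve_rows),
         agreement_by_correctness = dplyr::bind_rows(agree_rows),
         by_quality = by_quality,
         quality_stats = quality_stats,
         cohort = cohort,
         config = config),
    class = "benchmark_result")

  if (!is.null(out_dir)) {
    readr::write_csv(res$accuracy, file.path(out_dir, "accuracy.csv"), progress = FALSE)
    readr::write_csv(res$curves, file.path(out_dir, "agreement_curves.csv"), progress = FALSE)
    readr::write_csv(res$agreement_by_correctness,
                     file.path(out_dir, "agreement_by_correctness.csv"), progress = FALSE)
    readr::write_csv(res$by_quality, file.path(out_dir, "accuracy_by_quality.csv"),
                     progress = FALSE)
    write_experiment_config(config, file.path(out_dir, "config.json"))
  }
  res
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  agg <- x$accuracy |>
    dplyr::summarise(ensemble_accuracy = mean(.data$ensemble_accuracy),
                     .by = c("train_site", "rho", "test_site"))
  print(tidyr::pivot_wider(agg, names_from = "test_site",
                           values_from = "ensemble_accuracy"))
  invisible(x)
}
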