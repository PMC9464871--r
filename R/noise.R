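#' Per-patient single-class tile selection
#'
#' For each training patient, tiles of exactly one class are retained
#' (the patient contributes either its cancerous or its non-cancerous
#' tiles, never both). Patients with only one class present are forced
#' to that class. With `balance = TRUE` (default) the free choices are
#' made greedily so the retained tile counts of the two classes stay as
#' close as possible; with `balance = FALSE` each free choice is a fair
#' coin. Deterministic under `seed`.
#'
#' @param cohort A `tile_cohort`.
#' @param training_patients Character vector of patient ids.
#' @param seed Integer seed.
#' @param balance Balance retained tile counts across classes?
#' @return List with `retained` (the retained cohort rows) and
#'   `patient_class_choice` (named integer vector, patient -> class).
#' @export
select_single_class <- function(cohort, training_patients, seed = 1L,
                                balance = TRUE) {
  if (length(training_patients) == 0) abort_bad("empty training set")
  tiles <- tiles_of(cohort, training_patients)
  if (nrow(tiles) == 0) abort_bad("empty training set")
  per_pat <- split(tiles$class_label, tiles$patient_id)

  choice <- with_seed(seed, {
    ord <- sample(names(per_pat))
    cnt <- c(`0` = 0L, `1` = 0L)
    ch <- stats::setNames(integer(length(per_pat)), names(per_pat))
    for (p in ord) {
      cls <- per_pat[[p]]
      n0 <- sum(cls == 0L); n1 <- sum(cls == 1L)
      pick <- if (n0 == 0L) 1L
      else if (n1 == 0L) 0L
      else if (!balance) sample(0:1, 1)
      else {
        d0 <- abs((cnt[["0"]] + n0) - cnt[["1"]])
        d1 <- abs(cnt[["0"]] - (cnt[["1"]] + n1))
        if (d0 < d1) 0L else if (d1 < d0) 1L else sample(0:1, 1)
      }
      ch[p] <- pick
      cnt[as.character(pick)] <- cnt[as.character(pick)] +
        (if (pick == 0L) n0 else n1)
    }
    ch
  })

  retained <- tiles |>
    dplyr::filter(.data$class_label == choice[.data$patient_id])
  list(retained = retained, patient_class_choice = choice)
}

#' Exact-fraction label-flip plan
#'
#' Selects exactly `round_half_up(rho * N)` of the `N` retained training
#' tiles uniformly without replacement (across patients and classes) to
#' have their labels flipped. `rho = 0` gives an empty flip set.
#'
#' @param retained Retained training tiles (rows of a `tile_cohort`),
#'   or the list returned by [select_single_class()].
#' @param rho Noise level, `0 <= rho < 0.5`. The reference study sweeps
#'   `{0, 0.05, ..., 0.30}`.
#' @param seed Integer seed.
#' @return A `noise_plan`: list with `rho`, `seed`, `flipped_tiles`,
#'   `retained_tiles`, `patient_class_choice` (if available).
#' @export
inject_label_noise <- function(retained, rho, seed = 1L) {
  choice <- NULL
  if (is.list(retained) && !is.data.frame(retained) &&
      !is.null(retained$retained)) {
    choice <- retained$patient_class_choice
    retained <- retained$retained
  }
  if (rho < 0 || rho >= 0.5) {
    abort_bad("noise level would exceed label informativeness (need 0 <= rho < 0.5)")
  }
  n <- nrow(retained)
  n_flip <- round_half_up(rho * n)
  flipped <- if (n_flip == 0L) character(0) else
    with_seed(seed, sort(sample(retained$tile_id, n_flip)))
  structure(
    list(rho = rho, seed = as.integer(seed), flipped_tiles = flipped,
         retained_tiles = retained$tile_id,
         patient_class_choice = choice),
    class = "noise_plan")
}

#' @export
print.noise_plan <- function(x, ...) {
  cat(sprintf("<noise_plan> rho = %.2f: %d of %d retained tiles flipped (seed %d)\n",
              x$rho, length(x$flipped_tiles), length(x$retained_tiles), x$seed))
  invisible(x)
}

#' Apply a noise plan to tile labels
#'
#' Returns training labels: flipped tiles get `1 - label`, all others
#' keep theirs. The cohort's ground-truth labels are never mutated.
#' Applying the same plan to its own output restores the input
#' (flipping is an involution).
#'
#' @param tiles Data frame with `tile_id` and a label column
#'   (`label` if present, else `class_label`).
#' @param plan A `noise_plan`.
#' @return Tibble with `tile_id` and `label`.
#' @export
apply_noise <- function(tiles, plan) {
  stopifnot(inherits(plan, "noise_plan"))
  lab <- if ("label" %in% names(tiles)) tiles$label else tiles$class_label
  unknown <- setdiff(plan$flipped_tiles, tiles$tile_id)
  if (length(unknown)) {
    abort_bad("noise plan references unknown tile(s): ",
              paste(utils::head(unknown, 3), collapse = ", "))
  }
  flip <- tiles$tile_id %in% plan$flipped_tiles
  tibble::tibble(tile_id = tiles$tile_id,
                 label = as.integer(ifelse(flip, 1L - lab, lab)))
}

#' One-call noise plan: single-class selection plus label flipping
#'
#' @inheritParams select_single_class
#' @inheritParams inject_label_noise
#' @return A `noise_plan` (see [inject_label_noise()]).
#' @export
make_noise_plan <- function(cohort, training_patients, rho, seed = 1L,
                            balance = TRUE) {
  sel <- select_single_class(cohort, training_patients,
                             seed = derive_seed(seed, 1L), balance = balance)
  inject_label_noise(sel, rho, seed = derive_seed(seed, 2L))
}

#' Serialize / restore a noise plan as JSON
#' @param plan A `noise_plan`.
#' @param path JSON file path.
#' @export
write_noise_plan <- function(plan, path) {
  jsonlite::write_json(
    list(rho = plan$rho, seed = plan$seed,
         flipped_tiles = plan$flipped_tiles,
         retained_tiles = plan$retained_tiles,
         patient_class_choice = as.list(plan$patient_class_choice)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_noise_plan
#' @export
read_noise_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  choice <- x$patient_class_choice
  if (length(choice)) choice <- stats::setNames(as.integer(unlist(choice)),
                                                names(choice))
  structure(
    list(rho = x$rho, seed = as.integer(x$seed),
         flipped_tiles = as.character(x$flipped_tiles),
         retained_tiles = as.character(x$retained_tiles),
         patient_class_choice = choice),
    class = "noise_plan")
}
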