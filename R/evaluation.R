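#' Reject tiles below an agreement threshold
#'
#' Tiles whose ensemble agreement falls below `threshold` are deemed
#' unclassifiable and discarded; the rest keep their majority-vote
#' label. The partition is exact: every input tile is either retained
#' or discarded.
#'
#' @param votes A `vote_matrix`.
#' @param threshold Integer in `{ceiling(n/2), ..., n}` for `n` members.
#' @return List with `retained` and `discarded`, both tibbles as from
#'   [majority_vote()].
#' @export
agreement_filter <- function(votes, threshold) {
  n <- ncol(votes)
  t_min <- ceiling(n / 2)
  if (threshold < t_min || threshold > n) {
    abort_bad("threshold must be between ", t_min, " and ", n)
  }
  mv <- majority_vote(votes)
  list(retained = dplyr::filter(mv, .data$agreement >= threshold),
       discarded = dplyr::filter(mv, .data$agreement < threshold))
}

#' Accuracy/retention curve over agreement thresholds
#'
#' For every agreement threshold `t` from the bare majority to
#' unanimity, tiles with agreement `>= t` are retained and scored
#' against the truth. False positives/negatives take class 1 (cancer)
#' as positive. Where nothing is retained the accuracy is `NA` (flagged
#' by `undefined`), never 0. Discard bookkeeping counts, among the
#' tiles dropped at `t` relative to the full set, how many the ensemble
#' had right or wrong.
#'
#' @param votes A `vote_matrix`.
#' @param truth Named truth vector or tibble (`tile_id`, `class_label`).
#' @return An `agreement_curve` tibble: `threshold`, `n_retained`,
#'   `accuracy`, `false_positives`, `false_negatives`,
#'   `n_discarded_correct`, `n_discarded_incorrect`, `undefined`.
#' @export
accuracy_by_agreement <- function(votes, truth) {
  n <- ncol(votes)
  mv <- majority_vote(votes)
  y <- truth_vector(truth, mv$tile_id)
  correct <- mv$ensemble_label == y
  rows <- lapply(ceiling(n / 2):n, function(t) {
    keep <- mv$agreement >= t
    n_ret <- sum(keep)
    tibble::tibble(
      threshold = t,
      n_retained = n_ret,
      accuracy = if (n_ret) mean(correct[keep]) else NA_real_,
      false_positives = sum(keep & mv$ensemble_label == 1L & y == 0L),
      false_negatives = sum(keep & mv$ensemble_label == 0L & y == 1L),
      n_discarded_correct = sum(!keep & correct),
      n_discarded_incorrect = sum(!keep & !correct),
      undefined = n_ret == 0L)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("agreement_curve", class(out))
  out
}

#' Accuracy stratified by site, quality grade, or patient
#'
#' Scores the majority-vote labels against truth within groups defined
#' by cohort metadata. For `by = "patient"` this is the per-patient mean
#' accuracy. When `pROC` is installed an AUC over the fraction of
#' member votes for class 1 is included for groups with both classes.
#'
#' @param votes A `vote_matrix`.
#' @param cohort A `tile_cohort` covering the voted tiles (supplies
#'   truth labels and grouping metadata).
#' @param by One of `"site"`, `"quality"`, `"patient"`.
#' @param auc Compute vote-fraction AUC per group (default FALSE)?
#' @return A `performance_report` tibble: `group`, `n_tiles`,
#'   `accuracy`(, `auc`).
#' @export
stratified_performance <- function(votes, cohort, by = c("site", "quality", "patient"),
                                   auc = FALSE) {
  by <- match.arg(by)
  key <- c(site = "site_id", quality = "quality_grade", patient = "patient_id")[[by]]
  mv <- majority_vote(votes)
  n <- ncol(votes)
  df <- dplyr::inner_join(mv, cohort, by = "tile_id")
  if (nrow(df) < nrow(mv)) {
    abort_bad("cohort is missing metadata for ", nrow(mv) - nrow(df), " voted tile(s)")
  }
  out <- df |>
    dplyr::mutate(group = .data[[key]],
                  score = .data$votes_for_1 / n,
                  correct = .data$ensemble_label == .data$class_label) |>
    dplyr::summarise(
      n_tiles = dplyr::n(),
      accuracy = mean(.data$correct),
      auc = if (auc && requireNamespace("pROC", quietly = TRUE) &&
                dplyr::n_distinct(.data$class_label) == 2) {
        as.numeric(pROC::auc(pROC::roc(.data$class_label, .data$score,
                                       quiet = TRUE, direction = "<")))
      } else NA_real_,
      .by = "group")
  if (!auc) out$auc <- NULL
  class(out) <- c("performance_report", class(out))
  out
}

#' Evaluate the effect of an external tile-exclusion list
#'
#' Removes the listed tiles (e.g. a third-party quality-control tool's
#' rejections) from the evaluated set and reports accuracy before and
#' after, so the tool's effect on the classifier can be quantified.
#' Unknown ids are ignored (their count is reported).
#'
#' @param votes A `vote_matrix`.
#' @param truth Truth labels (named vector or tibble).
#' @param excluded Character vector of tile ids, or a file with one
#'   tile id per line.
#' @return List: `retained` (majority-vote tibble on the remainder),
#'   `delta` (tibble with accuracy before/after and the difference),
#'   `n_unknown`.
#' @export
apply_exclusion_list <- function(votes, truth, excluded) {
  if (length(excluded) == 1 && is.character(excluded) && file.exists(excluded)) {
    excluded <- readLines(excluded, warn = FALSE)
    excluded <- excluded[nzchar(excluded)]
  }
  mv <- majority_vote(votes)
  y <- truth_vector(truth, mv$tile_id)
  n_unknown <- length(setdiff(excluded, mv$tile_id))
  keep <- !mv$tile_id %in% excluded
  acc_before <- mean(mv$ensemble_label == y)
  acc_after <- if (any(keep)) mean((mv$ensemble_label == y)[keep]) else NA_real_
  list(retained = mv[keep, ],
       delta = tibble::tibble(n_before = nrow(mv), n_after = sum(keep),
                              accuracy_before = acc_before,
                              accuracy_after = acc_after,
                              delta = acc_after - acc_before),
       n_unknown = n_unknown)
}

#' Flag confidently contradicted labels for human review
#'
#' Lists tiles whose majority-vote label contradicts the recorded truth
#' with agreement at or above `review_threshold`, sorted most
#' confidently contradicted first. High-agreement contradictions are
#' candidate annotation errors; no label is changed automatically.
#'
#' @param votes A `vote_matrix`.
#' @param truth Truth labels.
#' @param review_threshold Minimum agreement for review (default:
#'   unanimity minus 2).
#' @return Tibble of contradicted tiles with `agreement`, sorted
#'   descending.
#' @export
flag_suspect_labels <- function(votes, truth,
                                review_threshold = ncol(votes) - 2L) {
  mv <- majority_vote(votes)
  y <- truth_vector(truth, mv$tile_id)
  mv |>
    dplyr::mutate(truth = y) |>
    dplyr::filter(.data$ensemble_label != .data$truth,
                  .data$agreement >= review_threshold) |>
    dplyr::arrange(dplyr::desc(.data$agreement), .data$tile_id)
}

#' Export a curve or report as tabular text / JSON
#' @param x An `agreement_curve` or `performance_report`.
#' @param path Output path; `.json` writes JSON, anything else CSV.
#' @export
write_report <- function(x, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = FALSE, pretty = TRUE, digits = NA)
  } else {
    readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  }
  invisible(path)
}
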