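#' Ensemble training configuration
#'
#' @param n_members Odd number of ensemble members (default 15, as in
#'   the reference design; desk-scale runs typically use 7).
#' @param epochs Training epochs per member (default 10). The checkpoint
#'   kept is the epoch with the best validation accuracy (earliest on
#'   ties), so later epochs can only help, never hurt, the saved model.
#' @param backend A `tile_backend` (default [pooled_mlp_backend()]).
#'   The loss is binary cross-entropy and the optimizer Adamax-style by
#'   backend contract.
#' @param seed Integer master seed; member seeds are derived from it.
#' @return A `train_config` list.
#' @export
train_config <- function(n_members = 15L, epochs = 10L,
                         backend = pooled_mlp_backend(), seed = 1L) {
  if (n_members %% 2 == 0 || n_members < 3) {
    abort_bad("n_members must be odd and >= 3")
  }
  stopifnot(epochs >= 1, inherits(backend, "tile_backend"))
  structure(list(n_members = as.integer(n_members),
                 epochs = as.integer(epochs),
                 backend = backend, seed = as.integer(seed)),
            class = "train_config")
}

#' Train one ensemble member with best-epoch checkpointing
#'
#' Runs `config$epochs` training epochs; after each, validation accuracy
#' is computed and the state with the maximum validation accuracy is
#' kept (ties go to the earliest epoch). Training labels may be
#' noise-flipped; validation labels must be clean, since they drive
#' checkpoint selection.
#'
#' @param train_tiles,val_tiles Rows of a `tile_cohort`.
#' @param train_labels,val_labels Binary integer vectors aligned with
#'   the tiles.
#' @param config A [train_config()].
#' @param member_seed Integer seed for this member.
#' @param features Optional precomputed feature matrix (rownames =
#'   tile ids) covering all tiles; computed on the fly if `NULL`.
#' @return A `member_model`: backend state at the best epoch plus
#'   `best_val_accuracy`, `best_epoch`, `val_history`.
#' @export
train_member <- function(train_tiles, train_labels, val_tiles, val_labels,
                         config, member_seed = 1L, features = NULL) {
  stopifnot(inherits(config, "train_config"))
  if (nrow(train_tiles) == 0 || nrow(val_tiles) == 0) {
    abort_bad("train and validation sets must be non-empty")
  }
  stopifnot(length(train_labels) == nrow(train_tiles),
            length(val_labels) == nrow(val_tiles),
            all(train_labels %in% 0:1), all(val_labels %in% 0:1))
  if (length(unique(train_labels)) < 2) {
    abort_bad("single-class training set")
  }
  be <- config$backend
  X <- if (is.null(features)) tile_features(train_tiles, be) else
    features[train_tiles$tile_id, , drop = FALSE]
  Xv <- if (is.null(features)) tile_features(val_tiles, be) else
    features[val_tiles$tile_id, , drop = FALSE]

  state <- be$init(ncol(X), seed = derive_seed(member_seed, 1L))
  best <- list(state = NULL, acc = -Inf, epoch = NA_integer_)
  history <- numeric(config$epochs)
  for (e in seq_len(config$epochs)) {
    state <- be$train_epoch(state, X, train_labels,
                            seed = derive_seed(member_seed, 10L + e))
    acc <- mean((be$predict(state, Xv) >= 0.5) == (val_labels == 1L))
    history[e] <- acc
    if (acc > best$acc) best <- list(state = state, acc = acc, epoch = e)
  }
  structure(list(state = best$state,
                 best_val_accuracy = best$acc,
                 best_epoch = best$epoch,
                 val_history = history,
                 backend_name = be$name,
                 backend_params = be$params),
            class = "member_model")
}

#' Train a noisy-label bagging ensemble
#'
#' Member `i` trains on the retained tiles of member partition `i` with
#' noise-applied labels and validates on the (clean-labelled) retained
#' tiles of its validation patients. When `noise_plan` is `NULL` all
#' tiles are used with their true labels. The fitted ensemble records
#' its split and noise plans for provenance.
#'
#' @param cohort A `tile_cohort`.
#' @param plan A `split_plan` with member partitions filled.
#' @param noise_plan A `noise_plan` or `NULL`.
#' @param config A [train_config()].
#' @param features Optional precomputed feature matrix for the cohort.
#' @return An `ensemble_model`.
#' @export
train_ensemble <- function(cohort, plan, noise_plan, config, features = NULL) {
  stopifnot(inherits(plan, "split_plan"), inherits(config, "train_config"))
  if (length(plan$members) != config$n_members) {
    abort_bad("plan has ", length(plan$members), " member partitions but ",
              "config$n_members = ", config$n_members)
  }
  pool_tiles <- tiles_of(cohort, plan$train_pool)
  if (!is.null(noise_plan)) {
    pool_tiles <- dplyr::filter(pool_tiles,
                                .data$tile_id %in% noise_plan$retained_tiles)
    labels <- apply_noise(pool_tiles, noise_plan)
    train_label <- stats::setNames(labels$label, labels$tile_id)
  } else {
    train_label <- stats::setNames(pool_tiles$class_label, pool_tiles$tile_id)
  }
  truth_label <- stats::setNames(pool_tiles$class_label, pool_tiles$tile_id)
  if (is.null(features)) features <- tile_features(pool_tiles, config$backend)

  members <- lapply(seq_len(config$n_members), function(i) {
    m <- plan$members[[i]]
    tr <- tiles_of(pool_tiles, m$train)
    va <- tiles_of(pool_tiles, m$validation)
    mseed <- derive_seed(config$seed, plan$repeat_index, i)
    tryCatch(
      train_member(tr, train_label[tr$tile_id], va, truth_label[va$tile_id],
                   config, member_seed = mseed, features = features),
      error = function(e) abort_bad("member ", i, ": ", conditionMessage(e)))
  })
  structure(list(members = members, config = config, plan = plan,
                 noise_plan = noise_plan),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  rho <- if (is.null(x$noise_plan)) 0 else x$noise_plan$rho
  cat(sprintf("<ensemble_model> %d members (%s backend), repeat %d, rho = %.2f\n",
              length(x$members), x$config$backend$name,
              x$plan$repeat_index, rho))
  cat(sprintf("  member best validation accuracy: %.3f (mean)\n",
              mean(vapply(x$members, `[[`, numeric(1), "best_val_accuracy"))))
  invisible(x)
}

#' Collect the binary votes of every member on a set of tiles
#'
#' A member votes 1 when its predicted probability of class 1 is at
#' least 0.5 (the boundary case votes 1 by convention). Rows follow the
#' input tile order.
#'
#' @param ensemble An `ensemble_model`.
#' @param tiles Rows of a `tile_cohort`.
#' @param features Optional precomputed feature matrix.
#' @return A `vote_matrix`: integer matrix (tiles x members) with tile
#'   ids as row names.
#' @export
predict_members <- function(ensemble, tiles, features = NULL) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  be <- ensemble$config$backend
  X <- if (is.null(features)) tile_features(tiles, be) else
    features[tiles$tile_id, , drop = FALSE]
  votes <- vapply(ensemble$members,
                  function(m) as.integer(be$predict(m$state, X) >= 0.5),
                  integer(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X),
                  dimnames = list(tiles$tile_id,
                                  paste0("m", seq_along(ensemble$members))))
  structure(votes, class = c("vote_matrix", "matrix"))
}

#' Construct a vote matrix from raw votes
#' @param votes Binary integer matrix, tiles x members, tile ids as
#'   row names.
#' @return A `vote_matrix`.
#' @export
vote_matrix <- function(votes) {
  votes <- as.matrix(votes)
  if (!all(votes %in% 0:1)) abort_bad("votes must be 0/1")
  if (is.null(rownames(votes))) abort_bad("vote matrix needs tile ids as row names")
  if (is.null(colnames(votes))) colnames(votes) <- paste0("m", seq_len(ncol(votes)))
  storage.mode(votes) <- "integer"
  structure(votes, class = c("vote_matrix", "matrix"))
}

#' Majority vote and ensemble agreement per tile
#'
#' The ensemble label is the class voted for by most members; the
#' agreement (ensemble confidence) is the number of members matching
#' that label, so for `n` members it lies in `{ceiling(n/2), ..., n}`.
#' An odd member count makes the vote tie-free.
#'
#' @param votes A `vote_matrix`.
#' @return Tibble: `tile_id`, `votes_for_1`, `ensemble_label`,
#'   `agreement`.
#' @export
majority_vote <- function(votes) {
  n <- ncol(votes)
  if (n %% 2 == 0) abort_bad("majority vote requires an odd member count")
  v1 <- as.integer(rowSums(unclass(votes)))
  label <- as.integer(v1 > n - v1)
  tibble::tibble(tile_id = rownames(votes),
                 votes_for_1 = v1,
                 ensemble_label = label,
                 agreement = pmax(v1, n - v1))
}

#' Mean individual member accuracy ("group" performance)
#'
#' The unweighted mean over members of each member's own tile accuracy,
#' as opposed to the accuracy of the majority-vote label ("ensemble"
#' performance).
#'
#' @param votes A `vote_matrix`.
#' @param truth Named vector (tile id -> 0/1) or tibble with `tile_id`
#'   and `class_label`.
#' @return A single number in `[0, 1]`.
#' @export
group_accuracy <- function(votes, truth) {
  y <- truth_vector(truth, rownames(votes))
  mean(colMeans(unclass(votes) == y))
}

truth_vector <- function(truth, tile_ids) {
  if (is.data.frame(truth)) {
    truth <- stats::setNames(truth$class_label, truth$tile_id)
  }
  missing <- setdiff(tile_ids, names(truth))
  if (length(missing)) {
    abort_bad("truth labels missing for tile(s): ",
              paste(utils::head(missing, 3), collapse = ", "))
  }
  as.integer(truth[tile_ids])
}

#' Save / load a fitted ensemble
#'
#' The model directory holds the member states in R's native
#' serialization plus a JSON manifest (backend name/parameters, seeds,
#' split and noise plans) so a run is auditable without loading the
#' weights.
#'
#' @param ensemble An `ensemble_model`.
#' @param dir Output directory.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(ensemble$members, file.path(dir, "members.rds"))
  cfg <- ensemble$config
  manifest <- list(
    n_members = cfg$n_members, epochs = cfg$epochs, seed = cfg$seed,
    backend = list(name = cfg$backend$name, params = cfg$backend$params),
    best_val_accuracy = vapply(ensemble$members, `[[`, numeric(1),
                               "best_val_accuracy"),
    best_epoch = vapply(ensemble$members, `[[`, integer(1), "best_epoch"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_split_plans(list(ensemble$plan), file.path(dir, "split_plan.json"))
  if (!is.null(ensemble$noise_plan)) {
    write_noise_plan(ensemble$noise_plan, file.path(dir, "noise_plan.json"))
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  backend <- backend_from_spec(manifest$backend$name,
                               as.list(manifest$backend$params))
  config <- train_config(n_members = manifest$n_members,
                         epochs = manifest$epochs, backend = backend,
                         seed = manifest$seed)
  plan <- read_split_plans(file.path(dir, "split_plan.json"))[[1]]
  np_path <- file.path(dir, "noise_plan.json")
  noise_plan <- if (file.exists(np_path)) read_noise_plan(np_path) else NULL
  structure(list(members = readRDS(file.path(dir, "members.rds")),
                 config = config, plan = plan, noise_plan = noise_plan),
            class = "ensemble_model")
}

#' Write / read a vote matrix as tabular text
#'
#' Columns: `tile_id`, one 0/1 column per member, `ensemble_label`,
#' `agreement`.
#'
#' @param votes A `vote_matrix`.
#' @param path CSV path.
#' @export
write_vote_matrix <- function(votes, path) {
  mv <- majority_vote(votes)
  out <- dplyr::bind_cols(
    tibble::tibble(tile_id = rownames(votes)),
    tibble::as_tibble(as.data.frame(unclass(votes))),
    mv[c("ensemble_label", "agreement")])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_vote_matrix
#' @export
read_vote_matrix <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cols <- grep("^m[0-9]+$", names(x), value = TRUE)
  votes <- as.matrix(x[cols])
  rownames(votes) <- x$tile_id
  vote_matrix(votes)
}
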