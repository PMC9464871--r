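#' Split plans
#'
#' A `split_plan` describes one repeat of an experiment: the held-out
#' test patients, the pool of patients available for training and
#' validation, and (once [make_member_splits()] has run) one
#' train/validation partition per ensemble member. The sampling unit is
#' always the patient — tiles of one patient never cross a split.
#'
#' @name split_plan
NULL

new_split_plan <- function(repeat_index, test_patients, train_pool,
                           members = list()) {
  structure(
    list(repeat_index = as.integer(repeat_index),
         test_patients = sort(test_patients),
         train_pool = sort(train_pool),
         members = members),
    class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> repeat %d: %d test patients, pool %d, %d member partition(s)\n",
              x$repeat_index, length(x$test_patients), length(x$train_pool),
              length(x$members)))
  invisible(x)
}

#' Repeated patient-level train/test splits
#'
#' Each repeat holds out `round_half_up(test_fraction * n_patients)`
#' patients. Test membership is balanced across repeats by a greedy
#' round-robin: each repeat takes the patients with the fewest test
#' appearances so far (random tie-break), so appearance counts differ by
#' at most one and every patient is tested at least once whenever
#' `n_repeats * test_fraction >= 1`.
#'
#' @param cohort A `tile_cohort`.
#' @param n_repeats Number of repeats, `>= 1`.
#' @param test_fraction Fraction of patients held out per repeat, in (0, 1).
#' @param seed Integer seed.
#' @return List of `split_plan`s (member partitions empty).
#' @export
make_repeat_splits <- function(cohort, n_repeats = 10L, test_fraction = 0.25,
                               seed = 1L) {
  stopifnot(n_repeats >= 1, test_fraction > 0, test_fraction < 1)
  patients <- sort(unique(cohort$patient_id))
  n <- length(patients)
  if (n < 4) abort_bad("too few patients to split (need at least 4, got ", n, ")")
  n_test <- max(1L, round_half_up(test_fraction * n))
  counts <- stats::setNames(integer(n), patients)
  with_seed(seed, {
    lapply(seq_len(n_repeats) - 1L, function(r) {
      ord <- order(counts, stats::runif(n))
      test <- patients[ord[seq_len(n_test)]]
      counts[test] <<- counts[test] + 1L
      new_split_plan(r, test, setdiff(patients, test))
    })
  })
}

n_choose_k <- function(n, k) exp(lchoose(n, k))

#' Fill a plan's member-level train/validation partitions
#'
#' The repeat's training pool is divided into `n_members` distinct
#' train/validation partitions, one per ensemble member. Validation sets
#' are pairwise distinct as patient sets; training sets may overlap
#' (bagging-style). Each member's train and validation sets together
#' cover the whole pool.
#'
#' @param plan A `split_plan`.
#' @param n_members Odd integer `>= 3` (default 15).
#' @param val_fraction Fraction of the pool used for validation per
#'   member (default 0.2); every validation set has at least 1 patient.
#' @param seed Integer seed.
#' @return The plan with `members` filled: a list of
#'   `list(train =, validation =)` patient-id vectors.
#' @export
make_member_splits <- function(plan, n_members = 15L, val_fraction = 0.2,
                               seed = 1L) {
  stopifnot(inherits(plan, "split_plan"))
  if (n_members < 3 || n_members %% 2 == 0) {
    abort_bad("n_members must be an odd integer >= 3")
  }
  pool <- plan$train_pool
  n <- length(pool)
  n_val <- max(1L, round_half_up(val_fraction * n))
  if (n_val >= n) abort_bad("validation fraction leaves no training patients")
  if (n_choose_k(n, n_val) < n_members) {
    need <- n_val + n_members  # smallest pool with >= n_members distinct sets
    abort_bad("training pool too small for ", n_members,
              " distinct validation sets of size ", n_val,
              " (pool ", n, ", need at least ", need, " patients)")
  }
  members <- with_seed(derive_seed(seed, plan$repeat_index), {
    if (n_val == 1L) {
      picks <- sample(pool, n_members)
      lapply(picks, function(p) list(train = setdiff(pool, p), validation = p))
    } else {
      seen <- character(0)
      out <- vector("list", n_members)
      i <- 1L
      tries <- 0L
      while (i <= n_members) {
        tries <- tries + 1L
        if (tries > 1000L * n_members) {
          abort_bad("could not draw ", n_members, " distinct validation sets")
        }
        v <- sort(sample(pool, n_val))
        key <- paste(v, collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[i]] <- list(train = setdiff(pool, v), validation = v)
        i <- i + 1L
      }
      out
    }
  })
  plan$members <- members
  plan
}

#' Site-restricted splits with a shared cross-site test pool
#'
#' Per repeat, `n_test_per_site` patients are held out from every site;
#' together they form the common test pool. The training pool contains
#' only patients of `train_site` (minus its held-out patients), or the
#' union of all sites for `train_site = "all"`. For a fixed seed the
#' held-out test pools are identical whichever `train_site` is chosen,
#' so accuracies of site-restricted models are directly comparable.
#'
#' @param cohort A `tile_cohort`.
#' @param train_site A site id present in the cohort, or `"all"`.
#' @param n_test_per_site Held-out patients per site per repeat.
#' @param n_repeats Number of repeats.
#' @param seed Integer seed.
#' @return List of `split_plan`s (member partitions empty).
#' @export
make_site_splits <- function(cohort, train_site = "all", n_test_per_site = 7L,
                             n_repeats = 10L, seed = 1L) {
  sites <- sort(unique(cohort$site_id))
  if (!identical(train_site, "all") && !train_site %in% sites) {
    abort_bad("unknown site id \"", train_site, "\"; available: ",
              paste(sites, collapse = ", "))
  }
  pats <- cohort_patients(cohort)
  by_site <- split(pats$patient_id, pats$site_id)
  small <- names(by_site)[vapply(by_site, length, integer(1)) <= n_test_per_site]
  if (length(small)) {
    abort_bad("site(s) ", paste(small, collapse = ", "), " have too few ",
              "patients for n_test_per_site = ", n_test_per_site)
  }
  lapply(seq_len(n_repeats) - 1L, function(r) {
    test <- unlist(lapply(seq_along(sites), function(si) {
      with_seed(derive_seed(seed, r, si), sample(sort(by_site[[sites[si]]]),
                                                 n_test_per_site))
    }), use.names = FALSE)
    pool_src <- if (identical(train_site, "all")) unlist(by_site, use.names = FALSE)
                else by_site[[train_site]]
    new_split_plan(r, test, setdiff(pool_src, test))
  })
}

#' Verify patient-level disjointness of split plans
#'
#' Scans every plan: test vs. member train/validation disjointness,
#' train vs. validation disjointness per member, and pairwise
#' distinctness of member validation sets.
#'
#' @param plans List of `split_plan`s.
#' @return Invisibly `TRUE`; errors describing the first violation.
#' @export
check_split_plans <- function(plans) {
  for (plan in plans) {
    for (i in seq_along(plan$members)) {
      m <- plan$members[[i]]
      if (length(intersect(plan$test_patients, c(m$train, m$validation)))) {
        abort_bad("repeat ", plan$repeat_index, " member ", i,
                  ": test patients leak into train/validation")
      }
      if (length(intersect(m$train, m$validation))) {
        abort_bad("repeat ", plan$repeat_index, " member ", i,
                  ": train and validation overlap")
      }
    }
    keys <- vapply(plan$members,
                   function(m) paste(sort(m$validation), collapse = "|"),
                   character(1))
    if (anyDuplicated(keys)) {
      abort_bad("repeat ", plan$repeat_index,
                ": duplicate member validation sets")
    }
  }
  invisible(TRUE)
}

#' Serialize / restore split plans as JSON
#' @param plans List of `split_plan`s.
#' @param path JSON file path.
#' @export
write_split_plans <- function(plans, path) {
  x <- lapply(plans, function(p) {
    list(repeat_index = p$repeat_index, test_patients = p$test_patients,
         train_pool = p$train_pool,
         members = lapply(p$members, function(m)
           list(train = m$train, validation = m$validation)))
  })
  jsonlite::write_json(x, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split_plans
#' @export
read_split_plans <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(x, function(p) {
    new_split_plan(p$repeat_index, as.character(p$test_patients),
                   as.character(p$train_pool),
                   members = lapply(p$members, function(m)
                     list(train = as.character(m$train),
                          validation = as.character(m$validation))))
  })
}

#' Extract the tiles of a patient set
#' @param cohort A `tile_cohort`.
#' @param patients Character vector of patient ids.
#' @return The cohort rows of those patients.
#' @export
tiles_of <- function(cohort, patients) {
  dplyr::filter(cohort, .data$patient_id %in% patients)
}
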