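#' Tile cohort container
#'
#' A cohort is a tibble with one row per tile and columns `tile_id`,
#' `patient_id`, `site_id`, `quality_grade` (1/2/3), `class_label` (0/1),
#' `image_path`. Every split, noise plan and report indexes into it.
#' Invariants enforced at construction: unique tile ids, binary class
#' labels, and each patient belonging to exactly one site.
#'
#' @param tiles A data frame with the manifest columns.
#' @return A `tile_cohort` tibble.
#' @export
new_tile_cohort <- function(tiles) {
  needed <- c("tile_id", "patient_id", "site_id", "quality_grade",
              "class_label", "image_path")
  missing <- setdiff(needed, names(tiles))
  if (length(missing)) {
    abort_bad("manifest is missing column(s): ", paste(missing, collapse = ", "))
  }
  tiles <- tibble::as_tibble(tiles)[needed]
  tiles$quality_grade <- as.integer(tiles$quality_grade)
  tiles$class_label <- as.integer(tiles$class_label)
  if (anyDuplicated(tiles$tile_id)) {
    d <- tiles$tile_id[duplicated(tiles$tile_id)][1]
    abort_bad("duplicate tile_id: ", d, " (row ",
              which(tiles$tile_id == d)[2], ")")
  }
  bad <- which(!tiles$class_label %in% c(0L, 1L))
  if (length(bad)) {
    abort_bad("class_label must be 0 or 1 (row ", bad[1], ")")
  }
  bad <- which(!tiles$quality_grade %in% 1:3)
  if (length(bad)) {
    abort_bad("quality_grade must be 1, 2 or 3 (row ", bad[1], ")")
  }
  multi <- tiles |>
    dplyr::distinct(.data$patient_id, .data$site_id) |>
    dplyr::count(.data$patient_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi)) {
    p <- multi$patient_id[1]
    abort_bad("patient ", p, " is mapped to more than one site (row ",
              which(tiles$patient_id == p)[1], ")")
  }
  class(tiles) <- c("tile_cohort", class(tibble::tibble()))
  tiles
}

#' Patient-level index of a cohort
#'
#' @param cohort A `tile_cohort`.
#' @return Tibble with one row per patient: `patient_id`, `site_id`,
#'   `quality_grade`, `n_tiles`.
#' @export
cohort_patients <- function(cohort) {
  cohort |>
    dplyr::summarise(site_id = .data$site_id[1],
                     quality_grade = .data$quality_grade[1],
                     n_tiles = dplyr::n(),
                     .by = "patient_id")
}

#' Read / write a tile manifest
#'
#' The manifest is a UTF-8 comma-separated file with a header row and
#' one row per tile; `read_manifest()` validates the cohort invariants
#' and errors naming the offending row. Relative `image_path` entries
#' are resolved against the manifest's directory.
#'
#' @param path CSV file path.
#' @return `read_manifest()`: a `tile_cohort`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_bad("manifest not found: ", path)
  tiles <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  rel <- !is.na(tiles$image_path) & !grepl("^(/|[A-Za-z]:)", tiles$image_path)
  tiles$image_path[rel] <- file.path(dirname(path), tiles$image_path[rel])
  new_tile_cohort(tiles)
}

#' @rdname read_manifest
#' @param cohort A `tile_cohort`.
#' @export
write_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "tile_cohort"))
  out <- cohort
  # store paths relative to the manifest when they live beneath it
  root <- paste0(normalizePath(dirname(path), mustWork = FALSE), "/")
  out$image_path <- ifelse(startsWith(out$image_path, root),
                           substring(out$image_path, nchar(root) + 1L),
                           out$image_path)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.tile_cohort <- function(x, ...) {
  pats <- cohort_patients(x)
  cat(sprintf("<tile_cohort> %d tiles, %d patients, %d site(s)\n",
              nrow(x), nrow(pats), dplyr::n_distinct(x$site_id)))
  NextMethod()
}
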