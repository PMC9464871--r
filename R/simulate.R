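#' Tissue source site profile
#'
#' A site bundles its patient count, its mix of pathologist-style quality
#' grades (1 good, 2 medium, 3 poor), the degradation realizing each
#' grade, and the JPEG quality its scanner pipeline stores tiles at.
#' Quality grade is assigned per patient (all of a patient's tiles share
#' one grade), mirroring per-slide quality scores.
#'
#' @param site_id Short unique string.
#' @param n_patients Positive integer.
#' @param quality_mix Named probabilities over grades `"1"`,`"2"`,`"3"`,
#'   summing to 1.
#' @param degradation_by_grade Named list of [degradation_profile()]s
#'   covering every grade with nonzero probability.
#' @param jpeg_quality Integer 1-100 used when writing this site's tiles
#'   to disk, or `"none"` for lossless PNG.
#' @return A `site_profile` list.
#' @export
site_profile <- function(site_id, n_patients, quality_mix,
                         degradation_by_grade = default_degradations(),
                         jpeg_quality = "none") {
  stopifnot(is.character(site_id), nchar(site_id) > 0, n_patients >= 1)
  if (is.null(names(quality_mix)) ||
      !all(names(quality_mix) %in% c("1", "2", "3"))) {
    abort_bad("quality_mix must be named with grades \"1\", \"2\", \"3\"")
  }
  if (any(quality_mix < 0) || abs(sum(quality_mix) - 1) > 1e-9) {
    abort_bad("quality_mix probabilities must be non-negative and sum to 1")
  }
  active <- names(quality_mix)[quality_mix > 0]
  if (!all(active %in% names(degradation_by_grade))) {
    abort_bad("every grade with nonzero probability needs a degradation profile")
  }
  if (!identical(jpeg_quality, "none")) {
    stopifnot(is.numeric(jpeg_quality), jpeg_quality >= 1, jpeg_quality <= 100)
    jpeg_quality <- as.integer(jpeg_quality)
  }
  structure(
    list(site_id = site_id, n_patients = as.integer(n_patients),
         quality_mix = quality_mix,
         degradation_by_grade = degradation_by_grade,
         jpeg_quality = jpeg_quality),
    class = "site_profile")
}

#' Default three-site study design
#'
#' Emulates the structure behind the cross-site experiments: site A is a
#' high-quality source stored with strong JPEG compression (quality 30),
#' site B a mixed/low-quality source stored at JPEG quality 70, and site
#' C an intermediate-quality external site stored losslessly. The
#' counterintuitive pairing of the best tissue with the strongest file
#' compression is deliberate: at these settings file compression is a
#' far weaker artifact than blur/contrast/stain degradation.
#'
#' @param n_patients Patients per site (default 30).
#' @return List of three [site_profile()]s.
#' @export
default_sites <- function(n_patients = 30L) {
  list(
    site_profile("A", n_patients, c("1" = 0.8, "2" = 0.2, "3" = 0),
                 jpeg_quality = 30L),
    site_profile("B", n_patients, c("1" = 0.15, "2" = 0.45, "3" = 0.4),
                 jpeg_quality = 70L),
    site_profile("C", n_patients, c("1" = 0.3, "2" = 0.5, "3" = 0.2),
                 jpeg_quality = "none")
  )
}

write_tile_image <- function(img, path, jpeg_quality) {
  if (identical(jpeg_quality, "none")) {
    png::writePNG(img, path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      abort_bad("writing JPEG tiles requires the EBImage package")
    }
    EBImage::writeImage(EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color"),
                        path, quality = as.integer(jpeg_quality))
  }
  invisible(path)
}

#' Read a tile image (PNG or JPEG) as a unit-scale array
#' @param path Image file path.
#' @return H x W x 3 array on `[0, 1]`.
#' @export
read_tile_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
    if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
    img
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      abort_bad("reading JPEG tiles requires the EBImage package")
    }
    aperm(as.array(EBImage::readImage(path)), c(2, 1, 3))
  }
}

#' Generate a synthetic multi-site tile cohort
#'
#' For every patient: one quality grade is sampled from the site's
#' quality mix, one stain jitter is drawn, and `tiles_per_patient` tiles
#' are rendered (class sampled per tile at `class_balance`), degraded by
#' the grade's profile, and written to disk (PNG, or JPEG at the site's
#' quality). The whole cohort — metadata and pixels — is a pure function
#' of `seed` and the configuration.
#'
#' @param sites List of [site_profile()]s with unique ids.
#' @param tiles_per_patient Tiles per patient, `>= 2` (default 8).
#' @param tile_size Tile edge in pixels (default 64).
#' @param class_balance Probability a tile is class 1, in (0, 1).
#' @param seed Integer master seed.
#' @param out_dir Directory for images and `manifest.csv`.
#' @param textures Named list of class textures as [default_textures()].
#' @return A `tile_cohort` tibble (one row per tile) with columns
#'   `tile_id`, `patient_id`, `site_id`, `quality_grade`, `class_label`,
#'   `image_path`.
#' @export
generate_cohort <- function(sites, tiles_per_patient = 8L, tile_size = 64L,
                            class_balance = 0.5, seed = 1L,
                            out_dir = tempfile("cohort_"),
                            textures = default_textures()) {
  stopifnot(tiles_per_patient >= 2, class_balance > 0, class_balance < 1)
  ids <- vapply(sites, function(s) s$site_id, character(1))
  if (anyDuplicated(ids)) abort_bad("duplicate site_id: ", ids[duplicated(ids)][1])
  if (sum(vapply(sites, function(s) s$n_patients, integer(1))) == 0) {
    abort_bad("zero patients")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list()
  for (si in seq_along(sites)) {
    s <- sites[[si]]
    ext <- if (identical(s$jpeg_quality, "none")) ".png" else ".jpg"
    grades <- with_seed(derive_seed(seed, si, 1L), {
      sample(as.integer(names(s$quality_mix)), s$n_patients,
             replace = TRUE, prob = s$quality_mix)
    })
    for (p in seq_len(s$n_patients)) {
      patient_id <- sprintf("%s_P%02d", s$site_id, p)
      grade <- grades[p]
      prof <- s$degradation_by_grade[[as.character(grade)]]
      pseed <- derive_seed(seed, si * 100L + p)
      classes <- with_seed(derive_seed(pseed, 2L), {
        stats::rbinom(tiles_per_patient, 1, class_balance)
      })
      for (t in seq_len(tiles_per_patient)) {
        tile_id <- sprintf("%s_T%02d", patient_id, t)
        tseed <- derive_seed(pseed, 10L + t)
        img <- render_tile(textures[[as.character(classes[t])]],
                           patient_stain_seed = pseed, tile_seed = tseed,
                           size = tile_size)
        img <- degrade(img, prof, seed = derive_seed(tseed, 3L))
        path <- file.path(out_dir, paste0(tile_id, ext))
        write_tile_image(img, path, s$jpeg_quality)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          tile_id = tile_id, patient_id = patient_id, site_id = s$site_id,
          quality_grade = grade, class_label = classes[t], image_path = path)
      }
    }
  }
  cohort <- new_tile_cohort(dplyr::bind_rows(rows))
  write_manifest(cohort, file.path(out_dir, "manifest.csv"))
  cohort
}
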