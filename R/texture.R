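#' Texture parameters for one tile class
#'
#' Synthetic tiles emulate H&E-stained tissue as elliptical "cell" blobs
#' on a stained background. The two classes are made learnably distinct
#' through blob density and size: the cancer class renders many small,
#' dark, nucleus-like blobs, the non-cancer class fewer, larger, paler
#' structures. Colors live on the unit scale (RGB in `[0, 1]`).
#'
#' @param class_id 0 (non-cancer) or 1 (cancer).
#' @param blob_density Expected blobs per 1000 square pixels.
#' @param blob_radius_mean,blob_radius_sd Blob radius distribution, pixels.
#' @param blob_eccentricity_range Length-2 numeric in `[0, 1)`.
#' @param foreground_color,background_color RGB triples on the unit scale.
#' @param color_jitter_sd Standard deviation of the per-patient log-normal
#'   stain jitter (one multiplicative RGB factor per patient, shared by all
#'   of that patient's tiles — models lab/batch staining variation).
#' @return A `texture_params` list.
#' @export
texture_params <- function(class_id,
                           blob_density,
                           blob_radius_mean,
                           blob_radius_sd = blob_radius_mean / 4,
                           blob_eccentricity_range = c(0, 0.6),
                           foreground_color = c(0.35, 0.22, 0.55),
                           background_color = c(0.91, 0.76, 0.84),
                           color_jitter_sd = 0.06) {
  stopifnot(class_id %in% c(0L, 1L), blob_density >= 0,
            blob_radius_mean > 0, blob_radius_sd >= 0,
            length(blob_eccentricity_range) == 2,
            all(blob_eccentricity_range >= 0), all(blob_eccentricity_range < 1),
            length(foreground_color) == 3, length(background_color) == 3,
            all(foreground_color >= 0 & foreground_color <= 1),
            all(background_color >= 0 & background_color <= 1),
            color_jitter_sd >= 0)
  structure(
    list(class_id = as.integer(class_id),
         blob_density = blob_density,
         blob_radius_mean = blob_radius_mean,
         blob_radius_sd = blob_radius_sd,
         blob_eccentricity_range = blob_eccentricity_range,
         foreground_color = foreground_color,
         background_color = background_color,
         color_jitter_sd = color_jitter_sd),
    class = "texture_params")
}

#' Default class textures
#'
#' Class 1 (cancer): dense small dark nucleus-like blobs, tightly
#' distributed so cancer tiles form a compact cluster in texture space.
#' Class 0 (non-cancer): sparse large pale structures with wide
#' radius/count spread, so non-cancer tiles are the heterogeneous,
#' heavy-tailed class — as stroma/fat/necrosis are against tumor sheets.
#' Both classes cover a similar tile area fraction so mean color alone
#' is a weak cue and classifiers must pick up texture scale.
#'
#' @return Named list with elements `"0"` and `"1"`.
#' @export
default_textures <- function() {
  list(
    "0" = texture_params(0L, blob_density = 0.8, blob_radius_mean = 5.5,
                         blob_radius_sd = 2.0,
                         blob_eccentricity_range = c(0, 0.7),
                         foreground_color = c(0.62, 0.40, 0.66),
                         background_color = c(0.92, 0.78, 0.85)),
    "1" = texture_params(1L, blob_density = 7.0, blob_radius_mean = 2.2,
                         blob_radius_sd = 0.3,
                         blob_eccentricity_range = c(0, 0.4),
                         foreground_color = c(0.32, 0.20, 0.52),
                         background_color = c(0.90, 0.74, 0.82))
  )
}

#' Render one synthetic tissue tile
#'
#' Deterministic for fixed seeds. The per-patient stain jitter is drawn
#' from `patient_stain_seed` only, so all tiles of a patient share one
#' stain cast; blob placement is drawn from `tile_seed`.
#'
#' @param texture A [texture_params()] object.
#' @param patient_stain_seed,tile_seed Non-negative integer seeds.
#' @param size Tile edge length in pixels, at least 32.
#' @return A `size x size x 3` array on `[0, 1]` with attribute
#'   `"blobs"`: a tibble logging every placed blob
#'   (center `x`,`y`, `radius`, `eccentricity`, `theta`, `area`).
#' @export
render_tile <- function(texture, patient_stain_seed, tile_seed, size = 64L) {
  stopifnot(inherits(texture, "texture_params"))
  if (size < 32) abort_bad("tile too small for texture model (size >= 32 required)")
  size <- as.integer(size)

  jitter <- with_seed(derive_seed(patient_stain_seed, 7L), {
    exp(stats::rnorm(3, 0, texture$color_jitter_sd))
  })
  fg <- pmin(1, pmax(0, texture$foreground_color * jitter))
  bg <- pmin(1, pmax(0, texture$background_color * jitter))

  img <- array(rep(bg, each = size * size), dim = c(size, size, 3))

  n_expected <- texture$blob_density * size^2 / 1000
  log_rows <- with_seed(tile_seed, {
    n <- stats::rpois(1, n_expected)
    if (n == 0) NULL else tibble::tibble(
      x = stats::runif(n, 1, size),
      y = stats::runif(n, 1, size),
      radius = pmax(0.8, stats::rnorm(n, texture$blob_radius_mean,
                                      texture$blob_radius_sd)),
      eccentricity = stats::runif(n, texture$blob_eccentricity_range[1],
                                  texture$blob_eccentricity_range[2]),
      theta = stats::runif(n, 0, pi),
      shade = stats::runif(n, 0.9, 1.1)
    )
  })

  if (!is.null(log_rows)) {
    for (k in seq_len(nrow(log_rows))) {
      b <- log_rows[k, ]
      # semi-axes: area preserved at pi * r^2 for any eccentricity
      a_ax <- b$radius / (1 - b$eccentricity^2)^0.25
      b_ax <- b$radius * (1 - b$eccentricity^2)^0.25
      r_max <- a_ax + 1
      xr <- max(1L, floor(b$x - r_max)):min(size, ceiling(b$x + r_max))
      yr <- max(1L, floor(b$y - r_max)):min(size, ceiling(b$y + r_max))
      if (!length(xr) || !length(yr)) next
      dx <- matrix(rep(xr - b$x, each = length(yr)), nrow = length(yr))
      dy <- matrix(rep(yr - b$y, times = length(xr)), nrow = length(yr))
      u <- dx * cos(b$theta) + dy * sin(b$theta)
      v <- -dx * sin(b$theta) + dy * cos(b$theta)
      d <- sqrt((u / a_ax)^2 + (v / b_ax)^2) * b$radius
      alpha <- pmin(1, pmax(0, b$radius + 0.75 - d))  # ~1.5 px soft edge
      col <- pmin(1, fg * b$shade)
      for (ch in 1:3) {
        img[yr, xr, ch] <- img[yr, xr, ch] * (1 - alpha) + col[ch] * alpha
      }
    }
    log_rows$area <- pi * log_rows$radius^2
  } else {
    log_rows <- tibble::tibble(x = numeric(), y = numeric(), radius = numeric(),
                               eccentricity = numeric(), theta = numeric(),
                               shade = numeric(), area = numeric())
  }

  img <- clamp01(img)
  attr(img, "blobs") <- log_rows
  img
}
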