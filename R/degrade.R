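#' Image degradation profile
#'
#' One profile bundles the five artifact operators used to realize a
#' quality grade: per-channel stain gain, additive brightness shift,
#' contrast compression toward the image mean, Gaussian blur, and JPEG
#' recompression. Applied in the fixed order
#' stain gain -> brightness -> contrast -> blur -> JPEG, mirroring the
#' physical acquisition chain (staining and illumination act on the
#' tissue, optics blur the scene, compression happens last).
#'
#' @param blur_sigma Gaussian blur standard deviation in pixels, `>= 0`.
#' @param contrast_factor Scaling toward the image mean, in `(0, 1]`
#'   (1 = unchanged).
#' @param brightness_shift Additive intensity magnitude in `[-0.3, 0.3]`
#'   on the unit scale. The sign of the applied shift is randomized per
#'   call (tiles may come out darker or brighter); the magnitude is fixed.
#' @param stain_gain Length-3 multiplicative RGB factors in `[0.6, 1.4]`.
#' @param jpeg_quality Integer 1-100, or `"none"` to skip recompression.
#' @return A `degradation_profile` list.
#' @export
degradation_profile <- function(blur_sigma = 0,
                                contrast_factor = 1,
                                brightness_shift = 0,
                                stain_gain = c(1, 1, 1),
                                jpeg_quality = "none") {
  stopifnot(blur_sigma >= 0,
            contrast_factor > 0, contrast_factor <= 1,
            abs(brightness_shift) <= 0.3,
            length(stain_gain) == 3,
            all(stain_gain >= 0.6 & stain_gain <= 1.4))
  if (!identical(jpeg_quality, "none")) {
    if (!is.numeric(jpeg_quality) || jpeg_quality < 1 || jpeg_quality > 100) {
      abort_bad("jpeg_quality must be an integer in 1..100 or \"none\"")
    }
    jpeg_quality <- as.integer(jpeg_quality)
  }
  structure(
    list(blur_sigma = blur_sigma, contrast_factor = contrast_factor,
         brightness_shift = brightness_shift, stain_gain = stain_gain,
         jpeg_quality = jpeg_quality),
    class = "degradation_profile")
}

is_identity_profile <- function(p) {
  p$blur_sigma == 0 && p$contrast_factor == 1 && p$brightness_shift == 0 &&
    all(p$stain_gain == 1) && identical(p$jpeg_quality, "none")
}

#' Gaussian blur with reflect padding
#'
#' Separable discrete Gaussian convolution; the kernel is normalized so
#' total intensity is conserved (to well under 1e-6 away from borders).
#' Borders are reflect-padded (edge pixel duplicated).
#'
#' @param img 2-d matrix or H x W x C array on the unit scale.
#' @param sigma Standard deviation in pixels; 0 returns the input.
#' @return Blurred array, same shape. Not clipped.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur_mat <- function(m) {
    n1 <- nrow(m); n2 <- ncol(m)
    refl <- function(idx, n) {
      # reflect with edge duplication: ... 2 1 | 1 2 ... n | n n-1 ...
      idx <- ((idx - 1) %% (2 * n))
      ifelse(idx < n, idx + 1, 2 * n - idx)
    }
    conv1 <- function(mm, n) {
      out <- 0
      for (s in -r:r) out <- out + k[s + r + 1] * mm[refl(seq_len(n) + s, n), , drop = FALSE]
      out
    }
    m <- conv1(m, n1)
    m <- t(conv1(t(m), n2))
    m
  }
  if (length(dim(img)) == 2) return(blur_mat(img))
  out <- img
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- blur_mat(img[, , ch])
  attributes(out) <- attributes(img)
  out
}

jpeg_roundtrip <- function(img, quality) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort_bad("JPEG recompression requires the EBImage package")
  }
  f <- tempfile(fileext = ".jpg")
  on.exit(unlink(f), add = TRUE)
  # EBImage stores images x-major; ours are row (y) major
  EBImage::writeImage(EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color"),
                      f, quality = as.integer(quality))
  aperm(as.array(EBImage::readImage(f)), c(2, 1, 3))
}

#' Apply a degradation profile to a tile
#'
#' Operator order is fixed: stain gain, brightness, contrast, blur, JPEG.
#' The identity profile returns the input bit-exactly. Deterministic for
#' a fixed seed (the seed only chooses the sign of the brightness shift).
#'
#' @param img H x W x 3 array on the unit scale.
#' @param profile A [degradation_profile()].
#' @param seed Integer seed.
#' @return Degraded image on `[0, 1]`, clipped.
#' @export
degrade <- function(img, profile, seed = 0L) {
  stopifnot(inherits(profile, "degradation_profile"))
  if (max(img) > 1 + 1e-12 || min(img) < -1e-12) {
    abort_bad("image must be on the unit scale [0, 1]")
  }
  if (is_identity_profile(profile)) return(img)
  at <- attributes(img)
  x <- img
  x <- sweep(x, 3, profile$stain_gain, `*`)
  if (profile$brightness_shift != 0) {
    sgn <- with_seed(seed, sample(c(-1, 1), 1))
    x <- x + sgn * profile$brightness_shift
  }
  if (profile$contrast_factor < 1) {
    m <- mean(x)
    x <- m + profile$contrast_factor * (x - m)
  }
  x <- gaussian_blur(x, profile$blur_sigma)
  x <- clamp01(x)
  if (!identical(profile$jpeg_quality, "none")) {
    x <- jpeg_roundtrip(x, profile$jpeg_quality)
    x <- clamp01(x)
  }
  attributes(x) <- at
  x
}

#' Default degradation profiles by quality grade
#'
#' Grade 1 (good) is the identity; grade 2 (medium) applies mild blur,
#' contrast loss, brightness shift and stain imbalance; grade 3 (poor)
#' applies stronger versions of all four plus JPEG recompression.
#' Magnitudes are package defaults chosen so that grade 3 costs a
#' clean-trained classifier a measurable but not catastrophic amount of
#' accuracy (degraded tiles land near the decision margin rather than
#' deep inside the wrong class); all are overridable.
#'
#' @return Named list `"1"`, `"2"`, `"3"` of [degradation_profile()]s.
#' @export
default_degradations <- function() {
  list(
    "1" = degradation_profile(),
    "2" = degradation_profile(blur_sigma = 0.8, contrast_factor = 0.75,
                              brightness_shift = 0.06,
                              stain_gain = c(1.10, 0.92, 1.05)),
    "3" = degradation_profile(blur_sigma = 1.1, contrast_factor = 0.68,
                              brightness_shift = 0.10,
                              stain_gain = c(1.20, 0.82, 1.10),
                              jpeg_quality = 50L)
  )
}
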