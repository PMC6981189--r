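#' Tiny 3D image fixtures with ROI and control-region compartments
#'
#' Builds a small synthetic volume that mimics the geometry the method works
#' on: a spherical target ROI surrounded by control-region compartments (an
#' air cuboid, an adipose-like cuboid, a trachea-like cylinder) on a soft
#' tissue background, with HU-like base intensities. Degradations emulate
#' acquisition effects: isotropic Gaussian smoothing (reconstruction-kernel
#' proxy), additive noise from one of the four families, and a radial
#' cupping-artifact gradient.
#'
#' @param shape Integer length-3 volume shape (x, y, z).
#' @param intensities Named base intensities for `background`, `roi`, `air`,
#'   `adipose`, `trachea`.
#' @param smooth_sd Gaussian smoothing sd in voxels (0 = off).
#' @param noise_family `"gaussian"`, `"rayleigh"`, `"poisson"` or
#'   `"gamma"`.
#' @param noise_magnitude Noise scale in intensity units (0 = off).
#' @param cupping Amplitude of the radial intensity gradient (0 = off).
#' @param seed Integer seed.
#' @return List with `volume` (3D array) and `masks` (named list of logical
#'   3D arrays; compartments are mutually disjoint).
#' @export
generate_image_fixture <- function(shape = c(32, 32, 16),
                                   intensities = c(background = 40,
                                                   roi = 80, air = -1000,
                                                   adipose = -100,
                                                   trachea = -950),
                                   smooth_sd = 0, noise_family = "gaussian",
                                   noise_magnitude = 0, cupping = 0,
                                   seed = 1) {
  stopifnot(length(shape) == 3, noise_magnitude >= 0, smooth_sd >= 0)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  ax <- slice.index(array(0, shape), 1)
  ay <- slice.index(array(0, shape), 2)
  az <- slice.index(array(0, shape), 3)
  # compartment geometry scaled to the volume
  roi <- (ax - nx * 0.5)^2 + (ay - ny * 0.5)^2 + (az - nz * 0.5)^2 <=
    (min(nx, ny, nz) * 0.2)^2
  air <- ax <= nx * 0.15 & ay <= ny * 0.3
  adipose <- ax >= nx * 0.75 & ay <= ny * 0.3
  trachea <- (ax - nx * 0.25)^2 + (ay - ny * 0.8)^2 <= (nx * 0.06)^2
  trachea <- trachea & !roi & !air & !adipose
  masks <- list(roi = roi, air = air & !roi, adipose = adipose & !roi,
                trachea = trachea)
  vol <- array(intensities[["background"]], shape)
  vol[masks$roi] <- intensities[["roi"]]
  vol[masks$air] <- intensities[["air"]]
  vol[masks$adipose] <- intensities[["adipose"]]
  vol[masks$trachea] <- intensities[["trachea"]]
  if (cupping > 0) {
    r2 <- ((ax - nx / 2) / nx)^2 + ((ay - ny / 2) / ny)^2
    vol <- vol + cupping * r2 * 4
  }
  if (smooth_sd > 0) vol <- gaussian_blur3(vol, smooth_sd)
  if (noise_magnitude > 0) {
    vol <- vol + withr::with_seed(seed, {
      sample_noise(noise_family, length(vol), noise_magnitude)
    })
  }
  list(volume = vol, masks = masks)
}

# centred noise draws from the four supported families, scaled to sd ~ mag
sample_noise <- function(family, n, mag) {
  switch(family,
    gaussian = rnorm(n, sd = mag),
    rayleigh = {
      x <- mag * sqrt(-2 * log(runif(n)))  # inverse-CDF Rayleigh
      x - mag * sqrt(pi / 2)
    },
    poisson = mag * (rpois(n, lambda = 4) - 4) / 2,
    gamma = mag * (rgamma(n, shape = 4, rate = 2) - 2) / 1,
    abort(paste("unknown noise family:", family))
  )
}

# separable 3D Gaussian convolution (reflective borders); kernel support
# 3 sd each side
gaussian_blur3 <- function(vol, sd) {
  half <- max(1L, ceiling(3 * sd))
  k <- dnorm(-half:half, sd = sd)
  k <- k / sum(k)
  conv_axis <- function(v, axis) {
    n <- dim(v)[axis]
    idx <- vapply(seq_len(n), function(i) {
      j <- i + (-half:half)
      j[j < 1] <- 2 - j[j < 1]
      j[j > n] <- 2 * n - j[j > n]
      j
    }, integer(2 * half + 1))
    out <- array(0, dim(v))
    for (o in seq_len(2 * half + 1)) {
      sl <- switch(axis,
                   v[idx[o, ], , , drop = FALSE],
                   v[, idx[o, ], , drop = FALSE],
                   v[, , idx[o, ], drop = FALSE])
      out <- out + k[o] * sl
    }
    out
  }
  conv_axis(conv_axis(conv_axis(vol, 1), 2), 3)
}

#' Extract the compact per-compartment feature bank
#'
#' A deterministic, documented stand-in for a full radiomics feature bank:
#' per compartment, first-order statistics (mean, sd, skewness, 10th/90th
#' percentile), 32-bin histogram entropy and uniformity, mean gradient
#' magnitude, and one grey-level co-occurrence contrast (unit offset along
#' x, 32 grey levels over the compartment's intensity range).
#'
#' @param volume 3D numeric array.
#' @param masks Named list of logical arrays (same shape), one per
#'   compartment.
#' @return Tibble with columns `compartment`, `feature`, `value`.
#' @export
extract_fixture_features <- function(volume, masks) {
  purrr::map_dfr(names(masks), function(nm) {
    mask <- masks[[nm]]
    stopifnot(identical(dim(mask), dim(volume)))
    if (!any(mask)) abort(paste("empty mask:", nm))
    x <- volume[mask]
    p <- hist_probs(x, bins = 32)
    entropy <- -sum(ifelse(p > 0, p * log2(p), 0))
    feats <- c(
      mean = mean(x), sd = sd(x),
      skewness = if (sd(x) == 0) 0 else mean((x - mean(x))^3) / sd(x)^3,
      entropy = entropy,
      uniformity = sum(p^2),
      p10 = unname(quantile(x, 0.10, type = 7)),
      p90 = unname(quantile(x, 0.90, type = 7)),
      gradient_mean = gradient_mean(volume, mask),
      glcm_contrast = glcm_contrast(volume, mask, grey_levels = 32)
    )
    tibble::tibble(compartment = nm, feature = names(feats),
                   value = unname(feats))
  })
}

hist_probs <- function(x, bins) {
  if (diff(range(x)) == 0) return(c(1, rep(0, bins - 1)))
  cuts <- seq(min(x), max(x), length.out = bins + 1)
  counts <- tabulate(pmin(findInterval(x, cuts, rightmost.closed = TRUE),
                          bins), bins)
  counts / sum(counts)
}

# mean central-difference gradient magnitude over masked voxels
gradient_mean <- function(volume, mask) {
  d <- dim(volume)
  shift <- function(axis, by) {
    idx <- pmin(pmax(seq_len(d[axis]) + by, 1), d[axis])
    switch(axis,
           volume[idx, , , drop = FALSE],
           volume[, idx, , drop = FALSE],
           volume[, , idx, drop = FALSE])
  }
  gx <- (shift(1, 1) - shift(1, -1)) / 2
  gy <- (shift(2, 1) - shift(2, -1)) / 2
  gz <- (shift(3, 1) - shift(3, -1)) / 2
  mean(sqrt(gx[mask]^2 + gy[mask]^2 + gz[mask]^2))
}

# co-occurrence contrast, symmetric unit offset along x, within the mask
glcm_contrast <- function(volume, mask, grey_levels = 32) {
  rng <- range(volume[mask])
  if (diff(rng) == 0) return(0)
  q <- array(0L, dim(volume))
  q[mask] <- pmin(
    1L + as.integer((volume[mask] - rng[1]) / diff(rng) * grey_levels),
    grey_levels
  )
  d <- dim(volume)
  a <- q[1:(d[1] - 1), , , drop = FALSE]
  b <- q[2:d[1], , , drop = FALSE]
  keep <- a > 0L & b > 0L  # both voxels inside the mask
  if (!any(keep)) return(0)
  mean((a[keep] - b[keep])^2)
}
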