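#' Synthetic CT phantom specification
#'
#' Describes a spatially continuous slice sequence containing a bright
#' convex "kidney" ellipse abutting a larger, similar-intensity neighbor
#' structure (the liver/spleen confound), over a darker background, with
#' additive Gaussian noise and a low-frequency multiplicative
#' inhomogeneity field. The kidney's semi-axes vary smoothly with a
#' mid-stack maximum and its center drifts at most one pixel per slice,
#' emulating the spatial continuity the crop propagation and automatic
#' seeding rely on.
#'
#' @param n_slices Number of slices, default 20.
#' @param shape Slice shape, default \code{c(128, 128)}.
#' @param kidney_intensity Default 0.62.
#' @param neighbor_intensity Default 0.58 (must differ from the kidney by
#'   at least 0.02 -- close enough to be confusable, separable enough
#'   that the task is well posed).
#' @param background_intensity Default 0.25.
#' @param kidney_axes Maximal (row, col) semi-axes of the kidney ellipse,
#'   default \code{c(26, 40)}. The default makes the kidney fill roughly
#'   half of its 10-px-extended bounding rectangle, the proportion a
#'   tightly boxed kidney occupies in sub-millimeter CT, so the crop
#'   geometry matches the setting the modal-cluster rule assumes.
#' @param noise_sd Additive Gaussian noise sd, default 0.03.
#' @param inhomogeneity Amplitude of the low-frequency multiplicative
#'   gain field (<= 0.05), default 0.01: small relative to the 0.04
#'   kidney/neighbor contrast, as intensity clustering presumes roughly
#'   stationary class means (stronger bias fields would call for
#'   bias-field correction, which is outside this pipeline).
#' @param rng_seed Seed for the noise, default 0.
#' @return A list of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(n_slices = 20L, shape = c(128L, 128L),
                         kidney_intensity = 0.62, neighbor_intensity = 0.58,
                         background_intensity = 0.25,
                         kidney_axes = c(26, 40),
                         noise_sd = 0.03, inhomogeneity = 0.01,
                         rng_seed = 0L) {
  if (abs(kidney_intensity - neighbor_intensity) < 0.02)
    stop("kidney and neighbor intensities must differ by >= 0.02", call. = FALSE)
  if (inhomogeneity > 0.05)
    stop("inhomogeneity amplitude must be <= 0.05", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_slices = as.integer(n_slices), shape = as.integer(shape),
                 kidney_intensity = kidney_intensity,
                 neighbor_intensity = neighbor_intensity,
                 background_intensity = background_intensity,
                 kidney_axes = kidney_axes,
                 noise_sd = noise_sd, inhomogeneity = inhomogeneity,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

ellipse_mask <- function(shape, center, semi_axes) {
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  c <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  m <- ((r - center[1L]) / semi_axes[1L])^2 + ((c - center[2L]) / semi_axes[2L])^2 <= 1
  matrix(as.integer(m), shape[1L], shape[2L])
}

#' Generate a synthetic phantom sequence with ground truth
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return List: \code{volume} (a \code{\link{ct_volume}}), \code{truth}
#'   (list of noiseless kidney masks), \code{start_index} (slice with the
#'   largest kidney cross-section), \code{start_bbox} (that slice's truth
#'   MBR extended by 10 px), \code{spec}. The result carries a
#'   \code{clip_fraction} attribute (fraction of pixels clipped to
#'   \code{[0, 1]} after noise).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$rng_seed)

  n <- spec$n_slices
  shp <- spec$shape
  mid <- (n + 1) / 2
  half <- max(1, (n - 1) / 2)
  base_center <- c(shp[1L] / 2, shp[2L] / 2 + shp[2L] %/% 8)
  nb_axes <- c(min(spec$kidney_axes[1L] * 2.1, shp[1L] / 2 - 4),
               spec$kidney_axes[2L] * 0.5)
  # neighbor abuts the kidney's left flank (4 px overlap, kidney drawn last)
  nb_center <- c(shp[1L] / 2,
                 base_center[2L] - spec$kidney_axes[2L] - nb_axes[2L] + 4)

  rr <- matrix(seq_len(shp[1L]), shp[1L], shp[2L])
  cc <- matrix(seq_len(shp[2L]), shp[1L], shp[2L], byrow = TRUE)
  field <- 1 + spec$inhomogeneity * sin(2 * pi * rr / shp[1L] + 0.7) *
    cos(2 * pi * cc / shp[2L] + 0.3)

  slices <- vector("list", n)
  truth <- vector("list", n)
  clipped <- 0
  for (s in seq_len(n)) {
    # Gentle mid-stack maximum: a 20-slice stack at sub-millimeter slice
    # spacing spans a small fraction of a kidney, so adjacent
    # cross-sections stay close (truth Jaccard ~0.95 slice-to-slice).
    f <- sqrt(1 - 0.25 * ((s - mid) / half)^2)
    g <- sqrt(1 - 0.15 * ((s - mid) / half)^2)
    drift <- c(round(2.5 * sin(2 * pi * (s - 1) / max(1, n - 1))),
               round(2.5 * cos(2 * pi * (s - 1) / max(1, n - 1))) - round(2.5))
    center <- base_center + drift
    kid <- ellipse_mask(shp, center, spec$kidney_axes * f)
    nb <- ellipse_mask(shp, nb_center + c(drift[1L], 0), nb_axes * g)
    img <- matrix(spec$background_intensity, shp[1L], shp[2L])
    img[nb == 1L] <- spec$neighbor_intensity
    img[kid == 1L] <- spec$kidney_intensity    # kidney drawn last: truth intact
    img <- img * field
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd),
                          shp[1L], shp[2L])
    clipped <- clipped + sum(img < 0 | img > 1)
    img <- pmin(pmax(img, 0), 1)
    slices[[s]] <- img
    truth[[s]] <- kid
  }
  areas <- vapply(truth, sum, numeric(1))
  start_index <- which.max(areas)
  out <- list(volume = ct_volume(slices),
              truth = truth,
              start_index = start_index,
              start_bbox = extended_mbr(truth[[start_index]], 10L, shp),
              spec = spec)
  attr(out, "clip_fraction") <- clipped / (n * prod(shp))
  out
}

#' Two-region piecewise-constant test image
#'
#' Left half at one intensity, right half at another (odd widths give the
#' extra column to the right half); the analytic fixture on which GrowCut
#' must recover the exact half-split from a single seed per region.
#'
#' @param nrow,ncol Image shape.
#' @param intensity_a,intensity_b Distinct intensities in \code{[0, 1]}.
#' @return Grayscale image matrix.
#' @export
generate_two_region <- function(nrow, ncol, intensity_a, intensity_b) {
  if (intensity_a == intensity_b)
    stop("intensities must be distinct", call. = FALSE)
  if (min(intensity_a, intensity_b) < 0 || max(intensity_a, intensity_b) > 1)
    stop("intensities must lie in [0, 1]", call. = FALSE)
  left <- ncol %/% 2L
  cbind(matrix(intensity_a, nrow, left),
        matrix(intensity_b, nrow, ncol - left))
}
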