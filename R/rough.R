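#' Rough-segmentation parameters
#'
#' @param margin Pixels by which the minimum bounding rectangle is
#'   extended on each side before cropping the next slice, default 10.
#' @param connectivity 8 (default) or 4, for connected-component
#'   extraction.
#' @param smooth_radius Disk radius of the contour-smoothing
#'   opening/closing, default 2; 0 disables smoothing.
#' @param median_window Median-filter window applied to the full slice
#'   before cropping, default 3; 0 or 1 disables.
#' @param max_failures Consecutive per-slice failures after which
#'   propagation stops in a direction, default 2.
#' @param min_component_frac Minimum fraction of the modal cluster that
#'   its largest connected region must hold, default 0.75. A kidney
#'   cross-section is one coherent region; when the modal cluster is a
#'   scatter of noise fragments (as in a crop containing no organ) the
#'   slice is declared failed rather than producing a spurious mask.
#' @return A list of class \code{"rough_params"}.
#' @export
rough_params <- function(margin = 10L, connectivity = 8L, smooth_radius = 2L,
                         median_window = 3L, max_failures = 2L,
                         min_component_frac = 0.75) {
  if (margin < 0L) stop("margin must be >= 0", call. = FALSE)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  if (smooth_radius < 0L) stop("smooth_radius must be >= 0", call. = FALSE)
  structure(list(margin = as.integer(margin), connectivity = as.integer(connectivity),
                 smooth_radius = as.integer(smooth_radius),
                 median_window = as.integer(median_window),
                 max_failures = as.integer(max_failures),
                 min_component_frac = min_component_frac),
            class = "rough_params")
}

#' Crop an image to a bounding box
#'
#' @param image Matrix.
#' @param box \code{\link{bbox}} within the image.
#' @return The sub-matrix covered by the box.
#' @export
crop <- function(image, box) {
  check_bbox_within(box, dim(image))
  image[box["row_lo"]:box["row_hi"], box["col_lo"]:box["col_hi"], drop = FALSE]
}

# Re-embed a cropped mask at full-slice coordinates.
embed_mask <- function(mask, box, shape) {
  full <- matrix(0L, shape[1], shape[2])
  full[box["row_lo"]:box["row_hi"], box["col_lo"]:box["col_hi"]] <- mask
  full
}

#' Mask of the modal cluster
#'
#' Extracts the cluster containing the most pixels (in a tight kidney
#' crop this is the kidney tissue class). Exact ties are broken toward
#' the cluster with the higher centroid, i.e. the brighter tissue.
#'
#' @param labels Integer label matrix (values 1..c).
#' @param centroids Cluster centroids, indexed by label.
#' @return Binary mask of the modal label.
#' @export
select_max_cluster <- function(labels, centroids) {
  if (length(labels) == 0L) stop("empty label image", call. = FALSE)
  counts <- tabulate(labels, nbins = length(centroids))
  best <- which(counts == max(counts))
  if (length(best) > 1L) best <- best[which.max(centroids[best])]
  matrix(as.integer(labels == best), nrow(labels), ncol(labels))
}

# Connected-component labelling by breadth-first flood fill.
label_components <- function(mask, connectivity = 8L) {
  mask <- validate_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  off <- neighbor_offsets(if (connectivity == 8L) "moore8" else "neumann4")
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  remaining <- which(mask == 1L)
  while (length(remaining) > 0L) {
    seed <- remaining[1L]
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier) > 0L) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (o in off) {
        rr <- r + o[1L]; cc <- c + o[2L]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        idx <- (cc[ok] - 1L) * nr + rr[ok]
        idx <- idx[mask[idx] == 1L & lab[idx] == 0L]
        if (length(idx) > 0L) {
          lab[idx] <- cur
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
    remaining <- remaining[lab[remaining] == 0L]
  }
  lab
}

#' Largest connected foreground region
#'
#' Keeps only the maximum-area connected component (the candidate kidney
#' region). Area ties go to the component whose top-left-most pixel is
#' smallest in (row, col) order. An all-zero mask is returned unchanged
#' with a warning and attribute \code{empty = TRUE}.
#'
#' @param mask Binary mask.
#' @param connectivity 8 (default) or 4.
#' @return Binary mask of the largest component.
#' @export
largest_connected_region <- function(mask, connectivity = 8L) {
  mask <- validate_mask(mask)
  if (sum(mask) == 0L) {
    warning("all-zero mask: no connected region", call. = FALSE)
    return(structure(mask, empty = TRUE))
  }
  lab <- label_components(mask, connectivity)
  areas <- tabulate(lab[lab > 0L])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    # lexicographically smallest (row, col) first-pixel wins
    first_px <- vapply(best, function(b) {
      idx <- which(lab == b)
      r <- (idx - 1L) %% nrow(lab) + 1L
      c <- (idx - 1L) %/% nrow(lab) + 1L
      o <- order(r, c)[1L]
      c(r[o], c[o])
    }, integer(2))
    best <- best[order(first_px[1L, ], first_px[2L, ])[1L]]
  }
  matrix(as.integer(lab == best), nrow(mask), ncol(mask))
}

#' Fill interior holes
#'
#' Background regions not 4-connected to the image border are set to
#' foreground (vessels rejected by the clustering leave holes inside the
#' kidney). The output always contains the input.
#'
#' @param mask Binary mask.
#' @return Mask with holes filled.
#' @export
fill_holes <- function(mask) {
  mask <- validate_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  reached <- matrix(FALSE, nr, nc)
  border <- unique(c(which(row(mask) == 1L), which(row(mask) == nr),
                     which(col(mask) == 1L), which(col(mask) == nc)))
  frontier <- border[mask[border] == 0L]
  reached[frontier] <- TRUE
  off <- neighbor_offsets("neumann4")
  while (length(frontier) > 0L) {
    r <- (frontier - 1L) %% nr + 1L
    c <- (frontier - 1L) %/% nr + 1L
    nxt <- integer(0)
    for (o in off) {
      rr <- r + o[1L]; cc <- c + o[2L]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      idx <- (cc[ok] - 1L) * nr + rr[ok]
      idx <- idx[mask[idx] == 0L & !reached[idx]]
      if (length(idx) > 0L) {
        reached[idx] <- TRUE
        nxt <- c(nxt, idx)
      }
    }
    frontier <- unique(nxt)
  }
  out <- mask
  out[mask == 0L & !reached] <- 1L
  out
}

disc_brush <- function(radius) EBImage::makeBrush(2L * radius + 1L, shape = "disc")

#' Smooth a mask contour
#'
#' Morphological opening followed by closing with a disk structuring
#' element; removes spurs and small indentations on the candidate kidney
#' contour. Radius 0 is the identity.
#'
#' @param mask Binary mask.
#' @param radius Disk radius, default 2.
#' @return Smoothed binary mask.
#' @export
smooth_contour <- function(mask, radius = 2L) {
  mask <- validate_mask(mask)
  if (radius == 0L) return(mask)
  b <- disc_brush(as.integer(radius))
  out <- EBImage::closing(EBImage::opening(mask, b), b)
  matrix(as.integer(out > 0), nrow(mask), ncol(mask))
}

#' Extended minimum bounding rectangle
#'
#' The tight bounding rectangle of the mask foreground, expanded by
#' \code{margin} pixels on all four sides and clamped to the image; used
#' to crop the adjacent slice, exploiting the spatial continuity of the
#' sequence.
#'
#' @param mask Non-empty binary mask.
#' @param margin Extension in pixels, default 10.
#' @param shape Image shape \code{c(rows, cols)}; defaults to the mask's.
#' @return A \code{\link{bbox}}.
#' @export
extended_mbr <- function(mask, margin = 10L, shape = dim(mask)) {
  mask <- validate_mask(mask)
  if (sum(mask) == 0L) stop("cannot take the MBR of an empty mask", call. = FALSE)
  rr <- range(row(mask)[mask == 1L])
  cc <- range(col(mask)[mask == 1L])
  bbox(max(1L, rr[1L] - margin), max(1L, cc[1L] - margin),
       min(shape[1L], rr[2L] + margin), min(shape[2L], cc[2L] + margin))
}

#' Rough segmentation of one slice
#'
#' The six-step per-slice procedure: median-filter the full slice, crop,
#' cluster with SKFCM, extract the modal cluster, keep the largest
#' connected region, fill holes, smooth the contour, and compute the
#' extended MBR that crops the adjacent slice. If the candidate region is
#' empty after smoothing the slice is flagged as failed (mask all zero,
#' next box = input box) rather than raising an error; the sequence
#' driver decides the fallback.
#'
#' @param image Full grayscale slice.
#' @param box Crop \code{\link{bbox}} (manual for the seed slice,
#'   propagated otherwise).
#' @param skfcm SKFCM parameters.
#' @param rough Rough-stage parameters.
#' @return A list of class \code{"rough_result"}: \code{mask} (full-slice
#'   coordinates), \code{next_bbox}, \code{bbox} (the crop used),
#'   \code{cluster_labels} (over the crop), \code{converged},
#'   \code{failed}.
#' @export
rough_segment_slice <- function(image, box, skfcm = skfcm_params(),
                                rough = rough_params()) {
  validate_gray_image(image)
  check_bbox_within(box, dim(image))
  filtered <- if (rough$median_window >= 3L)
    median_filter(image, rough$median_window) else image
  cropped <- crop(filtered, box)
  fit <- skfcm_cluster(cropped, skfcm)
  modal <- select_max_cluster(fit$labels, fit$centroids)
  m <- suppressWarnings(largest_connected_region(modal, rough$connectivity))
  # a coherent organ candidate is one dominant connected region; a
  # fragmented modal cluster means the crop holds no such structure
  fragmented <- sum(modal) == 0L ||
    sum(m) / sum(modal) < rough$min_component_frac
  m <- fill_holes(m)
  m <- smooth_contour(m, rough$smooth_radius)
  failed <- fragmented || sum(m) == 0L
  if (failed) {
    return(structure(list(mask = matrix(0L, nrow(image), ncol(image)),
                          next_bbox = box, bbox = box,
                          cluster_labels = fit$labels,
                          converged = fit$converged, failed = TRUE),
                     class = "rough_result"))
  }
  full_mask <- embed_mask(m, box, dim(image))
  nb <- extended_mbr(full_mask, rough$margin, dim(image))
  structure(list(mask = full_mask, next_bbox = nb, bbox = box,
                 cluster_labels = fit$labels,
                 converged = fit$converged, failed = FALSE),
            class = "rough_result")
}

#' Rough segmentation of a slice sequence
#'
#' Starting from one manually boxed slice (the slice with the largest
#' kidney contour, typically mid-kidney), propagates the crop rectangle
#' independently up-stack and down-stack: each slice is cropped by its
#' predecessor's extended MBR. On a failed slice the predecessor's box is
#' reused; after \code{max_failures} consecutive failures propagation
#' stops in that direction.
#'
#' @param volume A \code{\link{ct_volume}}.
#' @param start_index Index of the manually boxed slice.
#' @param start_bbox Manual \code{\link{bbox}} enclosing the kidney on
#'   that slice.
#' @param skfcm,rough Parameter objects.
#' @return Named list (by slice index, as character) of
#'   \code{rough_result}; slices never reached are absent.
#' @export
rough_segment_sequence <- function(volume, start_index, start_bbox,
                                   skfcm = skfcm_params(),
                                   rough = rough_params()) {
  n <- length(volume$slices)
  if (start_index < 1L || start_index > n)
    stop("start_index out of range", call. = FALSE)
  results <- list()
  seed_res <- rough_segment_slice(volume$slices[[start_index]], start_bbox,
                                  skfcm, rough)
  results[[as.character(start_index)]] <- seed_res
  for (step in c(1L, -1L)) {
    box <- seed_res$next_bbox
    failures <- 0L
    i <- start_index + step
    while (i >= 1L && i <= n && failures < rough$max_failures) {
      res <- rough_segment_slice(volume$slices[[i]], box, skfcm, rough)
      results[[as.character(i)]] <- res
      if (res$failed) {
        failures <- failures + 1L   # reuse the previous box once, then stop
      } else {
        failures <- 0L
        box <- res$next_bbox
      }
      i <- i + step
    }
  }
  results[order(as.integer(names(results)))]
}
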