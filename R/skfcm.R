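#' SKFCM parameters
#'
#' Parameters of the spatially constrained kernel fuzzy c-means
#' clustering used for rough segmentation.
#'
#' @param c Number of clusters (>= 2). Default 4, the cluster count that
#'   separates kidney parenchyma, similar-intensity neighbor tissue and
#'   background in abdominal CT crops.
#' @param m Fuzziness exponent (> 1), default 2.
#' @param alpha Weight of the spatial penalty term (>= 0), default 1:
#'   equal weight to the neighborhood-mean term.
#' @param sigma Gaussian kernel bandwidth in normalized-intensity units
#'   (> 0), default 0.2 -- of the order of inter-tissue contrast after
#'   rescaling to \code{[0, 1]}.
#' @param eps Convergence tolerance on the infinity norm of the centroid
#'   change, default 1e-4.
#' @param max_iter Iteration cap, default 200.
#' @param rng_seed Reserved for optional random restarts; the default
#'   initialization is deterministic and ignores it.
#' @return A list of class \code{"skfcm_params"}.
#' @export
skfcm_params <- function(c = 4L, m = 2, alpha = 1, sigma = 0.2,
                         eps = 1e-4, max_iter = 200L, rng_seed = 0L) {
  c <- as.integer(c)
  if (c < 2L) stop("c must be >= 2", call. = FALSE)
  if (m <= 1) stop("m must be > 1", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  structure(list(c = c, m = m, alpha = alpha, sigma = sigma, eps = eps,
                 max_iter = as.integer(max_iter), rng_seed = as.integer(rng_seed)),
            class = "skfcm_params")
}

#' Gaussian kernel
#'
#' \code{K(x, v) = exp(-(x - v)^2 / (2 sigma^2))}; the kernel-induced
#' distance \code{1 - K} replaces the squared Euclidean distance of plain
#' fuzzy c-means. Vectorized over \code{x} and \code{v}.
#'
#' @param x,v Numeric (intensities / centroids).
#' @param sigma Bandwidth, > 0.
#' @return Values in \code{(0, 1]}.
#' @export
gaussian_kernel <- function(x, v, sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  exp(-((x - v)^2) / (2 * sigma^2))
}

#' Neighborhood-mean image
#'
#' Each pixel is replaced by the arithmetic mean of its 8 neighbors
#' (center excluded), reflect-padded at the borders. This is the spatial
#' feature coupled to each pixel by the SKFCM penalty term.
#'
#' @param image Grayscale image matrix.
#' @return Matrix of the same shape with values in \code{[0, 1]}.
#' @export
spatial_mean <- function(image) {
  validate_gray_image(image)
  nr <- nrow(image); nc <- ncol(image)
  pad <- pad_reflect(image, 1L)
  acc <- matrix(0, nr, nc)
  for (o in neighbor_offsets("moore8"))
    acc <- acc + pad[(2L + o[1]):(1L + o[1] + nr), (2L + o[2]):(1L + o[2] + nc)]
  acc / 8
}

# Kernel-induced distances, c x N: d_ik = (1 - K(x_k, v_i)) + alpha (1 - K(xbar_k, v_i))
skfcm_distances <- function(x, xbar, v, params) {
  d <- vapply(v, function(vi) {
    (1 - gaussian_kernel(x, vi, params$sigma)) +
      params$alpha * (1 - gaussian_kernel(xbar, vi, params$sigma))
  }, numeric(length(x)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L)  # single pixel
  t(d)
}

#' Membership update
#'
#' One alternating-iteration update of the fuzzy partition matrix:
#' \code{u_ik} is proportional to \code{d_ik^(-1/(m-1))} where
#' \code{d_ik} is the kernel-induced distance of pixel k to centroid i
#' plus the alpha-weighted distance of its neighborhood mean, normalized
#' so memberships sum to 1 over clusters. Pixels at exactly zero distance
#' to one or more centroids get full membership split equally among those
#' singular clusters.
#'
#' @param x Numeric vector of pixel intensities.
#' @param xbar Neighborhood means (same length).
#' @param v Numeric vector of centroids.
#' @param params \code{\link{skfcm_params}}.
#' @return c x N membership matrix, columns summing to 1.
#' @export
update_memberships <- function(x, xbar, v, params) {
  d <- skfcm_distances(x, xbar, v, params)
  w <- d^(-1 / (params$m - 1))
  u <- sweep(w, 2L, colSums(w), "/")
  sing <- colSums(d == 0) > 0L
  if (any(sing)) {
    zs <- d[, sing, drop = FALSE] == 0
    u[, sing] <- sweep(zs * 1, 2L, colSums(zs), "/")
  }
  if (!all(is.finite(u)))
    stop("non-finite memberships encountered", call. = FALSE)
  u
}

#' Centroid update
#'
#' \code{v_i = sum_k u_ik^m [K(x_k,v_i) x_k + alpha K(xbar_k,v_i) xbar_k] /
#' sum_k u_ik^m [K(x_k,v_i) + alpha K(xbar_k,v_i)]}, with the previous
#' iterate's centroids inside the kernel. A centroid whose denominator
#' vanishes (empty cluster) is re-seeded from the pixel with the lowest
#' maximum membership.
#'
#' @inheritParams update_memberships
#' @param u c x N membership matrix.
#' @return Updated centroid vector.
#' @export
update_centroids <- function(x, xbar, u, v, params) {
  um <- u^params$m
  v_new <- numeric(length(v))
  for (i in seq_along(v)) {
    kx <- gaussian_kernel(x, v[i], params$sigma)
    kb <- gaussian_kernel(xbar, v[i], params$sigma)
    den <- sum(um[i, ] * (kx + params$alpha * kb))
    if (den == 0) {
      idx <- which.min(apply(u, 2L, max))
      warning(sprintf("empty cluster %d re-seeded from pixel %d", i, idx),
              call. = FALSE)
      v_new[i] <- x[idx]
    } else {
      v_new[i] <- sum(um[i, ] * (kx * x + params$alpha * kb * xbar)) / den
    }
  }
  v_new
}

# Objective J_m = sum_i sum_k u^m (1-K(x,v_i)) + alpha sum_i sum_k u^m (1-K(xbar,v_i))
skfcm_objective <- function(x, xbar, u, v, params) {
  d <- skfcm_distances(x, xbar, v, params)
  sum(u^params$m * d)
}

#' SKFCM clustering of an image
#'
#' Alternates membership and centroid updates from a deterministic
#' quantile initialization until the infinity-norm centroid change drops
#' below \code{eps} or \code{max_iter} is reached. Centroids are sorted
#' ascending on return (with membership rows permuted to match) so that
#' cluster indices are reproducible; hard labels are the argmax
#' membership, ties resolved to the lowest cluster index.
#'
#' @param image Grayscale image matrix (typically a cropped slice).
#' @param params \code{\link{skfcm_params}}.
#' @return A list of class \code{"skfcm_fit"}: \code{membership} (c x N,
#'   pixels in column-major order), \code{centroids} (ascending),
#'   \code{labels} (integer matrix, 1..c), \code{objective} (J_m trace,
#'   one value per iteration), \code{converged}, \code{iterations}.
#' @export
skfcm_cluster <- function(image, params = skfcm_params()) {
  validate_gray_image(image)
  x <- as.vector(image)
  if (length(unique(x)) < params$c)
    warning("image has fewer distinct values than clusters; fit is degenerate",
            call. = FALSE)
  xbar <- as.vector(spatial_mean(image))
  # Deterministic initialization: evenly spaced intensity quantiles.
  v <- as.numeric(stats::quantile(x, probs = (seq_len(params$c) - 0.5) / params$c,
                                  names = FALSE, type = 7))
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  u <- NULL
  while (iter < params$max_iter) {
    iter <- iter + 1L
    u <- update_memberships(x, xbar, v, params)
    v_new <- update_centroids(x, xbar, u, v, params)
    trace <- c(trace, skfcm_objective(x, xbar, u, v_new, params))
    delta <- max(abs(v_new - v))
    v <- v_new
    if (delta < params$eps) { converged <- TRUE; break }
  }
  ord <- order(v)
  v <- v[ord]
  u <- u[ord, , drop = FALSE]
  labels <- matrix(apply(u, 2L, which.max), nrow(image), ncol(image))
  structure(list(membership = u, centroids = v, labels = labels,
                 objective = trace, converged = converged, iterations = iter),
            class = "skfcm_fit")
}

#' @export
print.skfcm_fit <- function(x, ...) {
  cat(sprintf("<skfcm_fit: %d clusters, %d iterations, %s; centroids %s>\n",
              length(x$centroids), x$iterations,
              if (x$converged) "converged" else "NOT converged",
              paste(sprintf("%.3f", x$centroids), collapse = ", ")))
  invisible(x)
}
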