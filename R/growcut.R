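#' GrowCut parameters
#'
#' @param neighborhood \code{"moore8"} (default) or \code{"neumann4"}.
#' @param max_iter Iteration cap, default 500.
#' @param max_feature_norm Normalizing constant of the attack-force
#'   function; 1 because intensities are pre-normalized to \code{[0, 1]}.
#' @return A list of class \code{"growcut_params"}.
#' @export
growcut_params <- function(neighborhood = c("moore8", "neumann4"),
                           max_iter = 500L, max_feature_norm = 1) {
  neighborhood <- match.arg(neighborhood)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  structure(list(neighborhood = neighborhood, max_iter = as.integer(max_iter),
                 max_feature_norm = max_feature_norm),
            class = "growcut_params")
}

#' Attack-force attenuation g
#'
#' \code{g(d) = 1 - d / max_norm}: a neighbor's attack force is its
#' strength attenuated linearly by the feature distance, so similar
#' intensities conquer easily and contrast edges resist.
#'
#' @param d Nonnegative feature distance(s), \code{<= max_norm}.
#' @param max_norm Maximum feature norm (1 for normalized intensities).
#' @return Value(s) in \code{[0, 1]}, monotone decreasing in \code{d}.
#' @export
attack_g <- function(d, max_norm = 1) {
  if (any(d < 0) || any(d > max_norm))
    stop("d must lie in [0, max_norm]", call. = FALSE)
  1 - d / max_norm
}

#' Initialize the cellular-automaton state
#'
#' Seeded cells start with their seed label and full strength 1; all
#' other cells are unlabeled with strength 0. Every cell's feature is
#' its image intensity.
#'
#' @param image Grayscale image matrix.
#' @param seeds Integer matrix in \{-1, 0, +1\} (background / unlabeled /
#'   foreground), same shape; must contain at least one +1 and one -1.
#' @return A list of class \code{"cell_states"}: \code{label},
#'   \code{strength}, \code{feature} matrices.
#' @export
init_states <- function(image, seeds) {
  validate_gray_image(image)
  if (!identical(dim(seeds), dim(image)))
    stop("seed matrix shape must equal image shape", call. = FALSE)
  if (!all(seeds %in% c(-1L, 0L, 1L)))
    stop("seed values must be in {-1, 0, +1}", call. = FALSE)
  if (!any(seeds == 1L) || !any(seeds == -1L))
    stop("need at least one foreground (+1) and one background (-1) seed",
         call. = FALSE)
  label <- matrix(as.integer(seeds), nrow(image), ncol(image))
  strength <- matrix(0, nrow(image), ncol(image))
  strength[label != 0L] <- 1
  structure(list(label = label, strength = strength, feature = image),
            class = "cell_states")
}

# Shift a matrix by (dr, dc), padding vacated cells with `fill`.
shift_matrix <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r0 <- max(1L, 1L + dr); r1 <- min(nr, nr + dr)
  c0 <- max(1L, 1L + dc); c1 <- min(nc, nc + dc)
  if (r0 <= r1 && c0 <= c1)
    out[r0:r1, c0:c1] <- m[(r0:r1) - dr, (c0:c1) - dc, drop = FALSE]
  out
}

#' One synchronous GrowCut step
#'
#' All cells read the time-t grid and write time t+1. Each neighbor q
#' attacks cell p with force \code{g(|C_p - C_q|) * theta_q}; among
#' attackers whose force strictly exceeds \code{theta_p}, the one with
#' maximal force conquers p (label copied, strength set to the force).
#' Force ties are broken by the fixed row-major neighbor scan order.
#'
#' @param states \code{\link{init_states}} output (or a previous step's).
#' @param params \code{\link{growcut_params}}.
#' @return List: \code{states} (updated), \code{changed} (number of cells
#'   whose label or strength changed).
#' @export
growcut_step <- function(states, params = growcut_params()) {
  lab <- states$label; th <- states$strength; feat <- states$feature
  best_force <- matrix(-Inf, nrow(lab), ncol(lab))
  best_label <- matrix(0L, nrow(lab), ncol(lab))
  for (o in neighbor_offsets(params$neighborhood)) {
    q_th <- shift_matrix(th, o[1L], o[2L], fill = -Inf)
    q_lab <- shift_matrix(lab, o[1L], o[2L], fill = 0L)
    q_feat <- shift_matrix(feat, o[1L], o[2L], fill = 0)
    force <- (1 - abs(feat - q_feat) / params$max_feature_norm) * q_th
    force[q_th == -Inf] <- -Inf
    take <- force > best_force   # strict: first offset in scan order wins ties
    best_force[take] <- force[take]
    best_label[take] <- q_lab[take]
  }
  conquered <- best_force > th
  lab[conquered] <- best_label[conquered]
  th[conquered] <- best_force[conquered]
  list(states = structure(list(label = lab, strength = th, feature = feat),
                          class = "cell_states"),
       changed = sum(conquered))
}

#' GrowCut segmentation
#'
#' Iterates the cellular automaton until no cell changes (or
#' \code{max_iter} is reached, in which case the result carries
#' \code{converged = FALSE}). The returned mask is the +1-labeled region;
#' cells still unlabeled at termination count as background.
#'
#' @param image Grayscale image matrix.
#' @param seeds Seed label matrix in \{-1, 0, +1\}.
#' @param params \code{\link{growcut_params}}.
#' @return Binary mask with attributes \code{converged} and
#'   \code{iterations}.
#' @export
growcut_segment <- function(image, seeds, params = growcut_params()) {
  states <- init_states(image, seeds)
  iter <- 0L
  converged <- FALSE
  while (iter < params$max_iter) {
    iter <- iter + 1L
    step <- growcut_step(states, params)
    states <- step$states
    if (step$changed == 0L) { converged <- TRUE; break }
  }
  mask <- matrix(as.integer(states$label == 1L), nrow(image), ncol(image))
  attr(mask, "converged") <- converged
  attr(mask, "iterations") <- iter
  mask
}
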