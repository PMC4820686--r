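#' Seed-generation parameters
#'
#' Thresholds controlling automatic seed placement from a template
#' contour. At each traced contour point the local vertical change
#' \code{d_y} decides the placement axis: below \code{T_h} the contour is
#' locally horizontal and seeds go vertically (foreground \code{T1}
#' pixels inside, background \code{T2} pixels outside); otherwise they go
#' horizontally. Offsets must exceed the expected contour drift between
#' adjacent thin slices yet stay inside thin kidney sections.
#'
#' @param T_h Altitude-difference threshold in pixels, default 1.
#' @param T1 Inward (foreground) seed offset in pixels, default 3.
#' @param T2 Outward (background) seed offset in pixels, default 3.
#' @param step Contour subsampling stride (also the half-window of the
#'   altitude difference), default 1.
#' @return A list of class \code{"seed_params"}.
#' @export
seed_params <- function(T_h = 1L, T1 = 3L, T2 = 3L, step = 1L) {
  if (T1 < 1L || T2 < 1L || T_h < 0L || step < 1L)
    stop("need T1 >= 1, T2 >= 1, T_h >= 0, step >= 1", call. = FALSE)
  structure(list(T_h = as.integer(T_h), T1 = as.integer(T1),
                 T2 = as.integer(T2), step = as.integer(step)),
            class = "seed_params")
}

# Moore neighborhood in clockwise order (rows increase downward),
# starting west: W NW N NE E SE S SW.
.trace_dirs <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                        0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                      ncol = 2L, byrow = TRUE)

#' Trace the outer contour of a mask
#'
#' Moore-neighbor boundary tracing of the single foreground component:
#' returns the 8-connected outer boundary pixels in clockwise order,
#' starting from the top-left-most boundary pixel. Consecutive points are
#' 8-adjacent and the chain is closed.
#'
#' @param mask Binary mask with exactly one connected (8-connectivity)
#'   foreground component.
#' @return Integer matrix with columns \code{row}, \code{col}.
#' @export
contour_points <- function(mask) {
  mask <- validate_mask(mask)
  if (sum(mask) == 0L) stop("empty mask has no contour", call. = FALSE)
  lab <- label_components(mask, 8L)
  if (max(lab) > 1L)
    stop("mask must have exactly one connected foreground component", call. = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask == 1L)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  o <- order(r, c)[1L]
  start <- c(r[o], c[o])
  fg <- function(p) p[1L] >= 1L && p[1L] <= nr && p[2L] >= 1L && p[2L] <= nc &&
    mask[p[1L], p[2L]] == 1L
  pts <- list(start)
  cur <- start
  b_dir <- 1L                      # backtrack direction: west of the start pixel
  max_steps <- 8L * length(idx) + 8L
  steps <- 0L
  repeat {
    found <- FALSE
    for (k in 1:8) {
      d <- (b_dir - 1L + k) %% 8L + 1L
      cand <- cur + .trace_dirs[d, ]
      if (fg(cand)) {
        prev_d <- (b_dir - 1L + k - 1L) %% 8L + 1L  # last background cell checked
        prev_cell <- cur + .trace_dirs[prev_d, ]
        # direction index from cand to prev_cell
        delta <- prev_cell - cand
        b_dir <- which(.trace_dirs[, 1L] == delta[1L] & .trace_dirs[, 2L] == delta[2L])
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break                              # isolated single pixel
    if (cur[1L] == start[1L] && cur[2L] == start[2L] && b_dir == 1L) break
    pts[[length(pts) + 1L]] <- cur
    steps <- steps + 1L
    if (steps >= max_steps) break
  }
  out <- do.call(rbind, pts)
  colnames(out) <- c("row", "col")
  out
}

#' Altitude difference along a contour
#'
#' The local vertical change at a contour point: the absolute row
#' difference between the points \code{step} positions ahead and behind
#' on the traced chain (cyclic). Flat, horizontal contour stretches give
#' 0; vertical stretches give \code{2 * step}.
#'
#' @param contour Matrix from \code{\link{contour_points}}.
#' @param index Position on the chain (1-based).
#' @param step Half-window on the chain, default 1.
#' @return Nonnegative integer \code{d_y}.
#' @export
altitude_difference <- function(contour, index, step = 1L) {
  n <- nrow(contour)
  ahead <- (index - 1L + step) %% n + 1L
  behind <- (index - 1L - step) %% n + 1L
  as.integer(abs(contour[ahead, 1L] - contour[behind, 1L]))
}

#' Generate seed labels from a template mask
#'
#' The automatic-seeding step of the improved GrowCut: the contour of an
#' adjacent, already-segmented slice (the seed template) is traced, and
#' at each (subsampled) contour point a foreground seed is placed
#' \code{T1} pixels inside the contour and a background seed \code{T2}
#' pixels outside -- vertically where the contour is locally horizontal
#' (\code{d_y < T_h}), horizontally otherwise. The interior side is found
#' by testing which offset candidate lies inside the template; candidates
#' out of bounds or failing the inside/outside test are discarded.
#'
#' @param template_mask Single-component binary template mask.
#' @param params \code{\link{seed_params}}.
#' @param image_shape Shape of the target slice, default the template's.
#' @return Integer seed matrix in \{-1, 0, +1\} with at least one
#'   foreground and one background seed.
#' @export
generate_seeds <- function(template_mask, params = seed_params(),
                           image_shape = dim(template_mask)) {
  template_mask <- validate_mask(template_mask)
  pts <- contour_points(template_mask)
  nr <- image_shape[1L]; nc <- image_shape[2L]
  inb <- function(p) p[1L] >= 1L && p[1L] <= nr && p[2L] >= 1L && p[2L] <= nc
  inside <- function(p) p[1L] >= 1L && p[1L] <= nrow(template_mask) &&
    p[2L] >= 1L && p[2L] <= ncol(template_mask) &&
    template_mask[p[1L], p[2L]] == 1L
  seeds <- matrix(0L, nr, nc)
  for (i in seq(1L, nrow(pts), by = params$step)) {
    p <- pts[i, ]
    dy <- altitude_difference(pts, i, params$step)
    axis <- if (dy < params$T_h) c(1L, 0L) else c(0L, 1L)
    dir <- 0L
    for (sgn in c(1L, -1L)) {
      if (inside(p + sgn * params$T1 * axis)) { dir <- sgn; break }
    }
    if (dir == 0L) next
    fg <- p + dir * params$T1 * axis
    if (inb(fg)) seeds[fg[1L], fg[2L]] <- 1L
    bg <- p - dir * params$T2 * axis
    if (inb(bg) && !inside(bg)) seeds[bg[1L], bg[2L]] <- -1L
  }
  if (!any(seeds == 1L))
    stop("template too thin to place any foreground seed; reduce T1", call. = FALSE)
  if (!any(seeds == -1L))
    stop("no background seed could be placed; reduce T2", call. = FALSE)
  seeds
}

# Solidity = area / number of lattice points in the convex hull of the
# foreground pixel centers (Pick's theorem makes the hull count exact).
mask_solidity <- function(mask) {
  idx <- which(mask == 1L)
  n <- length(idx)
  if (n <= 2L) return(1)
  r <- (idx - 1L) %% nrow(mask) + 1L
  c <- (idx - 1L) %/% nrow(mask) + 1L
  h <- grDevices::chull(c, r)
  if (length(h) <= 2L) return(1)
  hx <- c[h]; hy <- r[h]
  shoelace <- abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
  edges <- cbind(diff(c(hx, hx[1L])), diff(c(hy, hy[1L])))
  boundary_pts <- sum(apply(abs(edges), 1L, function(e) {
    if (e[1L] == 0 && e[2L] == 0) 0 else .gcd(e[1L], e[2L])
  }))
  hull_lattice <- shoelace + boundary_pts / 2 + 1   # I + B by Pick's theorem
  min(1, n / hull_lattice)
}

.gcd <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }

#' Does a rough mask need refinement?
#'
#' A slice is flagged when its mask area changes by more than
#' \code{threshold} relative to the adjacent (toward-seed) slice's mask,
#' or when its solidity (area over convex-hull area) drops below
#' \code{min_solidity} -- both symptoms of the rough stage leaking into a
#' neighboring structure or losing part of the kidney.
#'
#' @param prev_mask Non-empty adjacent-slice mask.
#' @param curr_mask Current-slice mask.
#' @param threshold Relative area-change threshold, default 0.10.
#' @param min_solidity Solidity floor, default 0.85.
#' @return Logical flag.
#' @export
needs_refinement <- function(prev_mask, curr_mask, threshold = 0.10,
                             min_solidity = 0.85) {
  a_prev <- sum(prev_mask)
  if (a_prev == 0L) stop("previous mask is empty", call. = FALSE)
  a_curr <- sum(curr_mask)
  if (abs(a_curr - a_prev) / a_prev > threshold) return(TRUE)
  if (a_curr == 0L) return(TRUE)
  mask_solidity(curr_mask) < min_solidity
}

#' Refine one slice with automatically seeded GrowCut
#'
#' Generates seed labels from the template mask (an adjacent slice's
#' accepted segmentation), runs the GrowCut automaton on the cropped
#' window of the current slice, and re-embeds the result at full-slice
#' coordinates. No user interaction is consumed.
#'
#' @param image Full grayscale slice to refine.
#' @param template_mask Full-slice template mask from the adjacent slice.
#' @param seed_par \code{\link{seed_params}}.
#' @param growcut_par \code{\link{growcut_params}}.
#' @param box Crop window; defaults to the template's extended MBR.
#' @param margin Margin for the default crop window, default 10.
#' @return Full-slice binary mask with attributes \code{converged} and
#'   \code{iterations}.
#' @export
refine_slice <- function(image, template_mask, seed_par = seed_params(),
                         growcut_par = growcut_params(), box = NULL,
                         margin = 10L) {
  validate_gray_image(image)
  template_mask <- validate_mask(template_mask, dim(image))
  if (sum(template_mask) == 0L) stop("template mask is empty", call. = FALSE)
  # canonicalize the template: single component, no holes (stray pixels
  # from an earlier refinement would otherwise break contour tracing)
  template_mask <- fill_holes(largest_connected_region(template_mask))
  if (is.null(box)) box <- extended_mbr(template_mask, margin, dim(image))
  check_bbox_within(box, dim(image))
  tmpl_crop <- crop(template_mask, box)
  img_crop <- crop(image, box)
  seeds <- generate_seeds(tmpl_crop, seed_par, dim(img_crop))
  m <- growcut_segment(img_crop, seeds, growcut_par)
  conv <- attr(m, "converged"); iters <- attr(m, "iterations")
  if (sum(m) > 0L) m <- fill_holes(largest_connected_region(m))
  out <- embed_mask(m, box, dim(image))
  attr(out, "converged") <- conv
  attr(out, "iterations") <- iters
  out
}
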