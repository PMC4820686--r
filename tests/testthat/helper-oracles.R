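# Independent reference implementations used as oracles. These are
# deliberately written with naive loops, independent of the package's
# vectorized code paths.

# GrowCut state transition as a quadruple loop over cells and neighbors,
# with the same strict-improvement rule and first-wins tie-break.
naive_growcut_step <- function(st, neighborhood = "moore8") {
  off <- if (neighborhood == "moore8")
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else
    list(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  nr <- nrow(st$label); nc <- ncol(st$label)
  lab2 <- st$label; th2 <- st$strength
  changed <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      bf <- -Inf; bl <- 0L
      for (o in off) {
        rr <- r + o[1L]; cc <- c + o[2L]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        f <- (1 - abs(st$feature[r, c] - st$feature[rr, cc])) * st$strength[rr, cc]
        if (f > bf) { bf <- f; bl <- st$label[rr, cc] }
      }
      if (bf > st$strength[r, c]) {
        lab2[r, c] <- bl; th2[r, c] <- bf
        changed <- changed + 1L
      }
    }
  }
  list(states = list(label = lab2, strength = th2, feature = st$feature),
       changed = changed)
}

# Connected components by depth-first flood fill with an explicit stack.
flood_fill_components <- function(mask, connectivity = 8L) {
  off <- if (connectivity == 8L)
    list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else
    list(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask == 1L)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack) > 0L) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] > 0L) next
      lab[p] <- cur
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (o in off) {
        rr <- r + o[1L]; cc <- c + o[2L]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          q <- (cc - 1L) * nr + rr
          if (mask[q] == 1L && lab[q] == 0L) stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

# 8-neighbor mean by explicit per-pixel loops, reflect-padded.
naive_spatial_mean <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) { if (i < 1) 1 - i else if (i > n) 2 * n + 1 - i else i }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      s <- 0
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        s <- s + img[refl(r + dr, nr), refl(c + dc, nc)]
      }
      out[r, c] <- s / 8
    }
  }
  out
}

# Star-shaped random blob: a disc with a smooth random polar perturbation;
# guaranteed a single 8-connected component.
random_blob <- function(shape = c(40L, 40L), r0 = 10, seed = 1L) {
  set.seed(seed)
  center <- c(shape[1L] / 2, shape[2L] / 2) + stats::runif(2, -3, 3)
  amp <- stats::runif(3, 0, 0.2)
  phase <- stats::runif(3, 0, 2 * pi)
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  c <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  theta <- atan2(r - center[1L], c - center[2L])
  rad <- r0 * (1 + amp[1] * sin(theta + phase[1]) + amp[2] * sin(2 * theta + phase[2]) +
                 amp[3] * sin(3 * theta + phase[3]))
  m <- sqrt((r - center[1L])^2 + (c - center[2L])^2) <= rad
  matrix(as.integer(m), shape[1L], shape[2L])
}

# Axis-aligned ellipse mask (independent of the package's internal helper).
raster_ellipse <- function(shape, center, semi) {
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  c <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  m <- ((r - center[1L]) / semi[1L])^2 + ((c - center[2L]) / semi[2L])^2 <= 1
  matrix(as.integer(m), shape[1L], shape[2L])
}

jaccard <- function(a, b) {
  cm <- confusion(a, b)
  compute_metrics(cm)$overlap
}
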