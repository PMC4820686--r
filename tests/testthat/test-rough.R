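test_that("crop returns the exact sub-grid", {
  img <- matrix(1:100, 10, 10)
  expect_identical(crop(img, bbox(1, 1, 10, 10)), img)
  expect_identical(crop(img, bbox(4, 7, 4, 7)), matrix(img[4, 7], 1, 1))
  blk <- crop(img, bbox(3, 4, 4, 6))
  expect_identical(blk, img[3:4, 4:6])
})

test_that("modal cluster selection counts pixels and breaks ties toward brighter tissue", {
  lab <- matrix(c(rep(1L, 5), rep(2L, 10), rep(3L, 3)), 3, 6)
  m <- select_max_cluster(lab, c(0.2, 0.5, 0.8))
  expect_identical(sum(m), 10L)
  expect_true(all(m[lab == 2L] == 1L))
  # single cluster: everything selected
  expect_identical(select_max_cluster(matrix(1L, 2, 2), 0.5), matrix(1L, 2, 2))
  # exact tie: the cluster with the higher centroid wins
  tie <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  m_tie <- select_max_cluster(tie, c(0.3, 0.7))
  expect_true(all(m_tie[tie == 2L] == 1L) && sum(m_tie) == 2L)
})

test_that("largest connected region agrees with a flood-fill oracle", {
  m <- matrix(0L, 10, 10)
  m[2:4, 2:5] <- 1L          # area 12
  m[7:8, 7:9] <- 1L          # area 5 (minus one)
  m[8, 9] <- 0L
  out <- largest_connected_region(m, 8L)
  lab <- flood_fill_components(m, 8L)
  big <- which.max(tabulate(lab[lab > 0]))
  expect_identical(out, matrix(as.integer(lab == big), 10, 10))
  expect_identical(sum(out), 12L)
  # single blob unchanged
  single <- matrix(0L, 5, 5); single[2:3, 2:4] <- 1L
  expect_identical(largest_connected_region(single), single)
})

test_that("checkerboard under 4-connectivity keeps a single pixel", {
  cb <- matrix(as.integer((row(matrix(0, 6, 6)) + col(matrix(0, 6, 6))) %% 2), 6, 6)
  out <- largest_connected_region(cb, 4L)
  expect_identical(sum(out), 1L)
  # the tie rule picks the component whose first pixel is top-left-most
  idx <- which(out == 1L)
  all_idx <- which(cb == 1L)
  r <- (all_idx - 1L) %% 6L + 1L; c <- (all_idx - 1L) %/% 6L + 1L
  first <- all_idx[order(r, c)][1L]
  expect_identical(idx, first)
})

test_that("empty mask yields a warning, not an error", {
  expect_warning(out <- largest_connected_region(matrix(0L, 3, 3)), "all-zero")
  expect_true(all(out == 0L))
})

test_that("hole filling closes enclosed background but not border-connected channels", {
  ring <- matrix(0L, 5, 5)
  ring[2:4, 2:4] <- 1L; ring[3, 3] <- 0L
  filled <- fill_holes(ring)
  expect_identical(filled[2:4, 2:4], matrix(1L, 3, 3))
  # solid mask unchanged
  solid <- matrix(1L, 4, 4)
  expect_identical(fill_holes(solid), solid)
  # a 1-px channel to the border keeps the cavity open
  chan <- matrix(1L, 7, 7)
  chan[3:5, 3:5] <- 0L
  chan[4, 6:7] <- 0L
  out <- fill_holes(chan)
  expect_identical(out, chan)
  # output always contains the input
  set.seed(21)
  rnd <- matrix(sample(0:1, 100, TRUE), 10, 10)
  expect_true(all(fill_holes(rnd) >= rnd))
  # cross-check against EBImage on an enclosed hole
  expect_identical(fill_holes(ring), matrix(as.integer(EBImage::fillHull(ring)), 5, 5))
})

test_that("contour smoothing removes spurs and erases sub-element objects", {
  expect_identical(smooth_contour(matrix(1L, 4, 4), 0L), matrix(1L, 4, 4))
  disk <- raster_ellipse(c(31, 31), c(16, 16), c(10, 10))
  spur <- disk
  spur[16, 27:30] <- 1L
  sm <- smooth_contour(spur, 2L)
  expect_identical(sm[16, 28:30], c(0L, 0L, 0L))
  expect_lt(abs(sum(sm) - sum(disk)) / sum(disk), 0.05)
  tiny <- matrix(0L, 9, 9); tiny[4:5, 4:5] <- 1L
  expect_identical(sum(smooth_contour(tiny, 3L)), 0L)
})

test_that("extended MBR arithmetic, clamping, and zero margin", {
  m <- matrix(0L, 100, 100)
  m[21:31, 41:56] <- 1L
  b <- extended_mbr(m, 10L)
  expect_identical(unclass(b)[1:4],
                   c(row_lo = 11L, col_lo = 31L, row_hi = 41L, col_hi = 66L))
  b0 <- extended_mbr(m, 0L)
  expect_identical(unclass(b0)[1:4],
                   c(row_lo = 21L, col_lo = 41L, row_hi = 31L, col_hi = 56L))
  top <- matrix(0L, 20, 20); top[1:3, 5:9] <- 1L
  bt <- extended_mbr(top, 10L)
  expect_identical(bt[["row_lo"]], 1L)
  expect_identical(bt[["col_hi"]], 19L)
  expect_error(extended_mbr(matrix(0L, 3, 3)), "empty")
})

# CT-like scene: bright kidney ellipse abutting a similar-intensity
# neighbor slab over a dark background (the four natural intensity
# populations -- background, edge band, neighbor, kidney -- that the
# c = 4 clustering presumes). `present` turns the organs off per slice.
make_scene_volume <- function(n, shape, centers, semis, noise = 0.02, seed = 99,
                              present = rep(TRUE, n)) {
  set.seed(seed)
  slices <- vector("list", n); truth <- vector("list", n)
  nb_semi <- c(shape[1] / 2 - 4, semis[1, 2] * 0.5)
  nb_center <- c(shape[1] / 2, centers[1, 2] - semis[1, 2] - nb_semi[2] + 4)
  for (s in seq_len(n)) {
    img <- matrix(0.25, shape[1], shape[2])
    if (present[s]) {
      kid <- raster_ellipse(shape, centers[s, ], semis[s, ])
      nb <- raster_ellipse(shape, nb_center, nb_semi)
      img[nb == 1L] <- 0.58
      img[kid == 1L] <- 0.62
    } else kid <- matrix(0L, shape[1], shape[2])
    img <- pmin(pmax(img + matrix(rnorm(prod(shape), 0, noise), shape[1], shape[2]), 0), 1)
    slices[[s]] <- img; truth[[s]] <- kid
  }
  list(vol = ct_volume(slices), truth = truth)
}

test_that("a phantom slice is roughly segmented with high overlap", {
  ph <- generate_phantom(phantom_spec(n_slices = 3, rng_seed = 1))
  res <- rough_segment_slice(ph$volume$slices[[2]], ph$start_bbox)
  expect_false(res$failed)
  expect_gte(jaccard(res$mask, ph$truth[[2]]), 0.9)
  # the propagated box always contains the returned mask
  inside <- crop(res$mask, res$next_bbox)
  expect_identical(sum(inside), sum(res$mask))
})

test_that("a slice without any bright structure is flagged, not an error", {
  set.seed(30)
  img <- pmin(pmax(matrix(rnorm(80 * 80, 0.25, 0.02), 80, 80), 0), 1)
  res <- rough_segment_slice(img, bbox(20, 20, 60, 60))
  expect_true(res$failed)
  expect_true(all(res$mask == 0L))
})

test_that("crop propagation tracks a smoothly drifting kidney across a sequence", {
  n <- 12
  shape <- c(128, 128)
  centers <- cbind(64 + round(2 * sin(seq(0, pi, length.out = n))),
                   80 + seq_len(n) %/% 4)
  scale <- sqrt(1 - 0.03 * ((seq_len(n) - (n + 1) / 2) / (n / 2))^2)
  semis <- cbind(26 * scale, 40 * scale)
  ev <- make_scene_volume(n, shape, centers, semis)
  start <- which.max(vapply(ev$truth, sum, 1))
  res <- rough_segment_sequence(ev$vol, start, extended_mbr(ev$truth[[start]], 10L, shape))
  expect_length(res, n)
  js <- vapply(seq_len(n), function(i) jaccard(res[[as.character(i)]]$mask, ev$truth[[i]]), 1)
  expect_true(all(js >= 0.85))
  # bit-reproducible
  res2 <- rough_segment_sequence(ev$vol, start, extended_mbr(ev$truth[[start]], 10L, shape))
  expect_identical(res, res2)
})

test_that("propagation halts within two slices after the structure vanishes", {
  n <- 10
  shape <- c(128, 128)
  centers <- matrix(rep(c(64, 80), each = n), n)
  semis <- matrix(rep(c(26, 40), each = n), n)
  ev <- make_scene_volume(n, shape, centers, semis,
                          present = c(rep(TRUE, 6), rep(FALSE, 4)))
  start <- 3L
  res <- rough_segment_sequence(ev$vol, start, extended_mbr(ev$truth[[start]], 10L, shape))
  reached <- as.integer(names(res))
  expect_lte(max(reached), 8L)   # structure gone from slice 7 on
  expect_true(res[["7"]]$failed)
})

test_that("single-slice volumes run without propagation", {
  ev <- make_scene_volume(1, c(128, 128), matrix(c(64, 80), 1), matrix(c(26, 40), 1))
  res <- rough_segment_sequence(ev$vol, 1L, extended_mbr(ev$truth[[1]], 10L, c(128, 128)))
  expect_length(res, 1L)
})
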