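#' Median filter
#'
#' Each output pixel is the median of its \code{window} x \code{window}
#' neighborhood in the input (the standard denoising step before
#' clustering: impulse noise is removed while organ edges are preserved).
#' Borders are reflect-padded, so no artificial extremes are introduced at
#' the image edge. \code{window = 1} is the identity.
#'
#' @param image Grayscale image matrix, values in \code{[0, 1]}.
#' @param window Odd window size, default 3.
#' @return Filtered image, same shape.
#' @export
median_filter <- function(image, window = 3L) {
  validate_gray_image(image)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer", call. = FALSE)
  if (window == 1L) return(image)
  r <- (window - 1L) %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  pad <- pad_reflect(image, r)
  # Stack the window^2 shifted copies, then take the per-pixel median.
  stk <- array(NA_real_, c(nr, nc, window * window))
  k <- 0L
  for (dr in seq_len(window)) {
    for (dc in seq_len(window)) {
      k <- k + 1L
      stk[, , k] <- pad[dr:(dr + nr - 1L), dc:(dc + nc - 1L)]
    }
  }
  matrix(apply(stk, c(1L, 2L), stats::median), nr, nc)
}
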