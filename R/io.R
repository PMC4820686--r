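#' Validate a grayscale image
#'
#' A grayscale image is a plain numeric matrix with all values finite and
#' in \code{[0, 1]} (intensities are normalized once, volume-wide, at load
#' time so that cluster centroids and GrowCut feature distances are
#' comparable across slices).
#'
#' @param image Numeric matrix.
#' @return The image, invisibly, after validation.
#' @export
validate_gray_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 1L || ncol(image) < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (!all(is.finite(image)))
    stop("image intensities must all be finite", call. = FALSE)
  if (min(image) < 0 || max(image) > 1)
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  invisible(image)
}

#' Validate a binary mask
#'
#' @param mask Matrix of 0/1 values.
#' @param shape Optional expected \code{c(rows, cols)}.
#' @return The mask as an integer matrix, invisibly.
#' @export
validate_mask <- function(mask, shape = NULL) {
  if (!is.matrix(mask))
    stop("mask must be a matrix", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop("mask values must be 0 or 1", call. = FALSE)
  if (!is.null(shape) && !identical(dim(mask), as.integer(shape)))
    stop("mask shape does not match the associated image", call. = FALSE)
  invisible(matrix(as.integer(mask), nrow(mask), ncol(mask)))
}

#' Construct a bounding box
#'
#' Bounding boxes use 1-based inclusive (row, col) coordinates, the native
#' R slicing convention; rows increase downward. \code{row_lo:row_hi} and
#' \code{col_lo:col_hi} are the indices covered.
#'
#' @param row_lo,col_lo First row/column covered (>= 1).
#' @param row_hi,col_hi Last row/column covered (inclusive).
#' @return An object of class \code{"bbox"}.
#' @export
bbox <- function(row_lo, col_lo, row_hi, col_hi) {
  b <- c(row_lo = as.integer(row_lo), col_lo = as.integer(col_lo),
         row_hi = as.integer(row_hi), col_hi = as.integer(col_hi))
  if (anyNA(b)) stop("bbox coordinates must be integers", call. = FALSE)
  if (b["row_lo"] < 1L || b["col_lo"] < 1L ||
      b["row_lo"] > b["row_hi"] || b["col_lo"] > b["col_hi"])
    stop("invalid bbox: need 1 <= lo <= hi", call. = FALSE)
  structure(b, class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox rows %d..%d, cols %d..%d>\n",
              x["row_lo"], x["row_hi"], x["col_lo"], x["col_hi"]))
  invisible(x)
}

check_bbox_within <- function(box, shape) {
  if (box["row_hi"] > shape[1] || box["col_hi"] > shape[2])
    stop("bbox exceeds image bounds", call. = FALSE)
  invisible(box)
}

#' Construct a CT volume
#'
#' @param slices List of grayscale image matrices, all the same shape,
#'   ordered by slice position (the slice-to-slice propagation and the
#'   automatic seeding both rely on spatial continuity of the sequence).
#' @param spacing Optional numeric length-3 \code{(pixel_mm, pixel_mm,
#'   slice_mm)} metadata.
#' @return An object of class \code{"ct_volume"}.
#' @export
ct_volume <- function(slices, spacing = NULL) {
  if (!is.list(slices) || length(slices) == 0L)
    stop("slices must be a non-empty list of matrices", call. = FALSE)
  shp <- dim(slices[[1L]])
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]]), shp))
      stop(sprintf("slice %d has shape %s, expected %s", i,
                   paste(dim(slices[[i]]), collapse = "x"),
                   paste(shp, collapse = "x")), call. = FALSE)
    validate_gray_image(slices[[i]])
  }
  structure(list(slices = slices, spacing = spacing), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  shp <- dim(x$slices[[1L]])
  cat(sprintf("<ct_volume: %d slices of %dx%d>\n", length(x$slices), shp[1], shp[2]))
  invisible(x)
}

#' @export
length.ct_volume <- function(x) length(x$slices)

#' Rescale raw slice data to [0, 1] over the whole volume
#'
#' \code{(v - min) / (max - min)} with the min/max taken volume-wide; a
#' constant volume maps to all zeros.
#'
#' @param slices List of numeric matrices (raw values, any range).
#' @return List of matrices with values in \code{[0, 1]}.
#' @export
normalize_volume <- function(slices) {
  rng <- range(vapply(slices, range, numeric(2)))
  lo <- rng[1]; hi <- rng[2]
  if (hi > lo) lapply(slices, function(s) (s - lo) / (hi - lo))
  else lapply(slices, function(s) array(0, dim(s)))
}

read_single_image <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- switch(ext,
    png  = png::readPNG(f),
    tif  = ,
    tiff = tiff::readTIFF(f),
    stop(sprintf("unreadable file (unsupported extension): %s", f), call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                                           c(1L, 2L), mean)
  img
}

#' Read a CT volume
#'
#' Reads an ordered slice sequence from a NIfTI file or a directory of
#' PNG/TIFF images (sorted lexicographically by filename). Intensities are
#' rescaled to \code{[0, 1]} over the whole volume at load.
#'
#' @param path File (NIfTI) or directory (image stack).
#' @param format One of \code{"nifti"}, \code{"image_stack"},
#'   \code{"auto"} (guess from path). DICOM series are not supported.
#' @return A \code{\link{ct_volume}}.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "image_stack", "dicom_dir")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("path does not exist: %s", path), call. = FALSE)
  if (format == "auto")
    format <- if (dir.exists(path)) "image_stack" else "nifti"
  if (format == "dicom_dir")
    stop("DICOM series reading is not supported; convert to NIfTI or a PNG/TIFF stack first",
         call. = FALSE)
  if (format == "nifti") {
    arr <- RNifti::readNifti(path)
    pix <- tryCatch(RNifti::pixdim(arr)[1:3], error = function(e) NULL)
    arr <- as.array(arr)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) != 3L)
      stop("expected a 2-D or 3-D NIfTI volume", call. = FALSE)
    slices <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
    return(ct_volume(normalize_volume(slices), spacing = pix))
  }
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L)
    stop(sprintf("no PNG/TIFF files found in %s", path), call. = FALSE)
  slices <- lapply(files, read_single_image)
  shp <- dim(slices[[1L]])
  for (i in seq_along(slices))
    if (!identical(dim(slices[[i]]), shp))
      stop(sprintf("mixed slice shapes: %s is %s, expected %s", files[i],
                   paste(dim(slices[[i]]), collapse = "x"),
                   paste(shp, collapse = "x")), call. = FALSE)
  ct_volume(normalize_volume(slices))
}

#' Write a stack of binary masks
#'
#' PNG stacks store masks as 8-bit \{0, 255\}; NIfTI stores \{0, 1\}.
#' A write-then-read round trip reproduces the masks bit-exactly.
#'
#' @param masks Non-empty list of binary mask matrices of uniform shape.
#' @param path Output directory (\code{png_stack}) or file (\code{nifti}).
#' @param format \code{"png_stack"} or \code{"nifti"}.
#' @return Invisibly, the files written.
#' @export
write_mask_stack <- function(masks, path, format = c("png_stack", "nifti")) {
  format <- match.arg(format)
  if (!is.list(masks) || length(masks) == 0L)
    stop("masks must be a non-empty list", call. = FALSE)
  shp <- dim(masks[[1L]])
  for (i in seq_along(masks)) {
    validate_mask(masks[[i]])
    if (!identical(dim(masks[[i]]), shp))
      stop("masks must all share one shape", call. = FALSE)
  }
  if (format == "nifti") {
    arr <- array(0, c(shp, length(masks)))
    for (i in seq_along(masks)) arr[, , i] <- masks[[i]]
    RNifti::writeNifti(arr, path)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- file.path(path, sprintf("mask_%04d.png", seq_along(masks)))
  for (i in seq_along(masks))
    png::writePNG(masks[[i]] * 1.0, files[i])
  invisible(files)
}

#' Read a stack of binary masks
#'
#' Inverse of \code{\link{write_mask_stack}}; any pixel above 0.5 is
#' foreground.
#'
#' @param path Directory of PNGs or a NIfTI file.
#' @param format \code{"png_stack"} or \code{"nifti"}.
#' @return List of integer 0/1 matrices.
#' @export
read_mask_stack <- function(path, format = c("png_stack", "nifti")) {
  format <- match.arg(format)
  if (format == "nifti") {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    return(lapply(seq_len(dim(arr)[3]),
                  function(k) matrix(as.integer(arr[, , k] > 0.5),
                                     dim(arr)[1], dim(arr)[2])))
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop(sprintf("no PNG masks in %s", path), call. = FALSE)
  lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  })
}

#' Read a manual seed image (traditional GrowCut mode)
#'
#' Red pixels (R channel strictly above G) become foreground seeds (+1),
#' green pixels background seeds (-1); everything else is unlabeled (0).
#'
#' @param path An RGB PNG file.
#' @return Integer matrix in \{-1, 0, +1\}.
#' @export
read_seed_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("seed image must be RGB", call. = FALSE)
  r <- img[, , 1L]; g <- img[, , 2L]
  seeds <- matrix(0L, nrow(r), ncol(r))
  seeds[r > g] <- 1L
  seeds[g > r] <- -1L
  seeds
}
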