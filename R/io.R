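#' Read a grayscale image from PNG or TIFF
#'
#' Reads an image file and returns a numeric matrix of intensities in
#' `[0, 255]`. Colour inputs are converted to luma by channel averaging.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix with values in `[0, 255]`.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , 1:min(3, dim(arr)[3]), drop = FALSE], c(1, 2), mean)
  arr * 255
}

#' Write a grayscale image to PNG or TIFF
#'
#' @param img Numeric matrix; values are clipped to `[0, 255]`.
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  x <- clip255(as_gray_matrix(img)) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}

#' Read or write a binary mask as a 0/255 PNG
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @return `read_mask` returns a logical matrix; `write_mask` returns `path`
#'   invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  write_gray(ifelse(mask, 255, 0), path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) read_gray(path) >= 128
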