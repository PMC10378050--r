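# Raster primitives used by the augmentation module. Images are numeric
# arrays of dimension (height, width, 3) with values in [0, 1].

.as_image <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (length(dim(img)) != 3L) stop("image must be an (h, w, channels) array")
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]   # drop alpha
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  img
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Read an image file into an (h, w, 3) array
#'
#' PNG files are read natively; JPEG files are read through \pkg{EBImage}
#' when it is installed. Grayscale and alpha-channel images are promoted to
#' 3 channels.
#'
#' @param path Image file path.
#' @return Numeric array (h, w, 3) with values in \code{[0, 1]}.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package; PNG is supported natively")
    }
    img <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(img)) == 3L) img <- aperm(img, c(2L, 1L, 3L)) else img <- t(img)
  } else {
    stop("unsupported image format: ", ext)
  }
  .as_image(img)
}

# bilinear resize to (h, w)
resize_image <- function(img, h, w = h) {
  img <- .as_image(img)
  sh <- dim(img)[1]; sw <- dim(img)[2]
  if (sh == h && sw == w) return(img)
  # centre-aligned source coordinates for each target pixel
  ys <- (seq_len(h) - 0.5) * sh / h + 0.5
  xs <- (seq_len(w) - 0.5) * sw / w + 0.5
  .bilinear_sample(img, outer(ys, rep(1, w)), outer(rep(1, h), xs))
}

# sample img at fractional coordinates (Y, X), zero outside the canvas;
# Y and X are (h, w) matrices of row/col positions
.bilinear_sample <- function(img, Y, X) {
  sh <- dim(img)[1]; sw <- dim(img)[2]
  flat <- img
  dim(flat) <- c(sh * sw, 3L)
  y0 <- as.vector(floor(Y)); x0 <- as.vector(floor(X))
  fy <- as.vector(Y) - y0; fx <- as.vector(X) - x0
  px <- function(yy, xx) {
    ok <- yy >= 1 & yy <= sh & xx >= 1 & xx <= sw
    lin <- pmin(pmax(yy, 1L), sh) + (pmin(pmax(xx, 1L), sw) - 1) * sh
    flat[lin, , drop = FALSE] * ok
  }
  v <- (1 - fy) * ((1 - fx) * px(y0, x0) + fx * px(y0, x0 + 1)) +
    fy * ((1 - fx) * px(y0 + 1, x0) + fx * px(y0 + 1, x0 + 1))
  array(v, c(dim(Y), 3L))
}

crop_image <- function(img, top, left, height, width) {
  img <- .as_image(img)
  if (top < 1 || left < 1 || top + height - 1 > dim(img)[1] ||
      left + width - 1 > dim(img)[2]) stop("crop window out of bounds")
  img[top:(top + height - 1), left:(left + width - 1), , drop = FALSE]
}

flip_horizontal <- function(img) .as_image(img)[, rev(seq_len(dim(img)[2])), , drop = FALSE]
flip_vertical   <- function(img) .as_image(img)[rev(seq_len(dim(img)[1])), , , drop = FALSE]

to_grayscale <- function(img) {
  img <- .as_image(img)
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  array(rep(g, 3L), c(dim(img)[1:2], 3L))
}

# brightness/contrast/saturation jitter; each factor multiplies towards or
# away from the relevant reference (zero, mean luminance, grayscale)
jitter_image <- function(img, brightness = 1, contrast = 1, saturation = 1) {
  img <- .as_image(img)
  img <- img * brightness
  mu <- mean(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  img <- (img - mu) * contrast + mu
  gray <- to_grayscale(.clamp01(img))
  .clamp01(gray + (img - gray) * saturation)
}

# rotate about the image centre by `degrees` (counter-clockwise), bilinear
# resampling, zero fill outside the original canvas
rotate_image <- function(img, degrees) {
  img <- .as_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  a <- degrees * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- outer(seq_len(h) - cy, rep(1, w))
  xx <- outer(rep(1, h), seq_len(w) - cx)
  # inverse rotation of target coordinates into the source frame
  Y <- cos(a) * yy - sin(a) * xx + cy
  X <- sin(a) * yy + cos(a) * xx + cx
  .bilinear_sample(img, Y, X)
}
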