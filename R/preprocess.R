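#' @importFrom stats quantile sd dnorm kmeans median integrate rnorm runif
#' @importFrom grDevices rgb2hsv convertColor
#' @importFrom utils read.csv write.csv
NULL

CHANNEL_NAMES <- c("R", "G", "B", "H", "S", "V", "L", "a", "b")
REGION_NAMES  <- c("nucleus", "cytoplasm", "background", "unstained")

#' Percentile contrast stretching
#'
#' Linearly rescales each channel of an 8-bit RGB image so that the lower
#' `sat_frac` quantile maps to 0 and the upper `1 - sat_frac` quantile maps to
#' 255, saturating (clipping) the tails. A channel whose two quantiles
#' coincide (e.g. a constant plane) is returned unchanged.
#'
#' @param img numeric array `H x W x 3` with values in `[0, 255]`.
#' @param sat_frac fraction of the intensity histogram saturated at each end
#'   (default 0.01, i.e. 1% low and 1% high).
#' @return 8-bit (rounded, clipped) array of the same shape.
#' @export
contrast_stretch <- function(img, sat_frac = 0.01) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L,
            sat_frac >= 0, sat_frac < 0.5)
  out <- img
  for (ch in 1:3) {
    plane <- img[, , ch]
    q <- stats::quantile(plane, c(sat_frac, 1 - sat_frac), names = FALSE)
    lo <- q[1]; hi <- q[2]
    if (hi <= lo) next  # degenerate channel: leave unchanged
    stretched <- 255 * (plane - lo) / (hi - lo)
    out[, , ch] <- pmin(pmax(round(stretched), 0), 255)
  }
  out
}

#' Expand an RGB image to the nine-channel color stack
#'
#' Builds the `H x W x 9` stack of color planes (R, G, B, H, S, V, L, a, b)
#' used by the color model and the level set. All planes are on a common
#' `[0, 255]` scale: R, G, B are passed through; hue maps the full hue circle
#' to `[0, 255]`; saturation and value map `[0, 1]` to `[0, 255]`; CIELAB L
#' maps `[0, 100]` and a, b map `[-128, 127]` to `[0, 255]` (clipped).
#'
#' @param img numeric array `H x W x 3`, 8-bit RGB.
#' @return numeric array `H x W x 9` with `dimnames[[3]]` naming the channels.
#' @export
to_channel_stack <- function(img) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  h <- dim(img)[1]; w <- dim(img)[2]
  rgb <- matrix(img, ncol = 3L)  # pixels x 3, column-major over (row, col)
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 255))
  lab <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  stack <- array(0, dim = c(h, w, 9L),
                 dimnames = list(NULL, NULL, CHANNEL_NAMES))
  stack[, , 1:3] <- img
  stack[, , 4] <- matrix(hsv[, 1] * 255, h, w)
  stack[, , 5] <- matrix(hsv[, 2] * 255, h, w)
  stack[, , 6] <- matrix(hsv[, 3] * 255, h, w)
  stack[, , 7] <- matrix(pmin(pmax(lab[, 1], 0), 100) * 2.55, h, w)
  stack[, , 8] <- matrix(pmin(pmax(lab[, 2], -128), 127) + 128, h, w)
  stack[, , 9] <- matrix(pmin(pmax(lab[, 3], -128), 127) + 128, h, w)
  stack
}

#' Remove unstained cells by hue thresholding
#'
#' Unstained cells (erythrocytes and other cells that do not take up the
#' stain) separate from stained plasma cells in the hue channel. Every pixel
#' whose hue (on the `[0, 255]` scale of [to_channel_stack()]) falls below
#' `hue_threshold` is replaced, in RGB, by the background color so that the
#' level set sees no extra region. Hue is compared with a plain `<`; the
#' circular wrap of hue is intentionally ignored.
#'
#' @param stack nine-channel stack of `img` (from [to_channel_stack()]).
#' @param img the RGB image the stack was computed from.
#' @param hue_threshold hue cutoff on the 8-bit scale (default 120).
#' @param bg_color length-3 RGB background color. Defaults to the background
#'   (Omega01) channel means of `model`; if neither is given, the median
#'   color of a `border_px`-wide image border is used.
#' @param model optional [fit_region_model()] result supplying `bg_color`.
#' @param border_px width of the border strip used by the fallback estimate.
#' @return RGB array with unstained-cell pixels painted over.
#' @export
remove_unstained <- function(stack, img, hue_threshold = 120,
                             bg_color = NULL, model = NULL, border_px = 10) {
  stopifnot(identical(dim(stack)[1:2], dim(img)[1:2]))
  if (is.null(bg_color)) {
    if (!is.null(model)) {
      bg_color <- model$mean["background", c("R", "G", "B")]
    } else {
      bg_color <- border_median_color(img, border_px)
    }
  }
  if (length(bg_color) != 3L || anyNA(bg_color))
    stop("background color is unconfigured: supply `bg_color` or `model`")
  mask <- stack[, , 4] < hue_threshold
  out <- img
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[mask] <- bg_color[ch]
    out[, , ch] <- plane
  }
  out
}

# Median color of a border strip; fallback background estimate when no
# fitted region model is available.
border_median_color <- function(img, border_px = 10) {
  h <- dim(img)[1]; w <- dim(img)[2]
  b <- min(border_px, floor(min(h, w) / 2))
  if (b < 1) stop("image too small for a border-based background estimate")
  sel <- matrix(FALSE, h, w)
  sel[c(seq_len(b), h - seq_len(b) + 1L), ] <- TRUE
  sel[, c(seq_len(b), w - seq_len(b) + 1L)] <- TRUE
  vapply(1:3, function(ch) stats::median(img[, , ch][sel]), numeric(1))
}
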