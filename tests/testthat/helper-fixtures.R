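# Shared fixtures, all built in code.

# Logical disk mask.
disk_mask <- function(h, w, cy, cx, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

# Uniform-color RGB image.
flat_rgb <- function(h, w, rgb) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# Paint a mask with a color.
paint <- function(img, mask, rgb) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- rgb[ch]
    img[, , ch] <- plane
  }
  img
}

# Hand-built region color model: `means`/`sds` are 4 x 9 matrices or single
# values recycled.
toy_model <- function(means, sds) {
  dn <- list(c("nucleus", "cytoplasm", "background", "unstained"),
             c("R", "G", "B", "H", "S", "V", "L", "a", "b"))
  structure(list(mean = matrix(means, 4, 9, dimnames = dn),
                 sd = matrix(sds, 4, 9, dimnames = dn)),
            class = "region_color_model")
}

# Weight matrix with a single nonzero channel per region (or a full matrix).
toy_weights <- function(channels = c(nucleus = "V", cytoplasm = "V",
                                     background = "V", unstained = "V"),
                        value = 1) {
  w <- matrix(0, 9, 4, dimnames = list(
    c("R", "G", "B", "H", "S", "V", "L", "a", "b"),
    c("nucleus", "cytoplasm", "background", "unstained")))
  for (r in names(channels)) w[channels[[r]], r] <- value
  w
}

# A stack whose 9 planes are all equal to the given matrix.
uniform_stack <- function(plane) {
  array(rep(plane, 9), c(dim(plane), 9),
        dimnames = list(NULL, NULL,
                        c("R", "G", "B", "H", "S", "V", "L", "a", "b")))
}

# Channel-weight table expected from the published reference distances
# (channel rows R,G,B,H,S,V,L,a,b; region columns).
reference_weight_matrix <- function() {
  w <- rbind(c(0,     0,    8.27,  0),
             c(0,     0,    15.89, 0),
             c(5.74,  1.17, 0,     0),
             c(1.76,  1.76, 0,     73.13),
             c(0,     0,    0,     0),
             c(14.48, 2.17, 0,     0),
             c(0,     0,    0,     0),
             c(0,     0,    0,     0),
             c(0,     0,    0,     6.70))
  dimnames(w) <- list(c("R", "G", "B", "H", "S", "V", "L", "a", "b"),
                      c("nucleus", "cytoplasm", "background", "unstained"))
  w
}

# Small scene spec for fast end-to-end tests.
small_scene_spec <- function(...) {
  default_scene_spec(size = 160, n_single = 4, clusters = c(2),
                     n_unstained = 2, ...)
}

# Fit a model from a scene's own ground truth (post contrast stretch, the
# coordinates the pipeline works in).
fit_scene_model <- function(scene) {
  stack <- to_channel_stack(contrast_stretch(scene$image))
  fit_region_model(stack, truth_region_masks(scene$truth$region_map))
}
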