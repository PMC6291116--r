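# Synthetic stained-smear scenes with ground truth. Colors are sampled in
# RGB and the remaining channels (H, S, V, L, a, b) emerge from the forward
# color-space conversion, keeping all nine planes mutually consistent.

#' Default synthetic scene specification
#'
#' The default constants are tuned so that a model fitted to a generated
#' scene reproduces the qualitative separability pattern of real
#' Jenner-Giemsa smears: nucleus and cytoplasm overlap in most channels but
#' separate (Bhattacharyya distance >= 1) in B, H and V; unstained cells are
#' widely separated from stained cells in hue (distance >= 3) and sit below
#' the hue-120 cutoff, while stained cells and background sit above it.
#'
#' @param size image side, pixels.
#' @param n_single number of isolated plasma cells.
#' @param clusters integer vector of cells-per-cluster (e.g. `c(2, 2, 2)`).
#' @param n_unstained number of unstained cells.
#' @param cell_radius,unstained_radius radius ranges `c(min, max)`, pixels.
#' @param overlap cluster overlap fraction in `[0, 0.6]`: neighboring cell
#'   centers in a cluster sit `(2 - 2 * overlap) * r` apart.
#' @param colors per-region RGB Gaussians: list with `mean` and `sd`, each a
#'   4 x 3 matrix (regions x RGB).
#' @param noise_sd additive Gaussian pixel noise (intensity levels).
#' @return list of class `scene_spec`.
#' @export
default_scene_spec <- function(size = 256,
                               n_single = 14,
                               clusters = c(2, 2, 2),
                               n_unstained = 6,
                               cell_radius = c(10, 14),
                               unstained_radius = c(9, 13),
                               overlap = 0.25,
                               colors = default_region_colors(),
                               noise_sd = 2) {
  stopifnot(n_single >= 0, n_unstained >= 0, all(clusters >= 2),
            overlap >= 0, overlap <= 0.6, all(cell_radius > 0))
  structure(list(size = size, n_single = n_single, clusters = clusters,
                 n_unstained = n_unstained, cell_radius = cell_radius,
                 unstained_radius = unstained_radius, overlap = overlap,
                 colors = colors, noise_sd = noise_sd),
            class = "scene_spec")
}

#' Default per-region RGB color Gaussians
#'
#' Nucleus: dark blue-violet; cytoplasm: lighter, bluer; background: pale
#' pink-gray; unstained cells: pale orange (erythrocyte-like, hue below the
#' 120 cutoff).
#'
#' @return list with 4 x 3 `mean` and `sd` matrices (regions x RGB).
#' @export
default_region_colors <- function() {
  mean <- rbind(nucleus    = c(125,  62, 150),
                cytoplasm  = c(118,  78, 195),
                background = c(225, 175, 240),
                unstained  = c(210, 145, 100))
  sd <- rbind(nucleus    = c(9, 9, 12),
              cytoplasm  = c(9, 9, 12),
              background = c(6, 6, 6),
              unstained  = c(8, 8, 8))
  colnames(mean) <- colnames(sd) <- c("R", "G", "B")
  list(mean = mean, sd = sd)
}

# One wobbly circle: pixel set of a disc whose radius is perturbed by <= 10%
# with a low-order angular harmonic.
.wobbly_disc <- function(h, w, cy, cx, r, amp, k, phase) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- rows - cy; dx <- cols - cx
  theta <- atan2(dy, dx)
  dy^2 + dx^2 <= (r * (1 + amp * sin(k * theta + phase)))^2
}

#' Generate a synthetic stained-smear scene
#'
#' Plasma cells are wobbly circles (radial perturbation <= 10%) with an
#' eccentric inner nucleus covering 55-75% of the cell radius; clusters place
#' cells `(2 - 2 * overlap) * r` apart. Placement is rejection-sampled so
#' that distinct objects (and clusters) do not touch. Ground truth (region
#' map, instance map, per-instance nucleus masks) is recorded before color
#' sampling.
#'
#' @param spec a `scene_spec` ([default_scene_spec()]).
#' @param seed integer RNG seed; the same seed reproduces the scene exactly.
#' @return list with `image` (`H x W x 3`, 8-bit RGB) and `truth`: list of
#'   `region_map` (1 nucleus, 2 cytoplasm, 3 background, 4 unstained),
#'   `instance_map`, `nucleus_map` (instance-labeled nuclei), and `manifest`
#'   (per-object placements; `cluster` is 0 for singles).
#' @export
generate_scene <- function(spec = default_scene_spec(), seed = 1) {
  set.seed(seed)
  h <- w <- spec$size
  region <- matrix(3L, h, w)       # background everywhere
  inst <- matrix(0L, h, w)
  nuc <- matrix(0L, h, w)
  placed <- data.frame(row = numeric(), col = numeric(), radius = numeric())
  manifest <- data.frame()
  max_retry <- 2000L

  place_center <- function(r, extra = 0) {
    margin <- r * 1.15 + extra
    for (i in seq_len(max_retry)) {
      cy <- stats::runif(1, margin, h - margin)
      cx <- stats::runif(1, margin, w - margin)
      if (nrow(placed) == 0 ||
          all(sqrt((placed$row - cy)^2 + (placed$col - cx)^2) >
              placed$radius + r + extra + 3))
        return(c(cy, cx))
    }
    stop("could not place all objects; use fewer or smaller cells")
  }

  draw_cell <- function(cy, cx, r, label, cluster_id) {
    amp <- stats::runif(1, 0.03, 0.1)
    k <- sample(3:5, 1)
    ph <- stats::runif(1, 0, 2 * pi)
    cell <- .wobbly_disc(h, w, cy, cx, r, amp, k, ph)
    rn <- r * stats::runif(1, 0.55, 0.75)
    off_max <- max(0, 0.88 * r - rn)
    off <- stats::runif(1, 0, off_max)
    ang <- stats::runif(1, 0, 2 * pi)
    nucleus <- .wobbly_disc(h, w, cy + off * sin(ang), cx + off * cos(ang),
                            rn, amp * 0.5, k, ph) & cell
    region[cell] <<- 2L
    region[nucleus] <<- 1L
    inst[cell] <<- label
    nuc[cell] <<- 0L     # a later cell in a cluster occludes its neighbor
    nuc[nucleus] <<- label
    manifest <<- rbind(manifest, data.frame(
      label = label, type = "plasma", cluster = cluster_id,
      row = cy, col = cx, radius = r, nucleus_radius = rn))
  }

  next_label <- 0L
  cluster_id <- 0L
  # clusters first (they need the most room)
  for (nc in spec$clusters) {
    cluster_id <- cluster_id + 1L
    r <- stats::runif(1, spec$cell_radius[1], spec$cell_radius[2])
    step <- (2 - 2 * spec$overlap) * r
    chain_len <- (nc - 1) * step
    ctr <- place_center(r + chain_len / 2, extra = 2)
    ang <- stats::runif(1, 0, 2 * pi)
    for (j in seq_len(nc)) {
      t <- (j - 1) - (nc - 1) / 2
      next_label <- next_label + 1L
      draw_cell(ctr[1] + t * step * sin(ang), ctr[2] + t * step * cos(ang),
                r, next_label, cluster_id)
    }
    placed <- rbind(placed, data.frame(row = ctr[1], col = ctr[2],
                                       radius = r + chain_len / 2))
  }
  for (i in seq_len(spec$n_single)) {
    r <- stats::runif(1, spec$cell_radius[1], spec$cell_radius[2])
    ctr <- place_center(r)
    next_label <- next_label + 1L
    draw_cell(ctr[1], ctr[2], r, next_label, 0L)
    placed <- rbind(placed, data.frame(row = ctr[1], col = ctr[2], radius = r))
  }
  for (i in seq_len(spec$n_unstained)) {
    r <- stats::runif(1, spec$unstained_radius[1], spec$unstained_radius[2])
    ctr <- place_center(r)
    cell <- .wobbly_disc(h, w, ctr[1], ctr[2], r,
                         stats::runif(1, 0.02, 0.08), sample(3:5, 1),
                         stats::runif(1, 0, 2 * pi))
    region[cell] <- 4L
    placed <- rbind(placed, data.frame(row = ctr[1], col = ctr[2], radius = r))
    manifest <- rbind(manifest, data.frame(
      label = 0L, type = "unstained", cluster = 0L,
      row = ctr[1], col = ctr[2], radius = r, nucleus_radius = NA))
  }

  img <- array(0, c(h, w, 3L))
  for (rg in 1:4) {
    sel <- region == rg
    n <- sum(sel)
    if (n == 0) next
    for (ch in 1:3) {
      v <- stats::rnorm(n, spec$colors$mean[rg, ch], spec$colors$sd[rg, ch]) +
        stats::rnorm(n, 0, spec$noise_sd)
      plane <- img[, , ch]
      plane[sel] <- v
      img[, , ch] <- plane
    }
  }
  img <- pmin(pmax(round(img), 0), 255)

  list(image = img,
       truth = list(region_map = region, instance_map = inst,
                    nucleus_map = nuc, manifest = manifest))
}

#' Region masks of a ground-truth region map
#'
#' @param region_map integer matrix from [generate_scene()].
#' @return named list of four logical masks suitable for
#'   [fit_region_model()].
#' @export
truth_region_masks <- function(region_map) {
  list(nucleus = region_map == 1L, cytoplasm = region_map == 2L,
       background = region_map == 3L, unstained = region_map == 4L)
}
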