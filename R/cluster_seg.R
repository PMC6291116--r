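# Cluster cell splitting. Touching plasma cells are separated by a
# marker-controlled watershed on distance transforms; a circular Hough
# transform acts as a circularity gate (plasma cells are approximately
# circular at 1000x), and a nucleus-to-cell area ratio rejects
# lymphocyte-like cells with scant cytoplasm.

#' Nuclei mask by k-means on the stained pixels
#'
#' Clusters the stained pixels in the (B, H, V) feature space -- the channels
#' in which the nucleus is separable from the cytoplasm -- and takes the
#' cluster with the lowest mean V (nuclei are dark) as the nuclei mask.
#' More liberal nucleus capture by the level set's nucleus phase can reject
#' true plasma cells downstream; re-clustering the stained pixels is the
#' preferred (Tool-1) nuclei source.
#'
#' @param stack nine-channel stack.
#' @param stained logical stained mask.
#' @param k number of clusters (default 2: nucleus vs cytoplasm).
#' @param seed RNG seed for the k-means initialization.
#' @return logical nuclei mask, a subset of `stained`.
#' @export
nuclei_mask_kmeans <- function(stack, stained, k = 2, seed = 1) {
  idx <- which(stained)
  if (length(idx) < k) {
    warning("fewer stained pixels than clusters; returning an empty mask")
    return(matrix(FALSE, nrow(stained), ncol(stained)))
  }
  feats <- cbind(B = stack[, , "B"][idx],
                 H = stack[, , "H"][idx],
                 V = stack[, , "V"][idx])
  set.seed(seed)
  km <- stats::kmeans(feats, centers = k, nstart = 10, iter.max = 50)
  dark <- which.min(tapply(feats[, "V"], km$cluster, mean))
  mask <- matrix(FALSE, nrow(stained), ncol(stained))
  mask[idx[km$cluster == dark]] <- TRUE
  mask
}

#' Nuclei mask from the level-set nucleus phase
#'
#' @param phase_mask result of [extract_phase_mask()].
#' @return logical mask of nucleus-phase pixels.
#' @export
nuclei_mask_levelset <- function(phase_mask) phase_mask == 1L

#' Circular Hough transform centers on a binary mask
#'
#' Accumulates votes from the mask's boundary pixels over circles with radii
#' in `[r_min, r_max]`. Scores are normalized by the circle circumference, so
#' a complete, isolated circular boundary scores near 1. Peaks above
#' `sensitivity` are returned greedily with non-maximum suppression: once a
#' peak is accepted, weaker peaks within its own detected radius (at least
#' `r_min`) are discarded -- two circle centers closer than a radius are the
#' same object.
#'
#' @param mask logical matrix.
#' @param r_min,r_max radius search range, pixels.
#' @param sensitivity minimum normalized accumulator score in `(0, 1)`.
#' @return data.frame (row, col, radius, score), best peaks first.
#' @export
cht_centers <- function(mask, r_min, r_max, sensitivity = 0.25) {
  stopifnot(r_min < r_max, r_min >= 1)
  empty <- data.frame(row = integer(), col = integer(),
                      radius = numeric(), score = numeric())
  if (!any(mask)) return(empty)
  h <- nrow(mask); w <- ncol(mask)
  # boundary = mask pixels with a 4-neighbor outside the mask (or the border)
  m <- matrix(as.numeric(mask), h, w)
  nb <- .shift_up(m) * .shift_down(m) * .shift_left(m) * .shift_right(m)
  edge <- which(mask & nb < 1)
  if (length(edge) == 0) return(empty)
  er <- (edge - 1L) %% h + 1L
  ec <- (edge - 1L) %/% h + 1L

  radii <- seq(max(1L, round(r_min)), round(r_max))
  best_score <- matrix(0, h, w)
  best_radius <- matrix(0, h, w)
  span <- max(radii)
  off <- expand.grid(dy = -span:span, dx = -span:span)
  dist <- round(sqrt(off$dy^2 + off$dx^2))
  for (r in radii) {
    ring <- off[dist == r, ]
    acc <- matrix(0L, h, w)
    for (i in seq_len(nrow(ring))) {
      rr <- er + ring$dy[i]
      cc <- ec + ring$dx[i]
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      ii <- rr[ok] + (cc[ok] - 1L) * h
      cnt <- tabulate(ii, nbins = h * w)
      acc <- acc + cnt
    }
    score <- acc / (2 * pi * r)
    better <- score > best_score
    best_score[better] <- score[better]
    best_radius[better] <- r
  }
  # greedy peak picking with non-max suppression
  peaks <- empty
  sc <- best_score
  repeat {
    mx <- max(sc)
    if (mx < sensitivity) break
    p <- which(sc == mx)[1]
    pr <- (p - 1L) %% h + 1L
    pc <- (p - 1L) %/% h + 1L
    peaks <- rbind(peaks, data.frame(row = pr, col = pc,
                                     radius = best_radius[p],
                                     score = mx))
    supp <- max(r_min, best_radius[p])
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    sc[(rows - pr)^2 + (cols - pc)^2 <= supp^2] <- 0
  }
  peaks[order(-peaks$score), , drop = FALSE]
}

#' Default CHT radius range from the stained components
#'
#' `r_min = lo * r_med`, `r_max = hi * r_med` where `r_med` is the median
#' equivalent-circle radius (`sqrt(area / pi)`) of the connected components.
#'
#' @param mask logical mask whose components set the scale.
#' @param lo,hi multipliers of the median equivalent radius.
#' @return `c(r_min, r_max)` in pixels.
#' @export
default_cht_range <- function(mask, lo = 0.25, hi = 1.5) {
  labs <- as.matrix(EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask))))
  if (max(labs) == 0) return(c(2, 10))
  areas <- tabulate(labs[labs > 0], nbins = max(labs))
  r_med <- stats::median(sqrt(areas / pi))
  c(max(1.5, lo * r_med), max(3, hi * r_med))
}

#' Split touching nuclei by watershed, keeping circular regions
#'
#' Watershed on the negated Euclidean distance transform of the nuclei mask
#' (markers at its regional minima, i.e. the distance-map maxima) separates
#' touching nuclei; regions that do not contain a circular-Hough center in
#' the given radius range are discarded as non-circular.
#'
#' The distance map is lightly Gaussian-smoothed (and re-masked) before the
#' watershed so that pixel-level boundary roughness does not seed spurious
#' basins.
#'
#' @param nuclei logical nuclei mask.
#' @param r_min,r_max CHT radius range (default from [default_cht_range()]).
#' @param sensitivity CHT peak threshold.
#' @param smooth_sigma Gaussian sigma (pixels) applied to the distance map
#'   before the watershed; 0 disables smoothing.
#' @param tolerance watershed basin-merging tolerance.
#' @return integer label matrix of retained nuclei.
#' @export
split_nuclei <- function(nuclei, r_min = NULL, r_max = NULL,
                         sensitivity = 0.25, smooth_sigma = 1.5,
                         tolerance = 2) {
  lab0 <- matrix(0L, nrow(nuclei), ncol(nuclei))
  if (!any(nuclei)) return(lab0)
  if (is.null(r_min) || is.null(r_max)) {
    rng <- default_cht_range(nuclei)
    if (is.null(r_min)) r_min <- rng[1]
    if (is.null(r_max)) r_max <- rng[2]
  }
  dm <- EBImage::distmap(matrix(as.numeric(nuclei), nrow(nuclei)))
  if (smooth_sigma > 0 && min(dim(dm)) > 8 * smooth_sigma) {
    dm <- as.matrix(EBImage::gblur(dm, sigma = smooth_sigma))
    dm[!nuclei] <- 0
  }
  labs <- as.matrix(EBImage::watershed(dm, tolerance = tolerance))
  peaks <- cht_centers(nuclei, r_min, r_max, sensitivity)
  keep_labels(labs, peaks)
}

# Retain labeled regions containing at least one CHT peak center; relabel
# consecutively. A peak sitting on a (zero-labeled) watershed line counts
# for the regions within 2 px of its center.
keep_labels <- function(labs, peaks) {
  if (nrow(peaks) == 0) return(matrix(0L, nrow(labs), ncol(labs)))
  h <- nrow(labs); w <- ncol(labs)
  hit <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    lab_here <- labs[peaks$row[i], peaks$col[i]]
    if (lab_here == 0) {
      rr <- max(1, peaks$row[i] - 2):min(h, peaks$row[i] + 2)
      cc <- max(1, peaks$col[i] - 2):min(w, peaks$col[i] + 2)
      lab_here <- setdiff(unique(as.vector(labs[rr, cc])), 0L)
    }
    hit <- union(hit, lab_here)
  }
  hit <- hit[hit > 0]
  out <- matrix(0L, nrow(labs), ncol(labs))
  for (i in seq_along(hit)) out[labs == hit[i]] <- i
  out
}

#' Split full cells from clusters with nucleus-seeded watershed
#'
#' Imposes markers at the centroids of the segmented nuclei (dilated to small
#' discs) on the negated distance transform of the stained mask and grows
#' them by marker-controlled watershed; retained regions must contain a CHT
#' center. Each nucleus is attached to the cell region containing its
#' centroid. With the default (large) `lambda` the growth metric is
#' dominated by in-plane distance, so touching cells of similar size split
#' along the perpendicular bisector of their markers -- the distance-ridge
#' neck for near-circular cells.
#'
#' @param stained logical stained mask.
#' @param nuclei_labels integer nuclei labels from [split_nuclei()].
#' @param r_min,r_max,sensitivity CHT parameters for the circularity gate on
#'   cells (defaults from the stained components).
#' @param marker_radius dilation radius of the centroid markers, pixels.
#' @param lambda trade-off between spatial distance and the distance-map
#'   gradient in the marker-growth metric (see [EBImage::propagate()]).
#' @param marker_merge markers closer than `marker_merge` times the median
#'   equivalent-circle radius of the nuclei are fused into one (fragments of
#'   a single nucleus must not split their cell); distinct nuclei in a
#'   cluster sit farther apart than this at any permitted overlap.
#' @return a `cell_instance_set`: list with `labels` (integer matrix),
#'   `nuclei` (integer matrix aligned to `labels`), and `instances`
#'   (data.frame: label, area, nucleus_area, ratio, centroid_row,
#'   centroid_col, circular).
#' @export
split_cells <- function(stained, nuclei_labels, r_min = NULL, r_max = NULL,
                        sensitivity = 0.25, marker_radius = 3,
                        lambda = 1e4, marker_merge = 1.5) {
  h <- nrow(stained); w <- ncol(stained)
  empty <- empty_instance_set(c(h, w))
  nl <- max(nuclei_labels)
  if (nl == 0 || !any(stained)) return(empty)
  if (is.null(r_min) || is.null(r_max)) {
    rng <- default_cht_range(stained)
    if (is.null(r_min)) r_min <- rng[1]
    if (is.null(r_max)) r_max <- rng[2]
  }
  # centroid markers, skipping nuclei outside the stained mask
  cents <- NULL
  for (i in seq_len(nl)) {
    px <- which(nuclei_labels == i)
    if (length(px) == 0) next
    cr <- round(mean((px - 1L) %% h + 1L))
    cc <- round(mean((px - 1L) %/% h + 1L))
    if (!stained[cr, cc]) {
      warning("nucleus ", i, " lies outside the stained mask; skipped")
      next
    }
    cents <- rbind(cents, c(cr, cc, length(px)))
  }
  if (is.null(cents)) return(empty)
  # fuse markers from fragments of the same nucleus (single linkage)
  r_eq <- sqrt(stats::median(cents[, 3]) / pi)
  grp <- seq_len(nrow(cents))
  if (nrow(cents) > 1) {
    d <- as.matrix(stats::dist(cents[, 1:2]))
    for (i in seq_len(nrow(cents) - 1)) for (j in (i + 1):nrow(cents)) {
      if (d[i, j] < marker_merge * r_eq) grp[grp == grp[j]] <- grp[i]
    }
  }
  seeds <- matrix(0L, h, w)
  for (k in seq_along(unique(grp))) {
    g <- unique(grp)[k]
    cr <- round(sum(cents[grp == g, 1] * cents[grp == g, 3]) /
                  sum(cents[grp == g, 3]))
    cc <- round(sum(cents[grp == g, 2] * cents[grp == g, 3]) /
                  sum(cents[grp == g, 3]))
    seeds[(matrix(seq_len(h), h, w) - cr)^2 +
            (matrix(seq_len(w), h, w, byrow = TRUE) - cc)^2 <=
            marker_radius^2 & stained] <- k
  }
  dm <- EBImage::distmap(matrix(as.numeric(stained), h))
  labs <- as.matrix(EBImage::propagate(-dm, seeds = seeds,
                                       mask = stained > 0, lambda = lambda))
  peaks <- cht_centers(stained, r_min, r_max, sensitivity)
  labs <- keep_labels(labs, peaks)
  build_instance_set(labs, nuclei_labels)
}

empty_instance_set <- function(shape) {
  structure(list(labels = matrix(0L, shape[1], shape[2]),
                 nuclei = matrix(0L, shape[1], shape[2]),
                 instances = data.frame(
                   label = integer(), area = integer(),
                   nucleus_area = integer(), ratio = numeric(),
                   centroid_row = numeric(), centroid_col = numeric(),
                   circular = logical())),
            class = "cell_instance_set")
}

# Assemble per-instance records; nuclei are clipped to their containing cell.
build_instance_set <- function(labs, nuclei_labels) {
  h <- nrow(labs); w <- ncol(labs)
  n <- max(labs)
  if (n == 0) return(empty_instance_set(c(h, w)))
  nuc_aligned <- matrix(0L, h, w)
  rows <- data.frame()
  for (i in seq_len(n)) {
    px <- which(labs == i)
    nuc_px <- px[nuclei_labels[px] > 0]
    nuc_aligned[nuc_px] <- i
    area <- length(px)
    rows <- rbind(rows, data.frame(
      label = i, area = area, nucleus_area = length(nuc_px),
      ratio = length(nuc_px) / area,
      centroid_row = mean((px - 1L) %% h + 1L),
      centroid_col = mean((px - 1L) %/% h + 1L),
      circular = TRUE))
  }
  structure(list(labels = labs, nuclei = nuc_aligned, instances = rows),
            class = "cell_instance_set")
}

#' Reject cells by nucleus-to-cell area ratio
#'
#' Lymphocyte-like stained cells have scant cytoplasm: their nucleus fills
#' most of the cell. Instances with `nucleus_area / area > ratio_max` are
#' removed.
#'
#' @param cells a `cell_instance_set`.
#' @param ratio_max maximum allowed ratio in `(0, 1]` (default 0.85).
#' @return filtered `cell_instance_set` with consecutive labels.
#' @export
filter_by_nucleus_ratio <- function(cells, ratio_max = 0.85) {
  stopifnot(ratio_max > 0, ratio_max <= 1)
  keep <- cells$instances$label[cells$instances$ratio <= ratio_max]
  subset_instances(cells, keep)
}

subset_instances <- function(cells, keep) {
  labs <- matrix(0L, nrow(cells$labels), ncol(cells$labels))
  nuc <- labs
  rows <- data.frame()
  for (i in seq_along(keep)) {
    labs[cells$labels == keep[i]] <- i
    nuc[cells$nuclei == keep[i]] <- i
    row <- cells$instances[cells$instances$label == keep[i], ]
    row$label <- i
    rows <- rbind(rows, row)
  }
  if (length(keep) == 0) return(empty_instance_set(dim(cells$labels)))
  structure(list(labels = labs, nuclei = nuc, instances = rows),
            class = "cell_instance_set")
}

#' @export
print.cell_instance_set <- function(x, ...) {
  cat("Cell instance set:", nrow(x$instances), "instance(s)\n")
  if (nrow(x$instances)) print(x$instances, row.names = FALSE)
  invisible(x)
}
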