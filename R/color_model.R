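# Region color model: per-region, per-channel Gaussians over the 9-plane
# stack; Bhattacharyya separability; threshold-based channel weighting;
# probability maps and mean-color distance images for the level-set energies.

PAIR_NAMES <- c("nucleus.cytoplasm", "nucleus.background", "nucleus.unstained",
                "cytoplasm.background", "cytoplasm.unstained",
                "background.unstained")

#' Fit the four-region Gaussian color model
#'
#' For each of the four regions of interest (plasma-cell nucleus, plasma-cell
#' cytoplasm, background, unstained cells) and each of the nine color
#' channels, fits a Gaussian by moments: the sample mean and sample standard
#' deviation of the stack values under the region mask.
#'
#' @param stack nine-channel stack from [to_channel_stack()].
#' @param region_masks named list of four logical masks
#'   (`nucleus`, `cytoplasm`, `background`, `unstained`), pairwise disjoint.
#' @return object of class `region_color_model`: list with `mean` and `sd`,
#'   each a 4 x 9 matrix (regions x channels).
#' @export
fit_region_model <- function(stack, region_masks) {
  stopifnot(all(REGION_NAMES %in% names(region_masks)))
  overlap <- Reduce(`+`, lapply(region_masks[REGION_NAMES], as.integer))
  if (any(overlap > 1L)) stop("region masks must be pairwise disjoint")
  mu <- sg <- matrix(NA_real_, 4, 9,
                     dimnames = list(REGION_NAMES, CHANNEL_NAMES))
  for (r in REGION_NAMES) {
    m <- region_masks[[r]]
    stopifnot(identical(dim(m), dim(stack)[1:2]))
    if (sum(m) < 2L)
      stop("region '", r, "' has fewer than 2 pixels; sd is undefined")
    for (ch in 1:9) {
      v <- stack[, , ch][m]
      mu[r, ch] <- mean(v)
      sg[r, ch] <- stats::sd(v)
    }
    if (any(sg[r, ] == 0))
      stop("region '", r, "' is constant in channel(s) ",
           paste(CHANNEL_NAMES[sg[r, ] == 0], collapse = ", "),
           "; a positive sd is required")
  }
  structure(list(mean = mu, sd = sg), class = "region_color_model")
}

#' Bhattacharyya distance between two univariate Gaussians
#'
#' Closed form of `-log integral sqrt(p q)` for Gaussian densities:
#' `D_B = (mu1 - mu2)^2 / (4 (s1^2 + s2^2)) + log((s1^2 + s2^2) / (2 s1 s2)) / 2`.
#' Zero iff the two Gaussians coincide.
#'
#' @param mu1,sigma1,mu2,sigma2 means and standard deviations (`sigma > 0`).
#' @return nonnegative distance (dimensionless). Vectorized.
#' @export
bhattacharyya_gaussian <- function(mu1, sigma1, mu2, sigma2) {
  if (any(sigma1 <= 0) || any(sigma2 <= 0))
    stop("standard deviations must be positive")
  s2 <- sigma1^2 + sigma2^2
  (mu1 - mu2)^2 / (4 * s2) + 0.5 * log(s2 / (2 * sigma1 * sigma2))
}

#' Bhattacharyya distance table for the six region pairs
#'
#' Evaluates [bhattacharyya_gaussian()] for every pair of distinct regions in
#' every channel of a fitted model.
#'
#' @param model a `region_color_model`.
#' @return 9 x 6 matrix (channels x region pairs), columns named
#'   `"<regionA>.<regionB>"`.
#' @export
distance_table <- function(model) {
  tab <- matrix(NA_real_, 9, 6, dimnames = list(CHANNEL_NAMES, PAIR_NAMES))
  for (pair in PAIR_NAMES) {
    rr <- strsplit(pair, ".", fixed = TRUE)[[1]]
    tab[, pair] <- bhattacharyya_gaussian(
      model$mean[rr[1], ], model$sd[rr[1], ],
      model$mean[rr[2], ], model$sd[rr[2], ])
  }
  tab
}

#' Published reference distance table
#'
#' The Bhattacharyya distance table measured on ground-truth-labeled regions
#' of Jenner-Giemsa-stained bone-marrow aspirate photomicrographs, as used to
#' derive the default channel weights. Six region pairs by nine channels.
#'
#' @param path CSV to read; defaults to the copy shipped with the package.
#' @return 9 x 6 matrix in the layout of [distance_table()].
#' @export
reference_distance_table <- function(path = system.file(
    "extdata", "reference_bhattacharyya_distances.csv",
    package = "plasmaseg")) {
  df <- utils::read.csv(path, check.names = FALSE)
  tab <- as.matrix(df[, PAIR_NAMES])
  rownames(tab) <- df$channel
  tab[CHANNEL_NAMES, ]
}

#' Assign channel weights from a distance table
#'
#' A channel contributes to a region's energy only if it discerns that region
#' from *both* of its competitors. For the nucleus the competitors are the
#' cytoplasm and the background (threshold `t_pc`); for the cytoplasm, the
#' nucleus and the background (`t_pc`); for the background and the unstained
#' cells, the nucleus and the cytoplasm (stricter threshold `t_bg`, since
#' plasma cells must be cleanly delineated from both). When both pair
#' distances clear the threshold (non-strict, `>=`) the weight is the larger
#' of the two distances; otherwise it is zero.
#'
#' @param table 9 x 6 distance table ([distance_table()] or
#'   [reference_distance_table()]).
#' @param t_pc threshold for the nucleus and cytoplasm rows (default 1).
#' @param t_bg threshold for the background and unstained rows (default 3).
#' @return 9 x 4 weight matrix (channels x regions), nonnegative.
#' @export
assign_weights <- function(table, t_pc = 1, t_bg = 3) {
  stopifnot(is.matrix(table), nrow(table) == 9L,
            all(PAIR_NAMES %in% colnames(table)))
  rule <- function(d1, d2, thr) ifelse(d1 >= thr & d2 >= thr, pmax(d1, d2), 0)
  w <- cbind(
    nucleus    = rule(table[, "nucleus.cytoplasm"],
                      table[, "nucleus.background"], t_pc),
    cytoplasm  = rule(table[, "nucleus.cytoplasm"],
                      table[, "cytoplasm.background"], t_pc),
    background = rule(table[, "nucleus.background"],
                      table[, "cytoplasm.background"], t_bg),
    unstained  = rule(table[, "nucleus.unstained"],
                      table[, "cytoplasm.unstained"], t_bg))
  rownames(w) <- rownames(table)
  w
}

# Shared weighted per-channel reduction over the stack. `fun(values, mu, sd)`
# returns the per-pixel contribution of one channel.
.weighted_channel_map <- function(stack, model, weights, region, fun) {
  wv <- weights[, region]
  if (sum(wv) <= 0)
    stop("region '", region, "' has an all-zero weight vector")
  acc <- matrix(0, dim(stack)[1], dim(stack)[2])
  for (ch in which(wv > 0)) {
    acc <- acc + wv[ch] *
      fun(stack[, , ch], model$mean[region, ch], model$sd[region, ch])
  }
  acc / sum(wv)
}

#' Per-region probability maps
#'
#' For each region, the weighted mixture of the per-channel Gaussian
#' densities evaluated at each pixel:
#' `p(U0(x) | region) = sum_c w_c N(U0_c(x); mu_c, sigma_c) / sum_c w_c`,
#' floored at `p_floor` so that the log-probability energy is finite.
#'
#' @param stack nine-channel stack.
#' @param model fitted `region_color_model`.
#' @param weights 9 x 4 weight matrix from [assign_weights()].
#' @param p_floor lower floor applied to the densities (default `1e-12`).
#' @return `H x W x 4` array, fourth-dimension names = regions.
#' @export
probability_maps <- function(stack, model, weights, p_floor = 1e-12) {
  maps <- array(NA_real_, c(dim(stack)[1:2], 4L),
                dimnames = list(NULL, NULL, REGION_NAMES))
  for (r in REGION_NAMES) {
    m <- .weighted_channel_map(stack, model, weights, r,
                               function(v, mu, sd) stats::dnorm(v, mu, sd))
    maps[, , r] <- pmax(m, p_floor)
  }
  maps
}

#' Per-region mean-color distance images
#'
#' For each region, the weighted mean over channels of the squared deviation
#' of a pixel from the region's mean color:
#' `U_d(x) = sum_c w_c (U0_c(x) - mu_c)^2 / sum_c w_c` (squared-intensity
#' units). Small for pixels whose color matches the region.
#'
#' @inheritParams probability_maps
#' @return `H x W x 4` array, fourth-dimension names = regions.
#' @export
distance_images <- function(stack, model, weights) {
  maps <- array(NA_real_, c(dim(stack)[1:2], 4L),
                dimnames = list(NULL, NULL, REGION_NAMES))
  for (r in REGION_NAMES) {
    maps[, , r] <- .weighted_channel_map(
      stack, model, weights, r, function(v, mu, sd) (v - mu)^2)
  }
  maps
}

#' @export
print.region_color_model <- function(x, ...) {
  cat("Four-region Gaussian color model (9 channels)\n\nMeans:\n")
  print(round(x$mean, 2))
  cat("\nStandard deviations:\n")
  print(round(x$sd, 2))
  invisible(x)
}

#' Serialize / restore a region color model as JSON
#'
#' @param model a `region_color_model`.
#' @param path file path.
#' @return `read_region_model` returns the restored model.
#' @export
write_region_model <- function(model, path) {
  jsonlite::write_json(list(mean = model$mean, sd = model$sd), path,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_region_model
#' @export
read_region_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dn <- list(REGION_NAMES, CHANNEL_NAMES)
  mk <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- dn
    m
  }
  structure(list(mean = mk(obj$mean), sd = mk(obj$sd)),
            class = "region_color_model")
}

#' Write a weight or distance table as CSV
#'
#' Channel-row, region-(or pair-)column layout.
#'
#' @param table matrix with channel rownames.
#' @param path file path.
#' @export
write_channel_table <- function(table, path) {
  df <- data.frame(channel = rownames(table), table, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
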