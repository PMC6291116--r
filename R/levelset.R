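# Four-phase (two-function) level set. The two fields phi1, phi2 encode the
# regions as sign combinations: nucleus (+,+), cytoplasm (+,-),
# background (-,+), unstained (-,-); the stained mask is {phi1 > 0}.
# The energy combines a negative-log-probability term and a mean-color
# distance term per phase, plus area and contour-length regularizers.

#' Level-set parameters
#'
#' @param eta1,eta2 relative weighting of the probability energy and the
#'   color-distance energy. The distance term is weighted more heavily
#'   (`eta2 = 3`) because on stain-normalized images the mean-color term
#'   captures cells crisply while the probability term absorbs residual
#'   subject-to-subject variation.
#' @param alpha1,alpha2 area regularizers (default 0: smears mix isolated
#'   cells and clusters, so constraining enclosed area hurts).
#' @param beta1,beta2 contour-length regularizers; the first field tracks the
#'   plasma-cell boundary and gets the tighter penalty (`beta1 = 2 > beta2 = 1`).
#' @param eps smoothing width (pixels) of the regularized Heaviside.
#' @param dt gradient-descent time step.
#' @param n_iter maximum number of iterations.
#' @param reinit_every iterations between signed-distance re-initializations.
#' @param tol relative energy-change stopping criterion over 10 iterations
#'   (set 0 to always run `n_iter` iterations); never triggers before two
#'   re-initialization cycles have completed.
#' @param max_step per-iteration cap on `|delta phi|` (pixels). The color
#'   energies span several orders of magnitude across an image; capping the
#'   step keeps the fields on the signed-distance scale so that the smoothed
#'   delta and the periodic re-initialization remain effective everywhere.
#' @return list of class `level_set_params`.
#' @export
level_set_params <- function(eta1 = 1, eta2 = 3, alpha1 = 0, alpha2 = 0,
                             beta1 = 2, beta2 = 1, eps = 1.5, dt = 0.5,
                             n_iter = 500, reinit_every = 20, tol = 1e-4,
                             max_step = 2) {
  stopifnot(eps > 0, dt > 0, beta1 >= 0, beta2 >= 0, n_iter >= 1,
            reinit_every >= 1, tol >= 0, max_step > 0)
  structure(list(eta1 = eta1, eta2 = eta2, alpha1 = alpha1, alpha2 = alpha2,
                 beta1 = beta1, beta2 = beta2, eps = eps, dt = dt,
                 n_iter = n_iter, reinit_every = reinit_every, tol = tol,
                 max_step = max_step),
            class = "level_set_params")
}

#' Smoothed Heaviside and its derivative
#'
#' `heaviside_eps(z) = (1 + (2/pi) atan(z/eps)) / 2` and
#' `delta_eps(z) = eps / (pi (eps^2 + z^2))`. The arctangent form has nonzero
#' support everywhere, which lets the evolution act on pixels far from the
#' current interface.
#'
#' @param z numeric (vectorized).
#' @param eps smoothing width in pixels.
#' @export
heaviside_eps <- function(z, eps = 1.5) {
  stopifnot(eps > 0)
  0.5 * (1 + (2 / pi) * atan(z / eps))
}

#' @rdname heaviside_eps
#' @export
delta_eps <- function(z, eps = 1.5) {
  stopifnot(eps > 0)
  (1 / pi) * eps / (eps^2 + z^2)
}

#' Initialize the two level-set fields as a grid of small circles
#'
#' Both fields are the signed distance to a regular lattice of circles
#' (positive inside); the second field's lattice is offset by half a spacing
#' to break the symmetry between the two functions. Seeding the whole image
#' with small contours speeds up convergence of the global evolution.
#'
#' @param shape `c(H, W)` in pixels.
#' @param radius circle radius, pixels.
#' @param spacing lattice pitch, pixels.
#' @return list of class `level_set_state` with fields `phi1`, `phi2`, `iter`.
#' @export
init_phis <- function(shape, radius = 8, spacing = 24) {
  h <- shape[1]; w <- shape[2]
  if (radius >= min(h, w) / 2)
    stop("initial circle radius must be below half the image size")
  circle_sdf <- function(offset) {
    cy <- seq(offset, h, by = spacing)
    cx <- seq(offset, w, by = spacing)
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    dmin <- matrix(Inf, h, w)
    for (y in cy) for (x in cx) {
      d <- sqrt((rows - y)^2 + (cols - x)^2)
      dmin <- pmin(dmin, d)
    }
    radius - dmin  # positive inside the nearest circle
  }
  structure(list(phi1 = circle_sdf(spacing / 2),
                 phi2 = circle_sdf(spacing),
                 iter = 0L),
            class = "level_set_state")
}

# Edge-replicated shifts for finite differences.
.shift_up    <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
.shift_down  <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
.shift_left  <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
.shift_right <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]

.grad_central <- function(m) {
  list(gy = (.shift_down(m) - .shift_up(m)) / 2,
       gx = (.shift_right(m) - .shift_left(m)) / 2)
}

# div(grad(phi) / |grad(phi)|) by central differences, |grad| floored.
.curvature <- function(phi, grad_floor = 1e-8) {
  g <- .grad_central(phi)
  mag <- pmax(sqrt(g$gx^2 + g$gy^2), grad_floor)
  nx <- g$gx / mag
  ny <- g$gy / mag
  (.shift_right(nx) - .shift_left(nx)) / 2 +
    (.shift_down(ny) - .shift_up(ny)) / 2
}

# -log probability maps, per region, as an H x W x 4 array.
.neg_log_maps <- function(pmaps) {
  arr <- -log(pmaps)
  dimnames(arr) <- dimnames(pmaps)
  arr
}

#' Total level-set energy with per-term breakdown
#'
#' `E = eta1 E_p + eta2 E_d + alpha1 A(phi1) + alpha2 A(phi2)
#'    + beta1 L(phi1) + beta2 L(phi2)` where `E_p` sums the per-phase
#' negative log-probabilities and `E_d` the per-phase color-distance images,
#' each weighted by the smoothed-Heaviside phase indicator products;
#' `A` is the smoothed area inside the contour and `L` the smoothed contour
#' length. Integrals are pixel sums.
#'
#' @param state a `level_set_state`.
#' @param pmaps probability maps ([probability_maps()]).
#' @param dimgs distance images ([distance_images()]).
#' @param params a `level_set_params`.
#' @return list with `total` and the named terms
#'   (`E_p`, `E_d`, `area1`, `area2`, `length1`, `length2`).
#' @export
energy_total <- function(state, pmaps, dimgs, params = level_set_params()) {
  stopifnot(identical(dim(state$phi1), dim(pmaps)[1:2]),
            identical(dim(pmaps), dim(dimgs)))
  eps <- params$eps
  H1 <- heaviside_eps(state$phi1, eps)
  H2 <- heaviside_eps(state$phi2, eps)
  ind <- list(nucleus = H1 * H2, cytoplasm = H1 * (1 - H2),
              background = (1 - H1) * H2, unstained = (1 - H1) * (1 - H2))
  FF <- .neg_log_maps(pmaps)
  E_p <- E_d <- 0
  for (r in REGION_NAMES) {
    E_p <- E_p + sum(FF[, , r] * ind[[r]])
    E_d <- E_d + sum(dimgs[, , r] * ind[[r]])
  }
  len_of <- function(Hm) {
    g <- .grad_central(Hm)
    sum(sqrt(g$gx^2 + g$gy^2))
  }
  terms <- c(E_p = E_p, E_d = E_d,
             area1 = sum(H1), area2 = sum(H2),
             length1 = len_of(H1), length2 = len_of(H2))
  total <- params$eta1 * terms["E_p"] + params$eta2 * terms["E_d"] +
    params$alpha1 * terms["area1"] + params$alpha2 * terms["area2"] +
    params$beta1 * terms["length1"] + params$beta2 * terms["length2"]
  list(total = unname(total), terms = terms)
}

#' Re-initialize a field to the signed Euclidean distance function
#'
#' Replaces `phi` by the exact Euclidean distance to the zero-crossing set,
#' keeping each pixel's sign. A field with a single sign (no interface) is
#' returned unchanged. The half-pixel offset places the implied interface
#' midway between the opposite-signed pixel pair, making the map idempotent.
#'
#' @param phi numeric matrix.
#' @return signed distance field with the same sign pattern.
#' @export
reinitialize_phi <- function(phi) {
  pos <- phi > 0
  if (all(pos) || !any(pos)) return(phi)
  d_in  <- as.matrix(EBImage::distmap(matrix(as.numeric(pos),  nrow(phi))))
  d_out <- as.matrix(EBImage::distmap(matrix(as.numeric(!pos), nrow(phi))))
  out <- ifelse(pos, d_in - 0.5, -(d_out - 0.5))
  out
}

#' Evolve the two level-set fields by gradient descent
#'
#' Explicit descent on the total energy. Per iteration, for the first field:
#' `phi1 <- phi1 + dt * delta_eps(phi1) * ( -eta1 ((F11-F01) H2 + (F10-F00)(1-H2))
#'  - eta2 ((G11-G01) H2 + (G10-G00)(1-H2)) - alpha1 + beta1 curv(phi1) )`
#' with `F = -log p` and `G` the distance images; the symmetric update (roles
#' of the two sign positions swapped, `alpha2`, `beta2`) drives `phi2`. Both
#' fields update simultaneously from the state at the start of the iteration.
#' Every `reinit_every` iterations both fields are re-initialized to signed
#' distance form. Evolution stops at `n_iter` or when the relative energy
#' change over 10 iterations falls below `tol`.
#'
#' @inheritParams energy_total
#' @return the evolved `level_set_state`; attribute `"energy_log"` holds a
#'   data.frame (iteration, total, E_p, E_d, reinit flag).
#' @export
evolve <- function(state, pmaps, dimgs, params = level_set_params()) {
  eps <- params$eps; dt <- params$dt
  FF <- .neg_log_maps(pmaps)
  F11 <- FF[, , "nucleus"];    G11 <- dimgs[, , "nucleus"]
  F10 <- FF[, , "cytoplasm"];  G10 <- dimgs[, , "cytoplasm"]
  F01 <- FF[, , "background"]; G01 <- dimgs[, , "background"]
  F00 <- FF[, , "unstained"];  G00 <- dimgs[, , "unstained"]
  phi1 <- state$phi1; phi2 <- state$phi2
  log_rows <- vector("list", params$n_iter)
  energies <- rep(NA_real_, params$n_iter)

  for (it in seq_len(params$n_iter)) {
    H2 <- heaviside_eps(phi2, eps)
    H1 <- heaviside_eps(phi1, eps)
    force1 <- -params$eta1 * ((F11 - F01) * H2 + (F10 - F00) * (1 - H2)) -
      params$eta2 * ((G11 - G01) * H2 + (G10 - G00) * (1 - H2)) -
      params$alpha1 + params$beta1 * .curvature(phi1)
    force2 <- -params$eta1 * ((F11 - F10) * H1 + (F01 - F00) * (1 - H1)) -
      params$eta2 * ((G11 - G10) * H1 + (G01 - G00) * (1 - H1)) -
      params$alpha2 + params$beta2 * .curvature(phi2)
    step1 <- dt * delta_eps(phi1, eps) * force1
    step2 <- dt * delta_eps(phi2, eps) * force2
    phi1 <- phi1 + sign(step1) * pmin(abs(step1), params$max_step)
    phi2 <- phi2 + sign(step2) * pmin(abs(step2), params$max_step)
    for (nm in c("phi1", "phi2")) {
      if (anyNA(get(nm)) || any(!is.finite(get(nm))))
        stop("non-finite values in ", nm, " at iteration ", it,
             "; check that probability maps are floored and params are sane")
    }
    did_reinit <- it %% params$reinit_every == 0L
    if (did_reinit) {
      phi1 <- reinitialize_phi(phi1)
      phi2 <- reinitialize_phi(phi2)
    }
    st <- structure(list(phi1 = phi1, phi2 = phi2, iter = state$iter + it),
                    class = "level_set_state")
    en <- energy_total(st, pmaps, dimgs, params)
    energies[it] <- en$total
    log_rows[[it]] <- data.frame(iteration = state$iter + it,
                                 total = en$total,
                                 E_p = unname(en$terms["E_p"]),
                                 E_d = unname(en$terms["E_d"]),
                                 reinit = did_reinit)
    if (params$tol > 0 && it > max(10, 2 * params$reinit_every)) {
      prev <- energies[it - 10]
      if (abs(energies[it] - prev) < params$tol * abs(prev)) break
    }
  }
  out <- structure(list(phi1 = phi1, phi2 = phi2,
                        iter = state$iter + it),
                   class = "level_set_state")
  attr(out, "energy_log") <- do.call(rbind, log_rows[seq_len(it)])
  out
}

#' Extract the four-phase label mask from the level-set state
#'
#' Labels by the sign pattern of the fields: nucleus (`phi1>0, phi2>0`),
#' cytoplasm (`phi1>0, phi2<=0`), background (`phi1<=0, phi2>0`), unstained
#' (`phi1<=0, phi2<=0`). The stained (plasma-cell) mask is `phi1 > 0`.
#'
#' @param state a `level_set_state`.
#' @return integer matrix with levels 1..4 and attribute `"labels"` giving
#'   the region names; every pixel carries exactly one label.
#' @export
extract_phase_mask <- function(state) {
  p1 <- state$phi1 > 0; p2 <- state$phi2 > 0
  lab <- matrix(4L, nrow(p1), ncol(p1))
  lab[p1 & p2]   <- 1L
  lab[p1 & !p2]  <- 2L
  lab[!p1 & p2]  <- 3L
  attr(lab, "labels") <- REGION_NAMES
  lab
}

#' Stained mask from a phase mask
#' @param phase_mask result of [extract_phase_mask()].
#' @return logical matrix, TRUE on nucleus or cytoplasm pixels.
#' @export
stained_mask <- function(phase_mask) phase_mask <= 2L

#' Post-level-set component filtering
#'
#' Drops connected components of the stained mask that are too small to be a
#' cell (noisy staining patches) and components whose cytoplasm area --
#' component pixels not covered by the nuclei mask -- is below a minimum
#' (lymphocyte-like cells with scant cytoplasm).
#'
#' @param stained logical stained mask.
#' @param nuclei logical nuclei mask (same shape).
#' @param min_component_px minimum component area, pixels.
#' @param min_cytoplasm_px minimum cytoplasm (component minus nuclei) area.
#' @return filtered logical mask.
#' @export
postfilter_components <- function(stained, nuclei,
                                  min_component_px = 200,
                                  min_cytoplasm_px = 0) {
  stopifnot(identical(dim(stained), dim(nuclei)))
  labs <- as.matrix(EBImage::bwlabel(matrix(as.numeric(stained),
                                            nrow(stained))))
  if (max(labs) == 0) return(stained)
  area <- tabulate(labs[labs > 0], nbins = max(labs))
  cyto <- tabulate(labs[labs > 0 & !nuclei], nbins = max(labs))
  keep <- which(area >= min_component_px & cyto >= min_cytoplasm_px)
  matrix(labs %in% keep, nrow(stained))
}
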