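test_that("circle-grid initialization produces signed distances to circles", {
  st <- init_phis(c(64, 64), radius = 6, spacing = 16)
  centers <- seq(8, 64, by = 16)
  expect_length(centers, 4)
  for (cy in centers) for (cx in centers)
    expect_equal(st$phi1[cy, cx], 6)
  area <- sum(st$phi1 > 0)
  expect_lt(abs(area - 16 * pi * 36) / (16 * pi * 36), 0.05)
  # determinism
  st2 <- init_phis(c(64, 64), radius = 6, spacing = 16)
  expect_identical(st$phi1, st2$phi1)
  expect_identical(st$phi2, st2$phi2)
  expect_error(init_phis(c(20, 20), radius = 10), "radius")
})

test_that("smoothed Heaviside and delta satisfy their identities", {
  expect_equal(heaviside_eps(0, 1.5), 0.5)
  z <- c(-7.3, -1, 0.2, 4)
  expect_equal(heaviside_eps(z, 2) + heaviside_eps(-z, 2), rep(1, 4))
  # finite-difference oracle for the derivative
  hstep <- 1e-6
  for (z0 in c(-3, 0, 2)) {
    num <- (heaviside_eps(z0 + hstep, 1.5) -
              heaviside_eps(z0 - hstep, 1.5)) / (2 * hstep)
    expect_equal(delta_eps(z0, 1.5), num, tolerance = 1e-6)
  }
})

test_that("energy vanishes when all couplings are off and for unit maps", {
  st <- init_phis(c(8, 8), radius = 2, spacing = 4)
  pm <- array(1, c(8, 8, 4),
              dimnames = list(NULL, NULL,
                              c("nucleus", "cytoplasm", "background", "unstained")))
  dm <- pm
  p0 <- level_set_params(eta1 = 0, eta2 = 0, alpha1 = 0, alpha2 = 0,
                         beta1 = 0, beta2 = 0)
  expect_equal(energy_total(st, pm, dm, p0)$total, 0)
  # probability maps identically 1 give a zero log-probability term
  en <- energy_total(st, pm, dm, level_set_params())
  expect_equal(unname(en$terms["E_p"]), 0)
})

test_that("energy matches a brute-force per-pixel oracle", {
  set.seed(21)
  h <- 4; w <- 4
  st <- structure(list(phi1 = matrix(rnorm(16), h),
                       phi2 = matrix(rnorm(16), h), iter = 0L),
                  class = "level_set_state")
  regions <- c("nucleus", "cytoplasm", "background", "unstained")
  pm <- array(runif(h * w * 4, 0.01, 1), c(h, w, 4),
              dimnames = list(NULL, NULL, regions))
  dm <- array(runif(h * w * 4, 0, 50), c(h, w, 4),
              dimnames = list(NULL, NULL, regions))
  pars <- level_set_params(eta1 = 1.3, eta2 = 0.7, alpha1 = 0.2,
                           alpha2 = 0.1, beta1 = 0, beta2 = 0, eps = 1.5)
  Hs <- function(z) 0.5 * (1 + (2 / pi) * atan(z / 1.5))
  ep <- ed <- a1 <- a2 <- 0
  for (i in 1:h) for (j in 1:w) {
    h1 <- Hs(st$phi1[i, j]); h2 <- Hs(st$phi2[i, j])
    ind <- c(h1 * h2, h1 * (1 - h2), (1 - h1) * h2, (1 - h1) * (1 - h2))
    ep <- ep + sum(-log(pm[i, j, ]) * ind)
    ed <- ed + sum(dm[i, j, ] * ind)
    a1 <- a1 + h1; a2 <- a2 + h2
  }
  expect_equal(energy_total(st, pm, dm, pars)$total,
               1.3 * ep + 0.7 * ed + 0.2 * a1 + 0.1 * a2, tolerance = 1e-10)
})

test_that("a phase that is optimal everywhere takes over the image", {
  h <- 48; w <- 48
  regions <- c("nucleus", "cytoplasm", "background", "unstained")
  pm <- array(1e-6, c(h, w, 4), dimnames = list(NULL, NULL, regions))
  pm[, , "nucleus"] <- 0.9
  dm <- array(100, c(h, w, 4), dimnames = list(NULL, NULL, regions))
  dm[, , "nucleus"] <- 0
  st <- init_phis(c(h, w), radius = 4, spacing = 12)
  out <- evolve(st, pm, dm, level_set_params(n_iter = 150, tol = 0))
  expect_gte(mean(out$phi1 > 0 & out$phi2 > 0), 0.99)
})

test_that("evolution is deterministic", {
  set.seed(33)
  h <- 24; w <- 24
  regions <- c("nucleus", "cytoplasm", "background", "unstained")
  pm <- array(runif(h * w * 4, 0.01, 1), c(h, w, 4),
              dimnames = list(NULL, NULL, regions))
  dm <- array(runif(h * w * 4, 0, 20), c(h, w, 4),
              dimnames = list(NULL, NULL, regions))
  st <- init_phis(c(h, w), radius = 3, spacing = 8)
  p <- level_set_params(n_iter = 40, tol = 0)
  o1 <- evolve(st, pm, dm, p)
  o2 <- evolve(st, pm, dm, p)
  expect_identical(o1$phi1, o2$phi1)
  expect_identical(o2$phi2, o2$phi2)
})

test_that("a dominant length penalty does not grow the interface", {
  set.seed(14)
  h <- 40; w <- 40
  regions <- c("nucleus", "cytoplasm", "background", "unstained")
  pm <- array(runif(h * w * 4, 0.01, 1), c(h, w, 4),
              dimnames = list(NULL, NULL, regions))
  dm <- array(runif(h * w * 4, 0, 1), c(h, w, 4),
              dimnames = list(NULL, NULL, regions))
  st <- init_phis(c(h, w), radius = 4, spacing = 10)
  pars <- level_set_params(beta1 = 1e4, beta2 = 1e4, n_iter = 60, tol = 0)
  iface_len <- function(phi) {
    en <- energy_total(structure(list(phi1 = phi, phi2 = phi, iter = 0L),
                                 class = "level_set_state"),
                       pm, dm, level_set_params())
    unname(en$terms["length1"])
  }
  out <- evolve(st, pm, dm, pars)
  expect_lte(iface_len(out$phi1), iface_len(st$phi1) + 1e-6)
})

test_that("reinitialization is a fixed point on a circle SDF", {
  h <- 64
  rows <- matrix(seq_len(h), h, h)
  cols <- t(rows)
  phi <- 15 - sqrt((rows - 32)^2 + (cols - 32)^2)
  out <- reinitialize_phi(phi)
  expect_lt(max(abs(out - phi)), 1)
})

test_that("reinitialization renormalizes a scaled SDF and preserves the zero set", {
  h <- 64
  rows <- matrix(seq_len(h), h, h)
  cols <- t(rows)
  phi <- 15 - sqrt((rows - 32)^2 + (cols - 32)^2)
  out <- reinitialize_phi(3 * phi)
  expect_identical(out > 0, phi > 0)
  expect_lt(max(abs(out - phi)), 1)
  # gradient magnitude near 1 away from the interface
  gx <- (out[, 3:h] - out[, 1:(h - 2)]) / 2
  gy <- (out[3:h, ] - out[1:(h - 2), ]) / 2
  mag <- sqrt(gx[2:(h - 1), ]^2 + gy[, 2:(h - 1)]^2)
  far <- abs(out[2:(h - 1), 2:(h - 1)]) > 2
  expect_gte(mean(mag[far] > 0.8 & mag[far] < 1.2), 0.95)
})

test_that("reinitialization is idempotent and ignores sign-pure fields", {
  h <- 32
  set.seed(6)
  phi <- matrix(rnorm(h * h), h)
  once <- reinitialize_phi(phi)
  expect_identical(reinitialize_phi(once), once)
  allpos <- matrix(5, h, h)
  expect_identical(reinitialize_phi(allpos), allpos)
})

test_that("phase extraction maps sign quadrants and partitions the image", {
  h <- 10
  quad <- function(v1, v2) {
    m <- matrix(v2, h, h)
    m[1:(h / 2), ] <- v1
    m
  }
  st <- structure(list(phi1 = quad(1, -1), phi2 = t(quad(1, -1)), iter = 0L),
                  class = "level_set_state")
  pm <- extract_phase_mask(st)
  expect_equal(pm[2, 2], 1L)  # +,+ nucleus
  expect_equal(pm[2, 9], 2L)  # +,- cytoplasm
  expect_equal(pm[9, 2], 3L)  # -,+ background
  expect_equal(pm[9, 9], 4L)  # -,- unstained
  expect_true(all(pm %in% 1:4))
  # constant-sign fields
  st2 <- structure(list(phi1 = matrix(1, 4, 4), phi2 = matrix(-1, 4, 4),
                        iter = 0L), class = "level_set_state")
  expect_true(all(extract_phase_mask(st2) == 2L))
  expect_true(all(stained_mask(extract_phase_mask(st2))))
})

test_that("component filtering enforces size and cytoplasm-area thresholds", {
  m <- matrix(FALSE, 40, 40)
  m[2:6, 2:3] <- TRUE  # 10 px component
  expect_true(!any(postfilter_components(m, m & FALSE,
                                         min_component_px = 50)))
  # 500 px component with 490 px nucleus -> cytoplasm 10 < 100 -> removed
  big <- matrix(FALSE, 40, 40)
  big[1:25, 1:20] <- TRUE
  nuc <- big
  nuc[16:25, 20] <- FALSE
  expect_equal(sum(big), 500)
  expect_equal(sum(big & !nuc), 10)
  out <- postfilter_components(big, nuc, min_component_px = 50,
                               min_cytoplasm_px = 100)
  expect_true(!any(out))
  # zero thresholds leave the mask unchanged
  expect_equal(postfilter_components(m, m & FALSE, 0, 0), m)
})

test_that("a model-matched two-color image is recovered with IoU >= 0.95", {
  set.seed(77)
  h <- 96
  cell <- disk_mask(h, h, 48, 48, 22)
  nucin <- disk_mask(h, h, 48, 44, 12)
  plane <- matrix(rnorm(h * h, 200, 8), h)      # background
  plane[cell] <- rnorm(sum(cell), 100, 8)       # cytoplasm
  plane[nucin] <- rnorm(sum(nucin), 60, 8)      # nucleus
  stack <- uniform_stack(plane)
  model <- toy_model(rep(c(60, 100, 200, 240), 9), 8)
  w <- toy_weights(value = 1)
  pm <- probability_maps(stack, model, w)
  dm <- distance_images(stack, model, w)
  st <- init_phis(c(h, h), radius = 5, spacing = 14)
  out <- evolve(st, pm, dm, level_set_params(n_iter = 200))
  stained <- out$phi1 > 0
  iou <- sum(stained & cell) / sum(stained | cell)
  expect_gte(iou, 0.95)
})
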