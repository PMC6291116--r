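test_that("Gaussian fit by moments recovers the generating parameters", {
  set.seed(42)
  h <- 200; w <- 1000  # nucleus mask holds 1e5 pixels
  stack <- array(rnorm(h * w * 9, 50, 5), c(h, w, 9))
  stack[1:100, , 1] <- rnorm(100 * w, 100, 15)
  masks <- list(nucleus = matrix(FALSE, h, w), cytoplasm = matrix(FALSE, h, w),
                background = matrix(FALSE, h, w), unstained = matrix(FALSE, h, w))
  masks$nucleus[1:100, ] <- TRUE
  masks$cytoplasm[101:150, 1:10] <- TRUE
  masks$background[151:180, 1:10] <- TRUE
  masks$unstained[181:200, 1:10] <- TRUE
  model <- fit_region_model(stack, masks)
  expect_lt(abs(model$mean["nucleus", 1] - 100), 0.5)
  expect_lt(abs(model$sd["nucleus", 1] - 15), 0.5)
})

test_that("fit rejects degenerate regions", {
  stack <- uniform_stack(matrix(7, 10, 10))
  masks <- list(nucleus = matrix(c(TRUE, TRUE, rep(FALSE, 98)), 10),
                cytoplasm = matrix(c(FALSE, FALSE, TRUE, TRUE, rep(FALSE, 96)), 10),
                background = matrix(c(rep(FALSE, 4), TRUE, TRUE, rep(FALSE, 94)), 10),
                unstained = matrix(c(rep(FALSE, 6), TRUE, TRUE, rep(FALSE, 92)), 10))
  expect_error(fit_region_model(stack, masks), "constant")
  masks$nucleus <- matrix(c(TRUE, rep(FALSE, 99)), 10)
  expect_error(fit_region_model(stack, masks), "fewer than 2")
})

test_that("fitting is deterministic over mask relabeling", {
  set.seed(9)
  stack <- array(rnorm(16 * 16 * 9, 100, 20), c(16, 16, 9))
  base <- list(nucleus = matrix(FALSE, 16, 16), cytoplasm = matrix(FALSE, 16, 16),
               background = matrix(FALSE, 16, 16), unstained = matrix(FALSE, 16, 16))
  m1 <- base; m1$nucleus[1:4, ] <- TRUE; m1$cytoplasm[5:8, ] <- TRUE
  m1$background[9:12, ] <- TRUE; m1$unstained[13:16, ] <- TRUE
  m2 <- list(nucleus = m1$cytoplasm, cytoplasm = m1$nucleus,
             background = m1$background, unstained = m1$unstained)
  f1 <- fit_region_model(stack, m1)
  f2 <- fit_region_model(stack, m2)
  expect_equal(f1$mean["nucleus", ], f2$mean["cytoplasm", ])
  expect_equal(f1$sd["nucleus", ], f2$sd["cytoplasm", ])
})

test_that("closed-form Bhattacharyya distance matches known values", {
  expect_equal(bhattacharyya_gaussian(3, 2, 3, 2), 0)
  expect_equal(bhattacharyya_gaussian(0, 1, 1, 1), 0.125)
  expect_equal(bhattacharyya_gaussian(0, 1, 0, 2), 0.5 * log(5 / 4))
  expect_error(bhattacharyya_gaussian(0, 0, 1, 1), "positive")
})

test_that("closed form agrees with quadrature of -ln integral sqrt(pq)", {
  quad_db <- function(m1, s1, m2, s2) {
    lo <- min(m1, m2) - 12 * max(s1, s2)
    hi <- max(m1, m2) + 12 * max(s1, s2)
    bc <- integrate(function(x) sqrt(dnorm(x, m1, s1) * dnorm(x, m2, s2)),
                    lo, hi, rel.tol = 1e-12, subdivisions = 2000L)$value
    -log(bc)
  }
  set.seed(123)
  for (i in 1:25) {
    s1 <- runif(1, 0.5, 30); s2 <- runif(1, 0.5, 30)
    m1 <- runif(1, -50, 50)
    m2 <- m1 + runif(1, -5, 5) * max(s1, s2)
    expect_equal(bhattacharyya_gaussian(m1, s1, m2, s2),
                 quad_db(m1, s1, m2, s2), tolerance = 1e-6)
  }
})

test_that("Bhattacharyya distance is symmetric, nonnegative, zero iff equal", {
  set.seed(4)
  for (i in 1:20) {
    p <- runif(4, c(-10, 0.1, -10, 0.1), c(10, 5, 10, 5))
    d1 <- bhattacharyya_gaussian(p[1], p[2], p[3], p[4])
    d2 <- bhattacharyya_gaussian(p[3], p[4], p[1], p[2])
    expect_equal(d1, d2)
    expect_gte(d1, 0)
  }
  expect_identical(bhattacharyya_gaussian(1, 2, 1, 2), 0)
})

test_that("weight rules reproduce the full published weight table", {
  tab <- reference_distance_table()
  w <- assign_weights(tab)
  expect_equal(w, reference_weight_matrix())
  # spot values
  expect_equal(w["V", "nucleus"], 14.48)
  expect_equal(w["H", "unstained"], 73.13)
  expect_equal(w["G", "background"], 15.89)
  # the cytoplasm-B cell relies on the non-strict comparison at exactly 1.00
  expect_equal(w["B", "cytoplasm"], 1.17)
})

test_that("an all-zero distance table yields all-zero weights", {
  tab <- reference_distance_table()
  tab[] <- 0
  expect_true(all(assign_weights(tab) == 0))
})

test_that("probability maps collapse to a single channel density", {
  plane <- matrix(c(90, 100, 110, 120), 2, 2)
  stack <- uniform_stack(plane)
  model <- toy_model(100, 10)
  w <- toy_weights(c(nucleus = "V", cytoplasm = "B",
                     background = "R", unstained = "H"))
  pm <- probability_maps(stack, model, w)
  expect_equal(pm[, , "nucleus"], dnorm(plane, 100, 10))
})

test_that("equal-weight two-channel mixture at the mean gives the peak density", {
  stack <- uniform_stack(matrix(0, 2, 2))
  model <- toy_model(0, 10)
  w <- toy_weights()
  w["B", ] <- 1  # V and B both weighted 1 for every region
  pm <- probability_maps(stack, model, w)
  expect_equal(unname(pm[1, 1, "nucleus"]), 1 / (10 * sqrt(2 * pi)),
               tolerance = 1e-12)
})

test_that("probability maps respect the convex-combination bound and floor", {
  set.seed(8)
  stack <- uniform_stack(matrix(runif(64, 0, 255), 8, 8))
  model <- toy_model(rep(c(50, 100, 150, 200), 9), 8)
  w <- matrix(runif(36), 9, 4,
              dimnames = dimnames(toy_weights()))
  pm <- probability_maps(stack, model, w)
  expect_true(all(pm > 0))
  expect_true(all(pm <= dnorm(0, 0, 8) + 1e-15))
})

test_that("all-zero region weights are rejected by name", {
  stack <- uniform_stack(matrix(1, 2, 2))
  model <- toy_model(0, 1)
  w <- toy_weights()
  w[, "cytoplasm"] <- 0
  expect_error(probability_maps(stack, model, w), "cytoplasm")
  expect_error(distance_images(stack, model, w), "cytoplasm")
})

test_that("distance images implement the weighted squared residual", {
  # two channels, weights (1, 3), residuals (2, -2) -> (4 + 3*4)/4 = 4
  stack <- uniform_stack(matrix(0, 2, 2))
  stack[, , "V"] <- 2
  stack[, , "B"] <- -2
  model <- toy_model(0, 1)
  w <- toy_weights(value = 1)   # V = 1
  w["B", ] <- 3
  di <- distance_images(stack, model, w)
  expect_equal(di[, , "nucleus"], matrix(4, 2, 2))
  # zero residual at the mean in every weighted channel
  stack0 <- uniform_stack(matrix(0, 2, 2))
  expect_equal(distance_images(stack0, model, w)[, , "nucleus"],
               matrix(0, 2, 2))
})

test_that("maps are invariant to uniform weight rescaling", {
  set.seed(2)
  stack <- uniform_stack(matrix(runif(36, 0, 255), 6, 6))
  model <- toy_model(rep(c(60, 120, 180, 240), 9), 12)
  w <- matrix(runif(36, 0.1, 2), 9, 4, dimnames = dimnames(toy_weights()))
  expect_equal(probability_maps(stack, model, w),
               probability_maps(stack, model, 2 * w))
  expect_equal(distance_images(stack, model, w),
               distance_images(stack, model, 7 * w))
})

test_that("distance table from a fitted model is symmetric in pair order", {
  model <- toy_model(rep(c(60, 120, 180, 240), 9), rep(c(5, 10, 15, 20), 9))
  tab <- distance_table(model)
  direct <- bhattacharyya_gaussian(model$mean["cytoplasm", "H"],
                                   model$sd["cytoplasm", "H"],
                                   model$mean["unstained", "H"],
                                   model$sd["unstained", "H"])
  expect_equal(unname(tab["H", "cytoplasm.unstained"]), direct)
  expect_true(all(tab >= 0))
})

test_that("model JSON and table CSV round-trip exactly", {
  model <- toy_model(rep(c(60.5, 120.25, 180, 240), 9),
                     rep(c(5.5, 10, 15, 20), 9))
  jf <- withr::local_tempfile(fileext = ".json")
  write_region_model(model, jf)
  back <- read_region_model(jf)
  expect_equal(back$mean, model$mean)
  expect_equal(back$sd, model$sd)
  cf <- withr::local_tempfile(fileext = ".csv")
  write_channel_table(reference_distance_table(), cf)
  expect_equal(reference_distance_table(cf), reference_distance_table())
})
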