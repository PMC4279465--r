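test_that("initialization seeds one component at the observed gray", {
  m <- init_model(matrix(100, 1, 1), gmm_params())
  px <- pixel_at(m, 1, 1)
  expect_equal(px$w, c(1, 0, 0))
  expect_equal(px$u[1], 100)
  expect_equal(px$v[1], 225)  # initial spread read as sigma = 15
  expect_equal(px$active, c(TRUE, FALSE, FALSE))
  # sigma^2 reading via the sensitivity switch
  m2 <- init_model(matrix(100, 1, 1), gmm_params(variance_is_sigma2 = TRUE))
  expect_equal(pixel_at(m2, 1, 1)$v[1], 15)
  # determinism and the perfect-match fixed point
  expect_identical(init_model(matrix(7, 2, 2)), init_model(matrix(7, 2, 2)))
  s <- process_frame(init_model(matrix(100, 2, 2)), matrix(100, 2, 2))
  expect_false(any(s$mask))
  expect_error(init_model(matrix(numeric(0), 0, 0)), "empty")
})

test_that("the match criterion is strict |x - u| < phi sigma", {
  mx <- function(sigma) pixel_mixture(1, 90, sigma^2)
  expect_equal(match_component(100, mx(5), phi = 2.5), 1L)      # 10 < 12.5
  expect_true(is.na(match_component(100, mx(3), phi = 2.5)))    # 10 >= 7.5
  expect_true(is.na(match_component(100, mx(4), phi = 2.5)))    # boundary 10 = 10
})

test_that("components rank by w/sigma with stable ties and empty slots last", {
  mx <- pixel_mixture(c(0.6, 0.3, 0.1), c(0, 0, 0), c(16, 100, 4))
  expect_equal(rank_components(mx), c(1L, 3L, 2L))   # keys 0.15, 0.03, 0.05
  tie <- pixel_mixture(c(0.5, 0.25, 0.25), c(0, 0, 0), c(4, 1, 1))
  expect_equal(rank_components(tie), c(1L, 2L, 3L))  # equal keys keep order
  single <- pixel_mixture(1, 10, 9)
  expect_equal(rank_components(single), 1L)
  empty <- pixel_mixture(c(0.1, 1, 0), c(0, 0, 0), c(100, 1, 1),
                         active = c(TRUE, TRUE, FALSE))
  expect_equal(rank_components(empty), c(2L, 1L, 3L))
})

test_that("background count is the smallest prefix strictly exceeding T_R", {
  expect_equal(background_count(c(0.2, 0.5, 0.3), 0.25), 2L)
  expect_equal(background_count(c(0.9, 0.05, 0.05), 0.25), 1L)
  expect_equal(background_count(c(0.5, 0.3, 0.2), 1 - 1e-12), 3L)
})

test_that("background count stays within [1, K] over random simplex draws", {
  set.seed(42)
  for (i in 1:200) {
    K <- sample(1:5, 1)
    w <- stats::rexp(K); w <- w / sum(w)
    B <- background_count(w, stats::runif(1, 0.01, 0.99))
    expect_true(B >= 1 && B <= K)
  }
})

test_that("matched updates keep fixed points and replace lowest weight on mismatch", {
  p <- gmm_params()
  mx <- pixel_mixture(c(1, 0, 0), c(100, 0, 0), c(225, 225, 225),
                      active = c(TRUE, FALSE, FALSE))
  up <- update_pixel(100, mx, p)
  expect_true(up$matched)
  expect_equal(up$mixture$u[1], 100)
  expect_equal(up$mixture$w[1], 1)
  mx2 <- pixel_mixture(c(0.7, 0.2, 0.1), c(100, 140, 180), c(4, 4, 4))
  up2 <- update_pixel(50, mx2, p)   # matches nothing
  expect_false(up2$matched)
  expect_true(any(up2$mixture$u == 50))
  # the weight-0.1 component (mean 180) was the one replaced
  expect_false(180 %in% up2$mixture$u)
  expect_equal(sum(up2$mixture$w), 1, tolerance = 1e-12)
})

test_that("a constant input contracts the matched mean monotonically", {
  p <- gmm_params()
  mx <- pixel_mixture(c(1, 0, 0), c(60, 0, 0), c(900, 225, 225),
                      active = c(TRUE, FALSE, FALSE))
  gap <- abs(60 - 90)
  for (i in 1:100) {
    mx <- update_pixel(90, mx, p)$mixture
    new_gap <- min(abs(mx$u[mx$active] - 90))
    expect_lte(new_gap, gap)
    gap <- new_gap
  }
  expect_lt(gap, 1)
})

test_that("weights stay normalized and variances floored through random updates", {
  p <- gmm_params()
  set.seed(7)
  mx <- pixel_mixture(c(1, 0, 0), c(128, 0, 0), c(225, 225, 225),
                      active = c(TRUE, FALSE, FALSE))
  for (i in 1:200) {
    x <- sample(0:255, 1)
    mx <- update_pixel(x, mx, p)$mixture
    expect_equal(sum(mx$w), 1, tolerance = 1e-9)
    expect_true(all(mx$v[mx$active] >= p$variance_floor))
  }
})

test_that("the frame engine equals the straight-line one-pixel transcription bit for bit", {
  p <- gmm_params()
  set.seed(11)
  xs <- round(c(100, 100 + rnorm(9, 0, 3), 200, 200 + rnorm(4, 0, 3),
                100 + rnorm(5, 0, 3)))
  oracle <- oracle_gmm_1px(xs, p)
  model <- init_model(matrix(xs[1], 1, 1), p)
  fg <- logical(length(xs))
  for (t in seq_along(xs)[-1]) {
    s <- process_frame(model, matrix(xs[t], 1, 1))
    model <- s$model
    fg[t] <- s$mask[1, 1]
    snap <- oracle$snapshots[[t]]
    expect_identical(as.numeric(model$w[1, 1, ]), snap$w)
    expect_identical(as.numeric(model$u[1, 1, ]), snap$u)
    expect_identical(as.numeric(model$v[1, 1, ]), snap$v)
    expect_identical(as.logical(model$active[1, 1, ]), snap$active)
  }
  expect_identical(fg, oracle$fg)
})

test_that("a step change in background gray is absorbed within a bounded time", {
  p <- gmm_params()
  xs <- c(rep(100, 60), rep(200, 40))
  oracle <- oracle_gmm_1px(xs, p)
  absorbed <- which(seq_along(xs) > 60 & !oracle$fg)
  expect_true(length(absorbed) > 0)
  measured <- absorbed[1] - 60
  expect_lte(measured, 30)
  # the engine absorbs at exactly the same frame
  model <- init_model(matrix(xs[1], 1, 1), p)
  fg <- logical(length(xs))
  for (t in seq_along(xs)[-1]) {
    s <- process_frame(model, matrix(xs[t], 1, 1))
    model <- s$model; fg[t] <- s$mask[1, 1]
  }
  expect_identical(fg, oracle$fg)
})

test_that("an injected dark particle is flagged foreground at low false-positive cost", {
  p <- particle_spec("rubber", base_area = 25)
  cfg <- scene_config(48, 48, 30, flicker_sigma = 2, pixel_noise_sigma = 2,
                      particles = list(p), seed = 5)
  sq <- generate_sequence(cfg)
  bg <- subtract_background(sq$frames)
  tp <- fp <- pos <- neg <- 0
  for (t in 11:30) {
    g <- sq$truth$masks[, , t]; m <- bg$masks[, , t]
    tp <- tp + sum(m & g); pos <- pos + sum(g)
    fp <- fp + sum(m & !g); neg <- neg + sum(!g)
  }
  expect_gte(tp / pos, 0.9)
  expect_lt(fp / neg, 0.01)
})

test_that("a static flickering scene stays background after warm-up", {
  cfg <- scene_config(48, 48, 30, flicker_sigma = 2, pixel_noise_sigma = 2,
                      seed = 6)
  sq <- generate_sequence(cfg)
  bg <- subtract_background(sq$frames)
  fp <- mean(bg$masks[, , 11:30])
  expect_lt(fp, 0.01)
})

test_that("frame dimension mismatches are rejected", {
  m <- init_model(matrix(100, 4, 4))
  expect_error(process_frame(m, matrix(100, 5, 4)), "dimensions")
})
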