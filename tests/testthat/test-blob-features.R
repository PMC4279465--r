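test_that("connected components are labeled in raster order with min_area filtering", {
  mask <- matrix(FALSE, 10, 10)
  mask[2:4, 2:4] <- TRUE
  mask[7:9, 6:8] <- TRUE
  blobs <- label_components(mask)
  expect_length(blobs, 2)
  expect_equal(vapply(blobs, `[[`, numeric(1), "area"), c(9, 9))
  # raster order: the blob whose first pixel comes first gets id 1
  expect_equal(blobs[[1]]$bbox[["rmin"]], 1)  # 0-based row of the upper blob
  expect_length(label_components(matrix(FALSE, 5, 5)), 0)
  big <- label_components(mask, min_area = 10)
  expect_length(big, 0)
})

test_that("diagonal pixels split under 4-connectivity and join under 8", {
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1] <- TRUE; mask[2, 2] <- TRUE
  expect_length(label_components(mask, connectivity = 4, min_area = 1), 2)
  expect_length(label_components(mask, connectivity = 8, min_area = 1), 1)
})

test_that("blob histograms are normalized with N = blob area", {
  b <- structure(list(gray = rep(10, 4)), class = "blob")
  p <- gray_histogram(b)
  expect_equal(p[11], 1)
  expect_equal(sum(p), 1)
  p2 <- gray_histogram(c(0, 0, 255, 255))
  expect_equal(p2[c(1, 256)], c(0.5, 0.5))
  expect_equal(sum(p2), 1, tolerance = 1e-12)
  expect_error(gray_histogram(numeric(0)), "empty")
})

test_that("gray statistics follow their defining formulas", {
  const <- gray_statistics(gray_histogram(rep(42, 9)))
  expect_equal(unname(const[c("var", "smooth", "m3", "entropy")]), rep(0, 4))
  expect_equal(unname(const["unif"]), 1)
  two <- gray_statistics(gray_histogram(c(0, 0, 255, 255)))
  expect_equal(unname(two["mean"]), 127.5)
  expect_equal(unname(two["var"]), 16256.25)
  expect_equal(unname(two["m3"]), 0)
  expect_equal(unname(two["unif"]), 0.5)
  expect_equal(unname(two["entropy"]), 1)
  expect_error(gray_statistics(c(0.5, 0.4)), "normalized")
})

test_that("gray statistics match a brute-force re-summation oracle", {
  set.seed(13)
  for (i in 1:10) {
    g <- sample(0:255, 8, replace = TRUE)
    got <- gray_statistics(gray_histogram(g))
    expect_equal(unname(got), unname(oracle_gray_stats(g)), tolerance = 1e-9)
  }
})

test_that("geometry reports pixel area and inclusive-extent side ratio", {
  sq <- label_components(`[<-`(matrix(FALSE, 8, 8), 2:4, 2:4, TRUE))[[1]]
  g <- geometry(sq)
  expect_equal(unname(g), c(9, 1))
  # 1 x 5 horizontal run: W (x extent) = 5, L (y extent) = 1
  run <- label_components(`[<-`(matrix(FALSE, 8, 8), 3, 2:6, TRUE))[[1]]
  expect_equal(unname(geometry(run)), c(5, 5))
  expect_equal(unname(geometry(run, invert = TRUE))[2], 1 / 5)
  # a rasterized disk has ratio exactly 1
  mask <- matrix(FALSE, 21, 21)
  mask[shape_disk(6) + 1] <- TRUE
  disk <- label_components(mask)[[1]]
  expect_equal(unname(geometry(disk))[2], 1)
})

test_that("Hu invariants of the 4-pixel L-blob match the term-by-term oracle", {
  coords <- cbind(c(0, 1, 2, 2), c(0, 0, 0, 1))
  got <- hu_moments(coords)
  expect_equal(unname(got), oracle_hu(coords), tolerance = 1e-14)
  frozen <- c(0.21875, 0.0244140625, 0.0054931640625, 0.0006103515625,
              3.12924385070801e-07, 2.6702880859375e-05,
              -1.07288360595703e-06)
  expect_equal(unname(got), frozen, tolerance = 1e-12)
})

test_that("Hu invariants match the oracle on random small blobs", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:25, 1)
    coords <- unique(cbind(sample(0:4, n, TRUE), sample(0:4, n, TRUE)))
    expect_equal(unname(hu_moments(coords)), oracle_hu(coords),
                 tolerance = 1e-12)
  }
})

test_that("Hu invariants are invariant to translation, rotation and scaling", {
  set.seed(31)
  for (i in 1:20) {
    shape <- if (i %% 2 == 0) shape_disk(sample(4:8, 1))
             else shape_ellipse(stats::runif(1, 4, 8), stats::runif(1, 3, 6),
                                stats::runif(1, 0, pi))
    h <- hu_moments(shape)
    shifted <- sweep(shape, 2, c(sample(1:30, 1), sample(1:30, 1)), `+`)
    expect_lt(max(abs(hu_moments(shifted) - h)), 1e-10)
    rot <- cbind(shape[, 2], max(shape[, 1]) - shape[, 1])  # 90 degrees
    expect_lt(max(abs(hu_moments(rot) - h)), 1e-6)
    scaled <- rbind(cbind(2 * shape[, 1],     2 * shape[, 2]),
                    cbind(2 * shape[, 1] + 1, 2 * shape[, 2]),
                    cbind(2 * shape[, 1],     2 * shape[, 2] + 1),
                    cbind(2 * shape[, 1] + 1, 2 * shape[, 2] + 1))
    expect_lt(max(abs(hu_moments(scaled) - h)), 1e-2)
  }
})

test_that("the full descriptor is pure and ordered canonically", {
  frame <- matrix(200, 12, 12)
  frame[4:6, 4:6] <- 30
  mask <- frame == 30
  b <- label_components(mask, frame = frame)[[1]]
  fv <- extract_features(b)
  expect_identical(names(fv), feature_names())
  expect_equal(unname(fv["f01_mean"]), 30)
  expect_equal(unname(fv[c("f02_var", "f03_smooth", "f04_m3", "f06_entropy")]),
               rep(0, 4))
  expect_equal(unname(fv["f05_unif"]), 1)
  expect_equal(unname(fv["f07_area"]), 9)
  expect_equal(unname(fv["f08_wl_ratio"]), 1)
  expect_identical(extract_features(b), fv)
})

test_that("feature order round-trips through the CSV writer", {
  d <- generate_feature_dataset(3, seed = 8)
  d$frame <- 1L; d$blob_id <- seq_len(nrow(d))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(d, path)
  back <- read_feature_csv(path)
  expect_equal(back[feature_names()], d[feature_names()], tolerance = 1e-12)
  expect_identical(as.character(back$label), as.character(d$label))
})

test_that("synthetic bubbles are round and hairs elongated in feature space", {
  mkblob <- function(klass, seed) {
    cfg <- scene_config(48, 48, 8, particles = list(particle_spec(klass)),
                        seed = seed)
    sq <- generate_sequence(cfg)
    b <- label_components(sq$truth$masks[, , 4], frame = sq$frames[, , 4])
    extract_features(b[[which.max(vapply(b, `[[`, numeric(1), "area"))]])
  }
  bubble <- mkblob("bubble", 61)
  hair <- mkblob("hair", 62)
  expect_lt(abs(bubble[["f08_wl_ratio"]] - 1), 0.2)
  expect_gt(abs(hair[["f08_wl_ratio"]] - 1), 0.5)
  expect_gt(hair[["f09_hu1"]], bubble[["f09_hu1"]])
})
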