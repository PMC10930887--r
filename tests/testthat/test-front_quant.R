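test_that("segmentation recovers the ground-truth band, with and without noise", {
  sim0 <- simulate_front_stack(width = 128, height = 128, n_frames = 3,
                               interface_row = 48, advance_rate = 2,
                               fork_rate = 0, noise_sigma = 0, seed = 1)
  masks0 <- mask_from_stack(sim0$stack)
  for (t in 0:2)
    expect_identical(masks0[[t + 1]], true_front_mask(sim0$truth, t))

  sim <- simulate_front_stack(width = 128, height = 128, n_frames = 3,
                              interface_row = 48, advance_rate = 2,
                              fork_rate = 0, seed = 2)  # default noise
  masks <- mask_from_stack(sim$stack)
  for (t in 0:2) {
    agree <- mean(masks[[t + 1]] == true_front_mask(sim$truth, t))
    expect_gte(agree, 0.99)
  }
})

test_that("uniform frames are a degenerate segmentation error", {
  st <- image_stack(list(matrix(0.5, 32, 32)))
  expect_error(mask_from_stack(st), "degenerate segmentation")
})

test_that("front extraction matches a per-column scan of the mask", {
  # uniform advance of 10 px past the interface
  m <- band_mask(100, 60, 40, 10)
  pr <- extract_front(m, 40)
  expect_equal(pr$depth, rep(10, 60))
  expect_equal(pr$interface_length, 60)

  # one 5-px-wide, 30-px-deep tongue on a 10-px baseline
  depth <- rep(10, 60); depth[25:29] <- 30
  m2 <- band_mask(100, 60, 40, depth)
  pr2 <- extract_front(m2, 40)
  # oracle: direct per-column scan
  scan <- sapply(seq_len(60), function(x) max(which(m2[, x])) - 40)
  expect_equal(pr2$depth, scan)
  expect_equal(pr2$depth[25:29], rep(30, 5))
  expect_equal(pr2$depth[c(1:24, 30:60)], rep(10, 55))
})

test_that("a mask that never reaches the interface gives an all-invalid profile", {
  m <- matrix(FALSE, 100, 40); m[1:10, ] <- TRUE   # band far above interface
  expect_warning(pr <- extract_front(m, 80), "all-invalid")
  expect_true(all(is.na(pr$depth)))
  expect_error(extract_front(matrix(FALSE, 10, 10), 5), "empty mask")
  expect_error(extract_front(m, 200), "interface_row outside")
})

test_that("detached objects ahead of the front are excluded from depth but not area", {
  m <- band_mask(100, 60, 40, 5)
  m[80:82, 10:12] <- TRUE   # detached cell cluster deep in the stroma
  pr_ex <- extract_front(m, 40, detached = "exclude")
  pr_in <- extract_front(m, 40, detached = "include")
  expect_equal(pr_ex$depth[10], 5)
  expect_equal(pr_in$depth[10], 42)
  ext <- normalized_extent(list(band_mask(100, 60, 40, 5), m),
                           interface_row = 40)
  expect_equal(ext$extent[2], 9 / 60)  # 9 detached px count toward area, L0 = 60
})

test_that("moving-average smoothing matches brute-force summation", {
  set.seed(42)
  for (n in c(25, 100, 400)) {
    d <- random_profile(n)
    for (w in c(1, 5, 20)) {
      sm <- smooth_profile(front_profile(d), window = w)
      expect_equal(sm$depth, oracle_moving_average(d, w), tolerance = 1e-12)
    }
  }
  # fixed points and identity
  cst <- front_profile(rep(7, 50))
  expect_equal(smooth_profile(cst, 20)$depth, rep(7, 50))
  rnd <- front_profile(runif(30))
  expect_equal(smooth_profile(rnd, 1)$depth, rnd$depth)
  expect_error(smooth_profile(rnd, 31), "larger than profile")
})

test_that("smoothing a unit impulse spreads 1/window over the covering span", {
  d <- rep(0, 200); d[100] <- 1
  sm <- smooth_profile(front_profile(d), 20)
  covered <- which(sm$depth > 0)
  expect_length(covered, 20)
  expect_true(all(abs(sm$depth[covered] - 1 / 20) < 1e-12))
  expect_equal(sm$depth, oracle_moving_average(d, 20))
})

test_that("smoothing preserves the interior mean and never exceeds the data range", {
  set.seed(7)
  for (rep in 1:20) {
    d <- random_profile(300)
    d[is.na(d)] <- mean(d, na.rm = TRUE)    # fully valid for mean check
    sm <- smooth_profile(front_profile(d), 20)$depth
    expect_true(all(sm >= min(d) - 1e-9 & sm <= max(d) + 1e-9))
    # interior positions have fully contained windows; their window sums
    # re-average to the data mean over a balanced stretch
    expect_equal(mean(sm[150:160]),
                 mean(oracle_moving_average(d, 20)[150:160]), tolerance = 1e-9)
  }
})

test_that("normalized extent is analytic for uniform and triangular advances", {
  W <- 200; interface <- 50
  m0 <- band_mask(200, W, interface, 0)
  # uniform advance d = 12: E = d exactly
  ext <- normalized_extent(list(m0, band_mask(200, W, interface, 12)),
                           interface_row = interface)
  expect_equal(ext$extent, c(0, 12))
  expect_equal(attr(ext, "units"), "px")
  # triangular advance 0..d: E = d/2 within 2% rasterization tolerance
  d_tri <- round(seq(0, 40, length.out = W))
  ext2 <- normalized_extent(list(m0, band_mask(200, W, interface, d_tri)),
                            interface_row = interface)
  expect_equal(ext2$extent[2], 20, tolerance = 0.02)
  # no movement
  ext3 <- normalized_extent(list(m0, m0), interface_row = interface)
  expect_equal(ext3$extent[2], 0)
  expect_error(normalized_extent(list(), interface_row = 1), "frames missing")
})

test_that("extent agrees between ROI-polygon areas and mask pixel counts", {
  W <- 100; interface <- 30
  m0 <- band_mask(120, W, interface, 0)
  m1 <- band_mask(120, W, interface, 15)
  ext_mask <- normalized_extent(list(m0, m1), interface_row = interface)
  # polygons tracing the invaded region only (beyond the interface line)
  poly0 <- structure(list(vertices = cbind(x = c(0, W, W, 0),
                                           y = c(0, 0, 0, 0)),
                          frame_index = 0, closed = TRUE),
                     class = "roi_polygon")
  poly1 <- structure(list(vertices = cbind(x = c(0, W, W, 0),
                                           y = c(0, 0, 15, 15)),
                          frame_index = 1, closed = TRUE),
                     class = "roi_polygon")
  ext_roi <- normalized_extent(list(poly0, poly1), L0 = W)
  expect_equal(ext_roi$extent[2], ext_mask$extent[2])
})

test_that("extent is invariant to interface-axis translation and stroma padding", {
  sim <- simulate_front_stack(width = 80, height = 100, n_frames = 4,
                              interface_row = 30, advance_rate = 3,
                              fork_rate = 1, noise_sigma = 0, seed = 5)
  masks <- mask_from_stack(sim$stack)
  e0 <- normalized_extent(masks, interface_row = 30)$extent
  shifted <- lapply(masks, function(m) m[, c(21:80, 1:20)])
  expect_equal(normalized_extent(shifted, interface_row = 30)$extent, e0)
  padded <- lapply(masks, function(m) rbind(m, matrix(FALSE, 25, 80)))
  expect_equal(normalized_extent(padded, interface_row = 30)$extent, e0)
})

test_that("extent from per-column depths equals extent from area counts", {
  sim <- simulate_front_stack(width = 120, height = 200, n_frames = 5,
                              interface_row = 60, advance_rate = 2,
                              fork_rate = 2, noise_sigma = 0, seed = 9)
  masks <- mask_from_stack(sim$stack)
  ext <- normalized_extent(masks, interface_row = 60)
  for (t in c(2, 4)) {
    pr <- extract_front(masks[[t + 1]], 60, frame_index = t)
    expect_equal(extent_from_profile(pr), ext$extent[t + 1])
  }
})

test_that("fold change recovers condition ratios and rejects degenerate controls", {
  fc <- fold_change(c(10, 11, 9, 10), c(10, 11, 9, 10))
  expect_equal(fc$fold_change, 1)
  expect_gt(fc$p_value, 0.9)
  expect_equal(fc$stars, "ns")
  expect_error(fold_change(c(1, 2), c(0, 0)), "control mean")
  expect_error(fold_change(c(1), c(1, 2)), "replicate")

  # doubling the advance rate doubles the final extent; imaging noise
  # provides the replicate-to-replicate variability of real locations
  final_E <- function(v, seed) {
    sim <- simulate_front_stack(width = 64, height = 128, n_frames = 8,
                                interface_row = 40, advance_rate = v,
                                fork_rate = 0, noise_sigma = 0.3, seed = seed)
    masks <- mask_from_stack(sim$stack)
    utils::tail(normalized_extent(masks, interface_row = 40)$extent, 1)
  }
  e1 <- sapply(1:4, function(s) final_E(2, s))
  e2 <- sapply(5:8, function(s) final_E(4, s))
  fc2 <- fold_change(e2, e1)
  expect_equal(fc2$fold_change, 2, tolerance = 0.05)
  expect_lt(fc2$p_value, 0.01)
})

test_that("extent slope recovers the generator advance rate within 5%", {
  sim <- simulate_front_stack(width = 256, height = 256, n_frames = 12,
                              interface_row = 100, advance_rate = 3,
                              fork_rate = 0, seed = 13)
  masks <- mask_from_stack(sim$stack)
  ext <- normalized_extent(masks, interface_row = 100)
  slope <- unname(coef(lm(extent ~ frame, data = ext))[2])
  expect_equal(slope, 3, tolerance = 0.05)
})
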