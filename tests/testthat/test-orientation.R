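# orientation_analysis: MIP, masking, structure tensor, per-slice angles

test_that("max_intensity_projection basics", {
  a <- array(0.5, c(4, 5, 3))
  st <- image_stack(list(actin = a), voxel_size = c(1, 1, 1))
  mp <- max_intensity_projection(st)
  expect_equal(mp$image, matrix(0.5, 4, 5))

  b <- array(0, c(6, 6, 4)); b[3, 4, 2] <- 1
  st2 <- image_stack(list(actin = b), voxel_size = c(1, 1, 1))
  mp2 <- max_intensity_projection(st2)
  expect_equal(which(mp2$image == 1), 3 + (4 - 1) * 6)
  expect_equal(mp2$argmax_k[3, 4], 2)

  expect_error(max_intensity_projection(st, channel = "collagen"),
               "empty stack|unknown")
})

test_that("mask_artifacts combines polygons and saturation", {
  im <- matrix(0.5, 60, 60)
  expect_true(all(mask_artifacts(im)))

  poly <- data.frame(x = c(10, 25, 25, 10), z = c(10, 10, 25, 25))
  m <- mask_artifacts(im, rois = list(poly))
  inside <- m[12:23, 12:23]
  expect_true(all(!inside))
  expect_true(all(m[30:60, ]))
  frac <- mean(!m)
  expect_gt(frac, 0.05); expect_lt(frac, 0.08)   # ~16x16 of 60x60

  # injected saturated disc is auto-masked
  im2 <- im
  cx <- 40; cz <- 40
  disc <- (row(im2) - cx)^2 + (col(im2) - cz)^2 <= 36
  im2[disc] <- 1
  m2 <- mask_artifacts(im2)
  expect_gte(mean(!m2[disc]), 0.95)

  expect_error(mask_artifacts(im, rois = list(data.frame(a = 1))),
               "malformed ROI")
})

test_that("structure tensor recovers stripe orientations and is equivariant", {
  for (ang in c(30, 45, 90, 135)) {
    im <- make_stripes(150, ang, 10)
    of <- local_orientation(im, window_sigma = 10, pixel_size = 1)
    err <- abs(axial_diff(of$alpha[of$valid], ang))
    expect_gte(mean(err < 1), 0.95)
  }
  # rotating the image by 90 degrees shifts alpha by 90 window-wise
  im <- make_stripes(150, 30, 10)
  im90 <- t(im)[ncol(im):1, ]            # counterclockwise 90-deg rotation
  of <- local_orientation(im, window_sigma = 10, pixel_size = 1)
  of90 <- local_orientation(im90, window_sigma = 10, pixel_size = 1)
  a <- axial_mean(of$alpha[of$valid], of$weight[of$valid])
  a90 <- axial_mean(of90$alpha[of90$valid], of90$weight[of90$valid])
  expect_lt(abs(axial_diff(a90, a + 90)), 1)
})

test_that("structure tensor agrees with the Fourier-spectrum oracle", {
  for (ang in c(20, 65, 110, 160)) {
    im <- make_stripes(160, ang, 11)
    of <- local_orientation(im, window_sigma = 12, pixel_size = 1)
    a_st <- axial_mean(of$alpha[of$valid], of$weight[of$valid])
    a_ft <- oracle_fourier_orientation(im)
    expect_lt(abs(axial_diff(a_st, a_ft)), 1)
  }
})

test_that("flat and noise images are invalidated, not errors", {
  flat <- matrix(1, 100, 100)
  of <- local_orientation(flat, window_sigma = 8, pixel_size = 1)
  expect_false(any(of$valid))
  expect_true(all(of$weight == 0))

  set.seed(21)
  noise <- matrix(stats::runif(150 * 150), 150, 150)
  ofn <- local_orientation(noise, window_sigma = 10, pixel_size = 1)
  expect_lt(stats::median(ofn$coherence), 0.2)
  expect_gte(mean(!ofn$valid), 0.9)

  expect_error(local_orientation(flat, window_sigma = 1, pixel_size = 1),
               "at least 2 pixels")
})

test_that("masked regions get zero weight", {
  im <- make_stripes(150, 40, 10)
  mask <- matrix(TRUE, 150, 150); mask[60:90, 60:90] <- FALSE
  of <- local_orientation(im, mask = mask, window_sigma = 8, pixel_size = 1)
  inside <- outer(of$x_px %in% 60:90, of$z_px %in% 60:90, "&")
  expect_true(all(of$weight[inside] == 0))
  expect_true(all(!of$valid[inside]))
})

test_that("orientation field exports to CSV", {
  im <- make_stripes(120, 50, 10)
  of <- local_orientation(im, window_sigma = 8, pixel_size = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  orientation_field_to_csv(of, path)
  d <- utils::read.csv(path)
  expect_setequal(names(d), c("x_px", "z_px", "alpha_deg", "weight",
                              "coherence", "valid"))
  expect_equal(nrow(d), length(of$x_px) * length(of$z_px))
})

test_that("slice orientation resolves a two-layer twist structure", {
  surf <- cylinder_surface(60, 70)
  cfg <- synthetic_config(
    surf,
    layers = data.frame(depth_min = c(0, 12), depth_max = c(12, 40),
                        theta = c(80, 110)),
    voxel_size = c(1, 1, 2), fiber_density = 0.006,
    attenuation_length = 1e4,   # no attenuation: deep layers stay visible
    noise = list(poisson_gain = 500, gaussian_sigma = 0.005), seed = 31)
  st <- render_helical_tissue(cfg)
  prof <- slice_orientation(st, roi_size_um = c(90, 90), window_sigma = 8)
  conf <- prof[prof$confident & prof$depth_um >= 0 & prof$depth_um <= 35, ]
  top <- conf$alpha_deg[conf$depth_um <= 8]
  deep <- conf$alpha_deg[conf$depth_um >= 16 & conf$depth_um <= 30]
  expect_gt(length(top), 2); expect_gt(length(deep), 2)
  expect_lt(abs(axial_diff(axial_mean(top), 80)), 5)
  expect_lt(abs(axial_diff(axial_mean(deep), 110)), 5)
  # the switch happens near the layer boundary (12 um +- 2 slices)
  sw <- conf$depth_um[which(abs(axial_diff(conf$alpha_deg, 110)) < 15)[1]]
  expect_lt(abs(sw - 12), 2 * st$voxel_size[3] + 2)
})

test_that("uniform-orientation stacks give constant per-slice angles", {
  surf <- cylinder_surface(60, 70)
  cfg <- synthetic_config(
    surf, layers = data.frame(depth_min = 0, depth_max = 30, theta = 65),
    voxel_size = c(1, 1, 2), fiber_density = 0.006,
    attenuation_length = 1e4,
    noise = list(poisson_gain = 500, gaussian_sigma = 0.005), seed = 32)
  st <- render_helical_tissue(cfg)
  prof <- slice_orientation(st, roi_size_um = c(90, 90), window_sigma = 8)
  conf <- prof[prof$confident & prof$depth_um >= 2 & prof$depth_um <= 25, ]
  expect_gt(nrow(conf), 5)
  expect_lt(max(abs(axial_diff(conf$alpha_deg, axial_mean(conf$alpha_deg)))),
            3)
  # slices far outside the tissue are low-confidence
  expect_true(all(!prof$confident[prof$intensity <
                                    0.05 * max(prof$intensity)]))
})
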