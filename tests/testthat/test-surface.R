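# surface_geometry: profiles, CMC solver, curvatures

test_that("principal curvatures and Euler endpoints match closed forms", {
  cyl <- cylinder_surface(100, 60)
  pc <- principal_curvatures(cyl, 0)
  expect_equal(pc$kappa_m, 0)
  expect_equal(pc$kappa_c, 1 / 100)
  expect_equal(normal_curvature(cyl, 0, 0), 1 / 100)
  expect_equal(normal_curvature(cyl, 0, 90), 0)

  ctn <- catenoid_surface(50, 40)
  pc <- principal_curvatures(ctn, 0)
  expect_equal(pc$kappa_m, -1 / 50, tolerance = 1e-10)
  expect_equal(pc$kappa_c, 1 / 50, tolerance = 1e-10)
  expect_equal(gaussian_curvature(ctn, 0), -1 / 50^2, tolerance = 1e-10)
  # asymptotic direction at the waist of a minimal surface
  expect_equal(normal_curvature(ctn, 0, 45), 0, tolerance = 1e-12)

  # umbilic: sphere has constant normal curvature in every direction
  sp <- sphere_surface(100)
  ks <- normal_curvature(sp, rep(25, 7), seq(0, 179, length.out = 7))
  expect_equal(ks, rep(1 / 100, 7), tolerance = 1e-9)
})

test_that("sign convention: bridge waist vs pore neck", {
  ctn_b <- catenoid_surface(60, 50, sense = "bridge")
  expect_lt(normal_curvature(ctn_b, 0, 90), 0)  # meridional concave
  expect_gt(normal_curvature(ctn_b, 0, 0), 0)   # equatorial convex
  ctn_p <- catenoid_surface(60, 50, sense = "pore")
  expect_gt(normal_curvature(ctn_p, 0, 90), 0)
  expect_lt(normal_curvature(ctn_p, 0, 0), 0)
  # Gaussian curvature is negative either way
  expect_lt(gaussian_curvature(ctn_b, 10), 0)
  expect_lt(gaussian_curvature(ctn_p, 10), 0)
})

test_that("Euler consistency: extrema of k_theta are the principal curvatures", {
  set.seed(11)
  surf <- solve_cmc_profile(200, 260, h = 1e-3)
  for (z in stats::runif(5, -120, 120)) {
    pc <- principal_curvatures(surf, z)
    ks <- normal_curvature(surf, rep(z, 181), seq(0, 180, length.out = 181))
    expect_equal(min(ks), min(pc$kappa_m, pc$kappa_c), tolerance = 1e-6)
    expect_equal(max(ks), max(pc$kappa_m, pc$kappa_c), tolerance = 1e-6)
    expect_equal(normal_curvature(surf, z, 0), pc$kappa_c)
    expect_equal(normal_curvature(surf, z, 90), pc$kappa_m)
  }
})

test_that("CMC solver reproduces the cylinder and catenoid closed forms", {
  s <- solve_cmc_profile(100, 120, h = 1 / 200)
  zz <- seq(-60, 60, length.out = 41)
  expect_equal(s$r(zz), rep(100, 41), tolerance = 1e-6)

  # catenoid: c cosh(d / (2c)) = R, outer branch
  s0 <- solve_cmc_profile(100, 120, h = 0)
  croot <- stats::uniroot(function(c) c * cosh(60 / c) - 100, c(55, 99.9),
                          tol = 1e-12)$root
  expect_equal(attr(s0, "waist_radius"), croot, tolerance = 1e-6)
  expect_equal(s0$r(zz), croot * cosh(zz / croot), tolerance = 1e-5)
})

test_that("CMC profiles have constant mean curvature across the domain", {
  for (h in c(0, 2e-4, 8e-4)) {
    s <- solve_cmc_profile(1000, 1250, h = h)
    zz <- seq(-600, 600, length.out = 101)
    expect_lt(max(abs(mean_curvature(s, zz) - h)), 1e-6)
  }
})

test_that("CMC solver errors with an admissible bracket when no solution exists", {
  # catenoid existence fails for d/R beyond ~1.33
  expect_error(solve_cmc_profile(100, 150, h = 0), "no CMC bridge solution")
  expect_error(solve_cmc_profile(100, 150, h = 0), "span")
  expect_error(solve_cmc_profile(1000, 1250, volume = 1), "admissible range")
})

test_that("volume-targeted bridge matches the brute-force area-minimization oracle", {
  # paper scaffold scale: pillar radius 1000 um, distance 1250 um, waisted
  s_ref <- solve_cmc_profile(1000, 1250, h = 2e-4)
  zs <- seq(-625, 625, length.out = 2001)
  rs <- s_ref$r(zs)
  vol <- pi * sum((rs[-1]^2 + rs[-2001]^2) / 2) * diff(zs)[1]

  s <- solve_cmc_profile(1000, 1250, volume = vol)
  expect_lt(abs(attr(s, "waist_radius") - attr(s_ref, "waist_radius")), 1)

  orc <- oracle_cmc_profile_minimization(1000, 1250, vol)
  expect_equal(orc$convergence, 0)
  expect_lt(abs(orc$waist - attr(s, "waist_radius")) / orc$waist, 0.01)
})

test_that("normal_curvature matches the finite-difference normal-section oracle", {
  set.seed(42)
  surf <- solve_cmc_profile(500, 600, h = 5e-4)
  for (i in 1:20) {
    z <- stats::runif(1, -250, 250)
    th <- stats::runif(1, 0, 180)
    k_pkg <- normal_curvature(surf, z, th)
    k_orc <- oracle_normal_section_curvature(surf, z, th)
    expect_equal(k_pkg, k_orc, tolerance = 1e-6)
  }
  # and on both senses of a catenoid
  for (sense in c("bridge", "pore")) {
    ctn <- catenoid_surface(80, 60, sense = sense)
    for (th in c(10, 45, 100, 170)) {
      expect_equal(normal_curvature(ctn, 15, th),
                   oracle_normal_section_curvature(ctn, 15, th),
                   tolerance = 1e-6)
    }
  }
})

test_that("silhouette fitting recovers cylinder and catenoid profiles", {
  # binary render of a cylinder, radius 100 px
  px <- 1
  nx <- 301; nz <- 201
  im <- matrix(0, nx, nz)
  cx <- 151
  im[(cx - 100):(cx + 100), ] <- 1
  s <- fit_profile_from_silhouette(im, px, sense = "bridge")
  zz <- seq(s$z_range[1] + 5, s$z_range[2] - 5, length.out = 51)
  expect_lt(max(abs(s$r(zz) - 100)), 0.5)

  # catenoid silhouette, recover within 1% on the central 80% of rows
  c0 <- 80
  rtrue <- function(z) c0 * cosh(z / c0)
  zpix <- seq_len(nz) - 101
  im2 <- matrix(0, nx, nz)
  for (j in seq_len(nz)) {
    r <- rtrue(zpix[j])
    im2[abs(seq_len(nx) - cx) <= r, j] <- 1
  }
  s2 <- fit_profile_from_silhouette(im2, px, sense = "bridge")
  zc <- zpix[abs(zpix) <= 80]            # central 80% of rows
  expect_lt(max(abs(s2$r(zc) - rtrue(zc)) / rtrue(zc)), 0.01)

  # dust artifact spanning 10 rows: those rows are rejected/interpolated
  im3 <- im2
  im3[, 40:49] <- 0                      # occlusion
  s3 <- fit_profile_from_silhouette(im3, px, sense = "bridge")
  expect_lt(max(abs(s3$r(zc) - rtrue(zc)) / rtrue(zc)), 0.01)

  # garbage image -> silhouette-not-found
  expect_error(fit_profile_from_silhouette(matrix(0, 50, 50), 1),
               "silhouette-not-found")
})

test_that("profile CSV round trip and OBJ export", {
  s <- catenoid_surface(70, 50)
  csv <- withr::local_tempfile(fileext = ".csv")
  profile_to_csv(s, csv)
  s2 <- profile_from_csv(csv)
  zz <- seq(-45, 45, length.out = 31)
  expect_equal(s2$r(zz), s$r(zz), tolerance = 1e-6)

  obj <- withr::local_tempfile(fileext = ".obj")
  surface_to_obj(s, obj, n_z = 10, n_phi = 12)
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), 10 * 12)
  expect_equal(sum(startsWith(lines, "f ")), 2 * 9 * 12)
})

test_that("mm units are converted to um", {
  s <- solve_cmc_profile(1, 1.25, h = 0.2, units = "mm")  # H = 2e-4 / um
  expect_equal(s$z_range, c(-625, 625))
  expect_equal(mean_curvature(s, 0), 2e-4, tolerance = 1e-9)
})
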