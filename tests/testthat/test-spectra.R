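test_that("readers parse wide, long and per-species layouts", {
  wl <- seq(300, 700, 1)
  dirn <- withr::local_tempdir()
  wide <- data.frame(wavelength = wl, sp1 = 0.2, sp2 = seq(0, 1, length.out = 401))
  fw <- file.path(dirn, "wide.csv")
  write.csv(wide, fw, row.names = FALSE)
  sw <- read_spectra(fw, "wide")
  expect_named(sw, c("sp1", "sp2"))
  expect_length(sw$sp1$wavelength, 401)
  expect_equal(sw$sp2$reflectance, seq(0, 1, length.out = 401))

  long <- data.frame(species_id = rep(c("a", "b"), each = 401),
                     wavelength = rep(wl, 2),
                     reflectance = c(rep(0.3, 401), rep(0.6, 401)))
  fl <- file.path(dirn, "long.tsv")
  write.table(long, fl, sep = "\t", row.names = FALSE, quote = FALSE)
  sl <- read_spectra(fl, "long")
  expect_equal(sl$b$reflectance[1], 0.6)

  psd <- file.path(dirn, "per_species")
  dir.create(psd)
  write.table(data.frame(wl, 0.25), file.path(psd, "sp1.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(w = wl, r = 0.5), file.path(psd, "sp2.tsv"), sep = "\t",
              row.names = FALSE)
  sd_ <- read_spectra(psd, "per_species_dir")
  expect_setequal(names(sd_), c("sp1", "sp2"))
  expect_equal(sd_$sp2$reflectance[100], 0.5)
})

test_that("shuffled wavelength rows are re-sorted to match the sorted parse", {
  wl <- seq(300, 700, 5)
  vals <- round(plogis((wl - 480) / 30), 5)
  dirn <- withr::local_tempdir()
  sorted_f <- file.path(dirn, "sorted.csv")
  shuffled_f <- file.path(dirn, "shuffled.csv")
  df <- data.frame(wavelength = wl, sp = vals)
  write.csv(df, sorted_f, row.names = FALSE)
  set.seed(42)
  write.csv(df[sample(nrow(df)), ], shuffled_f, row.names = FALSE)
  expect_equal(read_spectra(shuffled_f, "wide")$sp,
               read_spectra(sorted_f, "wide")$sp)
})

test_that("reader errors are informative", {
  dirn <- withr::local_tempdir()
  f <- file.path(dirn, "bad.csv")
  writeLines(c("wavelength,sp1", "300,0.5", "400,oops", "700,0.5"), f)
  expect_error(read_spectra(f, "wide"), "non-numeric")
  f2 <- file.path(dirn, "empty.csv")
  file.create(f2)
  expect_error(read_spectra(f2, "wide"), "empty|no lines|no data")
})

test_that("spectrum construction enforces invariants", {
  expect_error(refl_spectrum("x", 300, 0.5), "at least 2")
  expect_error(refl_spectrum("x", c(300, 400), 0.5), "equal length")
  expect_warning(refl_spectrum("x", c(300, 700), c(0.5, 1.2)), "glare")
  # duplicates averaged, negatives clipped
  sp <- refl_spectrum("x", c(300, 300, 700), c(0.2, 0.4, -0.1))
  expect_equal(sp$wavelength, c(300, 700))
  expect_equal(sp$reflectance, c(0.3, 0))
})

test_that("resampling interpolates linearly, clips at zero, respects edges", {
  sp <- refl_spectrum("x", c(300, 700), c(0.2, 0.2))
  rs <- resample_spectrum(sp)
  expect_equal(rs$reflectance, rep(0.2, 401))

  ramp <- refl_spectrum("x", c(300, 700), c(0, 1))
  expect_equal(resample_spectrum(ramp)$reflectance[201], 0.5)

  # edge extrapolation within 5 nm is constant; beyond is an error
  short <- refl_spectrum("x", c(304, 696), c(0.1, 0.3))
  expect_equal(resample_spectrum(short)$reflectance[1], 0.1)
  gap <- refl_spectrum("x", c(310, 700), c(0.1, 0.3))
  expect_error(resample_spectrum(gap), "gap of 10.0 nm")

  # idempotence on an already-gridded spectrum
  g <- default_grid()
  sp2 <- refl_spectrum("x", g, plogis((g - 500) / 40))
  expect_identical(resample_spectrum(sp2)$reflectance, sp2$reflectance)
})

test_that("mean background is the pointwise mean and scales linearly", {
  a <- flat_spectrum(0.1)
  b <- flat_spectrum(0.3)
  expect_equal(mean_background(list(a))$reflectance, a$reflectance)
  expect_equal(mean_background(list(a, b))$reflectance, rep(0.2, 401))
  expect_equal(mean_background(list(a, b))$species_id, "background")

  leaves <- lapply(1:10, gen_leaf_spectrum)
  m <- mean_background(leaves)
  # second, independent summation order
  acc <- rep(0, 401)
  for (i in 10:1) acc <- acc + leaves[[i]]$reflectance
  expect_equal(m$reflectance, acc / 10)
  # commutes with uniform scaling
  scaled <- lapply(leaves, function(s) refl_spectrum(s$species_id, s$wavelength,
                                                     2.5 * s$reflectance))
  expect_equal(suppressWarnings(mean_background(scaled))$reflectance,
               2.5 * m$reflectance, tolerance = 1e-12)

  off_grid <- refl_spectrum("x", seq(300, 700, 2), rep(0.1, 201))
  expect_error(mean_background(list(a, off_grid)), "common grid")
})

test_that("receptor template peaks at lambda_max, is positive and crosses once", {
  for (lm in c(350, 440, 540)) {
    s <- receptor_template(lm)
    expect_equal(max(s$sensitivity), 1)
    expect_equal(s$wavelength[which.max(s$sensitivity)], lm, tolerance = 1)
    expect_true(all(s$sensitivity > 0))
    expect_true(all(s$sensitivity <= 1))
  }
  # curves for 350 and 540 cross exactly once between their peaks
  s1 <- receptor_template(350)$sensitivity
  s2 <- receptor_template(540)$sensitivity
  between <- default_grid() > 350 & default_grid() < 540
  crossings <- sum(diff(sign(s1[between] - s2[between])) != 0)
  expect_equal(crossings, 1)
  # unimodal alpha band: one sign change of the derivative near the peak
  s <- receptor_template(440)$sensitivity
  alpha <- default_grid() > 380
  expect_equal(sum(diff(sign(diff(s[alpha]))) != 0), 1)
  expect_error(receptor_template(250), "300")
})

test_that("photon-flux illuminant is the wavelength-corrected daylight table", {
  il <- d65_photon_flux()
  expect_true(all(il$photon_flux >= 0))
  expect_equal(max(il$photon_flux), 1)
  # ratio to the raw daylight table is c * lambda for one constant c
  raw <- approx(beehexagon:::.d65_wavelength, beehexagon:::.d65_power,
                xout = il$wavelength)$y
  cvec <- il$photon_flux / (raw * il$wavelength)
  expect_lt(diff(range(cvec)), 1e-12)
  expect_lt(il$photon_flux[il$wavelength == 350],
            il$photon_flux[il$wavelength == 550])
  expect_error(d65_photon_flux(seq(250, 700, 1)), "300")
})

test_that("marker points sit at the steepest spectral transitions", {
  expect_identical(detect_marker_points(flat_spectrum(0.4)), numeric(0))

  g <- default_grid()
  step1 <- refl_spectrum("s", g, plogis((g - 500) / 15))
  mp <- detect_marker_points(step1)
  expect_length(mp, 1)
  expect_equal(mp, 500, tolerance = 1)

  double <- refl_spectrum("d", g, 0.4 * plogis((g - 400) / 10) +
                                   0.4 * plogis((g - 600) / 10))
  mp2 <- detect_marker_points(double)
  expect_length(mp2, 2)
  expect_equal(mp2, c(400, 600), tolerance = 2)
  # brute-force check: the same two wavelengths maximize finite differences
  sm <- as.numeric(stats::filter(double$reflectance, rep(1 / 11, 11), sides = 2))
  d <- abs(diff(sm))
  expect_equal(sort(g[order(-d)[1:2]]), round(mp2), tolerance = 3)

  expect_error(detect_marker_points(refl_spectrum("u", c(300, 400, 700), c(0, 1, 1))),
               "uniform grid")
})

test_that("one inflection stays one marker point under sub-smoothing-scale noise", {
  g <- default_grid()
  base <- 0.9 * plogis((g - 520) / 20)
  for (seed in 1:20) {
    set.seed(seed)
    noisy <- refl_spectrum("n", g, pmax(base + rnorm(401, 0, 0.002), 0))
    mp <- detect_marker_points(noisy)
    expect_length(mp, 1)
    expect_equal(mp, 520, tolerance = 10)
  }
})
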