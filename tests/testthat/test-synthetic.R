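test_that("every generator is a pure function of its seed", {
  expect_identical(gen_proteins(3, 3, 1, seed = 5), gen_proteins(3, 3, 1, seed = 5))
  expect_identical(gen_ion_table("urea", 0.3, 1e4, 0.1, seed = 5),
                   gen_ion_table("urea", 0.3, 1e4, 0.1, seed = 5))
  expect_identical(gen_plate(0.002, 0.08, c(0, 100, 200), c(50), 0.01, seed = 5),
                   gen_plate(0.002, 0.08, c(0, 100, 200), c(50), 0.01, seed = 5))
  expect_identical(gen_rate_data(table1_cah_pr(), 0.01, c(10, 100, 1000),
                                 0.05, seed = 5),
                   gen_rate_data(table1_cah_pr(), 0.01, c(10, 100, 1000),
                                 0.05, seed = 5))
  expect_identical(gen_chromatogram(noise_sd = 1, seed = 5),
                   gen_chromatogram(noise_sd = 1, seed = 5))
  # different seeds diverge
  expect_false(identical(gen_ion_table("urea", 0.3, 1e4, 0.1, seed = 5),
                         gen_ion_table("urea", 0.3, 1e4, 0.1, seed = 6)))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_proteins(1, 1, seed = 99))
  invisible(gen_ion_table("biuret", 0.2, 1e3, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("protein generator plants classes exactly and errors on impossible lengths", {
  gp <- gen_proteins(4, 3, 2, seed = 17)
  expect_equal(table(gp$truth$class)[["positive"]], 4)
  expect_equal(table(gp$truth$class)[["negative"]], 3)
  expect_equal(table(gp$truth$class)[["barbiturase_like"]], 2)
  # planted positives always carry a C-terminal motif instance
  for (id in gp$truth$seq_id[gp$truth$class == "positive"]) {
    h <- scan_motif(gp$sequences[[id]], cah_motif(), seq_id = id)
    expect_gte(max(h$relative_position), 0.75)
  }
  none <- gen_proteins(0, 3, 0, seed = 1)
  ref <- synthetic_reference_cah()
  expect_false(any(mine_cah(none$sequences, ref)$verdict == "CAH-candidate"))
  expect_error(gen_proteins(1, 1, length_range = c(5, 10)), "motif")
})

test_that("ion generator hits the scheme ratios and the pure-air closed form", {
  tab <- gen_ion_table("urea", 0, n_molecules = 2e5, seed = 11,
                       config = isotope_config(light_purity = 1,
                                               heavy_purity = 1))
  counts <- tab$areas[c("28", "29", "30")]
  expect_multinom_3sigma(counts, c(0.25, 0.5, 0.25))

  # nearly pure air: corrected m/z 29 collapses to ~0 and x matches natural ratio
  air <- gen_ion_table("urea", 0, n_molecules = 100, air_fraction = 0.999,
                       seed = 12)
  a <- air$areas
  q <- 0.9963
  expect_equal(a[["29"]] / a[["28"]], 2 * (1 - q) / q, tolerance = 0.5)
  corr <- correct_background(a, isotope_config(background_correction = "total_28"))
  expect_lt(corr[["29"]] / a[["29"]], 0.2)
})

test_that("noiseless plate and chromatogram generators reproduce their planted truths", {
  gp <- gen_plate(0.002, 0.08, c(0, 50, 100, 200), c(150, 20), 0, seed = 3)
  std <- gp$plate[gp$plate$role == "standard", ]
  cc <- fit_standard(std$concentration, std$response)
  est <- as.numeric(estimate_conc(cc, gp$plate$response[gp$plate$role == "sample"]))
  expect_equal(est, c(150, 20), tolerance = 1e-9)

  ch <- gen_chromatogram(noise_sd = 0, seed = 1)
  areas <- integrate_peaks(ch$time, ch$intensity,
                           data.frame(name = c("N2", "CO2", "N2O"),
                                      rt = c(1.84, 2.62, 2.88),
                                      half_width = 0.12))
  expect_equal(areas$area, c(1000, 400, 20), tolerance = 0.02)

  empty <- gen_chromatogram(peaks = NULL, noise_sd = 0, seed = 1)
  flat <- integrate_peaks(empty$time, empty$intensity,
                          data.frame(name = "w", rt = 2, half_width = 0.5))
  expect_equal(flat$area, 0)
})
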