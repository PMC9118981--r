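test_that("expected isotopomer distributions reproduce the mixture-model ratios", {
  expect_equal(as.numeric(expected_distribution("urea", "intermolecular")),
               c(1, 2, 1) / 4, tolerance = 1e-12)
  expect_equal(as.numeric(expected_distribution("urea", "intramolecular")),
               c(1, 0, 1) / 2, tolerance = 1e-12)
  expect_equal(as.numeric(expected_distribution("biuret", "intramolecular")),
               c(5, 2, 5) / 12, tolerance = 1e-12)
  # fully labeled pool collapses to m/z 30
  expect_equal(as.numeric(expected_distribution("urea", "intermolecular", p = 1)),
               c(0, 0, 1), tolerance = 1e-12)
})

test_that("distributions are probability vectors with label-swap symmetry at p = 0.5", {
  for (comp in c("urea", "biuret"))
    for (f in seq(0, 1, by = 0.1)) {
      d <- expected_distribution(comp, "mixture", f = f)
      expect_equal(sum(d), 1, tolerance = 1e-12)
      expect_equal(d[["28"]], d[["30"]], tolerance = 1e-12)
    }
})

test_that("ratio and fraction estimators are exact inverses over [0, 1]", {
  f <- seq(0, 1, length.out = 101)
  for (comp in c("urea", "biuret")) {
    x <- expected_ratio(comp, f)
    back <- as.numeric(fraction_intramolecular(comp, x))
    expect_equal(back, 100 * f, tolerance = 1e-9)
  }
  expect_equal(expected_ratio("urea", 0), 2, tolerance = 1e-12)
  expect_equal(expected_ratio("biuret", 0), 2, tolerance = 1e-12)
  expect_equal(expected_ratio("urea", 1), 0, tolerance = 1e-12)
  expect_equal(expected_ratio("biuret", 1), 0.4, tolerance = 1e-12)
  expect_error(expected_ratio("urea", 1.2), "\\[0, 1\\]")
})

test_that("fraction estimator is strictly decreasing in x and clamps out-of-range ratios", {
  x <- seq(0, 2, length.out = 50)
  for (comp in c("urea", "biuret")) {
    v <- as.numeric(fraction_intramolecular(comp, x, clamp = FALSE))
    expect_true(all(diff(v) < 0))
  }
  over <- fraction_intramolecular("urea", 2.3)
  expect_equal(as.numeric(over), 0)
  expect_true(attr(over, "clamped"))
  raw <- fraction_intramolecular("urea", 2.3, clamp = FALSE)
  expect_lt(as.numeric(raw), 0)
  expect_error(fraction_intramolecular("urea", -0.1), ">= 0")
})

test_that("background correction removes the air-derived m/z 29 component", {
  cfg <- isotope_config()
  # no air excess: identity on m/z 29
  no_air <- correct_background(c(`28` = 500, `29` = 990, `30` = 500), cfg)
  expect_equal(no_air[["29"]], 990)

  # pure air at the stated purity, total-28 mode: corrected 29 ~ 0
  cfg28 <- isotope_config(background_correction = "total_28")
  pure_air <- correct_background(c(`28` = 1000, `29` = 7.43, `30` = 0), cfg28)
  expect_lt(pure_air[["29"]], 0.01)
  expect_equal(attr(pure_air, "background29"),
               1000 * 2 * (1 - 0.9963) / 0.9963, tolerance = 1e-9)

  # q = 1: identity; never negative
  ident <- correct_background(c(`28` = 900, `29` = 100, `30` = 200),
                              isotope_config(light_purity = 1))
  expect_equal(ident[["29"]], 100)
  floor0 <- correct_background(c(`28` = 1e6, `29` = 1, `30` = 0), cfg)
  expect_gte(floor0[["29"]], 0)
})

test_that("the N2O 45/46 ratio is 2 under scrambled assembly and errors without m/z 46", {
  expect_equal(n2o_ratio(c(`44` = 1, `45` = 2, `46` = 1)), 2)
  expect_equal(n2o_ratio(c(`45` = 5, `46` = 5)), 1)
  expect_error(n2o_ratio(c(`45` = 5, `46` = 0)), "zero")

  # sampled from the binomial N2O distribution the ratio converges to 2
  set.seed(6)
  counts <- stats::rmultinom(1, 2e5, c(0.25, 0.5, 0.25))[, 1]
  r <- n2o_ratio(stats::setNames(counts, c("44", "45", "46")))
  expect_equal(r, 2, tolerance = 0.05)
})

test_that("peak integration matches geometry on rectangles and Gaussians", {
  t <- seq(0, 10, by = 0.001)
  flat <- integrate_peaks(t, rep(0, length(t)),
                          data.frame(name = "w", rt = 5, half_width = 1))
  expect_equal(flat$area, 0)

  # unit-height rectangle of width 2 inside a wider window
  y <- as.numeric(t >= 4 & t <= 6)
  rect <- integrate_peaks(t, y, data.frame(name = "r", rt = 5, half_width = 2))
  expect_equal(rect$area, 2, tolerance = 0.01)

  # Gaussian with known area over +/- 5 sigma
  A <- 37.5; s <- 0.05
  g <- A * dnorm(t, 5, s)
  gaus <- integrate_peaks(t, g,
                          data.frame(name = "g", rt = 5, half_width = 5 * s))
  expect_equal(gaus$area, A, tolerance = 0.01 * A)

  expect_error(integrate_peaks(t, g,
               data.frame(name = "bad", rt = 20, half_width = 0.1)),
               "empty_window")
})

test_that("the full mechanism pipeline returns 0% on pure intermolecular tables", {
  est <- estimate_mechanism(c(`28` = 2500, `29` = 5000, `30` = 2500), "urea")
  expect_equal(est$percent_intramolecular, 0, tolerance = 1e-9)
  expect_equal(est$x, 2, tolerance = 1e-12)
  expect_error(estimate_mechanism(c(`28` = 10, `29` = 5, `30` = 0), "urea"),
               "zero")
})

test_that("atom-pairing generator and closed-form distribution are mutual oracles", {
  ideal <- isotope_config(light_purity = 1, heavy_purity = 1)
  for (comp in c("urea", "biuret")) {
    for (f in c(0, 0.5)) {
      tab <- gen_ion_table(comp, f, n_molecules = 2e5, air_fraction = 0,
                           config = ideal, seed = 303)
      counts <- tab$areas[c("28", "29", "30")]
      probs <- as.numeric(expected_distribution(comp, "mixture", f = f))
      expect_multinom_3sigma(counts, probs)
    }
  }
})

test_that("generator tables with air contamination are deconvoluted back to the planted fraction", {
  for (f in c(0.1, 0.5)) {
    tab <- gen_ion_table("biuret", f, n_molecules = 5e5, air_fraction = 0.25,
                         seed = 404)
    est <- estimate_mechanism(tab$areas, "biuret")
    expect_lt(abs(est$percent_intramolecular - 100 * f), 2)
  }
})
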