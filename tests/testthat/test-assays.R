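test_that("noiseless standard-curve points are recovered exactly", {
  nmol <- c(0.075, 0.3, 1.25, 5)
  pts <- data.frame(nmol = nmol, absorbance = 0.05 + 0.2 * nmol)
  cv <- fit_standard_curve(pts)
  expect_equal(cv$slope, 0.2)
  expect_equal(cv$intercept, 0.05)
  expect_equal(cv$r_squared, 1)
  expect_error(fit_standard_curve(pts[1:2, ]), "3 standard-curve points")
  bad <- data.frame(nmol = nmol, absorbance = 0.5 - 0.1 * nmol)
  expect_error(fit_standard_curve(bad), "non-positive slope")
})

test_that("noisy standard-curve slope is recovered within 3 SE", {
  set.seed(101)
  nmol <- rep(c(0.075, 0.15, 0.3, 0.625, 1.25, 2.5, 5), each = 3)
  pts <- data.frame(nmol = nmol,
                    absorbance = 0.05 + 0.2 * nmol + rnorm(length(nmol), 0, 0.005))
  cv <- fit_standard_curve(pts)
  fit <- lm(absorbance ~ nmol, data = pts)
  se <- summary(fit)$coefficients["nmol", "Std. Error"]
  expect_lt(abs(cv$slope - 0.2), 3 * se)
  expect_gt(cv$r_squared, 0.99)
})

test_that("specific activity follows the blank-corrected curve arithmetic", {
  cv <- fit_standard_curve(data.frame(nmol = c(0, 1, 5),
                                      absorbance = c(0, 0.2, 1.0)))
  # A 0.4, blank 0 -> 2 nmol Pi over 10 min and 0.05 mg -> 4 nmol/min/mg
  expect_equal(as.numeric(specific_activity(0.4, 0, cv, 10, 0.05)), 4)
  expect_equal(as.numeric(specific_activity(0.2, 0.2, cv, 10, 0.05)), 0)
  neg <- specific_activity(0.1, 0.2, cv, 10, 0.05)
  expect_lt(as.numeric(neg), 0)           # reported as-is, not clamped
  expect_true(attr(neg, "flagged"))
  expect_error(specific_activity(0.4, 0, cv, 0, 0.05), "incubation")
  expect_error(specific_activity(0.4, 0, cv, 10, 0), "protein")
})

test_that("specific activity is linear in signal and inverse in time/protein", {
  cv <- fit_standard_curve(data.frame(nmol = c(0, 1, 5),
                                      absorbance = c(0.02, 0.22, 1.02)))
  set.seed(7)
  for (i in 1:20) {
    a <- runif(1, 0.1, 1); b <- runif(1, 0, 0.05)
    t <- runif(1, 5, 60); p <- runif(1, 0.01, 0.5); k <- runif(1, 1.5, 4)
    base <- as.numeric(specific_activity(a, b, cv, t, p))
    scaled <- as.numeric(specific_activity(b + k * (a - b), b, cv, t, p))
    expect_equal(scaled - (k - 1) * cv$intercept / (cv$slope * t * p),
                 k * base, tolerance = 1e-9)
    expect_equal(as.numeric(specific_activity(a, b, cv, k * t, p)) * k, base)
    expect_equal(as.numeric(specific_activity(a, b, cv, t, k * p)) * k, base)
  }
})

test_that("percent of control is the ratio to the control mean", {
  expect_equal(percent_of_control(0.21, 1.03), 100 * 0.21 / 1.03)
  expect_equal(round(percent_of_control(0.21, 1.03), 1), 20.4)
  expect_equal(percent_of_control(5, c(5, 5, 5)), 100)
  expect_equal(percent_of_control(0, c(1, 2)), 0)
  x <- runif(1, 0.1, 10)
  expect_equal(percent_of_control(x, x), 100)
  expect_error(percent_of_control(1, c(-1, 1)), "non-zero")
  expect_error(percent_of_control(1, numeric()), "control value")
})

test_that("galactolytic capacity is oligomycin minus post-2DG acidification", {
  tr <- data.frame(phase = rep(c("baseline", "galactose", "oligomycin", "2DG"),
                               each = 4),
                   ecar = c(10, 10, 10, 10, 12, 12, 12, 12,
                            30, 32, 31, 31, 5, 5, 6, 4))
  expect_equal(galactolytic_capacity(tr), 31 - 5)
  expect_equal(galactolytic_capacity(tr, reducer = "last"), 31 - 4)
  flat <- data.frame(phase = tr$phase, ecar = 7)
  expect_equal(galactolytic_capacity(flat), 0)
  # invariant under adding a constant to every cycle
  shifted <- tr; shifted$ecar <- shifted$ecar + 13.7
  expect_equal(galactolytic_capacity(shifted), galactolytic_capacity(tr))
  expect_error(galactolytic_capacity(tr[tr$phase != "2DG", ]), "2DG")
  expect_error(galactolytic_capacity(data.frame(phase = "lunch", ecar = 1)),
               "Unknown ECAR phase")
})

test_that("percent-of-baseline normalisation maps baseline to 100 and inverts", {
  tr <- data.frame(phase = rep(c("baseline", "galactose", "oligomycin", "2DG"),
                               each = 4),
                   ecar = c(10, 10, 10, 10, 12, 13, 12, 13,
                            25, 26, 24, 25, 5, 5, 5, 5))
  norm <- normalize_ecar_percent(tr)
  expect_equal(mean(norm$ecar[norm$phase == "baseline"]), 100)
  expect_equal(norm$ecar[9], 250)
  expect_equal(denormalize_ecar(norm)$ecar, tr$ecar)
  flat <- tr; flat$ecar <- 10
  expect_true(all(normalize_ecar_percent(flat)$ecar == 100))
  zero <- tr; zero$ecar[tr$phase == "baseline"] <- 0
  expect_error(normalize_ecar_percent(zero), "positive")
})

test_that("noiseless plate generation round-trips planted activities", {
  acts <- data.frame(sample_id = c("II.3", "CTRL"), ppi_mM = 0.1,
                     activity = c(0.21, 1.03), protein_mg = 0.05, minutes = 30)
  plate <- generate_plate(acts, slope = 0.2, intercept = 0.05, noise_sd = 0,
                          seed = 2L)
  res <- ppa_activity_table(plate)
  expect_equal(res$curve$slope, 0.2)
  got <- res$activities[order(res$activities$sample_id), ]
  expect_equal(got$activity, c(1.03, 0.21), tolerance = 1e-9)
  expect_equal(got$sem, c(0, 0))
  expect_false(any(got$flagged))
  # zero planted activity gives wells at blank + curve intercept
  acts0 <- data.frame(sample_id = "NULL0", ppi_mM = 0.05, activity = 0,
                      protein_mg = 0.05, minutes = 30)
  plate0 <- generate_plate(acts0, slope = 0.2, intercept = 0, noise_sd = 0)
  w <- plate0[plate0$role == "sample", ]
  b <- plate0[plate0$role == "blank", ]
  expect_true(all(w$absorbance == b$absorbance))
  res0 <- ppa_activity_table(plate0)
  expect_equal(res0$activities$activity, 0)
})

test_that("noisy plate recovery is unbiased within 3 SE over seeds", {
  acts <- data.frame(sample_id = "S", ppi_mM = 0.1, activity = 0.8,
                     protein_mg = 0.05, minutes = 30, n_replicates = 5)
  est <- sapply(1:100, function(s) {
    plate <- generate_plate(acts, noise_sd = 0.005, seed = s)
    ppa_activity_table(plate)$activities$activity
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.8), 3 * se)
})

test_that("plate and flux tables round-trip through their readers", {
  acts <- data.frame(sample_id = "S", ppi_mM = 0.1, activity = 0.5,
                     protein_mg = 0.05, minutes = 30)
  plate <- generate_plate(acts, noise_sd = 0.002, seed = 4L)
  pf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(plate, pf)
  expect_equal(as.data.frame(read_plate(pf)), as.data.frame(plate),
               tolerance = 1e-12)
  tr <- generate_flux(c(10, 12, 30, 5), noise_sd = 0.5, seed = 4L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tr, tf)
  expect_equal(as.data.frame(read_flux(tf)), as.data.frame(tr),
               tolerance = 1e-12)
})

test_that("synthetic flux traces carry the planted phase structure", {
  tr <- generate_flux(c(10, 12, 30, 5), noise_sd = 0, seed = 1L)
  expect_equal(nrow(tr), 16)
  expect_equal(unname(table(tr$phase)[c("baseline", "galactose",
                                        "oligomycin", "2DG")]),
               rep(4L, 4), ignore_attr = TRUE)
  expect_equal(diff(tr$timepoint_min), rep(9, 15))
  expect_equal(galactolytic_capacity(tr), 25)
  flat <- generate_flux(rep(8, 4), noise_sd = 0, seed = 1L)
  expect_equal(galactolytic_capacity(flat), 0)
  # noisy capacity lands within 3 SE of the planted difference
  caps <- sapply(1:100, function(s)
    galactolytic_capacity(generate_flux(c(10, 12, 30, 5), noise_sd = 2,
                                        seed = s)))
  se <- sd(caps) / sqrt(length(caps))
  expect_lt(abs(mean(caps) - 25), 3 * se)
  expect_error(generate_flux(c(1, 2)), "length 4")
})
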