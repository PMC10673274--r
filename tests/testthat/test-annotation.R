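test_that("a peak at the theoretical adduct mass matches with zero ppm error", {
  ref <- dbs_reference()
  galactitol <- ref$neutral_mass[ref$metabolite_id == "HMDB0000107"]
  peaks <- make_peaks(compute_adduct_mz(galactitol, "[M-H]-"))
  m <- match_peaks(peaks, ref)
  expect_equal(nrow(m), 1)
  expect_equal(m$metabolite_id, "HMDB0000107")
  expect_equal(m$adduct, "[M-H]-")
  expect_equal(m$ppm_error, 0)
})

test_that("the ppm window is inclusive at 5 ppm and rejects beyond it", {
  ref <- make_reference(200)
  theo <- compute_adduct_mz(200, "[M-H]-")
  inside <- match_peaks(make_peaks(theo * (1 + 4.9e-6)), ref)
  outside <- match_peaks(make_peaks(theo * (1 + 5.1e-6)), ref)
  expect_equal(nrow(inside), 1)
  expect_equal(nrow(outside), 0)
  # at the boundary the decision follows the <= inequality on the computed
  # ppm error, whatever floating rounding the construction produced
  edge_mz <- theo * (1 + 5e-6)
  edge_ppm <- (edge_mz - theo) / theo * 1e6
  at_edge <- match_peaks(make_peaks(edge_mz), ref)
  expect_equal(nrow(at_edge), as.integer(edge_ppm <= 5))
  expect_equal(inside$ppm_error, 4.9, tolerance = 1e-6)
})

test_that("windowed matching equals the exhaustive all-pairs oracle", {
  ad <- default_adducts()
  for (seed in 1:20) {
    set.seed(seed)
    ref <- make_reference(runif(20, 80, 550))
    # random peaks plus peaks planted near the 5 ppm boundary
    theo <- compute_adduct_mz(sample(ref$neutral_mass, 5), "[M-H]-")
    mz <- c(runif(40, 70, 600),
            theo * (1 + sample(c(-5.2, -5, -4.8, 4.8, 5, 5.2), 5,
                               replace = TRUE) * 1e-6))
    peaks <- make_peaks(mz, intensity = seq_along(mz))
    expect_equal(sort_matches(match_peaks(peaks, ref, ad, 5)),
                 sort_matches(brute_force_match(peaks, ref, ad, 5)))
  }
})

test_that("matching is restricted to the peak list's polarity", {
  ref <- make_reference(200)
  theo_pos <- compute_adduct_mz(200, "[M+H]+")
  m <- match_peaks(make_peaks(theo_pos, polarity = "negative"), ref)
  expect_equal(nrow(m), 0)
  m2 <- match_peaks(make_peaks(theo_pos, polarity = "positive"), ref)
  expect_equal(m2$adduct, "[M+H]+")
  expect_error(match_peaks(make_peaks(200), ref[0, ]), "Empty")
})

test_that("shrinking the ppm tolerance never adds matches", {
  set.seed(42)
  ref <- make_reference(runif(30, 80, 550))
  peaks <- make_peaks(runif(200, 70, 600))
  tols <- c(10, 5, 2, 1, 0.5)
  counts <- sapply(tols, function(t) nrow(match_peaks(peaks, ref, ppm_tol = t)))
  expect_true(all(diff(counts) <= 0))
})

test_that("identical-mass records merge into one '|'-joined annotation group", {
  ref <- dbs_reference()
  g <- group_isobars(ref)
  pair <- g[g$n_members > 1, ]
  expect_equal(nrow(pair), 1)
  expect_equal(pair$display_name, "N-Acetylglutamine | Glycyl-Hydroxyproline")
  expect_setequal(pair$member_ids[[1]], c("HMDB0006029", "HMDB0011173"))
  # everything else in the bundled reference is a singleton
  expect_equal(sum(g$n_members), nrow(ref))
})

test_that("isobar merging is single-linkage over near-coincident chains", {
  # A ~ B and B ~ C within 5 ppm, but A !~ C: one merged group
  base <- 300
  ref <- make_reference(c(base, base * (1 + 4e-6), base * (1 + 8e-6)))
  g <- group_isobars(ref, ppm_tol = 5)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_members, 3)
  # transitive-closure oracle over all pairs confirms one component
  mz <- outer(ref$neutral_mass, default_adducts()$mass_shift, "+")
  adj <- matrix(FALSE, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    adj[i, j] <- all(abs(mz[i, ] - mz[j, ]) / ((mz[i, ] + mz[j, ]) / 2) * 1e6 <= 5)
  }
  for (k in 1:3) adj <- adj | (adj %*% adj > 0)  # closure
  expect_true(all(adj))

  # well-separated masses stay singletons
  g2 <- group_isobars(make_reference(c(100, 200, 300)), ppm_tol = 5)
  expect_equal(g2$n_members, c(1, 1, 1))
})

test_that("adduct intensities sum within injection and average over injections", {
  ref <- make_reference(200)
  neg <- compute_adduct_mz(200, "[M-H]-")
  pos <- compute_adduct_mz(200, "[M+H]+")
  peaks <- dplyr::bind_rows(
    make_peaks(neg, intensity = 100, injection = 1L, polarity = "negative"),
    make_peaks(pos, intensity = 50, injection = 1L, polarity = "positive")
  )
  samples <- assemble_samples(peaks, c(S1 = "control"))
  mat <- summed_intensities(samples, ref)
  expect_equal(unname(mat$intensity[1, "S1"]), 150)

  # a metabolite with no matching peaks keeps a zero cell
  ref2 <- make_reference(c(200, 450))
  mat2 <- summed_intensities(samples, ref2)
  expect_equal(unname(mat2$intensity[, "S1"]), c(150, 0))

  # mean over triplicate injections of per-injection sums
  peaks3 <- dplyr::bind_rows(
    make_peaks(neg, intensity = 90, injection = 1L),
    make_peaks(neg, intensity = 110, injection = 2L),
    make_peaks(neg, intensity = 130, injection = 3L)
  )
  mat3 <- summed_intensities(assemble_samples(peaks3, c(S1 = "control")), ref)
  expect_equal(unname(mat3$intensity[1, "S1"]), 110)
  mat3m <- summed_intensities(assemble_samples(peaks3, c(S1 = "control")),
                              ref, reducer = "median")
  expect_equal(unname(mat3m$intensity[1, "S1"]), 110)
})

test_that("summed intensity is additive under peak splitting", {
  ref <- make_reference(200)
  theo <- compute_adduct_mz(200, "[M-H]-")
  whole <- make_peaks(theo, intensity = 100)
  split <- make_peaks(c(theo * (1 - 1e-6), theo * (1 + 1e-6)),
                      intensity = c(60, 40))
  m1 <- summed_intensities(assemble_samples(whole, c(S1 = "control")), ref)
  m2 <- summed_intensities(assemble_samples(split, c(S1 = "control")), ref)
  expect_equal(m1$intensity, m2$intensity)
})

test_that("annotation is invariant under peak and injection reordering", {
  ref <- dbs_reference()
  coh <- generate_cohort(cohort_spec(n_controls = 3, n_decoy_peaks = 30,
                                     seed = 5L), ref)
  mat <- summed_intensities(assemble_samples(coh$peaks, coh$roles), ref)
  set.seed(99)
  shuffled <- coh$peaks[sample(nrow(coh$peaks)), ]
  shuffled$injection <- c(2L, 3L, 1L)[shuffled$injection]
  mat2 <- summed_intensities(assemble_samples(shuffled, coh$roles), ref)
  expect_equal(mat2$intensity, mat$intensity)
})

test_that("exogenous- and drug-only annotation groups are excluded", {
  ref <- dplyr::bind_rows(
    make_reference(seq(100, by = 10, length.out = 13), prefix = "ENDO"),
    make_reference(seq(300.5, by = 10, length.out = 7), origin = "drug",
                   prefix = "DRUG")
  )
  peaks <- make_peaks(compute_adduct_mz(ref$neutral_mass, "[M-H]-"))
  mat <- summed_intensities(assemble_samples(peaks, c(S1 = "control")), ref)
  expect_equal(nrow(mat$intensity), 20)
  kept <- filter_exogenous(mat, ref)
  expect_equal(nrow(kept$intensity), 13)
  expect_true(all(grepl("^ENDO", purrr::map_chr(kept$groups$member_ids, 1))))

  # a mixed endogenous/exogenous isomer group is retained
  ref_mix <- dplyr::bind_rows(
    make_reference(250, prefix = "ENDO"),
    make_reference(250, origin = "exogenous", prefix = "EXO")
  )
  pk <- make_peaks(compute_adduct_mz(250, "[M-H]-"))
  mixed <- filter_exogenous(
    summed_intensities(assemble_samples(pk, c(S1 = "control")), ref_mix),
    ref_mix
  )
  expect_equal(nrow(mixed$intensity), 1)
  expect_equal(mixed$groups$n_members, 2)
})
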