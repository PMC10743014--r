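test_that("bundled specs encode the study's haplotype architecture", {
  spec <- promoter_cohort_spec("ATG16L1")
  expect_equal(nrow(spec$haplotypes), 7)
  expect_equal(spec$freqs$control, c(0.250, 0.625, 0.125, 0, 0, 0, 0))
  # control vector reproduces the observed control allele frequencies
  ctrl_alt <- colSums(spec$freqs$control *
                        (spec$haplotypes == rep(spec$panel$loci$alt,
                                                each = 7)))
  expect_equal(unname(ctrl_alt), c(0.750, 0.125, 0, 0),
               tolerance = 1e-12)
  # patient vector satisfies all four allele-frequency constraints
  pat <- spec$freqs$patient
  h <- spec$haplotypes
  expect_equal(sum(pat[h[, "rs1816753"] == "T"]), 0.232, tolerance = 1e-3)
  expect_equal(sum(pat[h[, "rs12476635"] == "C"]), 0.146, tolerance = 1e-3)
  expect_equal(sum(pat[h[, "rs74599577"] == "T"]), 0.024, tolerance = 1e-3)
  expect_equal(sum(pat[h[, "rs77820970"] == "T"]), 0.220, tolerance = 1e-3)
  expect_equal(sum(pat), 1, tolerance = 1e-9)
  expect_equal(unname(spec$n), c(28L, 56L))

  spec5 <- promoter_cohort_spec("ATG5")
  expect_equal(nrow(spec5$haplotypes), 2)
  expect_equal(unname(spec5$haplotypes[1, ]), c("T", "G"))
  expect_equal(unname(spec5$haplotypes[2, ]), c("C", "A"))
  expect_equal(spec5$freqs$control, c(0.518, 0.482))
  expect_equal(spec5$freqs$patient, c(0.536, 0.464))
})

test_that("generation is deterministic and respects degenerate specs", {
  spec <- promoter_cohort_spec("ATG16L1")
  a <- generate_cohort(spec, seed = 42)
  b <- generate_cohort(spec, seed = 42)
  expect_identical(a$a1, b$a1)
  expect_identical(a$a2, b$a2)
  c2 <- generate_cohort(spec, seed = 43)
  expect_false(identical(a$a1, c2$a1))
  # single haplotype at frequency 1 -> everyone homozygous everywhere
  mono <- cohort_spec(atg5_panel(), atg5_haplotypes(),
                      freqs = list(control = c(1, 0), patient = c(1, 0)),
                      n = c(control = 5L, patient = 5L))
  cc <- generate_cohort(mono, seed = 1)
  expect_true(all(cc$a1 == cc$a2))
  expect_true(all(cc$a1[, 1] == "T") && all(cc$a1[, 2] == "G"))
})

test_that("large patient cohorts recover the spec allele frequency", {
  spec <- promoter_cohort_spec("ATG16L1")
  big <- cohort_spec(spec$panel, spec$haplotypes,
                     freqs = list(control = spec$freqs$patient,
                                  patient = spec$freqs$patient),
                     n = c(control = 2L, patient = 5000L))
  cc <- generate_cohort(big, seed = 2024)
  af <- allele_freqs(cc, "rs77820970", group = "patient")
  t_freq <- af$freq[af$allele == "T"]
  se <- sqrt(0.220 * 0.780 / (2 * 5000))
  expect_lt(abs(t_freq - 0.220), 3 * se)
})

test_that("generated genotypes sit in Hardy-Weinberg proportions", {
  spec <- promoter_cohort_spec("ATG16L1")
  big <- cohort_spec(spec$panel, spec$haplotypes,
                     freqs = list(control = spec$freqs$patient,
                                  patient = spec$freqs$patient),
                     n = c(control = 2L, patient = 5000L))
  cc <- generate_cohort(big, seed = 7)
  for (rs in c("rs1816753", "rs77820970")) {
    gc <- genotype_counts(cc, rs, "patient")
    n <- sum(gc)
    p <- (2 * gc[["n_rr"]] + gc[["n_ra"]]) / (2 * n)
    expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chi2 <- sum((gc - expected)^2 / expected)
    expect_lt(chi2, stats::qchisq(0.999, df = 1))
  }
})

test_that("patient-exclusive haplotypes never reach controls", {
  spec <- promoter_cohort_spec("ATG16L1")
  for (s in 1:5) {
    cc <- generate_cohort(spec, seed = s)
    ctrl <- cc$group == "control"
    # hap4..hap7 all carry T at rs77820970 (and hap5 T at rs74599577)
    expect_true(all(cc$a1[ctrl, "rs77820970"] == "C"))
    expect_true(all(cc$a2[ctrl, "rs77820970"] == "C"))
    expect_true(all(cc$a1[ctrl, "rs74599577"] == "A"))
  }
})

test_that("expected burden matches hand-computed values", {
  spec <- promoter_cohort_spec("ATG16L1")
  # control group, wild-type reference: 2*(0.625*1 + 0.125*2) = 1.75
  expect_equal(unname(expected_burden(spec, "hap1")["control"]), 1.75)
  # control group, modal-haplotype reference: 2*(0.250*1 + 0.125*1) = 0.75
  expect_equal(unname(expected_burden(spec, "hap2")["control"]), 0.75)
  # a single fixed haplotype identical to the reference scores zero
  mono <- cohort_spec(atg5_panel(), atg5_haplotypes(),
                      freqs = list(control = c(1, 0), patient = c(1, 0)),
                      n = c(control = 5L, patient = 5L))
  expect_equal(unname(expected_burden(mono, "hap1")), c(0, 0))
})

test_that("phasing recovers spec frequencies on a large cohort", {
  spec <- promoter_cohort_spec("ATG16L1")
  big <- cohort_spec(spec$panel, spec$haplotypes,
                     freqs = list(control = spec$freqs$patient,
                                  patient = spec$freqs$patient),
                     n = c(control = 2L, patient = 5000L))
  cc <- generate_cohort(big, seed = 99)
  fit <- em_phase(cc, restarts = 3, seed = 1)
  est_key <- apply(fit$haplotypes, 1, paste, collapse = "")
  true_key <- apply(spec$haplotypes, 1, paste, collapse = "")
  est <- fit$freq[match(true_key, est_key)]
  est[is.na(est)] <- 0
  expect_lt(max(abs(est - spec$freqs$patient)), 0.02)
})
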