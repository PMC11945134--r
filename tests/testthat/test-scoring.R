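test_that("recovery_rate reproduces the published worked examples", {
  # BC1 plant scored at 108 markers, 82 homozygous recurrent, 26 het
  r <- recovery_rate(c(rep("RR", 82), rep("RD", 26)), id = "BC1-27")
  expect_equal(r$I, 108)
  expect_equal(r$S, 82)
  expect_equal(r$Rg, 87.96296, tolerance = 1e-6)
  # BC2 plant scored at 87 markers, 79 homozygous recurrent
  r2 <- recovery_rate(c(rep("RR", 79), rep("RD", 8)))
  expect_equal(r2$Rg, 95.4023, tolerance = 1e-5)
  # degenerate corners
  expect_equal(recovery_rate(rep("RR", 50))$Rg, 100)
  expect_equal(recovery_rate(rep("RD", 50))$Rg, 50)
  expect_error(recovery_rate(c(NA, NA), id = "x9"), "x9")
  expect_error(recovery_rate(c("RR", "XX")), "invalid genotype")
})

test_that("recovery_rate equals (I+S)/(2I) when dd = 0 and handles dd", {
  set.seed(101)
  for (k in 1:30) {
    I <- sample(5:150, 1)
    calls <- sample(c("RR", "RD"), I, replace = TRUE)
    r <- recovery_rate(calls)
    expect_equal(r$Rg, (r$I + r$S) / (2 * r$I) * 100)
    expect_equal(r$I, r$S + r$het + r$dd)
    # invariant to marker order
    expect_equal(recovery_rate(sample(calls))$Rg, r$Rg)
  }
  # with donor homozygotes the allele-counting form applies
  r <- recovery_rate(c(rep("RR", 5), rep("RD", 3), rep("DD", 2)))
  expect_equal(r$Rg, (2 * 5 + 3) / 20 * 100)
  expect_lt(r$Rg, (10 + 5) / 20 * 100)   # backcross formula would overstate
  # missing calls shrink I
  r2 <- recovery_rate(c("RR", "RD", NA, NA))
  expect_equal(r2$I, 2)
})

test_that("adding an RR call never decreases Rg (monotonicity)", {
  set.seed(33)
  for (k in 1:25) {
    calls <- sample(c("RR", "RD", "DD"), sample(3:60, 1), replace = TRUE)
    expect_gte(recovery_rate(c(calls, "RR"))$Rg, recovery_rate(calls)$Rg)
  }
})

test_that("chi_square_1to1 matches the brute-force statistic", {
  t0 <- chi_square_1to1(112, 112)
  expect_equal(t0$chi2, 0)
  expect_true(t0$pass)

  t1 <- chi_square_1to1(111, 113)
  expect_equal(t1$chi2, 2 * 1 / 112)
  expect_true(t1$pass)

  t2 <- chi_square_1to1(150, 50)
  expect_equal(t2$chi2, 50)
  expect_false(t2$pass)

  # exhaustive agreement with the oracle for n1 + n2 <= 200
  for (tot in c(1, 2, 7, 50, 137, 200)) {
    for (n1 in 0:tot) {
      expect_equal(chi_square_1to1(n1, tot - n1)$chi2,
                   oracle_chi2_1to1(n1, tot - n1))
    }
  }
  # Yates correction shrinks deviations by 0.5
  expect_equal(chi_square_1to1(111, 113, yates = TRUE)$chi2,
               2 * 0.25 / 112)
  expect_error(chi_square_1to1(0, 0), "> 0")
})

test_that("select_individuals applies strict thresholds in stable order", {
  t1 <- bc1_recovery_table()
  rep1 <- data.frame(id = t1$plant, Rg = t1$recovery)
  # the published BC1 table lists exactly the plants above 80%
  expect_equal(length(select_individuals(rep1, 80)), 18)
  expect_equal(length(select_individuals(rep1, 100)), 0)
  # strictness: a plant at exactly the threshold is excluded
  expect_false("BC1-35" %in% select_individuals(rep1, 80.55))

  t2 <- bc2_recovery_table()
  rep2 <- data.frame(id = t2$plant, Rg = t2$recovery)
  expect_equal(select_individuals(rep2, 94.5),
               c("BC2-36-12", "BC2-5-15"))
  # phenotype flag vetoes
  flag <- rep2$id != "BC2-36-12"
  expect_equal(select_individuals(rep2, 94.5, flag), "BC2-5-15")
  expect_error(select_individuals(rep2, 90, TRUE), "align")
})

test_that("homozygosity verdicts follow the 0.75^n null", {
  h <- homozygosity_by_progeny(rep(TRUE, 20))
  expect_equal(h$verdict, "homozygous")
  expect_equal(h$p_null, 0.75^20)

  expect_equal(homozygosity_by_progeny(c(rep(TRUE, 15), rep(FALSE, 5)))$verdict,
               "segregating")
  # all carriers but too few progeny: verdict withheld
  expect_equal(homozygosity_by_progeny(TRUE)$verdict, "inconclusive")
  expect_equal(homozygosity_by_progeny(rep(TRUE, 11))$verdict, "homozygous")
  expect_equal(homozygosity_by_progeny(rep(TRUE, 10))$verdict, "inconclusive")
  expect_error(homozygosity_by_progeny(logical(0)), "no progeny")
})

test_that("ddct computes 2^-ddCt and its symmetry", {
  expect_equal(ddct(25, 25, 0), 1)
  expect_equal(ddct(22, 25, 0), 8)
  expect_equal(ddct(20, 20, -1), 0.5)
  # ddCt = calibrator dCt => 1
  expect_equal(ddct(24.3, 21.1, 3.2), 1)
  # inversion symmetry: ddct(a, b, c) * ddct(b, a, -c) = 1
  set.seed(8)
  a <- runif(20, 15, 35); b <- runif(20, 15, 35); c0 <- runif(20, -3, 3)
  expect_equal(ddct(a, b, c0) * ddct(b, a, -c0), rep(1, 20))
  expect_error(ddct(Inf, 20), "finite")
})

test_that("the marker-count inversion oracle recovers published counts", {
  t1 <- infer_marker_count(bc1_recovery_table()$recovery, I_range = 90:130)
  expect_equal(t1$best_I, 108)
  expect_true(t1$all_explained)
  # uniqueness: no other I in 90..130 explains every entry
  full <- t1$coverage$I[t1$coverage$n_explained == 18]
  expect_equal(full, 108)

  t2 <- infer_marker_count(bc2_recovery_table()$recovery)
  expect_equal(t2$best_I, 87)
  # per-plant resolution near the mode
  rc <- resolve_marker_count(95.40, mode_I = t2$best_I)
  expect_equal(rc$I, 87)
  expect_equal(rc$S, 79)
  expect_error(resolve_marker_count(33.3, 87), "no integer")
})
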