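map10 <- make_maize_like_map()
locus8 <- list(chrom = "chr8", pos_cM = map_chrom_length(map10, "chr8") / 2)

test_that("gametes always tile the map with alternating ancestry", {
  set.seed(41)
  f1 <- f1_individual(map10)
  cur <- f1
  for (k in 1:200) {
    g <- meiosis(cur, map10)
    expect_true(oracle_hap_tiles(g, map10))
    # chain crosses to exercise mosaic parents, not just the F1
    cur <- diploid_individual(g, meiosis(cur, map10))
  }
})

test_that("homozygous parents give uniform gametes", {
  set.seed(4)
  rp <- recurrent_individual(map10)
  g <- meiosis(rp, map10)
  expect_equal(donor_fraction(g, map10), 0)
  dp <- donor_individual(map10)
  expect_equal(donor_fraction(meiosis(dp, map10), map10), 1)
})

test_that("recombinant fraction at 10 cM matches Haldane", {
  set.seed(50)
  map1 <- make_maize_like_map(1, lengths_cM = 50)
  f1 <- f1_individual(map1)
  n <- 4000
  rec <- vapply(seq_len(n), function(k) {
    g <- meiosis(f1, map1)
    ancestry_at(g, "chr1", 20) != ancestry_at(g, "chr1", 30)
  }, logical(1))
  r_hald <- (1 - exp(-2 * 0.10)) / 2          # 0.0906
  expect_lt(abs(mean(rec) - r_hald), 4 * sqrt(r_hald * (1 - r_hald) / n))
})

test_that("expected donor fraction halves each backcross generation", {
  set.seed(60)
  n <- 250
  fr <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    ind <- f1_individual(map10)
    for (g in 1:3) {
      ind <- backcross(ind, map10, 1)[[1]]
      fr[k, g] <- donor_fraction(ind, map10)
    }
  }
  for (g in 1:3)
    expect_lt(abs(mean(fr[, g]) - 2^-(g + 1)), 0.012)
})

test_that("selfing preserves the expected donor fraction", {
  set.seed(61)
  f1 <- f1_individual(map10)
  fr <- vapply(self_cross(f1, map10, 250), donor_fraction, numeric(1),
               map = map10)
  expect_lt(abs(mean(fr) - 0.5), 0.012)
})

test_that("carrier states and foreground selection are consistent", {
  f1 <- f1_individual(map10)
  expect_equal(carrier_state(f1, locus8), "hemizygous")
  expect_equal(carrier_state(recurrent_individual(map10), locus8), "absent")
  expect_equal(carrier_state(donor_individual(map10), locus8), "homozygous")

  # homozygous carriers are all retained
  homo <- replicate(10, donor_individual(map10), simplify = FALSE)
  fg <- foreground_select(homo, locus8)
  expect_equal(fg$n_positive, 10)
  expect_equal(length(fg$carriers), 10)

  # selfed hemizygote: carrier fraction expectation 3/4
  set.seed(70)
  f2 <- self_cross(f1, map10, 600)
  fg2 <- foreground_select(f2, locus8)
  expect_lt(abs(fg2$n_positive / 600 - 0.75), 4 * sqrt(0.75 * 0.25 / 600))

  # backcross: expectation 1/2, and the chi-square passes under the null
  set.seed(71)
  bc <- backcross(f1, map10, 600)
  fg3 <- foreground_select(bc, locus8)
  expect_lt(abs(fg3$n_positive / 600 - 0.5), 4 * sqrt(0.25 / 600))
  expect_s3_class(fg3$test, "segregation_test")
})

test_that("genotyping at markers recodes ancestry", {
  panel <- evenly_spaced_markers(map10, 20)
  expect_true(all(genotype_at_markers(recurrent_individual(map10), panel)
                  == "RR"))
  expect_true(all(genotype_at_markers(f1_individual(map10), panel) == "RD"))
  g <- genotype_at_markers(donor_individual(map10), panel)
  expect_true(all(g == "DD"))
  set.seed(80)
  gm <- genotype_at_markers(f1_individual(map10), panel, missing_rate = 0.3)
  expect_gt(sum(is.na(gm)), 10)
  bad_panel <- data.frame(marker = "m", chrom = "chr1", pos_cM = 9999)
  expect_error(genotype_at_markers(f1_individual(map10), bad_panel), "off")
})

test_that("marker-based Rg is an unbiased estimate of genome recovery", {
  set.seed(90)
  panel <- evenly_spaced_markers(map10, 20)
  f1 <- f1_individual(map10)
  pop <- backcross(f1, map10, 300)
  truth <- vapply(pop, function(x) (1 - donor_fraction(x, map10)) * 100,
                  numeric(1))
  marker <- recovery_report(genotype_population(pop, panel))$Rg
  expect_lt(abs(mean(marker - truth)), 0.5)      # paired, so tight
  expect_gt(stats::cor(marker, truth), 0.95)
})

test_that("offspring recovery expectation is (parent + 100)/2 both ways", {
  set.seed(95)
  panel <- evenly_spaced_markers(map10, 20)
  f1 <- f1_individual(map10)
  parent <- backcross(f1, map10, 1)[[1]]
  prep <- recovery_rate(genotype_at_markers(parent, panel), id = parent$id)
  # full map simulation
  off <- backcross(parent, map10, 400)
  full <- recovery_report(genotype_population(off, panel))$Rg
  # shortcut on the same (I, S)
  short <- marker_transmission_shortcut(prep$I, prep$S, 400)$Rg
  expected <- (prep$Rg + 100) / 2
  expect_lt(abs(mean(full) - expected), 0.5)
  expect_lt(abs(mean(short) - expected), 0.5)
  expect_lt(abs(mean(full) - mean(short)), 0.8)
})

test_that("simulation is deterministic under a fixed seed", {
  r1 <- simulate_bc1_recovery(n_positive = 20, seed = 123)
  r2 <- simulate_bc1_recovery(n_positive = 20, seed = 123)
  expect_identical(r1$reports, r2$reports)
  a <- simulate_backcross_population(f1_individual(map10), map10, 5,
                                     seed = 9, require_transgene = FALSE)
  b <- simulate_backcross_population(f1_individual(map10), map10, 5,
                                     seed = 9, require_transgene = FALSE)
  expect_equal(a, b)
})
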