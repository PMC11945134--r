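test_that("filter_gq is strict at the threshold and drops missing GQ", {
  s <- data.frame(site = letters[1:6],
                  gq = c(31L, 30L, 29L, 99L, NA, 45L))
  expect_warning(out <- filter_gq(s, quiet = TRUE), "missing GQ")
  expect_identical(out$site, c("a", "d", "f"))
  # empty in, empty out
  expect_equal(nrow(filter_gq(s[0, ], quiet = TRUE)), 0)
  # mixed fixture: 4 of 10 above threshold
  s2 <- data.frame(site = paste0("s", 1:10),
                   gq = c(10, 31, 30, 50, 28, 90, 30, 22, 5, 40))
  expect_equal(nrow(filter_gq(s2, quiet = TRUE)), 4)
})

test_that("filter_length_diff keeps the closed [30, 50] interval", {
  s <- data.frame(length_diff_bp = c(29L, 30L, 50L, 51L, 0L))
  out <- filter_length_diff(s, quiet = TRUE)
  expect_identical(out$length_diff_bp, c(30L, 50L))
  # 80-site fixture with every diff 1..80: 21 survivors
  s2 <- data.frame(length_diff_bp = 1:80)
  expect_equal(nrow(filter_length_diff(s2, quiet = TRUE)), 21)
})

test_that("gc_content counts G+C over ACGT and rejects bad input", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("ATGCATGCGC"), 0.6)
  expect_equal(gc_content("atgc"), 0.5)    # case-insensitive
  expect_error(gc_content(""), "non-empty")
  expect_error(gc_content("ACGN"), "non-ACGT")
})

test_that("filter_gc keeps the closed [0.55, 0.60] interval", {
  s <- data.frame(flank_gc = c(0.52, 0.55, 0.57, 0.60, 0.61))
  out <- filter_gc(s, quiet = TRUE)
  expect_equal(out$flank_gc, c(0.55, 0.57, 0.60))
})

test_that("extract_flank returns in-bounds windows and drops end sites", {
  set.seed(2)
  chrom <- rand_dna(10000)
  fl <- extract_flank(1000, chrom)
  expect_gte(nchar(fl$seq), 120)
  expect_lte(nchar(fl$seq), 150)
  expect_identical(fl$seq, substr(chrom, fl$start, fl$end))
  expect_true(fl$start <= 1000 && fl$end >= 1000)
  # determinism
  expect_identical(fl, extract_flank(1000, chrom))
  # near an end the window shifts but stays in bounds
  fl2 <- extract_flank(30, chrom)
  expect_equal(fl2$start, 1)
  # a site on a short contig with too little sequence is dropped
  expect_null(extract_flank(10, substr(chrom, 1, 100)))
})

test_that("has_repeat matches the brute-force tandem scan", {
  set.seed(31)
  # spec'd positives
  expect_true(has_repeat(paste0(rand_dna(60), strrep("A", 12), rand_dna(60))))
  expect_true(has_repeat(paste0(rand_dna(60), strrep("AT", 6), rand_dna(60))))
  # random + engineered cases against the oracle
  cases <- c(
    replicate(40, rand_dna(80)),
    replicate(10, paste0(rand_dna(30), strrep(rand_dna(3), 5), rand_dna(30))),
    replicate(10, paste0(rand_dna(30), strrep(rand_dna(6), 2), rand_dna(30))),
    "ACGTACGTACG",                       # period 4 but span 11 < 12
    strrep("ACGTG", 3))                  # period 5, span 15
  got <- vapply(cases, has_repeat, logical(1), USE.NAMES = FALSE)
  want <- vapply(cases, oracle_has_repeat, logical(1), USE.NAMES = FALSE)
  expect_identical(got, want)
  expect_true(any(want) && !all(want))   # the case set exercises both sides
})

test_that("divergence_class is exactly the three-case envelope", {
  grid <- expand.grid(diff = 0:5, mm = 0:5)
  hand <- with(grid, (diff == 0 & mm <= 2) | (diff == 1 & mm <= 1) |
                     (diff == 2 & mm == 0))
  expect_identical(divergence_class(grid$diff, grid$mm), hand)
  expect_error(divergence_class(-1, 0), ">= 0")
})

test_that("compute_divergence recovers planted divergence", {
  set.seed(77)
  ref <- rand_dna(400)
  flank <- substr(ref, 101, 250)
  # identical window
  expect_equal(compute_divergence(flank, ref),
               list(length_diff = 0, mismatches = 0))
  # one substitution
  sub1 <- flank
  substr(sub1, 75, 75) <- if (substr(flank, 75, 75) == "A") "C" else "A"
  expect_equal(compute_divergence(sub1, ref),
               list(length_diff = 0, mismatches = 1))
  # planted mutations agree with the DP edit-distance oracle
  for (k in 1:15) {
    n_sub <- sample(0:2, 1)
    del <- sample(0:2, 1)
    f <- substr(ref, 101, 250)
    if (del > 0) f <- paste0(substr(f, 1, 60), substr(f, 61 + del, 150))
    pos <- sample(setdiff(5:140, 58:64), n_sub)
    for (p in pos) {
      old <- substr(f, p, p)
      substr(f, p, p) <- setdiff(c("A", "C", "G", "T"), old)[sample(3, 1)]
    }
    dv <- compute_divergence(f, ref)
    expect_equal(dv$length_diff, del)
    expect_equal(dv$mismatches, n_sub)
    expect_equal(oracle_fitting_edit_distance(f, ref), n_sub + del)
  }
  # garbage fails the score floor
  expect_null(compute_divergence(rand_dna(150), ref))
})

test_that("the screening cascade matches its engineered ground truth", {
  fx <- make_cascade_fixture()
  out <- screen_candidates(fx$sites, quiet = TRUE)
  expect_identical(out$site, fx$sites$site[fx$truth])
  expect_equal(nrow(out), 7)
  log <- attr(out, "cascade_log")
  expect_equal(log$n_out, c(15, 12, 10, 8, 7))
  # contraction + order preservation at every stage
  expect_true(all(out$site %in% fx$sites$site))
  expect_false(is.unsorted(match(out$site, fx$sites$site)))
  # idempotence
  again <- screen_candidates(out, quiet = TRUE)
  expect_identical(again$site, out$site)
  # all-passing input is untouched
  pass <- fx$sites[fx$truth, ]
  expect_identical(screen_candidates(pass, quiet = TRUE)$site, pass$site)
})

test_that("greedy panel spacing reproduces the enumerated layout", {
  map1 <- make_maize_like_map(1, lengths_cM = 100)
  dense <- data.frame(site = paste0("c", 0:100), chrom = "chr1",
                      pos_cM = as.numeric(0:100))
  panel <- select_spaced_panel(dense, map1, spacing_cM = 20, quiet = TRUE)
  expect_equal(panel$pos_cM, c(0, 20, 40, 60, 80, 100))

  single <- dense[41, ]
  expect_equal(nrow(select_spaced_panel(single, map1, quiet = TRUE)), 1)

  expect_warning(empty <- select_spaced_panel(dense[0, ], map1, quiet = TRUE),
                 "empty")
  expect_equal(nrow(empty), 0)
})

test_that("a saturated candidate set on the default map gives ~108 markers", {
  m <- make_maize_like_map()
  dense <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    data.frame(chrom = m$chrom[i],
               pos_cM = as.numeric(0:floor(m$length_cM[i])))
  }))
  dense$site <- paste0("d", seq_len(nrow(dense)))
  panel <- select_spaced_panel(dense, m, spacing_cM = 20, quiet = TRUE)
  expect_equal(nrow(panel), sum(floor(m$length_cM / 20) + 1))
  expect_gte(nrow(panel), 100)
  expect_lte(nrow(panel), 110)
  # adjacent gaps within [spacing - tol, spacing + tol]
  for (ch in unique(panel$chrom)) {
    gaps <- diff(panel$pos_cM[panel$chrom == ch])
    expect_true(all(gaps >= 10 - 1e-9 & gaps <= 30 + 1e-9))
  }
})
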