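# Independent oracles used across test files. These deliberately re-derive
# quantities by brute force, not by calling the implementation under test.

# Fitting-alignment edit distance: whole `pattern` against the best window
# of `subject`, unit costs for substitution / insertion / deletion.
oracle_fitting_edit_distance <- function(pattern, subject) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  m <- length(p); n <- length(s)
  prev <- rep(0L, n + 1L)        # D[0, j] = 0: free start anywhere in subject
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    cur[1L] <- i
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j] + (p[i] != s[j]),  # sub / match
                         prev[j + 1L] + 1L,         # deletion from pattern
                         cur[j] + 1L)               # insertion
    }
    prev <- cur
  }
  min(prev)                       # free end anywhere in subject
}

# Brute-force tandem-repeat scan: TRUE iff some substring of length >=
# min_span is periodic with period k in [1, max_motif] and contains at
# least two full motif copies (length >= 2k).
oracle_has_repeat <- function(seq, max_motif = 6L, min_span = 12L) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  for (i in seq_len(max(0L, n - min_span + 1L))) {
    for (len in min_span:(n - i + 1L)) {
      sub <- s[i:(i + len - 1L)]
      for (k in seq_len(max_motif)) {
        if (2L * k > len) next
        if (all(sub[seq_len(len - k)] == sub[seq_len(len - k) + k]))
          return(TRUE)
      }
    }
  }
  FALSE
}

# Plain chi-square goodness of fit against 1:1.
oracle_chi2_1to1 <- function(n1, n2) {
  E <- (n1 + n2) / 2
  (n1 - E)^2 / E + (n2 - E)^2 / E
}

# Random DNA string.
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Tiling/alternation check for a haplotype against a map, independent of
# the package's internal validator.
oracle_hap_tiles <- function(hap, map) {
  for (i in seq_len(nrow(map))) {
    m <- hap[[map$chrom[i]]]
    if (nrow(m) == 0L) return(FALSE)
    if (abs(m[1, "start"]) > 1e-9) return(FALSE)
    if (abs(m[nrow(m), "end"] - map$length_cM[i]) > 1e-9) return(FALSE)
    if (nrow(m) > 1L) {
      if (any(abs(m[-1, "start"] - m[-nrow(m), "end"]) > 1e-9)) return(FALSE)
      if (any(m[-1, "anc"] == m[-nrow(m), "anc"])) return(FALSE)
    }
    if (any(m[, "end"] <= m[, "start"])) return(FALSE)
  }
  TRUE
}

# A small engineered candidate-site table with known per-filter ground
# truth. 20 sites; exactly 7 survive the full cascade (divergence columns
# used, no genome/reference alignment). Flanks are built repeat-free at a
# known GC, then repeats are injected where the fixture demands them.
make_cascade_fixture <- function() {
  # 90 bases, GC 52/90; blocks chosen so no 1-6 bp motif spans >= 12 bp
  gc_ok_flank <- function() {
    repeat {
      s <- rand_dna(150, gc = 0.575)
      if (!oracle_has_repeat(s) &&
          gc_content_chars(s) >= 0.55 && gc_content_chars(s) <= 0.60)
        return(s)
    }
  }
  gc_bad_flank <- function(gc) {
    repeat {
      s <- rand_dna(150, gc = gc)
      g <- gc_content_chars(s)
      if (!oracle_has_repeat(s) && (g < 0.55 || g > 0.60)) return(s)
    }
  }
  with_repeat <- function(s) {
    paste0(substr(s, 1, 60), strrep("AT", 7), substr(s, 75, 150))
  }
  set.seed(424242)
  n <- 20L
  # pass/fail design per site (TRUE = passes that filter); every failing
  # site fails exactly one filter, so per-stage survivor counts are
  # 20 -> 15 -> 12 -> 10 -> 8 -> 7
  gq_ok <- !seq_len(n) %in% c(4L, 8L, 12L, 16L, 20L)
  len_ok <- !seq_len(n) %in% c(1L, 5L, 13L)
  rep_ok <- !seq_len(n) %in% c(2L, 11L)
  gc_ok <- !seq_len(n) %in% c(9L, 17L)
  div_ok <- !seq_len(n) %in% 7L
  flanks <- vapply(seq_len(n), function(i) {
    s <- if (gc_ok[i]) gc_ok_flank() else gc_bad_flank(0.40)
    if (!rep_ok[i]) s <- with_repeat(s) else s
  }, character(1))
  sites <- data.frame(
    site = sprintf("fx%02d", seq_len(n)),
    chrom = "chr1",
    pos_cM = seq(2, 97, length.out = n),
    pos_bp = seq(2000, 97000, length.out = n),
    gq = ifelse(gq_ok, 45L, 30L),                         # 30 must drop
    length_diff_bp = ifelse(len_ok, 40L, 29L),
    flank_seq = flanks,
    length_diff_vs_ref = 1L,
    mismatches_vs_ref = ifelse(div_ok, 1L, 2L),           # (1,2) fails
    stringsAsFactors = FALSE)
  sites$flank_gc <- vapply(sites$flank_seq, gc_content_chars, numeric(1),
                           USE.NAMES = FALSE)
  truth <- gq_ok & len_ok & rep_ok & gc_ok & div_ok
  list(sites = sites, truth = truth,
       gq_ok = gq_ok, len_ok = len_ok, rep_ok = rep_ok,
       gc_ok = gc_ok, div_ok = div_ok)
}

gc_content_chars <- function(s) {
  v <- strsplit(s, "")[[1]]
  sum(v %in% c("G", "C")) / length(v)
}
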