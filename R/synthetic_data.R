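#' @title Synthetic founder, site and population generation
#' @description
#' Everything the pipeline consumes can be simulated: a maize-like genetic
#' map, a founder pair (recurrent and donor genomes differing only at InDel
#' sites, with a transgene locus on chromosome 8), candidate InDel site
#' tables with controllable length-difference, GC, repeat and GQ
#' distributions, and backcross populations. One top-level `seed` argument
#' fixes all randomness in each generator.
#' @name synthetic_data
NULL

.random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Overwrite a window of `seq` with a tandem repeat of a random 1-6 bp motif
# spanning >= `span` bases.
.inject_repeat <- function(seq, span = 14L) {
  n <- nchar(seq)
  k <- sample.int(6L, 1L)
  motif <- .random_dna(k)
  reps <- ceiling(span / k)
  tract <- substr(strrep(motif, reps), 1L, span)
  at <- sample.int(n - span + 1L, 1L)
  paste0(substr(seq, 1L, at - 1L), tract, substr(seq, at + span, n))
}

#' Simulate a table of candidate InDel sites
#'
#' Emulates the raw variant-calling output between two founders: sites with
#' map positions, allele length differences, flank sequences with
#' controllable GC, a configurable fraction carrying tandem repeats, GQ
#' values straddling the 30 threshold, and divergence-vs-reference counts.
#' The defaults are deliberately wide so every cascade filter has work to
#' do.
#'
#' @param map a [genetic_map()].
#' @param n number of sites (>= 0).
#' @param seed integer seed fixing all randomness (optional).
#' @param length_diff_range inclusive bp range for `length_diff_bp`,
#'   default `c(1, 80)` (uniform).
#' @param gc_range per-site flank GC sampling probability range, default
#'   `c(0.45, 0.70)` (uniform).
#' @param repeat_fraction fraction of flanks with an injected tandem
#'   repeat, default 0.15.
#' @param gq_mean,gq_sd normal parameters for GQ (rounded, clipped to
#'   `[0, 99]`), defaults 40 and 15 so values straddle 30.
#' @param divergence_max maximum simulated `length_diff_vs_ref` and
#'   `mismatches_vs_ref` (uniform on `0..divergence_max`), default 4.
#' @param flank_len simulated flank length, default 150.
#' @return data frame with columns `site`, `chrom`, `pos_cM`, `pos_bp`,
#'   `ref_allele`, `alt_allele`, `length_diff_bp`, `gq`, `flank_seq`,
#'   `flank_gc`, `length_diff_vs_ref`, `mismatches_vs_ref`; deterministic
#'   under `seed`.
#' @export
simulate_candidate_sites <- function(map, n, seed = NULL,
                                     length_diff_range = c(1L, 80L),
                                     gc_range = c(0.45, 0.70),
                                     repeat_fraction = 0.15,
                                     gq_mean = 40, gq_sd = 15,
                                     divergence_max = 4L,
                                     flank_len = 150L) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("`n` must be >= 0")
  if (repeat_fraction < 0 || repeat_fraction > 1)
    stop("`repeat_fraction` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  cols <- c("site", "chrom", "pos_cM", "pos_bp", "ref_allele", "alt_allele",
            "length_diff_bp", "gq", "flank_seq", "flank_gc",
            "length_diff_vs_ref", "mismatches_vs_ref")
  if (n == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    out$pos_cM <- numeric(0); out$pos_bp <- integer(0)
    out$length_diff_bp <- integer(0); out$gq <- integer(0)
    out$flank_gc <- numeric(0)
    out$length_diff_vs_ref <- integer(0); out$mismatches_vs_ref <- integer(0)
    return(out)
  }
  chrom <- sample(map$chrom, n, replace = TRUE,
                  prob = map$length_cM / map_total_length(map))
  L <- map_chrom_length(map, chrom)
  pos_cM <- stats::runif(n, 0, L)
  # physical positions on a notional 1000 bp/cM scale
  pos_bp <- pmax(1L, as.integer(round(pos_cM * 1000)))
  diffs <- sample.int(length_diff_range[2] - length_diff_range[1] + 1L, n,
                      replace = TRUE) + length_diff_range[1] - 1L
  gq <- pmin(pmax(round(stats::rnorm(n, gq_mean, gq_sd)), 0), 99)
  gc_p <- stats::runif(n, gc_range[1], gc_range[2])
  flank <- vapply(gc_p, function(g) .random_dna(flank_len, g), character(1))
  rep_flag <- stats::runif(n) < repeat_fraction
  flank[rep_flag] <- vapply(flank[rep_flag], .inject_repeat, character(1))
  ref <- vapply(diffs, function(d) .random_dna(d + 1L), character(1))
  alt <- substr(ref, 1L, 1L)
  ins <- stats::runif(n) < 0.5  # half the sites are insertions in the donor
  tmp <- ref[ins]; ref[ins] <- alt[ins]; alt[ins] <- tmp
  out <- data.frame(
    site = sprintf("site%05d", seq_len(n)),
    chrom = chrom, pos_cM = pos_cM, pos_bp = pos_bp,
    ref_allele = ref, alt_allele = alt,
    length_diff_bp = as.integer(diffs), gq = as.integer(gq),
    flank_seq = flank,
    flank_gc = vapply(flank, gc_content, numeric(1), USE.NAMES = FALSE),
    length_diff_vs_ref = sample.int(divergence_max + 1L, n, replace = TRUE) - 1L,
    mismatches_vs_ref = sample.int(divergence_max + 1L, n, replace = TRUE) - 1L,
    stringsAsFactors = FALSE)
  out[order(match(out$chrom, map$chrom), out$pos_cM), ][, cols] ->
    out
  rownames(out) <- NULL
  out
}

#' Simulate a founder pair
#'
#' Builds a recurrent-parent genome (random sequence per chromosome), a set
#' of InDel variant sites, and a donor genome identical to the recurrent
#' one except at those sites. The donor carries a transgene locus on
#' chromosome 8 (mid-chromosome) by default.
#'
#' @param map a [genetic_map()].
#' @param n_sites number of variant sites between the founders.
#' @param seed integer seed (optional).
#' @param bp_per_cM physical-to-genetic scale, default 500 bp/cM (kept
#'   small so synthetic genomes stay desk-sized).
#' @param transgene_locus list with `chrom` and `pos_cM`; default
#'   mid-chromosome 8 when the map has a `chr8`, else mid of the last
#'   chromosome.
#' @param gc baseline genome GC, default 0.47 (maize-like).
#' @param ... further arguments to [simulate_candidate_sites()].
#' @return list of class `founder_pair`: `recurrent_genome` and
#'   `donor_genome` (named character vectors), `sites` (variant table with
#'   founder genotypes `gt_recurrent = "0/0"`, `gt_donor = "1/1"`),
#'   `transgene_locus`, `map`, `bp_per_cM`.
#' @export
simulate_founder_pair <- function(map, n_sites = 200, seed = NULL,
                                  bp_per_cM = 500,
                                  transgene_locus = NULL, gc = 0.47, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(transgene_locus)) {
    ch <- if ("chr8" %in% map$chrom) "chr8" else map$chrom[nrow(map)]
    transgene_locus <- list(chrom = ch,
                            pos_cM = map_chrom_length(map, ch) / 2)
  }
  bp_len <- setNames(pmax(1000L, as.integer(round(map$length_cM * bp_per_cM))),
                     map$chrom)
  genome <- setNames(lapply(bp_len, .random_dna, gc = gc), map$chrom)
  genome <- unlist(genome)
  sites <- simulate_candidate_sites(map, n_sites, seed = NULL, ...)
  # rescale physical positions to this genome, keep clear of chromosome ends
  sites$pos_bp <- vapply(seq_len(nrow(sites)), function(i) {
    n <- bp_len[[sites$chrom[i]]]
    L <- map_chrom_length(map, sites$chrom[i])
    p <- as.integer(round(sites$pos_cM[i] / L * (n - 400L))) + 200L
    p
  }, integer(1))
  # deduplicate positions per chromosome so edits never overlap
  ord <- order(match(sites$chrom, map$chrom), sites$pos_bp)
  sites <- sites[ord, ]
  keep <- !logical(nrow(sites))
  for (ch in map$chrom) {
    i <- which(sites$chrom == ch)
    if (length(i) > 1L)
      keep[i[c(FALSE, diff(sites$pos_bp[i]) < 200)]] <- FALSE
  }
  sites <- sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  # make ref alleles agree with the recurrent genome at pos_bp
  for (i in seq_len(nrow(sites))) {
    w <- nchar(sites$ref_allele[i])
    sites$ref_allele[i] <- substr(genome[[sites$chrom[i]]], sites$pos_bp[i],
                                  sites$pos_bp[i] + w - 1L)
    sites$alt_allele[i] <- if (nchar(sites$alt_allele[i]) == 1L)
      substr(sites$ref_allele[i], 1L, 1L)
    else  # insertion in the donor: ref base + novel bases
      paste0(substr(sites$ref_allele[i], 1L, 1L),
             .random_dna(sites$length_diff_bp[i]))
  }
  sites$gt_recurrent <- "0/0"
  sites$gt_donor <- "1/1"
  # donor genome: apply alt alleles right-to-left so coordinates stay valid
  donor <- genome
  for (ch in map$chrom) {
    i <- rev(which(sites$chrom == ch))
    s <- donor[[ch]]
    for (j in i) {
      p <- sites$pos_bp[j]; w <- nchar(sites$ref_allele[j])
      s <- paste0(substr(s, 1L, p - 1L), sites$alt_allele[j],
                  substr(s, p + w, nchar(s)))
    }
    donor[[ch]] <- s
  }
  structure(list(recurrent_genome = genome, donor_genome = donor,
                 sites = sites, transgene_locus = transgene_locus,
                 map = map, bp_per_cM = bp_per_cM),
            class = "founder_pair")
}

#' Simulate a backcross population
#'
#' Crosses `other_parent` to the (fully inbred) recurrent parent: each
#' offspring receives one non-recombinant recurrent gamete and one
#' recombinant gamete from `other_parent`. When `other_parent` is
#' hemizygous for the transgene, the carrier fraction among offspring has
#' expectation 1/2.
#'
#' @param other_parent a `diploid_individual` (e.g. [f1_individual()]).
#' @param map a [genetic_map()].
#' @param n_offspring number of offspring (>= 1).
#' @param seed integer seed (optional).
#' @param locus transgene locus (list with `chrom`, `pos_cM`); when given
#'   and `require_transgene` is TRUE, `other_parent` must carry it.
#' @param require_transgene error when `other_parent` lacks the transgene
#'   (default TRUE when `locus` is given).
#' @param generation generation label, default `"BC"`.
#' @return list of `diploid_individual`.
#' @export
simulate_backcross_population <- function(other_parent, map, n_offspring,
                                          seed = NULL, locus = NULL,
                                          require_transgene = !is.null(locus),
                                          generation = "BC") {
  if (!is.null(seed)) set.seed(seed)
  if (require_transgene) {
    if (is.null(locus)) stop("`locus` needed to check transgene carriage")
    if (carrier_state(other_parent, locus) == "absent")
      stop("parent ", other_parent$id, " does not carry the transgene at ",
           locus$chrom, ":", locus$pos_cM, " cM")
  }
  backcross(other_parent, map, n_offspring, generation = generation)
}
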