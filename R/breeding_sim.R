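#' @title Forward-in-time backcross simulation
#' @description
#' Genomes are represented as ancestry mosaics: each haplotype is, per
#' chromosome, a matrix of segments `(start, end, anc)` with `anc` 0 for the
#' recurrent parent and 1 for the donor. Segments tile `[0, length_cM]`
#' without gaps or overlaps. Meiosis draws a Poisson number of crossovers per
#' chromosome with mean `length_cM / 100` and uniform positions (Haldane, no
#' interference), so recombination fractions follow
#' `r = (1 - exp(-2d)) / 2` for map distance `d` Morgans.
#' @name breeding_sim
NULL

ANC_RECURRENT <- 0
ANC_DONOR <- 1

.seg <- function(start, end, anc) {
  cbind(start = start, end = end, anc = anc)
}

# Merge adjacent segments with identical ancestry; drop empty segments.
.seg_normalize <- function(m) {
  m <- m[m[, "end"] > m[, "start"], , drop = FALSE]
  if (nrow(m) <= 1L) return(m)
  keep <- c(TRUE, m[-1L, "anc"] != m[-nrow(m), "anc"])
  grp <- cumsum(keep)
  start <- m[keep, "start"]
  end <- tapply(m[, "end"], grp, function(e) e[length(e)])
  .seg(start, as.numeric(end), m[keep, "anc"])
}

# Extract [a, b) from a segment matrix (clipping).
.seg_slice <- function(m, a, b) {
  s <- pmax(m[, "start"], a)
  e <- pmin(m[, "end"], b)
  keep <- e > s
  .seg(s[keep], e[keep], m[keep, "anc"])
}

#' Construct a uniform-ancestry haplotype
#'
#' @param map a [genetic_map()].
#' @param ancestry `"recurrent"` or `"donor"`.
#' @return a `haplotype`: named list (per chromosome) of segment matrices.
#' @export
uniform_haplotype <- function(map, ancestry = c("recurrent", "donor")) {
  ancestry <- match.arg(ancestry)
  anc <- if (ancestry == "donor") ANC_DONOR else ANC_RECURRENT
  h <- lapply(map$length_cM, function(L) .seg(0, L, anc))
  names(h) <- map$chrom
  structure(h, class = "haplotype")
}

#' Construct a diploid individual from two haplotypes
#'
#' @param hap1,hap2 `haplotype` objects on the same map.
#' @param id individual identifier.
#' @param generation generation label, e.g. `"F1"`, `"BC1"`.
#' @return a `diploid_individual`.
#' @export
diploid_individual <- function(hap1, hap2, id = NA_character_,
                               generation = NA_character_) {
  stopifnot(identical(names(hap1), names(hap2)))
  structure(list(hap1 = hap1, hap2 = hap2, id = id, generation = generation),
            class = "diploid_individual")
}

#' Founder individuals
#'
#' `recurrent_individual()` is homozygous recurrent everywhere;
#' `donor_individual()` homozygous donor; `f1_individual()` carries one
#' haplotype from each.
#'
#' @param map a [genetic_map()].
#' @param id individual identifier.
#' @return a `diploid_individual`.
#' @export
recurrent_individual <- function(map, id = "recurrent") {
  diploid_individual(uniform_haplotype(map, "recurrent"),
                     uniform_haplotype(map, "recurrent"), id, "P")
}

#' @rdname recurrent_individual
#' @export
donor_individual <- function(map, id = "donor") {
  diploid_individual(uniform_haplotype(map, "donor"),
                     uniform_haplotype(map, "donor"), id, "P")
}

#' @rdname recurrent_individual
#' @export
f1_individual <- function(map, id = "F1") {
  diploid_individual(uniform_haplotype(map, "recurrent"),
                     uniform_haplotype(map, "donor"), id, "F1")
}

# Check the tiling invariant of a haplotype against its map.
.hap_valid <- function(hap, map) {
  for (i in seq_len(nrow(map))) {
    m <- hap[[map$chrom[i]]]
    if (is.null(m) || nrow(m) == 0L) return(FALSE)
    if (m[1L, "start"] != 0) return(FALSE)
    if (abs(m[nrow(m), "end"] - map$length_cM[i]) > 1e-9) return(FALSE)
    if (nrow(m) > 1L && any(abs(m[-1L, "start"] - m[-nrow(m), "end"]) > 1e-9))
      return(FALSE)
  }
  TRUE
}

#' Ancestry of a haplotype at a position
#'
#' @param hap a `haplotype`.
#' @param chrom chromosome name.
#' @param pos_cM position(s) in cM.
#' @return integer vector, 0 = recurrent, 1 = donor.
#' @export
ancestry_at <- function(hap, chrom, pos_cM) {
  m <- hap[[chrom]]
  if (is.null(m)) stop("haplotype has no chromosome ", chrom)
  if (any(pos_cM < 0 | pos_cM > m[nrow(m), "end"]))
    stop("position off the end of ", chrom)
  idx <- findInterval(pos_cM, m[, "start"], rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  unname(m[idx, "anc"])
}

#' Donor-genome fraction
#'
#' Length-weighted fraction of the genome with donor ancestry, averaged over
#' the two haplotypes for an individual.
#'
#' @param x a `haplotype` or `diploid_individual`.
#' @param map a [genetic_map()].
#' @return numeric in `[0, 1]`.
#' @export
donor_fraction <- function(x, map) {
  hap_frac <- function(h) {
    d <- vapply(map$chrom, function(ch) {
      m <- h[[ch]]
      sum((m[, "end"] - m[, "start"]) * (m[, "anc"] == ANC_DONOR))
    }, numeric(1))
    sum(d) / map_total_length(map)
  }
  if (inherits(x, "haplotype")) return(hap_frac(x))
  (hap_frac(x$hap1) + hap_frac(x$hap2)) / 2
}

#' Simulate one meiosis
#'
#' Per chromosome: crossover count ~ Poisson(length_cM / 100), crossover
#' positions uniform on the chromosome, and the gamete alternates between the
#' two parental haplotypes starting from a fair-coin choice.
#'
#' @param parent a `diploid_individual`.
#' @param map a [genetic_map()].
#' @return a `haplotype` (the gamete).
#' @export
meiosis <- function(parent, map) {
  if (!.hap_valid(parent$hap1, map) || !.hap_valid(parent$hap2, map))
    stop("parent haplotypes do not tile the map")
  gam <- vector("list", nrow(map))
  names(gam) <- map$chrom
  for (i in seq_len(nrow(map))) {
    ch <- map$chrom[i]
    L <- map$length_cM[i]
    n_xo <- stats::rpois(1L, L / 100)
    brk <- c(0, sort(stats::runif(n_xo, 0, L)), L)
    src <- (sample.int(2L, 1L) + seq_len(length(brk) - 1L)) %% 2L + 1L
    haps <- list(parent$hap1[[ch]], parent$hap2[[ch]])
    pieces <- lapply(seq_along(src), function(k) {
      .seg_slice(haps[[src[k]]], brk[k], brk[k + 1L])
    })
    gam[[i]] <- .seg_normalize(do.call(rbind, pieces))
  }
  structure(gam, class = "haplotype")
}

#' Backcross a parent to the recurrent parent
#'
#' Each offspring receives one recombinant gamete from `parent` and one
#' non-recombinant pure-recurrent gamete, the recurrent parent being fully
#' inbred.
#'
#' @param parent a `diploid_individual` (e.g. an F1 or a selected BC plant).
#' @param map a [genetic_map()].
#' @param n number of offspring (>= 1).
#' @param generation generation label for the offspring.
#' @param id_prefix prefix for offspring ids.
#' @return list of `diploid_individual`.
#' @export
backcross <- function(parent, map, n, generation = "BC", id_prefix = generation) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  lapply(seq_len(n), function(k) {
    diploid_individual(uniform_haplotype(map, "recurrent"),
                       meiosis(parent, map),
                       id = paste0(id_prefix, "-", k),
                       generation = generation)
  })
}

#' Self-pollinate an individual
#'
#' Both offspring gametes are independent meioses of the same parent.
#'
#' @inheritParams backcross
#' @return list of `diploid_individual`.
#' @export
self_cross <- function(parent, map, n, generation = "F2", id_prefix = generation) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  lapply(seq_len(n), function(k) {
    diploid_individual(meiosis(parent, map), meiosis(parent, map),
                       id = paste0(id_prefix, "-", k),
                       generation = generation)
  })
}

#' Transgene carrier state at a locus
#'
#' The transgene travels with donor ancestry at its insertion locus: an
#' individual is a carrier when at least one haplotype is donor-derived
#' there, homozygous when both are.
#'
#' @param ind a `diploid_individual`.
#' @param locus list with `chrom` and `pos_cM`.
#' @return `"absent"`, `"hemizygous"` or `"homozygous"`.
#' @export
carrier_state <- function(ind, locus) {
  a <- ancestry_at(ind$hap1, locus$chrom, locus$pos_cM) +
       ancestry_at(ind$hap2, locus$chrom, locus$pos_cM)
  c("absent", "hemizygous", "homozygous")[a + 1L]
}

#' Foreground selection at the transgene locus
#'
#' Splits a population into transgene carriers and non-carriers (the
#' herbicide-spray / immunostrip / PCR assays collapsed into one error-free
#' carrier test; an optional assay error rate flips calls independently).
#'
#' @param population list of `diploid_individual`.
#' @param locus list with `chrom` and `pos_cM`.
#' @param error_rate probability a call is flipped (default 0).
#' @return list with `carriers` (the retained individuals), `n_positive`,
#'   `n_negative`, and `test` — the 1:1 [chi_square_1to1()] of the split.
#' @export
foreground_select <- function(population, locus, error_rate = 0) {
  is_carrier <- vapply(population, function(ind) {
    carrier_state(ind, locus) != "absent"
  }, logical(1))
  if (error_rate > 0) {
    flip <- stats::runif(length(is_carrier)) < error_rate
    is_carrier <- xor(is_carrier, flip)
  }
  n_pos <- sum(is_carrier)
  n_neg <- sum(!is_carrier)
  list(carriers = population[is_carrier],
       n_positive = n_pos, n_negative = n_neg,
       test = if (n_pos + n_neg > 0) chi_square_1to1(n_pos, n_neg) else NULL)
}

#' Genotype an individual at a marker panel
#'
#' Ancestry of the two haplotypes at each marker position is coded
#' co-dominantly: `RR` (both recurrent), `RD` (heterozygous), `DD` (both
#' donor). An optional missingness rate blanks calls at random, shrinking
#' the per-individual scored-marker count.
#'
#' @param ind a `diploid_individual`.
#' @param panel data frame with columns `marker`, `chrom`, `pos_cM`
#'   (e.g. from [evenly_spaced_markers()] or [select_spaced_panel()]).
#' @param missing_rate probability a call is missing (default 0).
#' @return named character vector of calls in `{RR, RD, DD, NA}`.
#' @export
genotype_at_markers <- function(ind, panel, missing_rate = 0) {
  calls <- character(nrow(panel))
  for (ch in unique(panel$chrom)) {
    i <- which(panel$chrom == ch)
    a <- ancestry_at(ind$hap1, ch, panel$pos_cM[i]) +
         ancestry_at(ind$hap2, ch, panel$pos_cM[i])
    calls[i] <- c("RR", "RD", "DD")[a + 1L]
  }
  if (missing_rate > 0)
    calls[stats::runif(length(calls)) < missing_rate] <- NA_character_
  names(calls) <- panel$marker
  calls
}

#' Genotype a population at a marker panel
#'
#' @param population list of `diploid_individual`.
#' @inheritParams genotype_at_markers
#' @return a genotype matrix (individuals x markers, character), with row
#'   names from individual ids.
#' @export
genotype_population <- function(population, panel, missing_rate = 0) {
  g <- t(vapply(population, genotype_at_markers, character(nrow(panel)),
                panel = panel, missing_rate = missing_rate))
  rownames(g) <- vapply(population, function(x) x$id, character(1))
  g
}
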