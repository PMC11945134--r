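#' @title InDel marker design
#' @description
#' Candidate InDel sites flow through a screening cascade before panel
#' selection: genotype quality (GQ strictly above 30), allele length
#' difference within 30-50 bp (amplicon-resolvable on agarose), flank
#' extraction (120-150 bp), tandem-repeat exclusion, flank GC within
#' 55-60% (closed interval), and a divergence-vs-reference envelope that
#' keeps only flanks nearly identical to the reference assembly so primers
#' amplify a unique locus. Survivors are thinned to an approximately even
#' ~20 cM panel by greedy left-to-right selection per chromosome.
#'
#' Sites are plain data frames, one row per candidate, with the columns
#' documented in [simulate_candidate_sites()]; every filter is a
#' contraction (`output` is a subset of `input`, order preserved) and logs
#' its in/out counts on the `cascade_log` attribute.
#' @name marker_design
NULL

.log_stage <- function(sites, stage, n_in, n_out, quiet = FALSE) {
  log <- attr(sites, "cascade_log")
  entry <- data.frame(stage = stage, n_in = n_in, n_out = n_out,
                      n_dropped = n_in - n_out, stringsAsFactors = FALSE)
  attr(sites, "cascade_log") <- rbind(log, entry)
  if (!quiet)
    message(sprintf("[%s] %d -> %d (%d dropped)", stage, n_in, n_out,
                    n_in - n_out))
  sites
}

#' Filter candidate sites on genotype quality
#'
#' Strict inequality: a site survives only if `gq > min_gq` in both
#' founders (the `gq` column carries the minimum of the two sample GQs).
#' Sites with missing GQ are dropped with a warning.
#'
#' @param sites candidate site data frame with a `gq` column.
#' @param min_gq threshold, default 30 (`gq = 30` is dropped).
#' @param quiet suppress the stage message.
#' @return the surviving subset, order preserved.
#' @export
filter_gq <- function(sites, min_gq = 30, quiet = FALSE) {
  n_in <- nrow(sites)
  miss <- is.na(sites$gq)
  if (any(miss))
    warning(sum(miss), " site(s) with missing GQ dropped")
  out <- sites[!miss & sites$gq > min_gq, , drop = FALSE]
  .log_stage(out, "filter_gq", n_in, nrow(out), quiet)
}

#' Filter candidate sites on allele length difference
#'
#' Closed interval: survives iff `lo <= length_diff_bp <= hi`.
#'
#' @param sites candidate site data frame with a `length_diff_bp` column.
#' @param lo,hi interval bounds in bp, default 30 and 50.
#' @inheritParams filter_gq
#' @return the surviving subset.
#' @export
filter_length_diff <- function(sites, lo = 30, hi = 50, quiet = FALSE) {
  n_in <- nrow(sites)
  out <- sites[sites$length_diff_bp >= lo & sites$length_diff_bp <= hi, ,
               drop = FALSE]
  .log_stage(out, "filter_length_diff", n_in, nrow(out), quiet)
}

#' GC content of a sequence
#'
#' `(#G + #C) / length` over the ACGT alphabet. Ambiguous bases (N etc.)
#' are an error: a flank containing them fails the site upstream.
#'
#' @param seq a single non-empty character string over `{A, C, G, T}`
#'   (case-insensitive).
#' @return numeric in `[0, 1]`.
#' @examples
#' gc_content("ATGCATGCGC")  # 0.6
#' @export
gc_content <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("`seq` must be a single non-empty string")
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- !s %in% c("A", "C", "G", "T")
  if (any(bad)) stop("non-ACGT character(s) in sequence: ",
                     paste(unique(s[bad]), collapse = ""))
  sum(s %in% c("G", "C")) / length(s)
}

#' Extract the flanking window around a site
#'
#' Returns a window of `flank_len` bases (default 150, must lie in
#' `[min_len, max_len]`) centered on the site within its chromosome
#' sequence; the amplicon-scale context used for GC and repeat screening.
#'
#' @param pos_bp 1-based site position.
#' @param chrom_seq chromosome sequence (character string).
#' @param min_len,max_len allowed window lengths, default 120 and 150.
#' @param flank_len requested window length, default `max_len`.
#' @return list with `seq`, `start`, `end` (1-based inclusive), or `NULL`
#'   when the site is too close to a chromosome end for `min_len`.
#' @export
extract_flank <- function(pos_bp, chrom_seq, min_len = 120, max_len = 150,
                          flank_len = max_len) {
  if (flank_len < min_len || flank_len > max_len)
    stop("`flank_len` must lie in [min_len, max_len]")
  n <- nchar(chrom_seq)
  half <- flank_len %/% 2L
  start <- pos_bp - half
  end <- start + flank_len - 1L
  if (start < 1L) { start <- 1L; end <- flank_len }
  if (end > n) { end <- n; start <- n - flank_len + 1L }
  if (start < 1L || end - start + 1L < min_len) return(NULL)
  list(seq = substr(chrom_seq, start, end), start = start, end = end)
}

#' Attach flanks to candidate sites
#'
#' Runs [extract_flank()] for every site against the founder genome and
#' recomputes `flank_gc`; sites too close to a chromosome end are dropped
#' with a warning.
#'
#' @param sites candidate site data frame.
#' @param genome named character vector of chromosome sequences.
#' @inheritParams extract_flank
#' @inheritParams filter_gq
#' @return sites with `flank_seq`, `flank_start`, `flank_end`, `flank_gc`
#'   columns filled in.
#' @export
attach_flanks <- function(sites, genome, min_len = 120, max_len = 150,
                          quiet = FALSE) {
  n_in <- nrow(sites)
  keep <- logical(n_in)
  seqs <- character(n_in); st <- integer(n_in); en <- integer(n_in)
  for (i in seq_len(n_in)) {
    fl <- extract_flank(sites$pos_bp[i], genome[[sites$chrom[i]]],
                        min_len, max_len)
    if (!is.null(fl)) {
      keep[i] <- TRUE
      seqs[i] <- fl$seq; st[i] <- fl$start; en[i] <- fl$end
    }
  }
  if (any(!keep))
    warning(sum(!keep), " site(s) too close to a chromosome end dropped")
  out <- sites[keep, , drop = FALSE]
  out$flank_seq <- seqs[keep]
  out$flank_start <- st[keep]
  out$flank_end <- en[keep]
  out$flank_gc <- vapply(out$flank_seq, gc_content, numeric(1), USE.NAMES = FALSE)
  .log_stage(out, "extract_flank", n_in, nrow(out), quiet)
}

#' Filter candidate sites on flank GC content
#'
#' Closed interval: survives iff `lo <= flank_gc <= hi`.
#'
#' @param sites candidate site data frame with a `flank_gc` column.
#' @param lo,hi bounds as fractions, default 0.55 and 0.60.
#' @inheritParams filter_gq
#' @return the surviving subset.
#' @export
filter_gc <- function(sites, lo = 0.55, hi = 0.60, quiet = FALSE) {
  n_in <- nrow(sites)
  out <- sites[sites$flank_gc >= lo & sites$flank_gc <= hi, , drop = FALSE]
  .log_stage(out, "filter_gc", n_in, nrow(out), quiet)
}

#' Tandem-repeat detection
#'
#' TRUE when the sequence contains a perfect tandem repeat of a short motif:
#' any motif of `min_motif`..`max_motif` bp repeated (at least two full
#' copies) to span at least `min_span` bp. The default policy (motifs 1-6 bp
#' spanning >= 12 bp) flags homopolymer runs, microsatellites and short
#' tandems that make amplicon sizing unreliable.
#'
#' @param seq a character string.
#' @param min_motif,max_motif motif length bounds, defaults 1 and 6.
#' @param min_span minimum tandem span in bp, default 12.
#' @return logical.
#' @examples
#' has_repeat("GATTACAAAAAAAAAAAAGATTACA")  # TRUE (A x 12)
#' has_repeat("ACGTACGA")                   # FALSE
#' @export
has_repeat <- function(seq, min_motif = 1L, max_motif = 6L, min_span = 12L) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(s)
  for (k in seq.int(min_motif, max_motif)) {
    if (2L * k > n) break
    eq <- s[seq_len(n - k)] == s[seq_len(n - k) + k]
    r <- rle(eq)
    run <- r$lengths[r$values]
    # a periodicity run of length r means a period-k region of r + k bases
    if (length(run) && any(run >= k & run + k >= min_span)) return(TRUE)
  }
  FALSE
}

#' Exclude candidate sites whose flank contains a tandem repeat
#'
#' @param sites candidate site data frame with `flank_seq`.
#' @param ... passed to [has_repeat()].
#' @inheritParams filter_gq
#' @return the surviving subset.
#' @export
filter_repeats <- function(sites, quiet = FALSE, ...) {
  n_in <- nrow(sites)
  rep_hit <- vapply(sites$flank_seq, has_repeat, logical(1), ...,
                    USE.NAMES = FALSE)
  out <- sites[!rep_hit, , drop = FALSE]
  .log_stage(out, "filter_repeats", n_in, nrow(out), quiet)
}

#' Reference-divergence envelope
#'
#' A flank passes specificity screening against the reference assembly iff
#' its best alignment satisfies one of: identical length with at most 2
#' mismatches; 1 bp length difference with at most 1 mismatch; 2 bp length
#' difference with no mismatch.
#'
#' @param length_diff_vs_ref absolute length difference (bp) of the aligned
#'   flank vs the reference window.
#' @param mismatches_vs_ref substitution count in the alignment.
#' @return logical (vectorized).
#' @examples
#' divergence_class(0, 2)  # TRUE
#' divergence_class(2, 1)  # FALSE
#' @export
divergence_class <- function(length_diff_vs_ref, mismatches_vs_ref) {
  if (any(length_diff_vs_ref < 0) || any(mismatches_vs_ref < 0))
    stop("counts must be >= 0")
  (length_diff_vs_ref == 0 & mismatches_vs_ref <= 2) |
  (length_diff_vs_ref == 1 & mismatches_vs_ref <= 1) |
  (length_diff_vs_ref == 2 & mismatches_vs_ref == 0)
}

#' Align a flank to a reference and count divergence
#'
#' Fitting alignment (whole flank vs best window of the reference) with unit
#' match/mismatch/gap scores, via [Biostrings::pairwiseAlignment()]. Returns
#' the net length difference (inserted minus deleted bases, absolute) and
#' the substitution count of the best alignment — the two quantities
#' classified by [divergence_class()].
#'
#' @param flank flank sequence (character).
#' @param reference reference sequence (character), e.g. one chromosome of
#'   the reference assembly.
#' @param min_score_frac alignments scoring below `min_score_frac *
#'   nchar(flank)` fail specificity; returns `NULL` (default 0.5).
#' @return list with `length_diff` and `mismatches`, or `NULL` when no
#'   alignment reaches the score floor.
#' @export
compute_divergence <- function(flank, reference, min_score_frac = 0.5) {
  if (!nzchar(flank)) stop("empty flank")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(flank), Biostrings::DNAString(reference),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 0, gapExtension = 1)
  if (Biostrings::score(al) < min_score_frac * nchar(flank)) return(NULL)
  ins <- sum(Biostrings::width(unlist(Biostrings::insertion(al))))
  del <- sum(Biostrings::width(unlist(Biostrings::deletion(al))))
  list(length_diff = abs(ins - del),
       mismatches = Biostrings::nmismatch(al))
}

#' Filter candidate sites on reference divergence
#'
#' When a `reference` genome is supplied, each flank is aligned with
#' [compute_divergence()]; otherwise the sites' stored
#' `length_diff_vs_ref` / `mismatches_vs_ref` columns (e.g. from an external
#' aligner) are classified directly.
#'
#' @param sites candidate site data frame.
#' @param reference optional named character vector of reference chromosome
#'   sequences.
#' @inheritParams filter_gq
#' @return the surviving subset.
#' @export
filter_divergence <- function(sites, reference = NULL, quiet = FALSE) {
  n_in <- nrow(sites)
  if (!is.null(reference)) {
    keep <- vapply(seq_len(n_in), function(i) {
      dv <- compute_divergence(sites$flank_seq[i],
                               reference[[sites$chrom[i]]])
      !is.null(dv) && divergence_class(dv$length_diff, dv$mismatches)
    }, logical(1))
  } else {
    keep <- divergence_class(sites$length_diff_vs_ref,
                             sites$mismatches_vs_ref)
  }
  out <- sites[keep, , drop = FALSE]
  .log_stage(out, "filter_divergence", n_in, nrow(out), quiet)
}

#' Run the full candidate-screening cascade
#'
#' Applies, in order: [filter_gq()], [filter_length_diff()],
#' [attach_flanks()] (skipped when flanks are already present and no genome
#' is given), [filter_repeats()], [filter_gc()], [filter_divergence()].
#' The output is a subset of the input with a complete `cascade_log`
#' attribute (stage, counts in/out) so the screening audit trail mirrors
#' what a panel-design report needs.
#'
#' @param sites candidate site data frame.
#' @param genome optional founder genome (named character vector) for flank
#'   extraction.
#' @param reference optional reference genome for divergence alignment.
#' @param min_gq,length_lo,length_hi,gc_lo,gc_hi cascade thresholds.
#' @inheritParams filter_gq
#' @return the surviving subset, with `cascade_log` attribute.
#' @export
screen_candidates <- function(sites, genome = NULL, reference = NULL,
                              min_gq = 30, length_lo = 30, length_hi = 50,
                              gc_lo = 0.55, gc_hi = 0.60, quiet = FALSE) {
  out <- filter_gq(sites, min_gq, quiet = quiet)
  out <- filter_length_diff(out, length_lo, length_hi, quiet = quiet)
  if (!is.null(genome)) out <- attach_flanks(out, genome, quiet = quiet)
  else if (is.null(out$flank_seq)) stop("no flanks present and no genome given")
  out <- filter_repeats(out, quiet = quiet)
  out <- filter_gc(out, gc_lo, gc_hi, quiet = quiet)
  out <- filter_divergence(out, reference, quiet = quiet)
  out
}

#' Select an evenly spaced marker panel
#'
#' Greedy left-to-right selection per chromosome: take the first candidate,
#' then repeatedly the candidate nearest to `last_selected + spacing_cM`
#' within a tolerance window of `spacing_cM / 2` on either side. Windows
#' without candidates leave a gap (common on chromosomes with few
#' polymorphisms between the founders) and selection restarts at the next
#' candidate beyond the window.
#'
#' @param sites screened candidate site data frame with `chrom` and
#'   `pos_cM` columns.
#' @param map a [genetic_map()] covering the sites' chromosomes.
#' @param spacing_cM target spacing, default 20.
#' @param tol_cM tolerance window half-width, default `spacing_cM / 2`.
#' @inheritParams filter_gq
#' @return a `marker_panel`: the selected subset of `sites`, sorted by
#'   `(chrom, pos_cM)`, with `target_spacing_cM` and per-chromosome counts
#'   as attributes.
#' @export
select_spaced_panel <- function(sites, map, spacing_cM = 20,
                                tol_cM = spacing_cM / 2, quiet = FALSE) {
  if (nrow(sites) == 0L) {
    warning("empty candidate set; empty panel")
    out <- sites
  } else {
    picks <- integer(0)
    for (ch in map$chrom) {
      idx <- which(sites$chrom == ch)
      if (length(idx) == 0L) {
        if (!quiet) message("[panel] no candidates on ", ch, "; gap left")
        next
      }
      idx <- idx[order(sites$pos_cM[idx])]
      pos <- sites$pos_cM[idx]
      L <- map_chrom_length(map, ch)
      sel <- 1L
      last <- pos[1L]
      repeat {
        target <- last + spacing_cM
        if (target - tol_cM > L) break
        win <- which(pos > last & abs(pos - target) <= tol_cM)
        if (length(win) == 0L) {
          # gap: restart beyond the window
          nxt <- which(pos > target + tol_cM)
          if (length(nxt) == 0L) break
          pick <- nxt[1L]
          if (!quiet)
            message(sprintf("[panel] gap on %s after %.1f cM", ch, last))
        } else {
          pick <- win[which.min(abs(pos[win] - target))]
        }
        sel <- c(sel, pick)
        last <- pos[pick]
      }
      picks <- c(picks, idx[sel])
    }
    out <- sites[picks, , drop = FALSE]
    out <- out[order(match(out$chrom, map$chrom), out$pos_cM), , drop = FALSE]
  }
  if (is.null(out$marker))
    out$marker <- sprintf("M%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "target_spacing_cM") <- spacing_cM
  attr(out, "per_chrom") <- table(factor(out$chrom, levels = map$chrom))
  class(out) <- c("marker_panel", "data.frame")
  out
}
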