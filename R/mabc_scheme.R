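#' Marker-transmission shortcut for backcross offspring
#'
#' Fast surrogate for the full map simulator when linkage can be ignored:
#' in a backcross of a parent with `S` homozygous-recurrent and `I - S`
#' heterozygous markers (no donor homozygotes), every offspring is `RR` at
#' the parent's `RR` markers and becomes `RR` at each heterozygous marker
#' independently with probability 1/2 (else stays `RD`). The offspring
#' expectation is therefore `E[Rg_offspring] = (Rg_parent + 100) / 2`.
#'
#' @param I parent scored-marker count.
#' @param S parent recurrent-homozygous count (`dd = 0` assumed; donor
#'   homozygotes are not supported in shortcut mode).
#' @param n_offspring number of offspring.
#' @param offspring_I optional scored-marker count for the offspring: when
#'   smaller than `I`, each offspring is scored at a random subset of
#'   `offspring_I` markers (missing-data emulation; the expectation is
#'   unchanged).
#' @param ids offspring ids.
#' @return data frame of offspring recovery reports (`id`, `I`, `S`,
#'   `het`, `dd`, `Rg`).
#' @examples
#' set.seed(1)
#' mean(marker_transmission_shortcut(108, 82, 1000)$Rg)  # ~93.98
#' @export
marker_transmission_shortcut <- function(I, S, n_offspring,
                                         offspring_I = I, ids = NULL) {
  if (S < 0 || S > I) stop("need 0 <= S <= I")
  if (offspring_I > I || offspring_I < 1) stop("need 1 <= offspring_I <= I")
  if (is.null(ids)) ids <- paste0("off-", seq_len(n_offspring))
  het <- I - S
  out <- do.call(rbind, lapply(seq_len(n_offspring), function(k) {
    # parent marker states: S x RR then het x RD; transmit
    calls <- c(rep("RR", S),
               ifelse(stats::runif(het) < 0.5, "RR", "RD"))
    if (offspring_I < I) calls <- calls[sample.int(I, offspring_I)]
    recovery_rate(calls, id = ids[k])
  }))
  rownames(out) <- NULL
  out
}

#' Simulate BC2 families from parent recovery rates
#'
#' Propagates a set of BC1 parent recovery rates through one further
#' backcross with the transmission shortcut: each parent's marker states
#' are initialized consistent with its recovery rate on an `I`-marker
#' panel (`S = round(I (Rg/50 - 1))`), then transmitted to its family.
#'
#' @param parent_rg numeric vector of parent recovery percentages.
#' @param family_sizes integer vector, offspring per parent.
#' @param I parent scored-marker count, default 108.
#' @param offspring_I offspring scored-marker count, default 87
#'   (missing data shrink per-individual denominators).
#' @param seed integer seed (optional).
#' @param parent_ids parent labels.
#' @return data frame of offspring reports with a `family` column;
#'   attribute `mean_Rg` is the family-size-weighted offspring mean.
#' @export
simulate_bc2_families <- function(parent_rg, family_sizes, I = 108,
                                  offspring_I = 87, seed = NULL,
                                  parent_ids = NULL) {
  if (length(parent_rg) != length(family_sizes))
    stop("`parent_rg` and `family_sizes` must align")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(parent_ids)) parent_ids <- paste0("P", seq_along(parent_rg))
  fams <- lapply(seq_along(parent_rg), function(j) {
    S <- round(I * (parent_rg[j] / 50 - 1))
    if (S < 0 || S > I)
      stop("parent Rg ", parent_rg[j], " not representable on ", I, " markers")
    rep <- marker_transmission_shortcut(
      I, S, family_sizes[j], offspring_I = offspring_I,
      ids = paste0(parent_ids[j], "-", seq_len(family_sizes[j])))
    rep$family <- parent_ids[j]
    rep
  })
  out <- do.call(rbind, fams)
  rownames(out) <- NULL
  attr(out, "mean_Rg") <- mean(out$Rg)
  out
}

#' Simulate a scored BC1 population
#'
#' Convenience wrapper for the common acceptance experiment: backcross an
#' F1 to the recurrent parent, retain `n_positive` transgene carriers
#' (generating offspring until enough carriers accumulate), genotype them
#' at a panel, and score recovery.
#'
#' @param map a [genetic_map()], default [make_maize_like_map()].
#' @param panel marker panel data frame (`marker`, `chrom`, `pos_cM`);
#'   default 108 evenly spaced markers at 20 cM.
#' @param n_positive carriers to retain, default 103.
#' @param locus transgene locus, default mid-chromosome 8.
#' @param seed integer seed (optional).
#' @param batch offspring simulated per round while collecting carriers.
#' @return list: `reports` (per-individual recovery), `mean_Rg`,
#'   `carriers` (the individuals), `segregation` (positive:negative split
#'   over all offspring generated).
#' @export
simulate_bc1_recovery <- function(map = make_maize_like_map(),
                                  panel = evenly_spaced_markers(map, 20),
                                  n_positive = 103,
                                  locus = list(chrom = "chr8",
                                               pos_cM = map_chrom_length(map, "chr8") / 2),
                                  seed = NULL, batch = 64L) {
  if (!is.null(seed)) set.seed(seed)
  f1 <- f1_individual(map)
  carriers <- list()
  n_pos <- 0L; n_neg <- 0L
  while (length(carriers) < n_positive) {
    pop <- backcross(f1, map, batch, generation = "BC1")
    fg <- foreground_select(pop, locus)
    n_pos <- n_pos + fg$n_positive
    n_neg <- n_neg + fg$n_negative
    carriers <- c(carriers, fg$carriers)
  }
  carriers <- carriers[seq_len(n_positive)]
  g <- genotype_population(carriers, panel)
  reports <- recovery_report(g)
  list(reports = reports, mean_Rg = mean(reports$Rg), carriers = carriers,
       segregation = c(positive = n_pos, negative = n_neg))
}

#' Configuration for a full MABC scheme run
#'
#' Defaults follow the classical two-backcross transgene-introgression
#' design: 224 BC1 seedlings sprayed, 103 positives scored, background
#' threshold >80% with 7 parents advanced; 70 BC2 positives, threshold
#' >90% with 2 picks; then two selfing generations with progeny-based
#' homozygosity testing.
#'
#' @param n_bc1 BC1 family size before foreground selection.
#' @param n_bc1_score number of BC1 positives scored (capped at the number
#'   of carriers obtained).
#' @param bc1_threshold,bc2_threshold strict background-selection
#'   thresholds (%).
#' @param n_bc1_pick,n_bc2_pick parents advanced after each round.
#' @param n_bc2_per_parent BC2 offspring per selected BC1 parent.
#' @param n_self_per_line,n_progeny_test selfing family size and progeny
#'   tested for homozygosity.
#' @param missing_rate genotype missingness rate, default 0.
#' @param seed integer seed.
#' @return list of class `mabc_config`.
#' @export
mabc_config <- function(n_bc1 = 224L, n_bc1_score = 103L,
                        bc1_threshold = 80, bc2_threshold = 90,
                        n_bc1_pick = 7L, n_bc2_pick = 2L,
                        n_bc2_per_parent = 10L,
                        n_self_per_line = 30L, n_progeny_test = 20L,
                        missing_rate = 0, seed = NULL) {
  cfg <- list(n_bc1 = n_bc1, n_bc1_score = n_bc1_score,
              bc1_threshold = bc1_threshold, bc2_threshold = bc2_threshold,
              n_bc1_pick = n_bc1_pick, n_bc2_pick = n_bc2_pick,
              n_bc2_per_parent = n_bc2_per_parent,
              n_self_per_line = n_self_per_line,
              n_progeny_test = n_progeny_test,
              missing_rate = missing_rate, seed = seed)
  stopifnot(cfg$n_bc1 >= 1, cfg$n_bc1_score >= 1,
            cfg$bc1_threshold >= 50, cfg$bc1_threshold <= 100,
            cfg$bc2_threshold >= 50, cfg$bc2_threshold <= 100)
  class(cfg) <- "mabc_config"
  cfg
}

#' Run a full marker-assisted backcross scheme
#'
#' F1 x recurrent -> BC1 (foreground selection, background scoring,
#' threshold, top-k pick) -> BC2 (same with the higher threshold, 2 picks)
#' -> two selfing generations with progeny-based homozygosity verdicts.
#' Parents are picked top-k by recovery rate (the phenotype-similarity
#' criterion of a real program is a policy hook, [select_individuals()]'s
#' `phenotype_ok`). If no individual passes a threshold the scheme stops
#' early and returns partial results.
#'
#' @param config an [mabc_config()].
#' @param map a [genetic_map()].
#' @param panel marker panel data frame; default 108 evenly spaced markers.
#' @param locus transgene locus; default mid-chromosome 8.
#' @return list of class `mabc_result` with per-generation reports,
#'   selected ids, segregation tests and summary means/SDs.
#' @export
run_mabc_scheme <- function(config = mabc_config(),
                            map = make_maize_like_map(),
                            panel = evenly_spaced_markers(map, 20),
                            locus = list(chrom = "chr8",
                                         pos_cM = map_chrom_length(map, "chr8") / 2)) {
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- list(generations = list(), config = config)
  summarize <- function(rep) c(mean = mean(rep$Rg), sd = stats::sd(rep$Rg),
                               n = nrow(rep))

  # BC1
  f1 <- f1_individual(map)
  bc1 <- backcross(f1, map, config$n_bc1, generation = "BC1")
  fg1 <- foreground_select(bc1, locus)
  scored1 <- fg1$carriers[seq_len(min(config$n_bc1_score,
                                      length(fg1$carriers)))]
  rep1 <- recovery_report(
    genotype_population(scored1, panel, config$missing_rate))
  sel1 <- select_individuals(rep1, config$bc1_threshold)
  pick1 <- utils::head(sel1, config$n_bc1_pick)
  res$generations$BC1 <- list(
    reports = rep1, segregation = fg1$test, selected = sel1, picked = pick1,
    summary = summarize(rep1))
  if (length(pick1) == 0L) {
    res$stopped <- "no BC1 individual passed the background threshold"
    class(res) <- "mabc_result"
    return(res)
  }

  # BC2
  parents1 <- scored1[match(pick1, vapply(scored1, `[[`, "", "id"))]
  bc2 <- list(); fg_pos <- 0L; fg_neg <- 0L
  for (p in parents1) {
    fam <- backcross(p, map, 2L * config$n_bc2_per_parent,
                     generation = "BC2", id_prefix = paste0(p$id, "-BC2"))
    fg <- foreground_select(fam, locus)
    fg_pos <- fg_pos + fg$n_positive; fg_neg <- fg_neg + fg$n_negative
    keep <- fg$carriers[seq_len(min(config$n_bc2_per_parent,
                                    length(fg$carriers)))]
    bc2 <- c(bc2, keep)
  }
  rep2 <- recovery_report(
    genotype_population(bc2, panel, config$missing_rate))
  sel2 <- select_individuals(rep2, config$bc2_threshold)
  pick2 <- utils::head(sel2, config$n_bc2_pick)
  res$generations$BC2 <- list(
    reports = rep2,
    segregation = chi_square_1to1(fg_pos, fg_neg),
    selected = sel2, picked = pick2, summary = summarize(rep2))
  if (length(pick2) == 0L) {
    res$stopped <- "no BC2 individual passed the background threshold"
    class(res) <- "mabc_result"
    return(res)
  }

  # two selfing generations with progeny homozygosity testing
  parents2 <- bc2[match(pick2, vapply(bc2, `[[`, "", "id"))]
  selfs <- list()
  for (p in parents2) {
    f2 <- self_cross(p, map, config$n_self_per_line, generation = "BCF2",
                     id_prefix = paste0(p$id, "-F2"))
    carriers <- Filter(function(x) carrier_state(x, locus) != "absent", f2)
    homo <- Filter(function(x) carrier_state(x, locus) == "homozygous",
                   carriers)
    line <- if (length(homo)) homo[[1L]] else NULL
    verdict <- NULL
    if (!is.null(line)) {
      f3 <- self_cross(line, map, config$n_progeny_test, generation = "BCF3",
                       id_prefix = paste0(line$id, "-F3"))
      verdict <- homozygosity_by_progeny(
        vapply(f3, function(x) carrier_state(x, locus) != "absent",
               logical(1)))
    }
    selfs[[p$id]] <- list(line_id = if (is.null(line)) NA else line$id,
                          n_carriers = length(carriers),
                          n_homozygous = length(homo), verdict = verdict)
  }
  res$generations$selfing <- selfs
  class(res) <- "mabc_result"
  res
}

#' @export
print.mabc_result <- function(x, ...) {
  cat("MABC scheme result\n")
  for (g in c("BC1", "BC2")) {
    gen <- x$generations[[g]]
    if (is.null(gen)) next
    cat(sprintf("  %s: n = %d, mean Rg = %.2f%% (sd %.2f), %d passed, picked: %s\n",
                g, gen$summary["n"], gen$summary["mean"], gen$summary["sd"],
                length(gen$selected), paste(gen$picked, collapse = ", ")))
  }
  if (!is.null(x$stopped)) cat("  stopped early:", x$stopped, "\n")
  if (!is.null(x$generations$selfing)) {
    for (nm in names(x$generations$selfing)) {
      s <- x$generations$selfing[[nm]]
      cat(sprintf("  selfing %s: line %s, verdict %s\n", nm, s$line_id,
                  if (is.null(s$verdict)) "none" else s$verdict$verdict))
    }
  }
  invisible(x)
}
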