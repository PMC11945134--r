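#' Published background-recovery tables
#'
#' Per-plant recurrent-parent background recovery rates from a published
#' maize transgene (AnVP1) introgression program: 18 BC1 plants that
#' exceeded the 80% background-selection threshold, and the 70 BC2 plants
#' descended from the seven advanced BC1 parents (families 1, 5, 8, 35, 36,
#' 47 and 83, named after their BC1 parent). These printed percentages are
#' inputs: the scored-marker counts behind them are recoverable with
#' [infer_marker_count()].
#'
#' @return data frame: `plant`, `recovery` (percent), and for the BC2
#'   table a `family` column.
#' @examples
#' nrow(bc1_recovery_table())  # 18
#' @export
bc1_recovery_table <- function() {
  utils::read.table(system.file("extdata", "bc1_recovery.tsv",
                                package = "mabcr"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname bc1_recovery_table
#' @export
bc2_recovery_table <- function() {
  utils::read.table(system.file("extdata", "bc2_recovery.tsv",
                                package = "mabcr"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' BC1 parents of the BC2 families
#'
#' Joins the two recovery tables: for each BC2 family, the parent plant,
#' its BC1 recovery rate and the family size.
#'
#' @return data frame: `family`, `parent`, `parent_rg`, `family_size`.
#' @export
bc2_family_parents <- function() {
  t1 <- bc1_recovery_table()
  t2 <- bc2_recovery_table()
  fam <- sort(unique(t2$family))
  parent <- paste0("BC1-", fam)
  i <- match(parent, t1$plant)
  if (anyNA(i)) stop("BC2 family without a BC1 parent entry")
  data.frame(family = fam, parent = parent, parent_rg = t1$recovery[i],
             family_size = as.integer(table(t2$family)[as.character(fam)]),
             stringsAsFactors = FALSE)
}

#' Recover integer marker counts behind printed recovery percentages
#'
#' A printed backcross recovery rate is `(I + S)/(2 I) x 100` for integer
#' scored-marker count `I` and recurrent-homozygous count `S`. Given a set
#' of printed percentages, this scans candidate values of `I` and counts,
#' for each, how many percentages are representable with some integer
#' `S` within `tol` (the tolerance absorbs truncation-vs-rounding of the
#' printed two decimals). The modal `I` — the one explaining the most
#' entries — is the panel-level scored count; entries it does not explain
#' reflect per-plant missing data.
#'
#' @param rg numeric vector of printed percentages.
#' @param I_range candidate integer counts, default `60:130`.
#' @param tol absolute tolerance on the printed percentage, default 0.011
#'   (two printed decimals, truncated or rounded).
#' @return list: `best_I` (modal count, smallest on ties), `coverage`
#'   (data frame of `I` and `n_explained`), `all_explained` (TRUE when
#'   `best_I` explains every entry), `S` (integer `S` per entry under
#'   `best_I`, `NA` where unexplained).
#' @examples
#' infer_marker_count(bc1_recovery_table()$recovery)$best_I  # 108
#' @export
infer_marker_count <- function(rg, I_range = 60:130, tol = 0.011) {
  explains <- function(I, r) {
    S <- round(I * (r / 50 - 1))
    ok <- S >= 0 & S <= I & abs((I + S) / (2 * I) * 100 - r) <= tol
    ifelse(ok, S, NA_integer_)
  }
  cov <- vapply(I_range, function(I) sum(!is.na(explains(I, rg))), integer(1))
  best <- I_range[which.max(cov)]
  list(best_I = best,
       coverage = data.frame(I = I_range, n_explained = cov),
       all_explained = cov[which.max(cov)] == length(rg),
       S = explains(best, rg))
}

#' Per-plant scored-marker count
#'
#' For a single printed percentage, returns the representable `(I, S)`
#' pairs in `I_range` and the one whose `I` is nearest to a panel-level
#' `mode_I` (ties toward the smaller `I`).
#'
#' @param rg one printed percentage.
#' @param mode_I panel-level modal count (e.g. from [infer_marker_count()]).
#' @inheritParams infer_marker_count
#' @return list: `I`, `S` (the resolved pair), `candidates` (data frame of
#'   all representable pairs).
#' @export
resolve_marker_count <- function(rg, mode_I, I_range = 60:130, tol = 0.011) {
  S <- round(I_range * (rg / 50 - 1))
  ok <- S >= 0 & S <= I_range &
    abs((I_range + S) / (2 * I_range) * 100 - rg) <= tol
  cand <- data.frame(I = I_range[ok], S = S[ok])
  if (nrow(cand) == 0L) stop("no integer (I, S) represents ", rg, "%")
  i <- order(abs(cand$I - mode_I), cand$I)[1L]
  list(I = cand$I[i], S = cand$S[i], candidates = cand)
}
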