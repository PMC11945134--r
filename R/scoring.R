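#' Background recovery rate for one individual
#'
#' The recurrent-parent genome recovery statistic used for background
#' selection. With `I` scored (non-missing) markers of which `S` are
#' homozygous recurrent (`RR`), `het` heterozygous (`RD`) and `dd` homozygous
#' donor (`DD`), the recurrent allele fraction is
#'
#'   `Rg = (2 S + het) / (2 I) x 100`
#'
#' which reduces exactly to the classical backcross formula
#' `Rg = (I + S) / (2 I) x 100` whenever `dd = 0` (no donor homozygotes can
#' occur in a clean backcross, but they can in data; the allele-counting form
#' handles them instead of failing). Missing calls shrink `I`, so scored
#' marker counts are per-individual.
#'
#' @param calls character vector of genotype calls in `{RR, RD, DD}`,
#'   `NA` for missing.
#' @param id individual identifier carried into the report.
#' @return A one-row data frame (class `recovery_report`) with columns
#'   `id`, `I`, `S`, `het`, `dd`, `Rg`.
#' @examples
#' recovery_rate(c(rep("RR", 82), rep("RD", 26)))$Rg  # 87.96296
#' @export
recovery_rate <- function(calls, id = NA_character_) {
  calls <- as.character(calls)
  bad <- !is.na(calls) & !calls %in% c("RR", "RD", "DD")
  if (any(bad))
    stop("invalid genotype codes: ", paste(unique(calls[bad]), collapse = ", "))
  scored <- calls[!is.na(calls)]
  if (length(scored) == 0L)
    stop("individual ", id, " has no scored markers")
  S <- sum(scored == "RR")
  het <- sum(scored == "RD")
  dd <- sum(scored == "DD")
  I <- length(scored)
  rg <- (2 * S + het) / (2 * I) * 100
  out <- data.frame(id = id, I = I, S = S, het = het, dd = dd, Rg = rg,
                    stringsAsFactors = FALSE)
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' Recovery reports for a genotype matrix
#'
#' @param gmat character matrix, individuals x markers, entries in
#'   `{RR, RD, DD, NA}`; row names are individual ids.
#' @return data frame of per-individual [recovery_rate()] reports.
#' @export
recovery_report <- function(gmat) {
  if (is.null(rownames(gmat))) rownames(gmat) <- paste0("ind", seq_len(nrow(gmat)))
  out <- do.call(rbind, lapply(seq_len(nrow(gmat)), function(i) {
    recovery_rate(gmat[i, ], id = rownames(gmat)[i])
  }))
  rownames(out) <- NULL
  out
}

#' Background recovery from marker counts
#'
#' The closed-form backcross statistic `Rg = (I + S)/(2 I) x 100`, valid when
#' no donor homozygotes occur.
#'
#' @param I scored marker count.
#' @param S recurrent-homozygous marker count, `0 <= S <= I`.
#' @return recovery percentage.
#' @examples
#' recovery_formula(108, 82)  # 87.96296
#' @export
recovery_formula <- function(I, S) {
  if (any(I < 1) || any(S < 0) || any(S > I))
    stop("need I >= 1 and 0 <= S <= I")
  (I + S) / (2 * I) * 100
}

#' Chi-square test of a 1:1 segregation ratio
#'
#' Goodness-of-fit of observed positive:negative counts against the 1:1
#' Mendelian expectation for a hemizygous transgene in a backcross.
#' `chi2 = sum (O - E)^2 / E` with `E = (n1 + n2)/2`; with `yates = TRUE`
#' the numerators are `(|O - E| - 0.5)^2`. The test passes (the ratio is
#' consistent with 1:1) when the statistic does not exceed the critical
#' value, 3.84 for df = 1 at alpha = 0.05.
#'
#' @param n1,n2 observed counts (e.g. herbicide-resistant vs withered).
#' @param yates apply Yates continuity correction (default FALSE).
#' @param critical_value chi-square critical value (default
#'   `qchisq(0.95, 1)` printed as 3.84).
#' @return list of class `segregation_test`: `n_positive`, `n_negative`,
#'   `chi2`, `df`, `p_value`, `critical_value`, `pass`.
#' @examples
#' chi_square_1to1(111, 113)$chi2    # 0.01785714
#' chi_square_1to1(150, 50)$pass     # FALSE
#' @export
chi_square_1to1 <- function(n1, n2, yates = FALSE, critical_value = 3.84) {
  if (n1 < 0 || n2 < 0 || n1 + n2 == 0) stop("need n1 + n2 > 0, counts >= 0")
  E <- (n1 + n2) / 2
  dev <- abs(c(n1, n2) - E)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / E)
  structure(list(n_positive = n1, n_negative = n2, chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, 1L, lower.tail = FALSE),
                 critical_value = critical_value,
                 yates = yates,
                 pass = chi2 <= critical_value),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("1:1 segregation test: %d:%d, chi2 = %.4f (df = 1%s), %s vs %.2f\n",
              x$n_positive, x$n_negative, x$chi2,
              if (x$yates) ", Yates-corrected" else "",
              if (x$pass) "PASS" else "FAIL", x$critical_value))
  invisible(x)
}

#' Background selection
#'
#' Keeps individuals whose recovery rate strictly exceeds the threshold and
#' whose phenotype is acceptable, ordered by descending `Rg` then id.
#' Phenotype similarity to the recurrent parent is an external boolean flag
#' (no phenotype-distance metric is computed).
#'
#' @param reports data frame of recovery reports ([recovery_report()]).
#' @param min_rg threshold percentage; selection requires `Rg > min_rg`.
#' @param phenotype_ok logical vector aligned with `reports` rows (default
#'   all TRUE).
#' @return character vector of selected ids, descending `Rg`.
#' @export
select_individuals <- function(reports, min_rg, phenotype_ok = NULL) {
  if (is.null(phenotype_ok)) phenotype_ok <- rep(TRUE, nrow(reports))
  if (length(phenotype_ok) != nrow(reports))
    stop("`phenotype_ok` must align with `reports` rows")
  keep <- reports$Rg > min_rg & phenotype_ok
  sel <- reports[keep, , drop = FALSE]
  sel$id[order(-sel$Rg, sel$id)]
}

#' Homozygosity verdict from progeny screening
#'
#' After selfing, a homozygous transgenic line yields all-carrier progeny
#' while a hemizygous one segregates. With lethal (herbicide) screening the
#' progeny of a hemizygote are carriers with probability 3/4, so observing
#' `n` carriers out of `n` has probability `0.75^n` under the segregating
#' null; the verdict is withheld while that false-positive probability
#' exceeds `confidence_floor`.
#'
#' @param progeny_carrier_flags logical vector, one entry per tested progeny.
#' @param confidence_floor maximum acceptable `0.75^n` for a homozygous call
#'   (default 0.05, reached at n >= 11).
#' @return list: `verdict` (`"homozygous"`, `"segregating"` or
#'   `"inconclusive"`), `n`, `n_carriers`, `p_null` (probability of the
#'   all-carrier observation under a hemizygous parent).
#' @examples
#' homozygosity_by_progeny(rep(TRUE, 20))$verdict     # "homozygous"
#' homozygosity_by_progeny(c(TRUE, FALSE))$verdict    # "segregating"
#' @export
homozygosity_by_progeny <- function(progeny_carrier_flags,
                                    confidence_floor = 0.05) {
  n <- length(progeny_carrier_flags)
  if (n == 0L) stop("no progeny tested")
  k <- sum(progeny_carrier_flags)
  p_null <- 0.75^n
  verdict <- if (k < n) "segregating"
             else if (p_null <= confidence_floor) "homozygous"
             else "inconclusive"
  list(verdict = verdict, n = n, n_carriers = k, p_null = p_null)
}

#' Relative expression by the 2^-ddCt method
#'
#' `relative_expression = 2^-((ct_target - ct_reference) - calibrator_dct)`.
#' The calibrator delta-Ct is an explicit input (taken from the calibrator
#' sample's own target-minus-reference Ct difference).
#'
#' @param ct_target Ct of the target gene in the sample.
#' @param ct_reference Ct of the reference gene in the same sample.
#' @param calibrator_dct delta-Ct of the calibrator sample (default 0).
#' @return relative expression (vectorized).
#' @examples
#' ddct(22, 25)        # 8
#' ddct(20, 20, -1)    # 0.5
#' @export
ddct <- function(ct_target, ct_reference, calibrator_dct = 0) {
  vals <- c(ct_target, ct_reference, calibrator_dct)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  2^-((ct_target - ct_reference) - calibrator_dct)
}
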