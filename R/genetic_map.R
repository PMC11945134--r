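#' Genetic maps
#'
#' A `genetic_map` holds an ordered set of chromosomes with lengths in
#' centiMorgans, and optionally per-chromosome marker positions. It is the
#' coordinate system shared by the marker-panel spacing step and the meiosis
#' simulator: crossover counts are Poisson with mean `length_cM / 100`
#' (Haldane model, no interference).
#'
#' @param chrom character vector of chromosome names.
#' @param length_cM numeric vector of chromosome lengths in cM, all positive.
#' @param positions optional named list of numeric vectors: marker positions
#'   (cM) per chromosome, strictly increasing and within `[0, length_cM]`.
#' @return An object of class `genetic_map`: a data frame with columns
#'   `chrom` and `length_cM`, plus a `positions` attribute.
#' @examples
#' gm <- genetic_map(c("chr1", "chr2"), c(150, 100))
#' map_total_length(gm)
#' @export
genetic_map <- function(chrom, length_cM, positions = NULL) {
  chrom <- as.character(chrom)
  length_cM <- as.numeric(length_cM)
  if (length(chrom) != length(length_cM))
    stop("`chrom` and `length_cM` must have the same length")
  if (length(chrom) < 1L) stop("a genetic map needs at least one chromosome")
  if (anyDuplicated(chrom)) stop("duplicate chromosome names")
  if (any(!is.finite(length_cM)) || any(length_cM <= 0))
    stop("chromosome lengths must be positive and finite (cM)")
  if (!is.null(positions)) {
    if (is.null(names(positions)) || !all(names(positions) %in% chrom))
      stop("`positions` must be a named list keyed by chromosome name")
    for (ch in names(positions)) {
      p <- positions[[ch]]
      L <- length_cM[match(ch, chrom)]
      if (is.unsorted(p, strictly = TRUE))
        stop("marker positions on ", ch, " must be strictly increasing")
      if (any(p < 0) || any(p > L))
        stop("marker positions on ", ch, " outside [0, ", L, "]")
    }
  }
  out <- data.frame(chrom = chrom, length_cM = length_cM,
                    stringsAsFactors = FALSE)
  attr(out, "positions") <- positions
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map:", nrow(x), "chromosomes,",
      format(sum(x$length_cM), nsmall = 1), "cM total\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Total map length in centiMorgans
#' @param map a `genetic_map`.
#' @return numeric scalar, the sum of chromosome lengths.
#' @export
map_total_length <- function(map) sum(map$length_cM)

#' Chromosome length lookup
#' @param map a `genetic_map`.
#' @param chrom chromosome name(s).
#' @return numeric vector of lengths in cM.
#' @export
map_chrom_length <- function(map, chrom) {
  i <- match(chrom, map$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  map$length_cM[i]
}

# Default maize-like chromosome lengths (cM), decreasing chr1..chr10.
# Chosen so that a saturated 20 cM greedy spacing yields exactly
# floor(L/20)+1 markers per chromosome, 108 genome-wide; total 2040 cM
# sits inside the usual 2000-2200 cM range quoted for maize genetic maps.
.maize_default_lengths <- c(288, 248, 228, 208, 208, 188, 188, 168, 168, 148)

#' Build a maize-like genetic map
#'
#' Default: 10 chromosomes with lengths decreasing from 288 to 148 cM
#' (2040 cM total), a realistic maize-scale genetic map on which a 20 cM
#' marker spacing yields a panel of 108 markers.
#'
#' @param n_chrom number of chromosomes (default 10).
#' @param lengths_cM optional explicit lengths; overrides `total`.
#' @param total optional total map length; default lengths (or, for
#'   `n_chrom != 10`, equal lengths) are rescaled to sum to `total`.
#' @return a [genetic_map()].
#' @examples
#' make_maize_like_map()                # the default 10-chromosome map
#' make_maize_like_map(total = 2100)    # rescaled to 2100 cM
#' make_maize_like_map(1, lengths_cM = 100)
#' @export
make_maize_like_map <- function(n_chrom = 10L, lengths_cM = NULL, total = NULL) {
  n_chrom <- as.integer(n_chrom)
  if (is.na(n_chrom) || n_chrom < 1L) stop("`n_chrom` must be >= 1")
  if (is.null(lengths_cM)) {
    lengths_cM <- if (n_chrom == 10L) .maize_default_lengths
                  else rep(204, n_chrom)
    if (!is.null(total)) lengths_cM <- lengths_cM * total / sum(lengths_cM)
  } else {
    if (length(lengths_cM) != n_chrom)
      stop("`lengths_cM` must have length `n_chrom`")
  }
  genetic_map(paste0("chr", seq_len(n_chrom)), lengths_cM)
}

#' Evenly spaced marker positions on a map
#'
#' Places markers every `spacing` cM from position 0 on each chromosome
#' (the idealized panel geometry used for simulation-based recovery checks).
#'
#' @param map a `genetic_map`.
#' @param spacing_cM spacing between adjacent markers, default 20.
#' @return data frame with columns `marker`, `chrom`, `pos_cM`.
#' @examples
#' nrow(evenly_spaced_markers(make_maize_like_map()))  # 108
#' @export
evenly_spaced_markers <- function(map, spacing_cM = 20) {
  if (spacing_cM <= 0) stop("`spacing_cM` must be positive")
  pieces <- lapply(seq_len(nrow(map)), function(i) {
    pos <- seq(0, map$length_cM[i], by = spacing_cM)
    data.frame(chrom = map$chrom[i], pos_cM = pos, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- data.frame(marker = paste0(out$chrom, "_", out$pos_cM, "cM"), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Convert base-pair positions to centiMorgans
#'
#' Linear interpolation: a chromosome of `bp_len` bases maps uniformly onto
#' `[0, length_cM]`. No recombination-rate profile is assumed.
#'
#' @param map a `genetic_map`.
#' @param chrom chromosome name(s), recycled against `pos_bp`.
#' @param pos_bp 1-based base-pair position(s).
#' @param bp_len named vector: physical length (bp) per chromosome.
#' @return numeric vector of cM positions.
#' @export
bp_to_cM <- function(map, chrom, pos_bp, bp_len) {
  L <- map_chrom_length(map, chrom)
  n <- bp_len[chrom]
  if (anyNA(n)) stop("`bp_len` missing entries for some chromosomes")
  if (any(pos_bp < 1 | pos_bp > n)) stop("`pos_bp` outside chromosome bounds")
  unname((pos_bp - 0.5) / n * L)
}

#' Read / write a genetic map as TSV
#'
#' Columns: `chrom`, `length_cM`. Marker positions, when present, are stored
#' as a comma-separated `positions` column.
#'
#' @param map a `genetic_map`.
#' @param path file path.
#' @return `read_map` returns a `genetic_map`; `write_map` returns `path`
#'   invisibly.
#' @export
write_map <- function(map, path) {
  pos <- attr(map, "positions")
  df <- as.data.frame(map)
  df$positions <- vapply(df$chrom, function(ch) {
    if (is.null(pos) || is.null(pos[[ch]])) ""
    else paste(pos[[ch]], collapse = ",")
  }, character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  pos <- NULL
  if ("positions" %in% names(df)) {
    keep <- nzchar(df$positions)
    if (any(keep)) {
      pos <- lapply(df$positions[keep],
                    function(s) as.numeric(strsplit(s, ",")[[1]]))
      names(pos) <- df$chrom[keep]
    }
  }
  genetic_map(df$chrom, as.numeric(df$length_cM), positions = pos)
}
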