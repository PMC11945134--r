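#' Read a minimal two-sample VCF
#'
#' Parses the subset of VCF 4.x this pipeline consumes: `CHROM`, `POS`
#' (1-based), `ID`, `REF`, `ALT`, `QUAL`, and per-sample `GT` and `GQ`
#' from the `FORMAT` column for up to two samples. Records with symbolic
#' or multi-allelic ALT are skipped with a warning. Anything else in the
#' file is ignored.
#'
#' @param path VCF file path (uncompressed).
#' @return data frame: `chrom`, `pos`, `id`, `ref`, `alt`, `qual`, then
#'   `gt_<sample>` and `gq_<sample>` per sample (GQ is `NA` when absent).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "##fileformat=VCF"))
    stop("missing VCF header (##fileformat) in ", path)
  hdr <- which(startsWith(lines, "#CHROM"))
  if (length(hdr) != 1L) stop("missing #CHROM header line in ", path)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) stop("VCF has no sample columns")
  samples <- cols[10:min(length(cols), 11L)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  recs <- list()
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L)
      stop("malformed VCF record at data line ", k, " (", length(f), " fields)")
    if (grepl("[][<>]", f[5]) || grepl(",", f[5], fixed = TRUE)) {
      warning("skipping symbolic/multi-allelic record at data line ", k)
      next
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt); gq_i <- match("GQ", fmt)
    rec <- list(chrom = f[1], pos = as.integer(f[2]), id = f[3],
                ref = f[4], alt = f[5],
                qual = suppressWarnings(as.numeric(f[6])))
    for (s in seq_along(samples)) {
      sv <- strsplit(f[9L + s], ":", fixed = TRUE)[[1]]
      rec[[paste0("gt_", samples[s])]] <-
        if (is.na(gt_i) || gt_i > length(sv)) NA_character_ else sv[gt_i]
      gq <- if (is.na(gq_i) || gq_i > length(sv)) NA else
        suppressWarnings(as.integer(sv[gq_i]))
      rec[[paste0("gq_", samples[s])]] <- gq
    }
    recs[[length(recs) + 1L]] <- rec
  }
  if (length(recs) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), ref = character(0),
                      alt = character(0), qual = numeric(0))
    for (s in samples) {
      out[[paste0("gt_", s)]] <- character(0)
      out[[paste0("gq_", s)]] <- integer(0)
    }
  } else {
    out <- do.call(rbind, lapply(recs, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  attr(out, "samples") <- samples
  out
}

#' Write a minimal two-sample VCF 4.2
#'
#' Inverse of [read_vcf()] for the supported subset; a writer-reader round
#' trip preserves all parsed fields.
#'
#' @param records data frame as returned by [read_vcf()], or a founder
#'   `sites` table with `chrom`, `pos_bp`, `ref_allele`, `alt_allele`,
#'   `gq`, `gt_recurrent`, `gt_donor` columns.
#' @param path output path.
#' @param samples sample names, default taken from the `samples` attribute
#'   or `c("recurrent", "donor")`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path,
                      samples = attr(records, "samples")) {
  r <- records
  if (!is.null(r$pos_bp)) {  # founder sites table
    if (is.null(samples)) samples <- c("recurrent", "donor")
    r <- data.frame(chrom = r$chrom, pos = r$pos_bp,
                    id = if (is.null(r$site)) "." else r$site,
                    ref = r$ref_allele, alt = r$alt_allele, qual = NA_real_,
                    stringsAsFactors = FALSE)
    r[[paste0("gt_", samples[1])]] <- records$gt_recurrent
    r[[paste0("gq_", samples[1])]] <- records$gq
    r[[paste0("gt_", samples[2])]] <- records$gt_donor
    r[[paste0("gq_", samples[2])]] <- records$gq
  }
  if (is.null(samples)) stop("sample names unknown")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  fmt_gq <- function(x) ifelse(is.na(x), ".", as.character(x))
  for (i in seq_len(nrow(r))) {
    cells <- vapply(samples, function(s) {
      paste0(r[[paste0("gt_", s)]][i], ":", fmt_gq(r[[paste0("gq_", s)]][i]))
    }, character(1))
    writeLines(paste(c(r$chrom[i], r$pos[i], r$id[i], r$ref[i], r$alt[i],
                       ifelse(is.na(r$qual[i]), ".", r$qual[i]), "PASS", ".",
                       "GT:GQ", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings; sequences are returned as a named
#' character vector, normalized to upper case.
#'
#' @param path file path.
#' @param seqs named character vector of sequences.
#' @param width line-wrap width for writing, default 70.
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(x))) stop("duplicate sequence ids in ", path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("`seqs` must have unique names")
  x <- Biostrings::DNAStringSet(toupper(unlist(seqs)))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read / write a genotype matrix as CSV
#'
#' Rows are individuals (first column `id`), columns markers, cells in
#' `{RR, RD, DD}` with empty or `NA` for missing.
#'
#' @param gmat character matrix with row names (ids) and column names
#'   (markers).
#' @param path file path.
#' @return `read_genotypes` returns a character matrix; `write_genotypes`
#'   returns `path` invisibly.
#' @export
write_genotypes <- function(gmat, path) {
  df <- data.frame(id = rownames(gmat), gmat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  bad <- !is.na(m) & !m %in% c("RR", "RD", "DD")
  if (any(bad)) stop("invalid genotype codes in ", path, ": ",
                     paste(unique(m[bad]), collapse = ", "))
  m
}

#' Write a marker panel as TSV and BED
#'
#' The TSV carries the marker metadata; the BED (0-based, half-open) the
#' flank windows when present.
#'
#' @param panel a marker panel data frame.
#' @param tsv_path,bed_path output paths; either may be `NULL` to skip.
#' @return invisibly, a list of the written paths.
#' @export
write_panel <- function(panel, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    keep <- intersect(c("marker", "site", "chrom", "pos_bp", "pos_cM",
                        "length_diff_bp", "flank_gc", "flank_seq"),
                      names(panel))
    utils::write.table(as.data.frame(panel)[, keep], tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    if (is.null(panel$flank_start))
      stop("panel has no flank coordinates for BED output")
    bed <- data.frame(chrom = panel$chrom,
                      start = panel$flank_start - 1L,  # 1-based -> 0-based
                      end = panel$flank_end,
                      name = if (is.null(panel$site)) panel$marker
                             else panel$site)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(list(tsv = tsv_path, bed = bed_path))
}

#' Write a run manifest
#'
#' Every CLI run emits a JSON manifest: package version, seed, input paths
#' with MD5 digests, and a timestamp, so deterministic stages can be
#' re-run and checked byte-for-byte.
#'
#' @param path output JSON path.
#' @param seed seed used (or `NA`).
#' @param inputs named character vector of input file paths.
#' @param extra named list of extra fields.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, seed = NA, inputs = character(0),
                           extra = list()) {
  digests <- if (length(inputs))
    as.list(tools::md5sum(unlist(inputs))) else list()
  m <- c(list(tool = "mabcr",
              version = as.character(utils::packageVersion("mabcr")),
              seed = seed,
              inputs = digests,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
         extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(m)
}
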