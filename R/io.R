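# Readers and writers for the plain-text formats the pipeline exchanges:
# FASTA (via Biostrings), BED/BedGraph, PAF with cs:Z tags, and the variant
# tables the patching and copy-number stages consume (VCF via vcfR).

#' Read a FASTA assembly
#'
#' Soft-masked (lowercase) bases are uppercased on read; masking never
#' affects any landmark or liftover call downstream.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_assembly <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # strip descriptions after first whitespace, as mappers do
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::DNAStringSet(toupper(x))
}

#' Write a FASTA assembly (60-column wrap)
#'
#' @param x DNAStringSet (or named character vector).
#' @param path output file.
#' @export
write_assembly <- function(x, path) {
  if (!is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a BED file (3-6 columns)
#'
#' @param path BED file; track/browser lines are skipped.
#' @return interval data.frame with optional `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines)) return(.empty_intervals())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(parts))
  get <- function(i) vapply(parts, `[[`, "", i)
  df <- intervals(seqid = get(1), start = as.integer(get(2)), end = as.integer(get(3)))
  if (ncol >= 4) df$name <- get(4)
  if (ncol >= 5) df$score <- suppressWarnings(as.numeric(get(5)))
  if (ncol >= 6) df$strand <- get(6)
  df
}

#' Write intervals as BED
#'
#' Columns beyond `seqid`/`start`/`end` named `name`, `score`, `strand`
#' are written in BED order when present.
#'
#' @param x interval data.frame.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$seqid, x$start, x$end)
  for (extra in c("name", "score", "strand")) {
    if (!is.null(x[[extra]])) cols <- c(cols, list(x[[extra]])) else break
  }
  write.table(as.data.frame(cols), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 4-column BedGraph track
#'
#' @param path BedGraph file (seqid, start, end, value).
#' @return data.frame with columns `seqid`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "integer", "integer", "numeric"))
  names(df) <- c("seqid", "start", "end", "value")
  df
}

#' Write a 4-column BedGraph track
#'
#' @param x data.frame with `seqid`, `start`, `end`, `value`.
#' @param path output file.
#' @export
write_bedgraph <- function(x, path) {
  write.table(x[, c("seqid", "start", "end", "value")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read PAF alignments (with optional cs:Z tags)
#'
#' Parses the 12 mandatory PAF columns and extracts `cs:Z:` and `tp:A:`
#' tags when present. Coordinates stay 0-based half-open as in PAF.
#'
#' @param path PAF file.
#' @return data.frame with columns `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`,
#'   `cs` (NA when absent) and `tp` ("P" assumed when absent).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(qname = character(), qlen = integer(), qstart = integer(),
                      qend = integer(), strand = character(), tname = character(),
                      tlen = integer(), tstart = integer(), tend = integer(),
                      nmatch = integer(), alen = integer(), mapq = integer(),
                      cs = character(), tp = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(parts, `[[`, "", i)
  tag <- function(prefix, default) {
    vapply(parts, function(p) {
      hit <- p[startsWith(p, prefix)]
      if (length(hit)) substring(hit[1], nchar(prefix) + 1L) else default
    }, "")
  }
  data.frame(
    qname = get(1), qlen = as.integer(get(2)),
    qstart = as.integer(get(3)), qend = as.integer(get(4)),
    strand = get(5), tname = get(6), tlen = as.integer(get(7)),
    tstart = as.integer(get(8)), tend = as.integer(get(9)),
    nmatch = as.integer(get(10)), alen = as.integer(get(11)),
    mapq = as.integer(get(12)),
    cs = tag("cs:Z:", NA_character_), tp = tag("tp:A:", "P"),
    stringsAsFactors = FALSE
  )
}

#' Write PAF alignments
#'
#' @param x data.frame as returned by [read_paf()].
#' @param path output file.
#' @export
write_paf <- function(x, path) {
  base <- apply(as.data.frame(x[, c("qname", "qlen", "qstart", "qend", "strand",
                                    "tname", "tlen", "tstart", "tend",
                                    "nmatch", "alen", "mapq")]),
                1, paste, collapse = "\t")
  tags <- paste0("tp:A:", if (is.null(x$tp)) "P" else x$tp)
  has_cs <- !is.null(x$cs) & !is.na(x$cs)
  tags[has_cs] <- paste0(tags[has_cs], "\tcs:Z:", x$cs[has_cs])
  writeLines(if (nrow(x)) paste(base, tags, sep = "\t") else character(), path)
  invisible(path)
}

#' Read a variant table from VCF
#'
#' Extracts position, REF/ALT, total depth and variant-allele ratio from an
#' uncompressed VCF. Depth is taken from INFO `DP`; the allele ratio from
#' INFO `VAF` when present, otherwise from `AD` on the first sample
#' (alt / (ref + alt)). Multi-allelic records keep the first ALT. Malformed
#' rows are dropped with a count carried in `attr(, "n_skipped")`.
#'
#' @param path VCF file.
#' @return data.frame with `seqid`, `pos` (1-based), `ref`, `alt`, `depth`,
#'   `ratio`.
#' @export
read_variants <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_variants requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- sub(",.*$", "", fix[, "ALT"])
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  vaf <- suppressWarnings(as.numeric(vcfR::extract.info(v, "VAF")))
  if (all(is.na(vaf)) && ncol(v@gt) >= 2) {
    ad <- vcfR::extract.gt(v, "AD")[, 1]
    counts <- strsplit(ad, ",", fixed = TRUE)
    vaf <- vapply(counts, function(x) {
      x <- suppressWarnings(as.numeric(x))
      if (length(x) < 2 || any(is.na(x)) || sum(x[1:2]) == 0) return(NA_real_)
      x[2] / (x[1] + x[2])
    }, 0)
  }
  df <- data.frame(seqid = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                   ref = fix[, "REF"], alt = alt, depth = dp, ratio = vaf,
                   stringsAsFactors = FALSE)
  ok <- !is.na(df$pos) & nzchar(df$ref) & nzchar(df$alt) & df$alt != "."
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Write a variant table as a minimal VCF
#'
#' Depth and allele ratio go to INFO as `DP` and `VAF`. Written uncompressed.
#'
#' @param x data.frame with `seqid`, `pos`, `ref`, `alt` and optional
#'   `depth`, `ratio`.
#' @param path output file.
#' @export
write_variants <- function(x, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele ratio\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- rep("", nrow(x))
  if (!is.null(x$depth)) info <- paste0("DP=", as.integer(round(x$depth)))
  if (!is.null(x$ratio)) {
    vaf <- paste0("VAF=", format(x$ratio, trim = TRUE, scientific = FALSE))
    info <- ifelse(nzchar(info), paste(info, vaf, sep = ";"), vaf)
  }
  info[!nzchar(info)] <- "."
  body <- if (nrow(x)) paste(x$seqid, x$pos, ".", x$ref, x$alt, ".", "PASS", info,
                             sep = "\t") else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
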