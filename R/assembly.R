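# Assembly contiguity statistics and variant-based reference patching.

# maximal N-runs of a single sequence as 0-based half-open intervals
.n_runs <- function(dna, min_run = 1L) {
  m <- gregexpr("N+", as.character(dna))[[1]]
  if (m[1] == -1) return(intervals())
  st <- as.integer(m) - 1L
  w <- attr(m, "match.length")
  keep <- w >= min_run
  intervals(seqid = rep("seq", sum(keep)), start = st[keep],
            end = st[keep] + w[keep])
}

.n50_l50 <- function(lengths) {
  lengths <- sort(lengths[lengths > 0], decreasing = TRUE)
  if (!length(lengths)) return(c(n50 = 0, l50 = 0))
  k <- which(cumsum(as.numeric(lengths)) >= sum(as.numeric(lengths)) / 2)[1]
  c(n50 = lengths[k], l50 = k)
}

#' Assembly contiguity statistics
#'
#' Computes scaffold and contig counts, N50/L50 for each, gap count and gap
#' density. A gap is a maximal run of N bases of length at least
#' `min_gap_run`; contigs are scaffolds split at gaps. N50 is the length of
#' the shortest piece in the smallest prefix of the descending-sorted
#' lengths whose sum reaches half the total; L50 is that prefix's size.
#' Gap density is gaps per Mb of total assembly length.
#'
#' @param assembly DNAStringSet (or named character vector).
#' @param min_gap_run minimum N-run length counted as a gap (default 1;
#'   set 10 for NCBI-style conventions).
#' @return list with `n_scaffolds`, `scaffold_n50`, `scaffold_l50`,
#'   `n_contigs`, `contig_n50`, `contig_l50`, `n_gaps`, `gap_density`,
#'   `total_bases`, `ungapped_bases`.
#' @export
assembly_stats <- function(assembly, min_gap_run = 1L) {
  if (!is(assembly, "DNAStringSet")) assembly <- Biostrings::DNAStringSet(assembly)
  if (!length(assembly)) stop("assembly has no sequences")
  scaff_len <- BiocGenerics::width(assembly)
  contig_len <- integer()
  n_gaps <- 0L
  gap_bases <- 0L
  for (i in seq_along(assembly)) {
    runs <- .n_runs(assembly[[i]], min_gap_run)
    n_gaps <- n_gaps + nrow(runs)
    gap_bases <- gap_bases + sum(runs$end - runs$start)
    bounds <- c(0L, rbind(runs$start, runs$end), scaff_len[i])
    seg <- matrix(bounds, ncol = 2, byrow = TRUE)
    contig_len <- c(contig_len, (seg[, 2] - seg[, 1])[seg[, 2] > seg[, 1]])
  }
  total <- sum(as.numeric(scaff_len))
  s50 <- .n50_l50(scaff_len)
  c50 <- .n50_l50(contig_len)
  list(n_scaffolds = length(assembly),
       scaffold_n50 = unname(s50["n50"]), scaffold_l50 = unname(s50["l50"]),
       n_contigs = length(contig_len),
       contig_n50 = unname(c50["n50"]), contig_l50 = unname(c50["l50"]),
       n_gaps = n_gaps, gap_density = n_gaps / (total / 1e6),
       total_bases = total, ungapped_bases = total - gap_bases)
}

#' Patch a reference with high-confidence variant alleles
#'
#' Replaces the reference allele with the variant allele at sites whose
#' sequencing depth is at least `min_depth` (inclusive) and whose variant
#' allele ratio strictly exceeds `min_ratio`. Indels shift downstream
#' coordinates; replacements are applied in original coordinates in one
#' pass, so callers supply positions on the input assembly. Sites whose
#' stated reference allele does not match the assembly are skipped and
#' flagged, not fatal; sites overlapping an earlier applied site are
#' likewise skipped.
#'
#' @param assembly DNAStringSet.
#' @param variants data.frame with `seqid`, `pos` (1-based), `ref`, `alt`
#'   and per-site `depth` and `ratio`.
#' @param min_depth inclusive depth threshold (default 30).
#' @param min_ratio strict allele-ratio threshold (default 0.90).
#' @return list with `assembly` (patched DNAStringSet) and `report` (the
#'   input sites plus `applied`, `reason` and `new_pos` columns; `new_pos`
#'   is the site's 1-based position on the patched assembly, accounting
#'   for upstream indel shifts).
#'
#' @details A site is recognised as already applied — and skipped — when
#' the variant allele is present at its position while the reference
#' allele is not (or, for insertions, even while the reference prefix
#' still matches). This makes patching idempotent: re-running the
#' applied-site report against the patched assembly applies nothing.
#' @export
patch_reference <- function(assembly, variants, min_depth = 30, min_ratio = 0.90) {
  if (!is(assembly, "DNAStringSet")) assembly <- Biostrings::DNAStringSet(assembly)
  v <- variants[order(variants$seqid, variants$pos), , drop = FALSE]
  v$applied <- FALSE
  v$new_pos <- NA_integer_
  v$reason <- "applied"
  v$reason[v$depth < min_depth] <- "low_depth"
  low_ratio <- v$depth >= min_depth & v$ratio <= min_ratio
  v$reason[low_ratio] <- "low_ratio"
  out <- assembly
  for (s in unique(v$seqid)) {
    idx <- which(v$seqid == s & v$reason == "applied")
    if (!s %in% names(assembly)) {
      v$reason[v$seqid == s & v$reason == "applied"] <- "unknown_sequence"
      next
    }
    if (!length(idx)) next
    seq <- assembly[[s]]
    grab <- function(from, to) {
      ok <- to <= length(seq) & from >= 1
      res <- rep(NA_character_, length(from))
      if (any(ok)) res[ok] <- as.character(Biostrings::extractAt(
        seq, IRanges::IRanges(from[ok], to[ok])))
      res
    }
    obs_ref <- grab(v$pos[idx], v$pos[idx] + nchar(v$ref[idx]) - 1L)
    obs_alt <- grab(v$pos[idx], v$pos[idx] + nchar(v$alt[idx]) - 1L)
    ref_ok <- !is.na(obs_ref) & obs_ref == v$ref[idx]
    alt_ok <- !is.na(obs_alt) & obs_alt == v$alt[idx]
    done <- alt_ok & (!ref_ok | nchar(v$alt[idx]) > nchar(v$ref[idx]))
    v$reason[idx[done]] <- "already_applied"
    v$reason[idx[!done & !ref_ok]] <- "ref_mismatch"
    idx <- idx[!done & ref_ok]
    if (length(idx) > 1) {
      keep <- rep(TRUE, length(idx))
      last_end <- v$pos[idx[1]] + nchar(v$ref[idx[1]]) - 1L
      for (j in seq_along(idx)[-1]) {
        if (v$pos[idx[j]] <= last_end) keep[j] <- FALSE
        else last_end <- v$pos[idx[j]] + nchar(v$ref[idx[j]]) - 1L
      }
      v$reason[idx[!keep]] <- "overlap"
      idx <- idx[keep]
    }
    if (!length(idx)) next
    patched <- Biostrings::replaceAt(
      seq, IRanges::IRanges(v$pos[idx], v$pos[idx] + nchar(v$ref[idx]) - 1L),
      Biostrings::DNAStringSet(v$alt[idx]))
    out[[s]] <- patched
    v$applied[idx] <- TRUE
    shift <- cumsum(c(0L, nchar(v$alt[idx]) - nchar(v$ref[idx])))
    v$new_pos[idx] <- v$pos[idx] + shift[seq_along(idx)]
  }
  v$reason[!v$applied & v$reason == "applied"] <- "not_applied"
  list(assembly = out, report = v)
}
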