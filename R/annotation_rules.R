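# Annotation-derived filter rules: functional overlap of filled gaps,
# novel-gene criteria, ORF detection, lncRNA classification and
# transcript-model filtering.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id identifiers.
#' @param seqid sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons interval data.frame (`start`, `end`, 0-based half-open),
#'   sorted and non-overlapping.
#' @param cds optional `c(start, end)` of the CDS span in genomic
#'   coordinates (within the exon union).
#' @param longest_orf_aa longest ORF length in amino acids (computed with
#'   [find_orfs()] when a spliced sequence is available).
#' @param blast_cover_fraction optional best-hit coverage fraction from an
#'   upstream homology search.
#' @param pseudogene logical.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, seqid, strand, exons,
                             cds = NULL, longest_orf_aa = 0L,
                             blast_cover_fraction = NA_real_,
                             pseudogene = FALSE) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1)
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] < head(exons$end, -1)))
    stop("exons overlap in transcript ", transcript_id)
  if (!is.null(cds)) {
    stopifnot(length(cds) == 2, cds[1] >= exons$start[1],
              cds[2] <= exons$end[nrow(exons)])
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 seqid = seqid, strand = strand, exons = exons, cds = cds,
                 longest_orf_aa = as.integer(longest_orf_aa),
                 blast_cover_fraction = blast_cover_fraction,
                 pseudogene = isTRUE(pseudogene)),
            class = "transcript_model")
}

.tx_span <- function(tx) c(tx$exons$start[1], tx$exons$end[nrow(tx$exons)])
.tx_spliced_length <- function(tx) sum(tx$exons$end - tx$exons$start)

#' Flag filled gaps overlapping functional features
#'
#' A fill is flagged for a feature class when any feature of that class
#' overlaps it by at least `min_overlap` bases.
#'
#' @param fills interval data.frame of filled-gap intervals (new-assembly
#'   coordinates), one row per fill.
#' @param feature_sets named list of interval data.frames (e.g.
#'   `list(exon = ..., atac_peak = ..., mirna = ...)`).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return list with `flags` (fills plus one logical column per class and
#'   `any_class`), `class_counts` and `combination_counts`.
#' @export
functional_overlap <- function(fills, feature_sets, min_overlap = 1L) {
  flags <- fills
  for (cl in names(feature_sets)) {
    fs <- merge_intervals(feature_sets[[cl]])
    flags[[cl]] <- vapply(seq_len(nrow(fills)), function(i) {
      d <- fs[fs$seqid == fills$seqid[i], , drop = FALSE]
      if (!nrow(d)) return(FALSE)
      any(pmin(d$end, fills$end[i]) - pmax(d$start, fills$start[i]) >= min_overlap)
    }, TRUE)
  }
  cls <- names(feature_sets)
  flags$any_class <- if (length(cls))
    Reduce(`|`, flags[cls]) else rep(FALSE, nrow(flags))
  combo <- if (length(cls) && nrow(flags)) {
    apply(as.matrix(flags[, cls, drop = FALSE]), 1, function(m)
      if (any(m)) paste(cls[m], collapse = "+") else "none")
  } else character()
  list(flags = flags,
       class_counts = vapply(cls, function(cl) sum(flags[[cl]]), 0L),
       combination_counts = table(combo))
}

#' Evaluate novel-gene criteria against filled gaps
#'
#' A gene is a novel-gene candidate when (1) at least 80% of its body is
#' covered by filled-gap sequence (inclusive bound), (2) it is not a
#' pseudogene, (3) it was not annotated on unplaced scaffolds of the old
#' assembly, and (4) no duplicated/homologous fragment of it exists
#' elsewhere in the genome. Criteria 2-4 are consumed as precomputed
#' booleans.
#'
#' @param genes data.frame with `gene_id`, `seqid`, `start`, `end`,
#'   `pseudogene`, `in_unplaced`, `homolog_elsewhere`.
#' @param fills interval data.frame of filled-gap intervals.
#' @param min_body_fraction inclusive coverage threshold (default 0.80).
#' @return `genes` with `body_fraction`, per-criterion logicals
#'   `crit1_body` ... `crit4_no_homolog` and `candidate`.
#' @export
novel_gene_candidates <- function(genes, fills, min_body_fraction = 0.80) {
  fills <- merge_intervals(fills)
  genes$body_fraction <- vapply(seq_len(nrow(genes)), function(i)
    covered_fraction(genes[i, c("seqid", "start", "end")], fills), 0)
  genes$crit1_body <- genes$body_fraction >= min_body_fraction
  genes$crit2_not_pseudo <- !genes$pseudogene
  genes$crit3_not_unplaced <- !genes$in_unplaced
  genes$crit4_no_homolog <- !genes$homolog_elsewhere
  genes$candidate <- genes$crit1_body & genes$crit2_not_pseudo &
    genes$crit3_not_unplaced & genes$crit4_no_homolog
  genes
}

.STOPS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame of a spliced transcript sequence
#'
#' Scans the three sense-strand frames for the longest ATG-initiated,
#' stop-terminated reading frame. The amino-acid length excludes the
#' stop. By default an ORF must end at a stop codon; `require_stop =
#' FALSE` also allows frames running off the sequence end.
#'
#' @param sequence spliced transcript sequence, 5' to 3' (character or
#'   DNAString).
#' @param require_stop require a terminating stop codon (default TRUE).
#' @return list with `aa_length`, `frame` (0-2), `start`, `end`
#'   (0-based half-open nt coordinates including the stop codon), or
#'   `aa_length = 0` when no ORF exists.
#' @export
find_orfs <- function(sequence, require_stop = TRUE) {
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  best <- list(aa_length = 0L, frame = NA_integer_,
               start = NA_integer_, end = NA_integer_)
  for (f in 0:2) {
    n_cod <- (n - f) %/% 3
    if (n_cod < 1) next
    codons <- substring(s, f + 1L + 3L * (seq_len(n_cod) - 1L),
                        f + 3L * seq_len(n_cod))
    atg <- which(codons == "ATG")
    stops <- which(codons %in% .STOPS)
    for (a in atg) {
      nxt <- stops[stops > a]
      if (length(nxt)) {
        stop_i <- nxt[1]
        aa <- stop_i - a
        end_nt <- f + 3L * stop_i
      } else {
        if (require_stop) next
        aa <- n_cod - a + 1L
        end_nt <- f + 3L * n_cod
      }
      if (aa > best$aa_length) {
        best <- list(aa_length = aa, frame = f,
                     start = f + 3L * (a - 1L), end = end_nt)
      }
    }
  }
  best
}

#' Long noncoding RNA classification
#'
#' A transcript is lncRNA when it has at least two exons, a spliced
#' length strictly greater than 200 nt, no ORF of 100 or more amino acids
#' (an ORF of exactly 100 aa meets the protein-coding definition, so the
#' coding call wins there), and no overlap with protein-coding exons on
#' the same strand.
#'
#' @param tx a [transcript_model()] with `longest_orf_aa` set.
#' @param coding_exons interval data.frame of protein-coding exons with a
#'   `strand` column.
#' @param min_length strict spliced-length bound in nt (default 200).
#' @param max_orf_aa ORFs at or above this length disqualify (default 100).
#' @return logical.
#' @export
classify_lncrna <- function(tx, coding_exons, min_length = 200L,
                            max_orf_aa = 100L) {
  stopifnot(inherits(tx, "transcript_model"))
  if (nrow(tx$exons) < 2) return(FALSE)
  if (.tx_spliced_length(tx) <= min_length) return(FALSE)
  if (tx$longest_orf_aa >= max_orf_aa) return(FALSE)
  ce <- coding_exons[coding_exons$seqid == tx$seqid &
                       coding_exons$strand == tx$strand, , drop = FALSE]
  for (i in seq_len(nrow(tx$exons))) {
    if (.overlaps_any(tx$seqid, tx$exons$start[i], tx$exons$end[i],
                      ce[, c("seqid", "start", "end")])) return(FALSE)
  }
  TRUE
}

# exon count wholly downstream (3'-ward) of the stop codon
.exons_past_stop <- function(tx) {
  if (is.null(tx$cds)) return(0L)
  if (tx$strand == "+") sum(tx$exons$start >= tx$cds[2])
  else sum(tx$exons$end <= tx$cds[1])
}

#' Filter transcript models
#'
#' Applies the three removal rules in order:
#' \enumerate{
#'   \item long single-exon models: exon count 1, genomic span > 10 kb and
#'     intronic fraction of the span < 10% (trivially true for a single
#'     exon, so the span alone decides);
#'   \item internal-priming artefacts: the genomic window directly
#'     downstream of the 3' end contains a polyA run (>= `polya_min` A on
#'     the plus strand, T on the minus strand, within `polya_window` bp);
#'   \item within genes that retain at least one high-scoring transcript
#'     (BLAST coverage >= 0.5 and at most 2 exons past the stop codon),
#'     members with more than 2 exons wholly downstream of the stop codon
#'     or BLAST coverage < 0.5 are removed.
#' }
#'
#' @param models list of [transcript_model()] objects.
#' @param genome optional DNAStringSet; rule 2 is skipped with a warning
#'   when absent.
#' @param max_single_exon_span rule 1 span bound in bp (default 10 kb).
#' @param max_intronic_fraction rule 1 strict intronic-fraction bound.
#' @param polya_window,polya_min rule 2 window (bp) and minimum A/T count.
#' @param min_blast rule 3 BLAST-coverage bound (default 0.5).
#' @param max_exons_past_stop rule 3 bound (default 2).
#' @return list with `retained` (models) and `log` (data.frame of
#'   `transcript_id`, `gene_id`, `rule` per removal).
#' @export
filter_transcripts <- function(models, genome = NULL,
                               max_single_exon_span = 10000L,
                               max_intronic_fraction = 0.10,
                               polya_window = 20L, polya_min = 12L,
                               min_blast = 0.5, max_exons_past_stop = 2L) {
  log <- data.frame(transcript_id = character(), gene_id = character(),
                    rule = character(), stringsAsFactors = FALSE)
  drop <- logical(length(models))
  note <- function(tx, rule) {
    log <<- rbind(log, data.frame(transcript_id = tx$transcript_id,
                                  gene_id = tx$gene_id, rule = rule,
                                  stringsAsFactors = FALSE))
  }
  if (is.null(genome))
    warning("no genome supplied; polyA/T rule (rule 2) skipped")
  for (i in seq_along(models)) {
    tx <- models[[i]]
    span <- .tx_span(tx)
    span_len <- span[2] - span[1]
    intronic <- (span_len - .tx_spliced_length(tx)) / span_len
    if (nrow(tx$exons) == 1 && span_len > max_single_exon_span &&
        intronic < max_intronic_fraction) {
      drop[i] <- TRUE; note(tx, "single_exon_long"); next
    }
    if (!is.null(genome)) {
      seq <- genome[[tx$seqid]]
      if (tx$strand == "+") {
        a <- span[2] + 1L; b <- min(length(seq), span[2] + polya_window)
        if (b >= a) {
          win <- Biostrings::subseq(seq, a, b)
          n_a <- Biostrings::letterFrequency(win, "A")[1]
          if (n_a >= polya_min) { drop[i] <- TRUE; note(tx, "polyA"); next }
        }
      } else {
        a <- max(1L, span[1] - polya_window + 1L); b <- span[1]
        if (b >= a) {
          win <- Biostrings::subseq(seq, a, b)
          n_t <- Biostrings::letterFrequency(win, "T")[1]
          if (n_t >= polya_min) { drop[i] <- TRUE; note(tx, "polyA"); next }
        }
      }
    }
  }
  survivors <- models[!drop]
  gene_of <- vapply(survivors, `[[`, "", "gene_id")
  is_high <- vapply(survivors, function(tx) {
    !is.na(tx$blast_cover_fraction) && tx$blast_cover_fraction >= min_blast &&
      .exons_past_stop(tx) <= max_exons_past_stop
  }, TRUE)
  drop2 <- logical(length(survivors))
  for (g in unique(gene_of)) {
    idx <- which(gene_of == g)
    if (!any(is_high[idx])) next
    for (i in idx) {
      tx <- survivors[[i]]
      bad_blast <- !is.na(tx$blast_cover_fraction) &&
        tx$blast_cover_fraction < min_blast
      if (.exons_past_stop(tx) > max_exons_past_stop || bad_blast) {
        drop2[i] <- TRUE; note(tx, "stop_exons_or_blast")
      }
    }
  }
  list(retained = survivors[!drop2], log = log)
}
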