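# Old-assembly gap extraction, flank placement on a new assembly,
# closed/artificial/unresolved classification, and filled-sequence profiling.

#' Extract N-run gaps and their flanks from an old assembly
#'
#' One record per maximal N-run of length >= `min_gap_run`. Each gap gets
#' up to `flank` bp of flanking sequence on either side; flanks are
#' clipped at sequence ends and at neighbouring gaps and flagged
#' `flank_truncated` when shorter than `flank`.
#'
#' @param old DNAStringSet (the gapped assembly).
#' @param flank flank width in bp (default 1000).
#' @param min_gap_run minimum N-run length counted as a gap (default 1).
#' @return data.frame with `gap_id`, `seqid`, `old_start`, `old_end`,
#'   `n_length`, left/right flank coordinates (`lf_start` ... `rf_end`)
#'   and `flank_truncated`.
#' @export
extract_gaps <- function(old, flank = 1000L, min_gap_run = 1L) {
  if (!is(old, "DNAStringSet")) old <- Biostrings::DNAStringSet(old)
  rows <- list()
  for (s in names(old)) {
    runs <- .n_runs(old[[s]], min_gap_run)
    if (!nrow(runs)) next
    len <- length(old[[s]])
    for (i in seq_len(nrow(runs))) {
      gs <- runs$start[i]; ge <- runs$end[i]
      lf_lo <- if (i > 1) runs$end[i - 1] else 0L
      rf_hi <- if (i < nrow(runs)) runs$start[i + 1] else len
      lf_start <- max(lf_lo, gs - flank)
      rf_end <- min(rf_hi, ge + flank)
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = s, old_start = gs, old_end = ge, n_length = ge - gs,
        lf_start = lf_start, lf_end = gs, rf_start = ge, rf_end = rf_end,
        flank_truncated = (gs - lf_start) < flank | (rf_end - ge) < flank,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, c(list(data.frame(
    seqid = character(), old_start = integer(), old_end = integer(),
    n_length = integer(), lf_start = integer(), lf_end = integer(),
    rf_start = integer(), rf_end = integer(), flank_truncated = logical())),
    rows))
  df <- cbind(gap_id = if (nrow(df)) sprintf("gap%05d", seq_len(nrow(df)))
              else character(), df)
  rownames(df) <- NULL
  df
}

.hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# seeded exact-k-mer anchor mapper, batched over queries: exact matches
# of max_mismatch + 1 disjoint seeds per query generate candidate
# diagonals (pigeonhole guarantees at least one seed is exact whenever a
# full-length placement with at most max_mismatch substitutions exists);
# candidates are verified over the full query by Hamming distance on both
# strands. One matchPDict pass per target sequence carries all seeds.
.map_queries <- function(queries, new, k, max_mismatch) {
  new_chars <- as.list(as.character(new))
  n_q <- length(queries)
  res <- vector("list", n_q)
  seed_q <- integer(); seed_off <- integer(); seed_strand <- character()
  seed_seq <- character()
  q_fwd <- character(n_q); q_rev <- character(n_q)
  for (i in seq_len(n_q)) {
    q <- queries[[i]]
    L <- nchar(q)
    if (is.na(q) || L < k) next
    q_fwd[i] <- q
    q_rev[i] <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
    n_seeds <- min(max_mismatch + 1L, L %/% k)
    offs <- if (n_seeds == 1) 0L else
      as.integer(round(seq(0, L - k, length.out = n_seeds)))
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") q_fwd[i] else q_rev[i]
      for (o in offs) {
        sd <- substr(qs, o + 1L, o + k)
        if (grepl("N", sd, fixed = TRUE)) next
        seed_q <- c(seed_q, i); seed_off <- c(seed_off, o)
        seed_strand <- c(seed_strand, strand); seed_seq <- c(seed_seq, sd)
      }
    }
  }
  if (!length(seed_seq)) return(res)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_seq))
  cand <- vector("list", n_q)  # per query: data.frame(seqid, start, strand)
  for (s in names(new_chars)) {
    m <- Biostrings::matchPDict(pd, new[[s]])
    starts <- BiocGenerics::start(m)
    for (j in which(lengths(starts) > 0)) {
      i <- seed_q[j]
      st <- (starts[[j]] - 1L) - seed_off[j]
      L <- nchar(q_fwd[i])
      st <- st[st >= 0 & st + L <= nchar(new_chars[[s]])]
      if (!length(st)) next
      cand[[i]] <- rbind(cand[[i]], data.frame(
        seqid = s, start = st, strand = seed_strand[j],
        stringsAsFactors = FALSE))
    }
  }
  for (i in seq_len(n_q)) {
    cc <- cand[[i]]
    if (is.null(cc)) next
    cc <- unique(cc)
    L <- nchar(q_fwd[i])
    best <- NULL; best_mm <- Inf; n_best <- 0L
    for (r in seq_len(nrow(cc))) {
      q <- if (cc$strand[r] == "+") q_fwd[i] else q_rev[i]
      tgt <- substr(new_chars[[cc$seqid[r]]], cc$start[r] + 1L, cc$start[r] + L)
      mm <- .hamming(q, tgt)
      if (mm > max_mismatch) next
      if (mm < best_mm) { best <- cc[r, ]; best_mm <- mm; n_best <- 1L }
      else if (mm == best_mm) n_best <- n_best + 1L
    }
    if (is.null(best)) next
    res[[i]] <- list(seqid = best$seqid, start = best$start,
                     end = best$start + L, strand = best$strand,
                     mapq = if (n_best == 1L) 60L else 0L,
                     mismatches = best_mm, multi_hit = n_best > 1L)
  }
  res
}

#' Place gap flanks on a new assembly
#'
#' Uses the built-in seeded exact-k-mer anchor mapper: a flank is placed
#' where its full length aligns with at most `max_mismatch` substitutions;
#' a unique placement gets mapq 60, multiple equally good placements mapq
#' 0 with the `multi_hit` flag, no placement leaves the flank unplaced.
#' Flanks shorter than `k` are skipped (they stay unplaced). For real
#' data, placements from an external mapper can be ingested instead with
#' [ingest_placements()].
#'
#' @param gaps data.frame from [extract_gaps()].
#' @param old,new DNAStringSets (flanks are read from `old`).
#' @param k seed k-mer length (default 31).
#' @param max_mismatch maximum substitutions across the flank (default 2).
#' @return `gaps` with placement columns `lp_seqid`, `lp_start`, `lp_end`,
#'   `lp_strand`, `lp_mapq`, `lp_multi` and the `rp_*` equivalents.
#' @export
place_flanks <- function(gaps, old, new, k = 31L, max_mismatch = 2L) {
  if (!is(old, "DNAStringSet")) old <- Biostrings::DNAStringSet(old)
  if (!is(new, "DNAStringSet")) new <- Biostrings::DNAStringSet(new)
  queries <- character(2L * nrow(gaps))  # interleaved left/right
  for (i in seq_len(nrow(gaps))) {
    oldseq <- old[[gaps$seqid[i]]]
    for (side in 1:2) {
      a <- if (side == 1) gaps$lf_start[i] else gaps$rf_start[i]
      b <- if (side == 1) gaps$lf_end[i] else gaps$rf_end[i]
      queries[2L * (i - 1L) + side] <- if (b - a >= k)
        as.character(Biostrings::subseq(oldseq, a + 1L, b)) else NA_character_
    }
  }
  hits <- .map_queries(queries, new, k, max_mismatch)
  for (side in c("l", "r")) {
    off <- if (side == "l") 1L else 2L
    h <- hits[seq.int(off, by = 2L, length.out = nrow(gaps))]
    get <- function(field, miss) vapply(h, function(x)
      if (is.null(x)) miss else x[[field]], miss)
    gaps[[paste0(side, "p_seqid")]] <- get("seqid", NA_character_)
    gaps[[paste0(side, "p_start")]] <- as.integer(get("start", NA_real_))
    gaps[[paste0(side, "p_end")]] <- as.integer(get("end", NA_real_))
    gaps[[paste0(side, "p_strand")]] <- get("strand", NA_character_)
    gaps[[paste0(side, "p_mapq")]] <- as.integer(get("mapq", NA_real_))
    gaps[[paste0(side, "p_multi")]] <- get("multi_hit", FALSE)
  }
  gaps
}

#' Ingest flank placements from external PAF alignments
#'
#' Expects flank query names of the form `<gap_id>:L` / `<gap_id>:R`
#' (as written by [write_flank_fasta()]). Only primary records are used;
#' a flank with several primary records is treated as unplaced with
#' `multi_hit`.
#'
#' @param gaps data.frame from [extract_gaps()].
#' @param paf data.frame from [read_paf()].
#' @return `gaps` with the same placement columns as [place_flanks()].
#' @export
ingest_placements <- function(gaps, paf) {
  paf <- paf[paf$tp != "S", , drop = FALSE]
  for (side in c("l", "r")) {
    tagname <- paste0(gaps$gap_id, ":", toupper(side))
    gaps[[paste0(side, "p_seqid")]] <- NA_character_
    gaps[[paste0(side, "p_start")]] <- NA_integer_
    gaps[[paste0(side, "p_end")]] <- NA_integer_
    gaps[[paste0(side, "p_strand")]] <- NA_character_
    gaps[[paste0(side, "p_mapq")]] <- NA_integer_
    gaps[[paste0(side, "p_multi")]] <- FALSE
    for (i in seq_len(nrow(gaps))) {
      hits <- paf[paf$qname == tagname[i], , drop = FALSE]
      if (nrow(hits) == 0) next
      if (nrow(hits) > 1) { gaps[[paste0(side, "p_multi")]][i] <- TRUE; next }
      gaps[[paste0(side, "p_seqid")]][i] <- hits$tname
      gaps[[paste0(side, "p_start")]][i] <- hits$tstart
      gaps[[paste0(side, "p_end")]][i] <- hits$tend
      gaps[[paste0(side, "p_strand")]][i] <- hits$strand
      gaps[[paste0(side, "p_mapq")]][i] <- hits$mapq
    }
  }
  gaps
}

#' Write gap flank sequences as FASTA for external mapping
#'
#' @param gaps data.frame from [extract_gaps()].
#' @param old DNAStringSet the flanks are read from.
#' @param path output FASTA.
#' @export
write_flank_fasta <- function(gaps, old, path) {
  if (!is(old, "DNAStringSet")) old <- Biostrings::DNAStringSet(old)
  seqs <- character(); nm <- character()
  for (i in seq_len(nrow(gaps))) {
    oldseq <- old[[gaps$seqid[i]]]
    if (gaps$lf_end[i] > gaps$lf_start[i]) {
      seqs <- c(seqs, as.character(
        Biostrings::subseq(oldseq, gaps$lf_start[i] + 1L, gaps$lf_end[i])))
      nm <- c(nm, paste0(gaps$gap_id[i], ":L"))
    }
    if (gaps$rf_end[i] > gaps$rf_start[i]) {
      seqs <- c(seqs, as.character(
        Biostrings::subseq(oldseq, gaps$rf_start[i] + 1L, gaps$rf_end[i])))
      nm <- c(nm, paste0(gaps$gap_id[i], ":R"))
    }
  }
  write_assembly(setNames(seqs, nm), path)
}

#' Classify lifted gaps as closed, artificial or unresolved
#'
#' A gap is closed when both flanks placed on the same sequence with
#' mapping quality strictly above `min_mapq`, in colinear same-strand
#' order with the gap-facing edges separated by a non-negative distance
#' strictly below `max_dist`, and no new-assembly N-run lies in the
#' inter-flank span. A gap is artificial when both placements lie on one
#' sequence and their intervals overlap (the old gap's flanks cover the
#' same new sequence, so no missing bases ever existed). Everything else
#' is unresolved. Closed gaps get `fill_start`/`fill_end`, the span
#' between the inner flank edges (length 0 for abutting flanks).
#'
#' @param gaps data.frame with placements from [place_flanks()] or
#'   [ingest_placements()].
#' @param new_gap_intervals interval data.frame of N-runs in the new
#'   assembly (e.g. from [extract_gaps()] on it, or [assembly_gap_intervals()]).
#' @param min_mapq strict mapq threshold (default 20).
#' @param max_dist strict inter-flank distance bound in bp (default 100 kb).
#' @return `gaps` with `status`, `fill_seqid`, `fill_start`, `fill_end`.
#' @export
classify_gap <- function(gaps, new_gap_intervals = NULL, min_mapq = 20L,
                         max_dist = 100000L) {
  if (is.null(new_gap_intervals)) new_gap_intervals <- .empty_intervals()
  gaps$status <- "unresolved"
  gaps$fill_seqid <- NA_character_
  gaps$fill_start <- NA_integer_
  gaps$fill_end <- NA_integer_
  for (i in seq_len(nrow(gaps))) {
    if (is.na(gaps$lp_seqid[i]) || is.na(gaps$rp_seqid[i])) next
    if (gaps$lp_seqid[i] != gaps$rp_seqid[i]) next
    overlap <- gaps$lp_start[i] < gaps$rp_end[i] &&
      gaps$rp_start[i] < gaps$lp_end[i]
    if (overlap) { gaps$status[i] <- "artificial"; next }
    if (gaps$lp_mapq[i] <= min_mapq || gaps$rp_mapq[i] <= min_mapq) next
    if (gaps$lp_strand[i] != gaps$rp_strand[i]) next
    if (gaps$lp_strand[i] == "+") {
      fill <- c(gaps$lp_end[i], gaps$rp_start[i])
    } else {
      fill <- c(gaps$rp_end[i], gaps$lp_start[i])
    }
    dist <- fill[2] - fill[1]
    if (dist < 0 || dist >= max_dist) next
    if (dist > 0 && .overlaps_any(gaps$lp_seqid[i], fill[1], fill[2],
                                  new_gap_intervals)) next
    gaps$status[i] <- "closed"
    gaps$fill_seqid[i] <- gaps$lp_seqid[i]
    gaps$fill_start[i] <- fill[1]
    gaps$fill_end[i] <- fill[2]
  }
  gaps
}

#' N-run intervals of an assembly
#'
#' @param assembly DNAStringSet.
#' @param min_gap_run minimum run length (default 1).
#' @return interval data.frame.
#' @export
assembly_gap_intervals <- function(assembly, min_gap_run = 1L) {
  if (!is(assembly, "DNAStringSet")) assembly <- Biostrings::DNAStringSet(assembly)
  out <- list()
  for (s in names(assembly)) {
    runs <- .n_runs(assembly[[s]], min_gap_run)
    if (nrow(runs)) { runs$seqid <- s; out[[s]] <- runs }
  }
  df <- do.call(rbind, c(list(.empty_intervals()), out))
  rownames(df) <- NULL
  df
}

#' Profile filled sequence of closed gaps
#'
#' For each closed gap: fill length, GC fraction over non-N fill bases and
#' the base-wise repeat coverage fraction. Zero-length fills (abutting
#' flanks) are reported with length 0 and NA content fractions.
#'
#' @param gaps classified data.frame from [classify_gap()].
#' @param new DNAStringSet (the new assembly).
#' @param repeats optional interval data.frame of repeat annotations.
#' @return data.frame with `gap_id`, `fill_length`, `gc`, `repeat_fraction`.
#' @export
fill_profile <- function(gaps, new, repeats = NULL) {
  if (!is(new, "DNAStringSet")) new <- Biostrings::DNAStringSet(new)
  closed <- gaps[gaps$status == "closed", , drop = FALSE]
  out <- data.frame(gap_id = closed$gap_id,
                    fill_length = closed$fill_end - closed$fill_start,
                    gc = NA_real_, repeat_fraction = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(closed))) {
    if (out$fill_length[i] == 0) next
    seq <- Biostrings::subseq(new[[closed$fill_seqid[i]]],
                              closed$fill_start[i] + 1L, closed$fill_end[i])
    lf <- Biostrings::letterFrequency(seq, letters = c("GC", "N"))
    denom <- length(seq) - lf["N"]
    out$gc[i] <- if (denom > 0) unname(lf["G|C"] / denom) else NA_real_
    out$repeat_fraction[i] <- if (!is.null(repeats)) covered_fraction(
      intervals(closed$fill_seqid[i], closed$fill_start[i], closed$fill_end[i]),
      repeats) else NA_real_
  }
  out
}

#' Liftover status summary
#'
#' Counts gaps by classification status, split by old-assembly sequence
#' class (placed chromosome vs unplaced scaffold, decided by a name
#' pattern). Status counts always sum to the total gap count.
#'
#' @param gaps classified data.frame from [classify_gap()].
#' @param unplaced_pattern regex on the old sequence name marking
#'   unplaced scaffolds.
#' @return data.frame with one row per sequence class plus a `total` row;
#'   columns `closed`, `artificial`, `unresolved`, `total`.
#' @export
liftover_summary <- function(gaps, unplaced_pattern = "^(chrUn|scaffold|unplaced)") {
  cls <- ifelse(grepl(unplaced_pattern, gaps$seqid), "unplaced", "placed")
  lv <- c("closed", "artificial", "unresolved")
  count_row <- function(sel) {
    st <- factor(gaps$status[sel], levels = lv)
    c(as.list(table(st)), total = sum(sel))
  }
  rows <- lapply(c(placed = "placed", unplaced = "unplaced"),
                 function(k) count_row(cls == k))
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out <- rbind(out, total = as.data.frame(count_row(rep(TRUE, nrow(gaps)))))
  out <- cbind(class = rownames(out), out)
  rownames(out) <- NULL
  out
}
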