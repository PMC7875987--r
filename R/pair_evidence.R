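# Paired-end (BAC-end) concordance, discordant-pair clustering, and
# per-read mapped-base fractions from cs difference strings.

#' Label end pairs as concordant or discordant
#'
#' A pair is concordant when both ends lie on the same sequence, in
#' convergent forward-reverse orientation (the leftmost end on the plus
#' strand, the rightmost on the minus strand), with an outer-span
#' distance strictly below `max_dist`. Pairs with an unplaced end are
#' excluded and counted separately.
#'
#' @param pairs data.frame with `pair_id`, `seq1`, `start1`, `end1`,
#'   `strand1`, `seq2`, `start2`, `end2`, `strand2` (0-based half-open;
#'   NA `seq` marks an unplaced end).
#' @param max_dist strict distance bound in bp (default 500 kb).
#' @return `pairs` with `status` (`concordant`/`discordant`/`excluded`)
#'   and `distance` (outer span; NA when ends are on different sequences).
#' @export
pair_concordance <- function(pairs, max_dist = 500000L) {
  n <- nrow(pairs)
  status <- rep("discordant", n)
  distance <- rep(NA_real_, n)
  unplaced <- is.na(pairs$seq1) | is.na(pairs$seq2)
  status[unplaced] <- "excluded"
  same <- !unplaced & pairs$seq1 == pairs$seq2
  distance[same] <- pmax(pairs$end1, pairs$end2)[same] -
    pmin(pairs$start1, pairs$start2)[same]
  left_is_1 <- pairs$start1 <= pairs$start2
  left_strand <- ifelse(left_is_1, pairs$strand1, pairs$strand2)
  right_strand <- ifelse(left_is_1, pairs$strand2, pairs$strand1)
  fr <- left_strand == "+" & right_strand == "-"
  conc <- same & fr & distance < max_dist
  status[conc & !unplaced] <- "concordant"
  pairs$status <- status
  pairs$distance <- distance
  pairs
}

#' Cluster discordant pair ends into breakpoint evidence
#'
#' Single-linkage clustering of the placed end positions of discordant
#' pairs: ends on one sequence within `window` bp of each other join one
#' cluster. Clusters report their interval and the number of distinct
#' supporting pairs, sorted by support descending.
#'
#' @param pairs labelled data.frame from [pair_concordance()].
#' @param window single-linkage distance in bp (default 50 kb).
#' @return data.frame with `seqid`, `start`, `end`, `n_pairs`.
#' @export
discordance_clusters <- function(pairs, window = 50000L) {
  d <- pairs[pairs$status == "discordant", , drop = FALSE]
  ends <- rbind(
    data.frame(seqid = d$seq1, pos = d$start1, pair = d$pair_id),
    data.frame(seqid = d$seq2, pos = d$start2, pair = d$pair_id))
  ends <- ends[!is.na(ends$seqid), , drop = FALSE]
  out <- list()
  for (s in unique(ends$seqid)) {
    e <- ends[ends$seqid == s, , drop = FALSE]
    e <- e[order(e$pos), , drop = FALSE]
    brk <- c(0L, cumsum(diff(e$pos) > window))
    for (g in split(e, brk)) {
      out[[length(out) + 1L]] <- data.frame(
        seqid = s, start = min(g$pos), end = max(g$pos),
        n_pairs = length(unique(g$pair)), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, c(list(data.frame(seqid = character(), start = integer(),
                                         end = integer(), n_pairs = integer())),
                         out))
  df <- df[order(-df$n_pairs, df$seqid, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.CS_GRAMMAR <- "(:[0-9]+)|(\\*[A-Za-z]{2})|(\\+[A-Za-z]+)|(-[A-Za-z]+)|(~[A-Za-z]{2}[0-9]+[A-Za-z]{2})"

# tokenize a cs:Z difference string; errors mention `where` on malformed
# input. Returns a data.frame of op (:,*,+,-,~) and query-consumed length.
.parse_cs <- function(cs, where = "record") {
  toks <- regmatches(cs, gregexpr(.CS_GRAMMAR, cs))[[1]]
  if (sum(nchar(toks)) != nchar(cs))
    stop("malformed cs string in ", where, ": ", cs)
  op <- substr(toks, 1, 1)
  qlen <- integer(length(toks))
  qlen[op == ":"] <- as.integer(substring(toks[op == ":"], 2))
  qlen[op == "*"] <- 1L
  qlen[op == "+"] <- nchar(toks[op == "+"]) - 1L
  data.frame(op = op, qlen = qlen, stringsAsFactors = FALSE)
}

# total length of the union of [start, end) segments given as a 2-col matrix
.union_length <- function(segs) {
  if (nrow(segs) == 1) return(segs[1, 2] - segs[1, 1])
  segs <- segs[order(segs[, 1]), , drop = FALSE]
  tot <- 0
  cur_s <- segs[1, 1]; cur_e <- segs[1, 2]
  for (i in seq_len(nrow(segs))[-1]) {
    if (segs[i, 1] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- segs[i, 1]; cur_e <- segs[i, 2]
    } else cur_e <- max(cur_e, segs[i, 2])
  }
  tot + (cur_e - cur_s)
}

#' Per-read mapped-base fraction from cs-tagged alignments
#'
#' For every read, the query bases consumed by match (`:`) and mismatch
#' (`*`) operations are collected across the read's primary and
#' supplementary records and unioned by query coordinate, so overlapping
#' split alignments are not double counted. Insertions (`+`) consume
#' query but are not mapped-to-reference bases; deletions (`-`) and
#' introns (`~`) consume target only. Secondary records (`tp:A:S`) are
#' excluded. The fraction is union size over read length; a read with no
#' records scores 0 (via [compare_mappability()]'s missing-read rule).
#'
#' @param paf alignment data.frame from [read_paf()]; `cs` must be
#'   present on every used record.
#' @return named numeric vector of fractions in [0, 1], one per read.
#' @export
mapped_fraction <- function(paf) {
  keep <- paf$tp != "S"
  cs <- paf$cs[keep]
  qname <- paf$qname[keep]
  qstart <- paf$qstart[keep]
  qend <- paf$qend[keep]
  qlen <- paf$qlen[keep]
  if (any(is.na(cs)))
    stop("record without cs tag: ", qname[which(is.na(cs))[1]])
  toks_all <- regmatches(cs, gregexpr(.CS_GRAMMAR, cs))
  n <- length(cs)
  segs <- vector("list", n)  # per record: 2-col matrix of mapped query spans
  for (i in seq_len(n)) {
    toks <- toks_all[[i]]
    if (sum(nchar(toks)) != nchar(cs[i]))
      stop("malformed cs string in ", qname[i], ": ", cs[i])
    op <- substr(toks, 1, 1)
    ql <- integer(length(toks))
    is_match <- op == ":"
    ql[is_match] <- as.integer(substring(toks[is_match], 2))
    is_mm <- op == "*"
    ql[is_mm] <- 1L
    plus <- op == "+"
    ql[plus] <- nchar(toks[plus]) - 1L
    ends <- qstart[i] + cumsum(ql)
    consumed <- if (length(ends)) ends[length(ends)] else qstart[i]
    if (consumed != qend[i])
      stop("cs query consumption (", consumed - qstart[i],
           ") does not match query span for ", qname[i])
    m <- is_match | is_mm
    segs[[i]] <- cbind(ends[m] - ql[m], ends[m])
  }
  by_read <- split(seq_len(n), qname)
  lens <- setNames(qlen[vapply(by_read, `[`, 0L, 1L)], names(by_read))
  out <- vapply(by_read, function(ii) {
    s <- if (length(ii) == 1) segs[[ii]] else do.call(rbind, segs[ii])
    if (!nrow(s)) return(0)
    .union_length(s)
  }, 0)
  out / lens
}

#' Compare per-read mapped fractions between two assemblies
#'
#' A read maps better in A when its mapped fraction there exceeds the B
#' fraction by strictly more than `delta` (an absolute difference of
#' fractions, i.e. percentage points of the read); symmetrically for B;
#' everything else is tied. Reads absent from one side score 0 there.
#'
#' @param frac_a,frac_b named fraction vectors from [mapped_fraction()].
#' @param delta strict absolute margin (default 0.05).
#' @return list with `counts` (`better_a`, `better_b`, `tied`) and
#'   `table` (per-read fractions, difference and call).
#' @export
compare_mappability <- function(frac_a, frac_b, delta = 0.05) {
  reads <- union(names(frac_a), names(frac_b))
  a <- setNames(rep(0, length(reads)), reads)
  b <- a
  a[names(frac_a)] <- frac_a
  b[names(frac_b)] <- frac_b
  call <- ifelse(a - b > delta, "better_a",
                 ifelse(b - a > delta, "better_b", "tied"))
  tab <- data.frame(read_id = reads, frac_a = unname(a), frac_b = unname(b),
                    diff = unname(a - b), call = unname(call),
                    stringsAsFactors = FALSE)
  list(counts = c(better_a = sum(call == "better_a"),
                  better_b = sum(call == "better_b"),
                  tied = sum(call == "tied")),
       table = tab)
}
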