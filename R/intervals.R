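#' @importFrom methods is
#' @importFrom stats median rbeta rbinom rnbinom runif setNames
#' @importFrom utils head read.table tail write.table
NULL

# All user-facing coordinates in this package are 0-based half-open
# [start, end), the BED convention. IRanges (1-based closed) is used
# internally for set algebra; these two helpers are the only place the
# conversion happens.

.to_ir <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

.from_ir <- function(ir) {
  data.frame(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
}

#' Construct an interval table
#'
#' Standard container for genomic intervals: a data.frame with columns
#' `seqid`, `start`, `end` in 0-based half-open coordinates, plus any
#' extra columns the caller supplies.
#'
#' @param seqid character vector of sequence identifiers.
#' @param start,end integer vectors, 0-based half-open.
#' @param ... further equal-length columns (e.g. `strand`, `name`).
#' @return data.frame with at least `seqid`, `start`, `end`.
#' @export
intervals <- function(seqid = character(), start = integer(), end = integer(), ...) {
  df <- data.frame(seqid = as.character(seqid), start = as.integer(start),
                   end = as.integer(end), ..., stringsAsFactors = FALSE)
  if (nrow(df) && any(df$end < df$start)) stop("interval end < start")
  df
}

.empty_intervals <- function() intervals()

#' Merge (reduce) an interval set
#'
#' Collapses overlapping or book-ended intervals per sequence; intervals
#' separated by at most `gap` bases are also merged.
#'
#' @param x interval data.frame (`seqid`, `start`, `end`).
#' @param gap maximum separation (bp) across which to merge; 0 merges only
#'   overlapping/abutting intervals.
#' @return merged interval data.frame, sorted by `seqid` then `start`.
#' @export
merge_intervals <- function(x, gap = 0L) {
  if (!nrow(x)) return(.empty_intervals())
  out <- lapply(split(x, x$seqid), function(d) {
    ir <- IRanges::reduce(.to_ir(d$start, d$end), min.gapwidth = gap + 1L)
    cbind(seqid = d$seqid[1], .from_ir(ir))
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[order(df$seqid, df$start), , drop = FALSE]
}

#' Total bases covered by an interval set
#'
#' Base-wise union length: overlapping intervals are not double counted.
#'
#' @inheritParams merge_intervals
#' @return integer, total covered bases.
#' @export
total_covered <- function(x) {
  m <- merge_intervals(x)
  if (!nrow(m)) return(0L)
  sum(m$end - m$start)
}

#' Fraction of a target covered by an interval set
#'
#' Computes |target intersect union(cover)| / |target| base-wise. Both
#' arguments use the package interval convention; the target may span
#' several rows (e.g. the exons of a gene), in which case its rows are
#' unioned first.
#'
#' @param target interval data.frame; total length must be > 0.
#' @param cover interval data.frame.
#' @return numeric fraction in [0, 1].
#' @export
covered_fraction <- function(target, cover) {
  tgt <- merge_intervals(target)
  len <- sum(tgt$end - tgt$start)
  if (len == 0) stop("covered_fraction: zero-length target")
  if (!nrow(cover)) return(0)
  cov <- merge_intervals(cover)
  tot <- 0L
  for (s in unique(tgt$seqid)) {
    t2 <- tgt[tgt$seqid == s, ]
    c2 <- cov[cov$seqid == s, ]
    if (!nrow(c2)) next
    ov <- IRanges::intersect(.to_ir(t2$start, t2$end), .to_ir(c2$start, c2$end))
    tot <- tot + sum(BiocGenerics::width(ov))
  }
  tot / len
}

# base-wise intersection of two interval tables -> interval table
.intersect_intervals <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(.empty_intervals())
  out <- list()
  for (s in intersect(unique(a$seqid), unique(b$seqid))) {
    a2 <- a[a$seqid == s, ]; b2 <- b[b$seqid == s, ]
    ov <- IRanges::intersect(.to_ir(a2$start, a2$end), .to_ir(b2$start, b2$end))
    if (length(ov)) out[[s]] <- cbind(seqid = s, .from_ir(ov))
  }
  if (!length(out)) return(.empty_intervals())
  df <- do.call(rbind, out); rownames(df) <- NULL
  df
}

# does any interval in `set` overlap [start,end) on seqid?
.overlaps_any <- function(seqid, start, end, set) {
  if (!nrow(set)) return(FALSE)
  s2 <- set[set$seqid == seqid, ]
  if (!nrow(s2)) return(FALSE)
  any(s2$start < end & s2$end > start)
}

#' Jaccard index of two interval sets
#'
#' Base-level Jaccard: |A intersect B| / |A union B|.
#'
#' @param a,b interval data.frames.
#' @return numeric in [0, 1]; 1 when both sets are empty.
#' @export
interval_jaccard <- function(a, b) {
  ia <- total_covered(a); ib <- total_covered(b)
  if (ia == 0 && ib == 0) return(1)
  inter <- total_covered(.intersect_intervals(merge_intervals(a), merge_intervals(b)))
  inter / (ia + ib - inter)
}

#' Tile sequences into fixed-width windows
#'
#' @param seqlens named integer vector of sequence lengths (bp).
#' @param window window width in bp.
#' @return interval data.frame with one row per window; the final window of
#'   each sequence may be shorter than `window`.
#' @export
tile_windows <- function(seqlens, window) {
  stopifnot(window >= 1)
  out <- lapply(names(seqlens), function(s) {
    len <- seqlens[[s]]
    if (len <= 0) return(NULL)
    starts <- seq.int(0L, len - 1L, by = window)
    intervals(seqid = s, start = starts, end = pmin(starts + window, len))
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
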