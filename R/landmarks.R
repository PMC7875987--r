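# Sequence landmark annotation: GC windows, extreme-GC regions, CpG islands,
# telomere repeat arrays and satellite-rich centromere blocks.

.as_dna <- function(x) {
  if (is(x, "DNAString")) return(x)
  if (is(x, "DNAStringSet")) {
    if (length(x) != 1) stop("expected a single sequence; got a set of ", length(x))
    return(x[[1]])
  }
  Biostrings::DNAString(toupper(as.character(x)))
}

#' Per-window GC fraction
#'
#' GC content in fixed, non-overlapping windows anchored at coordinate 0.
#' GC is computed over non-N bases only; windows that are entirely N carry
#' NA. The final partial window is included and normalised by its true
#' length.
#'
#' @param sequence a DNAString, single-sequence DNAStringSet, or character.
#' @param window window width in bp (default 50).
#' @param seqid sequence name used in the output track.
#' @return data.frame with `seqid`, `start`, `end`, `gc`.
#' @export
gc_windows <- function(sequence, window = 50L, seqid = "seq") {
  stopifnot(window >= 1)
  dna <- .as_dna(sequence)
  len <- length(dna)
  if (len == 0) return(cbind(.empty_intervals()[0, ], gc = numeric()))
  starts <- seq.int(0L, len - 1L, by = window)
  ends <- pmin(starts + as.integer(window), len)
  v <- Biostrings::Views(dna, start = starts + 1L, end = ends)
  lf <- Biostrings::letterFrequency(v, letters = c("GC", "N"))
  denom <- (ends - starts) - lf[, "N"]
  gc <- ifelse(denom > 0, lf[, "G|C"] / denom, NA_real_)
  intervals(seqid = seqid, start = starts, end = ends, gc = gc)
}

#' Extreme-GC regions
#'
#' Maximal runs of windows whose GC fraction strictly exceeds `threshold`
#' (default >90%), merged into intervals. All-N (NA) windows never qualify.
#'
#' @param track output of [gc_windows()].
#' @param threshold strict lower bound on window GC (default 0.90).
#' @return merged interval data.frame.
#' @export
extreme_gc_regions <- function(track, threshold = 0.90) {
  sel <- !is.na(track$gc) & track$gc > threshold
  if (!any(sel)) return(.empty_intervals())
  merge_intervals(track[sel, c("seqid", "start", "end")])
}

#' CpG island detection (Gardiner-Garden criteria)
#'
#' Slides a 200 bp window one base at a time; windows with GC >= 0.5 and
#' CpG observed/expected >= 0.6 qualify, where obs/exp =
#' (window length * #CG) / (#C * #G). Overlapping qualifying windows are
#' merged; the per-island statistics are recomputed over the merged span.
#' Islands shorter than 200 bp cannot arise and are discarded defensively.
#'
#' @param sequence DNAString / single-sequence DNAStringSet / character.
#' @param seqid sequence name for the output.
#' @param min_gc,min_obs_exp qualification thresholds.
#' @return data.frame with `seqid`, `start`, `end`, `length`, `gc`,
#'   `obs_exp` per island.
#' @export
cpg_islands <- function(sequence, seqid = "seq", min_gc = 0.5, min_obs_exp = 0.6) {
  dna <- .as_dna(sequence)
  len <- length(dna)
  w <- 200L
  empty <- data.frame(seqid = character(), start = integer(), end = integer(),
                      length = integer(), gc = numeric(), obs_exp = numeric())
  if (len < w) return(empty)
  r <- charToRaw(as.character(dna))
  isC <- r == charToRaw("C")
  isG <- r == charToRaw("G")
  cg <- isC[-len] & isG[-1]
  n <- len - w + 1L
  wsum <- function(flags, width) {
    cs <- cumsum(as.integer(flags))
    cs[width:length(flags)] - c(0L, cs)[seq_len(length(flags) - width + 1L)]
  }
  wC <- wsum(isC, w)[seq_len(n)]
  wG <- wsum(isG, w)[seq_len(n)]
  wCG <- wsum(cg, w - 1L)[seq_len(n)]
  gcfrac <- (wC + wG) / w
  obsexp <- ifelse(wC * wG > 0, w * wCG / (wC * wG), 0)
  qual <- gcfrac >= min_gc & obsexp >= min_obs_exp
  if (!any(qual)) return(empty)
  st <- which(qual) - 1L
  isl <- merge_intervals(intervals(seqid = seqid, start = st, end = st + w))
  isl <- isl[isl$end - isl$start >= w, , drop = FALSE]
  stats <- t(vapply(seq_len(nrow(isl)), function(i) {
    a <- isl$start[i] + 1L; b <- isl$end[i]
    nC <- sum(isC[a:b]); nG <- sum(isG[a:b]); L <- b - a + 1L
    nCG <- if (b > a) sum(cg[a:(b - 1L)]) else 0L
    c(gc = (nC + nG) / L, obs_exp = if (nC * nG > 0) L * nCG / (nC * nG) else 0)
  }, c(gc = 0, obs_exp = 0)))
  data.frame(seqid = isl$seqid, start = isl$start, end = isl$end,
             length = isl$end - isl$start, gc = stats[, "gc"],
             obs_exp = stats[, "obs_exp"])
}

# chain sorted unit start positions into runs where consecutive units are
# separated by <= max_gap non-repeat bases; returns per-run first/last/count
.chain_units <- function(starts, unit, max_gap) {
  if (!length(starts)) return(data.frame(first = integer(), last = integer(),
                                         n = integer()))
  starts <- sort(starts)
  gaps <- starts[-1] - (head(starts, -1) + unit)
  brk <- c(0L, cumsum(gaps > max_gap | gaps < 0))
  runs <- split(starts, brk)
  data.frame(first = vapply(runs, min, 0L), last = vapply(runs, max, 0L),
             n = lengths(runs), row.names = NULL)
}

#' Telomere repeat array detection
#'
#' Finds exact TTAGGG (plus strand) and CCCTAA (minus strand) unit
#' occurrences and chains consecutive units separated by at most
#' `max_variant_gap` non-repeat bases into arrays. Arrays with at least
#' `min_repeats` units are reported; reported arrays on the same strand
#' within `merge_gap` bp are merged (unit counts summed). An array is
#' flagged terminal when it starts or ends within `terminal_dist` of a
#' sequence end.
#'
#' @param sequence DNAString / single-sequence DNAStringSet / character.
#' @param min_repeats minimum unit count per array (default 12).
#' @param max_variant_gap maximum non-repeat bases between consecutive
#'   units (default 10, i.e. "less than 11 variant bases").
#' @param merge_gap merge reported arrays within this distance (default 100).
#' @param terminal_dist distance from a sequence end below which an array
#'   is called terminal (default 10 kb).
#' @param seqid sequence name for the output.
#' @return data.frame with `seqid`, `start`, `end`, `strand`,
#'   `repeat_count`, `terminal`.
#' @export
find_telomere_arrays <- function(sequence, min_repeats = 12L,
                                 max_variant_gap = 10L, merge_gap = 100L,
                                 terminal_dist = 10000L, seqid = "seq") {
  dna <- .as_dna(sequence)
  len <- length(dna)
  if (len == 0) stop("empty sequence")
  one_strand <- function(motif, strand) {
    hits <- BiocGenerics::start(Biostrings::matchPattern(motif, dna)) - 1L
    runs <- .chain_units(hits, 6L, max_variant_gap)
    runs <- runs[runs$n >= min_repeats, , drop = FALSE]
    if (!nrow(runs)) return(NULL)
    df <- data.frame(start = runs$first, end = runs$last + 6L,
                     strand = strand, repeat_count = runs$n)
    df <- df[order(df$start), , drop = FALSE]
    # merge arrays within merge_gap, summing unit counts
    brk <- c(0L, cumsum(df$start[-1] - head(df$end, -1) > merge_gap))
    grp <- split(df, brk)
    do.call(rbind, lapply(grp, function(g) data.frame(
      start = min(g$start), end = max(g$end), strand = strand,
      repeat_count = sum(g$repeat_count))))
  }
  out <- rbind(one_strand("TTAGGG", "+"), one_strand("CCCTAA", "-"))
  if (is.null(out) || !nrow(out)) {
    return(data.frame(seqid = character(), start = integer(), end = integer(),
                      strand = character(), repeat_count = integer(),
                      terminal = logical()))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  data.frame(seqid = seqid, start = out$start, end = out$end,
             strand = out$strand, repeat_count = out$repeat_count,
             terminal = out$start < terminal_dist | out$end > len - terminal_dist,
             row.names = NULL)
}

#' Centromere block annotation from satellite repeat content
#'
#' Computes, per fixed window, the base-wise union coverage of annotated
#' satellite repeats; windows whose satellite fraction strictly exceeds
#' `threshold` are merged into centromere blocks. Overlapping repeat
#' intervals are unioned first, so fractions are capped at 1. The final
#' partial window is normalised by its true length.
#'
#' @param repeats interval data.frame with a `name` (repeat class) column.
#' @param seqlens named integer vector of sequence lengths.
#' @param satellite_classes repeat classes counted as satellite.
#' @param window window width in bp (default 5 kb).
#' @param threshold strict lower bound on satellite fraction (default 0.80).
#' @return data.frame of blocks with `seqid`, `start`, `end`,
#'   `satellite_fraction` (minimum constituent-window fraction).
#' @export
find_centromere_blocks <- function(repeats, seqlens,
                                   satellite_classes = c("CarSat1", "Carsat2", "SAT1_CF"),
                                   window = 5000L, threshold = 0.80) {
  if (is.null(repeats$name)) stop("repeat annotation needs a 'name' (class) column")
  unknown <- setdiff(unique(repeats$name), satellite_classes)
  if (length(unknown))
    warning("ignoring non-satellite repeat classes: ", paste(unknown, collapse = ", "))
  sat <- repeats[repeats$name %in% satellite_classes, , drop = FALSE]
  empty <- data.frame(seqid = character(), start = integer(), end = integer(),
                      satellite_fraction = numeric())
  if (!nrow(sat)) return(empty)
  # clip to sequence bounds
  sat <- sat[sat$seqid %in% names(seqlens), , drop = FALSE]
  sat$start <- pmax(sat$start, 0L)
  sat$end <- pmin(sat$end, seqlens[sat$seqid])
  sat <- sat[sat$end > sat$start, , drop = FALSE]
  sat <- merge_intervals(sat)
  out <- list()
  for (s in unique(sat$seqid)) {
    len <- seqlens[[s]]
    d <- sat[sat$seqid == s, ]
    cvg <- IRanges::coverage(.to_ir(d$start, d$end), width = len)
    grid <- tile_windows(setNames(len, s), window)
    covered <- IRanges::viewSums(IRanges::Views(cvg, start = grid$start + 1L,
                                                end = grid$end))
    frac <- covered / (grid$end - grid$start)
    sel <- frac > threshold
    if (!any(sel)) next
    blocks <- merge_intervals(grid[sel, c("seqid", "start", "end")])
    blocks$satellite_fraction <- vapply(seq_len(nrow(blocks)), function(i)
      min(frac[sel & grid$start >= blocks$start[i] & grid$end <= blocks$end[i]]), 0)
    out[[s]] <- blocks
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
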