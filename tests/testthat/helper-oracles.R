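# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different mechanics (explicit loops, per-base
# vectors, regex scans) from the functions they verify.

rand_dna <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# regex-chaining telomere oracle: find unit occurrences with gregexpr,
# chain with an explicit loop, filter, then merge with a second loop
oracle_telomere <- function(s, motif = "TTAGGG", min_repeats = 12,
                            max_gap = 10, merge_gap = 100) {
  m <- gregexpr(motif, s, fixed = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer(),
                                    n = integer()))
  starts <- as.integer(m) - 1L
  runs <- list()
  cur <- c(starts[1], starts[1] + 6L, 1L)
  for (p in starts[-1]) {
    if (p - cur[2] <= max_gap && p >= cur[2]) {
      cur[2] <- p + 6L; cur[3] <- cur[3] + 1L
    } else {
      runs[[length(runs) + 1L]] <- cur
      cur <- c(p, p + 6L, 1L)
    }
  }
  runs[[length(runs) + 1L]] <- cur
  keep <- Filter(function(r) r[3] >= min_repeats, runs)
  if (!length(keep)) return(data.frame(start = integer(), end = integer(),
                                       n = integer()))
  merged <- list(keep[[1]])
  for (r in keep[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] <= merge_gap) {
      last[2] <- r[2]; last[3] <- last[3] + r[3]
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- r
  }
  data.frame(start = vapply(merged, `[`, 0, 1),
             end = vapply(merged, `[`, 0, 2),
             n = vapply(merged, `[`, 0, 3))
}

# sort-and-accumulate N50/L50 oracle
oracle_n50 <- function(lengths) {
  lengths <- sort(lengths, decreasing = TRUE)
  total <- sum(as.numeric(lengths))
  acc <- 0
  for (i in seq_along(lengths)) {
    acc <- acc + lengths[i]
    if (acc >= total / 2) return(c(n50 = lengths[i], l50 = i))
  }
}

# brute-force sense-strand ORF scan: translate every ATG forward until a
# stop, frame by frame, position by position
oracle_orf <- function(s) {
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (i in seq_len(max(0, n - 5))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i + 3
    aa <- 1L
    while (j + 2 <= n) {
      cod <- substr(s, j, j + 2)
      if (cod %in% stops) { if (aa > best) best <- aa; break }
      aa <- aa + 1L
      j <- j + 3
    }
  }
  best
}

# per-base membership oracle for interval-set partitions on one sequence
oracle_partition <- function(sets, seqlen) {
  member <- vapply(sets, function(d) {
    v <- logical(seqlen)
    for (i in seq_len(nrow(d))) v[(d$start[i] + 1L):d$end[i]] <- TRUE
    v
  }, logical(seqlen))
  keys <- apply(member, 1, function(m)
    if (any(m)) paste(names(sets)[m], collapse = "+") else "")
  tab <- table(keys[keys != ""])
  setNames(as.integer(tab), names(tab))
}

# per-window counting oracle for consensus calling on one sequence
oracle_consensus <- function(calls, nwin, window, min_fraction = 0.9,
                             dark_calls = NULL) {
  in_window <- function(regions, w) {
    ws <- (w - 1L) * window; we <- w * window
    any(regions$start < we & regions$end > ws)
  }
  retained <- logical(nwin)
  for (w in seq_len(nwin)) {
    supp <- sum(vapply(calls, in_window, TRUE, w = w))
    elig <- if (is.null(dark_calls)) length(calls)
      else length(calls) - sum(vapply(dark_calls, in_window, TRUE, w = w))
    if (elig > 0 && supp / elig > min_fraction) retained[w] <- TRUE
  }
  retained
}

# interval set from a logical per-window vector (for oracle comparison)
windows_as_intervals <- function(sel, window, seqid = "chr1") {
  if (!any(sel)) return(intervals())
  r <- rle(sel)
  e <- cumsum(r$lengths); s <- e - r$lengths
  intervals(seqid = seqid, start = s[r$values] * window,
            end = e[r$values] * window)
}
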