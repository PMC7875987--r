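# Per-sample dark and camouflaged region calling from windowed depth and
# high-MQ-fraction tracks, multi-sample consensus, technology intersection,
# variant extraction and depth-based copy-number estimation.

#' Construct a per-sample windowed profile
#'
#' Holds one sample's fixed-width window tracks: depth per window and,
#' optionally, the fraction of reads with high mapping quality (MQ > 10)
#' per window. The autosomal median depth used for copy-number
#' normalisation is computed over all windows of sequences not listed in
#' `sex_seqs`.
#'
#' @param sample_id sample identifier.
#' @param technology one of `ISR`, `LINKED`, `LONG`.
#' @param depth named list (per sequence) of per-window depth vectors, or
#'   a BedGraph-style data.frame (`seqid`, `start`, `end`, `value`).
#' @param mq like `depth`, for the high-MQ read fraction; may be NULL.
#' @param window window width in bp.
#' @param sex_seqs sequences excluded from the autosomal median.
#' @param median_chunk number of consecutive windows averaged before
#'   taking the median (default 100). Integer window depths at small
#'   windows have a discrete, right-skewed distribution whose raw median
#'   sits below the mean; the median of chunk means removes that bias
#'   while staying robust to copy-number outlier regions.
#' @return an object of class `sample_profile`.
#' @export
sample_profile <- function(sample_id, technology = c("ISR", "LINKED", "LONG"),
                           depth, mq = NULL, window, sex_seqs = character(),
                           median_chunk = 100L) {
  technology <- match.arg(technology)
  as_tracks <- function(x) {
    if (is.data.frame(x)) {
      x <- x[order(x$seqid, x$start), ]
      lapply(split(x, x$seqid), function(d) d$value)
    } else x
  }
  depth <- as_tracks(depth)
  mq <- if (!is.null(mq)) as_tracks(mq)
  if (!is.null(mq)) {
    stopifnot(identical(sort(names(depth)), sort(names(mq))),
              all(lengths(depth)[names(mq)] == lengths(mq)))
  }
  auto <- unlist(depth[setdiff(names(depth), sex_seqs)], use.names = FALSE)
  med <- if (length(auto) >= 2 * median_chunk) {
    n_chunk <- length(auto) %/% median_chunk
    idx <- seq_len(n_chunk * median_chunk)
    median(tapply(auto[idx], (idx - 1L) %/% median_chunk, mean))
  } else if (length(auto)) median(auto) else NA_real_
  structure(list(sample_id = sample_id, technology = technology,
                 depth = depth, mq = mq, window = as.integer(window),
                 sex_seqs = sex_seqs, median_depth = med),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("sample_profile", x$sample_id, sprintf("(%s)", x$technology),
      "-", length(x$depth), "sequences,", x$window, "bp windows, median depth",
      round(x$median_depth, 1), if (is.null(x$mq)) "(no MQ track)" else "",
      "\n")
  invisible(x)
}

# logical window selection per sequence -> merged bp intervals
.windows_to_regions <- function(sel_by_seq, window, seqlens) {
  out <- list()
  for (s in names(sel_by_seq)) {
    sel <- sel_by_seq[[s]]
    if (!any(sel)) next
    r <- rle(sel)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    keep <- which(r$values)
    out[[s]] <- intervals(
      seqid = s, start = (starts_idx[keep] - 1L) * window,
      end = pmin(ends_idx[keep] * window, seqlens[[s]]))
  }
  df <- do.call(rbind, c(list(.empty_intervals()), out))
  rownames(df) <- NULL
  df
}

.profile_seqlens <- function(profile) {
  # track lengths give an upper bound; the true length may end mid-window,
  # which only matters for the final window's right edge
  vapply(names(profile$depth),
         function(s) length(profile$depth[[s]]) * profile$window, 0)
}

#' Call dark-by-depth regions for one sample
#'
#' Selects windows with depth at or below the threshold (inclusive) and
#' merges adjacent selected windows. If the merged total exceeds `cap_bp`
#' (the guard against flooding the consensus with a low-coverage sample),
#' the integer threshold is decremented and the call repeated until the
#' total fits under the cap or the threshold reaches 0; the effective
#' threshold is reported.
#'
#' @param profile a [sample_profile()].
#' @param base_threshold starting inclusive depth threshold (default 5).
#' @param cap_bp maximum total dark bases per sample (default 60 Mb).
#' @param seqlens optional named true sequence lengths (clips the final
#'   window).
#' @return list with `regions` (merged interval data.frame) and
#'   `threshold` (effective integer threshold used).
#' @export
call_dark_sample <- function(profile, base_threshold = 5L, cap_bp = 60e6,
                             seqlens = NULL) {
  stopifnot(inherits(profile, "sample_profile"))
  if (is.null(seqlens)) seqlens <- .profile_seqlens(profile)
  thr <- as.integer(base_threshold)
  repeat {
    sel <- lapply(profile$depth, function(d) d <= thr)
    regions <- .windows_to_regions(sel, profile$window, seqlens)
    total <- if (nrow(regions)) sum(regions$end - regions$start) else 0
    if (total <= cap_bp || thr <= 0L) break
    thr <- thr - 1L
  }
  list(regions = regions, threshold = thr)
}

#' Call camouflaged regions for one sample
#'
#' Selects windows with adequate depth (>= `min_depth`, inclusive) whose
#' high-MQ read fraction is strictly below `max_mq_fraction`, and merges
#' adjacent selections. Such windows are covered but nearly no read maps
#' uniquely — the signature of near-identical duplications.
#'
#' @param profile a [sample_profile()] with an MQ track.
#' @param min_depth inclusive depth floor (default 10).
#' @param max_mq_fraction strict upper bound on the high-MQ fraction
#'   (default 0.10).
#' @param seqlens optional named true sequence lengths.
#' @return merged interval data.frame.
#' @export
call_camo_sample <- function(profile, min_depth = 10, max_mq_fraction = 0.10,
                             seqlens = NULL) {
  stopifnot(inherits(profile, "sample_profile"))
  if (is.null(profile$mq))
    stop("sample ", profile$sample_id, " has no MQ-fraction track")
  if (is.null(seqlens)) seqlens <- .profile_seqlens(profile)
  sel <- lapply(names(profile$depth), function(s)
    profile$depth[[s]] >= min_depth & profile$mq[[s]] < max_mq_fraction)
  names(sel) <- names(profile$depth)
  .windows_to_regions(sel, profile$window, seqlens)
}

# per-sample interval set -> logical window-coverage vectors on the grid
.cover_windows <- function(regions, window, seqlens) {
  out <- lapply(names(seqlens), function(s) {
    nwin <- as.integer(ceiling(seqlens[[s]] / window))
    sel <- logical(nwin)
    d <- regions[regions$seqid == s, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      a <- d$start[i] %/% window + 1L
      b <- min(nwin, as.integer(ceiling(d$end[i] / window)))
      if (b >= a) sel[a:b] <- TRUE
    }
    sel
  })
  names(out) <- names(seqlens)
  out
}

#' Across-sample consensus dark/camouflaged regions
#'
#' On the shared window grid, counts for every window the samples whose
#' call set covers it. For dark consensus all samples are eligible; for
#' camouflaged consensus, samples that are dark in a window are removed
#' from that window's denominator (their per-sample dark calls must be
#' supplied). Windows whose support fraction strictly exceeds
#' `min_fraction` are retained and merged; each merged region carries the
#' minimum window support fraction of its span. Windows with no eligible
#' sample are skipped and counted in `attr(, "n_skipped")`.
#'
#' @param calls named list (per sample) of per-sample merged interval
#'   data.frames (from [call_dark_sample()] or [call_camo_sample()]).
#' @param seqlens named sequence lengths defining the grid.
#' @param window grid window width in bp (default 25).
#' @param category `"dark"` or `"camouflaged"`.
#' @param min_fraction strict support-fraction threshold (default 0.9).
#' @param dark_calls per-sample dark interval sets, required when
#'   `category = "camouflaged"`.
#' @param technology label copied onto the output regions.
#' @return data.frame of consensus regions with `seqid`, `start`, `end`,
#'   `category`, `support_fraction`, `n_support`, `n_eligible`,
#'   `technology`.
#' @export
consensus_regions <- function(calls, seqlens, window = 25L,
                              category = c("dark", "camouflaged"),
                              min_fraction = 0.9, dark_calls = NULL,
                              technology = NA_character_) {
  category <- match.arg(category)
  if (category == "camouflaged" && is.null(dark_calls))
    stop("camouflaged consensus needs per-sample dark_calls for eligibility")
  samples <- names(calls)
  cover <- lapply(calls, .cover_windows, window = window, seqlens = seqlens)
  dark_cover <- if (category == "camouflaged")
    lapply(dark_calls[samples], .cover_windows, window = window, seqlens = seqlens)
  n_skipped <- 0L
  rows <- list()
  for (s in names(seqlens)) {
    nwin <- as.integer(ceiling(seqlens[[s]] / window))
    supp <- Reduce(`+`, lapply(cover, function(cv) as.integer(cv[[s]])))
    if (category == "dark") {
      elig <- rep(length(samples), nwin)
    } else {
      ineligible <- Reduce(`+`, lapply(dark_cover, function(cv) as.integer(cv[[s]])))
      elig <- length(samples) - ineligible
    }
    frac <- ifelse(elig > 0, supp / elig, NA_real_)
    n_skipped <- n_skipped + sum(elig == 0 & supp > 0)
    retained <- !is.na(frac) & frac > min_fraction
    if (!any(retained)) next
    r <- rle(retained)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    for (k in which(r$values)) {
      i <- starts_idx[k]:ends_idx[k]
      jmin <- i[which.min(frac[i])]
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = s, start = (starts_idx[k] - 1L) * window,
        end = min(ends_idx[k] * window, seqlens[[s]]),
        category = category, support_fraction = frac[jmin],
        n_support = supp[jmin], n_eligible = elig[jmin],
        technology = technology, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(list(data.frame(
    seqid = character(), start = integer(), end = integer(),
    category = character(), support_fraction = numeric(),
    n_support = integer(), n_eligible = integer(),
    technology = character())), rows))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Base-level partition of regions across technologies
#'
#' Splits the union of all region sets into disjoint pieces and assigns
#' every base to exactly one technology combination (e.g. `"ISR"`,
#' `"ISR+LONG"`). Per-technology totals over the cells equal each
#' technology's own merged length.
#'
#' @param sets named list (>= 2 entries, one per technology) of interval
#'   data.frames.
#' @return data.frame with `combination` and `bases`, plus
#'   `attr(, "union_bases")`.
#' @export
intersect_technologies <- function(sets) {
  if (length(sets) < 2) stop("need at least two technologies")
  techs <- names(sets)
  merged <- lapply(sets, merge_intervals)
  cells <- new.env()
  seqids <- unique(unlist(lapply(merged, function(d) d$seqid)))
  for (s in seqids) {
    per <- lapply(merged, function(d) {
      d2 <- d[d$seqid == s, , drop = FALSE]
      .to_ir(d2$start, d2$end)
    })
    all_ir <- do.call(c, unname(per))
    if (!length(all_ir)) next
    pieces <- IRanges::disjoin(all_ir)
    member <- vapply(per, function(ir)
      IRanges::overlapsAny(pieces, ir), logical(length(pieces)))
    if (length(pieces) == 1) member <- matrix(member, nrow = 1)
    keys <- apply(member, 1, function(m) paste(techs[m], collapse = "+"))
    w <- BiocGenerics::width(pieces)
    for (i in seq_along(keys)) {
      k <- keys[i]
      cells[[k]] <- (if (is.null(cells[[k]])) 0 else cells[[k]]) + w[i]
    }
  }
  keys <- ls(cells)
  out <- data.frame(combination = keys,
                    bases = vapply(keys, function(k) cells[[k]], 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$bases), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "union_bases") <- sum(out$bases)
  out
}

#' Extract and count variants overlapping regions
#'
#' A variant counts when its reference-spanning interval
#' (`[pos-1, pos-1+nchar(ref))`) intersects any region. When an annotation
#' set with a `name` class column is given, counted variants are
#' classified by the classes they overlap (`"unclassified"` otherwise).
#'
#' @param regions interval data.frame.
#' @param variants data.frame with `seqid`, `pos` (1-based), `ref`, `alt`.
#' @param annotation optional interval data.frame with a `name` column
#'   (e.g. exon/intron classes).
#' @return list with `variants` (the extracted records, input columns
#'   preserved) and `counts` (named integer per class, plus `total`).
#' @export
variants_in_regions <- function(regions, variants, annotation = NULL) {
  vint <- intervals(seqid = variants$seqid, start = variants$pos - 1L,
                    end = variants$pos - 1L + nchar(variants$ref))
  hit <- vapply(seq_len(nrow(vint)), function(i)
    .overlaps_any(vint$seqid[i], vint$start[i], vint$end[i], regions), TRUE)
  ext <- variants[hit, , drop = FALSE]
  counts <- c(total = sum(hit))
  if (!is.null(annotation) && nrow(ext)) {
    eint <- vint[hit, , drop = FALSE]
    cls <- lapply(seq_len(nrow(eint)), function(i) {
      a <- annotation[annotation$seqid == eint$seqid[i] &
                        annotation$start < eint$end[i] &
                        annotation$end > eint$start[i], , drop = FALSE]
      if (nrow(a)) unique(a$name) else "unclassified"
    })
    tab <- table(unlist(cls))
    counts <- c(counts, setNames(as.integer(tab), names(tab)))
  }
  list(variants = ext, counts = counts)
}

.region_mean_depth <- function(profile, region) {
  s <- region$seqid[1]
  d <- profile$depth[[s]]
  if (is.null(d)) stop("profile has no track for sequence ", s)
  w <- profile$window
  a <- region$start[1] %/% w + 1L
  b <- min(length(d), as.integer(ceiling(region$end[1] / w)))
  if (b < a) stop("region shorter than one window")
  mean(d[a:b])
}

#' Normalised-depth copy number of a region
#'
#' Total copy number as `2 * mean(region depth) / autosomal median depth`:
#' a diploid region at median depth scores 2.0.
#'
#' @param profile a [sample_profile()].
#' @param region single-row interval data.frame (length >= 1 window).
#' @return numeric total copy number.
#' @export
normalised_copy_number <- function(profile, region) {
  stopifnot(inherits(profile, "sample_profile"))
  if (is.na(profile$median_depth) || profile$median_depth == 0)
    stop("autosomal median depth is zero or undefined")
  2 * .region_mean_depth(profile, region) / profile$median_depth
}

#' Allelic copy number from diagnostic variant sites
#'
#' Separates the copies at the ancestral locus (reference allele) from
#' homologous copies inserted elsewhere (variant allele):
#' `cn_ref = 2 * mean(ref_depth) / median`,
#' `cn_hom = 2 * mean(alt_depth) / median`, alongside the total from
#' [normalised_copy_number()] and the consistency gap
#' `|cn_total - (cn_ref + cn_hom)|`.
#'
#' @param profile a [sample_profile()].
#' @param region single-row interval data.frame.
#' @param diagnostic_sites data.frame with `ref_depth` and `alt_depth`
#'   per site; zero rows leaves the allelic components undefined.
#' @return list of class `copy_number_call` with `region`, `cn_total`,
#'   `cn_ref`, `cn_hom`, `consistency`, `n_diagnostic_sites`.
#' @export
allelic_copy_number <- function(profile, region, diagnostic_sites) {
  cn_total <- normalised_copy_number(profile, region)
  n <- if (is.null(diagnostic_sites)) 0L else nrow(diagnostic_sites)
  if (n == 0) {
    cn_ref <- NA_real_; cn_hom <- NA_real_; gap <- NA_real_
  } else {
    med <- profile$median_depth
    cn_ref <- 2 * mean(diagnostic_sites$ref_depth) / med
    cn_hom <- 2 * mean(diagnostic_sites$alt_depth) / med
    gap <- abs(cn_total - (cn_ref + cn_hom))
  }
  structure(list(region = region, cn_total = cn_total, cn_ref = cn_ref,
                 cn_hom = cn_hom, consistency = gap,
                 n_diagnostic_sites = n),
            class = "copy_number_call")
}

#' @export
print.copy_number_call <- function(x, ...) {
  cat(sprintf("copy_number_call %s:%d-%d  cn_total=%.2f cn_ref=%.2f cn_hom=%.2f (%d sites)\n",
              x$region$seqid[1], x$region$start[1], x$region$end[1],
              x$cn_total, x$cn_ref, x$cn_hom, x$n_diagnostic_sites))
  invisible(x)
}
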