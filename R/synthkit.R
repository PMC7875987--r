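# Seeded synthetic genomes, degraded "old" assemblies, per-sample depth/MQ
# tracks, diagnostic variant sites and cs-tagged alignments with known
# ground truth. All randomness flows from the single integer seed carried
# by the plan; global RNG state is saved and restored around every draw.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic stream splitting: independent sub-seed per (seed, k)
.split_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6) * 2038 + (k %% 1e6) * 97 + 11) %% .Machine$integer.max
}

.random_bases <- function(n, gc) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# fixed satellite monomer (60 bp); tandem copies of it are the package's
# synthetic stand-in for carnivore satellite repeat units
.SAT_MONOMER <- "AGCATTCTGAGAAACTGCTTTGTGATGTGTGCATTCAACTCACAGAGTTGAACCTTCCTT"

#' Feature constructors for a genome plan
#'
#' Each helper returns one planted-feature description for
#' [genome_plan()]. Coordinates are 0-based half-open on the planned
#' sequence.
#'
#' @param seqid target sequence name.
#' @param start feature start (0-based).
#' @param end feature end (half-open); for array features the end is
#'   implied by the unit count.
#' @param n_units tandem unit count (telomere/satellite arrays).
#' @param strand `"+"` (TTAGGG) or `"-"` (CCCTAA) for telomere arrays.
#' @param mut_rate per-unit probability of one substituted base within a
#'   telomere unit.
#' @param monomer satellite monomer sequence; default a fixed 60 bp unit.
#' @param class repeat class label recorded in truth (satellites).
#' @param gc guaranteed minimum GC fraction for `feat_gc_extreme`.
#' @param src_start,src_end duplication source interval.
#' @param targets list of `c(seqid, start)` pairs for the extra copies;
#'   NULL places them at random non-clashing positions.
#' @param n_copies number of extra copies written into the assembly.
#' @param hom_copies diploid count of homologous copies carried by the
#'   simulated individual (drives depth and allelic-depth simulation);
#'   default `n_copies`.
#' @param div_spacing one diagnostic substitution per this many bp of
#'   duplicated copy (default 200).
#' @return a list describing the feature, for `genome_plan(features = ...)`.
#' @name plan_features
NULL

#' @rdname plan_features
#' @export
feat_telomere <- function(seqid, start, n_units = 20L, strand = "+", mut_rate = 0) {
  list(kind = "telomere_array", seqid = seqid, start = as.integer(start),
       end = as.integer(start + 6L * n_units), n_units = as.integer(n_units),
       strand = strand, mut_rate = mut_rate)
}

#' @rdname plan_features
#' @export
feat_satellite <- function(seqid, start, n_units = 100L, monomer = .SAT_MONOMER,
                           class = "CarSat1") {
  list(kind = "satellite_block", seqid = seqid, start = as.integer(start),
       end = as.integer(start + nchar(monomer) * n_units),
       n_units = as.integer(n_units), monomer = monomer, class = class)
}

#' @rdname plan_features
#' @export
feat_gc_extreme <- function(seqid, start, end, gc = 0.95) {
  list(kind = "gc_extreme", seqid = seqid, start = as.integer(start),
       end = as.integer(end), gc = gc)
}

#' @rdname plan_features
#' @export
feat_duplication <- function(seqid, src_start, src_end, n_copies = 1L,
                             targets = NULL, hom_copies = n_copies,
                             div_spacing = 200L) {
  list(kind = "duplication", seqid = seqid, start = as.integer(src_start),
       end = as.integer(src_end), n_copies = as.integer(n_copies),
       targets = targets, hom_copies = hom_copies,
       div_spacing = as.integer(div_spacing))
}

#' @rdname plan_features
#' @export
feat_dark_zone <- function(seqid, start, end) {
  list(kind = "dark_zone", seqid = seqid, start = as.integer(start),
       end = as.integer(end))
}

#' @rdname plan_features
#' @export
feat_camo_zone <- function(seqid, start, end) {
  list(kind = "camo_zone", seqid = seqid, start = as.integer(start),
       end = as.integer(end))
}

#' Build a synthetic genome plan
#'
#' @param seqlens named integer vector: length per sequence.
#' @param gc_background background GC fraction (default 0.41, a typical
#'   mammalian value).
#' @param features list of planted features from the `feat_*` constructors.
#' @param seed integer seed; fully determines the generated output.
#' @return an object of class `genome_plan`.
#' @export
genome_plan <- function(seqlens, gc_background = 0.41, features = list(), seed = 1L) {
  stopifnot(length(seqlens) >= 1, !is.null(names(seqlens)),
            gc_background >= 0, gc_background <= 1)
  for (f in features) {
    if (!f$seqid %in% names(seqlens))
      stop("feature on unknown sequence: ", f$seqid)
    if (f$start < 0 || f$end > seqlens[[f$seqid]] || f$end <= f$start)
      stop("feature outside sequence bounds: ", f$kind, " ",
           f$seqid, ":", f$start, "-", f$end)
  }
  structure(list(seqlens = seqlens, gc_background = gc_background,
                 features = features, seed = as.integer(seed)),
            class = "genome_plan")
}

# sequence-writing features must not overlap one another
.check_clashes <- function(writes) {
  if (nrow(writes) < 2) return(invisible())
  for (s in unique(writes$seqid)) {
    d <- writes[writes$seqid == s, ]
    d <- d[order(d$start), ]
    bad <- which(d$start[-1] < head(d$end, -1))
    if (length(bad))
      stop("overlapping incompatible features on ", s, ": ",
           d$what[bad[1]], " [", d$start[bad[1] + 1], ",", d$end[bad[1] + 1],
           ") clashes with ", d$what[bad[1] + 1], " [", d$start[bad[1]], ",",
           d$end[bad[1]], ")")
  }
  invisible()
}

#' Generate a synthetic genome with ground truth
#'
#' Writes the planned features into a random background sequence and
#' records every planted feature in a truth set. Telomere features are
#' tandem TTAGGG (or CCCTAA) arrays; satellite blocks are tandem copies of
#' a fixed monomer; extreme-GC windows are guaranteed to reach the
#' requested fraction; duplications copy the source interval to the target
#' positions with one diagnostic substitution per `div_spacing` bp
#' recorded as variant sites. Dark and camouflaged zones are recorded in
#' truth only and drive [simulate_tracks()].
#'
#' @param plan a [genome_plan()].
#' @return list with `sequences` (DNAStringSet) and `truth` (list of
#'   per-feature interval tables, `cn_table`, `variant_sites`, `seqlens`).
#' @export
generate_genome <- function(plan) {
  stopifnot(inherits(plan, "genome_plan"))
  .with_seed(plan$seed, {
    seqs <- lapply(plan$seqlens, function(n) .random_bases(n, plan$gc_background))
    truth <- list(telomere = NULL, satellite = NULL, gc_extreme = NULL,
                  dark = NULL, camo = NULL, cn_table = NULL,
                  variant_sites = NULL, seqlens = plan$seqlens)
    feats <- plan$features
    kinds <- vapply(feats, `[[`, "", "kind")

    # resolve duplication targets (random placement avoids declared writes)
    writes <- data.frame(seqid = character(), start = integer(),
                         end = integer(), what = character())
    add_write <- function(w, f, what) {
      rbind(w, data.frame(seqid = f$seqid, start = f$start, end = f$end,
                          what = what))
    }
    for (f in feats[kinds %in% c("telomere_array", "satellite_block", "gc_extreme")])
      writes <- add_write(writes, f, f$kind)
    for (i in which(kinds == "duplication")) {
      f <- feats[[i]]
      width <- f$end - f$start
      if (is.null(f$targets)) {
        tg <- list()
        guard <- 0
        while (length(tg) < f$n_copies && guard < 1000) {
          guard <- guard + 1
          s <- sample(names(plan$seqlens), 1)
          if (plan$seqlens[[s]] <= width) next
          st <- sample.int(plan$seqlens[[s]] - width, 1) - 1L
          if (.overlaps_any(s, st, st + width, writes) ||
              .overlaps_any(s, st, st + width,
                            data.frame(seqid = f$seqid, start = f$start, end = f$end)))
            next
          tg <- c(tg, list(c(s, st)))
          writes <- rbind(writes, data.frame(seqid = s, start = st,
                                             end = st + width, what = "duplication"))
        }
        if (length(tg) < f$n_copies) stop("could not place duplication copies")
        feats[[i]]$targets <- tg
      } else {
        for (t in f$targets)
          writes <- rbind(writes, data.frame(seqid = t[[1]],
                                             start = as.integer(t[[2]]),
                                             end = as.integer(t[[2]]) + width,
                                             what = "duplication"))
      }
    }
    .check_clashes(writes)
    zones <- do.call(rbind, c(list(writes[0, 1:3]), lapply(
      feats[kinds %in% c("dark_zone", "camo_zone")],
      function(f) data.frame(seqid = f$seqid, start = f$start, end = f$end))))
    if (nrow(zones) > 1) {
      z <- zones; z$what <- "dark/camo zone"
      .check_clashes(z)
    }

    put <- function(seqid, start0, txt) {
      s <- seqs[[seqid]]
      substr(s, start0 + 1L, start0 + nchar(txt)) <- txt
      seqs[[seqid]] <<- s
    }

    for (f in feats) {
      switch(f$kind,
        telomere_array = {
          unit <- if (f$strand == "+") "TTAGGG" else "CCCTAA"
          units <- rep(unit, f$n_units)
          if (f$mut_rate > 0) {
            hit <- runif(f$n_units) < f$mut_rate
            for (j in which(hit)) {
              pos <- sample.int(6L, 1)
              b <- sample(setdiff(c("A", "C", "G", "T"),
                                  substr(units[j], pos, pos)), 1)
              substr(units[j], pos, pos) <- b
            }
          }
          put(f$seqid, f$start, paste(units, collapse = ""))
          truth$telomere <- rbind(truth$telomere,
            intervals(f$seqid, f$start, f$end, strand = f$strand,
                      n_units = f$n_units))
        },
        satellite_block = {
          put(f$seqid, f$start, strrep(f$monomer, f$n_units))
          truth$satellite <- rbind(truth$satellite,
            intervals(f$seqid, f$start, f$end, name = f$class))
        },
        gc_extreme = {
          n <- f$end - f$start
          n_gc <- ceiling(f$gc * n)
          b <- c(sample(c("G", "C"), n_gc, replace = TRUE),
                 sample(c("A", "T"), n - n_gc, replace = TRUE))
          put(f$seqid, f$start, paste(sample(b), collapse = ""))
          truth$gc_extreme <- rbind(truth$gc_extreme,
            intervals(f$seqid, f$start, f$end, gc = f$gc))
        },
        dark_zone = {
          truth$dark <- rbind(truth$dark, intervals(f$seqid, f$start, f$end))
        },
        camo_zone = {
          truth$camo <- rbind(truth$camo, intervals(f$seqid, f$start, f$end))
        },
        duplication = NULL)
    }

    # duplications copy post-write sequence; diagnostic substitutions are
    # shared across copies so allelic depth aggregates per source site
    for (f in feats[kinds == "duplication"]) {
      width <- f$end - f$start
      src <- substr(seqs[[f$seqid]], f$start + 1L, f$end)
      offs <- if (f$div_spacing %/% 2L <= width - 1L)
        seq.int(f$div_spacing %/% 2L, width - 1L, by = f$div_spacing)
      else integer()
      alts <- vapply(offs, function(o) {
        sample(setdiff(c("A", "C", "G", "T"), substr(src, o + 1L, o + 1L)), 1)
      }, "")
      copy <- src
      for (j in seq_along(offs)) substr(copy, offs[j] + 1L, offs[j] + 1L) <- alts[j]
      for (t in f$targets) put(t[[1]], as.integer(t[[2]]), copy)
      truth$cn_table <- rbind(truth$cn_table, data.frame(
        seqid = f$seqid, start = f$start, end = f$end,
        copies_assembly = 1L + f$n_copies, cn_ref = 2,
        cn_hom = f$hom_copies, stringsAsFactors = FALSE))
      if (length(offs))
        truth$variant_sites <- rbind(truth$variant_sites, data.frame(
          seqid = f$seqid, pos = f$start + offs + 1L,
          ref = vapply(offs, function(o) substr(src, o + 1L, o + 1L), ""),
          alt = alts, region_start = f$start, region_end = f$end,
          stringsAsFactors = FALSE))
    }

    list(sequences = Biostrings::DNAStringSet(unlist(seqs)), truth = truth)
  })
}

#' Degrade a genome into a gapped "old" assembly
#'
#' Rebuilds each sequence with planted N-run gaps. For each plan entry the
#' old sequence keeps the new sequence up to `position`, inserts
#' `n_length` N bases, and resumes at `position + replaced_length -
#' overlap_length`: `replaced_length` true bases are removed under the
#' N-run, and with `overlap_length > 0` the bases immediately before the
#' gap reappear after it, so the gap's flanks overlap when lifted back —
#' an artificial gap when no sequence was removed at all.
#'
#' @param genome DNAStringSet (the "new"/true assembly).
#' @param gap_plan data.frame with `seqid`, `position` (0-based cut point),
#'   `replaced_length`, `n_length`, `overlap_length`; optional `expect`
#'   column overrides the derived closure expectation.
#' @return list with `old` (DNAStringSet) and `gaps` (truth table with
#'   old-assembly gap coordinates, new-assembly fill coordinates and the
#'   expected classification).
#' @export
degrade_assembly <- function(genome, gap_plan) {
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  gp <- gap_plan[order(gap_plan$seqid, gap_plan$position), , drop = FALSE]
  stopifnot(all(gp$replaced_length >= 0), all(gp$n_length > 0),
            all(gp$overlap_length >= 0))
  old <- as.character(genome)
  rows <- list()
  for (s in unique(gp$seqid)) {
    d <- gp[gp$seqid == s, , drop = FALSE]
    new_seq <- as.character(genome[[s]])
    new_len <- nchar(new_seq)
    if (any(d$position + d$replaced_length > new_len))
      stop("replaced_length exceeds available sequence on ", s)
    if (any(d$position[-1] < head(d$position + d$replaced_length, -1)))
      stop("gap plan entries nest/overlap on ", s)
    pieces <- character()
    cursor <- 0L
    old_pos <- 0L
    for (i in seq_len(nrow(d))) {
      p <- d$position[i]
      pieces <- c(pieces, substr(new_seq, cursor + 1L, p))
      old_pos <- old_pos + (p - cursor)
      gap_start <- old_pos
      pieces <- c(pieces, strrep("N", d$n_length[i]))
      old_pos <- old_pos + d$n_length[i]
      cursor <- p + d$replaced_length[i] - d$overlap_length[i]
      expect <- if (!is.null(d$expect)) d$expect[i]
        else if (d$overlap_length[i] > 0 && d$replaced_length[i] == 0) "artificial"
        else "closed"
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = s, old_start = gap_start, old_end = gap_start + d$n_length[i],
        n_length = d$n_length[i], fill_start = p,
        fill_end = p + d$replaced_length[i],
        replaced_length = d$replaced_length[i],
        overlap_length = d$overlap_length[i], expect = expect,
        stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, substr(new_seq, cursor + 1L, new_len))
    old[[s]] <- paste(pieces, collapse = "")
  }
  gaps <- do.call(rbind, rows)
  rownames(gaps) <- NULL
  list(old = Biostrings::DNAStringSet(old), gaps = gaps)
}

#' Simulate per-sample windowed depth and high-MQ-fraction tracks
#'
#' Depth per window is negative-binomial around the sample's mean depth
#' (dispersion `size = dispersion`); windows inside planted dark zones
#' draw around `dark_mu` (default 0.5x), windows over duplication sources
#' scale by the planted diploid copy number, and windows in camouflaged
#' zones keep normal depth but draw their high-MQ fraction near
#' `camo_mq` instead of the background near 1.
#'
#' @param truth truth set from [generate_genome()].
#' @param samples data.frame with `sample_id`, `technology`
#'   (`ISR`/`LINKED`/`LONG`), `mean_depth`.
#' @param window window width in bp (default 25).
#' @param dispersion negative-binomial size parameter (default 20).
#' @param dark_mu mean depth inside dark zones (default 0.5).
#' @param camo_mq,bg_mq Beta-distributed high-MQ fraction means inside
#'   camouflaged zones (default 0.02) and elsewhere (default 0.98).
#' @param seed integer seed.
#' @return named list of [sample_profile()] objects.
#' @export
simulate_tracks <- function(truth, samples, window = 25L, dispersion = 20,
                            dark_mu = 0.5, camo_mq = 0.02, bg_mq = 0.98,
                            seed = 1L) {
  stopifnot(window >= 1, all(samples$mean_depth > 0))
  grid <- tile_windows(truth$seqlens, window)
  zone_idx <- function(zones, s, nwin) {
    sel <- logical(nwin)
    if (is.null(zones)) return(sel)
    z <- zones[zones$seqid == s, , drop = FALSE]
    for (i in seq_len(nrow(z))) {
      a <- z$start[i] %/% window + 1L
      b <- min(nwin, as.integer(ceiling(z$end[i] / window)))
      sel[a:b] <- TRUE
    }
    sel
  }
  dup <- truth$cn_table
  out <- list()
  for (k in seq_len(nrow(samples))) {
    sid <- samples$sample_id[k]
    depth_tracks <- list()
    mq_tracks <- list()
    .with_seed(.split_seed(seed, k), {
      for (s in names(truth$seqlens)) {
        nwin <- sum(grid$seqid == s)
        mu <- rep(samples$mean_depth[k], nwin)
        if (!is.null(dup)) {
          d <- dup[dup$seqid == s, , drop = FALSE]
          for (i in seq_len(nrow(d))) {
            sel <- zone_idx(d[i, c("seqid", "start", "end")], s, nwin)
            mu[sel] <- samples$mean_depth[k] * (d$cn_ref[i] + d$cn_hom[i]) / 2
          }
        }
        dark_sel <- zone_idx(truth$dark, s, nwin)
        mu[dark_sel] <- dark_mu
        depth_tracks[[s]] <- rnbinom(nwin, size = dispersion, mu = mu)
        camo_sel <- zone_idx(truth$camo, s, nwin)
        conc <- 100
        mq <- rbeta(nwin, bg_mq * conc, (1 - bg_mq) * conc)
        mq[camo_sel] <- rbeta(sum(camo_sel), camo_mq * conc, (1 - camo_mq) * conc)
        mq_tracks[[s]] <- mq
      }
    })
    out[[sid]] <- sample_profile(sid, samples$technology[k], depth_tracks,
                                 mq_tracks, window = window)
  }
  out
}

#' Simulate allelic depths at diagnostic variant sites
#'
#' Draws reference- and variant-allele depths at each planted diagnostic
#' site: the reference allele around `mean_depth * cn_ref / 2`, the
#' variant allele (reads mis-mapped from homologous copies) around
#' `mean_depth * cn_hom / 2`.
#'
#' @param truth truth set from [generate_genome()] (needs `variant_sites`
#'   and `cn_table`).
#' @param mean_depth sample mean depth.
#' @param dispersion negative-binomial size parameter.
#' @param seed integer seed.
#' @return data.frame with `seqid`, `pos`, `ref`, `alt`, `ref_depth`,
#'   `alt_depth`.
#' @export
simulate_site_depths <- function(truth, mean_depth, dispersion = 20, seed = 1L) {
  vs <- truth$variant_sites
  if (is.null(vs) || !nrow(vs)) stop("truth has no diagnostic variant sites")
  cn <- truth$cn_table
  key <- paste(vs$seqid, vs$region_start)
  cn_key <- paste(cn$seqid, cn$start)
  m <- match(key, cn_key)
  .with_seed(seed, {
    vs$ref_depth <- rnbinom(nrow(vs), size = dispersion,
                            mu = mean_depth * cn$cn_ref[m] / 2)
    vs$alt_depth <- rnbinom(nrow(vs), size = dispersion,
                            mu = mean_depth * cn$cn_hom[m] / 2)
  })
  vs
}

#' Simulate cs-tagged alignments of reads against two assemblies
#'
#' Draws reads from the ancestral genome and emits PAF records with cs
#' difference strings for assembly A (the ancestral sequence itself) and
#' assembly B (the ancestral sequence with `deletions_b` removed). Reads
#' overlapping a deleted region produce truncated/split records in B;
#' reads entirely inside a deletion are unmapped in B. A fraction of reads
#' is emitted as two split (supplementary) records with overlapping query
#' spans to exercise union semantics, and a fraction gains a duplicate
#' secondary record (`tp:A:S`) that consumers must ignore. The planted
#' truth is the query-base union fraction covered by match/mismatch
#' operations per read per assembly.
#'
#' @param genome ancestral DNAStringSet (assembly A).
#' @param n_reads number of reads.
#' @param read_length read length in bp.
#' @param deletions_b interval data.frame deleted from assembly B.
#' @param mismatch_prob per-read probability of carrying one `*` mismatch.
#' @param insert_prob per-read probability of one 4 bp insertion (query
#'   bases that map nowhere, lowering the mapped fraction).
#' @param split_prob per-read probability of being emitted as two
#'   overlapping supplementary records.
#' @param secondary_prob per-read probability of an extra secondary record.
#' @param seed integer seed.
#' @return list with `paf_a`, `paf_b` (PAF data.frames as [read_paf()])
#'   and `truth` (`read_id`, `frac_a`, `frac_b`).
#' @export
simulate_cs_alignments <- function(genome, n_reads, read_length = 1000L,
                                   deletions_b = NULL, mismatch_prob = 0.3,
                                   insert_prob = 0.2, split_prob = 0.1,
                                   secondary_prob = 0.05, seed = 1L) {
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  seqlens <- setNames(BiocGenerics::width(genome), names(genome))
  if (is.null(deletions_b)) deletions_b <- .empty_intervals()
  .with_seed(seed, {
    # cs for a segment of n matched bases with optional planted mismatch or
    # insertion (both consume query; only the insertion is unmapped)
    seg_cs <- function(n, mism, ins) {
      a <- n %/% 2
      if (mism && n >= 3)
        list(cs = paste0(":", a, "*ac", ":", n - a - 1L), mapped = n, qlen = n)
      else if (ins && n >= 3)
        list(cs = paste0(":", a, "+acgt", ":", n - a), mapped = n, qlen = n + 4L)
      else list(cs = paste0(":", n), mapped = n, qlen = n)
    }
    # preallocated record columns (3 records/read upper bound); direct
    # indexed assignment keeps appends O(1)
    cap <- 3L * n_reads
    a_qname <- character(cap); a_qlen <- integer(cap)
    a_qstart <- integer(cap); a_qend <- integer(cap)
    a_tname <- character(cap); a_tstart <- integer(cap)
    a_cs <- character(cap); a_tp <- character(cap)
    b_qname <- character(cap); b_qlen <- integer(cap)
    b_qstart <- integer(cap); b_qend <- integer(cap)
    b_tname <- character(cap); b_tstart <- integer(cap)
    b_cs <- character(cap); b_tp <- character(cap)
    na <- 0L; nb <- 0L
    t_frac_a <- numeric(n_reads)
    t_frac_b <- numeric(n_reads)
    L <- as.integer(read_length)
    snames <- sample(names(seqlens), n_reads, replace = TRUE)
    if (any(seqlens[snames] <= L)) stop("sequence shorter than read length")
    s0s <- vapply(snames, function(s) sample.int(seqlens[[s]] - L, 1) - 1L, 0L)
    mism_v <- runif(n_reads) < mismatch_prob
    ins_v <- runif(n_reads) < insert_prob
    split_v <- runif(n_reads) < split_prob
    sec_v <- runif(n_reads) < secondary_prob
    qnames <- sprintf("read%06d", seq_len(n_reads))
    dels_by_seq <- split(deletions_b, deletions_b$seqid)
    for (r in seq_len(n_reads)) {
      sname <- snames[r]; s0 <- s0s[r]; qname <- qnames[r]
      if (split_v[r]) {
        # two supplementary records with overlapping query spans; union
        # covers the whole read
        cut <- L %/% 2
        ovl <- min(20L, cut)
        r1 <- seg_cs(cut, mism_v[r], FALSE)
        qlen <- r1$qlen + (L - cut)
        na <- na + 1L
        a_qname[na] <- qname; a_qlen[na] <- qlen
        a_qstart[na] <- 0L; a_qend[na] <- r1$qlen
        a_tname[na] <- sname; a_tstart[na] <- s0
        a_cs[na] <- r1$cs; a_tp[na] <- "P"
        na <- na + 1L
        a_qname[na] <- qname; a_qlen[na] <- qlen
        a_qstart[na] <- r1$qlen - ovl; a_qend[na] <- qlen
        a_tname[na] <- sname; a_tstart[na] <- s0 + cut - ovl
        a_cs[na] <- paste0(":", L - cut + ovl); a_tp[na] <- "P"
        t_frac_a[r] <- 1.0
      } else {
        sa <- seg_cs(L, mism_v[r], ins_v[r])
        qlen <- sa$qlen
        na <- na + 1L
        a_qname[na] <- qname; a_qlen[na] <- qlen
        a_qstart[na] <- 0L; a_qend[na] <- qlen
        a_tname[na] <- sname; a_tstart[na] <- s0
        a_cs[na] <- sa$cs; a_tp[na] <- "P"
        t_frac_a[r] <- sa$mapped / qlen
        if (sec_v[r]) {  # duplicate secondary record; consumers must skip it
          na <- na + 1L
          a_qname[na] <- qname; a_qlen[na] <- qlen
          a_qstart[na] <- 0L; a_qend[na] <- qlen
          a_tname[na] <- sname; a_tstart[na] <- s0
          a_cs[na] <- sa$cs; a_tp[na] <- "S"
        }
      }
      dels <- dels_by_seq[[sname]]
      hit <- if (is.null(dels)) integer() else
        which(dels$start < s0 + L & dels$end > s0)
      if (!length(hit)) {
        nb <- nb + 1L
        b_qname[nb] <- qname; b_qlen[nb] <- qlen
        b_qstart[nb] <- 0L; b_qend[nb] <- qlen
        b_tname[nb] <- sname; b_tstart[nb] <- s0
        b_cs[nb] <- paste0(":", qlen); b_tp[nb] <- "P"
        t_frac_b[r] <- 1.0
      } else {
        h <- hit[1]
        a <- max(0L, dels$start[h] - s0)      # query bases mapped before deletion
        b <- max(0L, (s0 + L) - dels$end[h])  # query bases mapped after it
        t_frac_b[r] <- (a + b) / qlen
        if (a > 0) {
          nb <- nb + 1L
          b_qname[nb] <- qname; b_qlen[nb] <- qlen
          b_qstart[nb] <- 0L; b_qend[nb] <- a
          b_tname[nb] <- sname; b_tstart[nb] <- s0
          b_cs[nb] <- paste0(":", a); b_tp[nb] <- "P"
        }
        if (b > 0) {
          nb <- nb + 1L
          b_qname[nb] <- qname; b_qlen[nb] <- qlen
          b_qstart[nb] <- qlen - b; b_qend[nb] <- qlen
          b_tname[nb] <- sname; b_tstart[nb] <- dels$end[h]
          b_cs[nb] <- paste0(":", b); b_tp[nb] <- "P"
        }
      }
    }
    as_paf <- function(qname, qlen, qstart, qend, tname, tstart, cs, tp, n) {
      i <- seq_len(n)
      data.frame(qname = qname[i], qlen = qlen[i], qstart = qstart[i],
                 qend = qend[i], strand = "+", tname = tname[i],
                 tlen = unname(seqlens[tname[i]]), tstart = tstart[i],
                 tend = tstart[i] + (qend[i] - qstart[i]),
                 nmatch = qend[i] - qstart[i], alen = qend[i] - qstart[i],
                 mapq = 60L, cs = cs[i], tp = tp[i], stringsAsFactors = FALSE)
    }
    list(paf_a = as_paf(a_qname, a_qlen, a_qstart, a_qend, a_tname, a_tstart,
                        a_cs, a_tp, na),
         paf_b = as_paf(b_qname, b_qlen, b_qstart, b_qend, b_tname, b_tstart,
                        b_cs, b_tp, nb),
         truth = data.frame(read_id = qnames, frac_a = t_frac_a,
                            frac_b = t_frac_b, stringsAsFactors = FALSE))
  })
}

#' Simulate qualifying patch variants for a genome
#'
#' Draws non-overlapping SNP, insertion and deletion sites whose stated
#' depth and allele ratio pass the patching thresholds, with context
#' constraints that keep patching unambiguous: an inserted sequence never
#' equals the bases that follow its site, and a deleted suffix never
#' equals the bases that follow the reference allele (so a patched site
#' can always be recognised as applied).
#'
#' @param genome DNAStringSet.
#' @param n number of variant sites.
#' @param p_snp,p_ins,p_del type mix (normalised internally).
#' @param indel_len indel length in bp (default 3).
#' @param depth_range,ratio_range uniform ranges for the per-site depth
#'   and variant allele ratio (defaults qualify under depth >= 30,
#'   ratio > 0.90).
#' @param seed integer seed.
#' @return variant data.frame (`seqid`, `pos`, `ref`, `alt`, `depth`,
#'   `ratio`) sorted by position.
#' @export
simulate_patch_variants <- function(genome, n, p_snp = 0.8, p_ins = 0.1,
                                    p_del = 0.1, indel_len = 3L,
                                    depth_range = c(30, 60),
                                    ratio_range = c(0.95, 1.0), seed = 1L) {
  if (!is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  seqlens <- setNames(BiocGenerics::width(genome), names(genome))
  chars <- lapply(as.character(genome), identity)
  bases <- c("A", "C", "G", "T")
  k <- as.integer(indel_len)
  .with_seed(seed, {
    # spread sites over the genome with enough spacing that ref alleles
    # and context windows never overlap
    spacing <- 3L * (k + 2L)
    total <- sum(seqlens)
    if (n * spacing * 2 > total)
      stop("genome too small for ", n, " spaced variant sites")
    per_seq <- pmax(0L, as.integer(round(n * seqlens / total)))
    while (sum(per_seq) < n) per_seq[which.max(seqlens)] <- per_seq[which.max(seqlens)] + 1L
    while (sum(per_seq) > n) per_seq[which.max(per_seq)] <- per_seq[which.max(per_seq)] - 1L
    rows <- vector("list", length(seqlens))
    for (si in seq_along(seqlens)) {
      m <- per_seq[si]
      if (m == 0) next
      s <- names(seqlens)[si]
      sc <- chars[[s]]
      usable <- seqlens[[s]] - 4L * k - 8L
      pos <- sort(sample.int(usable %/% spacing, m)) * spacing
      type <- sample(c("snp", "ins", "del"), m, replace = TRUE,
                     prob = c(p_snp, p_ins, p_del))
      ref <- character(m); alt <- character(m)
      for (i in seq_len(m)) {
        p <- pos[i]
        b <- substr(sc, p, p)
        if (type[i] == "snp") {
          ref[i] <- b
          alt[i] <- sample(setdiff(bases, b), 1)
        } else if (type[i] == "ins") {
          following <- substr(sc, p + 1L, p + k)
          repeat {
            insseq <- paste(sample(bases, k, replace = TRUE), collapse = "")
            if (insseq != following) break
          }
          ref[i] <- b
          alt[i] <- paste0(b, insseq)
        } else {
          deleted <- substr(sc, p + 1L, p + k)
          after <- substr(sc, p + k + 1L, p + 2L * k)
          if (deleted == after) { # patched site would still match ref
            ref[i] <- b          # fall back to a SNP at this site
            alt[i] <- sample(setdiff(bases, b), 1)
            type[i] <- "snp"
          } else {
            ref[i] <- paste0(b, deleted)
            alt[i] <- b
          }
        }
      }
      rows[[si]] <- data.frame(seqid = s, pos = pos, ref = ref, alt = alt,
                               stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$depth <- runif(nrow(out), depth_range[1], depth_range[2])
    out$ratio <- runif(nrow(out), ratio_range[1], ratio_range[2])
    rownames(out) <- NULL
    out
  })
}
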