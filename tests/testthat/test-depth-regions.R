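make_profile <- function(depth, mq = NULL, window = 25, id = "s1",
                         tech = "ISR") {
  sample_profile(id, tech, list(chr1 = depth),
                 if (!is.null(mq)) list(chr1 = mq), window = window)
}

test_that("dark calling is inclusive at the depth threshold", {
  p <- make_profile(c(30, 5, 6, 30, 5, 5, 30))
  r <- call_dark_sample(p)
  expect_equal(r$threshold, 5)
  expect_equal(r$regions$start, c(25, 100))
  expect_equal(r$regions$end, c(50, 150))
  expect_equal(nrow(call_dark_sample(make_profile(rep(30, 100)))$regions), 0)
})

test_that("the dark threshold decrements until the total fits the cap", {
  depth <- c(rep(5, 40), rep(3, 20), rep(30, 40))
  p <- make_profile(depth)
  r <- call_dark_sample(p, base_threshold = 5, cap_bp = 60 * 25)
  # brute force: per candidate threshold, total selected bases
  totals <- vapply(5:0, function(t) sum(depth <= t) * 25, 0)
  want_thr <- (5:0)[which(totals <= 60 * 25)[1]]
  expect_equal(r$threshold, want_thr)
  expect_lte(sum(r$regions$end - r$regions$start), 60 * 25)
})

test_that("camouflaged calling needs depth >=10 and MQ fraction strictly <0.10", {
  p <- make_profile(c(12, 12, 9, 12), c(0.05, 0.10, 0.05, 0.0999))
  r <- call_camo_sample(p)
  expect_equal(r$start, c(0, 75))
  expect_equal(r$end, c(25, 100))
  expect_error(call_camo_sample(make_profile(c(12, 12))), "s1")
})

test_that("dark and camouflaged calls never overlap within one sample", {
  set.seed(12)
  depth <- sample(0:40, 500, replace = TRUE)
  mq <- runif(500)
  p <- make_profile(depth, mq)
  d <- call_dark_sample(p)$regions
  cm <- call_camo_sample(p)
  if (nrow(d) && nrow(cm))
    expect_equal(total_covered(darkmap:::.intersect_intervals(d, cm)), 0)
})

test_that("consensus keeps 23/25 and drops 22/25 under the strict >0.9 rule", {
  seqlens <- c(chr1 = 250)
  win <- intervals("chr1", 100, 125)  # window index 5
  calls_for <- function(n) {
    calls <- lapply(seq_len(25), function(i)
      if (i <= n) win else intervals())
    names(calls) <- paste0("s", 1:25)
    calls
  }
  keep <- consensus_regions(calls_for(23), seqlens, 25, "dark")
  expect_equal(nrow(keep), 1)
  expect_equal(keep$support_fraction, 0.92)
  expect_equal(keep$n_support, 23)
  drop <- consensus_regions(calls_for(22), seqlens, 25, "dark")
  expect_equal(nrow(drop), 0)
})

test_that("camouflaged eligibility excludes dark samples; 9/10 is dropped", {
  seqlens <- c(chr1 = 250)
  win <- intervals("chr1", 100, 125)
  ids <- paste0("s", 1:25)
  camo <- setNames(lapply(1:25, function(i) if (i <= 9) win else intervals()), ids)
  dark <- setNames(lapply(1:25, function(i)
    if (i > 10) win else intervals()), ids)  # 15 dark -> 10 eligible
  r <- consensus_regions(camo, seqlens, 25, "camouflaged", dark_calls = dark)
  expect_equal(nrow(r), 0)  # 9/10 = 0.9 is not > 0.9
  camo10 <- setNames(lapply(1:25, function(i) if (i <= 10) win else intervals()), ids)
  r2 <- consensus_regions(camo10, seqlens, 25, "camouflaged", dark_calls = dark)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$n_eligible, 10)
})

test_that("consensus equals the per-window counting oracle and is stable", {
  set.seed(77)
  seqlens <- c(chr1 = 10000 * 25)
  ids <- paste0("s", 1:8)
  calls <- setNames(lapply(ids, function(i) {
    n <- sample(5:20, 1)
    st <- sort(sample(0:9990, n)) * 25
    merge_intervals(intervals("chr1", st, st + sample(1:40, n, replace = TRUE) * 25))
  }), ids)
  got <- consensus_regions(calls, seqlens, 25, "dark", min_fraction = 0.6)
  want <- windows_as_intervals(
    oracle_consensus(calls, 10000, 25, min_fraction = 0.6), 25)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  # permutation invariance in sample order
  perm <- consensus_regions(calls[sample(ids)], seqlens, 25, "dark",
                            min_fraction = 0.6)
  expect_equal(perm$start, got$start)
  # monotonicity: raising min_fraction never grows the retained set
  higher <- consensus_regions(calls, seqlens, 25, "dark", min_fraction = 0.8)
  expect_lte(total_covered(higher), total_covered(got))
  expect_equal(total_covered(darkmap:::.intersect_intervals(
    merge_intervals(higher), merge_intervals(got))), total_covered(higher))
})

test_that("technology intersection partitions bases exactly", {
  a <- intervals("chr1", c(0, 100), c(50, 150))
  ident <- intersect_technologies(list(ISR = a, LONG = a))
  expect_equal(ident$combination, "ISR+LONG")
  expect_equal(ident$bases, 100)
  disj <- intersect_technologies(list(ISR = intervals("chr1", 0, 50),
                                      LONG = intervals("chr1", 100, 120)))
  expect_setequal(disj$combination, c("ISR", "LONG"))
  set.seed(21)
  sets <- lapply(1:3, function(i) {
    st <- sort(sample(0:990, 12)) * 100
    merge_intervals(intervals("chr1", st, st + sample(1:500, 12, replace = TRUE)))
  })
  names(sets) <- c("ISR", "LINKED", "LONG")
  got <- intersect_technologies(sets)
  want <- oracle_partition(sets, 100000 + 500)
  expect_equal(setNames(got$bases, got$combination)[names(want)], want)
  # conservation: cells sum to the union, per-tech sums to merged lengths
  expect_equal(sum(got$bases), total_covered(do.call(rbind, sets)))
  for (tech in names(sets)) {
    in_tech <- grepl(tech, got$combination)
    expect_equal(sum(got$bases[in_tech]), total_covered(sets[[tech]]))
  }
})

test_that("variants are counted by half-open interval overlap", {
  regions <- intervals("chr1", 100, 200)
  v <- data.frame(seqid = "chr1", pos = c(100L, 101L, 200L, 201L),
                  ref = c("A", "A", "A", "AC"), alt = "T")
  r <- variants_in_regions(regions, v)
  # pos 100 (base 99, 0-based) is left of the region; pos 201 starts at 200
  expect_equal(r$variants$pos, c(101L, 200L))
  ann <- intervals("chr1", c(90, 150), c(120, 260), name = c("exon", "intron"))
  r2 <- variants_in_regions(regions, v, ann)
  expect_equal(unname(r2$counts["total"]), 2L)
  expect_equal(unname(r2$counts["exon"]), 1L)
  expect_equal(unname(r2$counts["intron"]), 1L)
})

test_that("normalised and allelic copy number follow their definitions", {
  p <- make_profile(rep(20, 400))
  region <- intervals("chr1", 1000, 2000)
  expect_equal(normalised_copy_number(p, region), 2.0)
  depth <- rep(20, 400); depth[41:80] <- 30
  p2 <- make_profile(depth)
  expect_equal(normalised_copy_number(p2, region), 3.0)
  sites <- data.frame(ref_depth = rep(20, 5), alt_depth = rep(10, 5))
  cn <- allelic_copy_number(p2, region, sites)
  expect_equal(cn$cn_ref, 2.0)
  expect_equal(cn$cn_hom, 1.0)
  expect_equal(cn$consistency, 0)
  cn0 <- allelic_copy_number(p2, region, data.frame(ref_depth = 20, alt_depth = 0))
  expect_equal(cn0$cn_hom, 0)
  cn_na <- allelic_copy_number(p2, region, NULL)
  expect_true(is.na(cn_na$cn_ref))
  expect_equal(cn_na$cn_total, 3.0)
  expect_error(normalised_copy_number(make_profile(rep(0, 400)), region), "zero")
})
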