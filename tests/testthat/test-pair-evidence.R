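mk_pairs <- function(seq2 = "chr1", start2, strand1 = "+", strand2 = "-",
                     start1 = 0L, w = 1000L, id = "p1") {
  data.frame(pair_id = id, seq1 = "chr1", start1 = start1,
             end1 = start1 + w, strand1 = strand1, seq2 = seq2,
             start2 = start2, end2 = start2 + w, strand2 = strand2,
             stringsAsFactors = FALSE)
}

test_that("pair concordance needs FR orientation and <500 kb strictly", {
  expect_equal(pair_concordance(mk_pairs(start2 = 99000L))$status, "concordant")
  # outer span exactly 500 kb is discordant
  expect_equal(pair_concordance(mk_pairs(start2 = 499000L))$status, "discordant")
  expect_equal(pair_concordance(mk_pairs(start2 = 498999L))$status, "concordant")
  expect_equal(pair_concordance(mk_pairs(start2 = 10000L, strand2 = "+"))$status,
               "discordant")                       # FF
  expect_equal(pair_concordance(mk_pairs(start2 = 10000L, strand1 = "-",
                                         strand2 = "+"))$status,
               "discordant")                       # RF (divergent)
  expect_equal(pair_concordance(mk_pairs(seq2 = "chr2", start2 = 1000L))$status,
               "discordant")
  p <- mk_pairs(start2 = 5000L)
  p$seq2 <- NA_character_
  expect_equal(pair_concordance(p)$status, "excluded")
})

test_that("concordance labels are invariant to swapping ends", {
  set.seed(81)
  n <- 50
  pairs <- data.frame(pair_id = paste0("p", 1:n), seq1 = "chr1",
                      start1 = sample(1:1e6, n), strand1 = sample(c("+", "-"), n, TRUE),
                      seq2 = "chr1", start2 = sample(1:1e6, n),
                      strand2 = sample(c("+", "-"), n, TRUE))
  pairs$end1 <- pairs$start1 + 800L
  pairs$end2 <- pairs$start2 + 800L
  swapped <- pairs
  names(swapped) <- sub("1$", "x", names(swapped))
  names(swapped) <- sub("2$", "1", names(swapped))
  names(swapped) <- sub("x$", "2", names(swapped))
  expect_equal(pair_concordance(pairs)$status, pair_concordance(swapped)$status)
})

test_that("discordant ends cluster by single linkage, matching union-find", {
  d <- pair_concordance(rbind(
    mk_pairs(start2 = 10000L, strand2 = "+", id = "a"),
    mk_pairs(start2 = 12000L, strand2 = "+", id = "b", start1 = 3000L),
    mk_pairs(start2 = 1000000L, strand2 = "+", id = "c", start1 = 990000L)))
  cl <- discordance_clusters(d, window = 50000)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$n_pairs[1], 2)
  # random positions vs a brute-force union-find oracle
  set.seed(82)
  n <- 40
  pos <- sample(1:2e6, n)
  pr <- data.frame(pair_id = paste0("p", 1:n), seq1 = "chr1", start1 = pos,
                   end1 = pos + 500L, strand1 = "+", seq2 = "chr1",
                   start2 = pos + 600L, end2 = pos + 1100L, strand2 = "+",
                   status = "discordant")
  cl2 <- discordance_clusters(pr, window = 30000)
  pts <- sort(c(pos, pos + 600L))
  parent <- seq_along(pts)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(pts)[-1])
    if (pts[i] - pts[i - 1] <= 30000) parent[find(i)] <- find(i - 1)
  n_clusters <- length(unique(vapply(seq_along(pts), find, 0)))
  expect_equal(nrow(cl2), n_clusters)
  expect_equal(sum(cl2$n_pairs >= 1), n_clusters)
})

test_that("mapped_fraction reads the cs grammar and unions query coverage", {
  paf1 <- data.frame(qname = "r", qlen = 100L, qstart = 0L, qend = 100L,
                     strand = "+", tname = "t", tlen = 1000L, tstart = 0L,
                     tend = 100L, nmatch = 100L, alen = 100L, mapq = 60L,
                     cs = ":100", tp = "P")
  expect_equal(unname(mapped_fraction(paf1)), 1.0)
  paf2 <- transform(paf1, cs = ":40+acgt:56")
  expect_equal(unname(mapped_fraction(paf2)), 0.96)
  # two records covering [0,60) and [40,100): union, not sum
  paf3 <- rbind(transform(paf1, qend = 60L, cs = ":60"),
                transform(paf1, qstart = 40L, cs = ":60"))
  expect_equal(unname(mapped_fraction(paf3)), 1.0)
  # deletions and introns consume no query; mismatches count as mapped
  paf4 <- transform(paf1, cs = ":40*ac:29-tt:30~gt100ag:0")
  expect_equal(unname(mapped_fraction(paf4)), 1.0)
  # secondary records are ignored
  paf5 <- rbind(transform(paf1, qend = 50L, cs = ":50"),
                transform(paf1, tp = "S"))
  expect_equal(unname(mapped_fraction(paf5)), 0.5)
  expect_error(mapped_fraction(transform(paf1, cs = ":40zz:60")), "malformed")
  expect_error(mapped_fraction(transform(paf1, cs = ":99")), "consumption")
})

test_that("mapped fractions on simulated alignments equal planted truth", {
  plan <- genome_plan(c(chr1 = 80000), seed = 91)
  g <- generate_genome(plan)
  sim <- simulate_cs_alignments(g$sequences, 300, 800,
                                deletions_b = intervals("chr1", 40000, 41000),
                                seed = 92)
  fa <- mapped_fraction(sim$paf_a)
  fb <- mapped_fraction(sim$paf_b)
  truth_a <- setNames(sim$truth$frac_a, sim$truth$read_id)
  truth_b <- setNames(sim$truth$frac_b, sim$truth$read_id)
  expect_equal(max(abs(fa[names(truth_a)] - truth_a)), 0, tolerance = 1e-12)
  common <- intersect(names(fb), names(truth_b))
  expect_equal(max(abs(fb[common] - truth_b[common])), 0, tolerance = 1e-12)
  # reads entirely unmapped in B are simply absent (0 via comparison rule)
  expect_true(all(truth_b[setdiff(names(truth_a), names(fb))] == 0))
})

test_that("mappability comparison uses a strict 5-point margin and is antisymmetric", {
  a <- c(r1 = 0.99, r2 = 0.93, r3 = 0.80, r4 = 0.50)
  b <- c(r1 = 0.90, r2 = 0.90, r3 = 0.90)
  r <- compare_mappability(a, b)
  tab <- setNames(r$table$call, r$table$read_id)
  expect_equal(unname(tab["r1"]), "better_a")   # 0.09 > 0.05
  expect_equal(unname(tab["r2"]), "tied")       # 0.03
  expect_equal(unname(tab["r3"]), "better_b")
  expect_equal(unname(tab["r4"]), "better_a")   # absent in B -> 0
  exact <- compare_mappability(c(r = 0.95), c(r = 0.90))
  expect_equal(unname(exact$counts["tied"]), 1L)  # diff exactly 0.05
  rev <- compare_mappability(b, a)
  expect_equal(unname(rev$counts["better_a"]), unname(r$counts["better_b"]))
  expect_equal(unname(rev$counts["better_b"]), unname(r$counts["better_a"]))
})
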