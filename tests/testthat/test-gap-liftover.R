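test_that("extract_gaps finds N-runs and clips flanks", {
  g <- extract_gaps(c(s = "ACGTNNNACGT"), flank = 1000)
  expect_equal(nrow(g), 1)
  expect_equal(c(g$old_start, g$old_end, g$n_length), c(4, 7, 3))
  expect_equal(c(g$lf_start, g$lf_end), c(0, 4))
  expect_true(g$flank_truncated)
  # N-run at position 0: empty left flank
  g2 <- extract_gaps(c(s = paste0("NNN", strrep("A", 20))))
  expect_equal(c(g2$lf_start, g2$lf_end), c(0, 0))
  # two gaps 500 bp apart truncate both inner flanks to 500 bp
  s3 <- paste0(strrep("A", 2000), "NN", strrep("C", 500), "NN", strrep("G", 2000))
  g3 <- extract_gaps(c(s = s3))
  expect_equal(g3$rf_end[1] - g3$rf_start[1], 500)
  expect_equal(g3$lf_end[2] - g3$lf_start[2], 500)
  expect_equal(g3$lf_end[1] - g3$lf_start[1], 1000)
})

test_that("flank placement agrees with a sliding-window Hamming oracle", {
  set.seed(41)
  genome <- Biostrings::DNAStringSet(c(chr1 = rand_dna(100000)))
  # verbatim unique flank
  q <- as.character(Biostrings::subseq(genome[[1]], 5001, 6000))
  hit <- darkmap:::.map_queries(list(q), genome, 31L, 2L)[[1]]
  expect_equal(hit$start, 5000)
  expect_equal(hit$mapq, 60)
  # flank occurring twice verbatim is ambiguous
  dup <- as.character(genome[[1]])
  substr(dup, 50001, 51000) <- q
  genome2 <- Biostrings::DNAStringSet(c(chr1 = dup))
  hit2 <- darkmap:::.map_queries(list(q), genome2, 31L, 2L)[[1]]
  expect_equal(hit2$mapq, 0)
  expect_true(hit2$multi_hit)
  # one substitution: cross-check position against brute-force Hamming scan
  q1 <- q
  substr(q1, 500, 500) <- setdiff(c("A", "C", "G", "T"), substr(q1, 500, 500))[1]
  hit3 <- darkmap:::.map_queries(list(q1), genome, 31L, 2L)[[1]]
  gs <- as.character(genome[[1]])
  mm <- vapply(seq_len(nchar(gs) - 1000 + 1), function(p)
    sum(charToRaw(substr(gs, p, p + 999)) != charToRaw(q1)), 0L)
  expect_equal(hit3$start, which.min(mm) - 1L)
  expect_equal(hit3$mismatches, min(mm))
})

test_that("gap classification applies the stated criteria strictly", {
  base <- data.frame(
    gap_id = "g", seqid = "old1", old_start = 100L, old_end = 200L,
    n_length = 100L, lf_start = 0L, lf_end = 100L, rf_start = 200L,
    rf_end = 300L, flank_truncated = FALSE,
    lp_seqid = "new1", lp_start = 1000L, lp_end = 2000L, lp_strand = "+",
    lp_mapq = 60L, lp_multi = FALSE,
    rp_seqid = "new1", rp_start = 7000L, rp_end = 8000L, rp_strand = "+",
    rp_mapq = 60L, rp_multi = FALSE, stringsAsFactors = FALSE)
  tweak <- function(...) {
    d <- base
    args <- list(...)
    for (k in names(args)) d[[k]] <- args[[k]]
    classify_gap(d, intervals(), min_mapq = 20, max_dist = 100000)$status
  }
  expect_equal(tweak(), "closed")
  expect_equal(tweak(lp_mapq = 20L), "unresolved")          # >20 is strict
  expect_equal(tweak(lp_mapq = 21L), "closed")
  expect_equal(tweak(rp_start = 2000L + 100000L, rp_end = 2000L + 101000L),
               "unresolved")                                # distance == 100 kb
  expect_equal(tweak(rp_start = 2000L + 99999L, rp_end = 2000L + 100999L),
               "closed")                                    # just under
  expect_equal(tweak(rp_start = 1970L, rp_end = 2970L), "artificial")  # 30 bp overlap
  expect_equal(tweak(rp_seqid = "new2"), "unresolved")
  expect_equal(tweak(rp_strand = "-"), "unresolved")
  # an N-run of the new assembly inside the span blocks closure
  d <- classify_gap(base, intervals("new1", 3000, 3100))
  expect_equal(d$status, "unresolved")
  # abutting flanks close with a zero-length fill
  z <- classify_gap(transform(base, rp_start = 2000L, rp_end = 3000L), intervals())
  expect_equal(z$status, "closed")
  expect_equal(z$fill_end - z$fill_start, 0L)
})

test_that("classification is symmetric under reverse-complementing the new assembly", {
  plan <- genome_plan(c(chr1 = 150000), seed = 51)
  g <- generate_genome(plan)
  gp <- data.frame(seqid = "chr1", position = c(30000, 70000, 110000),
                   replaced_length = c(400, 0, 250), n_length = 100,
                   overlap_length = c(0, 25, 0))
  d <- degrade_assembly(g$sequences, gp)
  gaps <- extract_gaps(d$old)
  fwd <- classify_gap(place_flanks(gaps, d$old, g$sequences),
                      assembly_gap_intervals(g$sequences))
  rc <- Biostrings::reverseComplement(g$sequences)
  names(rc) <- names(g$sequences)
  rev <- classify_gap(place_flanks(gaps, d$old, rc),
                      assembly_gap_intervals(rc))
  expect_equal(rev$status, fwd$status)
  expect_true(all(rev$lp_strand[!is.na(rev$lp_strand)] == "-"))
  expect_equal(fwd$fill_end - fwd$fill_start, rev$fill_end - rev$fill_start)
})

test_that("fill profiles match direct base counting", {
  plan <- genome_plan(c(chr1 = 60000), seed = 61, features = list(
    feat_gc_extreme("chr1", 30000, 30400, gc = 1.0)))
  g <- generate_genome(plan)
  gp <- data.frame(seqid = "chr1", position = 30000, replaced_length = 400,
                   n_length = 100, overlap_length = 0)
  d <- degrade_assembly(g$sequences, gp)
  gaps <- classify_gap(place_flanks(extract_gaps(d$old), d$old, g$sequences),
                       assembly_gap_intervals(g$sequences))
  reps <- intervals("chr1", 30100, 30200)
  fp <- fill_profile(gaps, g$sequences, reps)
  expect_equal(fp$fill_length, 400)
  expect_equal(fp$gc, 1.0)
  expect_equal(fp$repeat_fraction, 0.25)
})

test_that("liftover summaries conserve the total gap count", {
  gaps <- data.frame(gap_id = paste0("g", 1:5),
                     seqid = c("chr1", "chr1", "chrUn_1", "chr2", "chrUn_2"),
                     status = c("closed", "closed", "artificial", "closed",
                                "unresolved"))
  s <- liftover_summary(gaps)
  expect_equal(s$total[s$class == "total"], 5)
  expect_equal(s$closed[s$class == "placed"], 3)
  expect_equal(s$artificial[s$class == "unplaced"], 1)
  expect_equal(sum(s[s$class == "total", c("closed", "artificial", "unresolved")]),
               5)
  empty <- liftover_summary(gaps[0, ])
  expect_equal(empty$total[empty$class == "total"], 0)
})
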