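tx <- function(id = "t1", gene = "g1", exons, strand = "+", cds = NULL,
               orf = 0, blast = NA_real_, pseudo = FALSE) {
  transcript_model(id, gene, "chr1", strand,
                   data.frame(start = exons[, 1], end = exons[, 2]),
                   cds = cds, longest_orf_aa = orf,
                   blast_cover_fraction = blast, pseudogene = pseudo)
}

test_that("functional overlap flags fills by >=1 bp feature overlap", {
  fills <- intervals("chr1", c(0, 1000, 2000), c(500, 1500, 2500))
  feats <- list(exon = intervals("chr1", 100, 200),
                atac_peak = intervals("chr1", 1499, 1600))
  r <- functional_overlap(fills, feats)
  expect_equal(r$flags$exon, c(TRUE, FALSE, FALSE))
  expect_equal(r$flags$atac_peak, c(FALSE, TRUE, FALSE))  # 1 bp shared
  expect_equal(unname(r$class_counts["exon"]), 1L)
  expect_equal(sum(r$flags$any_class), 2)
  none <- functional_overlap(fills, list(mirna = intervals("chr2", 0, 100)))
  expect_equal(sum(none$flags$mirna), 0)
})

test_that("novel-gene criteria: 80% body coverage is inclusive, booleans veto", {
  fills <- intervals("chr1", 0, 800)
  genes <- data.frame(gene_id = c("a", "b", "c", "d"),
                      seqid = "chr1", start = 0L,
                      end = c(1000L, 1000L, 1000L, 1013L),
                      pseudogene = c(FALSE, TRUE, FALSE, FALSE),
                      in_unplaced = FALSE,
                      homolog_elsewhere = c(FALSE, FALSE, TRUE, FALSE))
  r <- novel_gene_candidates(genes, fills)
  expect_equal(r$body_fraction[1], 0.80)
  expect_true(r$candidate[1])                 # exactly 80% passes
  expect_false(r$candidate[2])                # pseudogene
  expect_false(r$candidate[3])                # homolog elsewhere
  expect_false(r$crit1_body[4])               # 800/1013 = 79% fails
})

test_that("find_orfs hits the 100 aa boundary and needs ATG and stop", {
  s <- paste0("ATG", strrep("GCT", 99), "TAA")
  o <- find_orfs(s)
  expect_equal(o$aa_length, 100)
  expect_equal(o$frame, 0)
  expect_equal(o$end - o$start, 303)
  expect_equal(find_orfs(strrep("GCT", 100))$aa_length, 0)
  expect_equal(find_orfs(paste0("ATG", strrep("GCT", 50)))$aa_length, 0)
  expect_equal(find_orfs(paste0("ATG", strrep("GCT", 50)),
                         require_stop = FALSE)$aa_length, 51)
})

test_that("find_orfs equals the brute-force frame scan on random sequences", {
  set.seed(71)
  for (rep in 1:60) {
    s <- rand_dna(sample(60:400, 1), gc = 0.5)
    expect_equal(find_orfs(s)$aa_length, oracle_orf(s), info = s)
  }
})

test_that("lncRNA classification applies all four conditions", {
  ex2 <- cbind(c(0, 500), c(150, 650))     # 2 exons, 300 nt spliced
  coding <- intervals("chr1", 10000, 11000, strand = "+")
  expect_true(classify_lncrna(tx(exons = ex2, orf = 99), coding))
  expect_false(classify_lncrna(tx(exons = cbind(0, 300), orf = 0), coding))
  ex200 <- cbind(c(0, 500), c(100, 600))   # exactly 200 nt spliced
  expect_false(classify_lncrna(tx(exons = ex200, orf = 0), coding))
  expect_false(classify_lncrna(tx(exons = ex2, orf = 100), coding))
  same_strand <- intervals("chr1", 100, 120, strand = "+")
  opp_strand <- intervals("chr1", 100, 120, strand = "-")
  expect_false(classify_lncrna(tx(exons = ex2, orf = 50), same_strand))
  expect_true(classify_lncrna(tx(exons = ex2, orf = 50), opp_strand))
})

test_that("lncRNA and coding calls are mutually exclusive at the boundary", {
  coding <- intervals("chr2", 0, 1, strand = "+")
  for (orf in c(98, 99, 100, 101, 150)) {
    t1 <- tx(exons = cbind(c(0, 500), c(150, 650)), orf = orf)
    is_coding <- orf >= 100
    expect_equal(classify_lncrna(t1, coding), !is_coding)
  }
})

test_that("transcript filter rules remove what the criteria describe", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    rand_dna(30000), strrep("A", 30), rand_dna(5000))))
  long_single <- tx("t_long", "g1", cbind(0, 12000))
  short_single <- tx("t_short", "g2", cbind(0, 1000))
  polya <- tx("t_polya", "g3", cbind(c(29000, 29500), c(29200, 30000)))
  clean2 <- tx("t_clean", "g4", cbind(c(100, 600), c(400, 1100)))
  # gene g5: a high scorer plus a member with 3 exons past the stop
  hi <- tx("t_hi", "g5", cbind(c(0, 1000), c(600, 1600)),
           cds = c(0, 1500), blast = 0.9)
  bad_stop <- tx("t_stop", "g5",
                 cbind(c(0, 1000, 2000, 3000, 4000),
                       c(600, 1600, 2100, 3100, 4100)),
                 cds = c(0, 1500), blast = 0.9)
  bad_blast <- tx("t_blast", "g5", cbind(c(0, 1000), c(600, 1600)),
                  cds = c(0, 1500), blast = 0.3)
  r <- filter_transcripts(list(long_single, short_single, polya, clean2,
                               hi, bad_stop, bad_blast), genome)
  kept <- vapply(r$retained, `[[`, "", "transcript_id")
  expect_setequal(kept, c("t_short", "t_clean", "t_hi"))
  expect_equal(r$log$rule[r$log$transcript_id == "t_long"], "single_exon_long")
  expect_equal(r$log$rule[r$log$transcript_id == "t_polya"], "polyA")
  expect_equal(sort(r$log$transcript_id[r$log$rule == "stop_exons_or_blast"]),
               c("t_blast", "t_stop"))
  expect_warning(filter_transcripts(list(short_single)), "polyA")
})

test_that("rule 3 never removes the last transcript of a gene", {
  # a lone low-blast transcript survives because no high scorer remains
  lone <- tx("t_lone", "g9", cbind(c(0, 1000), c(600, 1600)),
             cds = c(0, 1500), blast = 0.2)
  r <- filter_transcripts(list(lone), genome = NULL) |> suppressWarnings()
  expect_equal(length(r$retained), 1)
})
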