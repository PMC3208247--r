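test_that("PWM construction validates columns and files parse", {
  expect_error(pwm("bad", matrix(0.3, 4, 6)), "sum to 1")
  jas <- tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001.1 TESTTF",
    "A [ 10  0  0 10 ]",
    "C [  0 10  0  0 ]",
    "G [  0  0 10  0 ]",
    "T [  0  0  0  0 ]"), jas)
  ps <- read_pwms(jas)
  expect_named(ps, "TESTTF")
  expect_equal(ncol(ps$TESTTF$probs), 4)
  expect_equal(unname(ps$TESTTF$probs[, 1]), c(1, 0, 0, 0))
  expect_equal(unname(ps$TESTTF$probs[, 4]), c(1, 0, 0, 0))

  meme <- tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF M1 other_name",
    "letter-probability matrix: alength= 4 w= 4 nsites= 20 E= 0",
    " 0.25 0.25 0.25 0.25",
    " 1.00 0.00 0.00 0.00",
    " 0.00 0.50 0.50 0.00",
    " 0.00 0.00 0.00 1.00"), meme)
  pm <- read_pwms(meme)
  expect_named(pm, "M1")
  expect_equal(unname(pm$M1$probs[, 2]), c(1, 0, 0, 0))
})

test_that("consensus scanning finds embedded sites on both strands", {
  w <- consensus_pwm("ACGTAC")
  seqq <- paste0("TTTTT", "ACGTAC", "TTTTTTTT")
  expect_equal(scan_pwm(seqq, w, 0)$hits, 1)
  # the reverse complement of the site on the other strand
  rc <- paste0("GGGGG", "GTACGT", "GGGG")
  expect_equal(scan_pwm(rc, w, 0)$hits, 1)
  expect_equal(scan_pwm(rc, w, 0, both_strands = FALSE)$hits, 0)
  # all-background PWM scores every window exactly 0
  flat <- pwm("flat", matrix(0.25, 4, 5))
  res <- scan_pwm("ACGTACGTACGT", flat, 0)
  expect_equal(res$hits, res$n_windows)
  expect_equal(scan_pwm("ACGTACGTACGT", flat, 1e-9)$hits, 0)
  # windows containing N are skipped; motif longer than sequence -> 0 hits
  expect_equal(scan_pwm("ACNTAC", w, 0)$n_windows, 0)
  expect_equal(scan_pwm("ACG", w, 0)$hits, 0)
})

test_that("hit counts equal the exhaustive per-window rescoring oracle", {
  set.seed(55)
  for (i in 1:8) {
    seqq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    probs <- matrix(rgamma(4 * 7, 1), nrow = 4)
    probs <- sweep(probs, 2, colSums(probs), "/")
    w <- pwm("rand", probs)
    thr <- pwm_score_threshold(w, 0.5)
    got <- scan_pwm(seqq, w, thr)
    want <- scan_oracle_one_strand(seqq, w, thr) +
      scan_oracle_one_strand(revcomp_chr(seqq), w, thr)
    expect_equal(got$hits, want)
    # reverse-complementing the input leaves both-strand counts unchanged
    expect_equal(scan_pwm(revcomp_chr(seqq), w, thr)$hits, got$hits)
  }
})

test_that("promoter extraction slices -300/+100 windows strand-awarely", {
  fa <- toy_fasta()
  tr <- data.frame(
    transcript_id = c("tp.1", "tm.1"), gene = c("GP", "GM"),
    chrom = "ctgA", strand = c("+", "-"), coding = TRUE)
  ex <- rbind(
    data.frame(transcript_id = "tp.1", start = c(1000, 1400),
               end = c(1100, 1500)),
    data.frame(transcript_id = "tm.1", start = c(300, 700), end = c(400, 800)))
  models <- gene_model_set(tr, ex)
  pr <- extract_promoters(models, fa$path)
  p_plus <- pr[pr$gene == "GP", ]
  # + strand, tss 1000: genomic [700, 1100) -> 1-based substring 701..1100
  expect_equal(p_plus$start, 700); expect_equal(p_plus$end, 1100)
  expect_identical(p_plus$seq, unname(substr(fa$seqs["ctgA"], 701, 1100)))
  expect_equal(nchar(p_plus$seq), 400)
  # - strand, tss 799: genomic [700, 1100) reverse-complemented
  p_minus <- pr[pr$gene == "GM", ]
  expect_identical(p_minus$seq,
                   unname(revcomp_chr(substr(fa$seqs["ctgA"], 701, 1100))))
  expect_false(any(pr$truncated))
  # a TSS near the contig start yields a truncated, flagged window
  tr2 <- data.frame(transcript_id = "t0.1", gene = "G0", chrom = "ctgB",
                    strand = "+", coding = TRUE)
  ex2 <- data.frame(transcript_id = "t0.1", start = 100, end = 200)
  m2 <- gene_model_set(tr2, ex2)
  p0 <- extract_promoters(m2, fa$path)
  expect_true(p0$truncated)
  expect_equal(nchar(p0$seq), 200)
})

test_that("a mirrored minus-strand gene has the reverse-complement promoter", {
  fa <- toy_fasta()
  L <- 2000
  # mirror the + strand gene through the contig so the sequence context of
  # the mirrored TSS on the reverse strand of the reversed contig matches
  tr <- data.frame(transcript_id = "tp.1", gene = "GP", chrom = "ctgA",
                   strand = "+", coding = TRUE)
  ex <- data.frame(transcript_id = "tp.1", start = 1000, end = 1100)
  m_plus <- gene_model_set(tr, ex)
  tr$strand <- "-"
  ex_m <- data.frame(transcript_id = "tp.1", start = L - 1100, end = L - 1000)
  m_minus <- gene_model_set(tr, ex_m)
  genome_fwd <- Biostrings::DNAStringSet(c(ctgA = fa$seqs[["ctgA"]]))
  genome_rev <- Biostrings::DNAStringSet(
    c(ctgA = revcomp_chr(fa$seqs[["ctgA"]])))
  p1 <- extract_promoters(m_plus, genome_fwd)
  p2 <- extract_promoters(m_minus, genome_rev)
  expect_identical(p1$seq, p2$seq)
})

test_that("Fisher enrichment matches the hypergeometric tail-sum oracle", {
  hyper_tail <- function(fg_hits, fg_total, bg_hits, bg_total) {
    k <- fg_hits + bg_hits
    sum(dhyper(fg_hits:min(fg_total, k), fg_total, bg_total, k))
  }
  for (fg_total in c(3, 5, 10)) for (bg_total in c(4, 8, 12))
    for (fg_hits in 0:fg_total) for (bg_hits in c(0, 1, bg_total %/% 2,
                                                  bg_total)) {
      tab <- matrix(c(fg_hits, fg_total - fg_hits,
                      bg_hits, bg_total - bg_hits), nrow = 2)
      p_fisher <- fisher.test(tab, alternative = "greater")$p.value
      expect_equal(p_fisher, hyper_tail(fg_hits, fg_total, bg_hits, bg_total),
                   tolerance = 1e-12)
    }
})

test_that("motif enrichment flags planted foreground motifs", {
  set.seed(66)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
  cons <- "ACGTACGTAC"
  mk_set <- function(genes, planted) {
    data.frame(gene = genes, tss_group = paste0(genes, "_tss1"),
               chrom = "c", strand = "+", start = 0, end = 400,
               truncated = FALSE,
               seq = vapply(seq_along(genes), function(i) {
                 s <- rand_seq(400)
                 if (planted) paste0(substr(s, 1, 100), cons,
                                     substr(s, 111, 400)) else s
               }, character(1)), stringsAsFactors = FALSE)
  }
  fg <- mk_set(sprintf("f%02d", 1:10), TRUE)
  bg <- mk_set(sprintf("b%02d", 1:20), FALSE)
  pwms <- list(consensus_pwm(cons, "PLANTED"),
               consensus_pwm("GGGGGGCCCCCC", "DECOY"))
  enr <- motif_enrichment(fg, bg, pwms)
  expect_equal(enr$fg_hits[enr$motif == "PLANTED"], 10)
  expect_lt(enr$q[enr$motif == "PLANTED"], 1e-4)
  expect_gt(enr$q[enr$motif == "DECOY"], 0.5)
  # q-values do not depend on motif order
  enr_rev <- motif_enrichment(fg, bg, rev(pwms))
  expect_equal(enr$q[order(enr$motif)], enr_rev$q[order(enr_rev$motif)])
  # disjointness guard
  expect_error(motif_enrichment(fg, fg, pwms), "disjoint")
  # a motif with no hits anywhere has p = 1
  none <- motif_enrichment(fg, bg, list(consensus_pwm("TTTTTTTTTTTTTTTT",
                                                      "ABSENT")))
  expect_equal(none$p, 1)
})

test_that("enriched motifs are crossed with TF differential expression", {
  set.seed(77)
  sheet <- data.frame(sample_id = sprintf("s%d", 1:20),
                      group = rep(c("normal", "cancer_MSS"), each = 10),
                      patient_id = NA_character_)
  v <- rbind(TFUP = c(rnorm(10, 8, 0.2), rnorm(10, 10, 0.2)),
             TFFLAT = rnorm(20, 8, 0.2))
  colnames(v) <- sheet$sample_id
  gene_m <- structure(list(values = v, summarizer = "mean"),
                      class = "GeneExpressionMatrix")
  enriched <- data.frame(motif = c("M_UP", "M_FLAT", "M_NOq"),
                         fg_hits = c(9, 9, 1), fg_total = 10,
                         bg_hits = c(1, 1, 9), bg_total = 10,
                         odds_ratio = c(81, 81, 0.01),
                         p = c(1e-4, 1e-4, 0.9), q = c(3e-4, 3e-4, 0.9))
  tf_map <- c(M_UP = "TFUP", M_FLAT = "TFFLAT", M_NOq = "TFUP")
  hits <- cross_with_expression(enriched, gene_m, sheet, tf_map)
  expect_equal(hits$motif, "M_UP")
  expect_equal(hits$tf_gene, "TFUP")
  expect_equal(hits$direction, "up")
  # nothing enriched -> empty result
  none <- cross_with_expression(enriched[enriched$q > 0.5, ], gene_m,
                                sheet, tf_map)
  expect_equal(nrow(none), 0)
})
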