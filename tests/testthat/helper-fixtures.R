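# Fixtures built in code: toy gene models, a six-probe-set two-isoform gene,
# and small expression matrices used across the unit tests.

# Five genes: gA (2 TSSs, coding), gB (2 transcripts, same TSS), gC (2 TSSs,
# noncoding only), gD (single transcript), gE (2 TSSs 1 bp apart, coding).
toy_models <- function() {
  tr <- data.frame(
    transcript_id = c("gA.1", "gA.2", "gB.1", "gB.2", "gC.1", "gC.2",
                      "gD.1", "gE.1", "gE.2"),
    gene = c("gA", "gA", "gB", "gB", "gC", "gC", "gD", "gE", "gE"),
    chrom = "chr1",
    strand = c("+", "+", "+", "+", "-", "-", "+", "-", "-"),
    coding = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  ex <- rbind(
    data.frame(transcript_id = "gA.1", start = c(100, 500), end = c(200, 700)),
    data.frame(transcript_id = "gA.2", start = c(300, 500), end = c(400, 700)),
    data.frame(transcript_id = "gB.1", start = c(1000, 1500), end = c(1100, 1600)),
    data.frame(transcript_id = "gB.2", start = c(1000, 1300), end = c(1100, 1400)),
    data.frame(transcript_id = "gC.1", start = c(2000, 2500), end = c(2100, 2600)),
    data.frame(transcript_id = "gC.2", start = c(2000, 2300), end = c(2100, 2400)),
    data.frame(transcript_id = "gD.1", start = 3000, end = 3100),
    data.frame(transcript_id = "gE.1", start = c(4000, 4500), end = c(4100, 4600)),
    data.frame(transcript_id = "gE.2", start = c(4000, 4500), end = c(4100, 4601)))
  gene_model_set(tr, ex)
}

# One gene, two isoforms sharing three downstream exons; six probe sets:
# ps1, ps2 unique to the long (upstream-TSS) isoform, ps3 unique to the
# short isoform's own first exon, ps4-ps6 on the shared exons.
toy_gene6 <- function(strand = "+") {
  ex_long_uniq <- data.frame(start = c(100, 300), end = c(200, 400))
  ex_short_uniq <- data.frame(start = 500, end = 600)
  ex_shared <- data.frame(start = c(700, 900, 1100), end = c(800, 1000, 1200))
  tr <- data.frame(
    transcript_id = c("G.long", "G.short"), gene = "G", chrom = "chr1",
    strand = strand, coding = TRUE, stringsAsFactors = FALSE)
  ex <- rbind(
    cbind(transcript_id = "G.long", rbind(ex_long_uniq, ex_shared)),
    cbind(transcript_id = "G.short", rbind(ex_short_uniq, ex_shared)))
  if (strand == "-") {          # mirror through 1300 so TSS order flips
    new_start <- 1300 - ex$end
    ex$end <- 1300 - ex$start
    ex$start <- new_start
  }
  models <- gene_model_set(tr, ex)
  ps <- data.frame(
    probeset_id = paste0("ps", 1:6), chrom = "chr1",
    start = c(120, 320, 520, 720, 920, 1120),
    end = c(180, 380, 580, 780, 980, 1180),
    tier = c("extended", "extended", "extended", "core", "core", "core"),
    gene = "G", stringsAsFactors = FALSE)
  if (strand == "-") {
    new_start <- 1300 - ps$end
    ps$end <- 1300 - ps$start
    ps$start <- new_start
  }
  list(models = models, probesets = ps)
}

# Expression matrix over the six probe sets of toy_gene6 with given per-sample
# group labels; values supplied as a 6 x n matrix of log2 intensities.
toy_expr6 <- function(values, groups) {
  n <- length(groups)
  stopifnot(ncol(values) == n)
  ids <- sprintf("s%02d", seq_len(n))
  dimnames(values) <- list(paste0("ps", 1:6), ids)
  list(m = expression_matrix(values, transformed = TRUE),
       sheet = data.frame(sample_id = ids, group = groups,
                          patient_id = NA_character_,
                          stringsAsFactors = FALSE))
}

# small simulation for pipeline-level tests; any simulation_config argument
# can be overridden
small_sim_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 1, n_genes = 80, n_normal = 10, n_adenoma = 10,
         n_cancer = 10, n_cancer_msi = 2, n_pairs = 6),
    list(...))
  do.call(simulation_config, args)
}

# PWM with probability-1 columns spelling a consensus sequence
consensus_pwm <- function(seq, name = "CONS") {
  bases <- strsplit(seq, "")[[1]]
  probs <- vapply(bases, function(b) as.numeric(c("A", "C", "G", "T") == b),
                  numeric(4))
  pwm(name, probs)
}

# deterministic 2-contig FASTA written to a temp file; returns list(path, seqs)
toy_fasta <- function() {
  set.seed(404)
  s1 <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
              collapse = "")
  s2 <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
              collapse = "")
  path <- tempfile(fileext = ".fa")
  writeLines(c(">ctgA extra description", s1, ">ctgB", s2), path)
  list(path = path, seqs = c(ctgA = s1, ctgB = s2))
}

# independent two-way ANOVA oracle: partial F for the group:probeset
# interaction via QR-based lm fits
anova_oracle <- function(Y, tumor) {
  df <- data.frame(y = as.vector(Y),
                   p = factor(rep(seq_len(nrow(Y)), ncol(Y))),
                   g = factor(rep(tumor, each = nrow(Y))))
  full <- stats::lm(y ~ g * p, df)
  red <- stats::lm(y ~ g + p, df)
  a <- stats::anova(red, full)
  list(F = a$F[2], p = a$`Pr(>F)`[2])
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, seq_along(p))       # stable in p
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# closed-form equal-variance two-sample t
t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  t <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# exhaustive per-window PWM rescoring (forward strand of the given sequence)
scan_oracle_one_strand <- function(seq, x, thr) {
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- ncol(x$probs)
  n <- length(chars)
  hits <- 0L
  if (n < L) return(hits)
  for (i in seq_len(n - L + 1)) {
    w <- chars[i:(i + L - 1)]
    if (any(!w %in% c("A", "C", "G", "T"))) next
    sc <- sum(vapply(seq_len(L), function(j)
      log2(x$probs[w[j], j] / x$background[match(w[j], c("A", "C", "G", "T"))]),
      numeric(1)))
    if (sc >= thr) hits <- hits + 1L
  }
  hits
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
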