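si_from_values <- function(values, groups, tier = NULL) {
  g6 <- toy_gene6()
  ann <- annotate_probesets(g6$models, g6$probesets)
  te <- toy_expr6(values, groups)
  gm <- summarize_gene(te$m, ann, tier_filter = c("core", "extended"))
  list(si = splicing_index(te$m, gm, ann), sheet = te$sheet, ann = ann,
       m = te$m, gene_m = gm)
}

test_that("splicing index is probe minus gene and mean-centers per sample", {
  v <- matrix(c(5, 6, 7, 6, 6, 6), ncol = 1)
  x <- si_from_values(v, "normal")
  expect_equal(unname(x$si$values[, 1]),
               v[, 1] - mean(v[, 1]))
  expect_lt(abs(sum(x$si$values[, 1])), 1e-9)
  # probe 7.5, gene 6.0 -> SI 1.5
  gm <- list(values = matrix(6, 1, 1, dimnames = list("G", "s1")))
  class(gm) <- "GeneExpressionMatrix"
  m <- expression_matrix(matrix(7.5, 1, 1, dimnames = list("ps1", "s1")),
                         transformed = TRUE)
  ann1 <- data.frame(probeset_id = "ps1", gene = "G", tier = "core",
                     cls = "shared", tss_group = NA)
  expect_equal(unname(splicing_index(m, gm, ann1)$values[1, 1]), 1.5)
})

test_that("splicing ANOVA matches the lm partial-F oracle on random instances", {
  set.seed(202)
  for (rep in 1:100) {
    P <- sample(2:5, 1)
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    Y <- matrix(rnorm(P * (n1 + n2)), nrow = P)
    tumor <- c(rep(FALSE, n1), rep(TRUE, n2))
    got <- alttss:::.interaction_F(Y, tumor)
    want <- anova_oracle(Y, tumor)
    expect_equal(got$F, want$F, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    expect_equal(got$df1, P - 1)
    expect_equal(got$df2, (n1 + n2) * P - 2 * P)
  }
})

test_that("a hand-built pure interaction gives the expected sums of squares", {
  # 2 probe sets x (3+3) samples; +1 interaction on probe set 2 in tumor,
  # residuals placed by hand so every SS term is computable on paper
  Y <- rbind(c(0.1, -0.1, 0.0, 0.1, -0.1, 0.0),
             c(0.1, -0.1, 0.0, 1.1, 0.9, 1.0))
  tumor <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  # cell means: p1 (0,0), p2 (0,1); interaction SS = sum n (m_gp - mg - mp + m)^2
  # = 3*(0.25+0.25+0.25+0.25)*... grand = 0.25, mg = (0, 0.5), mp = (0, 0.5)
  # p1: normal 0-0+(-0.25)... each deviation is +-0.25 -> SS = 12*3*... = 0.75
  ss_int_hand <- 3 * ((0 - 0 - 0 + 0.25)^2 + (0 - 0.5 - 0 + 0.25)^2 +
                      (0 - 0 - 0.5 + 0.25)^2 + (1 - 0.5 - 0.5 + 0.25)^2)
  rss_hand <- sum(c(0.1, -0.1, 0, 0.1, -0.1, 0, 0.1, -0.1, 0, 0.1, -0.1, 0)^2)
  F_hand <- (ss_int_hand / 1) / (rss_hand / (6 * 2 - 4))
  got <- alttss:::.interaction_F(Y, tumor)
  expect_equal(got$F, F_hand, tolerance = 1e-10)
  expect_equal(got$p, pf(F_hand, 1, 8, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("degenerate inputs follow the no-interaction and no-noise conventions", {
  tumor <- c(FALSE, FALSE, TRUE, TRUE)
  # identical constant profiles per probe set in both groups: no interaction
  Y0 <- rbind(rep(1, 4), rep(2, 4))
  got <- alttss:::.interaction_F(Y0, tumor)
  expect_equal(got$F, 0)
  expect_equal(got$p, 1)
  expect_false(got$degenerate)
  # pure interaction without noise: p = 0 with the degeneracy flag
  Y1 <- rbind(c(0, 0, 0, 0), c(0, 0, 1, 1))
  got <- alttss:::.interaction_F(Y1, tumor)
  expect_equal(got$p, 0)
  expect_true(got$degenerate)
})

test_that("per-sample constants are absorbed before the ANOVA", {
  # a per-sample shift of all probe-level values (an array scaling effect)
  # cancels in the splicing index, so F is unchanged; and group-level
  # constants are absorbed by the group main effect within the ANOVA itself
  set.seed(7)
  groups <- rep(c("normal", "cancer_MSS"), each = 5)
  v <- matrix(rnorm(60, 8, 0.5), nrow = 6)
  x1 <- si_from_values(v, groups)
  shift <- matrix(rnorm(10, 0, 5), nrow = 6, ncol = 10, byrow = TRUE)
  x2 <- si_from_values(v + shift, groups)
  f1 <- splicing_anova(x1$si, x1$sheet)
  f2 <- splicing_anova(x2$si, x2$sheet)
  expect_equal(f1$F, f2$F, tolerance = 1e-8)

  Y <- matrix(rnorm(4 * 10), nrow = 4)
  tumor <- rep(c(FALSE, TRUE), each = 5)
  gshift <- matrix(rep(ifelse(tumor, 3, -1), each = 4), nrow = 4)
  expect_equal(alttss:::.interaction_F(Y, tumor)$F,
               alttss:::.interaction_F(Y + gshift, tumor)$F,
               tolerance = 1e-8)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # idempotent on already-adjusted monotone inputs
  q <- bh_adjust(runif(20))
  expect_true(all(bh_adjust(sort(q)) >= sort(q) - 1e-12))
  expect_true(all(bh_adjust(p <- runif(30)) >= p))
})

test_that("the filter cascade stages match hand evaluation and are monotone", {
  tab <- data.frame(
    gene = paste0("g", 1:10),
    q = c(0.2, 0.04, 1e-8, 1e-8, 1e-7, 0.5, 1e-9, 0.049, 1, 2e-7),
    max_abs_delta_si = c(2, 2, 0.4, 0.6, 0.51, 3, 0.5, 0.2, 1, 0.7))
  calls <- filter_cascade(tab, detection_config())
  expect_identical(calls$stage,
                   c("filtered_out", "discovery", "discovery", "stringent",
                     "stringent", "filtered_out", "discovery", "discovery",
                     "filtered_out", "stringent"))
  expect_true(all(calls$cls == "NONE"))
  # loosening stringent_q or shrinking si_threshold only grows the set
  base <- calls$gene[calls$stage == "stringent"]
  calls2 <- filter_cascade(tab, detection_config(stringent_q = 0.05,
                                                 si_threshold = 0.3))
  expect_true(all(base %in% calls2$gene[calls2$stage == "stringent"]))
})

test_that("positional classification separates ALT_TSS from cassette events", {
  groups <- rep(c("normal", "cancer_MSS"), each = 4)
  base <- matrix(8, nrow = 6, ncol = 8)
  set.seed(5)
  jit <- matrix(rnorm(48, 0, 0.03), nrow = 6)
  # ALT_TSS pattern: short-isoform first exon (ps3) up in tumor
  v <- base + jit; v[3, 5:8] <- v[3, 5:8] + 2
  x <- si_from_values(v, groups)
  res <- test_splicing(x$si, x$sheet)
  calls <- classify_alt_tss(filter_cascade(res), res, x$ann)
  expect_identical(calls$cls, "ALT_TSS")
  expect_identical(calls$tumor_preferred_tss, "G_tss2")
  expect_identical(calls$stage, "classified")

  # same signal on a shared exon (ps5): not an alternative TSS
  v2 <- base + jit; v2[5, 5:8] <- v2[5, 5:8] + 2
  x2 <- si_from_values(v2, groups)
  res2 <- test_splicing(x2$si, x2$sheet)
  calls2 <- classify_alt_tss(filter_cascade(res2), res2, x2$ann)
  expect_identical(calls2$cls, "AMBIGUOUS")

  # cassette exon: relabel ps3 as internal_unique and shift it
  x3 <- si_from_values(v, groups)
  ann3 <- x3$ann
  ann3$cls[ann3$probeset_id == "ps3"] <- "internal_unique"
  ann3$tss_group[ann3$probeset_id == "ps3"] <- NA
  res3 <- test_splicing(x3$si, x3$sheet)
  calls3 <- classify_alt_tss(filter_cascade(res3), res3, ann3)
  expect_identical(calls3$cls, "ALT_SPLICING")
})

test_that("validation requires significance and a consistent direction", {
  groups <- rep(c("normal", "cancer_MSS"), each = 6)
  base <- matrix(8, nrow = 6, ncol = 12)
  set.seed(9)
  mk <- function(shift) {
    v <- base + matrix(rnorm(72, 0, 0.05), nrow = 6)
    v[3, 7:12] <- v[3, 7:12] + shift
    si_from_values(v, groups)
  }
  x <- mk(2)
  res <- test_splicing(x$si, x$sheet)
  calls <- classify_alt_tss(filter_cascade(res), res, x$ann)
  expect_identical(calls$cls, "ALT_TSS")

  conf <- validate_candidates(calls, list(si = mk(2)$si, sheet = x$sheet),
                              x$ann)
  expect_true(conf$confirmed)
  flip <- validate_candidates(calls, list(si = mk(-2)$si, sheet = x$sheet),
                              x$ann)
  expect_false(flip$confirmed)
  expect_match(flip$reason, "flipped")
  # at-least-one rule across two cohorts
  both <- validate_candidates(
    calls, list(list(si = mk(-2)$si, sheet = x$sheet),
                list(si = mk(2)$si, sheet = x$sheet)), x$ann)
  expect_true(both$confirmed)
  # absent gene
  other <- mk(2)$si
  rownames(other$values) <- paste0("zz", 1:6)
  names(other$gene) <- paste0("zz", 1:6)
  other$gene[] <- "OTHER"
  miss <- validate_candidates(calls, list(si = other, sheet = x$sheet), x$ann)
  expect_false(miss$confirmed)
  expect_identical(miss$reason, "not measured")
})
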