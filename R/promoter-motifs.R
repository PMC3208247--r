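#' Position weight matrix
#'
#' @param name motif name.
#' @param probs 4 x L numeric matrix of base probabilities, rows in A, C, G,
#'   T order; every column must sum to 1.
#' @param background base-frequency 4-vector (default uniform).
#' @return A `PWM` object.
#' @export
pwm <- function(name, probs, background = rep(0.25, 4)) {
  stopifnot(is.matrix(probs), nrow(probs) == 4, ncol(probs) >= 4,
            length(background) == 4)
  if (any(abs(colSums(probs) - 1) > 1e-9))
    stop("every PWM column must sum to 1")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background frequencies must sum to 1")
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(name = name, probs = probs, background = background),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM %s (length %d), consensus %s\n", x$name, ncol(x$probs),
              paste(rownames(x$probs)[apply(x$probs, 2, which.max)],
                    collapse = "")))
  invisible(x)
}

#' Read PWMs from a JASPAR or MEME minimal file
#'
#' JASPAR: records of a `>ID name` header followed by four lines
#' `A [ n n ... ]` etc.; counts are converted to probabilities with an
#' optional per-cell pseudocount. MEME minimal: `MOTIF` blocks with a
#' `letter-probability matrix` section (rows = positions, columns A C G T).
#'
#' @param path file path.
#' @param format `"auto"` (sniffed), `"jaspar"` or `"meme"`.
#' @param pseudocount added to each JASPAR count before normalization
#'   (default 0).
#' @param background base-frequency 4-vector used for scanning.
#' @return list of [pwm()] objects.
#' @export
read_pwms <- function(path, format = c("auto", "jaspar", "meme"),
                      pseudocount = 0, background = rep(0.25, 4)) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto")
    format <- if (any(grepl("^MEME version", lines))) "meme" else "jaspar"
  if (format == "jaspar")
    .read_jaspar(lines, pseudocount, background)
  else
    .read_meme(lines, background)
}

.read_jaspar <- function(lines, pseudocount, background) {
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no JASPAR records found")
  out <- lapply(seq_along(heads), function(i) {
    h <- heads[i]
    nm <- sub("^>\\s*", "", lines[h])
    nm <- strsplit(nm, "\\s+")[[1]]
    nm <- nm[length(nm)]                       # prefer the name over the id
    rows <- lines[(h + 1):(h + 4)]
    counts <- do.call(rbind, lapply(rows, function(r) {
      num <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(num), "\\s+")[[1]])
    }))
    counts <- counts + pseudocount
    pwm(nm, sweep(counts, 2, colSums(counts), "/"), background)
  })
  stats::setNames(out, vapply(out, function(p) p$name, character(1)))
}

.read_meme <- function(lines, background) {
  starts <- grep("^MOTIF", lines)
  if (length(starts) == 0) stop("no MOTIF blocks found")
  out <- lapply(starts, function(s) {
    nm <- strsplit(trimws(sub("^MOTIF", "", lines[s])), "\\s+")[[1]][1]
    hdr <- grep("letter-probability matrix", lines)
    hdr <- min(hdr[hdr > s])
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    probs <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    pwm(nm, t(probs), background)
  })
  stats::setNames(out, vapply(out, function(p) p$name, character(1)))
}

#' Default log-odds threshold for a PWM
#'
#' A fraction (default 80%) of the motif's maximum attainable log2-odds
#' score.
#'
#' @param x a [pwm()].
#' @param frac fraction of the maximum score.
#' @return Scalar threshold.
#' @export
pwm_score_threshold <- function(x, frac = 0.8) {
  s <- log2(x$probs / x$background)
  frac * sum(apply(s, 2, max))
}

.encode_dna <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  m <- match(chars, c("A", "C", "G", "T"))   # N and anything else -> NA
  m
}

#' Scan a sequence with a PWM
#'
#' Slides the motif over both strands and counts windows whose summed
#' log2(prob/background) score reaches `score_threshold`. Windows containing
#' N (or any non-ACGT base) are skipped.
#'
#' @param seq character string or `DNAString`.
#' @param x a [pwm()].
#' @param score_threshold log2-odds score cutoff; default 80% of the motif's
#'   maximum score.
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return list with `hits` (count over both strands) and `n_windows`
#'   (scorable windows).
#' @export
scan_pwm <- function(seq, x, score_threshold = pwm_score_threshold(x),
                     both_strands = TRUE) {
  stopifnot(inherits(x, "PWM"), is.finite(score_threshold))
  S <- log2(x$probs / x$background)
  L <- ncol(S)
  scan_one <- function(code) {
    n <- length(code)
    if (n < L) return(c(hits = 0L, windows = 0L))
    nw <- n - L + 1L
    sc <- numeric(nw)
    for (j in seq_len(L)) sc <- sc + S[cbind(code[j:(j + nw - 1L)], j)]
    ok <- !is.na(sc)
    c(hits = sum(sc[ok] >= score_threshold), windows = sum(ok))
  }
  code <- .encode_dna(seq)
  fwd <- scan_one(code)
  if (!both_strands)
    return(list(hits = unname(fwd["hits"]), n_windows = unname(fwd["windows"])))
  rc <- rev(5L - code)                        # A<->T (1<->4), C<->G (2<->3)
  rev_ <- scan_one(rc)
  list(hits = unname(fwd["hits"] + rev_["hits"]),
       n_windows = unname(fwd["windows"] + rev_["windows"]))
}

#' Extract promoter windows around TSSs
#'
#' For a plus-strand TSS at 0-based position t the genomic window is
#' `[t - upstream, t + downstream)`; for a minus-strand TSS it is
#' `[t - downstream + 1, t + upstream + 1)` reverse-complemented, so every
#' promoter reads 5'->3' with the TSS at 0-based position `upstream`.
#' Windows running off a contig edge are truncated and flagged.
#'
#' @param models a `GeneModelSet`.
#' @param genome a `DNAStringSet` or path to a FASTA file.
#' @param tss_groups rows of [tss_group_table()] to extract (default: all
#'   groups of `models`).
#' @param upstream,downstream window extent in bp (defaults 300 and 100).
#' @return A `PromoterSet` data.frame: `gene`, `tss_group`, `chrom`,
#'   `strand`, `start`, `end` (genomic, 0-based half-open), `truncated`,
#'   `seq`.
#' @export
extract_promoters <- function(models, genome, tss_groups = NULL,
                              upstream = 300, downstream = 100) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (is.null(tss_groups)) tss_groups <- tss_group_table(models)
  stopifnot(all(tss_groups$chrom %in% names(genome)))
  n <- nrow(tss_groups)
  out <- tss_groups[, c("gene", "tss_group", "chrom", "strand", "tss")]
  out$start <- ifelse(out$strand == "+", out$tss - upstream,
                      out$tss - downstream + 1)
  out$end <- ifelse(out$strand == "+", out$tss + downstream,
                    out$tss + upstream + 1)
  out$truncated <- FALSE
  out$seq <- NA_character_
  for (i in seq_len(n)) {
    clen <- length(genome[[out$chrom[i]]])
    s <- max(out$start[i], 0); e <- min(out$end[i], clen)
    if (s > out$start[i] || e < out$end[i]) out$truncated[i] <- TRUE
    if (e <= s) { out$seq[i] <- ""; next }
    sq <- Biostrings::subseq(genome[[out$chrom[i]]], s + 1, e)
    if (out$strand[i] == "-") sq <- Biostrings::reverseComplement(sq)
    out$seq[i] <- as.character(sq)
    out$start[i] <- s; out$end[i] <- e
  }
  out$tss <- NULL
  class(out) <- c("PromoterSet", "data.frame")
  out
}

#' Motif over-representation: foreground vs background promoters
#'
#' For each motif, counts promoters with at least one PWM hit in the
#' foreground and background sets, and tests over-representation in the
#' foreground with a one-sided Fisher exact test; q-values are BH-adjusted
#' across motifs.
#'
#' @param fg,bg `PromoterSet`s; must be disjoint (by gene and TSS group) and
#'   nonempty.
#' @param pwms list of [pwm()] objects.
#' @param score_threshold scalar or per-motif vector; default 80% of each
#'   motif's maximum score.
#' @param count `"binary"` (promoters with >= 1 hit; default) or
#'   `"per_site"` (total hit windows).
#' @return data.frame with `motif`, `fg_hits`, `fg_total`, `bg_hits`,
#'   `bg_total`, `odds_ratio`, `p`, `q`.
#' @export
motif_enrichment <- function(fg, bg, pwms,
                             score_threshold = NULL,
                             count = c("binary", "per_site")) {
  count <- match.arg(count)
  stopifnot(nrow(fg) > 0, nrow(bg) > 0)
  key <- function(p) paste(p$gene, p$tss_group)
  if (length(intersect(key(fg), key(bg))) > 0)
    stop("foreground and background promoter sets must be disjoint")
  if (is.null(names(pwms)))
    names(pwms) <- vapply(pwms, function(p) p$name, character(1))
  thr <- if (is.null(score_threshold))
    vapply(pwms, pwm_score_threshold, numeric(1))
  else rep_len(score_threshold, length(pwms))

  tally <- function(promoters, w, t) {
    res <- lapply(promoters$seq, scan_pwm, x = w, score_threshold = t)
    hits <- vapply(res, `[[`, numeric(1), "hits")
    if (count == "binary")
      c(hits = sum(hits > 0), total = length(hits))
    else
      c(hits = sum(hits), total = sum(vapply(res, `[[`, numeric(1),
                                             "n_windows")))
  }
  rows <- lapply(seq_along(pwms), function(k) {
    f <- tally(fg, pwms[[k]], thr[k])
    b <- tally(bg, pwms[[k]], thr[k])
    tab <- matrix(c(f["hits"], f["total"] - f["hits"],
                    b["hits"], b["total"] - b["hits"]), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    or <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
    data.frame(motif = names(pwms)[k],
               fg_hits = unname(f["hits"]), fg_total = unname(f["total"]),
               bg_hits = unname(b["hits"]), bg_total = unname(b["total"]),
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Cross enriched motifs with transcription-factor expression
#'
#' Restricts enrichment results to motifs with q below `alpha`, maps each to
#' its transcription-factor gene, and keeps those whose TF is differentially
#' expressed between normal and tumor samples (BH-corrected unpaired t-test
#' q below `alpha`), tagged by direction in tumor.
#'
#' @param enriched output of [motif_enrichment()].
#' @param gene_m a `GeneExpressionMatrix` containing the TF genes.
#' @param sheet sample sheet.
#' @param tf_map named character vector, motif name -> TF gene symbol.
#' @param alpha significance level for both filters (default 0.05).
#' @return data.frame with `motif`, `tf_gene`, `direction` (`"up"`/`"down"`
#'   in tumor), `enrich_q`, `expr_q`, `estimate`.
#' @export
cross_with_expression <- function(enriched, gene_m, sheet, tf_map,
                                  alpha = 0.05) {
  sheet <- validate_sample_sheet(sheet)
  hits <- enriched[enriched$q < alpha, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(motif = character(0), tf_gene = character(0),
                      direction = character(0), enrich_q = numeric(0),
                      expr_q = numeric(0), estimate = numeric(0)))
  mapped <- hits$motif %in% names(tf_map)
  if (!all(mapped))
    message(sum(!mapped), " enriched motif(s) without a TF mapping were dropped")
  hits <- hits[mapped, , drop = FALSE]
  hits$tf_gene <- unname(tf_map[hits$motif])
  present <- hits$tf_gene %in% rownames(gene_m$values)
  if (!all(present))
    message(sum(!present), " TF gene(s) absent from the expression matrix were dropped")
  hits <- hits[present, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(motif = character(0), tf_gene = character(0),
                      direction = character(0), enrich_q = numeric(0),
                      expr_q = numeric(0), estimate = numeric(0)))

  tum <- is_tumor(sheet)
  v <- gene_m$values[, sheet$sample_id, drop = FALSE]
  tests <- lapply(hits$tf_gene, function(g) {
    x <- v[g, !tum]; y <- v[g, tum]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      list(p = 1, est = mean(y) - mean(x))
    else {
      tt <- stats::t.test(y, x, var.equal = TRUE)
      list(p = tt$p.value, est = mean(y) - mean(x))
    }
  })
  expr_q <- bh_adjust(vapply(tests, `[[`, numeric(1), "p"))
  est <- vapply(tests, `[[`, numeric(1), "est")
  keep <- expr_q < alpha
  data.frame(motif = hits$motif[keep], tf_gene = hits$tf_gene[keep],
             direction = ifelse(est[keep] > 0, "up", "down"),
             enrich_q = hits$q[keep], expr_q = expr_q[keep],
             estimate = est[keep], stringsAsFactors = FALSE)
}
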