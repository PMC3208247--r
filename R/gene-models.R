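#' Construct a set of gene models
#'
#' A `GeneModelSet` stores transcripts (one row per transcript) together with
#' their exon intervals. All coordinates are 0-based, half-open. The
#' transcription start site (TSS) of a transcript is its strand-aware 5' end:
#' the start of the first exon on the plus strand, the last base of the last
#' exon on the minus strand.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene`,
#'   `chrom`, `strand` (`"+"` or `"-"`), `coding` (logical).
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open genomic intervals).
#' @return An object of class `GeneModelSet` with elements `transcripts`
#'   (including a computed `tss` column) and `exons` (sorted by start within
#'   transcript).
#' @export
gene_model_set <- function(transcripts, exons) {
  stopifnot(is.data.frame(transcripts), is.data.frame(exons))
  need_t <- c("transcript_id", "gene", "chrom", "strand", "coding")
  need_e <- c("transcript_id", "start", "end")
  if (!all(need_t %in% names(transcripts)))
    stop("transcripts must have columns: ", paste(need_t, collapse = ", "))
  if (!all(need_e %in% names(exons)))
    stop("exons must have columns: ", paste(need_e, collapse = ", "))
  if (anyDuplicated(transcripts$transcript_id))
    stop("duplicated transcript_id")
  if (!all(transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    stop("exon rows reference unknown transcripts")
  if (any(exons$end <= exons$start))
    stop("every exon must satisfy start < end")

  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), c("transcript_id", "start", "end")]
  rownames(exons) <- NULL

  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  if (!all(transcripts$transcript_id %in% names(by_tx)))
    stop("transcript with zero exons: ",
         paste(setdiff(transcripts$transcript_id, names(by_tx)), collapse = ", "))
  for (tx in names(by_tx)) {
    idx <- by_tx[[tx]]
    if (length(idx) > 1) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1] < e[-length(e)]))
        stop("overlapping exons in transcript ", tx)
    }
  }

  # per-gene consistency of chrom and strand
  for (g in unique(transcripts$gene)) {
    sel <- transcripts$gene == g
    if (length(unique(transcripts$chrom[sel])) > 1L ||
        length(unique(transcripts$strand[sel])) > 1L)
      stop("transcripts of gene ", g, " disagree on chrom or strand")
  }

  first <- vapply(by_tx, function(i) min(exons$start[i]), numeric(1))
  last  <- vapply(by_tx, function(i) max(exons$end[i]),   numeric(1))
  transcripts$tss <- ifelse(transcripts$strand == "+",
                            first[transcripts$transcript_id],
                            last[transcripts$transcript_id] - 1)
  rownames(transcripts) <- NULL
  structure(list(transcripts = transcripts, exons = exons),
            class = "GeneModelSet")
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat(sprintf("GeneModelSet: %d transcripts, %d genes, %d exons\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene)),
              nrow(x$exons)))
  invisible(x)
}

#' Read gene models from BED12 or GFF3
#'
#' BED12 input: one line per transcript; the name field carries
#' `transcript_id|gene_symbol`; a transcript is coding when its thick (CDS)
#' interval is non-empty. GFF3 input: transcript features (`mRNA` or
#' `transcript`) carry `ID` and a `gene` attribute (or a `Parent` gene
#' feature); exon features point at their transcript via `Parent`; `mRNA`
#' features and transcripts with CDS children are coding. GFF3's 1-based
#' inclusive coordinates are converted to 0-based half-open on read.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bed"`, or `"gff3"`.
#' @return A [gene_model_set()].
#' @export
load_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) "gff3"
              else stop("cannot infer format of ", path, "; pass format=")
  }
  if (format == "bed") .load_models_bed(path) else .load_models_gff3(path)
}

.load_models_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) stop("no records in ", path)
  nm <- as.character(gr$name)
  if (any(!grepl("|", nm, fixed = TRUE)))
    stop("BED12 name field must be 'transcript_id|gene_symbol'; offending record: ",
         nm[which(!grepl("|", nm, fixed = TRUE))[1]])
  parts <- strsplit(nm, "|", fixed = TRUE)
  tx_id <- vapply(parts, `[`, character(1), 1)
  gene  <- vapply(parts, `[`, character(1), 2)
  blocks <- gr$blocks
  if (is.null(blocks)) stop(path, " is not BED12 (no block structure)")
  nblk <- lengths(blocks)
  if (any(nblk == 0)) stop("transcript with zero exons: ", tx_id[nblk == 0][1])
  thick <- gr$thick
  coding <- if (is.null(thick)) rep(FALSE, length(gr)) else
    BiocGenerics::width(thick) > 0
  transcripts <- data.frame(
    transcript_id = tx_id, gene = gene,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    coding = coding, stringsAsFactors = FALSE)
  if (any(!transcripts$strand %in% c("+", "-")))
    stop("BED12 transcript without strand: ",
         tx_id[!transcripts$strand %in% c("+", "-")][1])
  ubl <- unlist(blocks)                        # 1-based, relative to tx start
  exons <- data.frame(
    transcript_id = rep(tx_id, nblk),
    start = rep(BiocGenerics::start(gr) - 1L, nblk) + BiocGenerics::start(ubl) - 1L,
    end   = rep(BiocGenerics::start(gr) - 1L, nblk) + BiocGenerics::end(ubl),
    stringsAsFactors = FALSE)
  gene_model_set(transcripts, exons)
}

.load_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  type <- as.character(gr$type)
  is_tx <- type %in% c("mRNA", "transcript")
  if (!any(is_tx)) stop("no mRNA/transcript features in ", path)
  tx <- gr[is_tx]
  tx_id <- as.character(tx$ID)
  if (anyNA(tx_id)) stop("transcript feature without ID in ", path)

  # gene symbol: 'gene' attribute, else Name/ID of the Parent gene feature
  gene_attr <- if ("gene" %in% names(S4Vectors::mcols(tx)))
    as.character(tx$gene) else rep(NA_character_, length(tx))
  if (anyNA(gene_attr)) {
    genes <- gr[type == "gene"]
    gname <- as.character(if (!is.null(genes$Name)) genes$Name else genes$ID)
    names(gname) <- as.character(genes$ID)
    parent <- vapply(tx$Parent, function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
    miss <- is.na(gene_attr)
    gene_attr[miss] <- gname[parent[miss]]
  }
  if (anyNA(gene_attr))
    stop("transcript without gene attribution: ", tx_id[is.na(gene_attr)][1])

  parent_of <- function(feat) {
    vapply(feat$Parent, function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1))
  }
  ex <- gr[type == "exon"]
  if (length(ex) == 0) stop("no exon features in ", path)
  ex_parent <- parent_of(ex)
  keep <- ex_parent %in% tx_id
  ex <- ex[keep]; ex_parent <- ex_parent[keep]

  cds_parent <- character(0)
  if (any(type == "CDS")) cds_parent <- unique(parent_of(gr[type == "CDS"]))
  coding <- as.character(tx$type) == "mRNA" | tx_id %in% cds_parent

  transcripts <- data.frame(
    transcript_id = tx_id, gene = gene_attr,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = as.character(BiocGenerics::strand(tx)),
    coding = coding, stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = ex_parent,
    start = BiocGenerics::start(ex) - 1L,     # 1-based inclusive -> 0-based half-open
    end = BiocGenerics::end(ex),
    stringsAsFactors = FALSE)
  gene_model_set(transcripts, exons)
}

#' Write gene models as BED12
#'
#' Inverse of [load_gene_models()] for the BED12 dialect (name field
#' `transcript_id|gene`, thick interval spanning the transcript when coding).
#'
#' @param models a `GeneModelSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  stopifnot(inherits(models, "GeneModelSet"))
  tr <- models$transcripts
  by_tx <- split(models$exons, models$exons$transcript_id)
  txs <- lapply(seq_len(nrow(tr)), function(i) {
    e <- by_tx[[tr$transcript_id[i]]]
    tx_start <- min(e$start)
    gr <- GenomicRanges::GRanges(
      tr$chrom[i],
      IRanges::IRanges(tx_start + 1L, max(e$end)),
      strand = tr$strand[i])
    gr$name <- paste0(tr$transcript_id[i], "|", tr$gene[i])
    gr$thick <- if (tr$coding[i])
      IRanges::IRanges(tx_start + 1L, max(e$end))
    else IRanges::IRanges(tx_start + 1L, width = 0L)
    gr$blocks <- IRanges::IRangesList(
      IRanges::IRanges(e$start - tx_start + 1L, e$end - tx_start))
    gr
  })
  gr <- do.call(c, txs)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Genes with multiple distinct transcription start sites
#'
#' @param models a `GeneModelSet`.
#' @param min_distinct_tss minimum number of distinct TSS positions (default 2).
#' @param require_coding require at least one coding transcript (default TRUE).
#' @param min_tss_sep minimum separation (bp) for two TSSs to count as
#'   distinct; the default of 1 makes any nonzero coordinate difference count.
#' @return Character vector of gene symbols, sorted.
#' @export
find_multi_tss_genes <- function(models, min_distinct_tss = 2,
                                 require_coding = TRUE, min_tss_sep = 1) {
  stopifnot(inherits(models, "GeneModelSet"), min_tss_sep >= 1)
  tr <- models$transcripts
  if (nrow(tr) == 0) stop("empty GeneModelSet")
  keep <- vapply(split(seq_len(nrow(tr)), tr$gene), function(i) {
    tss <- sort(unique(tr$tss[i]))
    n_distinct <- if (length(tss) <= 1) length(tss)
                  else 1L + sum(diff(tss) >= min_tss_sep)
    n_distinct >= min_distinct_tss && (!require_coding || any(tr$coding[i]))
  }, logical(1))
  sort(names(keep)[keep])
}

#' TSS groups of a gene model set
#'
#' Groups each gene's transcripts by their TSS coordinate. Groups are ranked
#' in transcription order (rank 1 = most 5'), and a group id of the form
#' `<gene>_tss<rank>` is assigned, so rank 1 always denotes the longest
#' (most upstream) isoform class.
#'
#' @param models a `GeneModelSet`.
#' @return data.frame with columns `gene`, `tss_group`, `tss_rank`, `chrom`,
#'   `strand`, `tss`, `n_transcripts`.
#' @export
tss_group_table <- function(models) {
  stopifnot(inherits(models, "GeneModelSet"))
  tr <- models$transcripts
  out <- lapply(split(tr, tr$gene), function(d) {
    tss <- unique(d$tss)
    tss <- if (d$strand[1] == "+") sort(tss) else sort(tss, decreasing = TRUE)
    data.frame(gene = d$gene[1],
               tss_group = sprintf("%s_tss%d", d$gene[1], seq_along(tss)),
               tss_rank = seq_along(tss),
               chrom = d$chrom[1], strand = d$strand[1], tss = tss,
               n_transcripts = as.integer(table(factor(d$tss, levels = tss))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.transcript_tss_group <- function(models) {
  grp <- tss_group_table(models)
  key <- paste(grp$gene, grp$tss)
  ids <- grp$tss_group
  names(ids) <- key
  tr <- models$transcripts
  stats::setNames(ids[paste(tr$gene, tr$tss)], tr$transcript_id)
}

#' Read a probe-set catalog
#'
#' Tab-separated file with columns `probeset_id`, `chrom`, `start`, `end`
#' (0-based half-open), `tier` (`core`, `extended` or `full`) and optionally
#' `gene`.
#'
#' @param path file path.
#' @return data.frame of probe sets.
#' @export
load_probesets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probeset_id", "chrom", "start", "end", "tier")
  if (!all(need %in% names(df)))
    stop("probe-set catalog must have columns: ", paste(need, collapse = ", "))
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  validate_probesets(df)
  df
}

validate_probesets <- function(ps) {
  if (any(ps$end <= ps$start)) stop("probe set with start >= end")
  if (!all(ps$tier %in% c("core", "extended", "full")))
    stop("tier must be one of core/extended/full")
  if (anyDuplicated(ps$probeset_id)) stop("duplicated probeset_id")
  invisible(ps)
}

#' Annotate probe sets against gene models
#'
#' Maps each probe set to the transcripts whose exons it overlaps (>= 1 bp)
#' and classifies it: `shared` when all of the gene's transcripts support it,
#' `tss_unique` when exactly one TSS group supports it and the probe set lies
#' strictly 5' of the exonic region common to all TSS groups, `internal_unique`
#' for other partial support, and `unmapped` when it overlaps no exon of its
#' assigned gene (unmapped probe sets are excluded from all downstream
#' analyses).
#'
#' @param models a `GeneModelSet`.
#' @param probesets probe-set catalog data.frame (see [load_probesets()])
#'   with a `gene` column matching gene symbols in `models`.
#' @return data.frame with columns `probeset_id`, `gene`, `tier`, `cls`,
#'   `tss_group`, `supporting_transcripts` (comma-separated).
#' @export
annotate_probesets <- function(models, probesets) {
  stopifnot(inherits(models, "GeneModelSet"))
  validate_probesets(probesets)
  known <- unique(models$transcripts$gene)
  bad <- !is.na(probesets$gene) & !(probesets$gene %in% known)
  if (any(bad)) {
    warning(sum(bad), " probe set(s) assigned to genes absent from the models",
            " were excluded: ", paste(utils::head(unique(probesets$gene[bad]), 3),
                                      collapse = ", "))
    probesets <- probesets[!bad, , drop = FALSE]
  }
  probesets <- probesets[!is.na(probesets$gene), , drop = FALSE]
  tx2grp <- .transcript_tss_group(models)
  tr <- models$transcripts
  ex <- models$exons
  ex$gene <- tr$gene[match(ex$transcript_id, tr$transcript_id)]
  ex$chrom <- tr$chrom[match(ex$transcript_id, tr$transcript_id)]

  # one global overlap join, then restrict hits to the probe set's own gene
  ps_gr <- GenomicRanges::GRanges(probesets$chrom,
                                  IRanges::IRanges(probesets$start + 1L,
                                                   probesets$end))
  ex_gr <- GenomicRanges::GRanges(ex$chrom,
                                  IRanges::IRanges(ex$start + 1L, ex$end))
  hits <- GenomicRanges::findOverlaps(ps_gr, ex_gr, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  same_gene <- probesets$gene[qh] == ex$gene[sh]
  qh <- qh[same_gene]; sh <- sh[same_gene]
  sup <- split(ex$transcript_id[sh],
               factor(qh, levels = seq_len(nrow(probesets))))
  sup <- lapply(sup, unique)

  # strand-aware 5' boundary of the exonic region common to all TSS groups
  grp_of_ex <- tx2grp[ex$transcript_id]
  ex_by_key <- split(seq_len(nrow(ex)), paste(ex$gene, grp_of_ex, sep = "\r"))
  strand_of_gene <- vapply(split(tr$strand, tr$gene), `[`, character(1), 1)
  limit_of <- new.env()
  for (g in unique(probesets$gene)) {
    grps <- unique(tx2grp[tr$transcript_id[tr$gene == g]])
    covs <- lapply(paste(g, grps, sep = "\r"), function(k)
      .ivl_reduce(ex$start[ex_by_key[[k]]], ex$end[ex_by_key[[k]]]))
    common <- Reduce(.ivl_intersect, covs)
    assign(g, if (nrow(common) == 0) NULL
           else if (strand_of_gene[[g]] == "+") min(common[, 1])
           else max(common[, 2]),
           envir = limit_of)
  }

  n <- nrow(probesets)
  cls <- character(n)
  grp_id <- rep(NA_character_, n)
  tx_of_gene <- split(tr$transcript_id, tr$gene)
  for (i in seq_len(n)) {
    g <- probesets$gene[i]
    s <- sup[[i]]
    if (length(s) == 0) { cls[i] <- "unmapped"; next }
    if (setequal(s, tx_of_gene[[g]])) { cls[i] <- "shared"; next }
    grps <- unique(tx2grp[s])
    if (length(grps) == 1L) {
      lim <- get(g, envir = limit_of)
      strand <- strand_of_gene[[g]]
      upstream <- is.null(lim) ||
        (strand == "+" && probesets$end[i] <= lim) ||
        (strand == "-" && probesets$start[i] >= lim)
      if (upstream) { cls[i] <- "tss_unique"; grp_id[i] <- grps; next }
    }
    cls[i] <- "internal_unique"
  }
  out <- data.frame(probeset_id = probesets$probeset_id,
                    gene = probesets$gene, tier = probesets$tier,
                    cls = cls, tss_group = grp_id,
                    supporting_transcripts = vapply(sup, paste, character(1),
                                                    collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$probeset_id), ]
  rownames(out) <- NULL
  n_un <- sum(out$cls == "unmapped")
  if (n_un > 0)
    message(n_un, " probe set(s) overlap no exon of their gene (flagged unmapped)")
  out
}

#' Write a probe-set annotation as TSV
#' @param ann annotation data.frame from [annotate_probesets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# merge possibly-overlapping 0-based half-open intervals into disjoint ones
.ivl_reduce <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ks <- start[1]; ke <- end[1]; outs <- c(); oute <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ke) ke <- max(ke, end[i])
    else { outs <- c(outs, ks); oute <- c(oute, ke); ks <- start[i]; ke <- end[i] }
  }
  cbind(c(outs, ks), c(oute, ke))
}

# intersection of two disjoint sorted interval sets (matrices of start, end)
.ivl_intersect <- function(a, b) {
  outs <- c(); oute <- c()
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a[i, 1], b[j, 1]); e <- min(a[i, 2], b[j, 2])
    if (s < e) { outs <- c(outs, s); oute <- c(oute, e) }
    if (a[i, 2] < b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  cbind(outs, oute)
}
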