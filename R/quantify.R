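#' Mask genomic positions claimed by more than one gene
#'
#' Any base pair belonging to the exon unions of two or more distinct gene
#' ids is removed from all of them, so that no read can be counted to a
#' gene on the evidence of shared sequence. Genes left with zero exonic
#' length are dropped from quantification and recorded in the `dropped`
#' field.
#'
#' @param gm A `gene_models` object from [read_gene_models()] or
#'   [gene_models()].
#' @return The masked `gene_models` object (`masked = TRUE`). Masking is
#'   idempotent.
#' @export
mask_name_overlaps <- function(gm) {
  stopifnot(inherits(gm, "gene_models"))
  if (length(gm$exons) == 0L || isTRUE(gm$masked)) {
    gm$masked <- TRUE
    return(gm)
  }
  gr <- gm$exons
  # strand is ignored when deciding whether sequence is shared: a read
  # overlapping the locus cannot be attributed regardless of orientation
  gr_us <- gr
  GenomicRanges::strand(gr_us) <- "*"
  dj <- GenomicRanges::disjoin(gr_us)
  ov <- GenomicRanges::findOverlaps(dj, gr_us)
  ngenes <- tapply(S4Vectors::mcols(gr)$gene_id[S4Vectors::subjectHits(ov)],
                   S4Vectors::queryHits(ov),
                   function(g) length(unique(g)))
  shared <- dj[as.integer(names(ngenes))[ngenes > 1L]]
  if (length(shared) > 0L) {
    keep_ov <- GenomicRanges::setdiff(gr_us, shared, ignore.strand = TRUE)
    # intersect each gene's exons with the retained space
    hit <- GenomicRanges::findOverlaps(gr_us, keep_ov)
    pieces <- GenomicRanges::pintersect(
      gr[S4Vectors::queryHits(hit)], keep_ov[S4Vectors::subjectHits(hit)],
      ignore.strand = TRUE)
    S4Vectors::mcols(pieces)$hit <- NULL
    gr <- pieces
  }
  gid <- S4Vectors::mcols(gr)$gene_id
  len <- tapply(GenomicRanges::width(gr), gid, sum)
  genes <- gm$genes
  genes$effective_length <-
    as.integer(ifelse(is.na(len[genes$gene_id]), 0L, len[genes$gene_id]))
  dropped <- genes$gene_id[genes$effective_length == 0L]
  genes <- genes[genes$effective_length > 0L, ]
  gm$exons <- gr[gid %in% genes$gene_id]
  gm$genes <- genes
  gm$dropped <- sort(unique(c(gm$dropped, dropped)))
  gm$masked <- TRUE
  gm
}

#' Remove microRNA and snoRNA genes before quantification
#'
#' Small structural RNAs are excluded from expression quantification: they
#' are highly variable between preparations and are generally not
#' polyadenylated. A gene is removed when its biotype hint is miRNA or
#' snoRNA, or (as a fallback on the symbol) when its name starts with
#' `MIR`/`MIRLET` followed by a digit (or `LET` followed by alphanumerics)
#' or `SNOR` followed by an optional family letter and a digit, case
#' insensitively. The word-boundary requirement keeps genes such as
#' "MIRROR-like" untouched.
#'
#' @param gm A `gene_models` object.
#' @return The filtered `gene_models` object.
#' @export
filter_small_rna <- function(gm) {
  stopifnot(inherits(gm, "gene_models"))
  if (nrow(gm$genes) == 0L) return(gm)
  bt <- tolower(gm$genes$biotype_hint)
  by_biotype <- !is.na(bt) & bt %in% c("mirna", "snorna")
  sym <- gm$genes$gene_id
  by_symbol <- grepl("^(mir(let)?[0-9]|mirlet[a-z0-9]|snor[a-z]?[0-9])",
                     sym, ignore.case = TRUE)
  drop <- by_biotype | by_symbol
  if (any(drop)) {
    keep_ids <- gm$genes$gene_id[!drop]
    gm$genes <- gm$genes[!drop, ]
    gm$exons <- gm$exons[S4Vectors::mcols(gm$exons)$gene_id %in% keep_ids]
  }
  gm
}

#' Count species-assigned reads over masked exon unions
#'
#' A read is counted to a gene when its alignment interval in its assigned
#' genome overlaps the gene's (masked) exon union by at least one base
#' pair. Each read is counted at most once; when a read interval touches
#' two genes' territories, the gene with the larger overlap wins, ties
#' broken by gene id order. Reads overlapping no retained exonic sequence
#' are uncounted.
#'
#' @param assignments Assignment table from [assign_all()] (`read_id`,
#'   `label`, ...).
#' @param observations Observation table from [read_alignments()] for the
#'   genome being quantified (supplies each read's alignment interval).
#' @param gm `gene_models` for that genome (masked with
#'   [mask_name_overlaps()]; unmasked input is masked on the fly).
#' @return List with `counts` (named integer vector over
#'   `gm$genes$gene_id`) and `n_counted` (number of reads contributing).
#' @export
count_reads <- function(assignments, observations, gm) {
  stopifnot(inherits(gm, "gene_models"))
  if (!isTRUE(gm$masked)) gm <- mask_name_overlaps(gm)
  genome <- gm$genome_id
  counts <- setNames(integer(nrow(gm$genes)), gm$genes$gene_id)
  ids <- assignments$read_id[assignments$label == genome]
  if (length(ids) == 0L || length(gm$exons) == 0L)
    return(list(counts = counts, n_counted = 0L))
  obs <- observations[observations$read_id %in% ids &
                        observations$aligned, ]
  if (nrow(obs) == 0L) return(list(counts = counts, n_counted = 0L))
  reads <- GenomicRanges::GRanges(
    seqnames = obs$chrom,
    ranges = IRanges::IRanges(obs$start, obs$end))
  hit <- GenomicRanges::findOverlaps(reads, gm$exons, minoverlap = 1L,
                                     ignore.strand = TRUE)
  if (length(hit) == 0L) return(list(counts = counts, n_counted = 0L))
  olap <- GenomicRanges::width(GenomicRanges::pintersect(
    reads[S4Vectors::queryHits(hit)],
    gm$exons[S4Vectors::subjectHits(hit)], ignore.strand = TRUE))
  dt <- data.table(
    read = S4Vectors::queryHits(hit),
    gene = S4Vectors::mcols(gm$exons)$gene_id[S4Vectors::subjectHits(hit)],
    olap = olap)
  # a read split across several intervals of the same gene accumulates
  dt <- dt[, .(olap = sum(olap)), by = .(read, gene)]
  data.table::setorder(dt, read, -olap, gene)
  best <- dt[, .SD[1L], by = read]
  tab <- table(best$gene)
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, n_counted = nrow(best))
}

#' Reads per kilobase of exon model per million assigned reads
#'
#' @param counts Integer matrix (genes x samples) or vector of gene counts.
#' @param effective_length_bp Gene effective lengths in bp (masked exon
#'   union), recycled across samples.
#' @param total_assigned_reads Per-sample totals of species-assigned,
#'   gene-counted reads; defaults to the column sums of `counts`.
#' @return RPKM matrix/vector with the same shape as `counts`. Zero totals
#'   yield zero RPKM for all genes of that sample.
#' @export
rpkm <- function(counts, effective_length_bp,
                 total_assigned_reads = NULL) {
  vec <- is.null(dim(counts))
  m <- as.matrix(counts)
  if (length(effective_length_bp) != nrow(m))
    stop("effective_length_bp must have one entry per gene")
  if (any(effective_length_bp <= 0))
    stop("effective gene lengths must be positive")
  if (is.null(total_assigned_reads)) total_assigned_reads <- colSums(m)
  if (length(total_assigned_reads) != ncol(m))
    stop("total_assigned_reads must have one entry per sample")
  denom <- outer(effective_length_bp / 1e3, total_assigned_reads / 1e6)
  out <- m / denom
  out[, total_assigned_reads == 0] <- 0
  if (vec) out <- drop(out)
  out
}

#' Detected genes under a read-count cutoff
#'
#' @param counts Count vector or matrix (genes x samples).
#' @param cutoff Minimum read count for detection (default 1).
#' @return Logical vector/matrix: `counts >= cutoff`.
#' @export
detected_genes <- function(counts, cutoff = 1L) {
  counts >= cutoff
}

#' Trimmed mean of M-values normalization factors
#'
#' Pairwise TMM against a reference sample: per-gene log2 ratios (M) and
#' average log2 abundances (A) are computed on genes expressed in both
#' samples, doubly trimmed (30 % on M, 5 % on A), and the factor is two to
#' the precision-weighted mean of the surviving M values. Factors are
#' rescaled so their geometric mean is one; normalized expression is
#' `value / factor`. Designed for matrices of already depth- and
#' length-normalized values (RPKM), where no library size applies; weights
#' are inverse delta-method variances `1/x_s + 1/x_r`.
#'
#' @param x Expression matrix (genes x samples), at least two samples.
#' @param reference Reference sample (name or index), or `"auto"`: the
#'   sample whose upper quartile of positive values is closest to the mean
#'   upper quartile.
#' @param logratio_trim Two-sided trim fraction on M (default 0.3).
#' @param abundance_trim Two-sided trim fraction on A (default 0.05).
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(x, reference = "auto",
                        logratio_trim = 0.3, abundance_trim = 0.05) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("TMM normalization requires at least two samples")
  if (is.null(colnames(x))) colnames(x) <- paste0("S", seq_len(ncol(x)))
  allzero <- colSums(x > 0) == 0L
  if (any(allzero))
    stop("sample with all-zero expression: ",
         paste(colnames(x)[allzero], collapse = ", "))

  if (identical(reference, "auto")) {
    uq <- apply(x, 2L, function(v) quantile(v[v > 0], 0.75))
    ref <- which.min(abs(uq - mean(uq)))
  } else if (is.character(reference)) {
    ref <- match(reference, colnames(x))
    if (is.na(ref)) stop("reference sample not found: ", reference)
  } else {
    ref <- as.integer(reference)
  }

  f <- vapply(seq_len(ncol(x)), function(s) {
    if (s == ref) return(1)
    .tmm_pair(x[, s], x[, ref], logratio_trim, abundance_trim)
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(x))
}

.tmm_pair <- function(obs, ref, logratio_trim, abundance_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0L) return(1)
  M <- log2(obs / ref)
  A <- 0.5 * log2(obs * ref)
  w <- 1 / (1 / obs + 1 / ref)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abundance_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  fl <- sum(w[keep2] * M[keep2]) / sum(w[keep2])
  if (!is.finite(fl)) return(1)
  2^fl
}

#' Build a per-species expression matrix from assigned reads
#'
#' Convenience wrapper running small-RNA removal, multi-gene masking,
#' per-sample counting, RPKM, and (for two or more samples) TMM.
#'
#' @param assignment_list Named list (sample id -> assignment table from
#'   [assign_all()]).
#' @param observation_list Named list (sample id -> observation table for
#'   the quantified genome).
#' @param gm `gene_models` of the quantified genome.
#' @param remove_small_rna Drop miRNA/snoRNA genes first (default `TRUE`).
#' @return An `expression_matrix` object: list with `genome_id`,
#'   `gene_ids`, `sample_ids`, `counts`, `rpkm`, `tmm_factor`,
#'   `total_assigned_reads`, `effective_length`.
#' @export
expression_matrix <- function(assignment_list, observation_list, gm,
                              remove_small_rna = TRUE) {
  stopifnot(inherits(gm, "gene_models"))
  samples <- names(assignment_list)
  if (is.null(samples) || !identical(sort(samples),
                                     sort(names(observation_list))))
    stop("assignment_list and observation_list must share sample names")
  if (remove_small_rna) gm <- filter_small_rna(gm)
  gm <- mask_name_overlaps(gm)
  cts <- vapply(samples, function(s) {
    count_reads(assignment_list[[s]], observation_list[[s]], gm)$counts
  }, numeric(nrow(gm$genes)))
  cts <- matrix(as.integer(cts), nrow = nrow(gm$genes),
                dimnames = list(gm$genes$gene_id, samples))
  totals <- colSums(cts)
  rp <- rpkm(cts, gm$genes$effective_length, totals)
  tf <- if (ncol(cts) >= 2L && all(totals > 0)) tmm_factors(rp)
        else setNames(rep(1, ncol(cts)), samples)
  structure(list(genome_id = gm$genome_id, gene_ids = gm$genes$gene_id,
                 sample_ids = samples, counts = cts, rpkm = rp,
                 tmm_factor = tf, total_assigned_reads = totals,
                 effective_length = setNames(gm$genes$effective_length,
                                             gm$genes$gene_id)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix for genome '", x$genome_id, "': ",
      length(x$gene_ids), " genes x ", length(x$sample_ids), " samples\n",
      sep = "")
  cat("  assigned reads per sample:",
      paste(x$sample_ids, x$total_assigned_reads, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
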