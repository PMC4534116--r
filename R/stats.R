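#' Pseudo-count fold change between expression values
#'
#' Ratio of expression values after adding a small pseudo-value
#' representing the RPKM background, so that fold changes remain defined
#' and conservative at low expression.
#'
#' @param x,y Expression values (RPKM); vectorized.
#' @param pseudo Pseudo-value added to both (default 0.3 RPKM).
#' @return `(x + pseudo) / (y + pseudo)`.
#' @export
fold_change <- function(x, y, pseudo = 0.3) {
  (x + pseudo) / (y + pseudo)
}

#' SAM-style moderated difference statistic
#'
#' `d = (mean(x) - mean(y)) / (s + s0)` where `s` is the pooled standard
#' error of the mean difference (as in significance analysis of
#' microarrays) and `s0` a small positive regularizer guarding against
#' tiny variances.
#'
#' @param x,y Numeric vectors, at least two values each.
#' @param s0 Regularizing constant added to the standard error.
#' @return The statistic `d`.
#' @export
sam_statistic <- function(x, y, s0 = 0) {
  if (length(x) < 2L || length(y) < 2L)
    stop("sam_statistic requires at least two values per group")
  s <- .sam_se(x, y)
  if (s + s0 == 0)
    stop("zero variance in both groups with s0 = 0: statistic undefined")
  (mean(x) - mean(y)) / (s + s0)
}

.sam_se <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  sqrt((1 / n1 + 1 / n2) * pooled)
}

# vectorized per-gene means/SE for a genes x samples matrix and a 2-level
# grouping; returns list(d_num, s) without s0
.sam_components <- function(mat, idx1, idx2) {
  x1 <- mat[, idx1, drop = FALSE]
  x2 <- mat[, idx2, drop = FALSE]
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(num = m1 - m2, s = s, m1 = m1, m2 = m2)
}

#' Permutation test on SAM-style statistics with a pooled null
#'
#' Computes the per-gene statistic, then rebuilds it under label
#' permutations; the null distribution pools all genes' permuted
#' statistics, and each gene's p-value is the smoothed two-sided tail
#' probability `p = (1 + #\{|d*| >= |d|\}) / (1 + n_null)`. When the
#' number of distinct two-group splits is at most `n_perm`, all splits are
#' enumerated instead of sampled, which removes Monte-Carlo noise at small
#' sample sizes (e.g. triplicates).
#'
#' @param mat Numeric matrix, genes x samples.
#' @param labels Two-level grouping of the columns (factor/character).
#' @param n_perm Number of permutations to sample when exhaustive
#'   enumeration is infeasible (default 1000).
#' @param s0_rule How the regularizer is chosen from the observed per-gene
#'   standard errors: their `"median_s"` (default) or 5th percentile
#'   (`"percentile5"`).
#' @param seed Integer seed controlling sampled permutations.
#' @return List with `d` (observed statistics), `p` (per-gene p-values),
#'   `s0`, `exhaustive` (logical), `n_perm_used`, `mean_group1`,
#'   `mean_group2`, and `fdr` (Benjamini-Hochberg adjusted p-values).
#' @export
permutation_test <- function(mat, labels, n_perm = 1000L,
                             s0_rule = c("median_s", "percentile5"),
                             seed = 1L) {
  s0_rule <- match.arg(s0_rule)
  mat <- as.matrix(mat)
  labels <- as.character(labels)
  if (length(labels) != ncol(mat))
    stop("labels must have one entry per sample (column)")
  lv <- unique(labels)
  if (length(lv) != 2L)
    stop("permutation_test requires exactly two groups")
  idx1 <- which(labels == lv[1L])
  idx2 <- which(labels == lv[2L])
  if (length(idx1) == 0L || length(idx2) == 0L)
    stop("both groups must be non-empty")
  if (length(idx1) < 2L || length(idx2) < 2L)
    stop("at least two samples per group are required")

  obs <- .sam_components(mat, idx1, idx2)
  s0 <- switch(s0_rule,
               median_s = median(obs$s),
               percentile5 = unname(quantile(obs$s, 0.05)))
  if (s0 == 0 && any(obs$s == 0))
    s0 <- .Machine$double.eps
  d_obs <- obs$num / (obs$s + s0)

  n <- ncol(mat)
  n1 <- length(idx1)
  n_splits <- choose(n, n1)
  distinct <- if (n1 == n - n1) n_splits / 2 else n_splits
  exhaustive <- distinct <= n_perm

  if (exhaustive) {
    splits <- combn(n, n1, simplify = FALSE)
    if (n1 == n - n1) {
      # complementary splits give the same |d|; keep those containing col 1
      splits <- Filter(function(s) 1L %in% s, splits)
    }
  } else {
    set.seed(seed)
    splits <- replicate(n_perm, sort(sample.int(n, n1)), simplify = FALSE)
  }
  n_used <- length(splits)

  null_abs <- numeric(n_used * nrow(mat))
  pos <- 0L
  for (sp in splits) {
    comp <- setdiff(seq_len(n), sp)
    per <- .sam_components(mat, sp, comp)
    dv <- abs(per$num / (per$s + s0))
    null_abs[pos + seq_along(dv)] <- dv
    pos <- pos + length(dv)
  }
  null_sorted <- sort(null_abs)
  n_null <- length(null_sorted)
  # #{|d*| >= |d|} via binary search on the sorted pooled null
  ge <- n_null - findInterval(abs(d_obs) - 1e-12, null_sorted)
  p <- (1 + ge) / (1 + n_null)

  list(d = d_obs, p = p, s0 = s0, exhaustive = exhaustive,
       n_perm_used = n_used, mean_group1 = obs$m1, mean_group2 = obs$m2,
       fdr = bh_fdr(p))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values `q_(i) = min_(j >= i) p_(j) m / j`, capped at
#' one and mapped back to the input order (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Vector of p-values.
#' @return Vector of BH-adjusted p-values (FDR).
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' One-sided gene-list overlap test
#'
#' Tests whether the overlap of two gene lists drawn from a common
#' universe exceeds chance: hypergeometric upper tail
#' `P(X >= k)` with `n1` draws marked out of `N` and `n2` drawn.
#'
#' @param k Observed overlap.
#' @param n1,n2 Sizes of the two gene lists.
#' @param N Universe size (e.g. 24112 annotated human genes, 23225 mouse).
#' @return One-sided enrichment p-value.
#' @export
fisher_overlap <- function(k, n1, n2, N) {
  if (k > min(n1, n2)) stop("overlap k cannot exceed min(n1, n2)")
  if (n1 > N || n2 > N) stop("list sizes cannot exceed the universe N")
  if (k < max(0, n1 + n2 - N)) stop("overlap k below its feasible minimum")
  phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
}

#' Differentially expressed genes by fold change or FDR
#'
#' Two selection modes mirroring common practice with unequal group sizes:
#' `"fc"` selects detected genes whose pseudo-count fold change between
#' group means exceeds the cutoff in either direction; `"fdr"` selects
#' genes below an FDR cutoff from the SAM-statistic permutation test.
#'
#' @param mat Expression matrix (genes x samples), rownames = gene ids.
#' @param labels Two-level grouping of columns.
#' @param mode `"fc"` (default) or `"fdr"`.
#' @param fc_cutoff Fold-change cutoff (default 2).
#' @param fdr_cutoff FDR cutoff (default 0.05).
#' @param pseudo Pseudo-value for fold changes (default 0.3).
#' @param direction For mode `"fc"`: `"both"`, `"up"` (group1 over
#'   group2) or `"down"`.
#' @param ... Passed to [permutation_test()] in mode `"fdr"`.
#' @return data.table with `gene_id`, `mean_group1`, `mean_group2`,
#'   `fold_change`, and (mode `"fdr"`) `d`, `p`, `fdr`; one row per
#'   selected gene.
#' @export
de_genes <- function(mat, labels, mode = c("fc", "fdr"), fc_cutoff = 2,
                     fdr_cutoff = 0.05, pseudo = 0.3,
                     direction = c("both", "up", "down"), ...) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  mat <- as.matrix(mat)
  if (nrow(mat) == 0L)
    return(data.table(gene_id = character(), mean_group1 = numeric(),
                      mean_group2 = numeric(), fold_change = numeric()))
  if (is.null(rownames(mat))) rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("two groups are required")
  m1 <- rowMeans(mat[, labels == lv[1L], drop = FALSE])
  m2 <- rowMeans(mat[, labels == lv[2L], drop = FALSE])
  fc <- fold_change(m1, m2, pseudo)

  if (mode == "fc") {
    detected <- rowSums(mat > 0) > 0L
    sel <- switch(direction,
                  both = fc > fc_cutoff | fc < 1 / fc_cutoff,
                  up = fc > fc_cutoff,
                  down = fc < 1 / fc_cutoff)
    sel <- sel & detected
    out <- data.table(gene_id = rownames(mat)[sel],
                      mean_group1 = m1[sel], mean_group2 = m2[sel],
                      fold_change = fc[sel])
  } else {
    pt <- permutation_test(mat, labels, ...)
    sel <- pt$fdr < fdr_cutoff
    out <- data.table(gene_id = rownames(mat)[sel],
                      mean_group1 = m1[sel], mean_group2 = m2[sel],
                      fold_change = fc[sel], d = pt$d[sel], p = pt$p[sel],
                      fdr = pt$fdr[sel])
  }
  data.table::setorder(out, gene_id)
  out[]
}
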