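# exon-union counting, masking, RPKM, small-RNA filter, TMM

test_that("multi-gene masking removes shared bp and updates lengths", {
  # two genes sharing [51,100] of [1,100] and [51,150]
  ex <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                   start = c(1L, 51L), end = c(100L, 150L), strand = "+")
  gm <- mask_name_overlaps(gene_models(ex, "g"))
  expect_equal(sort(gm$genes$effective_length), c(50L, 50L))
  expect_equal(gm$dropped, character())

  # disjoint genes unchanged
  ex2 <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                    start = c(1L, 201L), end = c(100L, 300L), strand = "+")
  gm2 <- mask_name_overlaps(gene_models(ex2, "g"))
  expect_equal(gm2$genes$effective_length, c(100L, 100L))

  # an identical duplicated gene masks away entirely: both dropped
  ex3 <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                    start = 1L, end = 100L, strand = "+")
  gm3 <- mask_name_overlaps(gene_models(ex3, "g"))
  expect_equal(nrow(gm3$genes), 0L)
  expect_equal(gm3$dropped, c("G1", "G2"))

  # idempotent
  gm_again <- mask_name_overlaps(gm)
  expect_equal(gm_again$genes, gm$genes)
})

test_that("read counting follows the 1-bp overlap rule with masking", {
  ex <- data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
                   start = c(1L, 51L), end = c(100L, 150L), strand = "+")
  gm <- mask_name_overlaps(gene_models(ex, "g"))
  asn <- data.frame(read_id = c("r1", "r2", "r3"),
                    label = "g", reason = "unique_only")
  obs <- rbind(
    obs_row("g", TRUE, TRUE, 0, read_id = "r1", start = 11, end = 60),
    obs_row("g", TRUE, TRUE, 0, read_id = "r2", start = 60, end = 95),
    obs_row("g", TRUE, TRUE, 0, read_id = "r3", start = 101, end = 140))
  res <- count_reads(asn, obs, gm)
  # r1 overlaps G1's retained [1,50] by 40 bp -> G1; r2 lies entirely in
  # the masked shared region -> uncounted; r3 in G2's retained [101,150]
  expect_equal(res$counts, c(G1 = 1L, G2 = 1L))
  expect_equal(res$n_counted, 2L)
})

test_that("randomized counting matches the brute-force overlap oracle", {
  set.seed(31)
  for (rep in 1:3) {
    n_genes <- 6
    ex <- data.frame(
      gene_id = rep(sprintf("G%d", 1:n_genes), each = 2),
      chrom = "chr1",
      start = sort(sample(1:900, n_genes * 2)),
      end = 0L, strand = "+")
    ex$end <- ex$start + sample(20:80, n_genes * 2, TRUE)
    gm <- mask_name_overlaps(gene_models(ex, "g"))
    n_reads <- 60
    reads <- data.frame(
      read_id = sprintf("r%03d", 1:n_reads), chrom = "chr1",
      start = sample(1:950, n_reads, TRUE))
    reads$end <- reads$start + 49L
    asn <- data.frame(read_id = reads$read_id, label = "g",
                      reason = "unique_only")
    obs <- data.frame(read_id = reads$read_id, genome_id = "g",
                      aligned = TRUE, unique = TRUE, mismatches = 0L,
                      chrom = reads$chrom, start = reads$start,
                      end = reads$end, strand = "+")
    got <- count_reads(asn, obs, gm)$counts
    # oracle works on the masked exon set
    mex <- data.frame(
      gene_id = S4Vectors::mcols(gm$exons)$gene_id,
      chrom = as.character(GenomicRanges::seqnames(gm$exons)),
      start = GenomicRanges::start(gm$exons),
      end = GenomicRanges::end(gm$exons))
    want <- brute_counts(reads, mex)
    expect_equal(got[sort(names(got))], want[sort(names(want))])
  }
})

test_that("rpkm unit case, zeros and scale invariance", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  cts <- matrix(c(10, 0, 5, 20), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  r1 <- rpkm(cts, c(500, 2000), c(1e5, 2e5))
  r2 <- rpkm(3 * cts, c(500, 2000), 3 * c(1e5, 2e5))
  expect_equal(r1, r2)
  expect_true(all((r1 == 0) == (cts == 0)))
})

test_that("small RNA filtering removes miRNA/snoRNA by biotype or symbol", {
  ex <- data.frame(
    gene_id = c("MIR21", "SNORD14", "MIRROR1", "Mirlet7a", "ACTB", "X1"),
    chrom = "chr1", start = seq(1, 501, 100),
    end = seq(60, 560, 100), strand = "+",
    biotype_hint = c("", "", "", "", "protein_coding", "miRNA"))
  gm <- filter_small_rna(gene_models(ex, "g"))
  expect_equal(sort(gm$genes$gene_id), c("ACTB", "MIRROR1"))
})

test_that("detection cutoff", {
  expect_true(detected_genes(1))
  expect_false(detected_genes(0))
  expect_false(detected_genes(1, cutoff = 2))
})

test_that("TMM: identical samples and a global 2x shift give closed forms", {
  set.seed(2)
  v <- rlnorm(200, meanlog = 2)
  m <- cbind(s1 = v, s2 = v)
  expect_equal(unname(tmm_factors(m)), c(1, 1))

  m2 <- cbind(s1 = v, s2 = 2 * v)
  f <- tmm_factors(m2, reference = "s1")
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))
  expect_equal(exp(mean(log(f))), 1)
})

test_that("TMM factors match the direct trimmed weighted mean formula", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rlnorm(300 * 3, meanlog = 1, sdlog = 1.2), 300, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    m[sample(length(m), 40)] <- 0
    f <- tmm_factors(m, reference = "a")
    raw <- c(1, naive_tmm_pair(m[, "b"], m[, "a"]),
             naive_tmm_pair(m[, "c"], m[, "a"]))
    want <- raw / exp(mean(log(raw)))
    expect_equal(unname(f), want, tolerance = 1e-9)
  }
})

test_that("TMM agrees with edgeR on a counts matrix", {
  skip_if_not_installed("edgeR")
  set.seed(4)
  # equal library sizes so edgeR's lib-size scaling is a no-op and its
  # binomial weights approach the delta-method weights
  n <- 2000
  base <- rlnorm(n, 5, 1)
  cts <- cbind(s1 = rpois(n, base), s2 = rpois(n, base * 1.6))
  ours <- tmm_factors(cts, reference = "s1")
  theirs <- edgeR::calcNormFactors(cts, method = "TMM", refColumn = 1)
  lib <- colSums(cts)
  # edgeR factors normalize counts/lib; express ours on the same scale
  ours_lib <- tmm_factors(t(t(cts) / lib), reference = "s1")
  expect_equal(unname(ours_lib), unname(theirs), tolerance = 0.02)
})

test_that("TMM input validation", {
  expect_error(tmm_factors(matrix(1, 3, 1)), "two samples")
  m <- cbind(s1 = c(1, 2, 3), s2 = c(0, 0, 0))
  expect_error(tmm_factors(m), "s2")
})

test_that("expression_matrix pipeline on a small simulated sample", {
  fx <- small_sim_fixture(seed = 21, n_reads = 1500)
  asn <- assign_all(fx$obs)
  gmA <- gene_models(fx$sim$annotation, "genomeA")
  em <- expression_matrix(list(s1 = asn$assignments),
                          list(s1 = fx$obs$genomeA), gmA)
  expect_s3_class(em, "expression_matrix")
  # count conservation: total counted <= species-assigned reads
  expect_lte(sum(em$counts), asn$counts[["genomeA"]])
  expect_true(all((em$rpkm == 0) == (em$counts == 0)))
  expect_equal(unname(em$tmm_factor), 1)  # single sample
})
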