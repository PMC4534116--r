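# Independent reference implementations used as oracles by the tests.
# They are deliberately scalar/brute-force and share no code with the
# package internals.

# observation row builder
obs_row <- function(genome_id, aligned, unique = FALSE, m = NA_integer_,
                    read_id = "r1", chrom = "chr1", start = 1L,
                    end = 50L, strand = "+") {
  data.frame(read_id = read_id, genome_id = genome_id, aligned = aligned,
             unique = unique, mismatches = as.integer(m), chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             strand = strand, stringsAsFactors = FALSE)
}

# scalar truth-table classifier for the two-genome decision procedure,
# written straight from the stated rules
oracle_classify2 <- function(alnA, uniA, mA, alnB, uniB, mB,
                             Mu, Ms, D, strict = FALSE) {
  if (!alnA && !alnB) return(c("unassigned", "unaligned"))
  if (alnA && !alnB) {
    if (!uniA) return(c("ambiguous", "not_unique"))
    if (mA <= Mu) return(c("genomeA", "unique_only"))
    return(c("unassigned", "too_many_mismatches"))
  }
  if (!alnA && alnB) {
    if (!uniB) return(c("ambiguous", "not_unique"))
    if (mB <= Mu) return(c("genomeB", "unique_only"))
    return(c("unassigned", "too_many_mismatches"))
  }
  # aligned in both genomes
  if (strict) return(c("ambiguous", "shared_tie"))
  if (mA == mB) return(c("ambiguous", "shared_tie"))
  if (mA < mB) {
    if (!uniA) return(c("ambiguous", "not_unique"))
    if (mA <= Ms && (mB - mA) >= D)
      return(c("genomeA", "rescued_by_difference"))
    return(c("ambiguous", "shared_tie"))
  }
  if (!uniB) return(c("ambiguous", "not_unique"))
  if (mB <= Ms && (mA - mB) >= D)
    return(c("genomeB", "rescued_by_difference"))
  c("ambiguous", "shared_tie")
}

# every per-genome alignment state for the enumeration grids:
# unaligned, or aligned {unique, multimapped} x mismatches 0..4
genome_states <- function(max_m = 4L) {
  states <- list(list(aligned = FALSE, unique = FALSE, m = NA_integer_))
  for (u in c(TRUE, FALSE)) {
    for (m in 0:max_m) {
      states[[length(states) + 1L]] <-
        list(aligned = TRUE, unique = u, m = m)
    }
  }
  states
}

# naive full-scan ungapped aligner (both strands), best placements only
revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

naive_align <- function(read, genome, k) {
  L <- nchar(genome)
  gv <- strsplit(genome, "")[[1L]]
  best <- k + 1L
  hits <- data.frame(pos = integer(), strand = character(),
                     nm = integer(), stringsAsFactors = FALSE)
  for (st in c("+", "-")) {
    rs <- if (st == "+") read else revcomp_chr(read)
    rv <- strsplit(rs, "")[[1L]]
    w <- length(rv)
    if (w > L) next
    for (p in 1:(L - w + 1L)) {
      m <- sum(gv[p:(p + w - 1L)] != rv)
      if (m <= k)
        hits <- rbind(hits, data.frame(pos = p, strand = st, nm = m,
                                       stringsAsFactors = FALSE))
    }
  }
  if (nrow(hits) == 0L) return(hits)
  hits[hits$nm == min(hits$nm), , drop = FALSE]
}

# direct trimmed weighted mean TMM (one pair), written from the formula
naive_tmm_pair <- function(obs, ref, trimM = 0.3, trimA = 0.05) {
  ok <- obs > 0 & ref > 0
  obs <- obs[ok]; ref <- ref[ok]
  M <- log2(obs / ref)
  A <- 0.5 * log2(obs * ref)
  w <- 1 / (1 / obs + 1 / ref)
  n <- length(M)
  loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

# brute-force overlap counting: read counted to the gene with the largest
# 1d interval overlap with any part of its exon set (ties: first gene id)
brute_counts <- function(reads, exons) {
  genes <- sort(unique(exons$gene_id))
  counts <- setNames(integer(length(genes)), genes)
  for (i in seq_len(nrow(reads))) {
    ov <- setNames(numeric(length(genes)), genes)
    for (g in genes) {
      ex <- exons[exons$gene_id == g & exons$chrom == reads$chrom[i], ,
                  drop = FALSE]
      if (nrow(ex) == 0L) next
      ov[g] <- sum(pmax(0L, pmin(ex$end, reads$end[i]) -
                          pmax(ex$start, reads$start[i]) + 1L))
    }
    if (max(ov) >= 1) {
      win <- genes[which(ov == max(ov))][1L]
      counts[win] <- counts[win] + 1L
    }
  }
  counts
}

# exhaustive hypergeometric upper tail from binomial coefficients
brute_hyper_tail <- function(k, n1, n2, N) {
  js <- k:min(n1, n2)
  sum(choose(n1, js) * choose(N - n1, n2 - js)) / choose(N, n2)
}

# tiny simulated two-genome observation + truth set built from the
# package simulator through files (used by several modules)
small_sim_fixture <- function(seed = 7L, n_reads = 2000L,
                              divergence = 0.1, genome_length = 10000L,
                              n_genes = 20L, mix = 0.5) {
  cfg <- sim_config(genome_length_bp = genome_length, n_genes = n_genes,
                    n_reads = n_reads, divergence = divergence,
                    mix_proportion = mix, seed = seed)
  sim <- simulate_genomes(cfg)
  rs <- simulate_reads(sim, "s1", seed = seed + 100L)
  obs <- lapply(setNames(names(sim$genomes), names(sim$genomes)),
                function(g) {
    al <- oracle_align(rs$reads, sim$genomes[[g]], cfg$max_mismatch)
    f <- tempfile(fileext = ".sam")
    write_sam(al, rs$reads, nchar(sim$genomes[[g]]), f)
    read_alignments(f, g)
  })
  list(cfg = cfg, sim = sim, reads = rs$reads, truth = rs$truth,
       obs = obs)
}
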