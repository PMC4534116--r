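#' Simulation configuration
#'
#' Parameters of the synthetic two- (or three-) species benchmark:
#' orthologous toy genomes, transcript models, and error-bearing
#' single-end reads with per-read truth labels.
#'
#' @param genome_length_bp Genome length (default 50000 bp; the exhaustive
#'   oracle aligner is designed for genomes up to a few hundred kb).
#' @param n_genes Number of genes (default 100), laid out in
#'   non-overlapping windows.
#' @param exons_per_gene Integer range (min, max) of exons per gene
#'   (default `c(1, 3)`); every exon is at least as long as a read so
#'   reads never span junctions (the oracle aligner is ungapped).
#' @param divergence Per-bp substitution rate between orthologous genomes
#'   (default 0.10, emulating human/mouse exonic sequence divergence,
#'   where roughly 85-90 % of coding positions are identical).
#' @param error_rate Per-bp sequencing substitution error rate (default
#'   0.005).
#' @param read_length Read length in bp (default 50, typical short
#'   single-end RNA-seq).
#' @param n_reads Reads per simulated sample (default 50000).
#' @param mix_proportion Proportion of reads from genome A in a mixed
#'   sample (default 0.5).
#' @param n_genomes 2 or 3 orthologous genomes (default 2).
#' @param max_mismatch Mismatch ceiling of the oracle aligner (default
#'   10, the usual short-read aligner default).
#' @param seed Integer seed; every downstream draw is derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length_bp = 50000L, n_genes = 100L,
                       exons_per_gene = c(1L, 3L), divergence = 0.10,
                       error_rate = 0.005, read_length = 50L,
                       n_reads = 50000L, mix_proportion = 0.5,
                       n_genomes = 2L, max_mismatch = 10L, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 1,
            error_rate >= 0, error_rate <= 1,
            mix_proportion >= 0, mix_proportion <= 1,
            read_length >= 1, n_genomes %in% c(2L, 3L))
  structure(list(genome_length_bp = as.integer(genome_length_bp),
                 n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 divergence = divergence, error_rate = error_rate,
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads),
                 mix_proportion = mix_proportion,
                 n_genomes = as.integer(n_genomes),
                 max_mismatch = as.integer(max_mismatch),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")

# sample one element of x (avoids base sample()'s scalar expansion)
.sample1 <- function(x) x[sample.int(length(x), 1L)]

.rand_seq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                               collapse = "")

.mutate_seq <- function(seq, rate) {
  if (rate == 0) return(list(seq = seq, positions = integer()))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- .sample1(setdiff(.BASES, chars[i]))
  }
  list(seq = paste(chars, collapse = ""), positions = hit)
}

#' Simulate orthologous toy genomes and transcript models
#'
#' Genome A is random sequence; each further genome is derived from A by
#' independent per-bp substitutions at the configured divergence, so gene
#' coordinates are identical across genomes (perfect orthologs). Genes are
#' placed in non-overlapping windows, each with 1 or more exons at least
#' one read length long, on randomly chosen strands. Per-gene expression
#' weights (lognormal, heavy-tailed like real transcriptomes) are drawn
#' once per genome and reused by every sample simulated from the object,
#' so repeated samples share a biological state.
#'
#' @param config A [sim_config()] object.
#' @return A `sim_truth` list: `genomes` (named character sequences),
#'   `annotation` (data.table of exons: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, 1-based closed), `gene_weights` (named list per
#'   genome), `substitutions` (positions mutated per derived genome),
#'   `config`.
#' @export
simulate_genomes <- function(config = sim_config()) {
  set.seed(config$seed)
  L <- config$genome_length_bp
  gA <- .rand_seq(L)
  genome_ids <- c("genomeA", "genomeB", "genomeC")[seq_len(config$n_genomes)]
  genomes <- list(genomeA = gA)
  substitutions <- list()
  for (g in genome_ids[-1L]) {
    mut <- .mutate_seq(gA, config$divergence)
    genomes[[g]] <- mut$seq
    substitutions[[g]] <- mut$positions
  }

  # gene layout: one gene per window of the genome
  rl <- config$read_length
  win <- L %/% config$n_genes
  min_exon <- max(rl, 60L)
  exons <- list()
  for (i in seq_len(config$n_genes)) {
    lo <- (i - 1L) * win + 1L
    hi <- i * win
    n_ex <- .sample1(seq(config$exons_per_gene[1L],
                         config$exons_per_gene[2L]))
    # shrink exon count until they fit with >= 10 bp gaps
    while (n_ex > 1L && n_ex * min_exon + (n_ex - 1L) * 10L > (hi - lo - 10L))
      n_ex <- n_ex - 1L
    space <- (hi - lo + 1L)
    max_exon <- min(200L, (space - (n_ex - 1L) * 10L) %/% n_ex)
    len_range <- seq(min_exon, max(min_exon, max_exon))
    ex_len <- len_range[sample.int(length(len_range), n_ex,
                                   replace = TRUE)]
    slack <- space - sum(ex_len) - (n_ex - 1L) * 10L
    offset <- if (slack > 0L) sample.int(slack, 1L) else 1L
    starts <- integer(n_ex)
    cur <- lo + offset - 1L
    for (j in seq_len(n_ex)) {
      starts[j] <- cur
      cur <- cur + ex_len[j] + 10L
    }
    exons[[i]] <- data.table(
      gene_id = sprintf("gene%03d", i), chrom = "chr1",
      start = starts, end = starts + ex_len - 1L,
      strand = .sample1(c("+", "-")), biotype_hint = "protein_coding")
  }
  annotation <- data.table::rbindlist(exons)

  gene_weights <- lapply(genome_ids, function(g)
    setNames(rlnorm(config$n_genes, meanlog = 0, sdlog = 1),
             sprintf("gene%03d", seq_len(config$n_genes))))
  names(gene_weights) <- genome_ids

  structure(list(genomes = genomes, annotation = annotation,
                 gene_weights = gene_weights,
                 substitutions = substitutions, config = config),
            class = "sim_truth")
}

#' Simulate expression-weighted error-bearing reads with truth labels
#'
#' Reads are drawn gene-wise with the object's per-genome expression
#' weights, exon-wise proportional to the number of valid start positions,
#' and uniformly within the exon; the species of each read is Bernoulli in
#' the mix proportion. Substitution errors are injected per bp. Reads from
#' minus-strand genes are reverse-complemented. No read spans an exon
#' junction (exons are at least one read length long by construction).
#'
#' @param sim A `sim_truth` object from [simulate_genomes()].
#' @param sample_id Sample name, used as read-id prefix.
#' @param n_reads,mix_proportion,error_rate,read_length Override the
#'   values in `sim$config`.
#' @param seed Seed for this sample's draws (default derived from the
#'   config seed).
#' @return List with `reads` (named character vector of sequences) and
#'   `truth` (data.table: `read_id`, `genome_id`, `gene_id`,
#'   `true_position` (1-based genomic start), `strand`,
#'   `n_errors_injected`).
#' @export
simulate_reads <- function(sim, sample_id = "sample1",
                           n_reads = sim$config$n_reads,
                           mix_proportion = sim$config$mix_proportion,
                           error_rate = sim$config$error_rate,
                           read_length = sim$config$read_length,
                           seed = sim$config$seed + 1L) {
  stopifnot(inherits(sim, "sim_truth"))
  set.seed(seed)
  genome_ids <- names(sim$genomes)
  ann <- sim$annotation
  rl <- read_length

  # per-exon table with number of valid read start positions
  ex <- data.table::copy(ann)
  ex[, `:=`(n_starts = pmax(0L, (end - start + 1L) - rl + 1L))]
  ex <- ex[ex$n_starts > 0L, ]
  if (nrow(ex) == 0L) stop("read_length exceeds every exon length")

  # species of origin per read
  if (length(genome_ids) == 2L) {
    from_a <- runif(n_reads) < mix_proportion
    origin <- ifelse(from_a, genome_ids[1L], genome_ids[2L])
  } else {
    pr <- c(mix_proportion, rep((1 - mix_proportion) /
                                  (length(genome_ids) - 1L),
                                length(genome_ids) - 1L))
    origin <- sample(genome_ids, n_reads, replace = TRUE, prob = pr)
  }

  reads <- character(n_reads)
  seq_chars <- lapply(sim$genomes, function(g)
    strsplit(g, "", fixed = TRUE)[[1L]])

  out_gene <- character(n_reads)
  out_pos <- integer(n_reads)
  out_strand <- character(n_reads)
  out_err <- integer(n_reads)

  for (g in genome_ids) {
    ridx <- which(origin == g)
    if (length(ridx) == 0L) next
    w_gene <- sim$gene_weights[[g]]
    # exon sampling weight: gene weight split over its exons by start count
    ex_w <- w_gene[ex$gene_id] * ex$n_starts /
      tapply(ex$n_starts, ex$gene_id, sum)[ex$gene_id]
    pick <- sample.int(nrow(ex), length(ridx), replace = TRUE,
                       prob = ex_w)
    offs <- floor(runif(length(ridx)) * ex$n_starts[pick])
    pos <- ex$start[pick] + as.integer(offs)
    chars <- seq_chars[[g]]
    nerr <- rbinom(length(ridx), rl, error_rate)
    frag_mat <- matrix(chars[rep(pos, each = rl) +
                               rep.int(0:(rl - 1L), length(ridx))],
                       nrow = rl)
    for (j in which(nerr > 0L)) {
      at <- sample.int(rl, nerr[j])
      for (a in at)
        frag_mat[a, j] <- .sample1(setdiff(.BASES, frag_mat[a, j]))
    }
    seqs <- apply(frag_mat, 2L, paste, collapse = "")
    minus <- ex$strand[pick] == "-"
    if (any(minus))
      seqs[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[minus])))
    reads[ridx] <- seqs
    out_gene[ridx] <- ex$gene_id[pick]
    out_pos[ridx] <- pos
    out_strand[ridx] <- ex$strand[pick]
    out_err[ridx] <- nerr
  }

  ids <- sprintf("%s_r%06d", sample_id, seq_len(n_reads))
  names(reads) <- ids
  truth <- data.table(read_id = ids, genome_id = origin,
                      gene_id = out_gene, true_position = out_pos,
                      strand = out_strand, n_errors_injected = out_err)
  list(reads = reads, truth = truth)
}

#' Exhaustively align reads against a toy genome
#'
#' Enumerates, on both strands, every ungapped placement of each read with
#' at most `max_mismatch` substitutions (non-ACGT positions always
#' mismatch), and reports the best placement(s): minimal mismatch count,
#' with the number of co-optimal placements in the `NH` tag. A uniquely
#' best placement gets mapping quality 255, multimapped reads 3 — the
#' convention consumed by [read_alignments()]. Exactness is guaranteed by
#' pigeonhole seeding, so results match a naive full scan.
#'
#' @param reads Named character vector of read sequences.
#' @param genome Genome sequence (single chromosome, character scalar).
#' @param max_mismatch Mismatch ceiling (default 10).
#' @param chrom Chromosome name used in output records (default "chr1").
#' @return data.table of alignment records: `read_id`, `flag`, `chrom`,
#'   `pos` (1-based), `mapq`, `nm`, `nh`, `strand`; unmapped reads carry
#'   flag 4 and `NA` coordinates. Multiple best placements yield multiple
#'   records (secondaries flagged 0x100).
#' @export
oracle_align <- function(reads, genome, max_mismatch = 10L,
                         chrom = "chr1") {
  if (length(genome) != 1L || !is.character(genome))
    stop("genome must be a single character string")
  if (is.null(names(reads)) && length(reads) > 0L)
    names(reads) <- sprintf("read%06d", seq_along(reads))
  hits <- .oracle_scan_cpp(unname(reads), genome, as.integer(max_mismatch))
  dt <- as.data.table(hits)
  if (nrow(dt) == 0L)
    return(data.table(read_id = character(), flag = integer(),
                      chrom = character(), pos = integer(),
                      mapq = integer(), nm = integer(), nh = integer(),
                      strand = character()))
  dt[, read_id := names(reads)[dt$read]]
  mapped <- !is.na(dt$pos)
  # secondary flag for all but the first record of a multimapped read
  first <- !duplicated(dt$read)
  flag <- integer(nrow(dt))
  flag[mapped & dt$forward == 0L] <- bitwOr(flag[mapped & dt$forward == 0L],
                                            16L)
  flag[mapped & !first] <- bitwOr(flag[mapped & !first], 256L)
  flag[!mapped] <- 4L
  out <- data.table(
    read_id = dt$read_id,
    flag = flag,
    chrom = ifelse(mapped, chrom, NA_character_),
    pos = dt$pos,
    mapq = ifelse(!mapped, 0L, ifelse(dt$nh == 1L, 255L, 3L)),
    nm = dt$nm,
    nh = dt$nh,
    strand = ifelse(!mapped, NA_character_,
                    ifelse(dt$forward == 1L, "+", "-")))
  out
}

#' Write oracle alignments as a SAM file
#'
#' @param alignments Record table from [oracle_align()].
#' @param reads The named read sequences that were aligned (sequence and
#'   quality columns of the SAM records).
#' @param genome_length Reference length for the `@SQ` header line.
#' @param path Output path (plain-text SAM).
#' @param chrom Reference name (default "chr1").
#' @return Invisibly, the path.
#' @export
write_sam <- function(alignments, reads, genome_length, path,
                      chrom = "chr1") {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom,
                      as.integer(genome_length)))
  if (nrow(alignments) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  seqs <- unname(reads[alignments$read_id])
  rev <- !is.na(alignments$strand) & alignments$strand == "-"
  if (any(rev))
    seqs[rev] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[rev])))
  qual <- vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1L))
  mapped <- !is.na(alignments$pos)
  cigar <- ifelse(mapped, paste0(nchar(seqs), "M"), "*")
  lines <- paste(
    alignments$read_id,
    alignments$flag,
    ifelse(mapped, alignments$chrom, "*"),
    ifelse(mapped, alignments$pos, 0L),
    alignments$mapq,
    cigar,
    "*", 0L, 0L,
    seqs, qual,
    sep = "\t")
  tags <- ifelse(mapped,
                 sprintf("\tNM:i:%d\tNH:i:%d", alignments$nm,
                         alignments$nh),
                 "")
  writeLines(c(header, paste0(lines, tags)), path)
  invisible(path)
}

#' Write sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write reads as FASTQ with constant quality
#' @param reads Named character vector of read sequences.
#' @param path Output path (uncompressed).
#' @return Invisibly, the path.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1L))
  lines <- as.vector(rbind(paste0("@", names(reads)),
                           unname(reads), "+", unname(qual)))
  writeLines(lines, path)
  invisible(path)
}

#' Write gene models as a refFlat annotation file
#'
#' Each gene is written as a single transcript whose exons are the gene's
#' exon intervals (converted to refFlat's 0-based half-open convention).
#'
#' @param annotation Exon table (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`; 1-based closed).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_refflat <- function(annotation, path) {
  ann <- as.data.table(annotation)
  data.table::setorder(ann, gene_id, start)
  per_gene <- ann[, .(
    chrom = chrom[1L], strand = strand[1L],
    tx_start = min(start) - 1L, tx_end = max(end),
    n_exon = .N,
    ex_starts = paste0(paste(start - 1L, collapse = ","), ","),
    ex_ends = paste0(paste(end, collapse = ","), ",")),
    by = gene_id]
  lines <- with(per_gene, paste(
    gene_id, paste0(gene_id, ".t1"), chrom, strand, tx_start, tx_end,
    tx_start, tx_end, n_exon, ex_starts, ex_ends, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a complete on-disk benchmark fixture
#'
#' One call simulates genomes, a mixed sample and one pure sample per
#' species, aligns every sample's reads against every genome with the
#' oracle aligner, and writes FASTA genomes, refFlat annotations, FASTQ
#' reads, SAM alignments, truth tables and a manifest JSON recording the
#' configuration, so the full separation pipeline can run from files
#' alone.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @param pure_samples Also generate one single-species sample per genome
#'   (default `TRUE`; needed for mixing-fidelity analysis).
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
end_to_end_fixture <- function(config = sim_config(), dir,
                               pure_samples = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genomes(config)
  genome_ids <- names(sim$genomes)

  files <- list()
  for (g in genome_ids) {
    fa <- file.path(dir, paste0(g, ".fa"))
    write_fasta(setNames(sim$genomes[[g]], "chr1"), fa)
    rf <- file.path(dir, paste0(g, ".refflat"))
    write_refflat(sim$annotation, rf)
    files[[g]] <- list(fasta = fa, refflat = rf)
  }

  samples <- list(mixed = list(mix = config$mix_proportion, seed_off = 1L))
  if (pure_samples) {
    for (i in seq_along(genome_ids)) {
      mp <- if (i == 1L) 1 else 0
      if (length(genome_ids) == 3L && i >= 2L) {
        # three-genome mode: pure samples via origin forcing below
      }
      samples[[paste0("pure_", genome_ids[i])]] <-
        list(mix = mp, seed_off = 1L + i, force = genome_ids[i])
    }
  }

  manifest <- list(config = unclass(config), genomes = genome_ids,
                   samples = list())
  for (s in names(samples)) {
    sp <- samples[[s]]
    rs <- simulate_reads(sim, sample_id = s,
                         mix_proportion = sp$mix,
                         seed = config$seed + sp$seed_off)
    if (!is.null(sp$force) && length(genome_ids) > 2L) {
      # re-label: draw all reads from the forced genome
      rs <- .force_origin(sim, s, sp$force, config)
    }
    fq <- file.path(dir, paste0(s, ".fastq"))
    write_fastq(rs$reads, fq)
    tt <- file.path(dir, paste0(s, ".truth.tsv"))
    write_table(rs$truth, tt)
    sams <- list()
    for (g in genome_ids) {
      aln <- oracle_align(rs$reads, sim$genomes[[g]],
                          max_mismatch = config$max_mismatch)
      sam <- file.path(dir, paste0(s, ".", g, ".sam"))
      write_sam(aln, rs$reads, nchar(sim$genomes[[g]]), sam)
      sams[[g]] <- sam
    }
    manifest$samples[[s]] <- list(fastq = fq, truth = tt,
                                  alignments = sams,
                                  n_reads = length(rs$reads))
  }
  manifest$genome_files <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.force_origin <- function(sim, sample_id, genome, config) {
  # pure sample for a non-first genome: origin fixed, weights of that genome
  ids <- names(sim$genomes)
  stopifnot(genome %in% ids)
  # temporarily reorder so the forced genome is "A" with mix 1
  sim2 <- sim
  sim2$genomes <- sim$genomes[c(genome, setdiff(ids, genome))]
  sim2$gene_weights <- sim$gene_weights[c(genome, setdiff(ids, genome))]
  simulate_reads(sim2, sample_id = sample_id, mix_proportion = 1,
                 seed = config$seed + match(genome, ids) + 1L)
}
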