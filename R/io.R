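#' Read per-read alignment evidence from a SAM/BAM file
#'
#' Parses one genome's alignments into a table of per-read alignment
#' observations: whether the read aligned, whether the best alignment is
#' unique, and the edit distance (`NM` tag) of the best alignment.
#' Multimapping within the genome is collapsed to a single observation
#' carrying the smallest `NM`; the uniqueness flag records that the read
#' multimapped. Unmapped records yield `aligned = FALSE`.
#'
#' @param file Path to a SAM or BAM file. SAM input is converted on the fly.
#' @param genome_id Identifier of the genome the reads were aligned to
#'   (e.g. `"human"`, `"mouse"`).
#' @param uniqueness_rule How alignment uniqueness is encoded:
#'   `"mapq255"` (mapping quality 255 marks a unique alignment, the STAR
#'   convention) or `"nh_tag"` (`NH` tag equal to 1).
#' @return A `data.table` with one row per distinct read present in the
#'   file: `read_id`, `genome_id`, `aligned`, `unique`, `mismatches`
#'   (`NA` when unaligned), `chrom`, `start`, `end` (1-based, closed,
#'   reference coordinates of the best alignment), `strand`.
#' @export
read_alignments <- function(file, genome_id,
                            uniqueness_rule = c("mapq255", "nh_tag")) {
  uniqueness_rule <- match.arg(uniqueness_rule)
  if (!file.exists(file)) stop("alignment file not found: ", file)
  bam <- .as_bam(file)

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"),
    tag = c("NM", "NH"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)

  aln <- data.table(
    read_id = S4Vectors::mcols(ga)$qname,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga),
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    mapq = S4Vectors::mcols(ga)$mapq,
    nm = S4Vectors::mcols(ga)$NM,
    nh = S4Vectors::mcols(ga)$NH)

  if (nrow(aln) > 0L && anyNA(aln$nm)) {
    bad <- aln$read_id[which(is.na(aln$nm))[1L]]
    stop("aligned record without NM (edit distance) tag for read '",
         bad, "' in ", file)
  }

  # unmapped reads, recorded so every read in the file yields an observation
  un_param <- Rsamtools::ScanBamParam(
    what = "qname",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE))
  un <- unique(Rsamtools::scanBam(bam, param = un_param)[[1L]]$qname)

  if (nrow(aln) > 0L) {
    unique_flag <- if (uniqueness_rule == "mapq255") {
      aln$mapq == 255L
    } else {
      if (anyNA(aln$nh))
        stop("NH tag required for uniqueness_rule = 'nh_tag' but missing in ",
             file)
      aln$nh == 1L
    }
    aln[, `:=`(u = unique_flag)]
    n_aln <- aln[, .N, by = read_id]
    data.table::setorder(aln, read_id, nm)
    obs <- aln[, .SD[1L], by = read_id]
    obs <- merge(obs, n_aln, by = "read_id")
    out <- data.table(
      read_id = obs$read_id,
      genome_id = genome_id,
      aligned = TRUE,
      unique = obs$u & obs$N == 1L,
      mismatches = as.integer(obs$nm),
      chrom = obs$chrom,
      start = obs$start,
      end = obs$end,
      strand = obs$strand)
  } else {
    out <- .empty_observations(genome_id)
  }

  un <- setdiff(un, out$read_id)
  if (length(un) > 0L) {
    out <- rbind(out, data.table(
      read_id = un, genome_id = genome_id, aligned = FALSE, unique = FALSE,
      mismatches = NA_integer_, chrom = NA_character_, start = NA_integer_,
      end = NA_integer_, strand = NA_character_))
  }
  data.table::setorder(out, read_id)
  out[]
}

.empty_observations <- function(genome_id) {
  data.table(
    read_id = character(), genome_id = character(), aligned = logical(),
    unique = logical(), mismatches = integer(), chrom = character(),
    start = integer(), end = integer(), strand = character())
}

.as_bam <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "bam") return(file)
  dest <- tempfile(fileext = "")
  tryCatch(
    Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                     indexDestination = FALSE),
    error = function(e) stop("could not parse SAM/BAM file ", file, ": ",
                             conditionMessage(e)))
}

#' Read gene models (exon unions) from refFlat or GTF annotation
#'
#' Transcript exons are merged across all isoforms sharing a gene identifier
#' to an exon-union model per gene. refFlat coordinates (0-based half-open)
#' and GTF coordinates (1-based closed) are converted to the 1-based closed
#' convention used throughout the package at this boundary.
#'
#' @param file Annotation file path.
#' @param genome_id Genome the annotation belongs to.
#' @param format `"refflat"` or `"gtf"`.
#' @return A `gene_models` object: list with `exons` (a
#'   [GenomicRanges::GRanges] of the per-gene exon union, metadata column
#'   `gene_id`), `genes` (data.table: `gene_id`, `biotype_hint`,
#'   `effective_length`), `genome_id`, `masked` (logical, whether
#'   multi-gene masking has been applied) and `dropped` (gene ids removed
#'   by masking).
#' @export
read_gene_models <- function(file, genome_id, format = c("refflat", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(file)) stop("annotation file not found: ", file)
  if (format == "refflat") {
    exons <- .parse_refflat(file)
  } else {
    exons <- .parse_gtf(file)
  }
  gene_models(exons, genome_id)
}

# refFlat: geneName name chrom strand txStart txEnd cdsStart cdsEnd
#          exonCount exonStarts exonEnds   (0-based half-open)
.parse_refflat <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.table(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), biotype_hint = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed refFlat line ", which(nf < 11L)[1L], " in ", file,
         " (expected 11 tab-separated fields)")
  per_tx <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    n_exon <- suppressWarnings(as.integer(f[9L]))
    starts <- suppressWarnings(as.integer(strsplit(f[10L], ",", fixed = TRUE)[[1L]]))
    ends <- suppressWarnings(as.integer(strsplit(f[11L], ",", fixed = TRUE)[[1L]]))
    if (is.na(n_exon) || anyNA(starts) || anyNA(ends) ||
        length(starts) != n_exon || length(ends) != n_exon)
      stop("malformed refFlat line ", i, " in ", file)
    data.table(gene_id = f[1L], chrom = f[3L],
               start = starts + 1L, end = ends,   # to 1-based closed
               strand = f[4L], biotype_hint = "")
  })
  data.table::rbindlist(per_tx)
}

.parse_gtf <- function(file) {
  gr <- tryCatch(rtracklayer::import(file, format = "gtf"),
                 error = function(e) stop("malformed GTF file ", file, ": ",
                                          conditionMessage(e)))
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  mc <- S4Vectors::mcols(gr)
  gid <- if (!is.null(mc$gene_name)) as.character(mc$gene_name)
         else as.character(mc$gene_id)
  if (is.null(gid) || anyNA(gid))
    stop("GTF exons without gene_name/gene_id attribute in ", file)
  bt <- if (!is.null(mc$gene_biotype)) as.character(mc$gene_biotype)
        else if (!is.null(mc$gene_type)) as.character(mc$gene_type)
        else ""
  data.table(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),   # GTF already 1-based closed
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype_hint = bt)
}

#' Construct gene models from an exon table
#'
#' @param exons data.frame/data.table with columns `gene_id`, `chrom`,
#'   `start`, `end` (1-based closed), `strand` and optionally
#'   `biotype_hint`. Exons of the same gene are unioned across isoforms.
#' @param genome_id Genome identifier.
#' @return A `gene_models` object (see [read_gene_models()]).
#' @export
gene_models <- function(exons, genome_id) {
  exons <- as.data.table(exons)
  if (nrow(exons) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene_id <- character()
    return(structure(
      list(exons = gr,
           genes = data.table(gene_id = character(),
                              biotype_hint = character(),
                              effective_length = integer()),
           genome_id = genome_id, masked = FALSE, dropped = character()),
      class = "gene_models"))
  }
  if (any(exons$end < exons$start)) stop("exon with end < start")
  if (!"biotype_hint" %in% names(exons)) exons[, biotype_hint := ""]
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand)
  S4Vectors::mcols(gr)$gene_id <- exons$gene_id
  # exon union per gene across isoforms
  grl <- GenomicRanges::reduce(S4Vectors::split(gr, exons$gene_id))
  ugr <- unlist(grl, use.names = FALSE)
  S4Vectors::mcols(ugr)$gene_id <- rep(names(grl), lengths(grl))
  len <- setNames(sum(GenomicRanges::width(grl)), names(grl))
  bt <- exons[, .(biotype_hint = biotype_hint[1L]), by = gene_id]
  genes <- data.table(gene_id = names(len),
                      effective_length = as.integer(len))
  genes <- merge(genes, bt, by = "gene_id", all.x = TRUE, sort = TRUE)
  data.table::setcolorder(genes, c("gene_id", "biotype_hint",
                                   "effective_length"))
  structure(list(exons = ugr, genes = genes, genome_id = genome_id,
                 masked = FALSE, dropped = character()),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models for genome '", x$genome_id, "': ",
      nrow(x$genes), " genes, ", length(x$exons), " exon-union intervals",
      if (x$masked) ", multi-gene regions masked" else "", "\n", sep = "")
  if (length(x$dropped))
    cat("  dropped by masking:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Write a table to TSV with a deterministic layout
#'
#' Tab-separated, header row, rows sorted by the first column, `NA`
#' serialized as `"NA"`, doubles printed with up to 10 significant digits.
#'
#' @param x data.frame to write.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_table <- function(x, path) {
  x <- as.data.frame(x)
  if (nrow(x) > 0L && ncol(x) > 0L) x <- x[order(x[[1L]]), , drop = FALSE]
  num <- vapply(x, is.double, logical(1L))
  x[num] <- lapply(x[num], function(v) {
    out <- sprintf("%.10g", v)
    out[is.na(v)] <- NA_character_
    out
  })
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path File path.
#' @param col_types Optional named character vector mapping column names to
#'   types (`"character"`, `"integer"`, `"double"`, `"logical"`).
#' @return A data.table.
#' @export
read_table <- function(path, col_types = NULL) {
  x <- as.data.table(read.delim(path, sep = "\t", header = TRUE,
                                na.strings = "NA",
                                stringsAsFactors = FALSE,
                                check.names = FALSE))
  if (!is.null(col_types)) {
    for (nm in intersect(names(col_types), names(x))) {
      x[[nm]] <- switch(col_types[[nm]],
        character = as.character(x[[nm]]),
        integer = as.integer(x[[nm]]),
        double = as.numeric(x[[nm]]),
        logical = as.logical(x[[nm]]),
        x[[nm]])
    }
  }
  x
}
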