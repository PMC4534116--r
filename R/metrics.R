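#' Read loss ratio for a single-species sample
#'
#' Quantifies how many reads a single-species control loses to
#' cross-genome ambiguity: reads that align to more than one genome and
#' end up species-ambiguous, divided by the reads aligned to the genome
#' the sample actually came from.
#'
#' @param assignments Assignment table from [assign_all()].
#' @param observations Named list of per-genome observation tables.
#' @param true_genome Genome id the sample originates from.
#' @return A single ratio (0 when no read aligns to the true genome).
#' @export
read_loss_ratio <- function(assignments, observations, true_genome) {
  if (!true_genome %in% names(observations))
    stop("true_genome '", true_genome, "' not among observed genomes")
  amb <- assignments$read_id[assignments$label == "ambiguous" &
                               assignments$n_genomes_aligned >= 2L]
  oo <- observations[[true_genome]]
  n_origin <- sum(oo$aligned)
  if (n_origin == 0L) return(0)
  length(amb) / n_origin
}

#' Misassignment rate against known read origins
#'
#' Fraction of species-assigned reads assigned to a genome other than
#' their genome of origin. Zero (not NaN) when no read is assigned at all,
#' so that degenerate inputs such as identical genomes are well defined.
#'
#' @param assignments Assignment table from [assign_all()].
#' @param truth data.frame with `read_id` and `genome_id` (true origin).
#' @return List with `rate`, `n_assigned`, `n_misassigned` and
#'   `misassigned_read_ids`.
#' @export
misassignment_rate <- function(assignments, truth) {
  truth <- as.data.table(truth)
  if (!all(c("read_id", "genome_id") %in% names(truth)))
    stop("truth table must have columns read_id and genome_id")
  a <- assignments[!assignments$label %in% c("ambiguous", "unassigned"), ]
  n_assigned <- nrow(a)
  if (n_assigned == 0L)
    return(list(rate = 0, n_assigned = 0L, n_misassigned = 0L,
                misassigned_read_ids = character()))
  origin <- truth$genome_id[match(a$read_id, truth$read_id)]
  if (anyNA(origin))
    stop("assigned read(s) missing from the truth table, e.g. '",
         a$read_id[which(is.na(origin))[1L]], "'")
  wrong <- a$label != origin
  list(rate = sum(wrong) / n_assigned,
       n_assigned = n_assigned,
       n_misassigned = sum(wrong),
       misassigned_read_ids = a$read_id[wrong])
}

#' Gene loss caused by discarding species-shared reads
#'
#' Compares gene counts quantified with cross-genome-ambiguous reads
#' retained (uniqueness-only filtering) against counts after full species
#' separation. Among genes expressed before discarding, a gene suffering
#' "full loss" drops to zero counts; "partial loss" means fewer but
#' non-zero counts.
#'
#' @param counts_keep_shared Named count vector with shared reads kept.
#' @param counts_discard_shared Named count vector after separation, same
#'   gene universe.
#' @return List with `full_loss_fraction`, `partial_loss_fraction`,
#'   `n_expressed`, `full_loss_genes`, `partial_loss_genes`.
#' @export
gene_loss <- function(counts_keep_shared, counts_discard_shared) {
  if (length(counts_keep_shared) != length(counts_discard_shared))
    stop("count vectors must cover the same gene universe")
  if (!is.null(names(counts_keep_shared)) &&
      !is.null(names(counts_discard_shared))) {
    if (!identical(sort(names(counts_keep_shared)),
                   sort(names(counts_discard_shared))))
      stop("count vectors must cover the same gene universe")
    counts_discard_shared <-
      counts_discard_shared[names(counts_keep_shared)]
  }
  expressed <- counts_keep_shared > 0
  n_exp <- sum(expressed)
  if (n_exp == 0L)
    return(list(full_loss_fraction = 0, partial_loss_fraction = 0,
                n_expressed = 0L, full_loss_genes = character(),
                partial_loss_genes = character()))
  keep <- counts_keep_shared[expressed]
  disc <- counts_discard_shared[expressed]
  full <- disc == 0
  partial <- disc > 0 & disc < keep
  list(full_loss_fraction = sum(full) / n_exp,
       partial_loss_fraction = sum(partial) / n_exp,
       n_expressed = as.integer(n_exp),
       full_loss_genes = names(keep)[full],
       partial_loss_genes = names(keep)[partial])
}

#' Expression fidelity of mixing followed by separation
#'
#' Spearman rank correlation between a pure-sample expression vector and
#' the same species' expression recovered from an in-silico mixture, over
#' genes detected (non-zero) in at least one of the two vectors. Genes
#' undetected in both are excluded so a block of zero ties does not
#' dominate the rank correlation.
#'
#' @param pure Named expression vector (e.g. RPKM) of the pure sample.
#' @param separated Named expression vector of the species component
#'   recovered from the mixture, same gene universe.
#' @return Spearman rho (ties mid-ranked); `NA` if fewer than two genes
#'   are detected.
#' @export
mix_fidelity <- function(pure, separated) {
  if (length(pure) != length(separated))
    stop("expression vectors must cover the same gene universe")
  if (!is.null(names(pure)) && !is.null(names(separated)))
    separated <- separated[names(pure)]
  keep <- pure > 0 | separated > 0
  if (sum(keep) < 2L) return(NA_real_)
  cor(pure[keep], separated[keep], method = "spearman")
}

#' Species-ambiguous read fraction
#'
#' @param assignments Assignment table from [assign_all()].
#' @return List with `of_aligned` (denominator: reads aligned to at least
#'   one genome) and `of_all` (denominator: all reads).
#' @export
ambiguous_fraction <- function(assignments) {
  n_all <- nrow(assignments)
  n_aligned <- sum(assignments$n_genomes_aligned >= 1L)
  n_amb <- sum(assignments$label == "ambiguous")
  list(of_aligned = if (n_aligned == 0L) 0 else n_amb / n_aligned,
       of_all = if (n_all == 0L) 0 else n_amb / n_all)
}

#' Summarize separation performance
#'
#' Bundles the technical metrics for one separation run: ambiguous
#' fraction (both denominators), assigned fraction, and, when a truth
#' table is supplied, the misassignment rate.
#'
#' @param assignments Assignment table from [assign_all()].
#' @param counts Named label counts from [assign_all()].
#' @param truth Optional truth table (`read_id`, `genome_id`).
#' @return A `separation_metrics` list.
#' @export
separation_metrics <- function(assignments, counts, truth = NULL) {
  amb <- ambiguous_fraction(assignments)
  genomes <- setdiff(names(counts), c("ambiguous", "unassigned"))
  n_total <- nrow(assignments)
  assigned <- sum(counts[genomes])
  out <- list(
    n_reads = n_total,
    counts = counts,
    assigned_fraction = if (n_total == 0L) 0 else assigned / n_total,
    ambiguous_fraction_of_aligned = amb$of_aligned,
    ambiguous_fraction_of_all = amb$of_all)
  if (!is.null(truth)) {
    mis <- misassignment_rate(assignments, truth)
    out$misassignment_rate <- mis$rate
    out$n_misassigned <- mis$n_misassigned
    out$misassigned_read_ids <- mis$misassigned_read_ids
  }
  structure(out, class = "separation_metrics")
}

#' @export
print.separation_metrics <- function(x, ...) {
  cat("separation metrics over", x$n_reads, "reads\n")
  cat("  labels:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = ", "), "\n")
  cat(sprintf("  assigned fraction: %.4f\n", x$assigned_fraction))
  cat(sprintf("  ambiguous fraction (of aligned): %.4f\n",
              x$ambiguous_fraction_of_aligned))
  if (!is.null(x$misassignment_rate))
    cat(sprintf("  misassignment rate: %.6f (%d reads)\n",
                x$misassignment_rate, x$n_misassigned))
  invisible(x)
}
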