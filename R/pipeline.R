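#' Pipeline configuration
#'
#' @param genomes Named list, one entry per genome (at least two), each a
#'   list with `alignment` (SAM/BAM path) and `annotation` (refFlat/GTF
#'   path) and optionally `format` (`"refflat"` default, or `"gtf"`).
#' @param params [assignment_params()] for the separation step.
#' @param out_dir Output directory.
#' @param truth Optional truth table path (TSV: `read_id`, `genome_id`)
#'   enabling misassignment metrics.
#' @param uniqueness_rule Passed to [read_alignments()].
#' @param remove_small_rna Drop miRNA/snoRNA genes before quantification.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genomes, params = assignment_params(),
                            out_dir, truth = NULL,
                            uniqueness_rule = "mapq255",
                            remove_small_rna = TRUE, seed = 1L) {
  if (length(genomes) < 2L || is.null(names(genomes)))
    stop("config must name at least two genomes")
  for (g in names(genomes)) {
    for (f in c("alignment", "annotation")) {
      if (is.null(genomes[[g]][[f]]))
        stop("genome '", g, "' is missing its ", f, " file")
    }
  }
  structure(list(genomes = genomes, params = params, out_dir = out_dir,
                 truth = truth, uniqueness_rule = uniqueness_rule,
                 remove_small_rna = isTRUE(remove_small_rna),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full separation pipeline on one sample
#'
#' Stages: read per-genome alignments, classify every read, quantify each
#' species' assigned reads over its (masked, small-RNA-filtered) gene
#' models, and compute separation metrics (including gene loss against a
#' uniqueness-only baseline and, when a truth table is given, the
#' misassignment rate). All tables are written to `out_dir` with
#' deterministic ordering, plus a machine-readable `report.json`.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- names(config$genomes)

  for (g in genomes) {
    for (f in c("alignment", "annotation")) {
      path <- config$genomes[[g]][[f]]
      if (!file.exists(path))
        stop("pipeline stage 'inputs' failed: missing ", f,
             " file for genome '", g, "': ", path, call. = FALSE)
    }
  }

  gms <- .stage("annotation", {
    lapply(setNames(genomes, genomes), function(g) {
      fmt <- config$genomes[[g]]$format
      if (is.null(fmt)) fmt <- "refflat"
      read_gene_models(config$genomes[[g]]$annotation, g, fmt)
    })
  })

  obs <- .stage("alignment", {
    lapply(setNames(genomes, genomes), function(g)
      read_alignments(config$genomes[[g]]$alignment, g,
                      config$uniqueness_rule))
  })

  asn <- .stage("assignment", assign_all(obs, config$params))
  write_table(asn$assignments[, c("read_id", "label", "reason")],
              file.path(config$out_dir, "assignments.tsv"))

  truth <- NULL
  if (!is.null(config$truth)) {
    truth <- .stage("truth", read_table(config$truth))
  }
  metrics <- .stage("metrics",
                    separation_metrics(asn$assignments, asn$counts, truth))

  expr <- list()
  loss <- list()
  for (g in genomes) {
    expr[[g]] <- .stage(paste0("quantify:", g), {
      expression_matrix(setNames(list(asn$assignments), "sample1"),
                        setNames(list(obs[[g]]), "sample1"), gms[[g]],
                        remove_small_rna = config$remove_small_rna)
    })
    write_table(data.frame(gene_id = expr[[g]]$gene_ids,
                           count = expr[[g]]$counts[, 1L],
                           rpkm = expr[[g]]$rpkm[, 1L]),
                file.path(config$out_dir, paste0("expression_", g, ".tsv")))
    loss[[g]] <- .stage(paste0("gene_loss:", g), {
      keep <- unique_only_assignments(obs[[g]], g, config$params)
      gm <- gms[[g]]
      if (config$remove_small_rna) gm <- filter_small_rna(gm)
      gm <- mask_name_overlaps(gm)
      ck <- count_reads(keep, obs[[g]], gm)$counts
      gl <- gene_loss(ck, expr[[g]]$counts[, 1L])
      gl[c("full_loss_fraction", "partial_loss_fraction", "n_expressed")]
    })
  }

  report <- list(
    seed = config$seed,
    params = unclass(config$params),
    counts = as.list(metrics$counts),
    assigned_fraction = metrics$assigned_fraction,
    ambiguous_fraction_of_aligned = metrics$ambiguous_fraction_of_aligned,
    ambiguous_fraction_of_all = metrics$ambiguous_fraction_of_all,
    gene_loss = loss,
    total_assigned_reads = lapply(expr, function(e)
      unname(e$total_assigned_reads[1L])))
  if (!is.null(metrics$misassignment_rate)) {
    report$misassignment_rate <- metrics$misassignment_rate
    report$n_misassigned <- metrics$n_misassigned
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(report = report, assignments = asn$assignments,
                 counts = asn$counts, expression = expr,
                 gene_models = gms, observations = obs))
}

#' Uniqueness-only baseline read set
#'
#' The comparison set used for gene-loss analysis and pure-sample
#' quantification: reads uniquely aligned to one genome within the
#' mismatch budget, with no filter against the other genome (i.e. shared
#' reads are kept).
#'
#' @param obs_g Observation table for the genome (from
#'   [read_alignments()]).
#' @param genome_id The genome id to label kept reads with.
#' @param params [assignment_params()]; only `Mu` is used.
#' @return An assignment-shaped data.table (`read_id`, `label`, `reason`,
#'   `n_genomes_aligned`) usable with [count_reads()].
#' @export
unique_only_assignments <- function(obs_g, genome_id,
                                    params = assignment_params()) {
  keep <- obs_g$aligned & obs_g$unique & obs_g$mismatches <= params$Mu
  data.table(read_id = obs_g$read_id[keep],
             label = genome_id,
             reason = "unique_only",
             n_genomes_aligned = 1L)
}
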