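#' Assignment parameters
#'
#' Thresholds governing how a read is assigned to a species from its
#' per-genome alignments.
#'
#' @param Mu Maximum mismatches allowed for a read seen in only one genome
#'   (default 1).
#' @param Ms Maximum mismatches, in the winning genome, for a read seen in
#'   more than one genome (default 1).
#' @param D Minimum mismatch-count advantage the winning genome must have
#'   over every other aligned genome to rescue a shared read (default 2).
#' @param strict_mode If `TRUE`, disable rescue of shared reads entirely:
#'   any read aligning to more than one genome is species-ambiguous.
#' @return An `assignment_params` list.
#' @export
assignment_params <- function(Mu = 1L, Ms = 1L, D = 2L, strict_mode = FALSE) {
  Mu <- as.integer(Mu); Ms <- as.integer(Ms); D <- as.integer(D)
  if (is.na(Mu) || Mu < 0L) stop("Mu must be a non-negative integer")
  if (is.na(Ms) || Ms < 0L) stop("Ms must be a non-negative integer")
  if (is.na(D) || D < 1L) stop("D must be a positive integer")
  structure(list(Mu = Mu, Ms = Ms, D = D,
                 strict_mode = isTRUE(strict_mode)),
            class = "assignment_params")
}

#' Classify a single read from its per-genome alignment observations
#'
#' Decision procedure (two or more genomes):
#' 1. Aligned in no genome: `unassigned` / `unaligned`.
#' 2. Aligned in exactly one genome: if that alignment is unique and has at
#'    most `Mu` mismatches, assign that genome (`unique_only`); unique but
#'    too many mismatches gives `unassigned` / `too_many_mismatches`;
#'    non-unique gives `ambiguous` / `not_unique`.
#' 3. Aligned in several genomes: the candidate winner is the genome with
#'    the fewest mismatches. In strict mode the read is always
#'    `ambiguous` / `shared_tie`. Otherwise the winner must be unique in
#'    its own genome (`ambiguous` / `not_unique` if not), have at most `Ms`
#'    mismatches, and beat every other aligned genome by at least `D`
#'    mismatches (`rescued_by_difference`); otherwise the read is
#'    `ambiguous` / `shared_tie`. A non-unique alignment in a losing genome
#'    still counts as cross-genome evidence, entering with its best
#'    mismatch count.
#'
#' @param obs List or data.frame of alignment observations for one read,
#'   one per genome, each with `genome_id`, `aligned`, `unique`,
#'   `mismatches`.
#' @param params An [assignment_params()] object.
#' @return List with `label` (a genome id, `"ambiguous"` or
#'   `"unassigned"`) and `reason` (one of `unique_only`,
#'   `rescued_by_difference`, `shared_tie`, `not_unique`,
#'   `too_many_mismatches`, `unaligned`).
#' @export
classify_read <- function(obs, params = assignment_params()) {
  if (is.data.frame(obs)) {
    genome_id <- as.character(obs$genome_id)
    aligned <- as.logical(obs$aligned)
    uniq <- as.logical(obs$unique)
    mm <- as.integer(obs$mismatches)
  } else {
    genome_id <- vapply(obs, `[[`, character(1L), "genome_id")
    aligned <- vapply(obs, `[[`, logical(1L), "aligned")
    uniq <- vapply(obs, `[[`, logical(1L), "unique")
    mm <- vapply(obs, function(o) {
      m <- o$mismatches
      if (is.null(m) || length(m) == 0L) NA_integer_ else as.integer(m)
    }, integer(1L))
  }
  if (length(genome_id) < 2L)
    stop("classify_read requires observations for at least two genomes")
  if (anyDuplicated(genome_id))
    stop("duplicate genome_id in observations for one read")

  idx <- which(aligned)
  if (length(idx) == 0L)
    return(list(label = "unassigned", reason = "unaligned"))

  if (length(idx) == 1L) {
    i <- idx
    if (!uniq[i]) return(list(label = "ambiguous", reason = "not_unique"))
    if (mm[i] <= params$Mu)
      return(list(label = genome_id[i], reason = "unique_only"))
    return(list(label = "unassigned", reason = "too_many_mismatches"))
  }

  # shared between >= 2 genomes
  if (params$strict_mode)
    return(list(label = "ambiguous", reason = "shared_tie"))
  m_al <- mm[idx]
  w <- idx[which.min(m_al)]
  m_w <- mm[w]
  if (sum(m_al == m_w) > 1L)
    return(list(label = "ambiguous", reason = "shared_tie"))
  if (!uniq[w])
    return(list(label = "ambiguous", reason = "not_unique"))
  m_runner <- min(m_al[m_al != m_w])
  if (m_w <= params$Ms && (m_runner - m_w) >= params$D)
    return(list(label = genome_id[w], reason = "rescued_by_difference"))
  list(label = "ambiguous", reason = "shared_tie")
}

#' Assign all reads to species from per-genome alignment observations
#'
#' Vectorized application of the [classify_read()] decision procedure to
#' the joined read universe of two or more genomes. Reads absent from a
#' genome's alignment file are treated as unaligned in that genome.
#'
#' @param observations Named list of per-genome observation tables as
#'   returned by [read_alignments()]; names are genome ids (at least two).
#' @param params An [assignment_params()] object.
#' @return List with `assignments` (data.table: `read_id`, `label`,
#'   `reason`, plus `n_genomes_aligned`) and `counts` (named integer
#'   vector over genome ids, `"ambiguous"`, `"unassigned"`, summing to the
#'   number of distinct reads).
#' @export
assign_all <- function(observations, params = assignment_params()) {
  if (is.null(names(observations)) || any(!nzchar(names(observations))))
    stop("'observations' must be a named list (genome ids as names)")
  genomes <- names(observations)
  if (length(genomes) < 2L)
    stop("at least two genomes are required for species assignment")

  for (g in genomes) {
    o <- observations[[g]]
    if (anyDuplicated(o$read_id))
      stop("duplicate read_id within genome '", g,
           "' after multimapper collapse")
  }

  reads <- sort(unique(unlist(lapply(observations,
                                     function(o) o$read_id))))
  n <- length(reads)
  k <- length(genomes)
  if (n == 0L) {
    counts <- setNames(integer(k + 2L),
                       c(genomes, "ambiguous", "unassigned"))
    return(list(assignments = data.table(read_id = character(),
                                         label = character(),
                                         reason = character(),
                                         n_genomes_aligned = integer()),
                counts = counts))
  }

  A <- matrix(FALSE, n, k, dimnames = list(NULL, genomes))
  U <- matrix(FALSE, n, k)
  M <- matrix(NA_integer_, n, k)
  for (j in seq_len(k)) {
    o <- observations[[genomes[j]]]
    i <- match(o$read_id, reads)
    A[i, j] <- o$aligned
    U[i, j] <- o$unique
    M[i, j] <- ifelse(o$aligned, o$mismatches, NA_integer_)
  }

  Mx <- M
  Mx[!A] <- NA_integer_
  Minf <- Mx
  Minf[is.na(Minf)] <- .Machine$integer.max
  n_aligned <- rowSums(A)

  label <- rep("ambiguous", n)
  reason <- rep("shared_tie", n)

  none <- n_aligned == 0L
  label[none] <- "unassigned"
  reason[none] <- "unaligned"

  # exactly one aligned genome
  one <- n_aligned == 1L
  if (any(one)) {
    j1 <- max.col(A, ties.method = "first")
    u1 <- U[cbind(seq_len(n), j1)]
    m1 <- Mx[cbind(seq_len(n), j1)]
    nu <- one & !u1
    label[nu] <- "ambiguous"; reason[nu] <- "not_unique"
    ok <- one & u1 & m1 <= params$Mu
    label[ok] <- genomes[j1[ok]]; reason[ok] <- "unique_only"
    tm <- one & u1 & m1 > params$Mu
    label[tm] <- "unassigned"; reason[tm] <- "too_many_mismatches"
  }

  # shared reads
  multi <- which(n_aligned >= 2L)
  if (length(multi) > 0L && !params$strict_mode) {
    Mm <- Minf[multi, , drop = FALSE]
    jw <- max.col(-Mm, ties.method = "first")
    ii <- cbind(seq_along(multi), jw)
    mw <- Mm[ii]
    n_at_min <- rowSums(Mm == mw)
    M2 <- Mm
    M2[ii] <- .Machine$integer.max
    m2 <- do.call(pmin, lapply(seq_len(k), function(j) M2[, j]))
    uw <- U[multi, , drop = FALSE][ii]
    nu <- n_at_min == 1L & !uw
    label[multi[nu]] <- "ambiguous"; reason[multi[nu]] <- "not_unique"
    resc <- n_at_min == 1L & uw & mw <= params$Ms &
      (as.numeric(m2) - as.numeric(mw)) >= params$D
    label[multi[resc]] <- genomes[jw[resc]]
    reason[multi[resc]] <- "rescued_by_difference"
    # everything else among multi keeps the ambiguous/shared_tie default
  }

  assignments <- data.table(read_id = reads, label = label, reason = reason,
                            n_genomes_aligned = as.integer(n_aligned))
  lv <- c(genomes, "ambiguous", "unassigned")
  counts <- table(factor(label, levels = lv))
  counts <- setNames(as.integer(counts), lv)
  list(assignments = assignments, counts = counts)
}
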