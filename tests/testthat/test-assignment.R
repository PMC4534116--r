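# species assignment decision procedure

test_that("worked examples of the decision procedure", {
  p <- assignment_params(Mu = 1, Ms = 1, D = 2)
  cl <- function(oA, oB, params = p)
    classify_read(rbind(oA, oB), params)

  # unique to one genome, clean
  r <- cl(obs_row("genomeA", TRUE, TRUE, 0), obs_row("genomeB", FALSE))
  expect_equal(r, list(label = "genomeA", reason = "unique_only"))
  # perfect in both: tie
  r <- cl(obs_row("genomeA", TRUE, TRUE, 0), obs_row("genomeB", TRUE, TRUE, 0))
  expect_equal(r, list(label = "ambiguous", reason = "shared_tie"))
  # rescued by mismatch difference (3 - 0 >= 2, winner within Ms)
  r <- cl(obs_row("genomeA", TRUE, TRUE, 0), obs_row("genomeB", TRUE, TRUE, 3))
  expect_equal(r, list(label = "genomeA", reason = "rescued_by_difference"))
  # unique but too many mismatches
  r <- cl(obs_row("genomeA", TRUE, TRUE, 2), obs_row("genomeB", FALSE))
  expect_equal(r, list(label = "unassigned", reason = "too_many_mismatches"))
  # difference 1 < D = 2
  r <- cl(obs_row("genomeA", TRUE, TRUE, 1), obs_row("genomeB", TRUE, TRUE, 2))
  expect_equal(r, list(label = "ambiguous", reason = "shared_tie"))
  # aligned nowhere
  r <- cl(obs_row("genomeA", FALSE), obs_row("genomeB", FALSE))
  expect_equal(r, list(label = "unassigned", reason = "unaligned"))
  # multimapper in its own (only) genome can never win
  r <- cl(obs_row("genomeA", TRUE, FALSE, 0), obs_row("genomeB", FALSE))
  expect_equal(r, list(label = "ambiguous", reason = "not_unique"))
  # would-be winner multimapped while shared
  r <- cl(obs_row("genomeA", TRUE, FALSE, 0), obs_row("genomeB", TRUE, TRUE, 3))
  expect_equal(r, list(label = "ambiguous", reason = "not_unique"))
  # non-unique alignment in the loser blocks unique_only but still rescues
  r <- cl(obs_row("genomeA", TRUE, TRUE, 0), obs_row("genomeB", TRUE, FALSE, 3))
  expect_equal(r, list(label = "genomeA", reason = "rescued_by_difference"))
})

test_that("classify_read equals the truth-table oracle over the full grid", {
  states <- genome_states(4L)
  for (Mu in 0:2) for (Ms in 0:2) for (D in 1:3) {
    p <- assignment_params(Mu = Mu, Ms = Ms, D = D)
    for (sA in states) for (sB in states) {
      got <- classify_read(rbind(
        obs_row("genomeA", sA$aligned, sA$unique, sA$m),
        obs_row("genomeB", sB$aligned, sB$unique, sB$m)), p)
      want <- oracle_classify2(sA$aligned, sA$unique, sA$m,
                               sB$aligned, sB$unique, sB$m,
                               Mu, Ms, D)
      expect_equal(unlist(got, use.names = FALSE), want,
                   info = sprintf("A=%s B=%s Mu=%d Ms=%d D=%d",
                                  paste(unlist(sA), collapse = ","),
                                  paste(unlist(sB), collapse = ","),
                                  Mu, Ms, D))
    }
  }
})

test_that("strict mode labels equal an unattainably large mismatch advantage", {
  # reasons may differ (strict mode reports shared_tie by definition),
  # the label partition must be identical
  states <- genome_states(4L)
  p_strict <- assignment_params(Mu = 1, Ms = 1, D = 2, strict_mode = TRUE)
  p_huge <- assignment_params(Mu = 1, Ms = 1, D = 100)
  for (sA in states) for (sB in states) {
    o <- rbind(obs_row("genomeA", sA$aligned, sA$unique, sA$m),
               obs_row("genomeB", sB$aligned, sB$unique, sB$m))
    expect_equal(classify_read(o, p_strict)$label,
                 classify_read(o, p_huge)$label)
  }
})

test_that("three-genome mode: winner must beat every other aligned genome", {
  p <- assignment_params(Mu = 1, Ms = 1, D = 2)
  o3 <- function(mA, mB, mC) rbind(
    obs_row("genomeA", !is.na(mA), TRUE, mA),
    obs_row("genomeB", !is.na(mB), TRUE, mB),
    obs_row("genomeC", !is.na(mC), TRUE, mC))
  # beats both by >= 2
  expect_equal(classify_read(o3(0, 2, 4), p),
               list(label = "genomeA", reason = "rescued_by_difference"))
  # beats one by 2 but the other only by 1
  expect_equal(classify_read(o3(0, 1, 4), p),
               list(label = "ambiguous", reason = "shared_tie"))
  # unique to one genome requires no alignment in any other
  expect_equal(classify_read(o3(0, NA, NA), p),
               list(label = "genomeA", reason = "unique_only"))
  expect_equal(classify_read(o3(0, NA, 4), p),
               list(label = "genomeA", reason = "rescued_by_difference"))
})

test_that("fewer than two genomes is a configuration error", {
  expect_error(classify_read(obs_row("genomeA", TRUE, TRUE, 0)),
               "two genomes")
  expect_error(assign_all(list(genomeA = obs_row("genomeA", TRUE, TRUE, 0))),
               "two genomes")
})

# random observation tables for the vectorized path
random_observations <- function(n, genomes, seed) {
  set.seed(seed)
  ids <- sprintf("r%06d", seq_len(n))
  lapply(setNames(genomes, genomes), function(g) {
    aligned <- runif(n) < 0.8
    unique <- aligned & runif(n) < 0.85
    keep <- runif(n) < 0.95  # some reads absent from this genome's file
    data.frame(read_id = ids, genome_id = g, aligned = aligned,
               unique = unique,
               mismatches = ifelse(aligned, sample(0:4, n, TRUE),
                                   NA_integer_),
               chrom = ifelse(aligned, "chr1", NA), start = 1L, end = 50L,
               strand = "+", stringsAsFactors = FALSE)[keep, ]
  })
}

test_that("assign_all equals read-by-read classification and conserves reads", {
  obs <- random_observations(500, c("genomeA", "genomeB"), seed = 99)
  p <- assignment_params()
  res <- assign_all(obs, p)
  expect_equal(sum(res$counts), nrow(res$assignments))

  # composition oracle: every row equals classify_read on that read
  for (i in seq_len(nrow(res$assignments))) {
    rid <- res$assignments$read_id[i]
    o <- do.call(rbind, lapply(names(obs), function(g) {
      row <- obs[[g]][obs[[g]]$read_id == rid, ]
      if (nrow(row) == 0L) obs_row(g, FALSE, read_id = rid) else row
    }))
    want <- classify_read(o, p)
    expect_equal(res$assignments$label[i], want$label)
    expect_equal(res$assignments$reason[i], want$reason)
  }
})

test_that("swapping genome order only swaps the species labels", {
  obs <- random_observations(400, c("genomeA", "genomeB"), seed = 5)
  r1 <- assign_all(obs, assignment_params())
  r2 <- assign_all(rev(obs), assignment_params())
  a1 <- r1$assignments[order(r1$assignments$read_id), ]
  a2 <- r2$assignments[order(r2$assignments$read_id), ]
  expect_equal(a1$label, a2$label)   # labels are genome ids, not positions
  expect_equal(a1$reason, a2$reason)
  expect_equal(r1$counts[c("genomeA", "genomeB")],
               r2$counts[c("genomeA", "genomeB")])
})

test_that("threshold monotonicity", {
  obs <- random_observations(600, c("genomeA", "genomeB"), seed = 17)
  n_assigned <- function(res)
    sum(res$counts[c("genomeA", "genomeB")])
  n_ambig <- function(res) res$counts[["ambiguous"]]

  # raising D never converts ambiguous to assigned
  prevamb <- -1
  for (D in 1:5) {
    res <- assign_all(obs, assignment_params(D = D))
    expect_gte(n_ambig(res), prevamb)
    prevamb <- n_ambig(res)
  }
  # raising Mu or Ms never reduces assigned reads
  prev <- -1
  for (Mu in 0:4) {
    res <- assign_all(obs, assignment_params(Mu = Mu))
    expect_gte(n_assigned(res), prev)
    prev <- n_assigned(res)
  }
  prev <- -1
  for (Ms in 0:4) {
    res <- assign_all(obs, assignment_params(Ms = Ms))
    expect_gte(n_assigned(res), prev)
    prev <- n_assigned(res)
  }
})

test_that("empty inputs give an empty table and zero counts", {
  empty <- data.frame(read_id = character(), genome_id = character(),
                      aligned = logical(), unique = logical(),
                      mismatches = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character())
  res <- assign_all(list(genomeA = empty, genomeB = empty))
  expect_equal(nrow(res$assignments), 0L)
  expect_true(all(res$counts == 0L))
})

test_that("duplicate read within one genome is rejected", {
  dup <- rbind(obs_row("genomeA", TRUE, TRUE, 0),
               obs_row("genomeA", TRUE, TRUE, 1))
  expect_error(
    assign_all(list(genomeA = dup,
                    genomeB = obs_row("genomeB", FALSE))),
    "duplicate")
})
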