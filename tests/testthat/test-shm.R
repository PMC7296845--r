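# Replacement/silent mutation counting and the cohort comparison.

test_that("count_mutations classifies canonical single-base codon changes", {
  s <- count_mutations("ATGGCT", "ATGGCC")   # GCT -> GCC, both Ala
  expect_identical(c(s$total_mutations, s$replacement, s$silent), c(1L, 0L, 1L))
  r <- count_mutations("ATGGCT", "ATGACT")   # GCT -> ACT, Ala -> Thr
  expect_identical(c(r$total_mutations, r$replacement, r$silent), c(1L, 1L, 0L))
  expect_false(r$rs_defined)

  id <- count_mutations("ATGGCT", "ATGGCT")
  expect_identical(id$total_mutations, 0L)
  expect_true(is.na(id$rs_ratio))
})

test_that("multi-change and N codons follow the configured policy", {
  # GCT -> GCA + CAT -> CAC in one codon each is fine; TTA -> CTG is Leu -> Leu
  # with two changed bases: policy "translate" scores both as silent
  tr <- count_mutations("TTAAAA", "CTGAAA")
  expect_identical(c(tr$total_mutations, tr$replacement, tr$silent), c(2L, 0L, 2L))
  expect_identical(tr$ambiguous_codons, 1L)
  expect_identical(tr$ambiguous_mutations, 0L)

  ex <- count_mutations("TTAAAA", "CTGAAA", ambiguous_policy = "exclude")
  expect_identical(c(ex$total_mutations, ex$replacement, ex$silent), c(2L, 0L, 0L))
  expect_identical(ex$ambiguous_mutations, 2L)

  # N bases are never classified but differing bases count in the total
  nn <- count_mutations("ATGGCT", "ATGGNT")
  expect_identical(nn$total_mutations, 1L)
  expect_identical(nn$replacement + nn$silent, 0L)
  expect_identical(nn$ambiguous_mutations, 1L)
})

test_that("conservation: replacement + silent + unclassified = total, always", {
  alphabet <- c("A", "C", "G", "T", "N")
  for (seed in 1:30) {
    pair <- withr::with_seed(seed, {
      n <- 3 * sample(3:12, 1)
      g <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
      m <- g
      idx <- sample(n, sample(0:6, 1))
      m[idx] <- sample(alphabet, length(idx), replace = TRUE)
      list(g = paste(g, collapse = ""), m = paste(m, collapse = ""))
    })
    for (policy in c("translate", "exclude")) {
      s <- count_mutations(pair$g, pair$m, ambiguous_policy = policy)
      expect_identical(s$replacement + s$silent + s$ambiguous_mutations,
                       s$total_mutations)
    }
  }
})

test_that("frame shifts change classification but never the total", {
  pair <- simulate_ig_pair(igpair_spec(99, 6, 4, seed = 23))
  # pad so every offset leaves a whole number of codons plus a logged tail
  g <- paste0(pair$germline, "AA")
  m <- paste0(pair$mature, "AA")
  totals <- vapply(0:2, function(off)
    count_mutations(g, m, reading_frame_offset = off, strict = FALSE)$total_mutations,
    integer(1))
  expect_identical(totals, rep(totals[1], 3))
  expect_error(count_mutations(pair$germline, paste0(pair$mature, "A")),
               class = "mq_validation_error")
  expect_error(count_mutations(paste0(pair$germline, "A"), paste0(pair$mature, "A")),
               class = "mq_frame_error")
})

test_that("classification matches translation enumeration on short sequences", {
  for (seed in 1:25) {
    pair <- withr::with_seed(seed, {
      sp <- igpair_spec(3 * sample(6:10, 1),   # <= 30 nt, room for all mutations
                        n_replacement = sample(0:3, 1),
                        n_silent = sample(0:2, 1), seed = seed)
      simulate_ig_pair(sp)
    })
    got <- count_mutations(pair$germline, pair$mature)
    want <- oracle_count_rs(pair$germline, pair$mature)
    expect_identical(got$total_mutations, unname(want["total"]))
    expect_identical(got$replacement, unname(want["replacement"]))
    expect_identical(got$silent, unname(want["silent"]))
    # and the generator's planted truth round-trips exactly
    expect_identical(got$replacement, pair$truth$n_replacement)
    expect_identical(got$silent, pair$truth$n_silent)
  }
})

test_that("summarize_cohort: symmetry, planted medians, exact p-value parity", {
  mk <- function(nr, ns, seed) {
    p <- simulate_ig_pair(igpair_spec(150, nr, ns, seed = seed))
    list(germline = p$germline, mature = p$mature)
  }
  # two identical groups: zero difference, p = 1 under enumeration
  pairs <- c(lapply(1:3, function(s) mk(4, 2, s)), lapply(1:3, function(s) mk(4, 2, s)))
  res <- summarize_cohort(pairs, rep(c("LRR", "EPTP"), each = 3))
  expect_identical(res$observed_diff, 0)
  expect_identical(res$p_value, 1)
  expect_identical(res$method, "exact")

  # planted per-group totals give the planted medians
  plant <- list(c(2, 1), c(4, 2), c(8, 3), c(3, 1), c(5, 2), c(10, 4))
  pairs2 <- lapply(seq_along(plant), function(i)
    mk(plant[[i]][1], plant[[i]][2], 100 + i))
  groups2 <- rep(c("g1", "g2"), each = 3)
  res2 <- summarize_cohort(pairs2, groups2)
  totals <- vapply(plant, sum, numeric(1))
  expect_identical(unname(res2$group_medians),
                   c(median(totals[1:3]), median(totals[4:6])))
  # p-value matches exhaustive enumeration over all 20 assignments
  want <- oracle_median_perm_p(res2$summaries$total, groups2)
  expect_identical(unname(want["n_assignments"]), 20)
  expect_equal(res2$p_value, unname(want["p"]))

  expect_error(summarize_cohort(pairs2, rep("g1", 6)), class = "mq_validation_error")
})
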