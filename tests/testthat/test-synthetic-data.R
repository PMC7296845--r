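# Generators: stated-world semantics, planted ground truth, determinism.

test_that("simulate_stack honours the no-signal and onset semantics", {
  flat <- simulate_stack(stack_spec(6, 7, 5, background_level = 100,
                                    background_noise_sd = 0, seed = 3))
  for (f in flat$stack$frames) expect_true(all(f == 100))

  spec_bg <- stack_spec(10, 10, 8, background_noise_sd = 2, seed = 9)
  spec_cl <- stack_spec(10, 10, 8, background_noise_sd = 2, seed = 9,
                        clusters = list(cluster_spec(c(5, 5), 2, 5, c(30, 40, 50, 60))))
  bg <- simulate_stack(spec_bg)$stack$frames
  cl <- simulate_stack(spec_cl)$stack$frames
  # before onset the cluster stack is identical to the background-only stack
  for (t in 1:4) expect_identical(cl[[t]], bg[[t]])
  expect_false(identical(cl[[5]], bg[[5]]))
})

test_that("simulate_stack plants the advertised number of disjoint components", {
  spec <- stack_spec(24, 24, 4, background_noise_sd = 0, seed = 2,
                     clusters = list(
                       cluster_spec(c(5, 5), 2, 1, 50),
                       cluster_spec(c(5, 18), 2, 1, 60),
                       cluster_spec(c(18, 12), 3, 1, 70)))
  sim <- simulate_stack(spec)
  expect_identical(sim$truth$n_clusters, 3L)
  expect_identical(oracle_n_components(sim$truth$label_mask > 0, 8L), 3L)
})

test_that("generators are seed-deterministic (bit-identical repeats)", {
  sp <- stack_spec(8, 8, 5, background_noise_sd = 4, seed = 42,
                   clusters = list(cluster_spec(c(4, 4), 2, 3, c(10, 20))))
  expect_identical(simulate_stack(sp), simulate_stack(sp))

  tsp <- titration_spec(1.5, 800, c(0.1, 0.5, 1, 2, 5, 10), noise_sd = 10, seed = 7)
  expect_identical(simulate_titration(tsp), simulate_titration(tsp))

  csp <- fig2d_spec(noise_sd = 25, seed = 5)
  expect_identical(simulate_blocking_matrix(csp), simulate_blocking_matrix(csp))

  isp <- igpair_spec(150, 4, 2, seed = 13)
  expect_identical(simulate_ig_pair(isp), simulate_ig_pair(isp))

  expect_identical(simulate_dilution_series(c(40, 80, 160), 80, seed = 3),
                   simulate_dilution_series(c(40, 80, 160), 80, seed = 3))
})

test_that("simulate_titration reproduces the one-site model exactly at zero noise", {
  kd <- 2.5; bmax <- 640
  x <- c(0, 0.1, 0.5, kd, 5, 20, 1000 * kd)
  curve <- simulate_titration(titration_spec(kd, bmax, x, noise_sd = 0))
  expect_identical(curve$y, bmax * x / (x + kd))
  expect_identical(curve$y[x == 0], 0)                      # zero concentration
  expect_identical(curve$y[x == kd], bmax / 2)              # half-saturation
  expect_lt(abs(curve$y[x == 1000 * kd] - bmax) / bmax, 1e-3)  # near-saturation
})

test_that("simulate_blocking_matrix emits exact anchor signals at zero noise", {
  spec <- fig2d_spec()
  tab <- simulate_blocking_matrix(spec)
  within <- tab$entries$signal[tab$entries$first == "mAb01" &
                               tab$entries$second == "mAb02"]
  expect_identical(within, spec$signal_self)
  across <- tab$entries$signal[tab$entries$first == "mAb01" &
                               tab$entries$second == "mAb11"]
  expect_identical(across, spec$signal_control)
  expect_true(all(tab$control_entries$signal == spec$signal_control))
  expect_true(all(tab$self_entries$signal == spec$signal_self))
  # non-blockers do not even block themselves
  diag_nb <- tab$entries$signal[tab$entries$first == "mAb08" &
                                tab$entries$second == "mAb08"]
  expect_identical(diag_nb, spec$signal_control)
})

test_that("generator specs validate their invariants", {
  expect_error(stack_spec(8, 8, 3), class = "mq_validation_error")
  expect_error(stack_spec(8, 8, 5, global_gain_drift = c(1, 1, 0, 1, 1)),
               class = "mq_validation_error")
  expect_error(stack_spec(8, 8, 5, clusters = list(cluster_spec(c(4, 4), 2, 9, 1))),
               class = "mq_validation_error")
  expect_error(titration_spec(-1, 100, c(0, 1, 2, 3)), class = "mq_validation_error")
  expect_error(titration_spec(1, 100, c(0, 1)), class = "mq_validation_error")
  ids <- c("a", "b", "c")
  grp <- c(a = "g1", b = "g2", c = "non-blocker")
  expect_error(competition_spec(ids, grp, one_way_pairs = list(c("a", "b"))),
               class = "mq_validation_error")
  expect_error(competition_spec(ids, grp, signal_control = 50, signal_self = 50),
               class = "mq_validation_error")
  expect_error(igpair_spec(10, 1, 1), class = "mq_validation_error")
})

test_that("simulate_ig_pair plants exactly the requested mutations", {
  id_pair <- simulate_ig_pair(igpair_spec(90, 0, 0, seed = 1))
  expect_identical(id_pair$germline, id_pair$mature)

  pair <- simulate_ig_pair(igpair_spec(300, 2, 3, seed = 5))
  diffs <- which(strsplit(pair$germline, "")[[1]] != strsplit(pair$mature, "")[[1]])
  expect_identical(diffs, pair$truth$positions)
  expect_length(diffs, 5L)

  # TGG (Trp) admits no synonymous single-base change
  expect_error(simulate_ig_pair(igpair_spec(germline = "TGG", n_replacement = 0,
                                            n_silent = 1)),
               class = "mq_infeasible_spec")
})

test_that("simulate_dilution_series signals match the planted titre at low noise", {
  s <- simulate_dilution_series(c(40, 80, 160, 320, 640, 1280), 640,
                                noise_sd = 1, seed = 2)
  expect_true(all(s$signals[s$dilutions <= 640] > 900))
  expect_true(all(s$signals[s$dilutions > 640] < 200))
})
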