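test_that("a single-clone configuration yields the degenerate root tree", {
  cfg <- simulation_config(n_clones = 1, n_samples = 3,
                           burden_range = c(10, 20), seed = 5)
  truth <- simulate_truth(cfg)
  expect_equal(nrow(truth$nodes), 1L)
  expect_true(is.na(truth$nodes$parent_id))
  expect_equal(unname(truth$prevalence[1, ]), rep(1, 3))
  expect_true(check_truth_tree(truth)$ok)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_clones = 0), "n_clones")
  expect_error(simulation_config(n_samples = 0), "n_samples")
  expect_error(simulation_config(error_rate = 0.5), "error_rate")
  expect_error(simulation_config(burden_range = c(10, 5)), "burden_range")
})

test_that("simulation is deterministic given the seed and varies across seeds", {
  cfg <- simulation_config(n_clones = 3, burden_range = c(20, 40), seed = 11)
  t1 <- simulate_truth(cfg); t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)
  c1 <- simulate_counts(t1, cfg); c2 <- simulate_counts(t2, cfg)
  expect_identical(c1, c2)
  cfg2 <- simulation_config(n_clones = 3, burden_range = c(20, 40), seed = 12)
  t3 <- simulate_truth(cfg2)
  expect_false(identical(t1$prevalence, t3$prevalence))
  expect_false(identical(simulate_counts(t1, cfg)$alt,
                         simulate_counts(t1, cfg2)$alt))
})

test_that("random truth trees always satisfy the pigeonhole margin", {
  set.seed(202)
  draws <- data.frame(n_samples = sample(1:6, 1000, replace = TRUE),
                      n_clones = sample(1:6, 1000, replace = TRUE),
                      seed = sample.int(1e6, 1000))
  for (i in seq_len(nrow(draws))) {
    cfg <- simulation_config(n_samples = draws$n_samples[i],
                             n_clones = draws$n_clones[i],
                             burden_range = c(1, 5),
                             seed = draws$seed[i])
    chk <- check_truth_tree(simulate_truth(cfg), margin = 0.02)
    if (!chk$ok) fail(paste("violations at draw", i, ":",
                            paste(chk$violations, collapse = "; ")))
  }
  succeed()
})

test_that("pooled VAF of a clonal lineage converges to one half", {
  cfg <- simulation_config(n_clones = 1, n_samples = 2,
                           burden_range = c(10000, 10000),
                           depth_mean = 40, error_rate = 0, n_germline = 0,
                           seed = 3)
  truth <- simulate_truth(cfg)
  tab <- simulate_counts(truth, cfg)
  expect_lt(abs(sum(tab$alt) / sum(tab$depth) - 0.5), 0.005)
})

test_that("a clone absent from a sample yields zero alt reads without errors", {
  truth <- structure(list(
    nodes = data.frame(node_id = 1:2, parent_id = c(NA, 1L)),
    prevalence = matrix(c(1, 1, 0, 0.4), 2, 2, byrow = TRUE,
                        dimnames = list(c("clone1", "clone2"), c("S1", "S2"))),
    branch_burden = c(50L, 50L),
    assignment = setNames(rep(1:2, each = 50), sprintf("m%05d", 1:100)),
    germline_ids = character(0), seed = 1L), class = "truth_tree")
  cfg <- simulation_config(n_samples = 2, n_clones = 2,
                           burden_range = c(50, 50), error_rate = 0, seed = 1)
  tab <- simulate_counts(truth, cfg)
  expect_true(all(tab$alt[51:100, 1] == 0L))
  expect_true(all(tab$depth >= 1L))
})

test_that("germline injection appends flagged sites at VAF one half", {
  cfg <- simulation_config(n_clones = 2, burden_range = c(30, 50),
                           n_germline = 500, depth_mean = 40, seed = 9)
  truth <- simulate_truth(cfg)
  tab <- simulate_counts(truth, cfg)
  inj <- inject_germline(tab, truth, cfg)
  expect_equal(nrow(inj$table$sites), nrow(tab$sites) + 500L)
  expect_length(inj$truth$germline_ids, 500L)
  expect_length(intersect(inj$truth$germline_ids,
                          names(inj$truth$assignment)), 0L)
  g <- inj$table$sites$id %in% inj$truth$germline_ids
  expect_identical(sum(g), 500L)
  vafs <- inj$table$alt[g, ] / inj$table$depth[g, ]
  expect_gt(mean(vafs), 0.45)
  expect_lt(mean(vafs), 0.55)

  cfg0 <- simulation_config(n_clones = 2, burden_range = c(30, 50),
                            n_germline = 0, seed = 9)
  expect_identical(inject_germline(tab, truth, cfg0)$table, tab)
})

test_that("the truth-tree checker flags constructed violations", {
  bad <- structure(list(
    nodes = data.frame(node_id = 1:3, parent_id = c(NA, 1L, 1L)),
    prevalence = matrix(c(1, 1, 0.7, 0.6, 0.5, 0.5), 3, 2, byrow = TRUE),
    branch_burden = c(1L, 1L, 1L),
    assignment = setNames(1:3, c("m1", "m2", "m3")),
    germline_ids = character(0), seed = 1L), class = "truth_tree")
  chk <- check_truth_tree(bad)
  expect_false(chk$ok)
  expect_match(paste(chk$violations, collapse = " "), "pigeonhole")
})
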