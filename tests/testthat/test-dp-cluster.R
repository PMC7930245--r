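two_cluster_table <- function(seed, n = 100, depth = 40) {
  set.seed(seed)
  th <- rbind(c(0.5, 0.0), c(0.25, 0.25))
  z <- rep(1:2, each = n)
  alt <- matrix(rbinom(2 * n * 2, depth, th[z, ]), 2 * n, 2)
  list(table = make_table(alt, matrix(as.integer(depth), 2 * n, 2)),
       z = z, theta = th)
}

test_that("a single mutation always occupies exactly one cluster", {
  tab <- make_table(matrix(10L, 1, 2), matrix(40L, 1, 2))
  tr <- gibbs_run(tab, n_iter = 200, burn_in = 50, seed = 1)
  expect_true(all(tr$n_clusters == 1L))
  expect_equal(dim(tr$assignments), c(150L, 1L))
  expect_equal(unname(tr$coassign[1, 1]), 1)
})

test_that("empty input and bad iteration counts are rejected", {
  tab <- make_table(matrix(10L, 1, 2), matrix(40L, 1, 2))
  expect_error(gibbs_run(subset_sites(tab, FALSE)), "no somatic sites")
  expect_error(gibbs_run(tab, n_iter = 100, burn_in = 100), "burn_in")
})

test_that("the sampler is deterministic given a seed", {
  b <- two_cluster_table(3)
  t1 <- gibbs_run(b$table, n_iter = 300, burn_in = 100, seed = 99)
  t2 <- gibbs_run(b$table, n_iter = 300, burn_in = 100, seed = 99)
  expect_identical(t1$assignments, t2$assignments)
  expect_identical(t1$log_post, t2$log_post)
  t3 <- gibbs_run(b$table, n_iter = 300, burn_in = 100, seed = 100)
  expect_false(identical(t1$assignments, t3$assignments))
})

test_that("the two-cluster benchmark is recovered with accurate VAFs", {
  b <- two_cluster_table(1)
  tr <- gibbs_run(b$table, seed = 1)
  cl <- point_estimate(tr, b$table)
  expect_gte(ari(cl$assignment, b$z), 0.95)
  expect_equal(sum(cl$clusters$burden), 200L)
  # align recovered clusters to truth via first members
  ref <- cl$assignment[c(1, 101)]
  expect_lt(max(abs(cl$theta_hat[ref, ] - b$theta)), 0.05)
  # co-assignment matrix is a proper similarity
  expect_true(isSymmetric(unname(tr$coassign)))
  expect_true(all(diag(tr$coassign) == 1))
  expect_true(all(tr$coassign >= 0 & tr$coassign <= 1))
})

test_that("theta draws under a fixed partition match the conjugate posterior", {
  b <- two_cluster_table(5)
  tr <- gibbs_run(b$table, n_iter = 600, burn_in = 200, seed = 2)
  cl <- point_estimate(tr, b$table)
  dr <- posterior_theta(cl, b$table, n_draws = 4000, seed = 3)
  st <- somaclone:::cluster_stats(cl$assignment, b$table$alt, b$table$depth)
  for (k in seq_len(nrow(cl$theta_hat))) {
    for (s in 1:2) {
      a <- 1 + st$A[k, s]; bb <- 1 + st$D[k, s] - st$A[k, s]
      expect_equal(mean(dr[, k, s]), a / (a + bb),
                   tolerance = 4 * sqrt(a * bb / ((a + bb)^2 * (a + bb + 1)) / 4000) /
                     (a / (a + bb)))
      expect_equal(cl$theta_hat[k, s], a / (a + bb))
    }
  }
})

test_that("mutation order does not materially change the partition", {
  b <- two_cluster_table(7)
  tr1 <- gibbs_run(b$table, seed = 4)
  cl1 <- point_estimate(tr1, b$table)
  a1 <- ari(cl1$assignment, b$z)
  set.seed(8)
  perm <- sample.int(200)
  tabp <- subset_sites(b$table, perm)
  tr2 <- gibbs_run(tabp, seed = 4)
  cl2 <- point_estimate(tr2, tabp)
  a2 <- ari(cl2$assignment, b$z[perm])
  expect_lt(abs(a1 - a2), 0.02)
})

test_that("a tiny fixed concentration keeps one-cluster data in one cluster", {
  set.seed(21)
  alt <- matrix(rbinom(100 * 2, 40, 0.3), 100, 2)
  tab <- make_table(alt, matrix(40L, 100, 2))
  tr <- gibbs_run(tab, n_iter = 1000, burn_in = 300, seed = 5,
                  alpha_fixed = 1e-6)
  expect_gte(mean(tr$n_clusters == 1L), 0.99)
  cl <- point_estimate(tr, tab)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$burden, 100L)
})

test_that("small clusters are dissolved into their best surviving cluster", {
  set.seed(22)
  # 60 + 60 clearly separated mutations plus 3 extreme outliers
  alt <- rbind(matrix(rbinom(120, 40, 0.45), 60, 2),
               matrix(rbinom(120, 40, 0.10), 60, 2),
               matrix(c(40L, 0L), 3, 2, byrow = TRUE))
  tab <- make_table(alt, matrix(40L, 123, 2))
  tr <- gibbs_run(tab, n_iter = 800, burn_in = 300, seed = 6)
  cl <- point_estimate(tr, tab, min_cluster_size = 5)
  expect_true(all(cl$clusters$burden >= 5L))
  expect_equal(sum(cl$clusters$burden), 123L)
  expect_equal(length(cl$assignment), 123L)
})

test_that("cluster recovery does not degrade with deeper sequencing", {
  aris <- vapply(1:10, function(sd) {
    res <- numeric(2)
    for (j in 1:2) {
      depth <- c(10, 100)[j]
      b <- two_cluster_table(sd + 100, n = 60, depth = depth)
      tr <- gibbs_run(b$table, n_iter = 800, burn_in = 300, seed = sd)
      cl <- point_estimate(tr, b$table)
      res[j] <- ari(cl$assignment, b$z)
    }
    res[2] - res[1]
  }, 0)
  expect_gte(mean(aris), 0)
})
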