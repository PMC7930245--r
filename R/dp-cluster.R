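#' Dirichlet-process clustering of mutations across samples
#'
#' Clusters somatic mutations by their joint distribution of
#' variant-supporting reads and depths across all N samples, with a
#' mixture of per-sample binomials under a Dirichlet-process prior. The
#' collapsed Gibbs sampler integrates out cluster VAFs (conjugate
#' Beta(1,1) priors), moves assignments under the Chinese restaurant
#' process, and resamples the concentration `alpha` from its conditional
#' under a Gamma prior. Because the likelihood is on raw counts, samples
#' with different coverage are weighted naturally and no hard VAF cut-off
#' is involved. Mutations called absent in a sample still contribute
#' their (alt, depth) there: noise is the model's job, presence calls are
#' for reporting.
#'
#' @param table a [variant_table()] of somatic sites.
#' @param n_iter total Gibbs sweeps (default 2000).
#' @param burn_in discarded initial sweeps (default 500).
#' @param seed integer seed; the run is deterministic given it.
#' @param alpha_prior Gamma (shape, rate) prior on the DP concentration.
#' @param alpha_init initial concentration.
#' @param alpha_fixed if non-`NULL`, hold `alpha` fixed at this value.
#' @return object of class `dp_trace`: `assignments` (kept-states x
#'   mutations integer matrix), `log_post` (joint log posterior density of
#'   each kept state, up to a constant), `alpha`, `n_clusters`, `coassign`
#'   (mutation x mutation co-assignment frequency), `mutation_ids`.
#' @export
gibbs_run <- function(table, n_iter = 2000L, burn_in = 500L, seed = 1L,
                      alpha_prior = c(1, 1), alpha_init = 1,
                      alpha_fixed = NULL) {
  stopifnot(inherits(table, "variant_table"))
  if (nrow(table$sites) == 0L) stop("no somatic sites to cluster")
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  stopifnot(length(alpha_prior) == 2L, all(alpha_prior > 0))
  set.seed(as.integer(seed))
  fix <- !is.null(alpha_fixed)
  res <- .dp_gibbs_cpp(table$alt, table$depth,
                       as.integer(n_iter), as.integer(burn_in),
                       alpha_prior[1], alpha_prior[2],
                       if (fix) alpha_fixed else alpha_init, fix)
  dimnames(res$coassign) <- list(table$sites$id, table$sites$id)
  colnames(res$assignments) <- table$sites$id
  structure(c(res, list(mutation_ids = table$sites$id,
                        n_iter = as.integer(n_iter),
                        burn_in = as.integer(burn_in), seed = as.integer(seed))),
            class = "dp_trace")
}

#' @exportS3Method base::print
print.dp_trace <- function(x, ...) {
  cat(sprintf("dp_trace: %d mutations, %d kept states, cluster count %d-%d (median %d)\n",
              length(x$mutation_ids), nrow(x$assignments),
              min(x$n_clusters), max(x$n_clusters),
              as.integer(stats::median(x$n_clusters))))
  invisible(x)
}

cluster_stats <- function(z, alt, depth) {
  ids <- sort(unique(z))
  A <- rowsum(alt, z)[as.character(ids), , drop = FALSE]
  D <- rowsum(depth, z)[as.character(ids), , drop = FALSE]
  list(ids = ids, n = as.vector(table(factor(z, levels = ids))), A = A, D = D)
}

#' Point-estimate mutation clusters from a posterior trace
#'
#' The partition is the retained Gibbs state with maximal joint posterior
#' density (deterministic given the trace). Clusters smaller than
#' `min_cluster_size` are dissolved and their members reassigned to the
#' surviving cluster under which their counts are most likely; cluster
#' VAFs `theta_hat` are conditional posterior means `(1 + sum alt) /
#' (2 + sum depth)` under the final partition, and cellular prevalence is
#' `min(1, 2 theta_hat)` (heterozygous diploid mapping).
#'
#' @param trace a `dp_trace` from [gibbs_run()].
#' @param table the [variant_table()] the trace was fitted on.
#' @param min_cluster_size smallest reportable cluster (default 5).
#' @return object of class `mutation_clusters`: `assignment` (named
#'   vector mutation id -> cluster id), `clusters` (data.frame
#'   `cluster_id`, `burden`), `theta_hat` and `prevalence` (clusters x
#'   samples matrices).
#' @export
point_estimate <- function(trace, table, min_cluster_size = 5L) {
  stopifnot(inherits(trace, "dp_trace"), inherits(table, "variant_table"))
  if (!identical(trace$mutation_ids, table$sites$id)) {
    stop("trace and table refer to different mutations")
  }
  z <- trace$assignments[which.max(trace$log_post), ]
  st <- cluster_stats(z, table$alt, table$depth)

  small <- st$ids[st$n < min_cluster_size]
  keep <- setdiff(st$ids, small)
  if (length(keep) == 0L) {
    stop("degenerate partition: every cluster is below min_cluster_size")
  }
  if (length(small) > 0L) {
    ki <- match(keep, st$ids)
    theta <- (1 + st$A[ki, , drop = FALSE]) / (2 + st$D[ki, , drop = FALSE])
    theta <- pmin(pmax(theta, 1e-9), 1 - 1e-9)
    for (m in which(z %in% small)) {
      ll <- vapply(seq_along(keep), function(k) {
        sum(dbinom(table$alt[m, ], table$depth[m, ], theta[k, ], log = TRUE))
      }, 0)
      z[m] <- keep[which.max(ll)]
    }
    st <- cluster_stats(z, table$alt, table$depth)
  }

  relabel <- setNames(seq_along(st$ids), st$ids)
  assignment <- setNames(as.integer(relabel[as.character(z)]), table$sites$id)
  theta_hat <- (1 + st$A) / (2 + st$D)
  rownames(theta_hat) <- paste0("cluster", seq_along(st$ids))
  colnames(theta_hat) <- table$samples
  structure(list(assignment = assignment,
                 clusters = data.frame(cluster_id = seq_along(st$ids),
                                       burden = st$n),
                 theta_hat = theta_hat,
                 prevalence = vaf_to_prevalence(theta_hat)),
            class = "mutation_clusters")
}

#' @exportS3Method base::print
print.mutation_clusters <- function(x, ...) {
  cat(sprintf("mutation_clusters: %d clusters over %d mutations\n",
              nrow(x$clusters), length(x$assignment)))
  df <- cbind(x$clusters, round(x$theta_hat, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Posterior draws of cluster VAFs under a fixed partition
#'
#' With the partition held fixed, `theta_{k,s}` is conjugate:
#' Beta(1 + sum alt, 1 + sum(depth - alt)) over the cluster's members.
#' Used for reporting credible intervals on cluster VAFs.
#'
#' @param clusters a `mutation_clusters` object.
#' @param table the matching [variant_table()].
#' @param n_draws number of posterior draws.
#' @param seed integer seed.
#' @return array `n_draws` x clusters x samples.
#' @export
posterior_theta <- function(clusters, table, n_draws = 1000L, seed = 1L) {
  stopifnot(inherits(clusters, "mutation_clusters"))
  set.seed(as.integer(seed))
  st <- cluster_stats(clusters$assignment, table$alt, table$depth)
  K <- length(st$ids); S <- ncol(table$alt)
  out <- array(NA_real_, c(n_draws, K, S),
               dimnames = list(NULL, rownames(clusters$theta_hat), table$samples))
  for (k in seq_len(K)) {
    for (s in seq_len(S)) {
      out[, k, s] <- rbeta(n_draws, 1 + st$A[k, s], 1 + st$D[k, s] - st$A[k, s])
    }
  }
  out
}
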