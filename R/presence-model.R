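#' Beta-binomial log density
#'
#' Mean/overdispersion parameterisation: success probability is
#' Beta-distributed with mean `mu` and intra-site correlation `rho`
#' (`shape1 = mu(1-rho)/rho`, `shape2 = (1-mu)(1-rho)/rho`). As `rho`
#' approaches 0 the distribution reduces to Binomial(`size`, `mu`);
#' values of `rho` below 1e-12 are evaluated on the binomial limit for
#' numerical stability.
#'
#' @param x counts (vectorised).
#' @param size number of trials.
#' @param mu mean success probability in (0, 1).
#' @param rho overdispersion in \[0, 1).
#' @return log densities.
#' @export
dbetabinom_log <- function(x, size, mu, rho) {
  if (rho < 1e-12) return(dbinom(x, size, mu, log = TRUE))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
}

#' Beta-binomial upper-tail probability
#'
#' `P(X >= alt)` under the site error model; 1 when `alt <= 0`.
#'
#' @param alt observed variant reads.
#' @param size depth.
#' @param mu,rho model parameters, see [dbetabinom_log()].
#' @return upper-tail probability.
#' @export
pbetabinom_upper <- function(alt, size, mu, rho) {
  if (alt <= 0) return(1)
  if (alt > size) return(0)
  k <- alt:size
  min(1, sum(exp(dbetabinom_log(k, size, mu, rho))))
}

default_rho_grid <- function(n = 25L, lo = 1e-6, hi = 0.89) {
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Fit the site-specific sequencing-error model
#'
#' Likelihood maximisation on a logarithmic grid for the overdispersion
#' `rho`, with the error rate `mu` profiled as the depth-weighted mean
#' VAF (total alt / total depth), floored at `mu_min` (the pure-noise
#' floor) and capped at `mu_max`. Among grid values whose log-likelihood
#' lies within `rho_penalty` of the maximum, the smallest `rho` is
#' selected: the boundary (binomial) model is preferred whenever the data
#' cannot distinguish it from an overdispersed one (profile-likelihood
#' parsimony at half the 95% chi-square(1) quantile), which stops
#' small-sample variance noise from masquerading as overdispersion.
#' Deterministic.
#'
#' @param alt_counts,depths per-sample counts for one site; at least two
#'   samples with depth >= 1 are required.
#' @param rho_grid overdispersion grid (default 25 log-spaced points in
#'   \[1e-6, 0.89\]).
#' @param mu_min,mu_max bounds on the error rate.
#' @param rho_penalty log-likelihood margin for the parsimony rule.
#' @return list of class `site_error_model`: `mu`, `rho`,
#'   `n_samples_used`, `loglik`.
#' @export
fit_site_error <- function(alt_counts, depths, rho_grid = default_rho_grid(),
                           mu_min = 1e-6, mu_max = 0.499, rho_penalty = 1.92) {
  keep <- depths >= 1
  if (sum(keep) < 2L) stop("need at least two samples with depth >= 1")
  a <- alt_counts[keep]; d <- depths[keep]
  mu <- min(max(sum(a) / sum(d), mu_min), mu_max)
  if (sum(a) == 0L) {
    # Overdispersion is unidentifiable without any variant reads (the
    # likelihood of all-zero counts grows monotonically in rho, which would
    # pin rho at the top of the grid and fatten the tail for no reason);
    # default to the binomial floor.
    return(structure(list(mu = mu, rho = rho_grid[1], n_samples_used = sum(keep),
                          loglik = sum(dbetabinom_log(a, d, mu, rho_grid[1]))),
                     class = "site_error_model"))
  }
  ll <- vapply(rho_grid, function(r) sum(dbetabinom_log(a, d, mu, r)), 0)
  j <- min(which(ll >= max(ll) - rho_penalty))
  structure(list(mu = mu, rho = rho_grid[j], n_samples_used = sum(keep),
                 loglik = ll[j]),
            class = "site_error_model")
}

#' Presence p-value for one sample at one site
#'
#' Upper-tail probability of at least `alt` variant reads under the
#' fitted beta-binomial error model. `p = 1` when `alt = 0`; depth 0 is a
#' degenerate input and also yields `p = 1` (flagged via attribute).
#'
#' @param alt,depth observed counts.
#' @param model a `site_error_model` from [fit_site_error()].
#' @return p-value (attribute `degenerate` set when depth is 0).
#' @export
presence_pvalue <- function(alt, depth, model) {
  stopifnot(inherits(model, "site_error_model"), alt <= depth || depth == 0)
  if (depth == 0) return(structure(1, degenerate = TRUE))
  pbetabinom_upper(alt, depth, model$mu, model$rho)
}

#' Call true presence of somatic variants per sample
#'
#' For each (somatic) site, the sequencing-error model is estimated from
#' the samples that do not carry the variant: candidates with naive
#' VAF >= `vaf_fit_max` are excluded, and the sample under test is always
#' left out of its own fit so a weakly supported carrier cannot deflate
#' its own error estimate. Calling then iterates: samples called present
#' are removed from the error fits of the remaining samples and the site
#' is re-tested until the calls stabilise, so a carrier that happened to
#' draw few variant reads (slipping under the VAF cut-off) cannot inflate
#' the apparent noise for the other tissues. The per-site error rate is
#' floored at a pooled cohort-wide rate estimated from all low-VAF cells.
#' Sites where fewer than two usable samples remain fall back to the
#' pooled global model (logged). Samples with `alt = 0` are never present
#' (`p = 1`).
#'
#' @param table a [variant_table()] restricted to somatic-labelled sites.
#' @param threshold presence p-value threshold (default 1e-3, no
#'   multiplicity correction).
#' @param vaf_fit_max naive-VAF cut-off below which a sample is considered
#'   a non-carrier usable for error fitting (default 0.1).
#' @param rho_grid overdispersion grid, see [fit_site_error()].
#' @return object of class `presence_call`: `p` and `present` matrices
#'   (sites x samples), `fallback` logical matrix (pooled model used),
#'   `global` the pooled model, `threshold`.
#' @export
call_presence <- function(table, threshold = 1e-3, vaf_fit_max = 0.1,
                          rho_grid = default_rho_grid()) {
  stopifnot(inherits(table, "variant_table"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  A <- table$alt; D <- table$depth
  M <- nrow(A); S <- ncol(A)
  vaf <- naive_vaf(table)
  low <- D > 0L & vaf < vaf_fit_max

  # Pooled cohort-wide error floor from all non-carrier cells.
  if (!any(low)) stop("no low-VAF cells available to estimate the error floor")
  global_mu <- max(sum(A[low]) / sum(D[low]), 1e-6)
  n_pool <- min(sum(low), 2000L)
  pool_idx <- which(low)[seq_len(n_pool)]
  global <- fit_site_error(A[pool_idx], D[pool_idx], rho_grid = rho_grid,
                           mu_min = global_mu)

  p <- matrix(1, M, S, dimnames = dimnames(A))
  fallback <- matrix(FALSE, M, S, dimnames = dimnames(A))
  called <- matrix(FALSE, M, S)
  update_row <- function(i, excl) {
    # test every sample with variant reads against a model fitted on the
    # remaining low-VAF, not-called samples
    for (s in which(A[i, ] > 0L)) {
      fit_set <- low[i, ] & !excl
      fit_set[s] <- FALSE
      if (sum(fit_set) < 2L) {
        model <- global
        fallback[i, s] <<- TRUE
      } else {
        model <- fit_site_error(A[i, fit_set], D[i, fit_set],
                                rho_grid = rho_grid, mu_min = global_mu)
        fallback[i, s] <<- FALSE
      }
      p[i, s] <<- pbetabinom_upper(A[i, s], D[i, s], model$mu, model$rho)
    }
  }
  active <- which(rowSums(A) > 0L)
  for (i in active) update_row(i, rep(FALSE, S))
  called <- p < threshold
  # Samples called as carriers are excluded from error fits and the
  # affected sites re-tested, until the calls stabilise: a weakly
  # supported carrier below the VAF cut-off must not inflate the noise
  # estimate for the other samples. Exclusions only grow, so this
  # terminates (at most S passes; two in practice).
  repeat {
    redo <- active[vapply(active, function(i) any(low[i, ] & called[i, ]), TRUE)]
    if (length(redo) == 0L) break
    for (i in redo) update_row(i, called[i, ])
    new_called <- called | (p < threshold)
    if (identical(new_called, called)) break
    called <- new_called
  }
  structure(list(p = p, present = called, fallback = fallback,
                 global = global, threshold = threshold),
            class = "presence_call")
}

#' @exportS3Method base::print
print.presence_call <- function(x, ...) {
  cat(sprintf("presence_call: %d sites x %d samples, %d present at p < %g\n",
              nrow(x$p), ncol(x$p), sum(x$present), x$threshold))
  invisible(x)
}

#' Shared-mutation counts between samples
#'
#' Number of sites called present in both members of every sample pair —
#' the shared-branch support used to relate tissues.
#'
#' @param presence a `presence_call`.
#' @return symmetric integer matrix, samples x samples (diagonal: sites
#'   present in the sample).
#' @export
shared_mutation_counts <- function(presence) {
  stopifnot(inherits(presence, "presence_call"))
  pr <- presence$present
  storage.mode(pr) <- "integer"
  crossprod(pr)
}
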