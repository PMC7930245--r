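# Independent oracles and small builders shared across tests. These are
# deliberately written apart from the package implementation.

# Lower-tail binomial probability by direct enumeration of the tail.
brute_binom_lower <- function(alt, depth, p = 0.5) {
  k <- 0:alt
  sum(exp(lchoose(depth, k) + k * log(p) + (depth - k) * log1p(-p)))
}

# Step-up Benjamini-Hochberg, written from the definition.
brute_bh <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Beta-binomial upper tail by direct summation (shares no code with the
# package: density written from the Beta-function definition).
brute_bb_upper <- function(alt, n, mu, rho) {
  if (alt <= 0) return(1)
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  k <- alt:n
  sum(choose(n, k) * beta(k + a, n - k + b) / beta(a, b))
}

# Quick variant-table builder from count matrices.
make_table <- function(alt, depth, samples = paste0("S", seq_len(ncol(depth)))) {
  n <- nrow(depth)
  variant_table(data.frame(chrom = "1", pos = seq_len(n), ref = "A", alt = "T",
                           stringsAsFactors = FALSE),
                alt, depth, samples)
}

# Metadata with the first sample as tumour, the rest matched normals.
make_meta <- function(samples, sex = "female") {
  sample_meta(samples, c("tumour", rep("normal", length(samples) - 1L)),
              c(FALSE, rep(TRUE, length(samples) - 1L)), sex)
}

# Build a minimal mutation_clusters object from a prevalence matrix.
make_clusters <- function(prev, burden = rep(10L, nrow(prev))) {
  theta <- prev / 2
  rownames(theta) <- rownames(prev) <- paste0("cluster", seq_len(nrow(prev)))
  structure(list(assignment = setNames(rep(seq_len(nrow(prev)), burden),
                                       sprintf("m%03d", seq_len(sum(burden)))),
                 clusters = data.frame(cluster_id = seq_len(nrow(prev)),
                                       burden = burden),
                 theta_hat = theta,
                 prevalence = prev),
            class = "mutation_clusters")
}

# All rooted labelled trees over clusters (parent functions), kept when the
# pigeonhole and containment constraints hold; used to cross-check the
# greedy reconciliation against exhaustive enumeration.
enumerate_valid_trees <- function(prev, epsilon) {
  K <- nrow(prev)
  root_prev <- rep(1, ncol(prev))
  choices <- rep(list(0:K), K)  # 0 = attach to the unit root
  grids <- do.call(expand.grid, choices)
  valid <- list()
  for (r in seq_len(nrow(grids))) {
    parent <- as.integer(grids[r, ])
    if (any(parent == seq_len(K))) next
    # acyclic?
    ok <- TRUE
    for (k in seq_len(K)) {
      seen <- integer(0); cur <- k
      while (cur != 0L) {
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur); cur <- parent[cur]
      }
      if (!ok) break
    }
    if (!ok) next
    # containment + capacity per node (0 = root at prevalence 1)
    for (v in 0:K) {
      pv <- if (v == 0L) root_prev else prev[v, ]
      ch <- which(parent == v)
      if (length(ch) == 0L) next
      if (any(colSums(prev[ch, , drop = FALSE]) > pv + epsilon) ||
          any(apply(prev[ch, , drop = FALSE], 1, function(x) any(x - epsilon > pv)))) {
        ok <- FALSE; break
      }
    }
    if (ok) valid[[length(valid) + 1L]] <- parent
  }
  valid
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
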