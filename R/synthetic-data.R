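#' Configuration for the synthetic clone-tree generator
#'
#' The defaults describe the benchmark cohort the package is validated on:
#' a patient sampled across several tissues at ~40x whole-genome depth,
#' with an embryonic clone tree of a handful of clones each carrying
#' 150-300 mutations, a low per-read miscall rate, and a few hundred
#' germline variants at VAF 0.5 in every sample.
#'
#' @param n_samples number of sequenced samples (tissues), >= 1.
#' @param n_clones number of clones (tree nodes, including the ubiquitous
#'   root), >= 1.
#' @param burden_range integer range (min, max) of mutations per branch.
#' @param depth_mean expected sequencing depth; depths are Poisson,
#'   truncated at >= 1.
#' @param error_rate per-site per-read miscall probability in [0, 0.01].
#' @param n_germline number of germline variants to inject.
#' @param sex `"male"` or `"female"`.
#' @param seed integer seed; all generator randomness derives from it.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 5L, n_clones = 4L,
                              burden_range = c(150L, 300L),
                              depth_mean = 40, error_rate = 0.002,
                              n_germline = 500L,
                              sex = c("female", "male"), seed = 1L) {
  sex <- match.arg(sex)
  n_samples <- as.integer(n_samples); n_clones <- as.integer(n_clones)
  burden_range <- as.integer(burden_range); n_germline <- as.integer(n_germline)
  if (is.na(n_samples) || n_samples < 1L) stop("n_samples must be a positive integer")
  if (is.na(n_clones) || n_clones < 1L) stop("n_clones must be a positive integer")
  if (length(burden_range) != 2L || any(burden_range < 1L) ||
      burden_range[1] > burden_range[2]) {
    stop("burden_range must be an increasing pair of positive integers")
  }
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (error_rate < 0 || error_rate > 0.01) stop("error_rate must be in [0, 0.01]")
  if (n_germline < 0L) stop("n_germline must be non-negative")
  structure(list(n_samples = n_samples, n_clones = n_clones,
                 burden_range = burden_range, depth_mean = depth_mean,
                 error_rate = error_rate, n_germline = n_germline,
                 sex = sex, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a ground-truth clone tree
#'
#' Draws a random rooted tree of `n_clones` nodes, per-sample cellular
#' prevalences by recursive stick-breaking from the root down (the root is
#' the ubiquitous embryonic lineage at prevalence 1 in every sample), and
#' per-branch mutation burdens. By construction every parent strictly
#' dominates the sum of its children's prevalences in every sample by a
#' margin of at least 0.02, so the pigeonhole constraint holds exactly and
#' the tree is identifiable.
#'
#' @param config a [simulation_config()].
#' @return object of class `truth_tree`: list with `nodes` (data.frame
#'   `node_id`, `parent_id`; `NA` parent marks the root), `prevalence`
#'   (nodes x samples matrix), `branch_burden` (per node), `assignment`
#'   (named vector, mutation id -> node id), `germline_ids` (filled by
#'   [inject_germline()]), `seed`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  K <- config$n_clones
  S <- config$n_samples
  set.seed(derive_seed(config$seed, 1L))

  parent <- rep(NA_integer_, K)
  if (K > 1L) {
    for (k in 2:K) parent[k] <- sample.int(k - 1L, 1L)
  }

  # ancestor relation (excluding self), for the identifiability check below
  is_anc <- matrix(FALSE, K, K)
  for (k in seq_len(K)) {
    cur <- parent[k]
    while (!is.na(cur)) { is_anc[cur, k] <- TRUE; cur <- parent[cur] }
  }

  # Minimum prevalence each subtree needs so that every parent can dominate
  # the sum of its children by the 0.02 margin with room to spare: a leaf
  # needs only to stay positive, an internal node needs the margin plus its
  # children's needs.
  need <- rep(0.005, K)
  for (v in rev(seq_len(K))) {
    ch <- which(parent == v)
    if (length(ch) > 0L) need[v] <- 0.022 + sum(need[ch])
  }
  if (need[1] > 1) {
    stop("tree too large for the 0.02 dominance margin; reduce n_clones")
  }

  # Stick-breaking, parents before children (node ids are in creation order
  # so parent[k] < k always). Per sample, the parent's stick less the 0.02
  # dominance margin and the children's reserved needs is split
  # Dirichlet-style among the children plus a retained leftover;
  # independent per-sample weights give each clone a distinctive
  # prevalence profile across tissues. Draws are redrawn until every pair
  # of clones not in an ancestor relation mutually crosses (each exceeds
  # the other by a clear margin in at least one sample): without crossing
  # the pigeonhole constraint admits spurious nestings and no
  # reconciliation method could recover the topology. When the geometry
  # cannot support the full 0.1 crossing margin (few samples, many
  # siblings) the requirement is progressively relaxed.
  draw_prev <- function() {
    prev <- matrix(0, nrow = K, ncol = S,
                   dimnames = list(paste0("clone", seq_len(K)),
                                   paste0("S", seq_len(S))))
    prev[1, ] <- 1
    for (v in seq_len(K)) {
      ch <- which(parent == v)
      if (length(ch) == 0L) next
      for (s in seq_len(S)) {
        free <- prev[v, s] - 0.02 - sum(need[ch])
        g <- rgamma(length(ch) + 1L, shape = 1.2, rate = 1)
        prev[ch, s] <- need[ch] + free * g[-1] / sum(g)
      }
    }
    prev
  }
  identifiable <- function(prev, delta) {
    if (K < 2L) return(TRUE)
    for (i in seq_len(K - 1L)) {
      for (j in seq(i + 1L, K)) {
        if (is_anc[i, j] || is_anc[j, i]) {
          # an ancestor must clearly exceed its descendant somewhere, or
          # the two clones collapse to one VAF profile
          if (max(abs(prev[i, ] - prev[j, ])) <= delta) return(FALSE)
        } else if (max(prev[i, ] - prev[j, ]) <= delta ||
                   max(prev[j, ] - prev[i, ]) <= delta) {
          return(FALSE)
        }
      }
    }
    TRUE
  }
  prev <- draw_prev()
  delta <- 0.1
  tries <- 1L
  while (!identifiable(prev, delta)) {
    tries <- tries + 1L
    if (tries %% 200L == 0L) delta <- delta / 2
    if (delta < 0.01) break
    prev <- draw_prev()
  }

  burden <- sample(seq(config$burden_range[1], config$burden_range[2]),
                   K, replace = TRUE)
  mut_ids <- sprintf("m%05d", seq_len(sum(burden)))
  assignment <- setNames(rep(seq_len(K), times = burden), mut_ids)

  structure(list(nodes = data.frame(node_id = seq_len(K), parent_id = parent),
                 prevalence = prev, branch_burden = burden,
                 assignment = assignment, germline_ids = character(0),
                 seed = config$seed),
            class = "truth_tree")
}

#' @exportS3Method base::print
print.truth_tree <- function(x, ...) {
  cat(sprintf("truth_tree: %d clones, %d samples, %d somatic + %d germline mutations\n",
              nrow(x$nodes), ncol(x$prevalence), length(x$assignment),
              length(x$germline_ids)))
  invisible(x)
}

#' Independently verify a truth tree
#'
#' A checker deliberately written apart from the generator: verifies the
#' parent references form a single-rooted acyclic tree, prevalences lie in
#' \[0, 1\] with the root at 1 everywhere, burdens are non-negative and sum
#' to the number of somatic mutations, and the pigeonhole constraint (sum
#' of children's prevalences does not exceed the parent's, less `margin`)
#' holds for every node and sample.
#'
#' @param tree a `truth_tree`.
#' @param margin required dominance margin (0 checks the plain constraint).
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
check_truth_tree <- function(tree, margin = 0) {
  v <- character(0)
  nodes <- tree$nodes
  roots <- which(is.na(nodes$parent_id))
  if (length(roots) != 1L) v <- c(v, sprintf("expected 1 root, found %d", length(roots)))
  for (k in nodes$node_id) {
    seen <- integer(0); cur <- k
    while (!is.na(cur)) {
      if (cur %in% seen) { v <- c(v, sprintf("cycle through node %d", k)); break }
      seen <- c(seen, cur)
      cur <- nodes$parent_id[match(cur, nodes$node_id)]
    }
  }
  p <- tree$prevalence
  if (any(p < 0 | p > 1)) v <- c(v, "prevalence outside [0,1]")
  if (length(roots) == 1L && any(abs(p[roots, ] - 1) > 1e-12)) {
    v <- c(v, "root prevalence != 1 in some sample")
  }
  for (k in nodes$node_id) {
    ch <- nodes$node_id[!is.na(nodes$parent_id) & nodes$parent_id == k]
    if (length(ch) == 0L) next
    csum <- colSums(p[ch, , drop = FALSE])
    bad <- which(csum > p[k, ] - margin + 1e-12)
    if (length(bad) > 0L) {
      v <- c(v, sprintf("pigeonhole violated at node %d, sample(s) %s",
                        k, paste(bad, collapse = ",")))
    }
  }
  if (any(tree$branch_burden < 0)) v <- c(v, "negative branch burden")
  if (sum(tree$branch_burden) != length(tree$assignment)) {
    v <- c(v, "branch burdens do not sum to the somatic mutation count")
  }
  list(ok = length(v) == 0L, violations = v)
}

# Poisson depths truncated at >= 1 (zero-depth cells are resampled).
rpois_trunc1 <- function(n, lambda) {
  d <- rpois(n, lambda)
  while (any(d == 0L)) {
    z <- d == 0L
    d[z] <- rpois(sum(z), lambda)
  }
  d
}

#' Simulate read counts for a truth tree
#'
#' Each somatic mutation sits on one clone; in each sample its expected
#' VAF is half the clone's cellular prevalence (heterozygous diploid
#' assumption). Depth is Poisson(`depth_mean`) truncated at >= 1 per cell;
#' alt reads are Binomial(depth, VAF(1-e) + (1-VAF)e) with per-read
#' miscall rate `e = error_rate`, so sites absent from a sample still pick
#' up error support at rate `e`.
#'
#' @param truth a `truth_tree` from [simulate_truth()].
#' @param config the matching [simulation_config()].
#' @return a [variant_table()] with one row per somatic mutation, in
#'   `truth$assignment` order; site ids equal mutation ids.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "truth_tree"), inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 2L))
  M <- length(truth$assignment)
  S <- config$n_samples
  e <- config$error_rate

  vaf <- truth$prevalence[truth$assignment, , drop = FALSE] / 2
  p_eff <- vaf * (1 - e) + (1 - vaf) * e
  depth <- matrix(rpois_trunc1(M * S, config$depth_mean), nrow = M)
  alt <- matrix(rbinom(M * S, as.vector(depth), as.vector(p_eff)), nrow = M)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt_base <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  chrom <- as.character(rep_len(1:22, M))
  pos <- integer(M)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- 10000L + 173L * seq_along(idx)
  }
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt_base,
                      id = names(truth$assignment), stringsAsFactors = FALSE)
  variant_table(sites, alt, depth, paste0("S", seq_len(S)))
}

#' Append germline variants to a simulated table
#'
#' Germline heterozygous variants have expected VAF 0.5 in every sample,
#' including the matched reference; they provide the positives for the
#' germline/somatic classifier. Injected site ids are recorded in the
#' returned truth so simulated truth distinguishes germline from somatic
#' exactly.
#'
#' @param table a [variant_table()] from [simulate_counts()].
#' @param truth the matching `truth_tree`.
#' @param config the matching [simulation_config()].
#' @return list with elements `table` (the table with `n_germline` sites
#'   appended) and `truth` (with `germline_ids` filled in).
#' @export
inject_germline <- function(table, truth, config) {
  stopifnot(inherits(table, "variant_table"), inherits(truth, "truth_tree"),
            inherits(config, "simulation_config"))
  G <- config$n_germline
  if (G == 0L) return(list(table = table, truth = truth))
  set.seed(derive_seed(config$seed, 3L))
  S <- length(table$samples)

  depth <- matrix(rpois_trunc1(G * S, config$depth_mean), nrow = G)
  alt <- matrix(rbinom(G * S, as.vector(depth), 0.5), nrow = G)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, G, replace = TRUE)
  alt_base <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  ids <- sprintf("g%05d", seq_len(G))
  chrom <- as.character(rep_len(1:22, G))
  pos <- integer(G)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- 5000000L + 173L * seq_along(idx)
  }
  gsites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt_base,
                       id = ids, stringsAsFactors = FALSE)
  out <- variant_table(rbind(table$sites[names(table$sites) != "chrom_class"],
                             gsites),
                       rbind(table$alt, alt),
                       rbind(table$depth, depth),
                       table$samples)
  truth$germline_ids <- ids
  list(table = out, truth = truth)
}

#' Simulate a complete benchmark data set
#'
#' Convenience wrapper: [simulate_truth()], [simulate_counts()],
#' [inject_germline()], plus sample metadata (first sample labelled
#' `tumour`, remaining samples normal tissues in the matched-reference
#' set).
#'
#' @param config a [simulation_config()].
#' @return list with `truth`, `table`, `meta`.
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_truth(config)
  table <- simulate_counts(truth, config)
  inj <- inject_germline(table, truth, config)
  tissues <- c("tumour", rep_len(c("blood", "kidney", "hilum", "skin",
                                   "muscle", "nerve_root", "fat"),
                                 max(0L, config$n_samples - 1L)))
  tissues <- tissues[seq_len(config$n_samples)]
  meta <- sample_meta(paste0("S", seq_len(config$n_samples)), tissues,
                      c(FALSE, rep(TRUE, config$n_samples - 1L)),
                      config$sex)
  list(truth = inj$truth, table = inj$table, meta = meta)
}
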