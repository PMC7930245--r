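#' Map cluster VAFs to cellular prevalence
#'
#' Under the heterozygous diploid assumption a clone at cellular
#' prevalence f yields VAF f/2, so prevalence is `2 * theta`, capped at 1
#' (sampling noise can push VAF above 0.5).
#'
#' @param theta_hat numeric VAFs in \[0, 1\] (vector or matrix).
#' @return prevalences on the same shape.
#' @export
vaf_to_prevalence <- function(theta_hat) {
  stopifnot(all(theta_hat >= 0), all(theta_hat <= 1))
  p <- 2 * theta_hat
  p[p > 1] <- 1
  p
}

tree_depths <- function(parent) {
  depth <- rep(0L, length(parent))
  for (i in seq_along(parent)) {
    d <- 0L; cur <- parent[i]
    while (!is.na(cur)) { d <- d + 1L; cur <- parent[cur] }
    depth[i] <- d
  }
  depth
}

#' Reconcile mutation clusters into a clone tree
#'
#' Builds a rooted tree over clusters under the pigeonhole principle: in
#' every sample, the prevalences of a node's children may never sum to
#' more than the node's own prevalence (up to tolerance `epsilon`). The
#' cluster of highest mean prevalence is the root, provided it is
#' (near-)clonal in every sample; otherwise a synthetic unit root at
#' prevalence 1 is inserted. Remaining clusters are placed in descending
#' mean-prevalence order, each under the deepest node that both contains
#' it (parent prevalence >= cluster prevalence - epsilon in every sample)
#' and has spare capacity after its existing children; ties break on
#' minimal total prevalence slack. A cluster with no admissible parent
#' raises an incompatibility error naming the violating samples rather
#' than being silently placed.
#'
#' @param clusters a `mutation_clusters` object from [point_estimate()].
#' @param epsilon tolerance on the prevalence scale (default 0.05,
#'   absorbing binomial sampling noise at 30-40x depth).
#' @return object of class `clone_tree`: `nodes` (data.frame `node_id`,
#'   `parent_id`, `burden`, `synthetic_root`), `prevalence` and
#'   `clone_size` (nodes x samples), `epsilon`, `samples`.
#' @export
build_tree <- function(clusters, epsilon = 0.05) {
  stopifnot(inherits(clusters, "mutation_clusters"))
  if (!(epsilon >= 0 && epsilon < 1)) stop("epsilon must be in [0, 1)")
  prev <- clusters$prevalence
  K <- nrow(prev); S <- ncol(prev)
  ord <- order(rowMeans(prev), decreasing = TRUE)

  node_prev <- NULL; node_cluster <- integer(0); node_burden <- integer(0)
  parent <- integer(0); synthetic <- logical(0)
  first <- ord[1]
  if (all(prev[first, ] >= 1 - epsilon)) {
    node_prev <- prev[first, , drop = FALSE]
    node_cluster <- clusters$clusters$cluster_id[first]
    node_burden <- clusters$clusters$burden[first]
    parent <- NA_integer_; synthetic <- FALSE
    rest <- ord[-1]
  } else {
    node_prev <- matrix(1, 1, S)
    node_cluster <- NA_integer_; node_burden <- 0L
    parent <- NA_integer_; synthetic <- TRUE
    rest <- ord
  }

  for (k in rest) {
    pk <- prev[k, ]
    n_nodes <- nrow(node_prev)
    child_sum <- matrix(0, n_nodes, S)
    for (i in seq_len(n_nodes)) {
      ch <- which(parent == i)
      if (length(ch) > 0L) child_sum[i, ] <- colSums(node_prev[ch, , drop = FALSE])
    }
    containment <- vapply(seq_len(n_nodes), function(i)
      all(node_prev[i, ] >= pk - epsilon), TRUE)
    capacity <- vapply(seq_len(n_nodes), function(i)
      all(node_prev[i, ] - child_sum[i, ] >= pk - epsilon), TRUE)
    admissible <- which(containment & capacity)
    if (length(admissible) == 0L) {
      # report the least-violating candidate's failing samples
      slack <- vapply(seq_len(n_nodes), function(i)
        min(node_prev[i, ] - child_sum[i, ] - pk), 0)
      best <- which.max(slack)
      bad <- which(node_prev[best, ] - child_sum[best, ] < pk - epsilon)
      stop(sprintf(paste0("pigeonhole-infeasible cluster set: cluster %d ",
                          "(mean prevalence %.3f) has no admissible parent; ",
                          "closest candidate node %d violates sample(s) %s"),
                   clusters$clusters$cluster_id[k], mean(pk), best,
                   paste(colnames(prev)[bad], collapse = ", ")))
    }
    dep <- tree_depths(parent)
    cand <- admissible[dep[admissible] == max(dep[admissible])]
    if (length(cand) > 1L) {
      slack_tot <- vapply(cand, function(i) sum(node_prev[i, ] - pk), 0)
      cand <- cand[which.min(slack_tot)]
    }
    node_prev <- rbind(node_prev, pk)
    node_cluster <- c(node_cluster, clusters$clusters$cluster_id[k])
    node_burden <- c(node_burden, clusters$clusters$burden[k])
    parent <- c(parent, cand[1])
    synthetic <- c(synthetic, FALSE)
  }

  ids <- ifelse(is.na(node_cluster), "root",
                paste0("cluster", node_cluster))
  rownames(node_prev) <- ids
  colnames(node_prev) <- colnames(prev)
  nodes <- data.frame(node_id = ids,
                      parent_id = ifelse(is.na(parent), NA_character_,
                                         ids[parent]),
                      burden = node_burden,
                      synthetic_root = synthetic,
                      stringsAsFactors = FALSE)
  tree <- structure(list(nodes = nodes, prevalence = node_prev,
                         clone_size = NULL, epsilon = epsilon,
                         samples = colnames(prev)),
                    class = "clone_tree")
  tree$clone_size <- clone_sizes(tree)
  tree
}

#' Private clone fractions per node and sample
#'
#' A node's clone size in a sample is its prevalence minus the summed
#' prevalence of its children (clamped at 0): the fraction of cells
#' belonging to that clone and no descendant clone. These are the
#' per-tissue percentages annotated on the phylogenetic trees the
#' pipeline reports.
#'
#' @param tree a `clone_tree`.
#' @return numeric matrix, nodes x samples.
#' @export
clone_sizes <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  p <- tree$prevalence
  out <- p
  for (i in seq_len(nrow(p))) {
    ch <- which(!is.na(tree$nodes$parent_id) &
                  tree$nodes$parent_id == tree$nodes$node_id[i])
    if (length(ch) > 0L) {
      out[i, ] <- pmax(0, p[i, ] - colSums(p[ch, , drop = FALSE]))
    }
  }
  out
}

#' Verify the pigeonhole constraint on a clone tree
#'
#' Independent of [build_tree()] internals: checks the tree has a single
#' root and no cycles, and that for every node and sample the children's
#' prevalences sum to at most the node's prevalence plus `epsilon`.
#'
#' @param tree a `clone_tree`.
#' @param epsilon tolerance (defaults to the tree's own).
#' @return list: `pass` (logical), `violations` (data.frame `node_id`,
#'   `sample`, `excess`).
#' @export
check_pigeonhole <- function(tree, epsilon = tree$epsilon) {
  stopifnot(inherits(tree, "clone_tree"))
  nodes <- tree$nodes
  viol <- data.frame(node_id = character(0), sample = character(0),
                     excess = numeric(0), stringsAsFactors = FALSE)
  pass <- sum(is.na(nodes$parent_id)) == 1L
  for (i in seq_len(nrow(nodes))) {
    seen <- character(0); cur <- nodes$node_id[i]
    while (!is.na(cur)) {
      if (cur %in% seen) { pass <- FALSE; break }
      seen <- c(seen, cur)
      cur <- nodes$parent_id[match(cur, nodes$node_id)]
    }
  }
  p <- tree$prevalence
  for (i in seq_len(nrow(nodes))) {
    ch <- which(!is.na(nodes$parent_id) & nodes$parent_id == nodes$node_id[i])
    if (length(ch) == 0L) next
    csum <- colSums(p[ch, , drop = FALSE])
    excess <- csum - p[i, ] - epsilon
    bad <- which(excess > 1e-12)
    if (length(bad) > 0L) {
      pass <- FALSE
      viol <- rbind(viol, data.frame(node_id = nodes$node_id[i],
                                     sample = tree$samples[bad],
                                     excess = excess[bad],
                                     stringsAsFactors = FALSE))
    }
  }
  list(pass = pass, violations = viol)
}

#' @exportS3Method base::print
print.clone_tree <- function(x, ...) {
  cat(sprintf("clone_tree: %d nodes over %d samples (epsilon = %g)\n",
              nrow(x$nodes), length(x$samples), x$epsilon))
  df <- cbind(x$nodes[, c("node_id", "parent_id", "burden")],
              round(100 * x$clone_size, 1))
  print(df, row.names = FALSE)
  invisible(x)
}
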