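#' Full pipeline configuration
#'
#' Collects every stage parameter with range validation; unknown keys are
#' rejected. Defaults are the package-wide defaults of each stage.
#'
#' @param filter a [filter_config()].
#' @param presence_threshold presence p-value threshold.
#' @param presence_vaf_fit_max naive-VAF cut-off for error-model fitting.
#' @param n_iter,burn_in Gibbs sweeps and burn-in.
#' @param alpha_prior Gamma (shape, rate) prior on the DP concentration.
#' @param min_cluster_size smallest reportable cluster.
#' @param epsilon clone-tree prevalence tolerance.
#' @param seed integer seed for the whole run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_config(),
                            presence_threshold = 1e-3,
                            presence_vaf_fit_max = 0.1,
                            n_iter = 2000L, burn_in = 500L,
                            alpha_prior = c(1, 1),
                            min_cluster_size = 5L,
                            epsilon = 0.05, seed = 1L) {
  stopifnot(inherits(filter, "filter_config"))
  if (!(presence_threshold > 0 && presence_threshold < 1)) {
    stop("presence_threshold must be in (0, 1)")
  }
  if (!(presence_vaf_fit_max > 0 && presence_vaf_fit_max <= 0.5)) {
    stop("presence_vaf_fit_max must be in (0, 0.5]")
  }
  if (n_iter <= burn_in || burn_in < 0L) stop("need n_iter > burn_in >= 0")
  if (length(alpha_prior) != 2L || any(alpha_prior <= 0)) {
    stop("alpha_prior must be a positive (shape, rate) pair")
  }
  if (min_cluster_size < 1L) stop("min_cluster_size must be >= 1")
  if (!(epsilon >= 0 && epsilon < 1)) stop("epsilon must be in [0, 1)")
  structure(list(filter = filter,
                 presence_threshold = presence_threshold,
                 presence_vaf_fit_max = presence_vaf_fit_max,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 alpha_prior = as.numeric(alpha_prior),
                 min_cluster_size = as.integer(min_cluster_size),
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()] and
#' [filter_config()] (the latter nested under `filter:`). Unknown keys
#' are rejected.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  fargs <- y$filter
  y$filter <- NULL
  known <- setdiff(names(formals(pipeline_config)), "filter")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(fargs)) {
    funknown <- setdiff(names(fargs), names(formals(filter_config)))
    if (length(funknown) > 0L) {
      stop("unknown filter key(s): ", paste(funknown, collapse = ", "))
    }
    y$filter <- do.call(filter_config, fargs)
  }
  do.call(pipeline_config, y)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$filter <- unclass(out$filter)
  out
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical (alphabetically ordered) JSON serialisation;
#' changes iff any parameter changes.
#'
#' @param config a `pipeline_config`.
#' @return character hash.
#' @export
config_hash <- function(config) {
  lst <- config_as_list(config)
  lst$filter <- lst$filter[order(names(lst$filter))]
  lst <- lst[order(names(lst))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(lst, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full lineage-tracing pipeline
#'
#' Stages, in order: depth filtering, germline/somatic classification
#' (somatic sites retained), per-sample presence calling, DP clustering,
#' clone-tree reconciliation, and a report of pairwise shared-mutation
#' counts. Every artefact is written under `outdir` together with a
#' manifest recording the configuration hash and seed; identical
#' configuration and seed reproduce the bundle byte for byte. A stage
#' failure propagates with the stage name; artefacts of completed stages
#' are kept.
#'
#' @param table a [variant_table()] (all called sites).
#' @param meta a [sample_meta()] table.
#' @param config a [pipeline_config()].
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with the filtered table, classification,
#'   presence calls, trace, clusters, tree, shared-count matrix and
#'   manifest.
#' @export
run_pipeline <- function(table, meta, config = pipeline_config(),
                         outdir = tempfile("somaclone_run_")) {
  stopifnot(inherits(table, "variant_table"), inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  art <- function(x) file.path(outdir, x)

  dfres <- run_stage("depth_filter", depth_filter(table, meta, config$filter))
  cls <- run_stage("classify",
                   classify_germline_somatic(dfres$table, meta, config$filter))
  audit <- merge(data.frame(id = table$sites$id, stringsAsFactors = FALSE),
                 cls, by = "id", all.x = TRUE, sort = FALSE)
  audit$filter_rule <- dfres$log$rule[match(audit$id, dfres$log$id)]
  audit$label[!is.na(audit$filter_rule)] <- "depth_filtered"
  write.table(audit, art("site_audit.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  somatic <- run_stage("classify",
                       subset_sites(dfres$table, cls$label == "somatic"))
  write_variant_tsv(somatic, art("somatic_sites.tsv"))

  presence <- run_stage("presence",
                        call_presence(somatic,
                                      threshold = config$presence_threshold,
                                      vaf_fit_max = config$presence_vaf_fit_max))
  write_presence_tsv(presence, art("presence.tsv"))

  trace <- run_stage("cluster",
                     gibbs_run(somatic, n_iter = config$n_iter,
                               burn_in = config$burn_in,
                               seed = derive_seed(config$seed, 11L),
                               alpha_prior = config$alpha_prior))
  clusters <- run_stage("cluster",
                        point_estimate(trace, somatic,
                                       min_cluster_size = config$min_cluster_size))
  write.table(data.frame(mutation_id = names(clusters$assignment),
                         cluster_id = unname(clusters$assignment)),
              art("cluster_assignment.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  summ <- cbind(clusters$clusters, signif(clusters$theta_hat, 6))
  write.table(summ, art("cluster_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_coassignment(trace$coassign, art("coassignment.mtx"))

  tree <- run_stage("tree", build_tree(clusters, epsilon = config$epsilon))
  write_tree_json(tree, art("clone_tree.json"))
  write_tree_newick(tree, art("clone_tree.nwk"))

  shared <- run_stage("report", shared_mutation_counts(presence))
  write.table(data.frame(sample = rownames(shared), shared,
                         check.names = FALSE),
              art("shared_mutations.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  manifest <- list(package = "somaclone",
                   version = as.character(packageVersion("somaclone")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   config = config_as_list(config),
                   n_sites_input = nrow(table$sites),
                   n_sites_somatic = nrow(somatic$sites),
                   artefacts = c("site_audit.tsv", "somatic_sites.tsv",
                                 "presence.tsv", "cluster_assignment.tsv",
                                 "cluster_summary.tsv", "coassignment.mtx",
                                 "clone_tree.json", "clone_tree.nwk",
                                 "shared_mutations.tsv"))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(filtered = dfres, classification = cls, somatic = somatic,
                 presence = presence, trace = trace, clusters = clusters,
                 tree = tree, shared = shared, manifest = manifest,
                 outdir = outdir))
}
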