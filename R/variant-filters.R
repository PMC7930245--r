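#' Filtering and classification parameters
#'
#' Defaults reproduce the configured stringency of the analysis this
#' package implements: somatic calls at BH-adjusted q < 1e-5, removal of
#' sites at consistently low (<15x) or high (>50x) depth, thresholds
#' halved on X/Y for a male patient.
#'
#' @param q_cutoff FDR cut-off below which a site is called somatic.
#' @param depth_min,depth_max consistent-depth bounds (reads).
#' @param germline_vaf_null null VAF of a heterozygous germline variant.
#' @param sex_halving halve depth thresholds on X/Y for a male patient.
#' @param aggregate `"reference"` aggregates alt/depth over the matched
#'   normal samples only; `"all"` over every sample of the patient.
#' @param consistent `"every_sample"` removes a site only when the depth
#'   rule holds in each sample; `"mean"` applies the rule to mean depth.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(q_cutoff = 1e-5, depth_min = 15, depth_max = 50,
                          germline_vaf_null = 0.5, sex_halving = TRUE,
                          aggregate = c("all", "reference"),
                          consistent = c("every_sample", "mean")) {
  if (!(q_cutoff > 0 && q_cutoff < 1)) stop("q_cutoff must be in (0, 1)")
  if (!(depth_min < depth_max)) stop("depth_min must be below depth_max")
  if (!(germline_vaf_null > 0 && germline_vaf_null < 1)) {
    stop("germline_vaf_null must be in (0, 1)")
  }
  structure(list(q_cutoff = q_cutoff, depth_min = depth_min,
                 depth_max = depth_max, germline_vaf_null = germline_vaf_null,
                 sex_halving = isTRUE(sex_halving),
                 aggregate = match.arg(aggregate),
                 consistent = match.arg(consistent)),
            class = "filter_config")
}

#' One-sided binomial exact test against the germline expectation
#'
#' Lower-tail probability `P(X <= alt_total)` for
#' `X ~ Binomial(depth_total, vaf_null)`: a small p-value is evidence that
#' the aggregated VAF across the matched tissues lies below the germline
#' heterozygous expectation, i.e. that the variant is somatic.
#'
#' @param alt_total aggregated variant-supporting reads (vectorised).
#' @param depth_total aggregated depth; cells with depth 0 yield `NA`
#'   (the test is undefined; such sites are reported unclassifiable).
#' @param vaf_null null VAF, default 0.5.
#' @return numeric vector of exact lower-tail p-values.
#' @export
binomial_germline_pvalue <- function(alt_total, depth_total, vaf_null = 0.5) {
  if (any(alt_total < 0) || any(depth_total < 0)) stop("counts must be non-negative")
  if (any(alt_total > depth_total)) stop("alt_total must not exceed depth_total")
  p <- pbinom(alt_total, depth_total, vaf_null)
  p[depth_total == 0] <- NA_real_
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values; a thin wrapper over
#' [stats::p.adjust()] so the multiplicity correction used throughout the
#' package is explicit and testable. `NA` entries are propagated and do
#' not count towards the number of tests.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
bh_correct <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Classify sites as germline or somatic
#'
#' Aggregates alt reads and depth over the patient's matched tissue
#' samples (or all samples, see [filter_config()]), applies the one-sided
#' binomial exact test per site against the heterozygous-germline null,
#' corrects across sites with Benjamini-Hochberg, and labels a site
#' `somatic` iff `q < q_cutoff`. Sites with aggregated depth 0 are
#' `unclassifiable`.
#'
#' @param table a [variant_table()].
#' @param meta a [sample_meta()] table for the same samples.
#' @param config a [filter_config()].
#' @return data.frame: `id`, `alt_total`, `depth_total`, `p`, `q`,
#'   `label`.
#' @export
classify_germline_somatic <- function(table, meta, config = filter_config()) {
  meta <- check_meta(table, meta)
  sel <- if (config$aggregate == "reference") {
    which(meta$is_matched_reference)
  } else {
    seq_along(table$samples)
  }
  if (length(sel) == 0L) {
    stop("no matched reference samples available for germline classification")
  }
  alt_total <- rowSums(table$alt[, sel, drop = FALSE])
  depth_total <- rowSums(table$depth[, sel, drop = FALSE])
  p <- binomial_germline_pvalue(alt_total, depth_total, config$germline_vaf_null)
  q <- bh_correct(p)
  label <- ifelse(is.na(q), "unclassifiable",
                  ifelse(q < config$q_cutoff, "somatic", "germline"))
  data.frame(id = table$sites$id, alt_total = alt_total,
             depth_total = depth_total, p = p, q = q, label = label,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove sites of consistently aberrant depth
#'
#' A site is removed iff its depth is below `depth_min` in every sample,
#' or above `depth_max` in every sample ("consistently low/high"). For a
#' male patient both thresholds are halved on the X and Y chromosomes
#' (single-copy sequence runs at half depth). Idempotent.
#'
#' @param table a [variant_table()].
#' @param meta a [sample_meta()] table (supplies patient sex).
#' @param config a [filter_config()].
#' @return list: `table` (retained sites), `log` (data.frame `id`,
#'   `rule` in `low`/`high` for removed sites).
#' @export
depth_filter <- function(table, meta, config = filter_config()) {
  meta <- check_meta(table, meta)
  male <- all(meta$sex == "male")
  half <- config$sex_halving && male
  is_sex <- table$sites$chrom_class %in% c("X", "Y")
  dmin <- ifelse(half & is_sex, config$depth_min / 2, config$depth_min)
  dmax <- ifelse(half & is_sex, config$depth_max / 2, config$depth_max)
  if (config$consistent == "every_sample") {
    low <- rowSums(table$depth < dmin) == length(table$samples)
    high <- rowSums(table$depth > dmax) == length(table$samples)
  } else {
    md <- rowMeans(table$depth)
    low <- md < dmin
    high <- md > dmax
  }
  removed <- low | high
  log <- data.frame(id = table$sites$id[removed],
                    rule = ifelse(low[removed], "low", "high"),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = subset_sites(table, !removed), log = log)
}
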