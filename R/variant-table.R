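#' Multi-sample variant read-count table
#'
#' The common currency of the pipeline: per-site annotations plus matched
#' matrices of variant-supporting read counts and total depths, one column
#' per sample.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single bases) and optionally `id`. An id of the form
#'   `chrom:pos:ref:alt` is derived when absent. A `chrom_class` column
#'   (`autosome`, `X`, `Y`) is derived from `chrom` when absent.
#' @param alt_counts integer matrix, sites x samples, variant-supporting
#'   reads.
#' @param depths integer matrix, sites x samples, total depth; must satisfy
#'   `alt_counts <= depths` cell-wise.
#' @param samples character vector of sample ids naming the columns.
#'
#' @return An object of class `variant_table`: a list with elements
#'   `sites`, `alt`, `depth`, `samples`.
#' @export
variant_table <- function(sites, alt_counts, depths, samples = colnames(depths)) {
  stopifnot(is.data.frame(sites))
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0L) {
    stop("sites is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  alt_counts <- as.matrix(alt_counts)
  depths <- as.matrix(depths)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(depths)))
  samples <- as.character(samples)
  if (nrow(alt_counts) != nrow(sites) || nrow(depths) != nrow(sites) ||
      ncol(alt_counts) != length(samples) || ncol(depths) != length(samples)) {
    stop("dimensions of sites, alt_counts, depths and samples do not agree")
  }
  storage.mode(alt_counts) <- "integer"
  storage.mode(depths) <- "integer"
  if (anyNA(alt_counts) || anyNA(depths)) stop("read counts must not contain NA")
  if (any(alt_counts < 0L) || any(depths < 0L)) stop("read counts must be non-negative")
  if (any(alt_counts > depths)) stop("alt_counts must not exceed depths")
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (is.null(sites$id)) {
    sites$id <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  }
  if (anyDuplicated(sites$id)) stop("duplicate site ids (chrom:pos:ref:alt must be unique)")
  if (is.null(sites$chrom_class)) {
    sites$chrom_class <- ifelse(sites$chrom %in% c("X", "chrX"), "X",
                                ifelse(sites$chrom %in% c("Y", "chrY"), "Y", "autosome"))
  }
  rownames(alt_counts) <- rownames(depths) <- sites$id
  colnames(alt_counts) <- colnames(depths) <- samples
  structure(
    list(sites = sites, alt = alt_counts, depth = depths, samples = samples),
    class = "variant_table"
  )
}

#' @exportS3Method base::print
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples\n", nrow(x$sites), length(x$samples)))
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  chrc <- table(x$sites$chrom_class)
  cat("sites:", paste(sprintf("%s=%d", names(chrc), chrc), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), length(x$samples))

#' Naive per-cell variant allele fractions
#'
#' `alt/depth` with 0 where depth is 0.
#'
#' @param x a [variant_table()].
#' @return numeric matrix, sites x samples.
#' @export
naive_vaf <- function(x) {
  stopifnot(inherits(x, "variant_table"))
  v <- x$alt / x$depth
  v[x$depth == 0L] <- 0
  v
}

#' Subset a variant table by site
#'
#' @param x a [variant_table()].
#' @param i logical or integer index over sites.
#' @return a [variant_table()] with the selected sites.
#' @export
subset_sites <- function(x, i) {
  stopifnot(inherits(x, "variant_table"))
  variant_table(x$sites[i, , drop = FALSE],
                x$alt[i, , drop = FALSE],
                x$depth[i, , drop = FALSE],
                x$samples)
}

#' Per-sample metadata
#'
#' @param sample_id character sample ids (must match variant-table columns).
#' @param tissue character tissue label per sample.
#' @param is_matched_reference logical; whether the sample belongs to the
#'   patient's matched-normal reference set used for germline
#'   classification.
#' @param sex `"male"` or `"female"`; uniform within a patient, drives the
#'   halved depth thresholds on X/Y.
#'
#' @return data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, tissue, is_matched_reference, sex) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  sex <- match.arg(sex, c("male", "female"))
  out <- data.frame(sample_id = sample_id,
                    tissue = as.character(tissue),
                    is_matched_reference = as.logical(is_matched_reference),
                    sex = sex,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_meta", "data.frame")
  out
}

check_meta <- function(table, meta) {
  stopifnot(inherits(table, "variant_table"), is.data.frame(meta))
  if (!setequal(meta$sample_id, table$samples)) {
    stop("sample ids in metadata do not match the variant table")
  }
  meta[match(table$samples, meta$sample_id), , drop = FALSE]
}
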