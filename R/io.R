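#' Write a variant table as TSV
#'
#' Columns: `chrom`, `pos`, `ref`, `alt`, `id`, then `<sample>.alt` and
#' `<sample>.dp` per sample. The dialect round-trips exactly through
#' [read_variant_tsv()].
#'
#' @param table a [variant_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(table, path) {
  stopifnot(inherits(table, "variant_table"))
  df <- table$sites[, c("chrom", "pos", "ref", "alt", "id")]
  for (s in table$samples) {
    df[[paste0(s, ".alt")]] <- table$alt[, s]
    df[[paste0(s, ".dp")]] <- table$depth[, s]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the package's variant-table TSV dialect
#'
#' @param path file written by [write_variant_tsv()] (or following the
#'   same column convention).
#' @return a [variant_table()].
#' @export
read_variant_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "ref", "alt", "id")
  if (!all(need %in% names(df))) {
    stop("malformed variant TSV: expected columns ", paste(need, collapse = ", "))
  }
  alt_cols <- grep("\\.alt$", names(df), value = TRUE)
  dp_cols <- grep("\\.dp$", names(df), value = TRUE)
  samples <- sub("\\.alt$", "", alt_cols)
  if (length(samples) == 0L || !setequal(samples, sub("\\.dp$", "", dp_cols))) {
    stop("malformed variant TSV: per-sample .alt/.dp columns do not pair up")
  }
  for (cc in c(alt_cols, dp_cols)) {
    bad <- which(is.na(suppressWarnings(as.integer(df[[cc]]))))
    if (length(bad) > 0L) {
      stop(sprintf("malformed count in column %s at line %d of %s",
                   cc, bad[1] + 1L, path))
    }
  }
  alt <- as.matrix(df[, paste0(samples, ".alt"), drop = FALSE])
  dp <- as.matrix(df[, paste0(samples, ".dp"), drop = FALSE])
  variant_table(df[, need], alt, dp, samples)
}

#' Write a variant table as multi-sample VCF
#'
#' Minimal VCFv4.2 with per-sample `AD` (ref,alt depths) and `DP`
#' genotype fields; reference-supporting depth is `depth - alt`.
#'
#' @param table a [variant_table()].
#' @param path output file (plain text).
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(table, path) {
  stopifnot(inherits(table, "variant_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=somaclone",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", table$samples), collapse = "\t")),
             con)
  gt <- matrix("", nrow(table$sites), length(table$samples))
  for (j in seq_along(table$samples)) {
    gt[, j] <- sprintf("./.:%d,%d:%d",
                       table$depth[, j] - table$alt[, j],
                       table$alt[, j], table$depth[, j])
  }
  body <- paste(table$sites$chrom, table$sites$pos, table$sites$id,
                table$sites$ref, table$sites$alt, ".", "PASS", ".",
                "GT:AD:DP",
                apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a multi-sample VCF into a variant table
#'
#' Uses vcfR. Per-sample alt counts come from the `AD` genotype field
#' (last value = alt-supporting reads) and depths from `DP` (falling back
#' to the sum of `AD` when `DP` is absent). Multi-allelic records are
#' rejected; 1-based VCF coordinates are preserved.
#'
#' @param path VCF file (plain or gzipped).
#' @return a [variant_table()].
#' @export
read_variant_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic VCF records are not supported; split them first")
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || all(is.na(ad))) {
    stop("VCF lacks per-sample AD (allele depth) genotype fields")
  }
  alt <- ad; alt[] <- as.integer(sub(".*,", "", ad))   # keeps matrix dims
  refc <- ad; refc[] <- as.integer(sub(",.*", "", ad))
  storage.mode(alt) <- "integer"
  storage.mode(refc) <- "integer"
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(dp) || all(is.na(dp))) {
    dp <- refc + alt
  }
  storage.mode(dp) <- "integer"
  miss <- which(is.na(alt) | is.na(dp), arr.ind = TRUE)
  if (nrow(miss) > 0L) {
    stop(sprintf("missing AD/DP for sample %s at record %d",
                 colnames(ad)[miss[1, 2]], miss[1, 1]))
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  if (!is.null(fix$ID) && !all(is.na(fix$ID)) && !any(fix$ID == ".")) {
    sites$id <- fix$ID
  }
  variant_table(sites, alt, dp, colnames(ad))
}

#' Read variant input in either supported format
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return a [variant_table()].
#' @export
read_variant_input <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  switch(format, vcf = read_variant_vcf(path), tsv = read_variant_tsv(path))
}

#' Read a sample-metadata TSV
#'
#' Columns: `sample_id`, `tissue`, `is_matched_reference`, `sex`.
#'
#' @param path TSV file.
#' @return a [sample_meta()] table.
#' @export
read_sample_meta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "is_matched_reference", "sex")
  if (!all(need %in% names(df))) {
    stop("sample metadata must have columns ", paste(need, collapse = ", "))
  }
  sample_meta(df$sample_id, df$tissue, df$is_matched_reference,
              unique(df$sex))
}

#' Write a truth tree as JSON
#'
#' @param truth a `truth_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "truth_tree"))
  obj <- list(nodes = truth$nodes, prevalence = truth$prevalence,
              branch_burden = truth$branch_burden,
              assignment = as.list(truth$assignment),
              germline_ids = truth$germline_ids, seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a clone tree as JSON
#'
#' Nodes with parents, per-sample prevalence and clone size (as
#' percentages), and branch mutation burdens.
#'
#' @param tree a `clone_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "clone_tree"))
  nodes <- lapply(seq_len(nrow(tree$nodes)), function(i) {
    list(node_id = tree$nodes$node_id[i],
         parent_id = tree$nodes$parent_id[i],
         burden = tree$nodes$burden[i],
         synthetic_root = tree$nodes$synthetic_root[i],
         prevalence = as.list(round(tree$prevalence[i, ], 6)),
         clone_size_pct = as.list(round(100 * tree$clone_size[i, ], 2)))
  })
  jsonlite::write_json(list(epsilon = tree$epsilon, samples = tree$samples,
                            nodes = nodes),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

newick_node <- function(tree, id) {
  ch <- tree$nodes$node_id[!is.na(tree$nodes$parent_id) &
                             tree$nodes$parent_id == id]
  i <- match(id, tree$nodes$node_id)
  label <- sprintf("%s:%d", id, tree$nodes$burden[i])
  if (length(ch) == 0L) return(label)
  paste0("(", paste(vapply(ch, function(c) newick_node(tree, c), ""),
                    collapse = ","), ")", label)
}

#' Write a clone tree in newick format
#'
#' Branch lengths carry the mutation burden of the branch above each
#' node; internal nodes are labelled by cluster id (readable with
#' `ape::read.tree`).
#'
#' @param tree a `clone_tree`.
#' @param path output file.
#' @return the newick string, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "clone_tree"))
  root <- tree$nodes$node_id[is.na(tree$nodes$parent_id)]
  nwk <- paste0(newick_node(tree, root), ";")
  writeLines(nwk, path)
  invisible(nwk)
}

#' Write a presence matrix as TSV
#'
#' One row per site: presence flags (0/1) then p-values per sample.
#'
#' @param presence a `presence_call`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_presence_tsv <- function(presence, path) {
  stopifnot(inherits(presence, "presence_call"))
  df <- data.frame(id = rownames(presence$p), stringsAsFactors = FALSE)
  for (s in colnames(presence$p)) {
    df[[paste0(s, ".present")]] <- as.integer(presence$present[, s])
  }
  for (s in colnames(presence$p)) {
    df[[paste0(s, ".p")]] <- signif(presence$p[, s], 8)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a co-assignment matrix in sparse triplet text form
#'
#' Matrix-market-style: a comment header, a size line, then one
#' `i j value` line per nonzero upper-triangle entry.
#'
#' @param coassign symmetric co-assignment matrix from a `dp_trace`.
#' @param path output file.
#' @param min_value entries below this are treated as zero.
#' @return `path`, invisibly.
#' @export
write_coassignment <- function(coassign, path, min_value = 0.01) {
  idx <- which(upper.tri(coassign, diag = TRUE) & coassign >= min_value,
               arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate real symmetric",
               sprintf("%d %d %d", nrow(coassign), ncol(coassign), nrow(idx))),
             con)
  writeLines(sprintf("%d %d %.4f", idx[, 1], idx[, 2],
                     coassign[idx]), con)
  invisible(path)
}

#' Read a BED file of regions to exclude
#'
#' BED is 0-based half-open; returned intervals are 1-based closed to
#' match VCF coordinates.
#'
#' @param path BED file (first three columns used).
#' @return data.frame `chrom`, `start`, `end` (1-based closed).
#' @export
read_exclusion_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 3L) stop("BED file must have at least 3 columns")
  data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]) + 1L,
             end = as.integer(df[[3]]), stringsAsFactors = FALSE)
}

#' Drop sites falling in excluded regions
#'
#' @param table a [variant_table()].
#' @param regions data.frame from [read_exclusion_bed()].
#' @return a [variant_table()] without the masked sites.
#' @export
mask_regions <- function(table, regions) {
  stopifnot(inherits(table, "variant_table"))
  hit <- rep(FALSE, nrow(table$sites))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (table$sites$chrom == regions$chrom[i] &
                    table$sites$pos >= regions$start[i] &
                    table$sites$pos <= regions$end[i])
  }
  subset_sites(table, !hit)
}
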