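#' @useDynLib neutralcore, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats as.dist cmdscale coef fitted median optimize pbeta
#'   predict qnorm rbeta reorder residuals rmultinom rnorm rpois runif sd
#'   setNames var
#' @importFrom utils head read.delim write.table packageVersion
#' @importFrom graphics abline axis barplot legend lines par points
NULL

RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
UNASSIGNED <- "unassigned"

#' Assemble and validate an ASV dataset
#'
#' Bundles an ASV-by-sample count matrix with its taxonomy, sample metadata
#' and (optionally) a rooted phylogenetic tree, after cross-checking that
#' all identifiers agree. This is the central container passed to the
#' diversity, core-microbiome, neutral-model and log-contrast stages.
#'
#' @param counts integer matrix, ASV rows x sample columns, with row and
#'   column names.
#' @param taxonomy data.frame with one row per ASV (rownames = ASV ids) and
#'   the seven columns `domain`..`species`; missing assignments use the
#'   string `"unassigned"`.
#' @param metadata data.frame with one row per sample (rownames = sample
#'   ids); must contain `temperature` and `timepoint` columns.
#' @param tree optional `ape::phylo` tree whose tips cover every ASV; tips
#'   not present in `counts` are dropped.
#' @return an object of class `nc_dataset`: a list with elements `counts`,
#'   `taxonomy`, `metadata`, `tree`.
#' @seealso [read_dataset()] to build one from TSV files.
#' @export
nc_dataset <- function(counts, taxonomy, metadata, tree = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have ASV rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate ASV ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != round(counts))) stop("non-integer counts")
  storage.mode(counts) <- "integer"

  taxonomy <- as.data.frame(taxonomy)
  missing_tax <- setdiff(rownames(counts), rownames(taxonomy))
  if (length(missing_tax))
    stop("ASVs missing from taxonomy: ", paste(head(missing_tax, 5), collapse = ", "))
  if (!all(RANKS %in% colnames(taxonomy)))
    stop("taxonomy must have columns: ", paste(RANKS, collapse = ", "))
  taxonomy <- taxonomy[rownames(counts), RANKS, drop = FALSE]
  for (r in RANKS) {
    v <- as.character(taxonomy[[r]])
    v[is.na(v) | !nzchar(v)] <- UNASSIGNED
    taxonomy[[r]] <- v
  }

  metadata <- as.data.frame(metadata)
  extra <- setdiff(colnames(counts), rownames(metadata))
  if (length(extra))
    stop("samples in count table absent from metadata: ", paste(extra, collapse = ", "))
  metadata <- metadata[colnames(counts), , drop = FALSE]
  for (col in c("temperature", "timepoint"))
    if (!col %in% colnames(metadata) || anyNA(metadata[[col]]))
      stop("metadata must define '", col, "' for every sample")

  if (!is.null(tree)) {
    if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
    missing_tip <- setdiff(rownames(counts), tree$tip.label)
    if (length(missing_tip))
      stop("ASVs missing from tree: ", paste(head(missing_tip, 5), collapse = ", "))
    drop <- setdiff(tree$tip.label, rownames(counts))
    if (length(drop)) tree <- ape::drop.tip(tree, drop)
  }

  structure(list(counts = counts, taxonomy = taxonomy,
                 metadata = metadata, tree = tree),
            class = "nc_dataset")
}

#' @export
print.nc_dataset <- function(x, ...) {
  cat("ASV dataset:", nrow(x$counts), "taxa x", ncol(x$counts), "samples\n")
  cat("  read depth:", paste(range(colSums(x$counts)), collapse = "-"),
      " median", stats::median(colSums(x$counts)), "\n")
  if (!is.null(x$tree)) cat("  rooted tree with", length(x$tree$tip.label), "tips\n")
  grp <- if ("group" %in% colnames(x$metadata)) table(x$metadata$group) else NULL
  if (!is.null(grp))
    cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a dataset from TSV files
#'
#' Reads the abundance table (TSV, first column `feature_id`, remaining
#' columns sample ids), the taxonomy table (TSV with `feature_id` plus
#' either the seven rank columns or a single semicolon-delimited `Taxon`
#' column), the sample metadata (TSV, first column `sample_id`) and an
#' optional newick tree, then validates cross-references via [nc_dataset()].
#'
#' An abundance table stored transposed (samples as rows) is detected by
#' comparing identifiers against the metadata and auto-transposed with a
#' warning.
#'
#' @param abundance_path,taxonomy_path,metadata_path paths to TSV files.
#' @param tree_path optional path to a newick file with branch lengths.
#' @return an `nc_dataset`.
#' @export
read_dataset <- function(abundance_path, taxonomy_path, metadata_path,
                         tree_path = NULL) {
  for (p in c(abundance_path, taxonomy_path, metadata_path, tree_path))
    if (!file.exists(p)) stop("file not found: ", p)

  meta <- read.delim(metadata_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(meta[[1]]))
    stop("duplicate sample ids in metadata")
  rownames(meta) <- meta[[1]]
  meta <- meta[, -1, drop = FALSE]

  ab <- read.delim(abundance_path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(ab[[1]])
  counts <- as.matrix(ab[, -1, drop = FALSE])
  rownames(counts) <- ids
  # transposed file: sample ids down the first column instead of the header
  if (!any(colnames(counts) %in% rownames(meta)) &&
      any(ids %in% rownames(meta))) {
    warning("abundance table appears transposed (samples as rows); transposing")
    counts <- t(counts)
  }

  taxonomy <- read_taxonomy(taxonomy_path)
  tree <- if (!is.null(tree_path)) ape::read.tree(tree_path) else NULL
  nc_dataset(counts, taxonomy, meta, tree)
}

# Accepts either 7 explicit rank columns or a QIIME-style "Taxon" string.
read_taxonomy <- function(path) {
  tx <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(tx[[1]])) stop("duplicate ASV ids in taxonomy")
  rownames(tx) <- tx[[1]]
  tx <- tx[, -1, drop = FALSE]
  if (all(RANKS %in% tolower(colnames(tx)))) {
    colnames(tx) <- tolower(colnames(tx))
    return(tx[, RANKS])
  }
  taxcol <- intersect(c("Taxon", "taxon", "taxonomy", "Taxonomy"), colnames(tx))
  if (!length(taxcol))
    stop("taxonomy must have the 7 rank columns or a semicolon-delimited 'Taxon' column")
  parts <- strsplit(as.character(tx[[taxcol[1]]]), ";")
  out <- t(vapply(parts, function(p) {
    p <- sub("^\\s*[a-z]__", "", trimws(p))  # strip QIIME rank prefixes
    p[!nzchar(p)] <- UNASSIGNED
    length(p) <- 7L
    p[is.na(p)] <- UNASSIGNED
    p
  }, character(7)))
  colnames(out) <- RANKS
  data.frame(out, row.names = rownames(tx), stringsAsFactors = FALSE)
}

#' Remove contaminant and fully unassigned ASVs
#'
#' Drops ASVs classified as organelle contaminants (family or order matching
#' "Mitochondria", order matching "Chloroplast"; case-insensitive substring
#' match) and ASVs unassigned at every rank, mirroring standard 16S
#' pre-processing. The number removed per category is reported via
#' `message()`.
#'
#' @param ds an `nc_dataset`.
#' @return the filtered `nc_dataset`. Erroring if no ASVs survive.
#' @export
filter_contaminants <- function(ds) {
  stopifnot(inherits(ds, "nc_dataset"))
  tx <- ds$taxonomy
  mito <- grepl("mitochondria", tx$family, ignore.case = TRUE) |
          grepl("mitochondria", tx$order, ignore.case = TRUE)
  chloro <- grepl("chloroplast", tx$order, ignore.case = TRUE)
  unas <- Reduce(`&`, lapply(tx[RANKS], function(v) tolower(v) == UNASSIGNED))
  drop <- mito | chloro | unas
  message(sprintf("removed %d mitochondria, %d chloroplast, %d fully unassigned ASVs",
                  sum(mito), sum(chloro & !mito), sum(unas & !mito & !chloro)))
  if (all(drop)) stop("no ASVs remain after contaminant filtering")
  keep <- rownames(ds$counts)[!drop]
  subset_taxa(ds, keep)
}

subset_taxa <- function(ds, taxa) {
  tree <- ds$tree
  if (!is.null(tree)) tree <- ape::keep.tip(tree, taxa)
  structure(list(counts = ds$counts[taxa, , drop = FALSE],
                 taxonomy = ds$taxonomy[taxa, , drop = FALSE],
                 metadata = ds$metadata, tree = tree),
            class = "nc_dataset")
}

subset_samples <- function(ds, samples) {
  structure(list(counts = ds$counts[, samples, drop = FALSE],
                 taxonomy = ds$taxonomy,
                 metadata = ds$metadata[samples, , drop = FALSE],
                 tree = ds$tree),
            class = "nc_dataset")
}

#' Aggregate counts to a taxonomic rank
#'
#' Sums ASV counts sharing the same label at `rank`. ASVs unassigned at that
#' rank are pooled into a single `"Unassigned-<rank>"` row; column sums are
#' conserved exactly.
#'
#' @param ds an `nc_dataset`.
#' @param rank one of `domain`, `phylum`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @return integer matrix with rank labels as rownames.
#' @export
aggregate_to_rank <- function(ds, rank) {
  stopifnot(inherits(ds, "nc_dataset"))
  rank <- match.arg(rank, RANKS)
  lab <- ds$taxonomy[[rank]]
  lab[tolower(lab) == UNASSIGNED] <- paste0("Unassigned-", rank)
  out <- rowsum(ds$counts, group = lab, reorder = TRUE)
  storage.mode(out) <- "integer"
  out
}

#' Convert counts to relative abundances
#'
#' @param table count matrix (taxa x samples) with positive column sums.
#' @return matrix of proportions; every column sums to 1.
#' @export
relative_abundance <- function(table) {
  table <- as.matrix(table)
  tot <- colSums(table)
  if (any(tot <= 0))
    stop("zero-sum sample(s): ", paste(colnames(table)[tot <= 0], collapse = ", "))
  sweep(table, 2, tot, "/")
}

#' Keep the n most abundant taxa
#'
#' Ranks taxa by mean relative abundance across samples (ties broken by
#' lexicographic taxon id) and keeps the top `n`; the rest are dropped, not
#' pooled.
#'
#' @param table count matrix (taxa x samples).
#' @param n number of taxa to keep.
#' @return the subset count matrix, rows ordered by decreasing mean
#'   relative abundance.
#' @export
top_n_taxa <- function(table, n) {
  stopifnot(n >= 1)
  table <- as.matrix(table)
  if (n > nrow(table)) {
    warning("n exceeds the number of taxa; returning all rows")
    n <- nrow(table)
  }
  mra <- rowMeans(relative_abundance(table))
  ord <- order(-mra, rownames(table))
  table[ord[seq_len(n)], , drop = FALSE]
}
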