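#' Fraction tables: tube x density-fraction taxon abundance records
#'
#' A fraction table is the raw measurement object of a qSIP study: one
#' row per (tube, density fraction) holding the fraction's buoyant
#' density, its total 16S rRNA gene copy number from qPCR, and the
#' relative abundance of every taxon from amplicon sequencing. Taxa are
#' wide columns, so the layout matches the usual OTU-table convention.
#'
#' @name fraction_table
NULL

.ft_meta_cols <- c("tube_id", "treatment", "isotope", "replicate",
                   "fraction", "density", "total_copies")

#' Construct and validate a fraction table
#'
#' @param df data.frame with columns `tube_id`, `treatment`, `isotope`,
#'   `replicate`, `fraction`, `density`, `total_copies`, followed by one
#'   numeric column per taxon holding relative abundances. Row sums of
#'   the taxon columns may be below 1; the remainder is unclassified
#'   read mass and never enters per-taxon copy numbers.
#' @param design a [qsip_design()] against which treatment and isotope
#'   labels are checked.
#' @return The validated data.frame with class `fraction_table` and a
#'   `taxa` attribute listing the taxon columns.
#' @export
fraction_table <- function(df, design = qsip_design()) {
  missing <- setdiff(.ft_meta_cols, names(df))
  if (length(missing))
    stop("fraction table is missing required column(s): ",
         paste(missing, collapse = ", "))
  taxa <- setdiff(names(df), .ft_meta_cols)
  if (!length(taxa)) stop("fraction table has no taxon columns")

  bad_tr <- setdiff(unique(df$treatment), design$treatments)
  if (length(bad_tr))
    stop("treatment label(s) not in design: ", paste(bad_tr, collapse = ", "))
  bad_iso <- setdiff(unique(df$isotope), design$isotopes)
  if (length(bad_iso))
    stop("isotope label(s) not in design: ", paste(bad_iso, collapse = ", "))

  ab <- as.matrix(df[, taxa, drop = FALSE])
  storage.mode(ab) <- "double"
  if (anyNA(ab)) stop("NA abundances in fraction table")
  out_of_range <- which(ab < 0 | ab > 1, arr.ind = TRUE)
  if (nrow(out_of_range))
    stop("abundance outside [0, 1] at row(s): ",
         paste(unique(out_of_range[, 1]), collapse = ", "))
  rs <- rowSums(ab)
  if (any(rs > 1 + 1e-9))
    stop("taxon abundances sum to > 1 at row(s): ",
         paste(which(rs > 1 + 1e-9), collapse = ", "))
  if (any(df$density <= 0)) stop("densities must be strictly positive")
  if (any(df$total_copies < 0)) stop("total_copies must be non-negative")

  key <- paste(df$tube_id, df$fraction)
  if (anyDuplicated(key))
    stop("duplicate (tube_id, fraction) records at row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  trk <- paste(df$treatment, df$isotope, df$replicate)
  tubes <- !duplicated(df$tube_id)
  if (anyDuplicated(trk[tubes]))
    stop("multiple tubes share a (treatment, isotope, replicate) combination")

  df <- as.data.frame(df)
  attr(df, "taxa") <- taxa
  class(df) <- c("fraction_table", "data.frame")
  df
}

#' Taxon column names of a fraction table
#' @param table a `fraction_table`.
#' @export
taxa_names <- function(table) {
  tx <- attr(table, "taxa")
  if (is.null(tx)) setdiff(names(table), .ft_meta_cols) else tx
}

#' Read a fraction table from TSV
#'
#' Expects a tab-separated UTF-8 file with '.' decimals, the seven
#' metadata columns of [fraction_table()], then one column per taxon.
#'
#' @param path file path.
#' @inheritParams fraction_table
#' @return a validated `fraction_table`.
#' @export
read_fraction_table <- function(path, design = qsip_design()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  fraction_table(df, design)
}

#' Write a fraction table to TSV
#'
#' @param table a `fraction_table`.
#' @param path output file path.
#' @export
write_fraction_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phylogeny of taxa from a newick file
#'
#' Tip labels must be taxon ids; branch lengths are required because
#' downstream nearest-taxon distances are path-length sums.
#'
#' @param path newick file path.
#' @return An `ape` `phylo` object.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("unparseable newick file: ", path)
  validate_tree(tree)
}

#' @keywords internal
validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; lengths are required for MNTD/NTI")
  if (any(tree$edge.length < 0)) stop("negative branch lengths in tree")
  tree
}
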