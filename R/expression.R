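#' Read a regions-by-genes expression matrix
#'
#' Reads a TSV whose first column is `region_id` and whose remaining columns
#' are gene symbols (an Allen Human Brain Atlas style regional expression
#' table). By default the matrix is restricted and reordered to the
#' parcellation's left-hemisphere regions, because donor expression data for
#' the right hemisphere are typically unavailable; genes containing any
#' missing value on the scoped regions are dropped with a message.
#'
#' @param path path to the expression TSV.
#' @param parcellation the [parcellation] defining region order.
#' @param hemisphere analysis scope, default `"left"`.
#' @return Numeric matrix, scoped regions x genes, region ids as row names.
#' @export
read_expression_matrix <- function(path, parcellation,
                                   hemisphere = c("left", "right", "both")) {
  hemisphere <- match.arg(hemisphere)
  # duplicate detection must look at the raw header: read.delim silently
  # uniquifies repeated column names
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  dup <- hdr[duplicated(hdr)]
  if (length(dup)) {
    stop_msg("duplicate gene symbol: ", paste(unique(dup), collapse = ", "))
  }
  df <- read_tsv(path)
  if (!"region_id" %in% names(df)) {
    stop_msg("expression file lacks a region_id column")
  }
  genes <- setdiff(names(df), "region_id")
  scope <- parcellation_subset(parcellation, hemisphere)
  ids <- region_ids(scope)
  df$region_id <- as.character(df$region_id)
  common <- intersect(ids, df$region_id)
  if (!length(common)) {
    stop_msg("no overlapping regions between expression matrix and parcellation")
  }
  miss <- setdiff(ids, df$region_id)
  if (length(miss)) {
    stop_msg("expression matrix is missing scoped region(s): ",
             paste(miss, collapse = ", "))
  }
  m <- as.matrix(df[match(ids, df$region_id), genes, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  keep <- !apply(m, 2L, anyNA)
  if (any(!keep)) {
    message("read_expression_matrix: dropped ", sum(!keep),
            " gene(s) with missing values")
  }
  m[, keep, drop = FALSE]
}

#' Write a regions-by-genes expression matrix
#'
#' @param expr numeric matrix, regions x genes, region ids as row names.
#' @param path output TSV path.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(region_id = rownames(expr), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (g in colnames(expr)) df[[g]] <- fmt_full(expr[, g])
  write_tsv(df, path)
}

#' Read a plain-text gene list
#'
#' One HGNC-style symbol per line; blank lines and `#` comments are skipped.
#'
#' @param path path to the list file.
#' @return Character vector of symbols in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_msg("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Write a plain-text gene list
#'
#' @param genes character vector of symbols.
#' @param path output path.
#' @param header optional character vector written as `#`-prefixed comment
#'   lines before the symbols.
#' @export
write_gene_list <- function(genes, path, header = NULL) {
  out <- character(0)
  if (length(header)) out <- paste0("# ", header)
  writeLines(c(out, genes), path)
  invisible(path)
}
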