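#' Read and write the tabular formats used across the pipeline
#'
#' All tables are UTF-8 text with fixed dialects: site tables are CSV with
#' columns `site_id, x, y, <soil variables>, management`; community tables
#' are TSV with `taxon`, `lineage` (semicolon-separated ranks) and one
#' column per site; distance matrices are TSV with site ids as both header
#' row and first column; PCNM scores are CSV `site_id, PCNM1..`; kriging
#' surfaces are long-format CSV `x, y, prediction, kriging_variance`.
#'
#' @param path file path.
#' @param x object to write.
#' @name soilscape_io
NULL

#' @rdname soilscape_io
#' @export
read_site_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("site_id", "x", "y") %in% names(df)))
    stop("site table needs columns site_id, x, y", call. = FALSE)
  if ("management" %in% names(df)) df$management <- factor(df$management)
  structure(df, class = c("site_table", "data.frame"))
}

#' @rdname soilscape_io
#' @export
write_site_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname soilscape_io
#' @export
read_community_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("taxon", "lineage") %in% names(df)[1:2]))
    stop("community table needs first columns 'taxon' and 'lineage'",
         call. = FALSE)
  structure(df, class = c("community_table", "data.frame"))
}

#' @rdname soilscape_io
#' @export
write_community_table <- function(x, path) {
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname soilscape_io
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("distance matrix must be square with matching ids", call. = FALSE)
  asym <- abs(m - t(m))
  if (max(asym) > 1e-10) {
    cell <- arrayInd(which.max(asym), dim(asym))
    stop(sprintf("distance matrix asymmetric at (%s, %s): %g vs %g",
                 rownames(m)[cell[1]], colnames(m)[cell[2]],
                 m[cell[1], cell[2]], m[cell[2], cell[1]]), call. = FALSE)
  }
  structure(m, class = c("dist_matrix", "matrix"))
}

#' @rdname soilscape_io
#' @export
write_distance_matrix <- function(x, path) {
  m <- as.matrix(x)
  out <- data.frame(site_id = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname soilscape_io
#' @export
write_pcnm_scores <- function(x, path, site_ids = NULL) {
  V <- if (inherits(x, "spatial_eigenbasis")) x$vectors else as.matrix(x)
  df <- data.frame(site_id = if (is.null(site_ids)) seq_len(nrow(V))
                   else site_ids, V, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname soilscape_io
#' @export
read_pcnm_scores <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname soilscape_io
#' @export
write_kriging_surface <- function(x, path) {
  write.csv(x[, c("x", "y", "prediction", "kriging_variance")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Newick tree for UniFrac
#'
#' Thin wrapper over [ape::read.tree()] that insists on branch lengths,
#' which weighted UniFrac requires.
#'
#' @param path Newick file path.
#' @return `phylo` tree.
#' @export
read_unifrac_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("Newick tree has no branch lengths; UniFrac needs them",
         call. = FALSE)
  tree
}
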