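#' Write a covariance matrix as dense TSV
#'
#' Region abbreviations form the header row and first column.
#'
#' @param m square matrix with region dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scn_matrix <- function(m, path) {
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a dense covariance matrix written by [write_scn_matrix()]
#'
#' @param path input file.
#' @return square numeric matrix with region dimnames.
#' @export
read_scn_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' Write graph or correlation edges as TSV
#'
#' For a correlation matrix, writes `region_a region_b r` for every pair
#' (upper triangle); for a `"binary_graph"`, writes the retained edges.
#'
#' @param x a correlation matrix or a `"binary_graph"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path) {
  if (inherits(x, "binary_graph")) {
    labs <- x$regions %||% as.character(seq_len(x$n))
    df <- data.frame(region_a = labs[x$edges[, 1]],
                     region_b = labs[x$edges[, 2]])
  } else {
    ut <- which(upper.tri(x), arr.ind = TRUE)
    labs <- rownames(x) %||% as.character(seq_len(nrow(x)))
    df <- data.frame(region_a = labs[ut[, 1]], region_b = labs[ut[, 2]],
                     r = x[ut])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

# long-format AUC tables used by the pipeline
auc_long_tables <- function(aucs) {
  empty_glob <- data.frame(group = character(0), window = integer(0),
                           metric = character(0), auc = numeric(0),
                           stringsAsFactors = FALSE)
  empty_nod <- data.frame(group = character(0), metric = character(0),
                          window = integer(0), node = character(0),
                          auc = numeric(0), stringsAsFactors = FALSE)
  glob <- do.call(rbind, lapply(aucs$groups, function(g) {
    m <- aucs$global[[g]]
    if (ncol(m) == 0) return(NULL)
    data.frame(group = g,
               window = rep(seq_len(nrow(m)), times = ncol(m)),
               metric = rep(colnames(m), each = nrow(m)),
               auc = as.vector(m), stringsAsFactors = FALSE)
  }))
  nod <- do.call(rbind, lapply(aucs$groups, function(g) {
    do.call(rbind, lapply(names(aucs$nodal[[g]]), function(mn) {
      m <- aucs$nodal[[g]][[mn]]
      data.frame(group = g, metric = mn,
                 window = rep(seq_len(nrow(m)), times = ncol(m)),
                 node = rep(colnames(m), each = nrow(m)),
                 auc = as.vector(m), stringsAsFactors = FALSE)
    }))
  }))
  list(global = glob %||% empty_glob, nodal = nod %||% empty_nod)
}
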