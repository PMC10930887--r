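#' Expression matrix container
#'
#' Genes x cells numeric matrix with identifier lists and an optional
#' per-cell group label (e.g. tumor subtype: ER, HER2, TNBC).
#'
#' @param values numeric matrix, genes in rows, cells in columns.
#' @param genes character vector of gene identifiers (unique).
#' @param cells character vector of cell identifiers.
#' @param groups optional character/factor vector of per-cell group labels.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, genes = rownames(values),
                              cells = colnames(values), groups = NULL) {
  values <- as.matrix(values)
  if (is.null(genes) || is.null(cells))
    stop("gene and cell identifiers are required")
  if (length(genes) != nrow(values) || length(cells) != ncol(values))
    stop("dimension mismatch: matrix is ", nrow(values), " x ", ncol(values),
         " but ", length(genes), " genes / ", length(cells),
         " cells were supplied")
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)])[1:min(3, sum(duplicated(genes)))],
               collapse = ", "))
  if (!is.null(groups) && length(groups) != length(cells))
    stop("`groups` must have one label per cell")
  dimnames(values) <- list(genes, cells)
  structure(list(values = values, genes = genes, cells = cells,
                 groups = if (is.null(groups)) NULL else as.character(groups)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$groups)) "" else
                sprintf(" (%d groups)", length(unique(x$groups)))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix
#'
#' Two on-disk dialects are supported:
#' * Matrix-market coordinate file (`.mtx`) with sidecar one-ID-per-line
#'   gene and cell files (`path_genes`, `path_cells` required);
#' * dense CSV with gene identifiers in the first column and cell
#'   identifiers in the header (sidecar paths ignored).
#'
#' @param path_matrix matrix file (`.mtx` or `.csv`).
#' @param path_genes gene-ID sidecar (one per line), for `.mtx` input.
#' @param path_cells cell-ID sidecar, for `.mtx` input. Lines may be
#'   `id` or `id,group` to attach a per-cell group label.
#' @return An [expression_matrix].
#' @export
read_expression <- function(path_matrix, path_genes = NULL, path_cells = NULL) {
  if (grepl("\\.mtx$", path_matrix, ignore.case = TRUE)) {
    if (is.null(path_genes) || is.null(path_cells))
      stop("matrix-market input needs `path_genes` and `path_cells` sidecars")
    m <- as.matrix(Matrix::readMM(path_matrix))
    genes <- readLines(path_genes)
    cell_lines <- readLines(path_cells)
    parts <- strsplit(cell_lines, ",", fixed = TRUE)
    cells <- vapply(parts, `[[`, character(1), 1L)
    groups <- if (all(lengths(parts) >= 2L))
      vapply(parts, `[[`, character(1), 2L) else NULL
    expression_matrix(m, genes = genes, cells = cells, groups = groups)
  } else {
    df <- utils::read.csv(path_matrix, check.names = FALSE,
                          stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    expression_matrix(m, genes = genes, cells = colnames(m))
  }
}

#' Write an expression matrix (matrix-market + sidecars)
#'
#' @param em an [expression_matrix].
#' @param path_matrix output `.mtx` path.
#' @param path_genes output gene-ID sidecar path.
#' @param path_cells output cell-ID sidecar path (`id,group` lines when the
#'   matrix carries group labels).
#' @return `path_matrix`, invisibly.
#' @export
write_expression <- function(em, path_matrix, path_genes, path_cells) {
  stopifnot(inherits(em, "expression_matrix"))
  Matrix::writeMM(Matrix::Matrix(em$values, sparse = TRUE), path_matrix)
  writeLines(em$genes, path_genes)
  writeLines(if (is.null(em$groups)) em$cells
             else paste(em$cells, em$groups, sep = ","), path_cells)
  invisible(path_matrix)
}

#' Read a gene set from a plain-text file
#'
#' One gene identifier per line; blank lines are skipped and duplicates
#' removed on load.
#'
#' @param path text file path.
#' @param name gene-set label; defaults to the file name without extension.
#' @return A `gene_set`: list with `name` and `genes`.
#' @export
read_gene_set <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  genes <- trimws(readLines(path))
  genes <- unique(genes[nzchar(genes)])
  gene_set(name, genes)
}

#' Construct a gene set
#'
#' @param name label (e.g. "senescence", "SASP", "osc_pos").
#' @param genes character vector of gene identifiers; duplicates removed.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("gene set `", name, "` is empty")
  structure(list(name = name, genes = genes), class = "gene_set")
}
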