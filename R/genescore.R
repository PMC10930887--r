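#' Library-size normalize and log-transform raw counts
#'
#' Scales each cell to `scale_factor` total counts and applies
#' `log1p` — the conventional preprocessing before gene z-scaling when
#' raw single-cell counts are supplied. Use `method = "none"` for
#' matrices that are already normalized.
#'
#' @param em an [expression_matrix].
#' @param method `"lognorm"` (default) or `"none"`.
#' @param scale_factor target counts per cell (default 1e4).
#' @return A normalized [expression_matrix].
#' @export
normalize_expression <- function(em, method = c("lognorm", "none"),
                                 scale_factor = 1e4) {
  method <- match.arg(method)
  stopifnot(inherits(em, "expression_matrix"))
  if (method == "none") return(em)
  tot <- colSums(em$values)
  if (any(tot <= 0)) stop("cell(s) with zero total counts cannot be normalized")
  v <- log1p(sweep(em$values, 2, tot / scale_factor, "/"))
  expression_matrix(v, genes = em$genes, cells = em$cells, groups = em$groups)
}

#' Z-scale each gene across all cells
#'
#' Centers every gene row to mean 0 and scales it to unit variance
#' across cells. Zero-variance genes carry no per-cell information and
#' are dropped with a warning.
#'
#' @param em an [expression_matrix] of normalized expression.
#' @return A scaled [expression_matrix] (possibly fewer genes).
#' @export
scale_genes <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (ncol(em$values) < 2L) stop("scaling needs at least 2 cells")
  mu <- rowMeans(em$values)
  sdv <- apply(em$values, 1, stats::sd)
  drop <- sdv == 0 | is.na(sdv)
  if (any(drop))
    warning(sum(drop), " zero-variance gene(s) dropped before scaling")
  keep <- !drop
  v <- (em$values[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  expression_matrix(v, genes = em$genes[keep], cells = em$cells,
                    groups = em$groups)
}

#' Per-cell gene-set module score
#'
#' The module score of a cell is the mean z-scaled expression over the
#' gene-set members present in the matrix (mean scaled expression, a
#' per-cell Z score for the set). A set with zero overlap yields `NULL`
#' with a warning naming the set — never a column of zeros.
#'
#' @param scaled a z-scaled [expression_matrix] (see [scale_genes()]).
#' @param set a [gene_set].
#' @return Named numeric vector of per-cell scores with attribute
#'   `n_matched` (number of set genes found), or `NULL` on zero overlap.
#' @export
module_score <- function(scaled, set) {
  stopifnot(inherits(scaled, "expression_matrix"), inherits(set, "gene_set"))
  present <- intersect(set$genes, scaled$genes)
  if (!length(present)) {
    warning("gene set `", set$name, "` has zero overlap with the matrix")
    return(NULL)
  }
  sc <- colMeans(scaled$values[present, , drop = FALSE])
  attr(sc, "n_matched") <- length(present)
  sc
}

#' Module-score table for several gene sets
#'
#' @param scaled a z-scaled [expression_matrix].
#' @param sets list of [gene_set]s.
#' @return `data.frame` of class `module_score_table`: columns `cell`,
#'   `group` (NA when the matrix has no labels), then one score column
#'   per set that overlaps the matrix (missing sets are omitted, with the
#'   [module_score()] warning).
#' @export
module_score_table <- function(scaled, sets) {
  out <- data.frame(cell = scaled$cells,
                    group = if (is.null(scaled$groups)) NA_character_
                            else scaled$groups,
                    stringsAsFactors = FALSE)
  for (s in sets) {
    sc <- module_score(scaled, s)
    if (!is.null(sc)) out[[s$name]] <- unname(sc)
  }
  class(out) <- c("module_score_table", "data.frame")
  out
}

#' Pearson correlation between two module scores, within cell groups
#'
#' For each cell group (e.g. tumor subtype) with at least `min_cells`
#' cells, the Pearson correlation between the two sets' per-cell scores
#' and its two-sided p-value (t distribution, n - 2 df) are computed.
#' Groups below the minimum are skipped with a warning; zero-variance
#' score vectors give `r = NA` for that group with a warning.
#'
#' @param scores a `module_score_table` (see [module_score_table()]).
#' @param set_a,set_b score column names.
#' @param by_group compute within each `group` level (default `TRUE`);
#'   `FALSE` pools all cells as one group `"all"`.
#' @param min_cells minimum cells per group (default 3, the smallest n
#'   with a defined correlation p-value).
#' @return `data.frame` with columns `set_a`, `set_b`, `group`, `r`,
#'   `p_value`, `n_cells`.
#' @export
correlate_scores <- function(scores, set_a, set_b, by_group = TRUE,
                             min_cells = 3L) {
  stopifnot(inherits(scores, "module_score_table"))
  for (s in c(set_a, set_b))
    if (!s %in% names(scores))
      stop("no score column `", s, "` in the table")
  grp <- if (by_group && !all(is.na(scores$group))) scores$group
         else rep("all", nrow(scores))
  rows <- lapply(unique(grp), function(g) {
    a <- scores[[set_a]][grp == g]
    b <- scores[[set_b]][grp == g]
    n <- length(a)
    if (n < min_cells) {
      warning("group `", g, "` skipped: ", n, " < ", min_cells, " cells")
      return(NULL)
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("group `", g, "`: zero-variance score vector, r undefined")
      return(data.frame(set_a = set_a, set_b = set_b, group = g,
                        r = NA_real_, p_value = NA_real_, n_cells = n))
    }
    ct <- stats::cor.test(a, b, method = "pearson")
    data.frame(set_a = set_a, set_b = set_b, group = g,
               r = unname(ct$estimate), p_value = ct$p.value, n_cells = n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set_a = character(0), set_b = character(0),
                      group = character(0), r = numeric(0),
                      p_value = numeric(0), n_cells = integer(0))
  rownames(out) <- NULL
  out
}
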