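#' Venn decomposition of switch-gene sets across conditions
#'
#' Computes, for every non-empty combination of the input conditions, the
#' genes belonging to exactly that combination (so regions are disjoint and
#' their sizes sum to the union size).
#'
#' @param sets a list of `switch_gene_set` objects (see
#'   [extract_switch_genes()]) or a named list of character vectors.
#' @return A `venn_result`: list with `regions` (named by
#'   `"A&B"`-style combination keys, genes sorted), `counts`, `union_size`.
#' @export
intersect_switch_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets to intersect")
  if (all(vapply(sets, inherits, logical(1), "switch_gene_set"))) {
    labels <- vapply(sets, `[[`, "", "condition")
    if (anyDuplicated(labels)) stop("duplicate condition labels")
    sets <- stats::setNames(lapply(sets, `[[`, "genes"), labels)
  }
  venn_regions(sets)
}

#' Extract one region of a Venn decomposition
#'
#' @param venn a `venn_result`.
#' @param conditions character vector of condition labels; the region of
#'   genes in exactly these conditions is returned.
#' @return Sorted character vector (possibly empty).
#' @export
venn_region <- function(venn, conditions) {
  want <- vapply(strsplit(names(venn$regions), "&", fixed = TRUE),
                 function(s) setequal(s, conditions), logical(1))
  if (!any(want)) return(character(0))
  venn$regions[[which(want)]]
}

#' Bicluster switch-gene expression for heat-map rendering
#'
#' Rows (switch genes) are z-scored per gene, then rows and columns are
#' hierarchically clustered with distance 1 - Pearson correlation and
#' average linkage. Inputs are sorted by id before clustering so the result
#' does not depend on input order and ties merge deterministically.
#'
#' @param em an [expression_matrix()] containing the switch genes.
#' @param switch_set a `switch_gene_set` (or character vector of genes).
#' @return A `bicluster_result`: list with `row_order`, `col_order` (leaf
#'   orders), `row_hclust`, `col_hclust` (merge trees), and `matrix` (the
#'   standardized gene x sample matrix in input id order).
#' @export
bicluster_switch_expression <- function(em, switch_set) {
  genes <- if (inherits(switch_set, "switch_gene_set")) switch_set$genes
           else switch_set
  genes <- sort(unique(genes))
  missing <- setdiff(genes, gene_ids(em))
  if (length(missing) > 0) {
    stop("switch gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  if (length(genes) < 2) stop("need at least 2 switch genes to bicluster")
  vals <- em$values[genes, order(colnames(em$values)), drop = FALSE]
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance switch gene(s): ",
         paste(genes[sds == 0], collapse = ", "))
  }
  z <- row_zscore(vals)
  row_d <- stats::as.dist(1 - stats::cor(t(z)))
  col_d <- stats::as.dist(1 - stats::cor(z))
  row_h <- stats::hclust(row_d, method = "average")
  col_h <- stats::hclust(col_d, method = "average")
  structure(list(row_order = rownames(z)[row_h$order],
                 col_order = colnames(z)[col_h$order],
                 row_hclust = row_h, col_hclust = col_h,
                 matrix = z),
            class = "bicluster_result")
}
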