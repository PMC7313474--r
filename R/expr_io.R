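#' Construct an expression matrix object
#'
#' The basic container of the package: a dense matrix of log2 intensities
#' (rows = genes, columns = samples) together with a case/control label for
#' every sample.
#'
#' @param values numeric matrix of log2 intensities with unique rownames
#'   (gene ids) and unique colnames (sample ids).
#' @param condition named character vector mapping every sample id to
#'   `"case"` or `"control"`.
#' @return An object of class `expression_matrix` with elements `values`
#'   (the matrix) and `condition` (labels aligned to `colnames(values)`).
#' @export
expression_matrix <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!all(is.finite(values))) stop("values must be finite")
  condition <- unlist(condition)
  missing <- setdiff(colnames(values), names(condition))
  if (length(missing) > 0) {
    stop("sample(s) missing from label map: ", paste(missing, collapse = ", "))
  }
  condition <- condition[colnames(values)]
  bad <- !condition %in% c("case", "control")
  if (any(bad)) {
    stop("condition labels must be 'case' or 'control'; offending sample(s): ",
         paste(names(condition)[bad], collapse = ", "))
  }
  structure(list(values = values, condition = condition),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "case"), sum(x$condition == "control")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

gene_ids <- function(em) rownames(em$values)
sample_ids <- function(em) colnames(em$values)

subset_genes <- function(em, genes) {
  expression_matrix(em$values[genes, , drop = FALSE], em$condition)
}

#' Read a gene x sample expression table
#'
#' Reads a rectangular tab-separated table (first column gene ids, header row
#' sample ids). The GEO series-matrix dialect is handled by skipping
#' `!`-prefixed metadata lines. Unparseable cells are treated as missing;
#' genes with more than `max_missing_frac` missing cells are dropped and the
#' remainder are mean-imputed per gene (the imputed-cell count is reported
#' via a message and the `"n_imputed"` attribute).
#'
#' @param path path to the table.
#' @param label_map named character vector (sample -> "case"/"control"), or a
#'   two-column data frame (sample_id, condition), or a path to a two-column
#'   TSV in that layout.
#' @param already_log2 if `FALSE`, `log2(x + 1)` is applied to all values.
#' @param max_missing_frac genes with a larger fraction of missing cells are
#'   dropped (default 0.2).
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, label_map, already_log2 = TRUE,
                                  max_missing_frac = 0.2) {
  label_map <- as_label_map(label_map)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("expression table has no data rows: ", path)
  con <- textConnection(lines)
  on.exit(close(con))
  tab <- utils::read.table(con, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  genes <- tab[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  samples <- colnames(tab)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(tab[, -1, drop = FALSE])),
           nrow = length(genes),
           dimnames = list(genes, samples))
  )
  ## missing-value handling: drop heavily-missing genes, mean-impute the rest
  miss_frac <- rowMeans(is.na(vals))
  vals <- vals[miss_frac <= max_missing_frac, , drop = FALSE]
  if (nrow(vals) == 0) stop("no genes left after missing-value filtering")
  n_imputed <- sum(is.na(vals))
  if (n_imputed > 0) {
    for (i in which(rowSums(is.na(vals)) > 0)) {
      row <- vals[i, ]
      row[is.na(row)] <- mean(row, na.rm = TRUE)
      vals[i, ] <- row
    }
    message(n_imputed, " missing cell(s) mean-imputed per gene")
  }
  if (!already_log2) vals <- log2(vals + 1)
  em <- expression_matrix(vals, label_map)
  attr(em, "n_imputed") <- n_imputed
  em
}

as_label_map <- function(label_map) {
  if (is.character(label_map) && length(label_map) == 1 &&
      is.null(names(label_map)) && file.exists(label_map)) {
    df <- utils::read.table(label_map, header = FALSE, sep = "\t",
                            colClasses = "character")
    if (ncol(df) == 2 && identical(tolower(df[1, 1]), "sample_id")) {
      df <- df[-1, , drop = FALSE]
    }
    label_map <- stats::setNames(df[[2]], df[[1]])
  } else if (is.data.frame(label_map)) {
    label_map <- stats::setNames(as.character(label_map[[2]]),
                                 as.character(label_map[[1]]))
  }
  label_map
}

#' Write an expression matrix (and optionally its labels) to TSV
#'
#' @param em an [expression_matrix()].
#' @param path output path for the gene x sample table.
#' @param labels_path optional path for a two-column (sample_id, condition)
#'   TSV.
#' @export
write_expression_table <- function(em, path, labels_path = NULL) {
  df <- data.frame(gene_id = gene_ids(em),
                   em$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    utils::write.table(
      data.frame(sample_id = sample_ids(em), condition = em$condition),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(path)
}

#' Collapse probe-level rows to gene symbols
#'
#' For genes measured by several probes the probe with the highest mean
#' intensity across all samples is kept (a common microarray convention);
#' probes without a mapping are dropped.
#'
#' @param em an [expression_matrix()] with probe-level rows.
#' @param probe_to_gene named character vector (probe -> gene symbol) or a
#'   two-column data frame.
#' @return An [expression_matrix()] with unique gene-symbol rows.
#' @export
collapse_probes <- function(em, probe_to_gene) {
  if (is.data.frame(probe_to_gene)) {
    probe_to_gene <- stats::setNames(as.character(probe_to_gene[[2]]),
                                     as.character(probe_to_gene[[1]]))
  }
  probes <- intersect(gene_ids(em), names(probe_to_gene))
  if (length(probes) == 0) stop("no probe maps to a gene symbol")
  genes <- probe_to_gene[probes]
  means <- rowMeans(em$values[probes, , drop = FALSE])
  ## keep, per gene, the probe with the highest mean intensity
  keep <- vapply(split(probes, genes),
                 function(p) p[which.max(means[p])], character(1))
  vals <- em$values[keep, , drop = FALSE]
  rownames(vals) <- names(keep)
  expression_matrix(vals, em$condition)
}

#' Read a GMT gene-set file
#'
#' Standard GMT layout: one set per line with name, description, then member
#' gene ids, tab-separated. Lines with fewer than three fields are skipped
#' with a warning; members are de-duplicated.
#'
#' @param path path to the GMT file.
#' @return A `gene_set_collection`: a list with `sets` (named list of
#'   character vectors) and `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, 1L) >= 3
  if (any(!ok)) {
    warning(sum(!ok), " malformed GMT line(s) skipped")
  }
  fields <- fields[ok]
  if (length(fields) == 0) stop("no valid gene sets in ", path)
  names_ <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names_)) stop("duplicate gene-set names")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  sets <- lapply(sets, function(s) s[nzchar(s)])
  empty <- vapply(sets, length, 1L) == 0
  if (any(empty)) {
    warning(sum(empty), " empty gene set(s) dropped")
    sets <- sets[!empty]; names_ <- names_[!empty]; fields <- fields[!empty]
  }
  if (length(sets) == 0) stop("no non-empty gene sets in ", path)
  structure(list(sets = stats::setNames(sets, names_),
                 descriptions = stats::setNames(
                   vapply(fields, `[[`, "", 2), names_)),
            class = "gene_set_collection")
}

#' Read a 2-3 column interaction edge list
#'
#' Loads source/target(/relation) edges from a delimited file. Self-loops are
#' removed and duplicate edges collapsed; for undirected tables each pair is
#' canonicalized (alphabetical order) before de-duplication. Extra columns
#' beyond the third are ignored.
#'
#' @param path path to the TSV.
#' @param directed whether edges are directed (TF -> target style).
#' @param header whether the first line is a header.
#' @return An `interaction_table`: list with `edges` (data frame with
#'   columns source, target, relation) and `directed`.
#' @export
read_interaction_table <- function(path, directed = FALSE, header = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (header && length(lines) > 0) lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) length(f) >= 2 && all(nzchar(f[1:2])),
               logical(1))
  if (any(!ok)) warning(sum(!ok), " malformed interaction line(s) skipped")
  fields <- fields[ok]
  if (length(fields) == 0) stop("no edges in ", path)
  edges <- data.frame(
    source = vapply(fields, `[[`, "", 1),
    target = vapply(fields, `[[`, "", 2),
    relation = vapply(fields, function(f) if (length(f) >= 3) f[[3]] else "",
                      character(1)),
    stringsAsFactors = FALSE)
  interaction_table(edges, directed = directed)
}

#' @rdname read_interaction_table
#' @param edges data frame with columns source, target and optionally
#'   relation.
#' @export
interaction_table <- function(edges, directed = FALSE) {
  if (is.null(edges$relation)) edges$relation <- ""
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  if (!directed) {
    swap <- edges$source > edges$target
    tmp <- edges$source[swap]
    edges$source[swap] <- edges$target[swap]
    edges$target[swap] <- tmp
  }
  edges <- edges[!duplicated(edges[, c("source", "target")]), , drop = FALSE]
  if (nrow(edges) == 0) stop("interaction table has no edges after cleaning")
  rownames(edges) <- NULL
  structure(list(edges = edges, directed = directed),
            class = "interaction_table")
}
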