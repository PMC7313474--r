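`%||%` <- function(a, b) if (is.null(a)) b else a

## population standard deviation (divisor n, not n-1)
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

## z-score each row of a matrix; rows with zero sd become all-zero
row_zscore <- function(x) {
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  s[s == 0] <- 1
  (x - m) / s
}

## Region decomposition over named sets: for every non-empty combination of
## input sets, the elements belonging to exactly that combination.
## Returns a list with `regions` (named list of sorted character vectors,
## names like "A&B"), `counts`, and `union_size`.
venn_regions <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  labels <- names(sets)
  if (is.null(labels) || anyNA(labels) || any(labels == "") ||
      anyDuplicated(labels)) {
    stop("set labels must be unique and non-empty")
  }
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  key <- apply(membership, 1, function(row) paste(labels[row], collapse = "&"))
  regions <- split(universe, key)
  regions <- lapply(regions, sort)
  ## stable order: by number of sets in the combination (desc), then name
  n_sets <- vapply(strsplit(names(regions), "&", fixed = TRUE), length, 1L)
  ord <- order(-n_sets, names(regions))
  regions <- regions[ord]
  structure(
    list(regions = regions,
         counts = vapply(regions, length, 1L),
         labels = labels,
         union_size = length(universe)),
    class = "venn_result"
  )
}

#' @export
print.venn_result <- function(x, ...) {
  cat("Venn decomposition over sets:", paste(x$labels, collapse = ", "), "\n")
  for (nm in names(x$regions)) {
    genes <- x$regions[[nm]]
    shown <- paste(utils::head(genes, 8), collapse = ", ")
    if (length(genes) > 8) shown <- paste0(shown, ", ...")
    cat(sprintf("  %-20s n=%d  %s\n", nm, length(genes), shown))
  }
  invisible(x)
}
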