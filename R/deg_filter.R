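#' Filtering configuration
#'
#' Bundles the thresholds of the pre-processing and differential-filtering
#' stage. The fold-change limit is scanned between `fc_min` and `fc_max`
#' (linear scale) to retain between `target_low` and `target_high` genes for
#' network analysis.
#'
#' @param fc_min,fc_max linear fold-change scan bounds (defaults 1.5 and 4).
#' @param target_low,target_high desired retained-gene band (1000-2000).
#' @param alpha FDR level for the BH-adjusted differential test (0.05).
#' @param expression_floor_quantile genes whose mean intensity falls below
#'   this quantile of all gene means are treated as unexpressed (0.10).
#' @param grid_step step of the fold-change threshold scan (0.05).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(fc_min = 1.5, fc_max = 4,
                          target_low = 1000, target_high = 2000,
                          alpha = 0.05, expression_floor_quantile = 0.10,
                          grid_step = 0.05) {
  stopifnot(fc_min > 0, fc_min <= fc_max,
            target_low < target_high,
            alpha > 0, alpha < 1,
            expression_floor_quantile >= 0, expression_floor_quantile < 1,
            grid_step > 0)
  structure(list(fc_min = fc_min, fc_max = fc_max,
                 target_low = target_low, target_high = target_high,
                 alpha = alpha,
                 expression_floor_quantile = expression_floor_quantile,
                 grid_step = grid_step),
            class = "filter_config")
}

#' Remove unexpressed and invariant genes
#'
#' Drops genes whose mean intensity is below the
#' `expression_floor_quantile` of all gene means, and genes with zero
#' variance (which carry no correlation information).
#'
#' @param em an [expression_matrix()].
#' @param cfg a [filter_config()].
#' @return The pruned [expression_matrix()].
#' @export
prefilter_expression <- function(em, cfg = filter_config()) {
  means <- rowMeans(em$values)
  vars <- apply(em$values, 1, stats::var)
  floor_val <- stats::quantile(means, cfg$expression_floor_quantile,
                               names = FALSE)
  keep <- means >= floor_val & vars > 0
  if (!any(keep)) stop("no genes survive the expression pre-filter")
  subset_genes(em, gene_ids(em)[keep])
}

#' Per-gene differential statistics
#'
#' Computes, for every gene, the log2 fold change (difference of case and
#' control means on the log2 scale), a two-sided Welch t-test p-value, and
#' the Benjamini-Hochberg adjusted q-value.
#'
#' @param em an [expression_matrix()] with at least 2 samples per condition.
#' @return A data frame of class `diff_stats` with columns `gene`, `log2fc`,
#'   `p`, `q` and a `retained` flag (all `FALSE` until a threshold is
#'   applied, see [mark_retained()]).
#' @export
differential_stats <- function(em) {
  case <- em$values[, em$condition == "case", drop = FALSE]
  ctrl <- em$values[, em$condition == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per condition")
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- apply(case, 1, stats::var); v2 <- apply(ctrl, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  ## degenerate genes: both groups constant
  zero_se <- se2 == 0
  p[zero_se] <- ifelse(m1[zero_se] == m2[zero_se], 1, 0)
  q <- stats::p.adjust(p, method = "BH")
  structure(data.frame(gene = gene_ids(em),
                       log2fc = m1 - m2,
                       p = p, q = q,
                       retained = FALSE,
                       row.names = NULL,
                       stringsAsFactors = FALSE),
            class = c("diff_stats", "data.frame"))
}

#' Select the linear fold-change threshold adaptively
#'
#' Scans thresholds over `[fc_min, fc_max]` on a `grid_step` grid (ascending)
#' and returns the smallest threshold whose retained count (genes with
#' `|linear FC| >= t` and `q < alpha`) falls inside the target band. If no
#' threshold lands in the band, the threshold whose count is closest to the
#' band is returned (ties broken toward the lower threshold) with
#' `in_band = FALSE`.
#'
#' @param ds a [differential_stats()] result.
#' @param cfg a [filter_config()].
#' @return List with `threshold` (linear scale), `retained` (count),
#'   `in_band` flag, and `grid` (data frame of threshold vs count).
#' @export
select_fold_change_threshold <- function(ds, cfg = filter_config()) {
  if (!any(ds$q < cfg$alpha)) {
    stop("no gene significant at alpha = ", cfg$alpha,
         "; reconsider alpha or the input data")
  }
  grid <- seq(cfg$fc_min, cfg$fc_max, by = cfg$grid_step)
  abs_fc <- 2^abs(ds$log2fc)
  sig <- ds$q < cfg$alpha
  counts <- vapply(grid, function(t) sum(abs_fc >= t & sig), 1L)
  in_band <- counts >= cfg$target_low & counts <= cfg$target_high
  if (any(in_band)) {
    i <- which(in_band)[1]
    warn <- FALSE
  } else {
    dist <- pmax(cfg$target_low - counts, counts - cfg$target_high, 0)
    tied <- which(dist == min(dist))
    ## when every candidate over-retains, the highest threshold is the
    ## closest approach to the band; otherwise prefer the lowest threshold
    i <- if (all(counts[tied] > cfg$target_high)) tied[length(tied)]
         else tied[1]
    warn <- TRUE
    warning("no threshold lands in the retained-gene band [",
            cfg$target_low, ", ", cfg$target_high, "]; using closest (",
            grid[i], " -> ", counts[i], " genes)")
  }
  list(threshold = grid[i], retained = counts[i], in_band = !warn,
       grid = data.frame(threshold = grid, retained = counts))
}

#' Flag retained genes in a diff_stats table
#'
#' @param ds a [differential_stats()] result.
#' @param threshold linear fold-change threshold.
#' @param alpha FDR level.
#' @return `ds` with the `retained` column updated.
#' @export
mark_retained <- function(ds, threshold, alpha = 0.05) {
  ds$retained <- 2^abs(ds$log2fc) >= threshold & ds$q < alpha
  ds
}

#' Restrict an expression matrix to differentially expressed genes
#'
#' @param em an [expression_matrix()].
#' @param ds the matching [differential_stats()] table.
#' @param threshold linear fold-change threshold (>= 1).
#' @param alpha FDR level.
#' @param min_genes hard floor below which the downstream network would be
#'   degenerate (default 10).
#' @return The filtered [expression_matrix()]; the updated `diff_stats`
#'   table is attached as attribute `"diff_stats"`.
#' @export
apply_filter <- function(em, ds, threshold, alpha = 0.05, min_genes = 10) {
  stopifnot(threshold >= 1)
  ds <- mark_retained(ds, threshold, alpha)
  keep <- ds$gene[ds$retained]
  if (length(keep) < min_genes) {
    stop("only ", length(keep), " genes retained; network would be degenerate")
  }
  out <- subset_genes(em, keep)
  attr(out, "diff_stats") <- ds
  out
}

#' Histogram of log2 fold changes with retained flags
#'
#' Bin counts for the familiar grey/red filtering histogram: all tested genes
#' per bin plus the retained genes per bin.
#'
#' @param ds a [differential_stats()] table with `retained` flags set.
#' @param binwidth histogram bin width on the log2 scale (default 0.25).
#' @return Data frame with columns `mid`, `count`, `retained_count`.
#' @export
fold_change_histogram <- function(ds, binwidth = 0.25) {
  rng <- range(ds$log2fc)
  breaks <- seq(floor(rng[1] / binwidth) * binwidth,
                ceiling(rng[2] / binwidth) * binwidth + binwidth,
                by = binwidth)
  bin <- cut(ds$log2fc, breaks, include.lowest = TRUE)
  data.frame(mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
             count = as.integer(table(bin)),
             retained_count = as.integer(
               tapply(ds$retained, bin, sum, default = 0)))
}
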