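#' Specification of a synthetic two-condition expression study
#'
#' Describes a latent-factor generative model with planted correlation
#' modules and planted switch genes. Each module m has a latent factor; a
#' module gene is `baseline + w * factor + noise`, with the loading `w`
#' chosen so the expected within-condition correlation of two module genes
#' is `rho_within` (closed form `rho = w^2 / (w^2 + noise_sd^2)`). A planted
#' switch gene loads negatively, with equal weight, on two different module
#' factors, the weight chosen so its expected correlation with genes of its
#' anchor modules is `rho_switch`; its neighbors therefore lie mostly
#' outside any one module. The condition effect enters through the factor
#' means (case samples `+delta/2`, control `-delta/2` with
#' `delta = log2fc_signal / w`) so module genes shift by exactly
#' `log2fc_signal` log2 units and switch genes shift oppositely through
#' their negative loadings, keeping the correlation structure and the
#' differential signal consistent.
#'
#' @param n_modules number of planted modules (default 4).
#' @param genes_per_module genes per module (default 300).
#' @param n_switch planted switch genes (default 20).
#' @param n_background unstructured, lowly expressed genes (default 15).
#' @param n_case,n_control samples per condition (defaults 20/20).
#' @param rho_within target within-module, within-condition Pearson
#'   correlation, in (0, 1) (default 0.7).
#' @param rho_switch target switch-to-anchor-module correlation, in (-1, 0)
#'   (default -0.5); feasibility requires `rho_within > 2 * rho_switch^2`.
#' @param log2fc_signal per-module case/control effect on the log2 scale
#'   (default 1, i.e. a linear fold change of 2, inside the 1.5-4 band).
#' @param noise_sd i.i.d. Gaussian noise standard deviation (default 0.3).
#' @param baseline,baseline_sd mean and spread of expressed-gene baseline
#'   log2 intensities (defaults 8 and 1.5).
#' @param background_baseline baseline of the unstructured genes (default
#'   5, below the expressed genes, emulating "slightly expressed").
#' @param seed RNG seed; runs with the same spec are byte-identical.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_modules = 4, genes_per_module = 300,
                           n_switch = 20, n_background = 15,
                           n_case = 20, n_control = 20,
                           rho_within = 0.7, rho_switch = -0.5,
                           log2fc_signal = 1, noise_sd = 0.3,
                           baseline = 8, baseline_sd = 1.5,
                           background_baseline = 5, seed = 1) {
  stopifnot(n_modules >= 2, genes_per_module >= 1, n_switch >= 1,
            n_background >= 1, n_case >= 2, n_control >= 2,
            noise_sd > 0, log2fc_signal >= 0)
  if (rho_within <= 0 || rho_within >= 1) {
    stop("rho_within must be in (0, 1)")
  }
  if (rho_switch >= 0 || rho_switch <= -1) {
    stop("rho_switch must be in (-1, 0)")
  }
  if (rho_within <= 2 * rho_switch^2) {
    stop("infeasible correlation targets: need rho_within > 2 * rho_switch^2")
  }
  structure(list(n_modules = n_modules, genes_per_module = genes_per_module,
                 n_switch = n_switch, n_background = n_background,
                 n_case = n_case, n_control = n_control,
                 rho_within = rho_within, rho_switch = rho_switch,
                 log2fc_signal = log2fc_signal, noise_sd = noise_sd,
                 baseline = baseline, baseline_sd = baseline_sd,
                 background_baseline = background_baseline, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic expression matrix with planted ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return List with `em` (an [expression_matrix()]) and `truth` (data
#'   frame of class `synthetic_truth` with columns `gene`, `role`
#'   (module/switch/background), `module` (anchor pair `"a+b"` for switch
#'   genes), `is_switch`, `true_log2fc`).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  s <- spec
  n <- s$n_case + s$n_control
  is_case <- c(rep(TRUE, s$n_case), rep(FALSE, s$n_control))
  samples <- c(sprintf("CASE%02d", seq_len(s$n_case)),
               sprintf("CTRL%02d", seq_len(s$n_control)))
  w <- s$noise_sd * sqrt(s$rho_within / (1 - s$rho_within))
  v <- abs(s$rho_switch) * s$noise_sd /
    sqrt(s$rho_within - 2 * s$rho_switch^2)
  delta <- s$log2fc_signal / w
  ## latent factors: one per module, condition effect centered on the mean
  factors <- matrix(stats::rnorm(s$n_modules * n), nrow = s$n_modules)
  factors <- factors + rep(ifelse(is_case, delta / 2, -delta / 2),
                           each = s$n_modules)

  n_mod_genes <- s$n_modules * s$genes_per_module
  n_genes <- n_mod_genes + s$n_switch + s$n_background
  genes <- c(sprintf("M%d.G%03d", rep(seq_len(s$n_modules),
                                      each = s$genes_per_module),
                     rep(seq_len(s$genes_per_module), s$n_modules)),
             sprintf("SW.G%02d", seq_len(s$n_switch)),
             sprintf("BG.G%02d", seq_len(s$n_background)))

  vals <- matrix(stats::rnorm(n_genes * n, sd = s$noise_sd),
                 nrow = n_genes, dimnames = list(genes, samples))
  base <- c(stats::rnorm(n_mod_genes + s$n_switch,
                         s$baseline, s$baseline_sd),
            stats::rnorm(s$n_background, s$background_baseline,
                         s$baseline_sd / 3))
  vals <- vals + base

  module_of <- rep(seq_len(s$n_modules), each = s$genes_per_module)
  vals[seq_len(n_mod_genes), ] <- vals[seq_len(n_mod_genes), ] +
    w * factors[module_of, , drop = FALSE]

  ## switch genes load negatively on a cycling pair of module factors
  pairs <- utils::combn(s$n_modules, 2)
  anchor <- matrix(0L, nrow = s$n_switch, ncol = 2)
  for (i in seq_len(s$n_switch)) {
    anchor[i, ] <- pairs[, ((i - 1) %% ncol(pairs)) + 1]
  }
  sw_rows <- n_mod_genes + seq_len(s$n_switch)
  for (i in seq_len(s$n_switch)) {
    vals[sw_rows[i], ] <- vals[sw_rows[i], ] -
      v * (factors[anchor[i, 1], ] + factors[anchor[i, 2], ])
  }

  condition <- stats::setNames(ifelse(is_case, "case", "control"), samples)
  truth <- data.frame(
    gene = genes,
    role = c(rep("module", n_mod_genes), rep("switch", s$n_switch),
             rep("background", s$n_background)),
    module = c(as.character(module_of),
               paste0(anchor[, 1], "+", anchor[, 2]),
               rep(NA_character_, s$n_background)),
    is_switch = c(rep(FALSE, n_mod_genes), rep(TRUE, s$n_switch),
                  rep(FALSE, s$n_background)),
    true_log2fc = c(rep(s$log2fc_signal, n_mod_genes),
                    rep(-2 * v * delta, s$n_switch),
                    rep(0, s$n_background)),
    row.names = NULL, stringsAsFactors = FALSE)
  class(truth) <- c("synthetic_truth", "data.frame")
  list(em = expression_matrix(vals, condition), truth = truth)
}

#' Precision and recall of a called switch-gene set against planted truth
#'
#' Precision is `|called ∩ planted| / |called|` (1 when both empty, `NA`
#' when nothing was called but switch genes were planted); recall is
#' `|called ∩ planted| / |planted|`.
#'
#' @param truth a `synthetic_truth` data frame.
#' @param called a `switch_gene_set` or character vector of called genes.
#' @return List with `precision`, `recall`, `n_called`, `n_planted`,
#'   `true_positives`.
#' @export
evaluate_recovery <- function(truth, called) {
  if (inherits(called, "switch_gene_set")) called <- called$genes
  called <- unique(called)
  planted <- truth$gene[truth$is_switch]
  tp <- length(intersect(called, planted))
  precision <- if (length(called) == 0) {
    if (length(planted) == 0) 1 else NA_real_
  } else tp / length(called)
  recall <- if (length(planted) == 0) 1 else tp / length(planted)
  list(precision = precision, recall = recall,
       n_called = length(called), n_planted = length(planted),
       true_positives = tp)
}

#' Write synthetic study fixtures to a directory
#'
#' Emits `expr.tsv` and `labels.tsv` (the expression study), `truth.tsv`
#' (ground truth), plus toy annotation fixtures driven by the planted
#' structure: `pathways.gmt` (one set per planted module plus one holding
#' the switch genes), `tf_edges.tsv` (synthetic regulators targeting switch
#' genes) and `chem_edges.tsv` (synthetic chemicals, one linked to many
#' switch genes).
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_expression(spec)
  write_expression_table(gen$em, file.path(dir, "expr.tsv"),
                         labels_path = file.path(dir, "labels.tsv"))
  utils::write.table(gen$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- gen$truth
  sw <- truth$gene[truth$is_switch]
  gmt <- c(vapply(seq_len(spec$n_modules), function(m) {
    paste(c(sprintf("MODULE_%d_SET", m), "planted module",
            truth$gene[truth$role == "module" & truth$module == m]),
          collapse = "\t")
  }, character(1)),
  paste(c("SWITCH_SET", "planted switch genes", sw), collapse = "\t"))
  writeLines(gmt, file.path(dir, "pathways.gmt"))
  tf <- data.frame(source = rep(sprintf("TF%02d", 1:3),
                                times = c(length(sw),
                                          ceiling(length(sw) / 2), 2)),
                   target = c(sw, sw[seq_len(ceiling(length(sw) / 2))],
                              sw[1:2]))
  utils::write.table(tf, file.path(dir, "tf_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  chem <- data.frame(source = rep(c("chem_A", "chem_B"),
                                  times = c(min(6, length(sw)), 2)),
                     target = c(sw[seq_len(min(6, length(sw)))], sw[1:2]))
  utils::write.table(chem, file.path(dir, "chem_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
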