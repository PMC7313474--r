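#' Default pipeline configuration
#'
#' Every threshold that affects pipeline output, with the method's standard
#' values as defaults: fold-change band 1.5-4 targeting 1000-2000 retained
#' genes, BH FDR 0.05, edge rule |PCC| >= 0.6 at edge FDR 0.05, switch rule
#' Zg < 2.5 / Kpi > 0.8 / APCC < 0, strong-hub flag at Zg > 5, chemical
#' degree floor 4.
#'
#' @param expr,labels paths to the expression table and label TSV (omit when
#'   `synthetic` is given).
#' @param synthetic optional [synthetic_spec()] used instead of input files.
#' @param condition_label condition name stamped on the switch set.
#' @param already_log2 whether the expression table is already log2.
#' @param fc_min,fc_max,target_low,target_high,alpha,floor_quantile
#'   differential-filter settings (see [filter_config()]).
#' @param pcc_floor,alpha_edge,corr_scope network settings.
#' @param k `"auto"` (SSE scree elbow) or an integer community count.
#' @param k_min,k_max scree search range when `k = "auto"`.
#' @param replicates k-means random restarts.
#' @param seed RNG seed controlling clustering and removal curves.
#' @param apcc_party,zg_hub,kpi_switch,zg_strong_hub cartography thresholds.
#' @param robustness logical: compute removal curves (default `FALSE`).
#' @param fraction_grid,repeats removal-curve settings.
#' @param gmt,ppi,tf_edges,chem_edges optional annotation inputs (paths).
#' @param min_chem_degree chemical-ranking degree floor.
#' @param out_dir optional directory for stage outputs (TSV + manifest).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expr = NULL, labels = NULL, synthetic = NULL,
                            condition_label = "case",
                            already_log2 = TRUE,
                            fc_min = 1.5, fc_max = 4,
                            target_low = 1000, target_high = 2000,
                            alpha = 0.05, floor_quantile = 0.10,
                            pcc_floor = 0.6, alpha_edge = 0.05,
                            corr_scope = "all",
                            k = "auto", k_min = 2, k_max = 10,
                            replicates = 50, seed = 17,
                            apcc_party = 0.5, zg_hub = 2.5,
                            kpi_switch = 0.8, zg_strong_hub = 5,
                            robustness = FALSE,
                            fraction_grid = seq(0, 0.5, 0.05), repeats = 20,
                            gmt = NULL, ppi = NULL, tf_edges = NULL,
                            chem_edges = NULL, min_chem_degree = 4,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$synthetic) && (is.null(cfg$expr) || is.null(cfg$labels))) {
    stop("config must provide either `synthetic` or both `expr` and `labels`")
  }
  if (cfg$fc_min > cfg$fc_max) stop("fc_min must not exceed fc_max")
  if (cfg$target_low >= cfg$target_high) {
    stop("target_low must be below target_high")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$pcc_floor < 0 || cfg$pcc_floor > 1) {
    stop("pcc_floor must be in [0, 1]")
  }
  if (!identical(cfg$k, "auto") &&
      (!is.numeric(cfg$k) || cfg$k < 2)) {
    stop("k must be \"auto\" or an integer >= 2")
  }
  if (!cfg$corr_scope %in% c("all", "case_only")) {
    stop("corr_scope must be 'all' or 'case_only'")
  }
  invisible(cfg)
}

#' Run the full switch-gene mining pipeline
#'
#' Executes the stages in order -- differential filter, co-expression
#' network, community cartography (with switch-gene extraction), optional
#' robustness curves, and optional annotation analyses -- and assembles a
#' reproducibility manifest echoing every threshold, input digests, and
#' per-stage gene/edge counts. Any stage failure aborts with the stage
#' name.
#'
#' @param config a [pipeline_config()] or a path to a JSON file of the same
#'   fields.
#' @return List with `switch_set`, `diff`, `fc_selection`, `network`,
#'   `partition`, `cartography`, `curves` (when requested), `enrichment`,
#'   `chemicals` (when inputs given), and `manifest`.
#' @export
run_switch_pipeline <- function(config) {
  if (is.character(config)) {
    raw <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(raw$synthetic)) raw$synthetic <- do.call(synthetic_spec,
                                                          raw$synthetic)
    config <- do.call(pipeline_config, raw)
  }
  validate_pipeline_config(config)
  cfg <- config
  stages <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## -- load ---------------------------------------------------------------
  em0 <- run_stage("load", function() {
    if (!is.null(cfg$synthetic)) generate_expression(cfg$synthetic)$em
    else read_expression_table(cfg$expr, cfg$labels,
                               already_log2 = cfg$already_log2)
  })
  stages$load <- list(status = "run", genes = nrow(em0$values),
                      samples = ncol(em0$values))

  ## -- filter -------------------------------------------------------------
  fcfg <- filter_config(cfg$fc_min, cfg$fc_max, cfg$target_low,
                        cfg$target_high, cfg$alpha, cfg$floor_quantile)
  filt <- run_stage("filter", function() {
    em1 <- prefilter_expression(em0, fcfg)
    ds <- differential_stats(em1)
    sel <- select_fold_change_threshold(ds, fcfg)
    emf <- apply_filter(em1, ds, sel$threshold, cfg$alpha)
    list(em = emf, ds = attr(emf, "diff_stats"), sel = sel,
         prefiltered = nrow(em1$values))
  })
  stages$filter <- list(status = "run",
                        prefiltered_genes = filt$prefiltered,
                        threshold = filt$sel$threshold,
                        in_band = filt$sel$in_band,
                        retained_genes = nrow(filt$em$values))

  ## -- network ------------------------------------------------------------
  net <- run_stage("network", function() {
    corr <- correlation_matrix(filt$em, cfg$corr_scope)
    n_s <- if (cfg$corr_scope == "all") ncol(filt$em$values)
           else sum(filt$em$condition == "case")
    build_network(corr, cfg$pcc_floor, cfg$alpha_edge, n_s)
  })
  stages$network <- list(status = "run", nodes = length(net$nodes),
                         edges = nrow(net$edges),
                         negative_edges = sum(net$edges$weight < 0),
                         isolated = length(net$isolated))

  ## -- cartography --------------------------------------------------------
  carto <- run_stage("cartography", function() {
    if (identical(cfg$k, "auto")) {
      scree <- choose_k_scree(filt$em, cfg$k_min:cfg$k_max,
                              replicates = max(5, cfg$replicates %/% 2),
                              seed = cfg$seed)
      k <- scree$k
    } else {
      scree <- NULL
      k <- as.integer(cfg$k)
    }
    part <- kmeans_partition(filt$em, k, cfg$replicates, seed = cfg$seed + 1)
    th <- cartography_thresholds(zg_hub = cfg$zg_hub,
                                 kpi_switch = cfg$kpi_switch,
                                 apcc_party = cfg$apcc_party,
                                 zg_strong_hub = cfg$zg_strong_hub,
                                 kpi_nonhub = c(0.05, 0.62, cfg$kpi_switch))
    cart <- node_cartography(net, part, th)
    sw <- suppressWarnings(extract_switch_genes(cart, cfg$condition_label))
    list(part = part, cart = cart, switch_set = sw, scree = scree, k = k)
  })
  stages$cartography <- list(status = "run", k = carto$k,
                             sse = carto$part$sse,
                             fight_club = sum(
                               carto$cart$hub_class == "fight_club"),
                             switch_genes = length(carto$switch_set$genes))

  ## -- robustness ---------------------------------------------------------
  curves <- NULL
  if (isTRUE(cfg$robustness)) {
    curves <- run_stage("robustness", function() {
      removal_curves(net, carto$cart, fraction_grid = cfg$fraction_grid,
                     repeats = cfg$repeats, seed = cfg$seed + 2)
    })
    stages$robustness <- list(status = "run",
                              classes = unique(curves$class_label))
  } else {
    stages$robustness <- list(status = "skipped")
  }

  ## -- compare (cross-condition) ------------------------------------------
  ## a single-condition run has nothing to intersect; recorded for manifest
  stages$compare <- list(status = "skipped",
                         note = "single condition; use intersect_switch_sets")

  ## -- enrich / annotate ---------------------------------------------------
  enrichment <- chemicals <- NULL
  if (!is.null(cfg$gmt) && length(carto$switch_set$genes) > 0) {
    enrichment <- run_stage("enrich", function() {
      gsc <- read_gmt(cfg$gmt)
      universe <- gene_ids(em0)
      if (!is.null(cfg$ppi)) {
        ppi <- read_interaction_table(cfg$ppi, directed = FALSE)
        mcn <- minimum_connected_subnetwork(ppi, carto$switch_set$genes)
        universe <- mcn$nodes
      }
      query <- intersect(carto$switch_set$genes, universe)
      ora_hypergeometric(query, gsc, universe)
    })
    stages$enrich <- list(status = "run", sets_tested = nrow(enrichment))
  } else {
    stages$enrich <- list(status = "skipped")
  }
  if (!is.null(cfg$chem_edges) && length(carto$switch_set$genes) > 0) {
    chemicals <- run_stage("chemicals", function() {
      ce <- read_interaction_table(cfg$chem_edges, directed = TRUE)
      rank_chemicals(ce, carto$switch_set$genes, cfg$min_chem_degree)
    })
  }

  manifest <- build_manifest(cfg, stages)
  result <- list(switch_set = carto$switch_set,
                 diff = filt$ds, fc_selection = filt$sel,
                 network = net, partition = carto$part,
                 cartography = carto$cart, scree = carto$scree,
                 curves = curves, enrichment = enrichment,
                 chemicals = chemicals, manifest = manifest)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, cfg$out_dir)
  result
}

build_manifest <- function(cfg, stages) {
  inputs <- Filter(Negate(is.null),
                   list(expr = cfg$expr, labels = cfg$labels, gmt = cfg$gmt,
                        ppi = cfg$ppi, tf_edges = cfg$tf_edges,
                        chem_edges = cfg$chem_edges))
  digests <- if (length(inputs) > 0) {
    lapply(inputs, function(p) unname(tools::md5sum(p)))
  } else list()
  echo <- cfg
  class(echo) <- NULL
  echo$synthetic <- if (is.null(cfg$synthetic)) NULL
                    else unclass(cfg$synthetic)
  list(package_version = as.character(utils::packageVersion("switchscan")),
       config = echo,
       input_digests = digests,
       stages = stages)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$diff, file.path(out_dir, "diffstats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(result$network, file.path(out_dir, "network.tsv"))
  utils::write.table(result$cartography,
                     file.path(out_dir, "cartography.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(result$switch_set$genes,
             file.path(out_dir, "switch_genes.txt"))
  if (!is.null(result$curves)) {
    utils::write.table(result$curves, file.path(out_dir, "curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}
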