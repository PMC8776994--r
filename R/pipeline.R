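# End-to-end orchestration: configuration, group-comparison reports, and
# the full analysis chain (simulate/load -> subtype discovery -> score
# pipeline -> infiltration -> survival reports) with a reproducibility
# manifest.

#' Build a pipeline configuration
#'
#' Thresholds default to the values the analysis is designed around:
#' `|log2FC| > 1` with adjusted p < 0.05 for differential expression,
#' Cox p < 0.01 for the prognostic screen, Pearson r > 0.3 for
#' correlation-proxy sets, minprop 0.1 for the cutpoint search and
#' alpha 0.25 for ssGSEA.
#'
#' @param simulation A [sim_config()] list (cohort is simulated), or
#'   `NULL` when file inputs are given.
#' @param expression,clinical,gene_sets,weights Optional input file paths
#'   (TSV / TSV / GMT / two-column TSV), used when `simulation` is `NULL`.
#' @param lfc,fdr,cox_p,r_threshold,minprop,alpha Analysis thresholds.
#' @param k_range,n_runs Consensus-clustering controls.
#' @param seed Master seed for NMF (and simulation when no explicit
#'   simulation seed is given).
#' @param out_dir Run directory to create.
#' @return Validated `PipelineConfig` list.
#' @export
pipeline_config <- function(simulation = NULL,
                            expression = NULL, clinical = NULL,
                            gene_sets = NULL, weights = NULL,
                            lfc = 1, fdr = 0.05, cox_p = 0.01,
                            r_threshold = 0.3, minprop = 0.1, alpha = 0.25,
                            k_range = 2:4, n_runs = 100L, seed = 1L,
                            out_dir = tempfile("m6a_run_")) {
  cfg <- list(simulation = simulation, expression = expression,
              clinical = clinical, gene_sets = gene_sets, weights = weights,
              lfc = lfc, fdr = fdr, cox_p = cox_p,
              r_threshold = r_threshold, minprop = minprop, alpha = alpha,
              k_range = as.integer(k_range), n_runs = as.integer(n_runs),
              seed = as.integer(seed), out_dir = out_dir)
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1L && x > 0 && x <= 1
  if (!in01(cfg$fdr)) stop("fdr must lie in (0, 1]", call. = FALSE)
  if (!in01(cfg$cox_p)) stop("cox_p must lie in (0, 1]", call. = FALSE)
  if (cfg$lfc <= 0) stop("lfc must be positive", call. = FALSE)
  if (cfg$minprop <= 0 || cfg$minprop >= 0.5)
    stop("minprop must lie in (0, 0.5)", call. = FALSE)
  if (cfg$alpha < 0) stop("alpha must be nonnegative", call. = FALSE)
  if (abs(cfg$r_threshold) >= 1) stop("r_threshold must lie in (-1, 1)", call. = FALSE)
  if (any(cfg$k_range < 2L)) stop("k_range values must be >= 2", call. = FALSE)
  if (cfg$n_runs < 2L) stop("n_runs must be >= 2", call. = FALSE)
  if (is.null(cfg$simulation) &&
      (is.null(cfg$expression) || is.null(cfg$clinical)))
    stop("either a simulation config or expression + clinical paths are required",
         call. = FALSE)
  if (!is.null(cfg$simulation)) validate_sim_config(cfg$simulation)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' All [pipeline_config()] fields are accepted as top-level YAML keys; a
#' `simulation:` mapping is passed through [sim_config()] (its `seed` is
#' mandatory there).
#'
#' @param path YAML file path.
#' @return Validated `PipelineConfig` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) y$simulation <- do.call(sim_config, y$simulation)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or file loading and sample
#' alignment), NMF consensus subtyping of the regulator genes with
#' survival-guided selection of k, the m6A score pipeline (differential
#' expression -> signature -> prognostic screen -> PCA score -> cutpoint
#' groups), ssGSEA infiltration scoring of the provided gene sets, the
#' stemness index when weights are available, and Kaplan-Meier / log-rank
#' survival reports for subtypes and score groups. Every artifact is
#' written under `config$out_dir` in stage-numbered files together with a
#' `manifest.json` recording the config hash, seed, and per-stage gene and
#' sample counts; a rerun with the identical config reproduces identical
#' artifacts.
#'
#' @param config A [pipeline_config()] list.
#' @return The run directory path, invisibly; the manifest list as
#'   attribute `manifest`.
#' @export
run_full_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
                   seed = config$seed, stages = list())

  # stage 1: inputs
  if (!is.null(config$simulation)) {
    cohort <- simulate_cohort(config$simulation)
    expr <- cohort$expr; clinical <- cohort$clinical
    gene_sets <- cohort$gene_sets
    write_cohort(cohort, file.path(config$out_dir, "01_cohort"))
  } else {
    expr <- read_expression(config$expression)
    clinical <- read_clinical(config$clinical)
    al <- align_samples(expr, clinical)
    expr <- al$expr; clinical <- al$clinical
    gene_sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets)
  }
  manifest$stages$input <- list(n_genes = nrow(expr), n_samples = ncol(expr))
  message("input: ", nrow(expr), " genes x ", ncol(expr), " samples")

  # stage 2: subtype discovery on the regulator panel
  registry <- load_regulator_registry()
  panel <- intersect(registry$symbol, rownames(expr))
  if (length(panel) < 2L)
    stop("pipeline failed at stage 'subtype': fewer than 2 registry genes ",
         "in the expression matrix", call. = FALSE)
  X <- nmf_input(expr[panel, , drop = FALSE])
  sub <- select_k(X, clinical, k_range = config$k_range,
                  n_runs = config$n_runs, seed = config$seed)
  utils::write.table(
    data.frame(sample_id = names(sub$labels), subtype = unname(sub$labels)),
    file.path(config$out_dir, "02_subtypes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sub$consensus,
                     file.path(config$out_dir, "02_consensus.tsv"),
                     sep = "\t", quote = FALSE)
  manifest$stages$subtype <- list(k = sub$k, n_regulators = length(panel),
                                  average_silhouette = sub$average_silhouette,
                                  logrank_p = sub$logrank_p)
  message("subtype: k = ", sub$k, ", silhouette = ",
          signif(sub$average_silhouette, 3))

  # stage 3: m6A score chain
  score_tab <- run_score_pipeline(expr, clinical, sub$labels,
                                  lfc = config$lfc, fdr = config$fdr,
                                  cox_p = config$cox_p,
                                  minprop = config$minprop)
  if (!is.null(config$weights)) {
    w <- read_weights(config$weights)
    score_tab$mRNAsi <- as.numeric(stemness_index(expr, w))
  }
  utils::write.table(score_tab, file.path(config$out_dir, "03_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$score <- attr(score_tab, "stage_counts")

  # stage 4: infiltration
  if (!is.null(gene_sets) && length(gene_sets)) {
    infil <- immune_infiltration(expr, gene_sets, alpha = config$alpha)
    write_enrichment(infil, file.path(config$out_dir, "04_infiltration.tsv"))
    manifest$stages$infiltration <- list(n_sets = nrow(infil))
  }

  # stage 5: survival reports
  surv_report <- list(
    subtype_logrank = logrank_test(clinical$time, clinical$event, sub$labels),
    score_group_logrank = logrank_test(clinical$time, clinical$event,
                                       score_tab$score_group))
  km <- km_curve(clinical$time, clinical$event)
  utils::write.table(km, file.path(config$out_dir, "05_km_overall.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(surv_report, file.path(config$out_dir, "05_survival.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$survival <- lapply(surv_report, `[[`, "p")

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- config$out_dir
  attr(out, "manifest") <- manifest
  invisible(out)
}

#' Compare one or many value vectors across sample groups
#'
#' Dispatches to the Wilcoxon rank-sum test for two groups and the
#' Kruskal-Wallis test for more; with several value vectors, a batch table
#' with BH-adjusted p-values is returned.
#'
#' @param values Numeric vector, or named list of numeric vectors.
#' @param groups Group labels aligned with the values.
#' @return data.frame with columns `variable`, `test`, `statistic`, `p`,
#'   `adjP`.
#' @export
compare_groups_report <- function(values, groups) {
  if (!is.list(values)) values <- list(value = values)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  rows <- lapply(names(values), function(nm) {
    v <- values[[nm]]
    if (length(v) != length(groups))
      stop("values and groups lengths differ for '", nm, "'", call. = FALSE)
    split_v <- split(v, droplevels(groups))
    if (length(split_v) == 2L) {
      res <- wilcoxon_rank_sum(split_v[[1L]], split_v[[2L]])
      data.frame(variable = nm, test = "wilcoxon",
                 statistic = res$statistic, p = res$p)
    } else {
      res <- kruskal_wallis(split_v)
      data.frame(variable = nm, test = "kruskal-wallis",
                 statistic = res$statistic, p = res$p)
    }
  })
  out <- do.call(rbind, rows)
  out$adjP <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
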