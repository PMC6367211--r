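# End-to-end orchestration: discovery (simulate/load -> associate ->
# select -> co-functionality -> clusters) and single-cell CN counting
# (simulate/load -> modal profile -> counts -> group comparison), with
# stage-level logging, deterministic outputs and a checksummed manifest.

#' Build a pipeline run configuration
#'
#' Defaults reproduce the anchored analysis settings: top 250 positively
#' associated genes and a co-functionality threshold of 0.5. The full
#' configuration is echoed into every manifest so parameter decisions are
#' auditable in every run. Unknown keys in a configuration file are hard
#' errors (silent typos corrupt science).
#'
#' @param seed master seed for all simulation stages
#' @param outdir output directory
#' @param stages named logical list toggling stages; missing entries default
#'   to `TRUE`. Discovery stages: `simulate`, `associate`, `select`,
#'   `cofun`, `clusters`. CN stages: `simulate`, `modal`, `counts`,
#'   `compare`.
#' @param top_n genes selected from the association ranking (default 250)
#' @param tau co-functionality network threshold (default 0.5)
#' @param assoc_method association correlation flavor
#' @param cofun_method co-functionality correlation flavor
#' @param min_set_size,max_set_fraction gene-set size filters
#' @param min_cluster_size minimum reported cluster size
#' @param whole_chrom_fraction whole-chromosome event fraction
#' @param control_condition control label for the modal profile
#' @param metric aberration-count metric for the group comparison
#' @param adjust multiple-comparison adjustment for the Dunn tests
#' @param inputs named list of input paths (`expression`, `scores`, `gmt`,
#'   `cn_calls`) used when simulation is toggled off
#' @param sim_expression,sim_cn named lists of generator overrides passed to
#'   [expression_sim_config()] / [cn_sim_config()]
#' @return a validated `RunConfig` list
#' @export
run_config <- function(seed = 1, outdir = "cofunr_run",
                       stages = list(), top_n = 250, tau = 0.5,
                       assoc_method = "spearman", cofun_method = "pearson",
                       min_set_size = 5, max_set_fraction = 0.5,
                       min_cluster_size = 2, whole_chrom_fraction = 0.9,
                       control_condition = "control", metric = "total",
                       adjust = "bonferroni", inputs = list(),
                       sim_expression = list(), sim_cn = list()) {
  cfg <- list(seed = seed, outdir = outdir, stages = stages, top_n = top_n,
              tau = tau, assoc_method = assoc_method,
              cofun_method = cofun_method, min_set_size = min_set_size,
              max_set_fraction = max_set_fraction,
              min_cluster_size = min_cluster_size,
              whole_chrom_fraction = whole_chrom_fraction,
              control_condition = control_condition, metric = metric,
              adjust = adjust, inputs = inputs,
              sim_expression = sim_expression, sim_cn = sim_cn)
  cofunctionality_correlation_flavor(cfg$cofun_method)
  if (!cfg$assoc_method %in% c("spearman", "pearson"))
    stop("unknown association method: ", cfg$assoc_method)
  structure(cfg, class = "RunConfig")
}

#' Load a run configuration from JSON
#'
#' Any key not understood by [run_config()] (at the top level or inside
#' `stages`, `inputs`, `sim_expression`, `sim_cn`) is a hard error.
#'
#' @param path JSON file path
#' @return a `RunConfig`
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (sub in c("sim_expression", "sim_cn")) {
    fun <- if (sub == "sim_expression") expression_sim_config else cn_sim_config
    bad <- setdiff(names(raw[[sub]]), names(formals(fun)))
    if (length(bad))
      stop("unknown key(s) in ", sub, ": ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(names(raw$inputs),
                 c("expression", "scores", "gmt", "cn_calls", "coregulation"))
  if (length(bad))
    stop("unknown key(s) in inputs: ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

stage_on <- function(config, name) isTRUE(config$stages[[name]] %||% TRUE)

run_stage <- function(name, code) {
  message("[", name, "] running")
  tryCatch(force(code), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

config_for_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$stages <- as.list(cfg$stages)
  cfg
}

write_manifest <- function(config, outdir, files) {
  files <- sort(files)
  entries <- lapply(files, function(f)
    list(path = f, md5 = unname(tools::md5sum(file.path(outdir, f)))))
  manifest <- list(tool = "cofunr", version = pkg_version(),
                   config = config_for_manifest(config), files = entries)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the discovery pipeline
#'
#' Simulates (or loads) expression, instability scores and gene sets, ranks
#' genes by instability association, selects the top `top_n`, computes the
#' co-functionality network over those genes and extracts clusters. Every
#' file written is listed with its md5 checksum in `manifest.json`; reruns
#' with the same configuration and seed are byte-identical.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with `association`, `top_genes`, `network`,
#'   `clusters`, `truth` (when simulated) and `manifest`
#' @export
run_discovery <- function(config = run_config()) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- list()
  expr <- scores <- sets <- NULL

  if (stage_on(config, "simulate")) {
    sim <- run_stage("simulate", {
      sim_cfg <- do.call(expression_sim_config,
                         c(config$sim_expression, list(seed = config$seed)))
      simulate_expression(sim_cfg)
    })
    expr <- sim$expression; scores <- sim$scores; sets <- sim$sets
    out$truth <- sim$truth
  } else if (!is.null(config$inputs$expression)) {
    loaded <- run_stage("load", list(
      expr = read_expression_tsv(config$inputs$expression),
      scores = read_instability_tsv(config$inputs$scores),
      sets = read_gmt(config$inputs$gmt)))
    expr <- loaded$expr
    scores <- loaded$scores
    sets <- loaded$sets
  }

  if (stage_on(config, "associate") && !is.null(expr)) {
    out$association <- run_stage("associate",
      associate(expr, scores, method = config$assoc_method))
    write_association_tsv(out$association,
                          file.path(config$outdir, "association.tsv"),
                          list(method = config$assoc_method))
    files <- c(files, "association.tsv")
  }

  if (stage_on(config, "select") && !is.null(out$association)) {
    out$top_genes <- run_stage("select",
      select_top(out$association, n = config$top_n))
    con <- file(file.path(config$outdir, "top_genes.txt"), "w")
    writeLines(c(output_header(list(artifact = "top_genes",
                                    top_n = config$top_n)),
                 out$top_genes), con)
    close(con)
    files <- c(files, "top_genes.txt")
  }

  if (stage_on(config, "cofun") && !is.null(out$top_genes)) {
    out$network <- run_stage("cofun", {
      coreg <- if (!is.null(config$inputs$coregulation))
        read_coregulation_tsv(config$inputs$coregulation)
      else build_coregulation(expr, method = config$assoc_method)
      fl <- functional_likelihood(coreg, sets, out$top_genes,
                                  min_set_size = config$min_set_size,
                                  max_set_fraction = config$max_set_fraction)
      w <- cofunctionality_matrix(fl, flavor = config$cofun_method)
      threshold_network(w, tau = config$tau)
    })
    write_network_edgelist(out$network,
                           file.path(config$outdir, "network.tsv"))
    files <- c(files, "network.tsv")
  }

  if (stage_on(config, "clusters") && !is.null(out$network)) {
    out$clusters <- run_stage("clusters",
      extract_clusters(out$network, min_cluster_size = config$min_cluster_size))
    write_clusters_tsv(out$clusters,
                       file.path(config$outdir, "clusters.tsv"),
                       list(tau = config$tau,
                            min_cluster_size = config$min_cluster_size))
    files <- c(files, "clusters.tsv")
  }

  out$manifest <- write_manifest(config, config$outdir, files)
  invisible(out)
}

#' Run the single-cell copy-number counting pipeline
#'
#' Simulates (or loads) single-cell copy-number state calls, derives the
#' modal profile of the control condition, counts focal and
#' whole-chromosome aberrations per cell and compares conditions with a
#' Kruskal-Wallis test plus Dunn pairwise tests. Outputs and manifest as in
#' [run_discovery()].
#'
#' @param config a [run_config()]
#' @return invisibly, a list with `profiles`, `modal`, `counts`,
#'   `comparison`, `truth` (when simulated) and `manifest`
#' @export
run_scna <- function(config = run_config()) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- list()
  profiles <- NULL

  if (stage_on(config, "simulate")) {
    sim <- run_stage("simulate", {
      sim_cfg <- do.call(cn_sim_config,
                         c(config$sim_cn, list(seed = config$seed)))
      simulate_cn_profiles(sim_cfg)
    })
    profiles <- sim$profiles
    out$truth <- sim$truth
  } else if (!is.null(config$inputs$cn_calls)) {
    profiles <- run_stage("load", read_cn_calls(config$inputs$cn_calls))
  }
  out$profiles <- profiles

  if (stage_on(config, "modal") && !is.null(profiles)) {
    out$modal <- run_stage("modal",
      modal_profile(profiles, config$control_condition))
  }

  if (stage_on(config, "counts") && !is.null(out$modal)) {
    out$counts <- run_stage("counts",
      count_aberrations(profiles, out$modal,
                        whole_chrom_fraction = config$whole_chrom_fraction))
    write_counts_tsv(out$counts, file.path(config$outdir, "counts.tsv"),
                     list(control = config$control_condition,
                          whole_chrom_fraction = config$whole_chrom_fraction))
    files <- c(files, "counts.tsv")
  }

  if (stage_on(config, "compare") && !is.null(out$counts)) {
    out$comparison <- run_stage("compare",
      compare_groups(out$counts, metric = config$metric,
                     adjust = config$adjust))
    cmp <- out$comparison
    jsonlite::write_json(
      list(metric = cmp$metric, statistic = cmp$statistic, df = cmp$df,
           p_value = cmp$p_value, summary = cmp$summary,
           pairwise = cmp$pairwise, adjust = cmp$adjust),
      file.path(config$outdir, "stats.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, "stats.json")
  }

  out$manifest <- write_manifest(config, config$outdir, files)
  invisible(out)
}
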