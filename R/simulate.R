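# Synthetic-data generators with known planted truth. The expression
# generator emulates copy-number-driven expression whose dosage effects
# define a per-sample instability (SCNA burden) score, plus a planted
# co-functional gene module co-annotated across gene sets. The CN generator
# emulates AneuFinder-style integer state calls for G1 single cells on a
# diploid background with planted focal segments and whole-chromosome
# aneuploidies. Each generator draws from named RNG sub-streams
# (see [substream_seed()]) so generators never perturb each other.

#' Configuration for the synthetic expression / gene-set world
#'
#' Defaults describe the world the discovery pipeline is tested against:
#' 2,000 genes x 300 samples, 240 dosage-responsive (driver) genes grouped
#' into co-altered regions of 8, a planted 11-gene co-functional module
#' spread across distinct regions, and 500 gene sets of which 20 co-annotate
#' the module. `noise_sd` and `module_latent_sd` may be 0 to realize the
#' noiseless and null-control limiting cases.
#'
#' @param n_genes number of genes
#' @param n_samples number of samples
#' @param n_instability_driver_genes genes living in alterable regions
#' @param planted_module_size size of the planted co-functional module
#' @param n_gene_sets number of gene sets in the synthetic database
#' @param n_coannotation_sets sets that jointly annotate the planted module
#' @param dosage_effect_size mean expression shift per altered copy
#' @param noise_sd independent per-gene, per-sample noise SD
#' @param module_latent_sd SD of the shared latent factor added to module
#'   genes (their co-regulation signal)
#' @param module_score_coupling correlation of the module latent factor with
#'   the standardized instability score; makes module genes rank near the
#'   top of the association, as a proliferation/instability-tracking
#'   cell-cycle module would
#' @param region_size genes per co-altered region
#' @param lambda_range range of per-sample Poisson means for the number of
#'   altered regions
#' @param set_size_range gene-set sizes are drawn log-uniformly in this range
#' @param seed master seed
#' @return validated `ExpressionSimConfig` list
#' @export
expression_sim_config <- function(n_genes = 2000, n_samples = 300,
                                  n_instability_driver_genes = 240,
                                  planted_module_size = 11,
                                  n_gene_sets = 500,
                                  n_coannotation_sets = 20,
                                  dosage_effect_size = 1.5,
                                  noise_sd = 1,
                                  module_latent_sd = 2,
                                  module_score_coupling = 0.3,
                                  region_size = 8,
                                  lambda_range = c(2, 12),
                                  set_size_range = c(10, 200),
                                  seed = 1) {
  cfg <- list(n_genes = n_genes, n_samples = n_samples,
              n_instability_driver_genes = n_instability_driver_genes,
              planted_module_size = planted_module_size,
              n_gene_sets = n_gene_sets,
              n_coannotation_sets = n_coannotation_sets,
              dosage_effect_size = dosage_effect_size, noise_sd = noise_sd,
              module_latent_sd = module_latent_sd,
              module_score_coupling = module_score_coupling,
              region_size = region_size, lambda_range = lambda_range,
              set_size_range = set_size_range, seed = seed)
  if (cfg$planted_module_size > cfg$n_genes)
    stop("planted module larger than gene universe")
  if (cfg$n_instability_driver_genes > cfg$n_genes)
    stop("more driver genes than genes")
  if (cfg$n_instability_driver_genes - cfg$planted_module_size <
        cfg$region_size)
    stop("driver genes must cover the planted module (one singleton region ",
         "per module gene) plus at least one region of size ", cfg$region_size)
  if (cfg$n_coannotation_sets > cfg$n_gene_sets)
    stop("n_coannotation_sets exceeds n_gene_sets")
  if (cfg$noise_sd < 0 || cfg$module_latent_sd < 0)
    stop("noise/latent SDs must be >= 0")
  if (abs(cfg$module_score_coupling) > 1)
    stop("module_score_coupling must lie in [-1, 1]")
  if (cfg$n_samples < 3) stop("need >= 3 samples")
  structure(cfg, class = "ExpressionSimConfig")
}

#' Simulate expression, instability scores and gene sets with planted truth
#'
#' Each sample draws a number of altered regions (Poisson, with a mean drawn
#' uniformly per sample from `lambda_range`); genes of altered regions get a
#' `dosage_effect_size` expression shift, and the instability score is the
#' sample's alteration count. Planted-module genes sit in distinct regions
#' and additionally share a latent factor (SD `module_latent_sd`) that is
#' coupled to the instability score with correlation
#' `module_score_coupling`; the module is co-annotated in the first
#' `n_coannotation_sets` gene sets. Fully reproducible from the seed.
#'
#' @param cfg an [expression_sim_config()]
#' @return list with `expression` ([expression_matrix()]), `scores`
#'   ([instability_scores()]), `sets` ([gene_set_collection()]) and `truth`
#'   (driver genes, module genes, regions, co-annotating set names, scores)
#' @export
simulate_expression <- function(cfg = expression_sim_config()) {
  stopifnot(inherits(cfg, "ExpressionSimConfig"))
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  sample_ids <- sprintf("s%04d", seq_len(cfg$n_samples))
  # non-module drivers form co-altered blocks of `region_size`; every planted
  # module gene is its own singleton region, so module co-expression comes
  # from the shared latent factor alone (and vanishes in the null control)
  n_block <- (cfg$n_instability_driver_genes - cfg$planted_module_size) %/%
    cfg$region_size
  n_regions <- n_block + cfg$planted_module_size

  layout <- with_seed(substream_seed(cfg$seed, "layout"), {
    drivers <- sort(sample.int(cfg$n_genes, cfg$n_instability_driver_genes))
    module_pos <- sample.int(length(drivers), cfg$planted_module_size)
    module <- drivers[module_pos]
    others <- drivers[-module_pos]
    region_of <- integer(length(drivers))
    region_of[-module_pos] <- rep(seq_len(n_block), length.out = length(others))
    region_of[module_pos] <- n_block + seq_len(cfg$planted_module_size)
    list(drivers = drivers, region_of = region_of, module = module)
  })

  alt <- with_seed(substream_seed(cfg$seed, "alterations"), {
    lambda <- stats::runif(cfg$n_samples, cfg$lambda_range[1], cfg$lambda_range[2])
    n_alt <- stats::rpois(cfg$n_samples, lambda)
    hit <- matrix(0, n_regions, cfg$n_samples)
    for (s in seq_len(cfg$n_samples))
      if (n_alt[s] > 0)
        hit[sample.int(n_regions, min(n_alt[s], n_regions)), s] <- 1
    list(n_alt = n_alt, hit = hit)
  })

  latent <- with_seed(substream_seed(cfg$seed, "latent"), {
    eta <- stats::rnorm(cfg$n_samples)
    sc <- alt$n_alt
    std_score <- if (stats::sd(sc) > 0) (sc - mean(sc)) / stats::sd(sc)
                 else rep(0, cfg$n_samples)
    a <- cfg$module_score_coupling
    a * std_score + sqrt(1 - a^2) * eta
  })

  vals <- with_seed(substream_seed(cfg$seed, "noise"), {
    matrix(stats::rnorm(cfg$n_genes * cfg$n_samples, sd = cfg$noise_sd),
           cfg$n_genes, cfg$n_samples)
  })
  vals[layout$drivers, ] <- vals[layout$drivers, ] +
    cfg$dosage_effect_size * alt$hit[layout$region_of, , drop = FALSE]
  vals[layout$module, ] <- vals[layout$module, ] +
    rep(cfg$module_latent_sd * latent, each = length(layout$module))

  sets <- with_seed(substream_seed(cfg$seed, "genesets"), {
    lo <- cfg$set_size_range[1]
    hi <- min(cfg$set_size_range[2], floor(0.4 * cfg$n_genes))
    sizes <- pmax(lo, pmin(hi, round(exp(stats::runif(cfg$n_gene_sets,
                                                      log(lo), log(hi))))))
    members <- vector("list", cfg$n_gene_sets)
    module_ids <- gene_ids[layout$module]
    # co-annotating sets carry the module plus filler drawn from non-driver
    # genes: pathway co-members need not themselves be dosage-responsive
    filler <- setdiff(gene_ids, gene_ids[layout$drivers])
    for (k in seq_len(cfg$n_gene_sets)) {
      if (k <= cfg$n_coannotation_sets) {
        extra <- max(0L, sizes[k] - length(module_ids))
        members[[k]] <- c(module_ids, sample(filler, min(extra, length(filler))))
      } else {
        members[[k]] <- sample(gene_ids, sizes[k])
      }
    }
    names(members) <- sprintf("set%04d", seq_len(cfg$n_gene_sets))
    gene_set_collection(members, rep("synthetic gene set", cfg$n_gene_sets))
  })

  rownames(vals) <- gene_ids
  colnames(vals) <- sample_ids
  truth <- list(
    driver_genes = gene_ids[layout$drivers],
    module_genes = gene_ids[layout$module],
    regions = split(gene_ids[layout$drivers], layout$region_of),
    coannotation_sets = names(sets)[seq_len(cfg$n_coannotation_sets)],
    scores = stats::setNames(alt$n_alt, sample_ids))
  list(expression = expression_matrix(vals),
       scores = instability_scores(alt$n_alt, sample_ids),
       sets = sets, truth = truth)
}

#' Configuration for the synthetic single-cell copy-number world
#'
#' Defaults: 48 G1-like cells per condition (the experimental design being
#' emulated sorts 48 single cells per condition), 22 chromosomes x 50 bins on
#' a diploid background; a control condition with zero event rates plus a
#' treated condition with planted focal and whole-chromosome events.
#'
#' @param n_cells_per_condition cells per condition (default 48)
#' @param conditions named list; each entry a list with `focal_rate` and
#'   `whole_chrom_rate` (expected events per cell)
#' @param n_chromosomes,bins_per_chromosome grid dimensions
#' @param bin_width bin width in bp (coordinates only; 0-based half-open)
#' @param focal_length_range inclusive range of focal event lengths in bins;
#'   default keeps events strictly below the whole-chromosome fraction
#' @param whole_chrom_fraction used to derive the default focal length cap
#' @param miscall_rate independent per-bin probability of a +/-1 state
#'   miscall, in [0, 0.2]
#' @param seed master seed
#' @return validated `CNSimConfig` list
#' @export
cn_sim_config <- function(n_cells_per_condition = 48,
                          conditions = list(
                            control = list(focal_rate = 0, whole_chrom_rate = 0),
                            treated = list(focal_rate = 3, whole_chrom_rate = 1)),
                          n_chromosomes = 22, bins_per_chromosome = 50,
                          bin_width = 1e6, focal_length_range = NULL,
                          whole_chrom_fraction = 0.9,
                          miscall_rate = 0, seed = 1) {
  if (is.null(focal_length_range))
    focal_length_range <- c(1, ceiling(whole_chrom_fraction *
                                         bins_per_chromosome) - 1L)
  cfg <- list(n_cells_per_condition = n_cells_per_condition,
              conditions = conditions, n_chromosomes = n_chromosomes,
              bins_per_chromosome = bins_per_chromosome, bin_width = bin_width,
              focal_length_range = focal_length_range,
              whole_chrom_fraction = whole_chrom_fraction,
              miscall_rate = miscall_rate, seed = seed)
  if (is.null(names(cfg$conditions)) || anyDuplicated(names(cfg$conditions)))
    stop("conditions must be uniquely named")
  for (cd in cfg$conditions)
    if (cd$focal_rate < 0 || cd$whole_chrom_rate < 0)
      stop("event rates must be >= 0")
  if (cfg$miscall_rate < 0 || cfg$miscall_rate > 0.2)
    stop("miscall_rate must lie in [0, 0.2]")
  if (cfg$bins_per_chromosome < 2) stop("need >= 2 bins per chromosome")
  if (cfg$focal_length_range[1] < 1 ||
      cfg$focal_length_range[2] >= cfg$whole_chrom_fraction *
        cfg$bins_per_chromosome)
    stop("focal lengths must lie in [1, whole_chrom_fraction * bins)")
  structure(cfg, class = "CNSimConfig")
}

#' Simulate single-cell copy-number profiles with planted events
#'
#' Every cell starts diploid (state 2). Per cell, the number of
#' whole-chromosome events is Poisson(`whole_chrom_rate`); each shifts every
#' bin of a distinct chromosome by +/-1. The number of focal events is
#' Poisson(`focal_rate`); each shifts a contiguous run of bins by +/-1 on a
#' chromosome without a whole-chromosome event, placed with at least one
#' unaffected bin between events so planted events map one-to-one onto
#' deviation runs (an event that cannot be placed after 100 tries is dropped
#' and not recorded). Miscalls then flip single bins by +/-1 independently
#' with probability `miscall_rate`. The truth record lists every realized
#' planted event and per-cell planted counts.
#'
#' @param cfg a [cn_sim_config()]
#' @return list with `profiles` ([cn_profile_set()]) and `truth` (list with
#'   `events` and per-cell `counts` data.frames)
#' @export
simulate_cn_profiles <- function(cfg = cn_sim_config()) {
  stopifnot(inherits(cfg, "CNSimConfig"))
  nb <- cfg$bins_per_chromosome
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  bins <- data.frame(
    chrom = rep(chroms, each = nb),
    start = rep((seq_len(nb) - 1L) * cfg$bin_width, cfg$n_chromosomes),
    end = rep(seq_len(nb) * cfg$bin_width, cfg$n_chromosomes))
  n_bins_total <- nrow(bins)
  chrom_offset <- stats::setNames((seq_along(chroms) - 1L) * nb, chroms)

  all_states <- list(); all_cond <- character(0)
  events <- list(); ev_i <- 0L
  for (cond in names(cfg$conditions)) {
    rates <- cfg$conditions[[cond]]
    states <- with_seed(substream_seed(cfg$seed, paste0("events_", cond)), {
      st <- matrix(2L, cfg$n_cells_per_condition, n_bins_total)
      for (i in seq_len(cfg$n_cells_per_condition)) {
        cell_id <- sprintf("%s_c%02d", cond, i)
        n_whole <- stats::rpois(1L, rates$whole_chrom_rate)
        whole_chr <- if (n_whole > 0)
          sample(chroms, min(n_whole, length(chroms))) else character(0)
        for (chr in whole_chr) {
          dir <- sample(c(-1L, 1L), 1L)
          idx <- chrom_offset[[chr]] + seq_len(nb)
          st[i, idx] <- st[i, idx] + dir
          ev_i <- ev_i + 1L
          events[[ev_i]] <- data.frame(
            cell_id = cell_id, condition = cond, type = "whole_chromosome",
            chrom = chr, start_bin = 1L, n_bins = nb, direction = dir,
            stringsAsFactors = FALSE)
        }
        n_focal <- stats::rpois(1L, rates$focal_rate)
        if (n_focal > 0) {
          avail_chr <- setdiff(chroms, whole_chr)
          occ <- lapply(stats::setNames(avail_chr, avail_chr),
                        function(x) logical(nb))
          for (k in seq_len(n_focal)) {
            if (!length(avail_chr)) break
            chr <- if (length(avail_chr) == 1L) avail_chr else
              sample(avail_chr, 1L)
            len <- sample(seq(cfg$focal_length_range[1],
                              cfg$focal_length_range[2]), 1L)
            placed <- FALSE
            for (try in seq_len(100L)) {
              s <- sample.int(nb - len + 1L, 1L)
              span <- max(1L, s - 1L):min(nb, s + len)
              if (!any(occ[[chr]][span])) {
                occ[[chr]][s:(s + len - 1L)] <- TRUE
                dir <- sample(c(-1L, 1L), 1L)
                idx <- chrom_offset[[chr]] + s:(s + len - 1L)
                st[i, idx] <- pmax(0L, st[i, idx] + dir)
                ev_i <- ev_i + 1L
                events[[ev_i]] <- data.frame(
                  cell_id = cell_id, condition = cond, type = "focal",
                  chrom = chr, start_bin = s, n_bins = len, direction = dir,
                  stringsAsFactors = FALSE)
                placed <- TRUE
                break
              }
            }
          }
        }
      }
      st
    })
    if (cfg$miscall_rate > 0) {
      states <- with_seed(substream_seed(cfg$seed, paste0("miscall_", cond)), {
        flip <- matrix(stats::runif(length(states)) < cfg$miscall_rate,
                       nrow(states), ncol(states))
        delta <- matrix(sample(c(-1L, 1L), length(states), replace = TRUE),
                        nrow(states), ncol(states))
        noisy <- states + flip * delta
        noisy[noisy < 0L] <- 0L
        noisy
      })
    }
    rownames(states) <- sprintf("%s_c%02d", cond,
                                seq_len(cfg$n_cells_per_condition))
    all_states[[cond]] <- states
    all_cond <- c(all_cond, rep(cond, cfg$n_cells_per_condition))
  }
  states <- do.call(rbind, all_states)
  ev <- if (ev_i > 0) do.call(rbind, events) else
    data.frame(cell_id = character(), condition = character(),
               type = character(), chrom = character(),
               start_bin = integer(), n_bins = integer(),
               direction = integer(), stringsAsFactors = FALSE)
  cell_ids <- rownames(states)
  counts <- data.frame(
    cell_id = cell_ids,
    condition = all_cond,
    n_focal = vapply(cell_ids, function(cl)
      sum(ev$cell_id == cl & ev$type == "focal"), integer(1)),
    n_whole_chromosome = vapply(cell_ids, function(cl)
      sum(ev$cell_id == cl & ev$type == "whole_chromosome"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(profiles = cn_profile_set(states, bins, all_cond),
       truth = list(events = ev, counts = counts))
}
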