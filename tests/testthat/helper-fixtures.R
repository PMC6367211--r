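# Fixture builders. Everything is generated in code; nothing is read from
# static files.

toy_expression <- function(values, genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, genes, samples)
}

# A CNProfileSet from a named list of per-cell state vectors over a single
# grid of `n_chrom` chromosomes x `nb` bins each.
toy_cn <- function(states_by_cell, condition, n_chrom = 1L, nb = NULL) {
  states <- do.call(rbind, states_by_cell)
  rownames(states) <- names(states_by_cell)
  if (is.null(nb)) nb <- ncol(states) / n_chrom
  bins <- data.frame(chrom = rep(paste0("chr", seq_len(n_chrom)), each = nb),
                     start = rep((seq_len(nb) - 1L) * 1000L, n_chrom),
                     end = rep(seq_len(nb) * 1000L, n_chrom))
  cn_profile_set(states, bins, condition)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

expr_tsv_lines <- function(mat, genes, samples) {
  c(paste(c("gene_id", samples), collapse = "\t"),
    vapply(seq_along(genes), function(i)
      paste(c(genes[i], mat[i, ]), collapse = "\t"), character(1)))
}

# Small discovery-world config used by pipeline tests (fast, still carries
# the planted signal).
small_expr_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes = 400, n_samples = 80, n_instability_driver_genes = 100,
         n_gene_sets = 80, n_coannotation_sets = 10,
         set_size_range = c(10, 80), seed = seed),
    list(...))
  do.call(expression_sim_config, args)
}

small_cn_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_cells_per_condition = 6, n_chromosomes = 6,
         bins_per_chromosome = 20, seed = seed),
    list(...))
  do.call(cn_sim_config, args)
}
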