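# Transcriptome-wide association between gene expression and per-sample
# genomic instability, and top-N selection of positively associated genes.

# Row-wise average ranks (ties averaged), the standard Spearman convention.
rank_rows <- function(m) {
  t(apply(m, 1L, rank, ties.method = "average"))
}

# Pearson correlation of each row of `m` with vector `y`; rows with zero
# variance return NA.
row_cor <- function(m, y) {
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  mc <- m - rowMeans(m)
  sm <- sqrt(rowSums(mc^2))
  num <- as.numeric(mc %*% yc)
  out <- num / (sm * sy)
  out[sm == 0 | sy == 0] <- NA_real_
  out
}

#' Rank genes by association with genomic instability
#'
#' For every gene, computes the correlation between its expression vector and
#' the per-sample instability score over the shared samples, plus a
#' Fisher-transformed standardized statistic `z = atanh(rho) * sqrt(m - 3)`
#' (`m` = shared sample count). Genes with zero expression variance are
#' retained with `rho = 0`, `z = 0` and `degenerate = TRUE`, so ranks cover
#' the full transcriptome. Ranks are a permutation of `1..G`, descending in
#' `z` with ties broken by higher `rho` then lexicographic gene ID.
#'
#' @param expr an [expression_matrix()]
#' @param inst an [instability_scores()] vector
#' @param method correlation flavor, `"spearman"` (default) or `"pearson"`
#' @return an `AssociationTable` data.frame with columns `gene_id`, `rho`,
#'   `z`, `rank`, `degenerate`
#' @export
associate <- function(expr, inst, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(colnames(expr), names(inst))
  if (length(shared) < 3L)
    stop("fewer than 3 shared samples between expression and instability scores")
  y <- as.numeric(inst[shared])
  if (length(unique(y)) < 2L) stop("instability scores constant over shared samples")
  x <- unclass(expr)[, shared, drop = FALSE]
  m <- length(shared)
  if (method == "spearman") {
    x <- rank_rows(x)
    y <- rank(y, ties.method = "average")
  }
  rho <- row_cor(x, y)
  degenerate <- is.na(rho)
  if (any(degenerate))
    message(sum(degenerate), " gene(s) with constant expression flagged degenerate")
  rho[degenerate] <- 0
  rho <- pmin(1, pmax(-1, rho))
  z <- atanh(rho) * sqrt(m - 3)
  z[degenerate] <- 0
  gene_id <- rownames(expr)
  ord <- order(-z, -rho, gene_id, method = "radix")
  rk <- integer(length(z))
  rk[ord] <- seq_along(z)
  tab <- data.frame(gene_id = gene_id, rho = rho, z = z, rank = rk,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  attr(tab, "n_samples") <- m
  attr(tab, "method") <- method
  class(tab) <- c("AssociationTable", "data.frame")
  tab
}

#' Select the top-N associated genes
#'
#' Returns the `n` genes with the largest `z` (positive direction; the
#' smallest `z` for `direction = "negative"`). Ties at the boundary break by
#' higher `rho`, then lexicographically smaller gene ID (the table's rank
#' order already encodes this).
#'
#' @param table an `AssociationTable` from [associate()]
#' @param n number of genes to keep (default 250)
#' @param direction `"positive"` (default) or `"negative"`
#' @return character vector of `n` gene IDs in selection order
#' @export
select_top <- function(table, n = 250, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(inherits(table, "AssociationTable"))
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  if (n > nrow(table)) stop("n = ", n, " exceeds gene count ", nrow(table))
  ord <- if (direction == "positive") {
    order(table$rank)
  } else {
    # mirrored tie rule at the low end: lower z, lower rho, then gene ID
    order(table$z, table$rho, table$gene_id, method = "radix")
  }
  table$gene_id[ord][seq_len(n)]
}
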