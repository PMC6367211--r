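# Guilt-by-association co-functionality: co-regulation matrix ->
# functional-likelihood vectors over a gene-set database -> co-functionality
# correlations -> thresholded network -> clusters.

# Pairwise Pearson correlation of the rows of `m`; constant rows get 0
# against every partner (flagged via attribute), diagonal exactly 1.
row_cor_matrix <- function(m) {
  sds <- apply(m, 1L, stats::sd)
  degenerate <- which(sds == 0 | is.na(sds))
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[degenerate, ] <- 0
  cc[, degenerate] <- 0
  cc <- (cc + t(cc)) / 2
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  diag(cc) <- 1
  attr(cc, "degenerate") <- rownames(m)[degenerate]
  cc
}

#' Build a gene co-regulation matrix from expression
#'
#' Pairwise Spearman correlation of gene expression profiles across samples;
#' a reconstruction of the co-regulation structure that large precomputed
#' resources capture. Genes with constant expression get correlation 0
#' against all partners and are flagged (attribute `degenerate`).
#'
#' @param expr an [expression_matrix()]
#' @param method `"spearman"` (default) or `"pearson"`
#' @return a [coregulation_matrix()]
#' @export
build_coregulation <- function(expr, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- unclass(expr)
  if (ncol(x) < 3L) stop("co-regulation needs >= 3 samples")
  cc <- row_cor_matrix(if (method == "spearman") rank_rows(x) else x)
  if (length(attr(cc, "degenerate")))
    message(length(attr(cc, "degenerate")),
            " constant gene(s) set to zero co-regulation")
  out <- coregulation_matrix(cc)
  attr(out, "degenerate") <- attr(cc, "degenerate")
  attr(out, "method") <- method
  out
}

#' Load a precomputed co-regulation matrix
#'
#' Alternative entry point: accepts a symmetric gene-by-gene matrix TSV
#' (header of gene IDs, first column of gene IDs) such as an exported
#' co-regulation network, and validates it.
#'
#' @param path TSV file path
#' @return a [coregulation_matrix()]
#' @export
read_coregulation_tsv <- function(path) {
  raw <- read_tsv_raw(path)
  g <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- g
  coregulation_matrix(vals)
}

#' Functional-likelihood vectors for query genes against a gene-set database
#'
#' For query gene `g` and set `S`, the likelihood is the Spearman correlation
#' between (a) `g`'s co-regulation vector over all background genes except
#' `g` itself and (b) the 0/1 membership indicator of `S` over those same
#' genes, with `g` excluded from the indicator (otherwise annotated query
#' genes would trivially self-correlate). The background universe is every
#' gene of the co-regulation matrix, not just the query genes -- likelihoods
#' computed over a selected subset alone would be dominated by selection
#' effects. Since the indicator is binary, its ranks are an affine transform
#' of the indicator itself, so the Spearman coefficient equals the Pearson
#' correlation of the ranked co-regulation vector with the raw indicator.
#'
#' @param coreg a [coregulation_matrix()]
#' @param sets a [gene_set_collection()]
#' @param query_genes character vector of genes to score (subset of the
#'   co-regulation universe)
#' @param min_set_size,max_set_fraction set-size filters applied after
#'   intersection with the universe (see [filter_gene_sets()])
#' @return a [functional_likelihood_matrix()] (query genes x retained sets)
#' @export
functional_likelihood <- function(coreg, sets, query_genes,
                                  min_set_size = 5, max_set_fraction = 0.5) {
  stopifnot(inherits(coreg, "CoRegulationMatrix"))
  universe <- rownames(coreg)
  query_genes <- as.character(query_genes)
  if (!all(query_genes %in% universe))
    stop("query genes absent from co-regulation universe: ",
         paste(utils::head(setdiff(query_genes, universe), 5), collapse = ", "))
  sets <- filter_gene_sets(sets, universe, min_set_size, max_set_fraction)
  ind <- matrix(0, length(universe), length(sets),
                dimnames = list(universe, names(sets)))
  for (j in seq_along(sets)) ind[sets[[j]], j] <- 1
  cm <- unclass(coreg)
  fl <- matrix(NA_real_, length(query_genes), length(sets),
               dimnames = list(query_genes, names(sets)))
  degenerate <- character(0)
  for (g in query_genes) {
    gi <- match(g, universe)
    x <- cm[gi, -gi]
    if (length(unique(x)) < 2L) {
      fl[g, ] <- 0
      degenerate <- c(degenerate, g)
      next
    }
    rx <- rank(x, ties.method = "average")
    zg <- ind[-gi, , drop = FALSE]
    # constant indicator columns (cannot happen after the size filters unless
    # the universe is tiny) would yield NA; guard anyway
    v <- suppressWarnings(stats::cor(rx, zg))[1L, ]
    v[is.na(v)] <- 0
    fl[g, ] <- v
  }
  if (length(degenerate))
    message(length(degenerate),
            " query gene(s) with constant co-regulation profile set to zero likelihood")
  out <- functional_likelihood_matrix(fl)
  attr(out, "degenerate") <- degenerate
  out
}

#' Resolve the co-functionality correlation flavor
#'
#' The correlation applied between functional-likelihood vectors. Likelihood
#' vectors are already comparable-scale coefficients, so the default is
#' Pearson; Spearman is available as a switch. Anything else is an error.
#'
#' @param flavor character, `"pearson"` or `"spearman"`
#' @return the validated flavor string
#' @export
cofunctionality_correlation_flavor <- function(flavor = "pearson") {
  if (!is.character(flavor) || length(flavor) != 1L ||
      !flavor %in% c("pearson", "spearman"))
    stop("unknown co-functionality correlation flavor: ",
         paste(flavor, collapse = ", "), " (use 'pearson' or 'spearman')")
  flavor
}

#' Co-functionality correlation matrix
#'
#' Correlates every pair of functional-likelihood vectors; a high value means
#' two genes have similar predicted biological functions. Genes with a
#' constant likelihood vector get weight 0 against every partner and are
#' flagged.
#'
#' @param fl a [functional_likelihood_matrix()]
#' @param flavor correlation flavor, see
#'   [cofunctionality_correlation_flavor()]
#' @return symmetric weight matrix with unit diagonal and attribute
#'   `flavor`
#' @export
cofunctionality_matrix <- function(fl, flavor = "pearson") {
  flavor <- cofunctionality_correlation_flavor(flavor)
  x <- unclass(fl)
  if (ncol(x) < 3L) stop("co-functionality needs >= 3 retained gene sets")
  if (flavor == "spearman") x <- rank_rows(x)
  w <- row_cor_matrix(x)
  if (length(attr(w, "degenerate")))
    message(length(attr(w, "degenerate")),
            " gene(s) with constant likelihood vector set to zero co-functionality")
  attr(w, "flavor") <- flavor
  w
}

#' Threshold a co-functionality weight matrix into a network
#'
#' Edges are gene pairs whose weight strictly exceeds `tau` (default 0.5).
#' At the boundary `tau = 1`, where strict exceedance is impossible, edges
#' are pairs with weight equal to 1 within 1e-12, i.e. genes with identical
#' likelihood vectors.
#'
#' @param weights symmetric numeric weight matrix with gene IDs as dimnames
#' @param tau threshold in (-1, 1]
#' @return a `CoFunctionalityNetwork`: list with `gene_ids`, `weights`,
#'   `tau` and an `edges` data.frame (`gene_a`, `gene_b`, `weight`)
#' @export
threshold_network <- function(weights, tau = 0.5) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= -1 || tau > 1)
    stop("tau must lie in (-1, 1], got ", tau)
  weights <- as.matrix(weights)
  if (max(abs(weights - t(weights))) > 1e-12) stop("weight matrix not symmetric")
  genes <- rownames(weights)
  up <- which(upper.tri(weights) &
                (if (tau == 1) weights >= 1 - 1e-12 else weights > tau),
              arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[up[, 1L]], gene_b = genes[up[, 2L]],
                      weight = weights[up], stringsAsFactors = FALSE)
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(gene_ids = genes, weights = weights, tau = tau,
                 edges = edges),
            class = "CoFunctionalityNetwork")
}

#' @export
print.CoFunctionalityNetwork <- function(x, ...) {
  cat(sprintf("CoFunctionalityNetwork: %d genes, %d edges (tau = %g)\n",
              length(x$gene_ids), nrow(x$edges), x$tau))
  invisible(x)
}

#' Extract gene clusters from a thresholded network
#'
#' Clusters are the connected components of the network with at least
#' `min_cluster_size` members (singletons excluded by default). Components
#' are returned sorted by size descending; within a size tie by mean
#' intra-cluster weight descending, then by lexicographically smallest
#' member. The mean intra-cluster weight averages the weight matrix over all
#' unordered member pairs.
#'
#' @param net a `CoFunctionalityNetwork` from [threshold_network()]
#' @param min_cluster_size minimum component size to report (default 2)
#' @return list of clusters, each a list with `members` (sorted gene IDs),
#'   `size` and `mean_weight`
#' @export
extract_clusters <- function(net, min_cluster_size = 2) {
  stopifnot(inherits(net, "CoFunctionalityNetwork"))
  e <- net$edges
  if (!nrow(e)) return(list())
  genes <- sort(unique(c(e$gene_a, e$gene_b)))
  comp <- stats::setNames(seq_along(genes), genes)
  # union-find with path compression
  find <- function(i) {
    while (comp[[i]] != i) {
      comp[[i]] <<- comp[[comp[[i]]]]
      i <- comp[[i]]
    }
    i
  }
  ia <- match(e$gene_a, genes)
  ib <- match(e$gene_b, genes)
  for (k in seq_len(nrow(e))) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) comp[[rb]] <- ra
  }
  roots <- vapply(seq_along(genes), find, integer(1))
  groups <- split(genes, roots)
  groups <- groups[lengths(groups) >= min_cluster_size]
  clusters <- lapply(groups, function(m) {
    m <- sort(m)
    w <- net$weights[m, m, drop = FALSE]
    list(members = m, size = length(m),
         mean_weight = mean(w[upper.tri(w)]))
  })
  sizes <- vapply(clusters, `[[`, numeric(1), "size")
  mw <- vapply(clusters, `[[`, numeric(1), "mean_weight")
  first <- vapply(clusters, function(cl) cl$members[1L], character(1))
  ord <- order(-sizes, -mw, first, method = "radix")
  unname(clusters[ord])
}
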