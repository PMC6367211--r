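# Domain types. All are thin S3 wrappers over base structures (matrices,
# data.frames, named vectors) with validators enforcing the pipeline's
# invariants at construction time; downstream code can therefore assume a
# validated object.

#' Construct an ExpressionMatrix
#'
#' Genes-by-samples matrix of real-valued (residual) expression. Row names are
#' gene identifiers, column names sample identifiers. Invariants: unique gene
#' and sample IDs, no missing values, at least 3 samples (rank correlations
#' are undefined below that).
#'
#' @param values numeric matrix, genes in rows, samples in columns
#' @param gene_ids,sample_ids optional identifier vectors overriding dimnames
#' @return a validated `ExpressionMatrix` (a classed numeric matrix)
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("expression matrix needs gene and sample identifiers")
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  validate_expression_matrix(structure(values,
                                       class = c("ExpressionMatrix", "matrix", "array")))
}

validate_expression_matrix <- function(x) {
  if (anyDuplicated(rownames(x))) stop("duplicate gene IDs in expression matrix")
  if (anyDuplicated(colnames(x))) stop("duplicate sample IDs in expression matrix")
  if (anyNA(x)) stop("expression matrix contains missing values after load")
  if (ncol(x) < 3L) stop("expression matrix needs >= 3 samples, got ", ncol(x))
  x
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Construct per-sample genomic instability scores
#'
#' A named numeric vector: one unitless instability (SCNA burden) score per
#' sample. Scores must not all be equal.
#'
#' @param score numeric vector
#' @param sample_ids sample identifiers (defaults to `names(score)`)
#' @return a validated `InstabilityScores` object
#' @export
instability_scores <- function(score, sample_ids = names(score)) {
  score <- as.numeric(score)
  if (is.null(sample_ids)) stop("instability scores need sample identifiers")
  names(score) <- as.character(sample_ids)
  if (anyDuplicated(names(score))) stop("duplicate sample IDs in instability scores")
  if (anyNA(score)) stop("missing instability scores")
  if (length(unique(score)) < 2L) stop("instability scores are all equal")
  structure(score, class = "InstabilityScores")
}

#' @export
print.InstabilityScores <- function(x, ...) {
  cat(sprintf("InstabilityScores: %d samples, range [%g, %g]\n",
              length(x), min(x), max(x)))
  invisible(x)
}

#' Construct a GeneSetCollection
#'
#' A named list of character vectors (member gene IDs per set) with a
#' parallel `description` attribute. Set names are unique, each set non-empty,
#' members deduplicated.
#'
#' @param members named list of character vectors
#' @param description character vector of free-text descriptions, one per set
#' @return a validated `GeneSetCollection`
#' @export
gene_set_collection <- function(members, description = rep("", length(members))) {
  if (is.null(names(members)) || anyDuplicated(names(members)))
    stop("gene set names must be present and unique")
  members <- lapply(members, function(m) unique(as.character(m)))
  if (any(lengths(members) == 0L)) stop("empty gene set")
  structure(members, description = as.character(description),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Filter a gene-set collection against a measured-gene universe
#'
#' Members are intersected with `universe`; sets smaller than `min_set_size`
#' or covering at least `max_set_fraction` of the universe are dropped (a
#' near-universal set has an (almost) constant membership indicator and
#' carries no guilt-by-association signal). Drops are reported via `message`.
#'
#' @param sets a `GeneSetCollection`
#' @param universe character vector of measured gene IDs
#' @param min_set_size minimum post-intersection size (default 5)
#' @param max_set_fraction maximum fraction of the universe a set may cover
#'   (default 0.5)
#' @return filtered `GeneSetCollection`
#' @export
filter_gene_sets <- function(sets, universe, min_set_size = 5,
                             max_set_fraction = 0.5) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  universe <- as.character(universe)
  inter <- lapply(unclass(sets), intersect, universe)
  sz <- lengths(inter)
  keep <- sz >= min_set_size & sz < max_set_fraction * length(universe)
  if (any(!keep))
    message(sum(!keep), " gene set(s) dropped by size filters (min_set_size=",
            min_set_size, ", max_set_fraction=", max_set_fraction, "): ",
            paste(utils::head(names(sets)[!keep], 5), collapse = ", "),
            if (sum(!keep) > 5) ", ...")
  if (!any(keep)) stop("no gene sets survive the size filters")
  gene_set_collection(inter[keep], attr(sets, "description")[keep])
}

#' Construct a CNProfileSet
#'
#' Integer copy-number states for a set of single cells over a common bin
#' grid. Bins are 0-based half-open `(chromosome, start, end)` triples,
#' non-overlapping and sorted within chromosome; the grid is identical across
#' cells and every chromosome has at least 2 bins.
#'
#' @param states integer matrix, cells in rows (row names = cell IDs), bins in
#'   columns
#' @param bins data.frame with columns `chrom`, `start`, `end`
#' @param condition character vector of condition labels, one per cell
#' @return a validated `CNProfileSet`
#' @export
cn_profile_set <- function(states, bins, condition) {
  states <- as.matrix(states)
  if (is.null(rownames(states))) stop("states matrix needs cell IDs as row names")
  if (anyDuplicated(rownames(states))) stop("duplicate cell IDs")
  if (anyNA(states)) stop("missing copy-number states")
  if (any(states != round(states))) stop("copy-number states must be integers")
  if (any(states < 0)) stop("negative copy-number state")
  storage.mode(states) <- "integer"
  bins <- data.frame(chrom = as.character(bins$chrom),
                     start = as.integer(bins$start),
                     end = as.integer(bins$end))
  if (nrow(bins) != ncol(states)) stop("bin count does not match state columns")
  validate_bins(bins)
  obj <- structure(list(states = states, bins = bins,
                        condition = stats::setNames(as.character(condition),
                                                    rownames(states))),
                   class = "CNProfileSet")
  obj
}

validate_bins <- function(bins) {
  if (any(bins$end <= bins$start)) stop("bin with end <= start")
  for (chr in unique(bins$chrom)) {
    b <- bins[bins$chrom == chr, ]
    if (nrow(b) < 2L) stop("chromosome ", chr, " has fewer than 2 bins")
    if (is.unsorted(b$start, strictly = TRUE)) stop("bins not sorted on ", chr)
    if (any(b$start[-1] < b$end[-nrow(b)])) stop("overlapping bins on ", chr)
  }
  invisible(bins)
}

#' @export
print.CNProfileSet <- function(x, ...) {
  cat(sprintf("CNProfileSet: %d cells x %d bins (%d chromosomes); conditions: %s\n",
              nrow(x$states), nrow(x$bins), length(unique(x$bins$chrom)),
              paste(sprintf("%s(%d)", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Construct a CoRegulationMatrix
#'
#' Symmetric gene-by-gene matrix of pairwise co-regulation coefficients in
#' [-1, 1] with unit diagonal. Small asymmetries (floating point) are
#' symmetrized; anything beyond 1e-12 is an error.
#'
#' @param values square numeric matrix with gene IDs as dimnames
#' @return a validated `CoRegulationMatrix`
#' @export
coregulation_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("co-regulation matrix must be square")
  if (is.null(rownames(values))) stop("co-regulation matrix needs gene IDs")
  if (anyDuplicated(rownames(values))) stop("duplicate gene IDs")
  colnames(values) <- rownames(values)
  if (max(abs(values - t(values))) > 1e-12) stop("co-regulation matrix not symmetric")
  values <- (values + t(values)) / 2
  if (any(values > 1 + 1e-12) || any(values < -1 - 1e-12))
    stop("co-regulation coefficients outside [-1, 1]")
  values[values > 1] <- 1
  values[values < -1] <- -1
  diag(values) <- 1
  structure(values, class = c("CoRegulationMatrix", "matrix", "array"))
}

#' @export
print.CoRegulationMatrix <- function(x, ...) {
  cat(sprintf("CoRegulationMatrix: %d genes\n", nrow(x)))
  invisible(x)
}

#' Construct a FunctionalLikelihoodMatrix
#'
#' One row per query gene, one column per retained gene set; entries are
#' rank-correlation coefficients in [-1, 1] describing how strongly the
#' gene's co-regulation profile tracks membership of the set.
#'
#' @param values numeric matrix, query genes x sets, with dimnames
#' @return a validated `FunctionalLikelihoodMatrix`
#' @export
functional_likelihood_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("functional likelihood matrix needs gene and set names")
  if (any(abs(values) > 1 + 1e-12)) stop("likelihood coefficients outside [-1, 1]")
  values[values > 1] <- 1
  values[values < -1] <- -1
  structure(values, class = c("FunctionalLikelihoodMatrix", "matrix", "array"))
}

#' @export
print.FunctionalLikelihoodMatrix <- function(x, ...) {
  cat(sprintf("FunctionalLikelihoodMatrix: %d genes x %d sets\n",
              nrow(x), ncol(x)))
  invisible(x)
}
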