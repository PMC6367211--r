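# Readers and writers for every on-disk artifact the pipeline touches.
# All files are UTF-8, tab-delimited, '.' decimal; writers emit a '#' header
# line recording tool version and parameters. Coordinates are 0-based
# half-open (BED convention) everywhere; AneuFinder-style 1-based input is
# handled by `one_based = TRUE` in `read_cn_calls()`.

read_tsv_raw <- function(path, header = TRUE) {
  utils::read.delim(path, header = header, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample IDs and a first column of gene IDs (or the
#' transpose, with `orientation = "samples_by_genes"`). Duplicate gene IDs
#' collapse to the row with the highest variance (with a warning); rows with
#' any missing value are dropped (reported via `message`) -- imputation would
#' contaminate downstream rank correlations. Gene-ID matching everywhere in
#' the package is exact-string and case-sensitive.
#'
#' @param path TSV file path
#' @param orientation `"genes_by_samples"` (default) or `"samples_by_genes"`
#' @return an [expression_matrix()]
#' @export
read_expression_tsv <- function(path,
                                orientation = c("genes_by_samples",
                                                "samples_by_genes")) {
  orientation <- match.arg(orientation)
  raw <- read_tsv_raw(path)
  if (ncol(raw) < 2L) stop("expression TSV needs an ID column plus data columns")
  ids <- as.character(raw[[1L]])
  dat <- raw[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow(dat), ncol(dat),
                 dimnames = list(ids, colnames(dat)))
  missing_tokens <- c("", "NA", "NaN", "nan", "na")
  for (j in seq_len(ncol(dat))) {
    cell <- dat[[j]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- is.na(num) & !(trimws(cell) %in% missing_tokens)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("unparseable numeric value '%s' at row %d (id '%s'), column '%s' in %s",
                   cell[i], i, ids[i], colnames(dat)[j], path))
    }
    vals[, j] <- num
  }
  if (orientation == "samples_by_genes") vals <- t(vals)
  # duplicate gene IDs: keep the highest-variance row
  g <- rownames(vals)
  if (anyDuplicated(g)) {
    v <- apply(vals, 1L, stats::var, na.rm = TRUE)
    v[is.na(v)] <- -Inf
    keep <- rep(TRUE, nrow(vals))
    for (dup in unique(g[duplicated(g)])) {
      idx <- which(g == dup)
      keep[setdiff(idx, idx[which.max(v[idx])])] <- FALSE
    }
    warning(sum(!keep), " duplicate gene row(s) collapsed to highest-variance row: ",
            paste(unique(g[duplicated(g)]), collapse = ", "))
    vals <- vals[keep, , drop = FALSE]
  }
  has_na <- rowSums(is.na(vals)) > 0L
  if (any(has_na)) {
    message(sum(has_na), " gene row(s) with missing values dropped: ",
            paste(utils::head(rownames(vals)[has_na], 5), collapse = ", "),
            if (sum(has_na) > 5) ", ...")
    vals <- vals[!has_na, , drop = FALSE]
  }
  if (ncol(vals) < 3L) stop("fewer than 3 samples in ", path)
  expression_matrix(vals)
}

#' Write an expression matrix to TSV
#' @param expr an [expression_matrix()]
#' @param path output path
#' @export
write_expression_tsv <- function(expr, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(list(artifact = "expression")), con)
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(expr)), function(i)
    paste(c(rownames(expr)[i], num_fmt(expr[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read per-sample instability scores from TSV
#'
#' Two tab-separated columns with a header: sample ID and numeric score.
#'
#' @param path TSV file path
#' @return an [instability_scores()] vector
#' @export
read_instability_tsv <- function(path) {
  raw <- read_tsv_raw(path)
  if (ncol(raw) < 2L) stop("instability TSV needs sample_id and score columns")
  sc <- suppressWarnings(as.numeric(raw[[2L]]))
  if (anyNA(sc)) {
    i <- which(is.na(sc))[1L]
    stop(sprintf("unparseable score '%s' at row %d in %s", raw[[2L]][i], i, path))
  }
  instability_scores(sc, raw[[1L]])
}

#' Write instability scores to TSV
#' @param inst an [instability_scores()] vector
#' @param path output path
#' @export
write_instability_tsv <- function(inst, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(list(artifact = "instability_scores")), con)
  writeLines("sample_id\tscore", con)
  writeLines(paste(names(inst), num_fmt(as.numeric(inst)), sep = "\t"), con)
  invisible(path)
}

#' Read a gene-set database in GMT format
#'
#' GMT: one set per line, `name TAB description TAB member TAB member ...`.
#' Duplicate members within a set are deduplicated; duplicate set names are
#' an error.
#'
#' @param path GMT file path
#' @return a [gene_set_collection()]
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("GMT line %d has %d field(s); need >= 3 (name, description, members)",
                 lineno[which(nf < 3L)[1L]], nf[nf < 3L][1L]))
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(members) <- nm
  gene_set_collection(members, desc)
}

#' Write a gene-set collection in GMT format
#' @param sets a [gene_set_collection()]
#' @param path output path
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"), character(1))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read single-cell copy-number state calls
#'
#' BED-like TSV, no header: chromosome, start, end, cell_id, condition,
#' integer copy-number state. Coordinates are 0-based half-open; AneuFinder
#' exports 1-based starts, so pass `one_based = TRUE` for such files (starts
#' are shifted by -1). The bin grid must be identical across cells.
#'
#' @param path TSV file path
#' @param one_based set `TRUE` if starts are 1-based (shifted by -1 on load)
#' @return a [cn_profile_set()]
#' @export
read_cn_calls <- function(path, one_based = FALSE) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "#", colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 6L) stop("CN calls TSV needs 6 columns: chrom start end cell_id condition state")
  names(raw)[1:6] <- c("chrom", "start", "end", "cell_id", "condition", "state")
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  if (anyNA(start) || anyNA(end)) stop("unparseable coordinate in ", path)
  state <- suppressWarnings(as.numeric(raw$state))
  if (anyNA(state) || any(state != round(state))) {
    i <- which(is.na(state) | state != round(state))[1L]
    stop(sprintf("non-integer copy-number state '%s' at data row %d in %s",
                 raw$state[i], i, path))
  }
  if (one_based) start <- start - 1
  key <- paste(raw$chrom, start, end, sep = ":")
  cells <- unique(raw$cell_id)
  ref_keys <- key[raw$cell_id == cells[1L]]
  if (anyDuplicated(ref_keys)) stop("duplicate bins for cell ", cells[1L])
  for (cl in cells[-1L]) {
    k <- key[raw$cell_id == cl]
    if (length(k) != length(ref_keys) || !setequal(k, ref_keys))
      stop("cells have differing bin grids (cell ", cl, " vs ", cells[1L], ")")
  }
  # canonical bin order: chromosomes in file order of first appearance,
  # starts ascending within chromosome
  first <- raw[raw$cell_id == cells[1L], ]
  first$start <- start[raw$cell_id == cells[1L]]
  first$end <- end[raw$cell_id == cells[1L]]
  chrom_order <- unique(first$chrom)
  ord <- order(match(first$chrom, chrom_order), first$start)
  bins <- data.frame(chrom = first$chrom[ord], start = first$start[ord],
                     end = first$end[ord])
  bin_key <- paste(bins$chrom, bins$start, bins$end, sep = ":")
  states <- matrix(NA_integer_, length(cells), nrow(bins),
                   dimnames = list(cells, NULL))
  cond <- character(length(cells))
  for (i in seq_along(cells)) {
    sel <- raw$cell_id == cells[i]
    states[i, match(key[sel], bin_key)] <- as.integer(state[sel])
    cl_cond <- unique(raw$condition[sel])
    if (length(cl_cond) != 1L)
      stop("cell ", cells[i], " carries multiple condition labels")
    cond[i] <- cl_cond
  }
  cn_profile_set(states, bins, cond)
}

#' Write single-cell copy-number state calls
#' @param profiles a [cn_profile_set()]
#' @param path output path
#' @export
write_cn_calls <- function(profiles, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(list(artifact = "cn_calls", coordinates = "0-based half-open")), con)
  b <- profiles$bins
  for (i in seq_len(nrow(profiles$states))) {
    cell <- rownames(profiles$states)[i]
    writeLines(paste(b$chrom, b$start, b$end, cell,
                     profiles$condition[[cell]], profiles$states[i, ],
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write a co-functionality network as an edge list
#'
#' TSV columns `gene_a`, `gene_b`, `weight` (full precision), one row per
#' edge above the network's threshold, in deterministic lexicographic order.
#'
#' @param net a `CoFunctionalityNetwork` from [threshold_network()]
#' @param path output path
#' @export
write_network_edgelist <- function(net, path) {
  stopifnot(inherits(net, "CoFunctionalityNetwork"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(list(artifact = "cofunctionality_network",
                                tau = net$tau)), con)
  writeLines("gene_a\tgene_b\tweight", con)
  e <- net$edges
  if (nrow(e)) {
    ord <- order(e$gene_a, e$gene_b, method = "radix")
    writeLines(paste(e$gene_a[ord], e$gene_b[ord], num_fmt(e$weight[ord]),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a network edge list written by [write_network_edgelist()]
#' @param path edge-list TSV path
#' @return data.frame with columns `gene_a`, `gene_b`, `weight`
#' @export
read_network_edgelist <- function(path) {
  raw <- read_tsv_raw(path)
  if (!nrow(raw))
    return(data.frame(gene_a = character(), gene_b = character(),
                      weight = numeric()))
  data.frame(gene_a = raw$gene_a, gene_b = raw$gene_b,
             weight = as.numeric(raw$weight))
}

#' Write an association table to TSV
#' @param tab an `AssociationTable` from [associate()]
#' @param path output path
#' @param params named list echoed into the header
#' @export
write_association_tsv <- function(tab, path, params = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(c(list(artifact = "association"), params)), con)
  writeLines("gene_id\trho\tz\trank\tdegenerate", con)
  writeLines(paste(tab$gene_id, num_fmt(tab$rho), num_fmt(tab$z), tab$rank,
                   as.integer(tab$degenerate), sep = "\t"), con)
  invisible(path)
}

#' Write aberration counts to TSV
#' @param counts an `AberrationCounts` data.frame from [count_aberrations()]
#' @param path output path
#' @param params named list echoed into the header
#' @export
write_counts_tsv <- function(counts, path, params = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(c(list(artifact = "aberration_counts"), params)), con)
  writeLines("cell_id\tcondition\tn_focal\tn_whole_chromosome", con)
  writeLines(paste(counts$cell_id, counts$condition, counts$n_focal,
                   counts$n_whole_chromosome, sep = "\t"), con)
  invisible(path)
}

#' Write extracted clusters to TSV
#' @param clusters list of clusters from [extract_clusters()]
#' @param path output path
#' @param params named list echoed into the header
#' @export
write_clusters_tsv <- function(clusters, path, params = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(output_header(c(list(artifact = "clusters"), params)), con)
  writeLines("cluster_rank\tsize\tmean_weight\tmembers", con)
  if (length(clusters))
    writeLines(vapply(seq_along(clusters), function(i)
      paste(i, clusters[[i]]$size, num_fmt(clusters[[i]]$mean_weight),
            paste(clusters[[i]]$members, collapse = ","), sep = "\t"),
      character(1)), con)
  invisible(path)
}
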