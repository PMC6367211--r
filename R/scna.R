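# Per-cell classification and counting of focal vs whole-chromosome
# copy-number deviations from the modal state of a control cell population,
# with rank-based comparison of counts across conditions.

#' Modal copy-number profile of a control population
#'
#' Per bin, the most frequent state across control cells. Ties break toward
#' the state nearest the genome-wide control median, then toward the lower
#' state; tie decisions are reported via `message`.
#'
#' @param profiles a [cn_profile_set()]
#' @param control_condition condition label of the control cells
#' @return a `ModalProfile`: list with `bins` and integer `modal_state`
#' @export
modal_profile <- function(profiles, control_condition = "control") {
  stopifnot(inherits(profiles, "CNProfileSet"))
  sel <- profiles$condition == control_condition
  if (!any(sel)) stop("no cells carry control condition '", control_condition, "'")
  if (sum(sel) < 3L)
    stop("need >= 3 control cells, got ", sum(sel))
  ctrl <- profiles$states[sel, , drop = FALSE]
  gw_median <- stats::median(as.numeric(ctrl))
  modal <- integer(ncol(ctrl))
  n_ties <- 0L
  for (j in seq_len(ncol(ctrl))) {
    tab <- table(ctrl[, j])
    cand <- as.integer(names(tab)[tab == max(tab)])
    if (length(cand) > 1L) {
      n_ties <- n_ties + 1L
      cand <- cand[order(abs(cand - gw_median), cand)]
    }
    modal[j] <- cand[1L]
  }
  if (n_ties > 0L)
    message(n_ties, " bin(s) with tied modal state resolved toward the ",
            "genome-wide control median (", gw_median, "), then the lower state")
  structure(list(bins = profiles$bins, modal_state = modal,
                 control_condition = control_condition),
            class = "ModalProfile")
}

#' @export
print.ModalProfile <- function(x, ...) {
  cat(sprintf("ModalProfile: %d bins, states %d-%d (control: %s)\n",
              length(x$modal_state), min(x$modal_state), max(x$modal_state),
              x$control_condition))
  invisible(x)
}

#' Classify one cell's deviations from the modal profile
#'
#' Within each chromosome, maximal runs of contiguous bins whose state
#' differs from the modal state are events; a run is split at any change of
#' deviation direction (gain vs loss), so every event has a uniform sign. An
#' event covering at least `whole_chrom_fraction` of the chromosome's bins
#' is one whole-chromosome event; every other event is one focal event.
#' Deviation magnitude is ignored (a state-4 bin and a state-3 bin against
#' modal 2 both count once).
#'
#' @param cell_states integer state vector over the modal profile's bins
#' @param modal a `ModalProfile`
#' @param whole_chrom_fraction fraction of a chromosome's bins an event must
#'   cover to count as whole-chromosome (default 0.9, tolerating edge-bin
#'   miscalls while excluding arm-level events)
#' @return data.frame with one row per event: `chrom`, `start_bin`,
#'   `end_bin` (1-based bin indices within the chromosome), `n_bins`,
#'   `direction` (+1 gain / -1 loss) and `type` (`"focal"` or
#'   `"whole_chromosome"`)
#' @export
classify_deviations <- function(cell_states, modal, whole_chrom_fraction = 0.9) {
  stopifnot(inherits(modal, "ModalProfile"))
  if (length(cell_states) != length(modal$modal_state))
    stop("cell states do not match the modal profile's bin grid")
  dev_sign <- sign(as.integer(cell_states) - modal$modal_state)
  chroms <- modal$bins$chrom
  out <- list()
  for (chr in unique(chroms)) {
    idx <- which(chroms == chr)
    s <- dev_sign[idx]
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ev <- which(r$values != 0)
    if (!length(ev)) next
    n_chr <- length(idx)
    len <- r$lengths[ev]
    whole <- len >= whole_chrom_fraction * n_chr - 1e-9
    out[[chr]] <- data.frame(
      chrom = chr, start_bin = starts[ev], end_bin = ends[ev], n_bins = len,
      direction = r$values[ev],
      type = ifelse(whole, "whole_chromosome", "focal"),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_bin = integer(),
                      end_bin = integer(), n_bins = integer(),
                      direction = integer(), type = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count focal and whole-chromosome aberrations per cell
#'
#' Sums event classes from [classify_deviations()] over chromosomes for
#' every cell of a profile set.
#'
#' @param profiles a [cn_profile_set()]
#' @param modal a `ModalProfile` on the same bin grid
#' @param whole_chrom_fraction see [classify_deviations()]
#' @return an `AberrationCounts` data.frame: `cell_id`, `condition`,
#'   `n_focal`, `n_whole_chromosome`
#' @export
count_aberrations <- function(profiles, modal, whole_chrom_fraction = 0.9) {
  stopifnot(inherits(profiles, "CNProfileSet"))
  if (!identical(dim(profiles$states)[2L], length(modal$modal_state)))
    stop("profile set and modal profile bin grids differ")
  cells <- rownames(profiles$states)
  n_focal <- integer(length(cells))
  n_whole <- integer(length(cells))
  # lean counting path: same run rule as classify_deviations() without
  # materializing per-event records (the conservation test pins equality)
  chrom_blocks <- split(seq_len(nrow(modal$bins)), modal$bins$chrom)
  dev <- sweep(profiles$states, 2L, modal$modal_state)
  for (i in seq_along(cells)) {
    s <- sign(dev[i, ])
    nf <- 0L; nw <- 0L
    for (b in chrom_blocks) {
      r <- rle(s[b])
      ev <- r$values != 0
      if (!any(ev)) next
      whole <- ev & (r$lengths >= whole_chrom_fraction * length(b) - 1e-9)
      nw <- nw + sum(whole)
      nf <- nf + sum(ev & !whole)
    }
    n_focal[i] <- nf
    n_whole[i] <- nw
  }
  out <- data.frame(cell_id = cells,
                    condition = unname(profiles$condition[cells]),
                    n_focal = n_focal, n_whole_chromosome = n_whole,
                    stringsAsFactors = FALSE)
  class(out) <- c("AberrationCounts", "data.frame")
  out
}

#' Compare aberration counts across conditions
#'
#' Omnibus Kruskal-Wallis rank test across conditions on the chosen metric,
#' followed by pairwise Dunn z-tests with multiple-comparison adjustment
#' (Bonferroni by default, matching common post-test practice; any
#' [stats::p.adjust()] method is accepted). Conditions with fewer than 3
#' cells are excluded with a warning. Per-condition medians and interquartile
#' ranges are reported alongside.
#'
#' @param counts an `AberrationCounts` data.frame from [count_aberrations()]
#' @param metric `"focal"`, `"whole_chromosome"` or `"total"`
#' @param adjust p-value adjustment method for the Dunn tests
#' @return a `GroupComparison`: list with `metric`, `summary` (condition,
#'   n, median, q1, q3), `statistic`, `df`, `p_value` and `pairwise`
#'   (group1, group2, z, p_raw, p_adj)
#' @export
compare_groups <- function(counts, metric = c("focal", "whole_chromosome",
                                              "total"),
                           adjust = "bonferroni") {
  metric <- match.arg(metric)
  y <- switch(metric,
              focal = counts$n_focal,
              whole_chromosome = counts$n_whole_chromosome,
              total = counts$n_focal + counts$n_whole_chromosome)
  g <- counts$condition
  sizes <- table(g)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning("condition(s) with < 3 cells excluded: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    y <- y[keep]; g <- g[keep]
  }
  if (length(unique(g)) < 2L)
    stop("need >= 2 conditions with >= 3 cells each")
  g <- factor(g)
  summ <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- y[g == lv]
    data.frame(condition = lv, n = length(v), median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  }))
  if (length(unique(y)) < 2L) {
    # all observations identical: no evidence against the null by construction
    stat <- 0; df <- nlevels(g) - 1L; p <- 1
  } else {
    kw <- stats::kruskal.test(y, g)
    stat <- unname(kw$statistic); df <- unname(kw$parameter); p <- kw$p.value
  }
  # Dunn pairwise z on the joint ranks with tie correction
  N <- length(y)
  r <- rank(y, ties.method = "average")
  tie_tab <- table(y)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  sigma2_base <- N * (N + 1) / 12 - tie_corr
  lv <- levels(g)
  pairs <- utils::combn(lv, 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    na <- sum(g == a); nb <- sum(g == b)
    se <- sqrt(sigma2_base * (1 / na + 1 / nb))
    z <- if (se > 0) (mean(r[g == a]) - mean(r[g == b])) / se else 0
    data.frame(group1 = a, group2 = b, z = z,
               p_raw = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = adjust)
  structure(list(metric = metric, summary = summ, statistic = stat, df = df,
                 p_value = p, pairwise = pw, adjust = adjust),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("GroupComparison on '%s': Kruskal-Wallis chi-sq = %.4g (df = %d), p = %.4g\n",
              x$metric, x$statistic, x$df, x$p_value))
  print(x$summary, row.names = FALSE)
  cat(sprintf("Pairwise Dunn tests (%s-adjusted):\n", x$adjust))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
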