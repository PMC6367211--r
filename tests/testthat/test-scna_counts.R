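# Modal profile, deviation classification, per-cell counting and group
# comparison.

test_that("modal_profile takes the per-bin mode with the stated tie rule", {
  cells <- list(c1 = rep(2L, 20), c2 = rep(2L, 20), c3 = rep(2L, 20),
                c4 = rep(2L, 20), c5 = rep(2L, 20))
  cells$c4[3] <- 3L; cells$c5[3] <- 3L              # (2,2,2,3,3) -> 2
  cn <- toy_cn(cells, rep("control", 5), n_chrom = 2, nb = 10)
  modal <- modal_profile(cn, "control")
  expect_equal(modal$modal_state, rep(2L, 20))
  # 4-cell tie (2,2,3,3): genome-wide median 2 -> resolves to 2
  tie <- list(a = rep(2L, 10), b = rep(2L, 10), c = rep(2L, 10),
              d = rep(2L, 10))
  tie$c[5] <- 3L; tie$d[5] <- 3L; tie$a[5] <- 2L; tie$b[5] <- 2L
  tie$c[6] <- 3L; tie$d[6] <- 3L
  cn2 <- toy_cn(tie, rep("control", 4), n_chrom = 1, nb = 10)
  expect_message(modal2 <- modal_profile(cn2, "control"), "tied")
  expect_equal(modal2$modal_state[5], 2L)
  expect_error(modal_profile(cn2, "treated"), "no cells")
})

test_that("tie resolution follows nearest-to-median-then-lower, exhaustively", {
  # enumerate candidate tie sets against a direct implementation of the rule
  rule <- function(cand, med) cand[order(abs(cand - med), cand)][1]
  for (med_states in list(rep(3L, 10), rep(2L, 10))) {
    for (pair in list(c(1L, 3L), c(2L, 4L), c(0L, 4L), c(3L, 4L))) {
      base <- med_states
      cells <- list(a = base, b = base, c = base, d = base)
      cells$a[2] <- pair[1]; cells$b[2] <- pair[1]
      cells$c[2] <- pair[2]; cells$d[2] <- pair[2]
      cn <- toy_cn(cells, rep("control", 4), n_chrom = 1, nb = 10)
      gw_med <- median(vapply(cells, as.numeric, numeric(10)))
      expect_equal(suppressMessages(modal_profile(cn, "control"))$modal_state[2],
                   rule(pair, gw_med),
                   info = paste("pair", paste(pair, collapse = ","),
                                "median", gw_med))
    }
  }
})

test_that("classify_deviations separates focal from whole-chromosome runs", {
  bins20 <- data.frame(chrom = "chr1", start = (0:19) * 1000,
                       end = (1:20) * 1000)
  modal <- structure(list(bins = bins20, modal_state = rep(2L, 20),
                          control_condition = "control"),
                     class = "ModalProfile")
  expect_equal(nrow(classify_deviations(rep(2L, 20), modal)), 0L)
  one_bin <- rep(2L, 20); one_bin[7] <- 3L
  ev <- classify_deviations(one_bin, modal)
  expect_equal(ev$type, "focal")
  expect_equal(ev$n_bins, 1L)
  # full chromosome gained -> one whole-chromosome event
  ev_full <- classify_deviations(rep(3L, 20), modal)
  expect_equal(ev_full$type, "whole_chromosome")
  # 18/20 bins = fraction 0.9 exactly -> whole-chromosome under the >= rule
  v18 <- c(2L, 2L, rep(3L, 18))
  expect_equal(classify_deviations(v18, modal)$type, "whole_chromosome")
  # 17/20 falls short
  v17 <- c(2L, 2L, 2L, rep(3L, 17))
  expect_equal(classify_deviations(v17, modal)$type, "focal")
  # a run mixing gain and loss splits at the sign change into two events
  mixed <- rep(2L, 20); mixed[5:8] <- 3L; mixed[9:11] <- 1L
  ev_m <- classify_deviations(mixed, modal)
  expect_equal(nrow(ev_m), 2L)
  expect_equal(ev_m$direction, c(1, -1))
  expect_equal(ev_m$type, c("focal", "focal"))
})

test_that("count_aberrations sums event classes per cell", {
  nb <- 20
  ctrl <- rep(2L, 2 * nb)
  cellX <- ctrl
  cellX[3:4] <- 3L; cellX[10:12] <- 1L         # two focal on chr1
  cellX[(nb + 1):(2 * nb)] <- 3L               # trisomic chr2
  cn <- toy_cn(list(c1 = ctrl, c2 = ctrl, c3 = ctrl, x = cellX),
               c("control", "control", "control", "treated"),
               n_chrom = 2, nb = nb)
  modal <- modal_profile(cn, "control")
  counts <- count_aberrations(cn, modal)
  expect_s3_class(counts, "AberrationCounts")
  expect_equal(counts$n_focal[counts$cell_id == "x"], 2L)
  expect_equal(counts$n_whole_chromosome[counts$cell_id == "x"], 1L)
  expect_equal(counts$n_focal[counts$cell_id == "c1"], 0L)
  # conservation: totals equal summed classify_deviations events
  total_events <- sum(vapply(rownames(cn$states), function(cl)
    nrow(classify_deviations(cn$states[cl, ], modal)), numeric(1)))
  expect_equal(sum(counts$n_focal + counts$n_whole_chromosome), total_events)
})

test_that("modal_profile is idempotent on its own output", {
  sim <- simulate_cn_profiles(small_cn_cfg(seed = 3))
  modal <- modal_profile(sim$profiles, "control")
  rep3 <- toy_cn(list(a = modal$modal_state, b = modal$modal_state,
                      c = modal$modal_state),
                 rep("control", 3),
                 n_chrom = length(unique(modal$bins$chrom)),
                 nb = sum(modal$bins$chrom == modal$bins$chrom[1]))
  expect_equal(modal_profile(rep3, "control")$modal_state, modal$modal_state)
})

test_that("lowering whole_chrom_fraction shifts events from focal to whole-chromosome monotonically", {
  set.seed(21)
  sim <- simulate_cn_profiles(small_cn_cfg(
    seed = 21, conditions = list(control = list(focal_rate = 0, whole_chrom_rate = 0),
                                 treated = list(focal_rate = 4, whole_chrom_rate = 1))))
  modal <- modal_profile(sim$profiles, "control")
  fracs <- c(0.95, 0.9, 0.7, 0.5, 0.3)
  prev <- NULL
  for (f in fracs) {
    cnt <- count_aberrations(sim$profiles, modal, whole_chrom_fraction = f)
    if (!is.null(prev)) {
      expect_true(all(cnt$n_whole_chromosome >= prev$n_whole_chromosome))
      expect_true(all(cnt$n_focal <= prev$n_focal))
    }
    prev <- cnt
  }
})

test_that("compare_groups: identical groups yield p = 1; extreme separation matches enumeration", {
  mk <- function(focal, cond) data.frame(cell_id = paste0(cond, seq_along(focal)),
                                         condition = cond, n_focal = focal,
                                         n_whole_chromosome = 0L)
  same <- rbind(mk(c(1, 2, 3), "a"), mk(c(1, 2, 3), "b"))
  cmp <- compare_groups(same, metric = "focal")
  expect_equal(cmp$p_value, 1)
  expect_true(all(cmp$pairwise$p_adj >= cmp$pairwise$p_raw - 1e-15))
  # (0,0,0,0) vs (5,5,5,5): statistic equals the tie-corrected maximum N-1
  extreme <- rbind(mk(rep(0, 4), "a"), mk(rep(5, 4), "b"))
  cmp2 <- compare_groups(extreme, metric = "focal")
  expect_equal(cmp2$statistic,
               bf_kw_stat(c(rep(0, 4), rep(5, 4)), rep(c("a", "b"), each = 4)),
               tolerance = 1e-12)
  expect_equal(cmp2$statistic, 7, tolerance = 1e-12)
  # distinct values: our statistic equals the maximum over all possible rank
  # assignments for the 4+4 design, attained by complete separation
  distinct <- rbind(mk(1:4, "a"), mk(5:8, "b"))
  cmp3 <- compare_groups(distinct, metric = "focal")
  combos <- utils::combn(8, 4)
  all_stats <- apply(combos, 2, function(idx) {
    grp <- rep("b", 8); grp[idx] <- "a"
    bf_kw_stat(1:8, grp)
  })
  expect_equal(cmp3$statistic, max(all_stats), tolerance = 1e-12)
})

test_that("compare_groups filters small conditions and reports medians/IQRs", {
  counts <- data.frame(
    cell_id = sprintf("c%02d", 1:11),
    condition = c(rep("a", 5), rep("b", 4), rep("tiny", 2)),
    n_focal = c(0, 1, 1, 2, 3, 4, 5, 6, 7, 9, 9),
    n_whole_chromosome = 0L)
  expect_warning(cmp <- compare_groups(counts, metric = "focal"), "tiny")
  expect_identical(cmp$summary$condition, c("a", "b"))
  expect_equal(cmp$summary$median, c(1, 5.5))
  expect_equal(cmp$summary$n, c(5L, 4L))
  expect_error(suppressWarnings(compare_groups(counts[1:7, ], metric = "focal")),
               ">= 2 conditions")
})
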