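# Co-regulation, functional likelihood, co-functionality weights,
# thresholding and cluster extraction.

test_that("build_coregulation matches the brute-force oracle on a 5x6 toy", {
  set.seed(3)
  m <- matrix(rnorm(30), 5, 6, dimnames = list(paste0("g", 1:5),
                                               paste0("s", 1:6)))
  m["g2", ] <- m["g1", ] * 3 - 1          # identical rank profile as g1
  coreg <- build_coregulation(expression_matrix(m))
  expect_equal(diag(unclass(coreg)), rep(1, 5), ignore_attr = TRUE)
  expect_equal(coreg["g1", "g2"], 1)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(coreg[i, j], bf_spearman(m[i, ], m[j, ]), tolerance = 1e-10)
  expect_equal(max(abs(unclass(coreg) - t(unclass(coreg)))), 0)
})

test_that("constant genes get zero co-regulation and are flagged", {
  m <- rbind(flat = rep(1, 6), a = rnorm(6), b = rnorm(6))
  expect_message(coreg <- build_coregulation(toy_expression(m, genes = rownames(m))),
                 "constant")
  expect_equal(unname(coreg["flat", c("a", "b")]), c(0, 0))
  expect_equal(coreg["flat", "flat"], 1)
  expect_identical(attr(coreg, "degenerate"), "flat")
})

test_that("functional likelihood has gene x set shape and honors exclusion rules", {
  set.seed(5)
  m <- matrix(rnorm(20 * 12), 20, 12,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:12)))
  coreg <- build_coregulation(expression_matrix(m))
  sets <- gene_set_collection(list(
    S1 = sprintf("g%02d", 1:6), S2 = sprintf("g%02d", c(2, 5, 8, 11, 14)),
    S3 = sprintf("g%02d", 10:16),
    ALL = sprintf("g%02d", 1:20)))          # covers the whole universe
  expect_message(fl <- functional_likelihood(coreg, sets, c("g01", "g07"),
                                             min_set_size = 3),
                 "dropped")
  expect_equal(dim(fl), c(2L, 3L))          # ALL filtered out
  expect_identical(colnames(fl), c("S1", "S2", "S3"))
  expect_true(all(abs(fl) <= 1))
  # every set dropped -> hard error
  expect_error(functional_likelihood(coreg, gene_set_collection(
    list(ALL = sprintf("g%02d", 1:20))), "g01"), "no gene sets survive")
})

test_that("perfect separation attains the maximum Spearman for the membership split", {
  # 6-gene toy; query A's co-regulation with members of S strictly exceeds
  # every non-member. Oracle: exhaustively rearrange A's 5 coefficients over
  # the background and take the max attainable Spearman vs the indicator.
  genes <- c("A", "B", "C", "D", "E", "F")
  w <- diag(6)
  dimnames(w) <- list(genes, genes)
  vals <- c(B = 0.9, C = 0.8, D = 0.1, E = -0.2, F = -0.5)
  for (g in names(vals)) w["A", g] <- w[g, "A"] <- vals[[g]]
  w[2:6, 2:6][upper.tri(w[2:6, 2:6])] <- 0.05
  w[2:6, 2:6][lower.tri(w[2:6, 2:6])] <- 0.05
  diag(w) <- 1
  coreg <- coregulation_matrix(w)
  sets <- gene_set_collection(list(S = c("B", "C"), PAD = c("C", "D", "E")))
  fl <- functional_likelihood(coreg, sets, "A", min_set_size = 2,
                              max_set_fraction = 0.9)
  ind <- c(1, 1, 0, 0, 0)  # membership of S over background B..F
  perms <- bf_permutations(5L)
  best <- max(apply(perms, 1L, function(p) bf_spearman(vals[p], ind)))
  expect_equal(fl["A", "S"], best, tolerance = 1e-12)
})

test_that("cofunctionality_matrix matches brute force and handles degenerate rows", {
  fl_vals <- rbind(a = c(0.9, 0.1, -0.3, 0.5),
                   b = c(0.9, 0.1, -0.3, 0.5),
                   c = c(-0.2, 0.4, 0.1, -0.6))
  colnames(fl_vals) <- paste0("S", 1:4)
  fl <- functional_likelihood_matrix(fl_vals)
  w <- cofunctionality_matrix(fl)
  expect_equal(w["a", "b"], 1)            # identical vectors
  expect_equal(diag(w), rep(1, 3), ignore_attr = TRUE)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(w[i, j], bf_pearson(fl_vals[i, ], fl_vals[j, ]),
                 tolerance = 1e-10)
  # spearman flavor is rank-based
  ws <- cofunctionality_matrix(fl, flavor = "spearman")
  expect_equal(ws["a", "c"], bf_spearman(fl_vals["a", ], fl_vals["c", ]),
               tolerance = 1e-10)
  # constant likelihood vector -> zero weights, flagged
  fl2 <- functional_likelihood_matrix(rbind(fl_vals, flat = rep(0.2, 4)))
  expect_message(w2 <- cofunctionality_matrix(fl2), "constant")
  expect_equal(unname(w2["flat", c("a", "b", "c")]), c(0, 0, 0))
  # unknown flavor is a hard error
  expect_error(cofunctionality_matrix(fl, flavor = "kendall"), "kendall")
  expect_identical(cofunctionality_correlation_flavor(), "pearson")
})

test_that("threshold_network applies a strict cutoff with the tau = 1 boundary rule", {
  genes <- c("A", "B", "C", "D")
  w <- diag(4)
  dimnames(w) <- list(genes, genes)
  w["A", "B"] <- w["B", "A"] <- 0.9
  w["B", "C"] <- w["C", "B"] <- 0.51
  w["C", "D"] <- w["D", "C"] <- 0.4
  net <- threshold_network(w, 0.5)
  expect_identical(paste(net$edges$gene_a, net$edges$gene_b),
                   c("A B", "B C"))
  # exactly-at-threshold weight is excluded (strict >)
  w["C", "D"] <- w["D", "C"] <- 0.5
  expect_equal(nrow(threshold_network(w, 0.5)$edges), 2L)
  # tau = 1: only (numerically) identical likelihood vectors connect
  w["A", "B"] <- w["B", "A"] <- 1 - 1e-14
  net1 <- threshold_network(w, 1)
  expect_identical(paste(net1$edges$gene_a, net1$edges$gene_b), "A B")
  expect_error(threshold_network(w, 1.2), "tau")
  expect_error(threshold_network(w, -1), "tau")
})

test_that("extract_clusters returns components ordered by size, weight, member", {
  genes <- c("A", "B", "C", "D", "E", "Y", "Z")
  w <- diag(7) * 0.0 + 0.1
  dimnames(w) <- list(genes, genes)
  add_edge <- function(a, b, v) w[a, b] <<- w[b, a] <<- v
  add_edge("A", "B", 0.9); add_edge("B", "C", 0.8)   # size-3 component
  add_edge("D", "E", 0.95)                           # size-2, heavy
  add_edge("Y", "Z", 0.6)                            # size-2, light
  diag(w) <- 1
  cl <- extract_clusters(threshold_network(w, 0.5))
  expect_equal(vapply(cl, `[[`, numeric(1), "size"), c(3, 2, 2))
  expect_identical(cl[[1]]$members, c("A", "B", "C"))
  expect_identical(cl[[2]]$members, c("D", "E"))     # heavier of the ties
  expect_identical(cl[[3]]$members, c("Y", "Z"))
  expect_equal(cl[[2]]$mean_weight, 0.95)
  # empty network
  expect_identical(extract_clusters(threshold_network(diag(3) |>
    (\(m) {dimnames(m) <- list(letters[1:3], letters[1:3]); m})(), 0.5)),
    list())
})

test_that("cluster extraction is invariant to gene input order", {
  sim <- simulate_expression(small_expr_cfg(seed = 2))
  expr <- sim$expression
  perm <- sample(nrow(expr))
  run <- function(e) {
    tab <- suppressMessages(associate(e, sim$scores))
    top <- select_top(tab, 100)
    coreg <- build_coregulation(e)
    fl <- suppressMessages(functional_likelihood(coreg, sim$sets, sort(top)))
    cl <- extract_clusters(threshold_network(cofunctionality_matrix(fl), 0.5))
    lapply(cl, `[[`, "members")
  }
  set.seed(1)
  expect_identical(run(expr),
                   run(expression_matrix(unclass(expr)[perm, ])))
})

test_that("increasing tau never increases edge count or largest cluster", {
  set.seed(8)
  n <- 30
  base <- matrix(rnorm(n * 10), n, 10)
  w <- stats::cor(t(base))
  dimnames(w) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  prev_edges <- Inf; prev_big <- Inf
  for (tau in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    net <- threshold_network(w, tau)
    cl <- extract_clusters(net)
    big <- if (length(cl)) cl[[1]]$size else 0
    expect_lte(nrow(net$edges), prev_edges)
    expect_lte(big, prev_big)
    prev_edges <- nrow(net$edges); prev_big <- big
  }
})
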