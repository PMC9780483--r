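# grouped fixture builder: Cp-style log2 quantities with known structure
grouped_q <- function(seed, genes = 5, groups = 4, n_per = 6, noise = 0.2,
                      offsets = NULL, loading = 0.5) {
  set.seed(seed)
  glab <- paste0("grp", seq_len(groups))
  samples <- paste0("s", seq_len(groups * n_per))
  grp <- setNames(rep(glab, each = n_per), samples)
  if (is.null(offsets)) offsets <- matrix(0, genes, groups)
  y <- matrix(0, genes, length(samples),
              dimnames = list(paste0("g", seq_len(genes)), samples))
  load_s <- rnorm(length(samples), 0, loading)
  for (i in seq_len(genes)) {
    y[i, ] <- rnorm(1, 0, 2) + offsets[i, match(grp, glab)] + load_s +
      rnorm(length(samples), 0, if (length(noise) > 1) noise[i] else noise)
  }
  list(q = q_obj(2^y, groups = grp), groups = grp)
}

test_that("a perfectly average gene attains zero variance, zero d, minimal stability", {
  set.seed(2)
  base <- matrix(rnorm(4 * 12), 4, 12)
  # gene 5 equal to the per-sample mean of all 5 genes: x solves x = (S + x)/5
  m5 <- colMeans(base)
  y <- rbind(base, m5)
  rownames(y) <- paste0("g", 1:5)
  colnames(y) <- paste0("s", 1:12)
  grp <- setNames(rep(c("A", "B"), each = 6), colnames(y))
  res <- normfinder(q_obj(2^y, groups = grp))
  expect_equal(unname(res$sigma2["g5", ]), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(abs(res$d_raw["g5", ])), c(0, 0), tolerance = 1e-9)
  expect_equal(which.min(res$stability), c(g5 = 5L))
})

test_that("intergroup deviations sum to zero across genes within each group", {
  for (seed in 1:5) {
    fx <- grouped_q(seed)
    res <- normfinder(fx$q)
    expect_lt(max(abs(colSums(res$d_raw))), 1e-9)
  }
})

test_that("stability values are location-invariant under per-sample loading shifts", {
  fx <- grouped_q(31)
  res <- normfinder(fx$q)
  shifted <- fx$q
  set.seed(99)
  shifts <- rnorm(length(shifted$samples), 0, 3)
  shifted$q <- sweep(shifted$q, 2L, 2^shifts, "*")
  res2 <- normfinder(shifted)
  expect_equal(res2$stability, res$stability, tolerance = 1e-9)
  expect_equal(res2$sigma2, res$sigma2, tolerance = 1e-9)
})

test_that("grouped decomposition agrees with the lm-based oracle (property)", {
  for (seed in 1:20) {
    set.seed(seed)
    fx <- grouped_q(seed + 40, genes = sample(3:6, 1), groups = sample(2:4, 1),
                    n_per = sample(2:4, 1))
    res <- normfinder(fx$q)
    orc <- oracle_normfinder(log2(fx$q$q), fx$groups)
    expect_equal(res$stability, orc, tolerance = 1e-9)
  }
})

test_that("ungrouped stability equals the corrected two-pass variance oracle", {
  for (seed in 1:10) {
    q <- random_q(5, 10, seed + 900)
    res <- ungrouped_stability(q)
    expect_equal(unname(res$stability),
                 sqrt(oracle_sigma2(log2(q$q))), tolerance = 1e-9)
  }
  expect_error(ungrouped_stability(random_q(2, 10, 1)),
               class = "refstab_error_insufficient")
  expect_error(ungrouped_stability(random_q(4, 2, 1)),
               class = "refstab_error_insufficient")
})

test_that("proportional genes all get zero ungrouped stability; noisy genes rank last", {
  qmat <- outer(c(1, 2, 0.5, 4), c(1, 3, 2, 5, 0.5, 2))
  rownames(qmat) <- paste0("g", 1:4)
  res <- ungrouped_stability(q_obj(qmat))
  expect_equal(unname(res$stability), rep(0, 4), tolerance = 1e-9)

  set.seed(8)
  base <- rnorm(20)
  y <- rbind(g1 = base + rnorm(20, 0, 0.1), g2 = base + rnorm(20, 0, 0.1),
             g3 = base + rnorm(20, 0, 0.1), g4 = base + rnorm(20, 0, 0.1),
             bad = base + rnorm(20, 0, 1.0))
  colnames(y) <- paste0("s", 1:20)
  res2 <- ungrouped_stability(q_obj(2^y))
  expect_equal(names(which.max(res2$stability)), "bad")
  expect_equal(res2$table$rank[res2$table$gene == "bad"], 5L)
})

test_that("a group-offset gene is the least stable in the grouped analysis", {
  off <- matrix(0, 5, 4)
  off[2, 3] <- 2                                   # 2-cycle offset in one group
  fx <- grouped_q(123, genes = 5, groups = 4, n_per = 10, noise = 0.2,
                  offsets = off)
  res <- normfinder(fx$q)
  expect_equal(names(which.max(res$stability)), "g2")
  expect_gt(max(abs(res$d_raw["g2", ])), 1)
})

test_that("equal-noise genes get equal stabilities at large n (symmetry)", {
  fx <- grouped_q(7, genes = 4, groups = 2, n_per = 600, noise = 0.3, loading = 0.5)
  res <- normfinder(fx$q)
  expect_lt(diff(range(res$stability)), 0.025)
})

test_that("zero group effects: grouped ranking converges to the ungrouped one", {
  fx <- grouped_q(55, genes = 6, groups = 3, n_per = 400,
                  noise = c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55))
  grouped <- normfinder(fx$q)
  ungrouped <- ungrouped_stability(fx$q)
  expect_identical(order(grouped$stability), order(ungrouped$stability))
  expect_identical(unname(order(grouped$stability)), 1:6)
})

test_that("best pair: duplicates of the most stable gene win; oracle equivalence", {
  set.seed(17)
  fx <- grouped_q(17, genes = 4, groups = 3, n_per = 8, noise = c(0.05, 0.4, 0.5, 0.6))
  dup <- fx$q
  dup$q <- rbind(dup$q, dup$q["g1", , drop = FALSE] * 2^rnorm(ncol(dup$q), 0, 0.01))
  rownames(dup$q)[5] <- "g1b"
  dup$genes <- rownames(dup$q)
  res <- normfinder(dup)
  expect_setequal(res$best_pair$genes, c("g1", "g1b"))

  for (seed in 1:8) {
    fx <- grouped_q(seed + 300, genes = 5, groups = 3, n_per = 5)
    res <- normfinder(fx$q)
    orc <- oracle_best_pair(log2(fx$q$q), fx$groups)
    expect_setequal(res$best_pair$genes, orc$genes)
    expect_equal(res$best_pair$stability, orc$stability, tolerance = 1e-9)
  }
})

test_that("opposite-sign group deviations cancel: the pair beats each member", {
  off <- matrix(0, 4, 2)
  off[1, ] <- c(1, -1)                             # mirror-image deviations
  off[2, ] <- c(-1, 1)
  fx <- grouped_q(29, genes = 4, groups = 2, n_per = 12, noise = 0.1, offsets = off)
  res <- normfinder(fx$q)
  expect_setequal(res$best_pair$genes, c("g1", "g2"))
  expect_lt(res$best_pair$stability, min(res$stability[c("g1", "g2")]))
})

test_that("best_pair stability never exceeds both members of any pair (invariant)", {
  fx <- grouped_q(91, genes = 5, groups = 3, n_per = 6)
  res <- normfinder(fx$q)
  for (i in 1:4) for (j in (i + 1):5) {
    pair_members <- res$stability[c(i, j)]
    expect_lte(res$best_pair$stability, max(pair_members) + 1e-12)
  }
})

test_that("group structure prerequisites are enforced", {
  fx <- grouped_q(3, groups = 2, n_per = 3)
  bad <- fx$groups
  bad[1:5] <- "grp1"                               # leaves grp2 with 1 sample
  expect_error(normfinder(q_obj(fx$q$q, groups = bad)),
               class = "refstab_error_insufficient")
  # single group falls back to the ungrouped analysis
  one <- setNames(rep("all", length(fx$groups)), names(fx$groups))
  res <- normfinder(q_obj(fx$q$q, groups = one))
  expect_false(res$grouped)
  expect_error(best_two_gene_combination(res),
               class = "refstab_error_not_applicable")
})

test_that("designed low-noise gene attains minimal stability in >= 95% of 200 seeds", {
  hits <- 0L
  for (seed in 1:200) {
    fx <- grouped_q(seed + 7000, genes = 6, groups = 4, n_per = 8,
                    noise = c(0.05, rep(0.5, 5)))
    res <- normfinder(fx$q)
    if (names(which.min(res$stability)) == "g1") hits <- hits + 1L
  }
  expect_gte(hits, 190L)
})
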