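test_that("pairwise variation matches hand computations and is symmetric", {
  q <- q_obj(rbind(a = c(1, 2, 4), b = c(1, 1, 1), c = c(2, 4, 8)))
  expect_equal(pairwise_variation(q, "a", "b"), 1)      # SD of (0, 1, 2)
  expect_equal(pairwise_variation(q, "a", "a"), 0)
  expect_equal(pairwise_variation(q, "a", "c"), 0)      # proportional rows
  expect_equal(pairwise_variation(q, "a", "b"), pairwise_variation(q, "b", "a"))
  expect_error(pairwise_variation(q_obj(rbind(a = 1, b = 2)), "a", "b"),
               class = "refstab_error_insufficient")
})

test_that("M is the mean pairwise SD and matches the brute-force oracle", {
  q <- q_obj(rbind(a = c(1, 2, 4), b = c(2, 4, 8), c = c(4, 8, 16)))
  expect_equal(m_value(q, "a"), 0)                      # mutually proportional
  q2 <- q_obj(rbind(a = c(1, 2, 4), b = c(1, 1, 1)))
  expect_equal(m_value(q2, "a"), pairwise_variation(q2, "a", "b"))  # 2-gene identity

  for (seed in 1:5) {
    q3 <- random_q(4, 5, seed)
    y <- log2(q3$q)
    for (g in q3$genes) {
      expect_equal(m_value(q3, g), oracle_m(y, g, q3$genes), tolerance = 1e-12)
    }
  }
  expect_error(m_value(q, "a", "a"), class = "refstab_error_insufficient")
})

test_that("stepwise exclusion removes designed-noisy genes first and final pair shares M", {
  set.seed(11)
  base <- 2^rnorm(8)                                    # shared profile
  qmat <- rbind(a = base * 2^rnorm(8, 0, 0.05),
                b = base * 2^rnorm(8, 0, 0.05),
                c = base * 2^rnorm(8, 0, 0.05),
                noisy = base * 2^rnorm(8, 0, 1.5))
  res <- genorm(q_obj(qmat))
  expect_equal(res$exclusion_order[1], "noisy")
  m <- setNames(res$table$m_at_exclusion, res$table$gene)
  expect_equal(unname(m[res$final_pair[1]]), unname(m[res$final_pair[2]]))
  expect_true(all(res$table$m_at_exclusion >= 0))

  # 3 proportional genes + 1 noisy: final pair M exactly 0
  qmat2 <- rbind(a = c(1, 2, 4), b = c(2, 4, 8), c = c(0.5, 1, 2),
                 noisy = c(1, 8, 2))
  res2 <- genorm(q_obj(qmat2))
  expect_equal(res2$exclusion_order[1], "noisy")
  expect_equal(res2$table$m_at_exclusion[match(res2$final_pair, res2$table$gene)],
               c(0, 0))
  expect_error(genorm(q_obj(qmat2[1:2, ])), class = "refstab_error_insufficient")
})

test_that("ranks follow the exclusion trajectory with a shared rank-1 pair", {
  q <- random_q(5, 10, 3)
  res <- genorm(q)
  rk <- setNames(res$table$rank, res$table$gene)
  expect_equal(sort(unname(rk)), c(1, 1, 3, 4, 5))
  expect_equal(unname(rk[res$final_pair]), c(1, 1))
  expect_equal(unname(rk[rev(res$exclusion_order)]), 3:5)
})

test_that("normalization factors are per-sample geometric means", {
  q <- q_obj(rbind(a = c(1, 4), b = c(4, 1)))
  expect_equal(unname(normalization_factor(q, c("a", "b"))), c(2, 2))
  expect_equal(normalization_factor(q, "a"), q$q["a", ])
  q3 <- random_q(3, 6, 9)
  expect_equal(unname(normalization_factor(q3, q3$genes)),
               unname(2^colMeans(log2(q3$q))), tolerance = 1e-12)
  expect_error(normalization_factor(q3, character(0)), class = "refstab_error_input")
})

test_that("V_n/n+1 is zero for proportional panels and matches the oracle", {
  qmat <- outer(c(1, 2, 0.5, 4), c(1, 3, 2, 5, 0.5))   # all rows proportional
  rownames(qmat) <- letters[1:4]
  colnames(qmat) <- paste0("s", 1:5)
  res <- genorm(q_obj(qmat))
  expect_equal(res$v_series$v, rep(0, 2), tolerance = 1e-12)
  expect_true(all(res$v_series$below_threshold))

  for (seed in 1:5) {
    q <- random_q(4, 6, seed + 100)
    res <- genorm(q)
    expect_equal(res$v_series$v, oracle_v(q$q, res$stability_order), tolerance = 1e-12)
    expect_equal(res$v_series$n, 2:3)
  }
  expect_error(pairwise_v(random_q(4, 6, 1), c("g1", "g2")),
               class = "refstab_error_insufficient")
})

test_that("stepwise ranking agrees with the brute-force oracle (property)", {
  for (seed in 1:30) {
    set.seed(seed)
    g <- sample(3:6, 1)
    n <- sample(3:8, 1)
    q <- random_q(g, n, seed + 500)
    res <- genorm(q)
    orc <- oracle_stepwise(log2(q$q))
    expect_identical(res$exclusion_order, orc$exclusion_order)
    expect_setequal(res$final_pair, orc$final_pair)
    expect_equal(setNames(res$table$m_at_exclusion, res$table$gene)[names(orc$m_at_exclusion)],
                 orc$m_at_exclusion, tolerance = 1e-12)
  }
})

test_that("geNorm statistics are invariant to rescaling a gene's quantities", {
  q <- random_q(5, 8, 77)
  res <- genorm(q)
  q2 <- q
  q2$q["g3", ] <- q2$q["g3", ] * 1000
  res2 <- genorm(q2)
  expect_identical(res2$exclusion_order, res$exclusion_order)
  expect_equal(res2$table$m_at_exclusion, res$table$m_at_exclusion, tolerance = 1e-9)
  expect_equal(res2$v_series$v, res$v_series$v, tolerance = 1e-9)
})

test_that("an inflated-noise gene has the worst full-panel M (property, 20 seeds)", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    base <- 2^rnorm(10)
    qmat <- t(vapply(1:5, function(i) base * 2^rnorm(10, 0, 0.2), numeric(10)))
    qmat[3, ] <- base * 2^rnorm(10, 0, 1.0)             # 5x noise ratio
    rownames(qmat) <- paste0("g", 1:5)
    colnames(qmat) <- paste0("s", 1:10)
    res <- genorm(q_obj(qmat))
    if (which.max(res$table$full_panel_m) == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("the M > 1.5 reliability flag is applied at the exclusion step", {
  set.seed(5)
  base <- 2^rnorm(12)
  qmat <- rbind(a = base, b = base * 2^rnorm(12, 0, 0.05),
                c = base * 2^rnorm(12, 0, 0.05),
                wild = base * 2^rnorm(12, 0, 3))
  res <- genorm(q_obj(qmat))
  tab <- res$table
  expect_true(tab$unreliable[tab$gene == "wild"])
  expect_false(any(tab$unreliable[tab$gene != "wild"]))
})
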