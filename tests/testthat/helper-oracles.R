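# Independent brute-force oracles. Deliberately written with explicit
# loops / textbook formulas / lm fits rather than the package's vectorised
# paths, so agreement is evidence and not tautology.

oracle_pair_sd <- function(y, a, b) {
  d <- y[a, ] - y[b, ]
  m <- sum(d) / length(d)
  sqrt(sum((d - m)^2) / (length(d) - 1))
}

oracle_m <- function(y, gene, gene_set) {
  acc <- 0
  n <- 0
  for (k in gene_set) {
    if (k == gene) next
    acc <- acc + oracle_pair_sd(y, gene, k)
    n <- n + 1
  }
  acc / n
}

# full stepwise exclusion, recomputing every pairwise SD from scratch
oracle_stepwise <- function(y) {
  remaining <- rownames(y)
  exclusion <- character(0)
  m_at <- numeric(0)
  while (length(remaining) > 2) {
    ms <- sapply(remaining, function(g) oracle_m(y, g, remaining))
    worst <- names(ms)[ms == max(ms)]
    worst <- worst[length(worst)]              # later-in-order tie break
    exclusion <- c(exclusion, worst)
    m_at[worst] <- max(ms)
    remaining <- setdiff(remaining, worst)
  }
  fm <- oracle_pair_sd(y, remaining[1], remaining[2])
  m_at[remaining] <- fm
  list(exclusion_order = exclusion, final_pair = remaining, m_at_exclusion = m_at)
}

oracle_nf <- function(qmat, genes) {
  sapply(colnames(qmat), function(s) prod(qmat[genes, s])^(1 / length(genes)))
}

oracle_v <- function(qmat, order_) {
  sapply(2:(length(order_) - 1), function(n) {
    ratio <- log2(oracle_nf(qmat, order_[1:n]) / oracle_nf(qmat, order_[1:(n + 1)]))
    stats::sd(ratio)
  })
}

# per-gene variances from a two-way layout via lm residuals and an exact
# solve of the unbiasedness system E[u_i] = (1 - 2/k) s_i + sum(s)/k^2
oracle_sigma2 <- function(yg) {
  k <- nrow(yg)
  n <- ncol(yg)
  df <- data.frame(y = as.vector(yg),
                   gene = factor(rep(rownames(yg), n), levels = rownames(yg)),
                   sample = factor(rep(colnames(yg), each = k)))
  r <- matrix(stats::resid(stats::lm(y ~ gene + sample, data = df)), k, n)
  u <- rowSums(r^2) / (n - 1)
  A <- diag(1 - 2 / k, k) + matrix(1 / k^2, k, k)
  pmax(0, as.vector(solve(A, u)))
}

# grouped NormFinder recomputed step by step with loops
oracle_normfinder <- function(y, groups) {
  genes <- rownames(y)
  k <- length(genes)
  glev <- unique(unname(groups[colnames(y)]))
  m <- length(glev)
  sigma2 <- matrix(0, k, m, dimnames = list(genes, glev))
  a <- matrix(0, k, m, dimnames = list(genes, glev))
  n_g <- integer(m)
  for (gi in seq_along(glev)) {
    cols <- names(groups)[groups == glev[gi]]
    yg <- y[, cols, drop = FALSE]
    n_g[gi] <- length(cols)
    sigma2[, gi] <- oracle_sigma2(yg)
    for (i in seq_len(k)) a[i, gi] <- mean(yg[i, ]) - mean(yg)
  }
  d <- a
  for (i in seq_len(k)) d[i, ] <- a[i, ] - mean(a[i, ])
  gamma2 <- sum(d^2) / ((k - 1) * (m - 1))
  stab <- numeric(k)
  for (i in seq_len(k)) {
    acc <- 0
    for (gi in seq_len(m)) {
      se2 <- sigma2[i, gi] / n_g[gi]
      dt <- if (gamma2 > 0) d[i, gi] * gamma2 / (gamma2 + se2) else 0
      acc <- acc + abs(dt) + sqrt(se2)
    }
    stab[i] <- acc / m
  }
  names(stab) <- genes
  stab
}

# centered textbook form (the raw-sums variant loses ~10 digits on
# uncentered Cp-scale data)
oracle_pearson <- function(x, y) {
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# exhaustive pair enumeration on the oracle's own decomposition
oracle_best_pair <- function(y, groups) {
  genes <- rownames(y)
  k <- length(genes)
  glev <- unique(unname(groups[colnames(y)]))
  m <- length(glev)
  sigma2 <- matrix(0, k, m); a <- matrix(0, k, m)
  n_g <- integer(m)
  for (gi in seq_along(glev)) {
    cols <- names(groups)[groups == glev[gi]]
    yg <- y[, cols, drop = FALSE]
    n_g[gi] <- length(cols)
    sigma2[, gi] <- oracle_sigma2(yg)
    for (i in seq_len(k)) a[i, gi] <- mean(yg[i, ]) - mean(yg)
  }
  d <- a
  for (i in seq_len(k)) d[i, ] <- a[i, ] - mean(a[i, ])
  gamma2 <- sum(d^2) / ((k - 1) * (m - 1))
  dt <- d
  for (i in seq_len(k)) for (gi in seq_len(m)) {
    se2 <- sigma2[i, gi] / n_g[gi]
    dt[i, gi] <- if (gamma2 > 0) d[i, gi] * gamma2 / (gamma2 + se2) else 0
  }
  best <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    s <- 0
    for (gi in seq_len(m)) {
      s <- s + abs((dt[i, gi] + dt[j, gi]) / 2) +
        sqrt((sigma2[i, gi] + sigma2[j, gi]) / (4 * n_g[gi]))
    }
    s <- s / m
    if (is.null(best) || s < best$stability) {
      best <- list(genes = c(genes[i], genes[j]), stability = s)
    }
  }
  best
}
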