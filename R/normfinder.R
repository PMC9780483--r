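#' NormFinder model-based stability analysis
#'
#' Decomposes log2 expression into sample-loading, gene, group and noise
#' components and scores each candidate gene by how much it deviates from
#' the common signal, both within groups (intragroup variance) and between
#' groups (systematic intergroup deviation d). Lower stability = better
#' reference gene.
#'
#' The grouped estimator works on y = log2(Q):
#' 1. within each group, form two-way residuals (gene and sample means
#'    removed) — the per-sample centering absorbs any loading shift;
#' 2. estimate each gene's intragroup variance with the small-panel
#'    correction for the centering step: with k genes,
#'    sigma2_i = (u_i - sum(u)/(k (k-1))) * k / (k - 2), u_i the raw
#'    residual mean square (negative estimates are clamped to 0);
#' 3. the raw intergroup deviation d_ig is the gene's centered group mean
#'    minus its across-group average; within every group the d's sum to 0
#'    across genes;
#' 4. d is shrunk toward 0 by the empirical-Bayes factor
#'    gamma2 / (gamma2 + sigma2_ig / n_g), gamma2 the empirical variance
#'    of the raw d estimates (denominator (k-1)(m-1) for the double
#'    centering);
#' 5. stability_i = mean over groups of |d~_ig| + SE_ig, with
#'    SE_ig = sqrt(sigma2_ig / n_g).
#'
#' With a single group (or `groups = NULL`) the analysis reduces to the
#' ungrouped estimator: stability_i = sqrt(max(0, sigma2_i)) from the same
#' corrected two-way decomposition over the pooled samples.
#'
#' @param q a [to_relative_quantities()] result with >= 3 genes.
#' @param groups named character vector sample -> group label; defaults to
#'   the groups carried by `q`. Grouped analysis needs >= 2 groups with
#'   >= 2 samples each.
#' @param best_pair evaluate the optimal two-gene combination (grouped
#'   analysis only).
#' @return an object of class `normfinder_result`: `table` (gene,
#'   stability, rank), `stability`, `grouped`, and for the grouped path
#'   `sigma2`, `d_raw`, `d_shrunk` (genes x groups matrices), `gamma2`,
#'   `group_sizes`, `best_pair` (list: genes, stability).
#' @export
normfinder <- function(q, groups = q$groups, best_pair = TRUE) {
  y <- log2_q(q)
  k <- length(q$genes)
  if (k < 3L) {
    rs_abort("NormFinder needs >= 3 genes (the centering correction requires k > 2)",
             "refstab_error_insufficient")
  }
  if (is.null(groups) || length(unique(groups[q$samples])) < 2L) {
    return(ungrouped_stability(q))
  }
  groups <- groups[q$samples]
  if (any(is.na(groups))) {
    rs_abort("every sample needs a group label for the grouped analysis",
             "refstab_error_validation")
  }
  glev <- unique(unname(groups))
  m <- length(glev)
  n_g <- vapply(glev, function(g) sum(groups == g), integer(1L))
  if (any(n_g < 2L)) {
    rs_abort(sprintf("group(s) with < 2 samples: %s",
                     paste(glev[n_g < 2L], collapse = ", ")),
             "refstab_error_insufficient")
  }

  sigma2 <- matrix(0, k, m, dimnames = list(q$genes, glev))
  a <- matrix(0, k, m, dimnames = list(q$genes, glev))  # centered group means
  for (g in glev) {
    yg <- y[, groups == g, drop = FALSE]
    sigma2[, g] <- corrected_intragroup_var(yg)
    a[, g] <- rowMeans(yg) - mean(yg)
  }
  d_raw <- a - rowMeans(a)
  gamma2 <- sum(d_raw^2) / ((k - 1L) * (m - 1L))
  se2 <- sweep(sigma2, 2L, n_g, "/")
  shrink <- if (gamma2 > 0) gamma2 / (gamma2 + se2) else 0 * se2
  d_shrunk <- d_raw * shrink
  stability <- rowMeans(abs(d_shrunk) + sqrt(se2))

  res <- structure(
    list(table = data.frame(gene = q$genes, stability = unname(stability),
                            rank = unname(competition_ranks(stability)),
                            stringsAsFactors = FALSE),
         stability = stability, grouped = TRUE,
         sigma2 = sigma2, d_raw = d_raw, d_shrunk = d_shrunk,
         gamma2 = gamma2, group_sizes = stats::setNames(n_g, glev),
         best_pair = NULL),
    class = "normfinder_result"
  )
  if (isTRUE(best_pair)) res$best_pair <- best_two_gene_combination(res)
  res
}

# Unbiased per-gene variances from a genes x samples block after removing
# gene and sample means. With k genes the raw residual mean squares u_i
# satisfy E[u_i] = (1 - 2/k) sigma2_i + sum(sigma2)/k^2; inverting gives
# the closed form below. Negative moment estimates are clamped to 0.
corrected_intragroup_var <- function(yg) {
  k <- nrow(yg)
  n <- ncol(yg)
  r <- yg - rowMeans(yg) - rep(colMeans(yg), each = k) + mean(yg)
  u <- rowSums(r^2) / (n - 1L)
  pmax(0, (u - sum(u) / (k * (k - 1L))) * k / (k - 2L))
}

#' NormFinder single-group stability
#'
#' The ungrouped reduction: no intergroup term exists, so a gene's
#' stability is the square root of its corrected variance of centered
#' residuals over the pooled samples.
#'
#' @param q a quantity matrix with >= 3 genes and >= 3 samples.
#' @return a `normfinder_result` with `grouped = FALSE`.
#' @export
ungrouped_stability <- function(q) {
  y <- log2_q(q)
  if (length(q$genes) < 3L) {
    rs_abort("NormFinder needs >= 3 genes", "refstab_error_insufficient")
  }
  if (length(q$samples) < 3L) {
    rs_abort("ungrouped NormFinder needs >= 3 samples", "refstab_error_insufficient")
  }
  stability <- sqrt(corrected_intragroup_var(y))
  names(stability) <- q$genes
  structure(
    list(table = data.frame(gene = q$genes, stability = unname(stability),
                            rank = unname(competition_ranks(stability)),
                            stringsAsFactors = FALSE),
         stability = stability, grouped = FALSE, best_pair = NULL),
    class = "normfinder_result"
  )
}

#' Optimal two-gene combination
#'
#' Exhaustively evaluates every gene pair on the grouped NormFinder scale:
#' the pair's intergroup deviation is the average of the two genes'
#' shrunken d values (opposite-sign deviations cancel — the rationale for
#' using two genes), and its sampling term is the standard error of that
#' average, sqrt((sigma2_a + sigma2_b) / (4 n_g)). The pair stability is
#' the across-group mean of |d_pair| + SE_pair, directly comparable to
#' single-gene stabilities.
#'
#' @param x a grouped `normfinder_result` (from [normfinder()]).
#' @return list with `genes` (character 2-vector) and `stability`.
#' @export
best_two_gene_combination <- function(x) {
  if (!inherits(x, "normfinder_result") || !isTRUE(x$grouped)) {
    rs_abort("the two-gene combination needs a grouped NormFinder analysis (>= 2 groups)",
             "refstab_error_not_applicable")
  }
  genes <- rownames(x$d_shrunk)
  n_g <- x$group_sizes[colnames(x$d_shrunk)]
  best <- NULL
  for (i in seq_len(length(genes) - 1L)) {
    for (j in (i + 1L):length(genes)) {
      d_pair <- (x$d_shrunk[i, ] + x$d_shrunk[j, ]) / 2
      se_pair <- sqrt((x$sigma2[i, ] + x$sigma2[j, ]) / (4 * n_g))
      s <- mean(abs(d_pair) + se_pair)
      if (is.null(best) || s < best$stability) {
        best <- list(genes = c(genes[i], genes[j]), stability = s)
      }
    }
  }
  best
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat(sprintf("NormFinder stability (%s analysis)\n",
              if (x$grouped) sprintf("grouped, %d groups", length(x$group_sizes)) else "ungrouped"))
  tab <- x$table[order(x$table$rank), ]
  tab$stability <- fmt_num(tab$stability)
  print(tab, row.names = FALSE)
  if (!is.null(x$best_pair)) {
    cat(sprintf("best two-gene combination: %s + %s (stability %s)\n",
                x$best_pair$genes[1L], x$best_pair$genes[2L],
                fmt_num(x$best_pair$stability)))
  }
  invisible(x)
}
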