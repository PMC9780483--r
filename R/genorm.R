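#' Pairwise variation between two genes
#'
#' The geNorm building block: the sample standard deviation (n-1
#' denominator) of the log2-transformed expression ratio Q_j/Q_k across
#' samples. Symmetric in its gene arguments and invariant to rescaling
#' either gene's quantities by a positive constant.
#'
#' @param q a [to_relative_quantities()] result.
#' @param gene_j,gene_k gene identifiers.
#' @return standard deviation in log2 units.
#' @export
pairwise_variation <- function(q, gene_j, gene_k) {
  y <- log2_q(q)
  if (!all(c(gene_j, gene_k) %in% q$genes)) {
    rs_abort("both genes must be present in the quantity matrix", "refstab_error_input")
  }
  if (length(q$samples) < 2L) {
    rs_abort("pairwise variation needs >= 2 samples", "refstab_error_insufficient")
  }
  stats::sd(y[gene_j, ] - y[gene_k, ])
}

#' geNorm expression-stability measure M
#'
#' The average pairwise variation of one gene against every other gene of
#' the candidate set; lower M means more stable expression.
#'
#' @param q a quantity matrix.
#' @param gene gene whose M is requested.
#' @param gene_set candidate set (defaults to all genes); must contain
#'   `gene` and at least one other gene.
#' @return M in log2 units.
#' @export
m_value <- function(q, gene, gene_set = q$genes) {
  if (!gene %in% gene_set) rs_abort("gene must belong to gene_set", "refstab_error_input")
  if (length(gene_set) < 2L) {
    rs_abort("M is undefined for a singleton gene set", "refstab_error_insufficient")
  }
  others <- setdiff(gene_set, gene)
  y <- log2_q(q)
  mean(vapply(others, function(k) stats::sd(y[gene, ] - y[k, ]), numeric(1L)))
}

# all M values for a gene set at once (vectorised over the pair SD matrix)
m_values_for_set <- function(y, gene_set) {
  k <- length(gene_set)
  sds <- matrix(0, k, k, dimnames = list(gene_set, gene_set))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      s <- stats::sd(y[gene_set[i], ] - y[gene_set[j], ])
      sds[i, j] <- s
      sds[j, i] <- s
    }
  }
  rowSums(sds) / (k - 1L)
}

#' Per-sample normalization factor
#'
#' The geometric mean of the chosen reference genes' relative quantities in
#' each sample.
#'
#' @param q a quantity matrix.
#' @param gene_subset non-empty character vector of genes.
#' @return named numeric vector, one NF per sample.
#' @export
normalization_factor <- function(q, gene_subset) {
  if (length(gene_subset) == 0L) {
    rs_abort("normalization factor needs a non-empty gene subset", "refstab_error_input")
  }
  if (!all(gene_subset %in% q$genes)) {
    rs_abort("unknown gene(s) in subset", "refstab_error_input")
  }
  apply(q$q[gene_subset, , drop = FALSE], 2L, geo_mean)
}

#' geNorm stepwise stability ranking
#'
#' Iteratively removes the gene with the highest M (ties broken toward the
#' gene appearing later in input order), recomputing M on the reduced set,
#' until two genes remain. Each gene's reported M is its M at the step of
#' its exclusion; the final surviving pair shares the SD of its log ratio
#' (an algebraic identity) and both members receive competition rank 1, the
#' next most stable gene rank 3. Genes whose M at exclusion exceeds 1.5 are
#' flagged unreliable. The V_n/n+1 series for the optimal number of
#' reference genes is included (see [pairwise_v()]).
#'
#' @param q a quantity matrix with >= 3 genes and >= 2 samples.
#' @param m_threshold reliability flag threshold on M (default 1.5).
#' @param v_threshold decision threshold on V_n/n+1 (default 0.15).
#' @return an object of class `genorm_result`: `table` (data.frame with
#'   gene, m_at_exclusion, full_panel_m, rank, unreliable), `exclusion_order`
#'   (least to most stable as removed), `stability_order` (most to least
#'   stable), `final_pair`, `v_series`, and the thresholds.
#' @export
genorm <- function(q, m_threshold = 1.5, v_threshold = 0.15) {
  genes <- q$genes
  if (length(genes) < 3L) {
    rs_abort("geNorm stepwise ranking needs >= 3 genes", "refstab_error_insufficient")
  }
  if (length(q$samples) < 2L) {
    rs_abort("geNorm needs >= 2 samples", "refstab_error_insufficient")
  }
  y <- log2_q(q)
  full_panel_m <- m_values_for_set(y, genes)

  remaining <- genes
  exclusion_order <- character(0)
  m_at_exclusion <- stats::setNames(numeric(length(genes)), genes)
  while (length(remaining) > 2L) {
    m <- m_values_for_set(y, remaining)
    worst_m <- max(m)
    # ties: remove the candidate appearing last in input order
    worst <- remaining[which(m == worst_m)]
    worst <- worst[length(worst)]
    m_at_exclusion[worst] <- worst_m
    exclusion_order <- c(exclusion_order, worst)
    remaining <- setdiff(remaining, worst)
  }
  final_m <- stats::sd(y[remaining[1L], ] - y[remaining[2L], ])
  m_at_exclusion[remaining] <- final_m
  stability_order <- c(remaining, rev(exclusion_order))

  ranks <- stats::setNames(integer(length(genes)), genes)
  ranks[stability_order] <- c(1L, 1L, seq(3L, length.out = length(genes) - 2L))

  tab <- data.frame(
    gene = genes,
    m_at_exclusion = unname(m_at_exclusion[genes]),
    full_panel_m = unname(full_panel_m[genes]),
    rank = unname(ranks[genes]),
    unreliable = unname(m_at_exclusion[genes] > m_threshold),
    stringsAsFactors = FALSE
  )
  res <- structure(
    list(table = tab, exclusion_order = exclusion_order,
         stability_order = stability_order, final_pair = remaining,
         m_threshold = m_threshold, v_threshold = v_threshold,
         v_series = NULL),
    class = "genorm_result"
  )
  res$v_series <- pairwise_v(q, res)
  res
}

#' Pairwise variation of normalization factors (V_n/n+1)
#'
#' For n = 2..G-1, the standard deviation across samples of
#' log2(NF_n / NF_n+1), where NF_n is built from the n most stable genes of
#' the stepwise ranking. Values below the 0.15 threshold indicate that the
#' (n+1)-th gene adds no practical benefit.
#'
#' @param q a quantity matrix.
#' @param ranking a `genorm_result`, or a character vector ordering genes
#'   from most to least stable.
#' @param v_threshold annotation threshold (default 0.15).
#' @return data.frame with columns `n`, `v`, `below_threshold`.
#' @export
pairwise_v <- function(q, ranking, v_threshold = 0.15) {
  order_ <- if (inherits(ranking, "genorm_result")) ranking$stability_order else as.character(ranking)
  if (length(order_) < 3L) {
    rs_abort("V_n/n+1 needs >= 3 genes", "refstab_error_insufficient")
  }
  if (inherits(ranking, "genorm_result")) v_threshold <- ranking$v_threshold
  ns <- 2:(length(order_) - 1L)
  v <- vapply(ns, function(n) {
    nf_n <- normalization_factor(q, order_[seq_len(n)])
    nf_n1 <- normalization_factor(q, order_[seq_len(n + 1L)])
    stats::sd(log2(nf_n / nf_n1))
  }, numeric(1L))
  data.frame(n = ns, v = v, below_threshold = v < v_threshold)
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability ranking\n")
  tab <- x$table[order(x$table$rank), ]
  tab$m_at_exclusion <- fmt_num(tab$m_at_exclusion)
  tab$full_panel_m <- fmt_num(tab$full_panel_m)
  print(tab, row.names = FALSE)
  cat(sprintf("most stable pair: %s + %s\n", x$final_pair[1L], x$final_pair[2L]))
  v <- x$v_series
  cat(sprintf("V_%d/%d = %s%s\n", v$n, v$n + 1L, fmt_num(v$v),
              ifelse(v$below_threshold, " (< 0.15: no extra gene needed)", "")), sep = "")
  invisible(x)
}
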