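#' Competition ranks
#'
#' Ranks scores so the best score gets rank 1 and tied scores share the
#' lowest applicable rank, with the next distinct score offset by the tie
#' group size (1, 1, 3 — the "standard competition" convention). Missing
#' scores, if permitted, are ranked after all scored entries, ordered by an
#' auxiliary score.
#'
#' @param scores numeric vector (optionally named). `NA` entries are only
#'   allowed when `missing_rank_by` is supplied.
#' @param direction `"ascending_better"` (low score = rank 1; M-values,
#'   NormFinder stability) or `"descending_better"` (high score = rank 1;
#'   BestKeeper r).
#' @param missing_rank_by auxiliary numeric vector (same length/names),
#'   ascending-better, used to order the missing-score entries after the
#'   scored ones.
#' @return integer vector of ranks, names preserved.
#' @export
competition_ranks <- function(scores, direction = c("ascending_better", "descending_better"),
                              missing_rank_by = NULL) {
  direction <- match.arg(direction)
  if (all(is.na(scores))) rs_abort("all scores are missing", "refstab_error_input")
  s <- if (direction == "descending_better") -scores else scores
  ranks <- rep(NA_integer_, length(s))
  ok <- !is.na(s)
  if (any(!ok) && is.null(missing_rank_by)) {
    rs_abort("missing scores need a missing_rank_by policy", "refstab_error_input")
  }
  sv <- s[ok]
  ranks[ok] <- vapply(sv, function(x) 1L + sum(sv < x), integer(1L))
  if (any(!ok)) {
    aux <- missing_rank_by[!ok]
    ranks[!ok] <- sum(ok) + order(order(aux))
  }
  names(ranks) <- names(scores)
  ranks
}

#' Geometric mean of rank numbers
#'
#' The consensus score: the k-th root of the product of a gene's per-method
#' ranks. Reported to 3 decimals; the unrounded value is what callers
#' should sort on.
#'
#' @param ranks numeric vector of ranks, all >= 1.
#' @return unrounded geometric mean (use `round(x, 3)` for display).
#' @export
geometric_mean_rank <- function(ranks) {
  if (length(ranks) == 0L) rs_abort("empty rank tuple", "refstab_error_input")
  if (any(!is.finite(ranks)) || any(ranks < 1)) {
    rs_abort("ranks must be finite and >= 1", "refstab_error_input")
  }
  geo_mean(ranks)
}

#' Consensus ranking from a per-method rank matrix
#'
#' @param rank_matrix genes x methods matrix (or data.frame) of competition
#'   ranks; rownames are gene identifiers.
#' @return an object of class `consensus_ranking`: `table` (gene, one rank
#'   column per method, geomean, final_rank) sorted by ascending geometric
#'   mean (ties broken by arithmetic mean rank, then input order),
#'   `final_order`, `methods`.
#' @export
consensus_from_ranks <- function(rank_matrix) {
  rm <- as.matrix(rank_matrix)
  if (is.null(rownames(rm))) rs_abort("rank matrix needs gene rownames", "refstab_error_input")
  genes <- rownames(rm)
  geomeans <- apply(rm, 1L, geometric_mean_rank)
  meanrank <- rowMeans(rm)
  ord <- order(geomeans, meanrank, seq_along(genes))
  tab <- data.frame(gene = genes, rm, geomean = unname(geomeans),
                    row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE)
  tab <- tab[ord, , drop = FALSE]
  tab$final_rank <- competition_ranks(tab$geomean)
  rownames(tab) <- NULL
  structure(
    list(table = tab, final_order = tab$gene,
         methods = colnames(rm)),
    class = "consensus_ranking"
  )
}

#' Aggregate per-method stability results into a consensus ranking
#'
#' Builds competition ranks per method with the correct direction (geNorm:
#' lower M better; NormFinder: lower stability better; BestKeeper: higher r
#' better), then combines them by the geometric mean of ranks. Genes the
#' BestKeeper analysis excluded (no r) are ranked after all its scored
#' genes, ordered by the auxiliary score (ascending geNorm M when
#' available, else input order).
#'
#' @param genorm a `genorm_result` (optional).
#' @param normfinder a `normfinder_result` (optional).
#' @param bestkeeper a `bestkeeper_result` (optional).
#' @return a `consensus_ranking`. At least two methods are required.
#' @export
aggregate_stability <- function(genorm = NULL, normfinder = NULL, bestkeeper = NULL) {
  methods <- list()
  universe <- NULL
  check_universe <- function(genes, label) {
    if (is.null(universe)) universe <<- genes
    else if (!setequal(universe, genes)) {
      rs_abort(sprintf(
        "gene universes differ for %s: only-in-%s = {%s}, missing-from-%s = {%s}",
        label, label, paste(setdiff(genes, universe), collapse = ", "),
        label, paste(setdiff(universe, genes), collapse = ", ")),
        "refstab_error_validation")
    }
  }
  aux <- NULL
  if (!is.null(genorm)) {
    check_universe(genorm$table$gene, "genorm")
    methods$genorm <- stats::setNames(genorm$table$rank, genorm$table$gene)
    aux <- stats::setNames(genorm$table$m_at_exclusion, genorm$table$gene)
  }
  if (!is.null(normfinder)) {
    check_universe(normfinder$table$gene, "normfinder")
    methods$normfinder <- stats::setNames(normfinder$table$rank, normfinder$table$gene)
  }
  if (!is.null(bestkeeper)) {
    check_universe(bestkeeper$table$gene, "bestkeeper")
    r <- stats::setNames(bestkeeper$table$r, bestkeeper$table$gene)
    aux_bk <- if (!is.null(aux)) aux[names(r)] else seq_along(r)
    methods$bestkeeper <- competition_ranks(r, direction = "descending_better",
                                            missing_rank_by = aux_bk)
  }
  if (length(methods) < 2L) {
    rs_abort("a consensus needs >= 2 methods", "refstab_error_config")
  }
  rm <- do.call(cbind, lapply(methods, function(v) v[universe]))
  rownames(rm) <- universe
  colnames(rm) <- names(methods)
  consensus_from_ranks(rm)
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat(sprintf("Consensus ranking (geometric mean of %s ranks)\n",
              paste(x$methods, collapse = " + ")))
  tab <- x$table
  tab$geomean <- fmt_num(tab$geomean)
  print(tab, row.names = FALSE)
  cat("final ordering:", paste(x$final_order, collapse = " > "), "\n")
  invisible(x)
}
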