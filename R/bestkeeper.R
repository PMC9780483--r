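#' Per-gene Cp descriptive statistics
#'
#' BestKeeper works on the raw Cp scale (not relative quantities), judging
#' dispersion directly in cycles. For every gene: arithmetic and geometric
#' mean Cp, min, max, sample SD (n-1) about the arithmetic mean, CV% =
#' 100 * SD / mean, and the SD > 1.00 unreliability flag.
#'
#' @param x a `cp_matrix` with >= 2 samples.
#' @param sd_threshold flag threshold on the Cp SD (default 1.00 cycle).
#' @return data.frame with one row per gene.
#' @export
bk_descriptives <- function(x, sd_threshold = 1.0) {
  if (length(x$samples) < 2L) {
    rs_abort("descriptive statistics need >= 2 samples", "refstab_error_insufficient")
  }
  v <- x$values
  sds <- apply(v, 1L, stats::sd)
  means <- rowMeans(v)
  data.frame(
    gene = x$genes,
    n = ncol(v),
    geo_mean_cp = apply(v, 1L, geo_mean),
    ar_mean_cp = means,
    min_cp = apply(v, 1L, min),
    max_cp = apply(v, 1L, max),
    sd_cp = sds,
    cv_pct = 100 * sds / means,
    sd_flag = sds > sd_threshold,
    stringsAsFactors = FALSE
  )
}

#' BestKeeper index
#'
#' Per-sample geometric mean of the retained genes' Cp values.
#'
#' @param x a `cp_matrix`.
#' @param retained_genes genes entering the index (>= 2).
#' @return named numeric vector, one index value (cycles) per sample.
#' @export
bestkeeper_index <- function(x, retained_genes) {
  if (length(retained_genes) < 2L) {
    rs_abort("the BestKeeper index needs >= 2 retained genes", "refstab_error_insufficient")
  }
  if (!all(retained_genes %in% x$genes)) {
    rs_abort("unknown gene(s) in retained set", "refstab_error_input")
  }
  apply(x$values[retained_genes, , drop = FALSE], 2L, geo_mean)
}

#' Correlate genes with the BestKeeper index
#'
#' Pearson correlation of each gene's Cp profile with the index, with a
#' two-sided p-value from the t transform on n-2 degrees of freedom.
#' Zero-variance genes get NA with a diagnostic.
#'
#' @param x a `cp_matrix` with >= 3 samples.
#' @param index per-sample index (see [bestkeeper_index()]).
#' @param genes genes to correlate (default all).
#' @return data.frame (gene, r, p, diagnostic).
#' @export
correlate_with_index <- function(x, index, genes = x$genes) {
  if (length(x$samples) < 3L) {
    rs_abort("correlation with the index needs >= 3 samples", "refstab_error_insufficient")
  }
  if (length(index) != length(x$samples)) {
    rs_abort("index length must equal the sample count", "refstab_error_input")
  }
  n <- length(index)
  rows <- lapply(genes, function(g) {
    cp <- x$values[g, ]
    if (stats::sd(cp) == 0 || stats::sd(index) == 0) {
      return(data.frame(gene = g, r = NA_real_, p = NA_real_,
                        diagnostic = "zero_variance", stringsAsFactors = FALSE))
    }
    r <- stats::cor(cp, index)
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
    data.frame(gene = g, r = r, p = p, diagnostic = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full BestKeeper analysis
#'
#' Computes descriptives, applies the SD > 1.00 unreliability flag, builds
#' the index from the unflagged analyzed genes, correlates every analyzed
#' gene (flagged or not) with the index, and ranks analyzed genes by
#' descending r. The classic tool caps the panel at 10 genes: with more
#' genes a pre-exclusion list must bring the analyzed count within
#' `max_genes` (pre-excluded genes keep their descriptives but get no r;
#' their final placement is handled by the consensus missing-score policy).
#'
#' @param x a `cp_matrix`.
#' @param max_genes compatibility cap on analyzed genes (default 10; raise
#'   to remove the limit).
#' @param exclude genes excluded from the analysis before it starts.
#' @param sd_threshold SD flag threshold (default 1.00 cycle).
#' @return an object of class `bestkeeper_result`: `table` (descriptives +
#'   r, p, rank), `index`, `analyzed`, `excluded`, `sd_flagged`, `retained`
#'   (the index genes), `diagnostics` (contains
#'   `"index_fallback_all_genes"` when fewer than two genes passed the SD
#'   rule and the index had to use every analyzed gene).
#' @export
bestkeeper <- function(x, max_genes = 10L, exclude = NULL, sd_threshold = 1.0) {
  exclude <- as.character(exclude)
  if (!all(exclude %in% x$genes)) {
    rs_abort("exclude list contains unknown gene(s)", "refstab_error_input")
  }
  analyzed <- setdiff(x$genes, exclude)
  if (length(analyzed) > max_genes) {
    rs_abort(sprintf(
      "BestKeeper analyzes at most %d genes (%d requested); supply a pre-exclusion list or raise max_genes",
      max_genes, length(analyzed)), "refstab_error_config")
  }
  desc <- bk_descriptives(x, sd_threshold = sd_threshold)
  flagged <- desc$gene[desc$sd_flag]
  retained <- setdiff(analyzed, flagged)
  diagnostics <- character(0)
  if (length(retained) < 2L) {
    # degenerate panel: (nearly) everything exceeds the SD rule, typically a
    # large shared loading shift on raw Cp; keep the flags but build the
    # index from all analyzed genes so the analysis stays defined
    diagnostics <- "index_fallback_all_genes"
    retained <- analyzed
  }
  if (length(retained) < 2L) {
    rs_abort("fewer than 2 analyzed genes; no index can be built",
             "refstab_error_insufficient")
  }
  idx <- bestkeeper_index(x, retained)
  corr <- correlate_with_index(x, idx, genes = analyzed)

  tab <- merge(desc, corr, by = "gene", all.x = TRUE, sort = FALSE)
  tab <- tab[match(x$genes, tab$gene), ]
  tab$r[tab$gene %in% exclude] <- NA_real_
  tab$p[tab$gene %in% exclude] <- NA_real_
  rk <- rep(NA_integer_, nrow(tab))
  scored <- tab$gene %in% analyzed & !is.na(tab$r)
  rk[scored] <- competition_ranks(tab$r[scored], direction = "descending_better")
  tab$rank <- rk
  rownames(tab) <- NULL
  structure(
    list(table = tab, index = idx, analyzed = analyzed, excluded = exclude,
         sd_flagged = flagged, retained = retained,
         sd_threshold = sd_threshold, diagnostics = diagnostics),
    class = "bestkeeper_result"
  )
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat(sprintf("BestKeeper analysis: %d genes analyzed%s%s\n",
              length(x$analyzed),
              if (length(x$excluded)) paste0(", pre-excluded: ", paste(x$excluded, collapse = ", ")) else "",
              if (length(x$sd_flagged)) paste0(", SD > 1 flagged: ", paste(x$sd_flagged, collapse = ", ")) else ""))
  tab <- x$table[order(is.na(x$table$rank), x$table$rank), c("gene", "sd_cp", "cv_pct", "r", "p", "rank")]
  for (col in c("sd_cp", "cv_pct", "r", "p")) tab[[col]] <- ifelse(is.na(tab[[col]]), "-", fmt_num(tab[[col]]))
  print(tab, row.names = FALSE)
  invisible(x)
}
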