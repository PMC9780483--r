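#' Published osteosarcoma cell-line panel scores
#'
#' Per-method stability scores from a published RT-qPCR reference-gene
#' study of 12 candidate genes across four human osteosarcoma cell lines
#' (HOS, Saos-2, MG-63, U2OS): geNorm M at exclusion, NormFinder stability,
#' and BestKeeper r. The two genes removed before the BestKeeper step
#' (RPL-29, GUSB — the tool caps its panel at 10 genes) have no r value.
#' Shipped as a worked example for the consensus module; load it with
#' [load_panel_scores()].
#'
#' @name osteosarcoma_panel_scores
#' @keywords datasets
NULL

#' Load the bundled osteosarcoma panel scores
#'
#' @return data.frame with columns `gene`, `genorm_m`,
#'   `normfinder_stability`, `bestkeeper_r` (NA for pre-excluded genes).
#' @export
load_panel_scores <- function() {
  path <- system.file("extdata", "osteosarcoma_panel_scores.tsv",
                      package = "refstab", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Consensus ranking from per-method score columns
#'
#' Convenience wrapper for score tables like [load_panel_scores()]:
#' derives competition ranks per method (geNorm M and NormFinder stability
#' ascending-better, BestKeeper r descending-better with missing r ranked
#' after all scored genes by ascending geNorm M) and aggregates them by the
#' geometric mean of ranks.
#'
#' @param scores data.frame with columns `gene`, `genorm_m`,
#'   `normfinder_stability`, `bestkeeper_r`.
#' @return a `consensus_ranking`.
#' @export
consensus_from_scores <- function(scores) {
  need <- c("gene", "genorm_m", "normfinder_stability", "bestkeeper_r")
  if (!all(need %in% names(scores))) {
    rs_abort(sprintf("score table needs columns: %s", paste(need, collapse = ", ")),
             "refstab_error_format")
  }
  rk <- cbind(
    genorm = competition_ranks(scores$genorm_m),
    normfinder = competition_ranks(scores$normfinder_stability),
    bestkeeper = competition_ranks(scores$bestkeeper_r,
                                   direction = "descending_better",
                                   missing_rank_by = scores$genorm_m)
  )
  rownames(rk) <- scores$gene
  consensus_from_ranks(rk)
}
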