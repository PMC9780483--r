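#' Run the full reference-gene stability workflow
#'
#' Orchestrates the paper-style workflow: read/collapse Cp data, transform
#' to relative quantities, run the selected stability methods, aggregate
#' them into a consensus ranking, and (optionally) write a report bundle of
#' plain-text artifacts.
#'
#' When the panel exceeds BestKeeper's gene cap and no explicit exclusion
#' list is supplied, the genes ranked worst on average by geNorm and
#' NormFinder are pre-excluded (mirroring the common practice of removing
#' the most unstable genes flagged simultaneously by both methods); the
#' choice is logged and recorded in the manifest.
#'
#' @param cp a `cp_matrix`, or a path to a Cp table.
#' @param layout table layout when `cp` is a path (see [read_cp_table()]).
#' @param groups optional sample -> group mapping (named vector or file
#'   path); defaults to groups carried by the matrix.
#' @param efficiencies scalar or per-gene named vector (or path to a
#'   two-column table); default 2.
#' @param methods subset of `c("genorm", "normfinder", "bestkeeper")`.
#' @param max_genes BestKeeper gene cap (default 10).
#' @param exclude explicit BestKeeper pre-exclusion list.
#' @param out_dir if non-NULL, the report bundle is written there.
#' @param verbose emit progress messages.
#' @return (invisibly) a list with `cp`, `q`, `genorm`, `normfinder`,
#'   `bestkeeper`, `consensus`, `bestkeeper_excluded`, `notes`.
#' @export
run_pipeline <- function(cp, layout = "wide", groups = NULL, efficiencies = 2,
                         methods = c("genorm", "normfinder", "bestkeeper"),
                         max_genes = 10L, exclude = NULL, out_dir = NULL,
                         verbose = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  notes <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    notes <<- c(notes, msg)
    if (verbose) message(msg)
  }

  if (is.character(cp)) {
    cp <- read_cp_table(cp, layout = layout, groups = groups)  # handles well expansion
  } else if (!is.null(groups)) {
    if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
      gt <- utils::read.table(groups, header = TRUE, sep = infer_sep(groups),
                              stringsAsFactors = FALSE)
      groups <- stats::setNames(as.character(gt[[2L]]), as.character(gt[[1L]]))
    }
    if (!is.null(cp$replicate_map) && !any(cp$samples %in% names(groups))) {
      groups <- stats::setNames(groups[cp$replicate_map$bio_sample],
                                cp$replicate_map$sample)
    }
    cp$groups <- groups[cp$samples]
    names(cp$groups) <- cp$samples
    cp <- validate_cp_matrix(cp)
  }
  if (!inherits(cp, "cp_matrix")) rs_abort("cp must be a cp_matrix or a file path", "refstab_error_input")
  if (!is.null(cp$replicate_map)) {
    cp <- collapse_replicates(cp)
    say("collapsed technical replicates: %d biological samples", length(cp$samples))
  }
  if (is.character(efficiencies) && length(efficiencies) == 1L && file.exists(efficiencies)) {
    efficiencies <- read_efficiency_table(efficiencies)
  }
  q <- to_relative_quantities(cp, efficiencies = efficiencies)

  res <- list(cp = cp, q = q, genorm = NULL, normfinder = NULL,
              bestkeeper = NULL, consensus = NULL,
              bestkeeper_excluded = NULL, notes = NULL)

  if ("genorm" %in% methods) {
    res$genorm <- genorm(q)
    unreliable <- res$genorm$table$gene[res$genorm$table$unreliable]
    if (length(unreliable)) say("geNorm flags M > 1.5 for: %s", paste(unreliable, collapse = ", "))
    say("geNorm most stable pair: %s + %s", res$genorm$final_pair[1L], res$genorm$final_pair[2L])
  }
  if ("normfinder" %in% methods) {
    if (is.null(cp$groups)) {
      say("no group mapping: NormFinder falls back to the ungrouped analysis")
    }
    res$normfinder <- normfinder(q, groups = cp$groups)
    if (!is.null(res$normfinder$best_pair)) {
      say("NormFinder best two-gene combination: %s + %s",
          res$normfinder$best_pair$genes[1L], res$normfinder$best_pair$genes[2L])
    }
  }
  if ("bestkeeper" %in% methods) {
    bk_exclude <- exclude
    if (is.null(bk_exclude) && length(cp$genes) > max_genes) {
      if (is.null(res$genorm) || is.null(res$normfinder)) {
        rs_abort(sprintf(
          "panel exceeds BestKeeper's %d-gene cap and no pre-exclusion list is available (needs geNorm + NormFinder or an explicit exclude)",
          max_genes), "refstab_error_config")
      }
      avg <- (res$genorm$table$rank + res$normfinder$table$rank) / 2
      drop_n <- length(cp$genes) - max_genes
      bk_exclude <- res$genorm$table$gene[order(-avg)][seq_len(drop_n)]
      say("pre-excluding %d gene(s) most unstable under geNorm+NormFinder for BestKeeper: %s",
          drop_n, paste(bk_exclude, collapse = ", "))
    }
    res$bestkeeper <- bestkeeper(cp, max_genes = max_genes, exclude = bk_exclude)
    res$bestkeeper_excluded <- bk_exclude
    if (length(res$bestkeeper$sd_flagged)) {
      say("BestKeeper SD > 1 flag: %s", paste(res$bestkeeper$sd_flagged, collapse = ", "))
    }
  }

  if (length(methods) >= 2L) {
    res$consensus <- aggregate_stability(genorm = res$genorm,
                                         normfinder = res$normfinder,
                                         bestkeeper = res$bestkeeper)
    say("consensus top gene: %s", res$consensus$final_order[1L])
  } else {
    say("single method requested: consensus skipped")
  }
  res$notes <- notes

  if (!is.null(out_dir)) write_report_bundle(res, out_dir)
  invisible(res)
}

# Plain-text report bundle. Numeric TSVs are written at full precision and
# deterministically; only the manifest carries a timestamp.
write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$genorm)) {
    wr(res$genorm$table, "genorm.tsv")
    wr(res$genorm$v_series, "genorm_v.tsv")
  }
  if (!is.null(res$normfinder)) {
    nf <- res$normfinder$table
    if (isTRUE(res$normfinder$grouped)) {
      d <- res$normfinder$d_shrunk
      s2 <- res$normfinder$sigma2
      colnames(d) <- paste0("d_", colnames(d))
      colnames(s2) <- paste0("sigma2_", colnames(s2))
      nf <- cbind(nf, as.data.frame(d)[nf$gene, , drop = FALSE],
                  as.data.frame(s2)[nf$gene, , drop = FALSE])
      rownames(nf) <- NULL
    }
    wr(nf, "normfinder.tsv")
    if (!is.null(res$normfinder$best_pair)) {
      jsonlite::write_json(
        list(gene_a = res$normfinder$best_pair$genes[1L],
             gene_b = res$normfinder$best_pair$genes[2L],
             combined_stability = res$normfinder$best_pair$stability),
        file.path(out_dir, "normfinder_pair.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(res$bestkeeper)) {
    wr(res$bestkeeper$table, "bestkeeper.tsv")
    wr(data.frame(sample = names(res$bestkeeper$index),
                  index_cp = unname(res$bestkeeper$index)), "bestkeeper_index.tsv")
  }
  if (!is.null(res$consensus)) {
    ct <- res$consensus$table
    ct$geomean <- round(ct$geomean, 3)
    wr(ct, "consensus.tsv")
  }
  summary_lines <- c(
    sprintf("genes analyzed: %d; samples: %d", length(res$cp$genes), length(res$cp$samples)),
    if (!is.null(res$consensus)) sprintf("most stable gene (consensus): %s", res$consensus$final_order[1L]),
    if (!is.null(res$genorm)) sprintf("geNorm most stable pair: %s + %s",
                                      res$genorm$final_pair[1L], res$genorm$final_pair[2L]),
    if (!is.null(res$normfinder) && !is.null(res$normfinder$best_pair))
      sprintf("NormFinder best combination: %s + %s",
              res$normfinder$best_pair$genes[1L], res$normfinder$best_pair$genes[2L]),
    res$notes
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  manifest <- list(
    package = "refstab",
    version = as.character(utils::packageVersion("refstab")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    genes = res$cp$genes, n_samples = length(res$cp$samples),
    groups = if (!is.null(res$cp$groups)) as.list(table(res$cp$groups)) else NULL,
    efficiencies = as.list(res$q$efficiencies),
    methods = c(if (!is.null(res$genorm)) "genorm",
                if (!is.null(res$normfinder)) "normfinder",
                if (!is.null(res$bestkeeper)) "bestkeeper"),
    bestkeeper_pre_excluded = res$bestkeeper_excluded,
    notes = res$notes
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
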