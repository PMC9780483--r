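#' Construct a Cp matrix
#'
#' The central container of the package: a genes x samples matrix of
#' quantification-cycle values (Cp/Cq/Ct), optionally annotated with a
#' technical-replicate map and a sample-to-group assignment (e.g. one group
#' per cell line).
#'
#' @param values numeric matrix, rows = genes, columns = samples (wells when
#'   technical replicates are present). Dimnames are used when `genes` /
#'   `samples` are omitted.
#' @param genes,samples character vectors of unique identifiers.
#' @param groups optional named character vector mapping every sample
#'   (column) to a group label.
#' @param replicate_map optional data.frame with columns `sample`,
#'   `bio_sample`, `replicate` describing which wells belong to the same
#'   biological sample.
#' @return an object of class `cp_matrix`.
#' @export
cp_matrix <- function(values, genes = rownames(values), samples = colnames(values),
                      groups = NULL, replicate_map = NULL) {
  values <- as.matrix(values)
  if (is.null(genes) || is.null(samples)) {
    rs_abort("cp_matrix() needs gene and sample identifiers", "refstab_error_format")
  }
  x <- new_cp_matrix(values, genes, samples, groups, replicate_map)
  validate_cp_matrix(x)
  x
}

# construct without validating (readers apply their on_missing policy first)
new_cp_matrix <- function(values, genes, samples, groups, replicate_map) {
  genes <- as.character(genes)
  samples <- as.character(samples)
  storage.mode(values) <- "double"
  dimnames(values) <- list(genes, samples)
  structure(
    list(values = values, genes = genes, samples = samples,
         groups = groups, replicate_map = replicate_map),
    class = "cp_matrix"
  )
}

#' Validate a Cp matrix
#'
#' Checks the container invariants: unique gene and sample identifiers,
#' all Cp values finite and inside the open interval (0, 45) cycles, a
#' complete group assignment when groups are present, and a consistent
#' replicate map.
#'
#' @param x a `cp_matrix`.
#' @param on_missing `"error"` (default) rejects non-finite cells naming the
#'   offending gene/sample; `"drop_samples"` removes every sample (column)
#'   containing a non-finite Cp. Genes are never dropped.
#' @return the validated (possibly column-reduced) `cp_matrix`, invisibly
#'   for the default path.
#' @export
validate_cp_matrix <- function(x, on_missing = c("error", "drop_samples")) {
  on_missing <- match.arg(on_missing)
  if (anyDuplicated(x$genes)) {
    rs_abort(sprintf("duplicate gene identifier(s): %s",
                     paste(unique(x$genes[duplicated(x$genes)]), collapse = ", ")),
             "refstab_error_format")
  }
  if (anyDuplicated(x$samples)) {
    rs_abort(sprintf("duplicate sample identifier(s): %s",
                     paste(unique(x$samples[duplicated(x$samples)]), collapse = ", ")),
             "refstab_error_format")
  }
  bad <- !is.finite(x$values) | x$values <= 0 | x$values >= 45
  if (any(bad)) {
    if (on_missing == "drop_samples") {
      keep <- !apply(bad, 2L, any)
      if (!any(keep)) rs_abort("all samples contain invalid Cp values", "refstab_error_validation")
      x$values <- x$values[, keep, drop = FALSE]
      x$samples <- x$samples[keep]
      if (!is.null(x$groups)) x$groups <- x$groups[x$samples]
      if (!is.null(x$replicate_map)) {
        x$replicate_map <- x$replicate_map[x$replicate_map$sample %in% x$samples, , drop = FALSE]
      }
    } else {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      rs_abort(sprintf(
        "invalid Cp value %s for gene '%s', sample '%s' (must be finite and in (0, 45) cycles)",
        format(x$values[idx[1L], idx[2L]]), x$genes[idx[1L]], x$samples[idx[2L]]),
        "refstab_error_validation")
    }
  }
  if (!is.null(x$groups)) {
    x$groups <- x$groups[x$samples]
    if (any(is.na(x$groups)) || length(x$groups) != length(x$samples)) {
      miss <- x$samples[is.na(x$groups)]
      rs_abort(sprintf("sample(s) without a group label: %s", paste(miss, collapse = ", ")),
               "refstab_error_validation")
    }
    names(x$groups) <- x$samples
  }
  if (!is.null(x$replicate_map)) {
    rm <- x$replicate_map
    need <- c("sample", "bio_sample", "replicate")
    if (!all(need %in% names(rm))) {
      rs_abort("replicate_map needs columns sample, bio_sample, replicate", "refstab_error_format")
    }
    if (!setequal(rm$sample, x$samples)) {
      rs_abort("replicate_map must cover exactly the samples of the matrix", "refstab_error_format")
    }
  }
  x
}

#' @export
print.cp_matrix <- function(x, ...) {
  cat(sprintf("cp_matrix: %d genes x %d samples", length(x$genes), length(x$samples)))
  if (!is.null(x$replicate_map)) {
    cat(sprintf(" (%d biological samples with technical replicates)",
                length(unique(x$replicate_map$bio_sample))))
  }
  if (!is.null(x$groups)) {
    cat(sprintf("\ngroups: %s", paste(sprintf("%s (n=%d)", names(table(x$groups)),
                                              as.integer(table(x$groups))), collapse = ", ")))
  }
  cat("\nCp range:", paste(fmt_num(range(x$values), 2), collapse = " - "), "cycles\n")
  invisible(x)
}

#' @export
dim.cp_matrix <- function(x) dim(x$values)

#' Read a Cp table from delimited text
#'
#' Two layouts are supported. `wide`: first column gene identifiers,
#' remaining columns one sample each. `long`: columns `sample`, `gene`,
#' `replicate` (optional), `cp`; wells are keyed internally as
#' `<sample>.r<replicate>` and a replicate map is recorded.
#'
#' @param path delimited text file; tab-separated unless the extension is
#'   `.csv` or `sep` is given.
#' @param layout `"wide"` or `"long"`.
#' @param sep field separator override.
#' @param groups optional: path to a two-column (sample, group) delimited
#'   file, or a named character vector.
#' @param on_missing passed to [validate_cp_matrix()].
#' @return a validated [cp_matrix()].
#' @export
read_cp_table <- function(path, layout = c("wide", "long"), sep = NULL,
                          groups = NULL, on_missing = c("error", "drop_samples")) {
  layout <- match.arg(layout)
  on_missing <- match.arg(on_missing)
  sep <- infer_sep(path, sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (layout == "wide") {
    gene_ids <- as.character(raw[[1L]])
    sample_ids <- colnames(raw)[-1L]
    vals <- raw[, -1L, drop = FALSE]
    num <- vapply(vals, function(col) suppressWarnings(as.numeric(as.character(col))),
                  numeric(nrow(vals)))
    num <- matrix(num, nrow = nrow(vals),
                  dimnames = list(gene_ids, sample_ids))
    nonnum <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
    if (nrow(nonnum) > 0L) {
      rs_abort(sprintf("non-numeric Cp '%s' for gene '%s', sample '%s'",
                       as.matrix(vals)[nonnum[1L, 1L], nonnum[1L, 2L]],
                       gene_ids[nonnum[1L, 1L]], sample_ids[nonnum[1L, 2L]]),
               "refstab_error_validation")
    }
    replicate_map <- NULL
  } else {
    names(raw) <- tolower(names(raw))
    if (!all(c("sample", "gene", "cp") %in% names(raw))) {
      rs_abort("long layout needs columns sample, gene[, replicate], cp", "refstab_error_format")
    }
    if (!"replicate" %in% names(raw)) raw$replicate <- 1L
    key <- paste(raw$sample, raw$gene, raw$replicate, sep = "\r")
    if (anyDuplicated(key)) {
      d <- raw[duplicated(key), , drop = FALSE][1L, ]
      rs_abort(sprintf("duplicate (sample, gene, replicate) triple: (%s, %s, %s)",
                       d$sample, d$gene, d$replicate), "refstab_error_format")
    }
    raw$well <- paste0(raw$sample, ".r", raw$replicate)
    gene_ids <- unique(as.character(raw$gene))
    wells <- unique(raw$well)
    num <- matrix(NA_real_, length(gene_ids), length(wells),
                  dimnames = list(gene_ids, wells))
    cpnum <- suppressWarnings(as.numeric(as.character(raw$cp)))
    bad <- which(is.na(cpnum) & !is.na(raw$cp))
    if (length(bad) > 0L) {
      rs_abort(sprintf("non-numeric Cp '%s' for gene '%s', sample '%s'",
                       raw$cp[bad[1L]], raw$gene[bad[1L]], raw$sample[bad[1L]]),
               "refstab_error_validation")
    }
    num[cbind(match(raw$gene, gene_ids), match(raw$well, wells))] <- cpnum
    sample_ids <- wells
    replicate_map <- unique(data.frame(sample = raw$well,
                                       bio_sample = as.character(raw$sample),
                                       replicate = raw$replicate,
                                       stringsAsFactors = FALSE))
  }

  grp <- NULL
  if (!is.null(groups)) {
    if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
      gt <- utils::read.table(groups, header = TRUE, sep = infer_sep(groups),
                              stringsAsFactors = FALSE)
      grp <- stats::setNames(as.character(gt[[2L]]), as.character(gt[[1L]]))
    } else {
      grp <- groups
    }
    # group files usually key biological samples; expand over wells if needed
    if (!is.null(replicate_map) && !any(sample_ids %in% names(grp))) {
      grp <- stats::setNames(grp[replicate_map$bio_sample], replicate_map$sample)
    }
  }
  x <- new_cp_matrix(num, gene_ids, sample_ids, grp, replicate_map)
  validate_cp_matrix(x, on_missing = on_missing)
}

#' Write a Cp matrix to delimited text
#'
#' @param x a `cp_matrix`.
#' @param path output file; `.csv` extension switches to comma separation.
#' @param layout `"wide"` (genes x samples) or `"long"` (sample, gene,
#'   replicate, cp rows).
#' @param sep separator override.
#' @return `path`, invisibly.
#' @export
write_cp_table <- function(x, path, layout = c("wide", "long"), sep = NULL) {
  layout <- match.arg(layout)
  sep <- infer_sep(path, sep)
  if (layout == "wide") {
    df <- data.frame(gene = x$genes, x$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    rm <- x$replicate_map
    if (is.null(rm)) {
      rm <- data.frame(sample = x$samples, bio_sample = x$samples, replicate = 1L)
    }
    long <- do.call(rbind, lapply(seq_along(x$genes), function(i) {
      data.frame(sample = rm$bio_sample[match(x$samples, rm$sample)],
                 gene = x$genes[i],
                 replicate = rm$replicate[match(x$samples, rm$sample)],
                 cp = x$values[i, ], stringsAsFactors = FALSE)
    }))
    utils::write.table(long, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Average technical replicates
#'
#' Collapses each gene's technical-replicate wells to one Cp per biological
#' sample by the arithmetic mean (on the Cp scale this equals the geometric
#' mean of the corresponding relative quantities). The replicate map is
#' cleared; groups are re-keyed to biological samples.
#'
#' @param x a `cp_matrix` with a replicate map.
#' @param method only `"mean"`.
#' @return a `cp_matrix` with one column per biological sample.
#' @export
collapse_replicates <- function(x, method = c("mean")) {
  method <- match.arg(method)
  if (is.null(x$replicate_map)) {
    rs_abort("collapse_replicates() needs a replicate map", "refstab_error_input")
  }
  rm <- x$replicate_map
  bio <- unique(rm$bio_sample)
  out <- matrix(NA_real_, length(x$genes), length(bio),
                dimnames = list(x$genes, bio))
  for (b in bio) {
    wells <- rm$sample[rm$bio_sample == b]
    if (length(wells) == 0L) {
      rs_abort(sprintf("biological sample '%s' has zero replicates", b),
               "refstab_error_missing")
    }
    out[, b] <- rowMeans(x$values[, wells, drop = FALSE])
  }
  grp <- NULL
  if (!is.null(x$groups)) {
    g <- vapply(bio, function(b) {
      u <- unique(x$groups[rm$sample[rm$bio_sample == b]])
      if (length(u) != 1L) {
        rs_abort(sprintf("biological sample '%s' has inconsistent group labels", b),
                 "refstab_error_validation")
      }
      u
    }, character(1L))
    grp <- stats::setNames(g, bio)
  }
  cp_matrix(out, x$genes, bio, groups = grp, replicate_map = NULL)
}

#' Convert Cp values to relative quantities
#'
#' Applies the efficiency-based transform Q\[g, s\] = E_g^-(Cp\[g, s\] -
#' calibrator_g). With the default calibrator (each gene's minimum Cp over
#' samples) quantities lie in (0, 1\] with the per-gene maximum exactly 1.
#' With perfect doubling chemistry (E = 2) this is the familiar Q =
#' 2^-dCp. All stability statistics downstream depend only on ratios of Q
#' between samples, so the calibrator choice does not affect them.
#'
#' @param x a `cp_matrix` (collapse replicates first if present).
#' @param efficiencies scalar or per-gene named vector of amplification
#'   efficiencies, each in (1, 2.2]. Default 2 (perfect doubling).
#' @param calibrator only `"per_gene_min"`.
#' @return an object of class `quantity_matrix` with elements `q` (genes x
#'   samples), `genes`, `samples`, `calibrator`, `efficiencies`, `groups`.
#' @export
to_relative_quantities <- function(x, efficiencies = 2,
                                   calibrator = c("per_gene_min")) {
  calibrator <- match.arg(calibrator)
  if (is.null(names(efficiencies))) {
    if (length(efficiencies) != 1L) {
      rs_abort("unnamed efficiencies must be a single scalar", "refstab_error_parameter")
    }
    eff <- stats::setNames(rep(as.numeric(efficiencies), length(x$genes)), x$genes)
  } else {
    eff <- efficiencies[x$genes]
    if (any(is.na(eff))) {
      rs_abort(sprintf("no efficiency for gene(s): %s",
                       paste(x$genes[is.na(eff)], collapse = ", ")),
               "refstab_error_parameter")
    }
  }
  if (any(!is.finite(eff)) || any(eff <= 1) || any(eff > 2.2)) {
    rs_abort("amplification efficiencies must lie in (1, 2.2]", "refstab_error_parameter")
  }
  cal <- apply(x$values, 1L, min)
  q <- eff ^ (-(x$values - cal))   # eff and cal recycle down columns (per gene)
  structure(
    list(q = q, genes = x$genes, samples = x$samples,
         calibrator = stats::setNames(cal, x$genes),
         efficiencies = eff, groups = x$groups),
    class = "quantity_matrix"
  )
}

#' @export
print.quantity_matrix <- function(x, ...) {
  cat(sprintf("quantity_matrix: %d genes x %d samples; efficiencies %s\n",
              length(x$genes), length(x$samples),
              paste(fmt_num(range(x$efficiencies), 2), collapse = "-")))
  invisible(x)
}

# log2 quantities, the working scale of geNorm and NormFinder
log2_q <- function(q) {
  if (!inherits(q, "quantity_matrix")) {
    rs_abort("expected a quantity_matrix (see to_relative_quantities())", "refstab_error_input")
  }
  log2(q$q)
}

#' Read a two-column gene -> efficiency table
#'
#' @param path delimited file with columns (gene, efficiency).
#' @return named numeric vector.
#' @export
read_efficiency_table <- function(path) {
  t <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                         stringsAsFactors = FALSE)
  stats::setNames(as.numeric(t[[2L]]), as.character(t[[1L]]))
}
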