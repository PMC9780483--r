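#' Define a synthetic Cp world with known stability ground truth
#'
#' The generative model mirrors the decomposition all three stability
#' algorithms assume for grouped RT-qPCR data:
#' Cp\[g, s, rep\] = baseline_g + offset\[g, group(s)\] + loading_s +
#' noise\[g, s\] + replicate jitter, with every noise term zero-mean
#' normal on the Cp scale (log-normal quantities). `loading_s` is shared by
#' all genes of a sample — the common RNA-input/RT-efficiency shift that
#' reference-gene normalization exists to remove.
#'
#' @param genes gene identifiers.
#' @param baseline per-gene baseline Cp, each in (5, 40) cycles.
#' @param noise_sd per-gene biological/stability noise SD (cycles).
#' @param group_offsets genes x groups matrix of group-specific expression
#'   offsets (cycles); 0 = stably expressed across groups.
#' @param loading_sd SD of the shared per-sample loading shift (cycles).
#' @param replicate_sd SD of the per-well technical jitter (cycles).
#' @param groups group labels (e.g. cell lines).
#' @param samples_per_group biological samples per group.
#' @param replicates technical replicates (wells) per biological sample.
#' @param seed integer seed recorded in the truth and used by
#'   [simulate_cp()].
#' @return an object of class `synthetic_truth`; `designed_stable` names
#'   the unique gene with minimal noise SD and all-zero offsets.
#' @export
synthetic_truth <- function(genes, baseline, noise_sd, group_offsets = NULL,
                            loading_sd = 0.5, replicate_sd = 0.1,
                            groups = c("HOS", "Saos-2", "MG-63", "U2OS"),
                            samples_per_group = 6L, replicates = 3L, seed = 1L) {
  k <- length(genes)
  if (anyDuplicated(genes)) rs_abort("duplicate gene identifiers", "refstab_error_config")
  if (length(baseline) != k || length(noise_sd) != k) {
    rs_abort("baseline and noise_sd must match the gene count", "refstab_error_config")
  }
  if (any(baseline <= 5 | baseline >= 40)) {
    rs_abort("baselines must lie in (5, 40) cycles", "refstab_error_config")
  }
  if (any(noise_sd < 0) || loading_sd < 0 || replicate_sd < 0) {
    rs_abort("all SDs must be >= 0", "refstab_error_config")
  }
  if (is.null(group_offsets)) {
    group_offsets <- matrix(0, k, length(groups))
  }
  group_offsets <- as.matrix(group_offsets)
  if (!all(dim(group_offsets) == c(k, length(groups)))) {
    rs_abort("group_offsets must be genes x groups", "refstab_error_config")
  }
  dimnames(group_offsets) <- list(genes, groups)
  if (samples_per_group < 1L || replicates < 1L) {
    rs_abort("need >= 1 sample per group and >= 1 replicate", "refstab_error_config")
  }
  zero_off <- rowSums(abs(group_offsets)) == 0
  cand <- which(noise_sd == min(noise_sd) & zero_off)
  designed <- if (length(cand) == 1L) genes[cand] else NA_character_
  structure(
    list(genes = genes,
         baseline = stats::setNames(baseline, genes),
         noise_sd = stats::setNames(noise_sd, genes),
         group_offsets = group_offsets,
         loading_sd = loading_sd, replicate_sd = replicate_sd,
         groups = groups, samples_per_group = as.integer(samples_per_group),
         replicates = as.integer(replicates), seed = as.integer(seed),
         designed_stable = designed),
    class = "synthetic_truth"
  )
}

#' Simulate a grouped Cp matrix from a synthetic truth
#'
#' Deterministic given the truth's seed: identical truth + seed yields a
#' bit-identical matrix. Wells are named `<group>_<i>.r<rep>` and carry a
#' replicate map and group labels, matching what [read_cp_table()] produces
#' from a long-layout file.
#'
#' @param truth a [synthetic_truth()].
#' @param seed optional override of `truth$seed`.
#' @return list with `cp` (a `cp_matrix`) and `truth` (with the seed
#'   actually used).
#' @export
simulate_cp <- function(truth, seed = truth$seed) {
  if (!inherits(truth, "synthetic_truth")) {
    rs_abort("simulate_cp() needs a synthetic_truth", "refstab_error_config")
  }
  truth$seed <- as.integer(seed)
  set.seed(truth$seed)
  k <- length(truth$genes)
  bio <- unlist(lapply(truth$groups, function(g) {
    sprintf("%s_%d", g, seq_len(truth$samples_per_group))
  }))
  grp_of_bio <- stats::setNames(rep(truth$groups, each = truth$samples_per_group), bio)
  n_bio <- length(bio)

  loading <- stats::rnorm(n_bio, 0, truth$loading_sd)
  noise <- matrix(stats::rnorm(k * n_bio, 0, truth$noise_sd), k, n_bio)  # SD recycles per gene
  base_mat <- truth$baseline + truth$group_offsets[, grp_of_bio, drop = FALSE] +
    rep(loading, each = k) + noise

  wells <- as.vector(vapply(bio, function(b) sprintf("%s.r%d", b, seq_len(truth$replicates)),
                            character(truth$replicates)))
  vals <- base_mat[, rep(seq_len(n_bio), each = truth$replicates), drop = FALSE] +
    matrix(stats::rnorm(k * length(wells), 0, truth$replicate_sd), k, length(wells))
  dimnames(vals) <- list(truth$genes, wells)

  rep_map <- data.frame(
    sample = wells,
    bio_sample = rep(bio, each = truth$replicates),
    replicate = rep(seq_len(truth$replicates), times = n_bio),
    stringsAsFactors = FALSE
  )
  groups <- stats::setNames(grp_of_bio[rep_map$bio_sample], rep_map$sample)
  cp <- cp_matrix(vals, truth$genes, wells, groups = groups, replicate_map = rep_map)
  list(cp = cp, truth = truth)
}

#' Built-in synthetic worlds
#'
#' Three presets, each a 12-gene, 4-group (cell-line) design run in
#' triplicate wells:
#' \describe{
#'   \item{clean}{one designed stable gene (`REF01`, noise SD 0.05 cycles,
#'     no group offsets) among 11 noisier genes (SD 0.5); loading SD 0.8.}
#'   \item{grouped-bias}{as `clean` with moderate gene noise (0.2) plus a
#'     single 2-cycle group-specific offset on `REF06` in the second group
#'     — detectable only by a group-aware method.}
#'   \item{paper-like}{baselines emulating a published osteosarcoma
#'     cell-line panel profile (18S lowest at ~15.7 cycles, PBGD highest at
#'     ~30.7), uniform moderate noise.}
#' }
#'
#' @param name preset name.
#' @param seed seed stored in the truth.
#' @param samples_per_group,replicates design overrides.
#' @return a [synthetic_truth()].
#' @export
preset_truth <- function(name = c("clean", "grouped-bias", "paper-like"),
                         seed = 1L, samples_per_group = 6L, replicates = 3L) {
  name <- match.arg(name)
  groups <- c("HOS", "Saos-2", "MG-63", "U2OS")
  if (name == "clean") {
    genes <- sprintf("REF%02d", 1:12)
    synthetic_truth(genes,
                    baseline = seq(16, 31, length.out = 12),
                    noise_sd = c(0.05, rep(0.5, 11)),
                    loading_sd = 0.8, replicate_sd = 0.1,
                    groups = groups, samples_per_group = samples_per_group,
                    replicates = replicates, seed = seed)
  } else if (name == "grouped-bias") {
    genes <- sprintf("REF%02d", 1:12)
    off <- matrix(0, 12, 4)
    off[6L, 2L] <- 2          # REF06 shifted 2 cycles in Saos-2 only
    synthetic_truth(genes,
                    baseline = seq(16, 31, length.out = 12),
                    noise_sd = c(0.05, rep(0.2, 11)),
                    group_offsets = off,
                    loading_sd = 0.8, replicate_sd = 0.1,
                    groups = groups, samples_per_group = samples_per_group,
                    replicates = replicates, seed = seed)
  } else {
    genes <- c("18S", "GAPDH", "ACTB", "B2M", "PPIA", "RPL-29",
               "PUM1", "HPRT-1", "TBP", "ALAS1", "GUSB", "PBGD")
    baseline <- c(15.7, 18.5, 19.2, 20.4, 21.3, 22.6,
                  24.1, 25.0, 26.4, 27.2, 28.6, 30.7)
    synthetic_truth(genes, baseline = baseline,
                    noise_sd = c(0.38, rep(0.45, 10), 0.90),
                    loading_sd = 0.5, replicate_sd = 0.15,
                    groups = groups, samples_per_group = samples_per_group,
                    replicates = replicates, seed = seed)
  }
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d genes, %d groups x %d samples x %d replicates (seed %d)\n",
              length(x$genes), length(x$groups), x$samples_per_group, x$replicates, x$seed))
  if (!is.na(x$designed_stable)) cat("designed stable gene:", x$designed_stable, "\n")
  invisible(x)
}
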