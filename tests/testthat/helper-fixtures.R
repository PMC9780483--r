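# Builders for small in-memory fixtures.

# quantity_matrix straight from a positive matrix (bypasses the Cp route
# so algorithm tests can state Q values directly)
q_obj <- function(qmat, groups = NULL) {
  qmat <- as.matrix(qmat)
  if (is.null(rownames(qmat))) rownames(qmat) <- sprintf("g%d", seq_len(nrow(qmat)))
  if (is.null(colnames(qmat))) colnames(qmat) <- sprintf("s%d", seq_len(ncol(qmat)))
  structure(list(q = qmat, genes = rownames(qmat), samples = colnames(qmat),
                 calibrator = NULL, efficiencies = NULL, groups = groups),
            class = "quantity_matrix")
}

# cp_matrix from a plain matrix with Cp values in range
cp_obj <- function(vals, groups = NULL) {
  vals <- as.matrix(vals)
  if (is.null(rownames(vals))) rownames(vals) <- sprintf("g%d", seq_len(nrow(vals)))
  if (is.null(colnames(vals))) colnames(vals) <- sprintf("s%d", seq_len(ncol(vals)))
  cp_matrix(vals, groups = groups)
}

# random positive quantity matrix (log-normal), reproducible
random_q <- function(genes, samples, seed, groups = NULL) {
  set.seed(seed)
  q_obj(matrix(2^rnorm(genes * samples), genes, samples), groups = groups)
}

# random Cp matrix: per-gene baseline with modest well-to-well scatter
random_cp <- function(genes, samples, seed, noise = 0.4) {
  set.seed(seed)
  base <- runif(genes, 18, 30)
  cp_obj(base + matrix(rnorm(genes * samples, 0, noise), genes, samples))
}
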