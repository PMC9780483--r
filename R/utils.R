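#' @keywords internal
"_PACKAGE"

# Classed conditions so callers/tests can distinguish failure modes.
rs_abort <- function(message, class) {
  stop(structure(
    class = c(class, "refstab_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @export
geo_mean <- function(x) {
  if (length(x) == 0L) rs_abort("geo_mean() needs a non-empty vector", "refstab_error_input")
  if (any(!is.finite(x)) || any(x <= 0)) {
    rs_abort("geo_mean() needs finite, strictly positive values", "refstab_error_input")
  }
  exp(mean(log(x)))
}

# Delimiter from extension unless given explicitly.
infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

fmt_num <- function(x, digits = 3) formatC(round(x, digits), format = "f", digits = digits)
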