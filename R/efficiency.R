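#' Estimate amplification efficiency from a dilution series
#'
#' Fits the standard curve Cp ~ log10(relative concentration) by ordinary
#' least squares and converts the slope to an amplification efficiency via
#' E = 10^(-1/slope). Perfect doubling chemistry gives slope
#' -1/log10(2) ~ -3.32 and E = 2. The squared correlation of the fit is
#' returned so callers can enforce the usual r^2 > 0.99 quality gate.
#'
#' @param concentration relative template concentrations (e.g. a 10-fold
#'   series 0.01-10); at least 3 distinct values are required and a span of
#'   at least two orders of magnitude is recommended (a narrower series
#'   triggers a warning).
#' @param cp observed Cp at each concentration. Replicate wells may simply
#'   repeat concentrations.
#' @param gene optional gene identifier carried into the result.
#' @return an object of class `efficiency_estimate`: list with `gene`,
#'   `slope`, `efficiency`, `r_squared`, `n_points`, and `diagnostics`
#'   (character vector; contains `"positive_slope"` for an inverted series).
#' @export
estimate_efficiency <- function(concentration, cp, gene = NA_character_) {
  concentration <- as.numeric(concentration)
  cp <- as.numeric(cp)
  if (length(concentration) != length(cp)) {
    rs_abort("concentration and cp must have equal length", "refstab_error_input")
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0) || any(!is.finite(cp))) {
    rs_abort("dilution series needs finite Cp and positive concentrations", "refstab_error_input")
  }
  distinct <- unique(concentration)
  if (length(distinct) < 3L) {
    rs_abort("standard curve needs >= 3 distinct dilution points", "refstab_error_fit")
  }
  lc <- log10(concentration)
  if (stats::var(lc) == 0) {
    rs_abort("zero variance in dilution concentrations", "refstab_error_fit")
  }
  diagnostics <- character(0)
  if (diff(range(lc)) < 2) {
    warning("dilution series spans less than two orders of magnitude")
    diagnostics <- c(diagnostics, "narrow_series")
  }
  fit <- stats::lm(cp ~ lc)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope == 0) {
    rs_abort("degenerate standard-curve fit (zero/undefined slope)", "refstab_error_fit")
  }
  if (slope > 0) diagnostics <- c(diagnostics, "positive_slope")
  r2 <- stats::cor(cp, lc)^2
  structure(
    list(gene = gene, slope = slope, efficiency = 10^(-1 / slope),
         r_squared = r2, n_points = length(distinct), diagnostics = diagnostics),
    class = "efficiency_estimate"
  )
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("efficiency_estimate%s: slope %.4f, E = %.4f, r^2 = %.4f (%d dilution points)\n",
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              x$slope, x$efficiency, x$r_squared, x$n_points))
  if (length(x$diagnostics)) cat("diagnostics:", paste(x$diagnostics, collapse = ", "), "\n")
  invisible(x)
}
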