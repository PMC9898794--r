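# Molecular-weight calibration: log-linear map between fraction index and
# apparent molecular weight, fitted from protein standards, plus the
# assembled-vs-monomer mass partition it enables.

#' Fit a fraction / molecular-weight calibration
#'
#' Ordinary least squares of log10(MW in kDa) on apex fraction:
#' \code{log10(mw) = intercept + slope * fraction}. For size-exclusion
#' chromatography the slope is expected to be negative (large complexes
#' elute first); a non-negative slope triggers a warning, not an error.
#'
#' @param standards data.frame with columns \code{fraction} (apex
#'   fraction of each standard's elution peak) and \code{mw_kda}; at
#'   least 2 standards with distinct fractions.
#' @return object of class \code{CalibrationModel}: \code{slope},
#'   \code{intercept}, \code{residuals}, \code{standards}.
#' @export
fit_calibration <- function(standards) {
  if (nrow(standards) < 2L)
    stop("calibration needs at least 2 standards")
  if (length(unique(standards$fraction)) < 2L)
    stop("calibration standards must have distinct apex fractions")
  if (any(standards$mw_kda <= 0))
    stop("standard molecular weights must be positive")
  fit <- stats::lm(log10(mw_kda) ~ fraction, data = standards)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0)
    warning("calibration slope is non-negative; expected MW to decrease with fraction")
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1L]),
         residuals = unname(stats::residuals(fit)),
         standards = standards),
    class = "CalibrationModel")
}

#' @export
print.CalibrationModel <- function(x, ...) {
  cat(sprintf("CalibrationModel: log10(kDa) = %.4f %+.4f * fraction (%d standards, RMSE %.3g)\n",
              x$intercept, x$slope, nrow(x$standards),
              sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Apparent molecular weight of a fraction
#'
#' Evaluates the calibration at (possibly fractional) fraction indices.
#' Values outside [1, n_fractions] are still returned; an
#' \code{"extrapolated"} attribute flags them when \code{n_fractions} is
#' given.
#'
#' @param model a \code{CalibrationModel}.
#' @param fraction numeric vector of fraction positions.
#' @param n_fractions optional design size used to flag extrapolation.
#' @return apparent MW in kDa.
#' @export
apparent_mw <- function(model, fraction, n_fractions = NULL) {
  mw <- 10^(model$intercept + model$slope * fraction)
  if (!is.null(n_fractions))
    attr(mw, "extrapolated") <- fraction < 1 | fraction > n_fractions
  mw
}

#' Fraction position of a molecular weight (inverse calibration)
#' @param model a \code{CalibrationModel}.
#' @param mw_kda molecular weight(s) in kDa.
#' @return fraction position(s).
#' @export
mw_to_fraction <- function(model, mw_kda) {
  (log10(mw_kda) - model$intercept) / model$slope
}

#' Assembled vs monomer mass partition per sample
#'
#' For each (condition, replicate) sample, the percentage of summed
#' protein mass eluting in fractions whose apparent MW exceeds
#' \code{factor} times the protein's monomer MW ("assembled" range),
#' summed over all proteins with a known monomer MW. The two percentages
#' partition 100% at the chosen factor.
#'
#' @param dataset an \code{ElutionDataset} with monomer MW metadata.
#' @param model a \code{CalibrationModel}.
#' @param factor monomer distance factor (default 1.2): signal counts as
#'   assembled where apparent MW > factor * monomer MW.
#' @return data.frame with one row per sample: \code{condition},
#'   \code{replicate}, \code{pct_assembled}, \code{pct_monomer}; the
#'   number of proteins excluded for missing monomer MW is attached as
#'   attribute \code{"n_excluded"}.
#' @export
assembled_mass_split <- function(dataset, model, factor = 1.2) {
  mw <- dataset$meta$monomer_mw_kda
  has_mw <- !is.na(mw) & mw > 0
  if (!any(has_mw))
    stop("no protein has a known monomer molecular weight")
  app <- apparent_mw(model, seq_len(dataset$n_fractions))
  # assembled[p, f]: does fraction f lie in protein p's assembled range?
  assembled <- outer(factor * mw[has_mw], app, FUN = "<")
  grid <- expand.grid(replicate = seq_len(dataset$n_replicates),
                      condition = .CONDITIONS, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tot <- 0; asm <- 0
    for (f in seq_len(dataset$n_fractions)) {
      col <- sample_cols(dataset, condition = grid$condition[i],
                         replicate = grid$replicate[i], fraction = f)
      v <- dataset$intensity[has_mw, col]
      tot <- tot + sum(v)
      asm <- asm + sum(v[assembled[, f]])
    }
    pct <- if (tot > 0) 100 * asm / tot else NA_real_
    data.frame(condition = grid$condition[i], replicate = grid$replicate[i],
               pct_assembled = pct, pct_monomer = 100 - pct)
  })
  out <- do.call(rbind, res)
  attr(out, "n_excluded") <- sum(!has_mw)
  out
}
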