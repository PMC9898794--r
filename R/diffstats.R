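# Summed-fraction and per-fraction differential analysis: normalization,
# left-censored MNAR imputation, empirical-Bayes moderated two-group
# test, Benjamini-Hochberg adjustment, and differential-protein calling.
#
# Abundance matrices are plain numeric matrices, proteins x samples, with
# NA marking missing values; the attribute "scale" records whether the
# matrix is "raw" or "log2".

#' Sum fraction intensities per condition and replicate
#'
#' Collapses the elution dimension: for each protein and each
#' (condition, replicate) sample, sums the intensities over all fractions
#' (missing treated as 0). A protein with zero total in a sample is
#' missing (NA) in that sample.
#'
#' @param dataset an \code{ElutionDataset}.
#' @return numeric matrix proteins x (2 * n_replicates) with NA for
#'   missing, columns named \code{<condition>_<replicate>},
#'   attribute \code{scale = "raw"}.
#' @export
sum_fractions <- function(dataset) {
  grid <- expand.grid(replicate = seq_len(dataset$n_replicates),
                      condition = .CONDITIONS, stringsAsFactors = FALSE)
  out <- matrix(NA_real_, nrow = n_proteins(dataset), ncol = nrow(grid))
  colnames(out) <- paste(grid$condition, grid$replicate, sep = "_")
  for (i in seq_len(nrow(grid))) {
    cols <- sample_cols(dataset, condition = grid$condition[i],
                        replicate = grid$replicate[i])
    s <- rowSums(dataset$intensity[, cols, drop = FALSE])
    s[s == 0] <- NA_real_
    out[, i] <- s
  }
  rownames(out) <- protein_labels(dataset)
  attr(out, "scale") <- "raw"
  attr(out, "groups") <- grid$condition
  out
}

# generalized log2: ~ log2(x) for large x, finite at 0
glog2 <- function(x, c) log2((x + sqrt(x^2 + c^2)) / 2)

#' Log2 normalization of a raw abundance matrix
#'
#' Two modes. \code{"vsn_glog"} (default) is a variance-stabilizing
#' transform: per-sample scale factors are first estimated from the
#' median of observed values and refined so the medians of transformed
#' values agree across samples, then a generalized log2
#' \code{glog2(x) = log2((x + sqrt(x^2 + c^2)) / 2)} is applied with the
#' glog width \code{c} set to a low quantile of the scaled data, followed
#' by two rounds of per-sample affine (median) recentring. For large
#' values glog2 approaches plain log2. \code{"median_log2"} is log2
#' followed by subtraction of each sample's median of observed values.
#' Missing values stay missing in both modes.
#'
#' @param matrix raw abundance matrix (NA = missing).
#' @param method \code{"vsn_glog"} or \code{"median_log2"}.
#' @param glog_c width of the generalized log; defaults to the 1st
#'   percentile of the scaled observed values (a detection-floor proxy),
#'   so the transform stabilizes variance near the floor and approaches
#'   plain log2 for values far above it.
#' @return log2-scale matrix with attribute \code{scale = "log2"}.
#' @export
log2_normalize <- function(matrix, method = c("vsn_glog", "median_log2"),
                           glog_c = NULL) {
  method <- match.arg(method)
  x <- matrix
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 2L))
    stop("sample(s) with <2 observed values: ",
         paste(colnames(x)[n_obs < 2L], collapse = ", "))
  if (method == "median_log2") {
    out <- log2(x)
    med <- apply(out, 2L, stats::median, na.rm = TRUE)
    out <- sweep(out, 2L, med - mean(med))
  } else {
    med_raw <- apply(x, 2L, stats::median, na.rm = TRUE)
    ref <- exp(mean(log(med_raw)))
    scaled <- sweep(x, 2L, ref / med_raw, `*`)
    c0 <- if (is.null(glog_c))
      stats::quantile(scaled, 0.01, na.rm = TRUE, names = FALSE) else glog_c
    if (!is.finite(c0) || c0 <= 0) c0 <- 1
    out <- glog2(scaled, c0)
    for (iter in 1:2) {
      med <- apply(out, 2L, stats::median, na.rm = TRUE)
      out <- sweep(out, 2L, med - mean(med))
    }
  }
  for (a in c("groups")) attr(out, a) <- attr(matrix, a)
  attr(out, "scale") <- "log2"
  attr(out, "normalization") <- method
  out
}

#' Left-censored MNAR imputation
#'
#' Missing-not-at-random imputation for label-free proteomics: for each
#' sample with observed mean \eqn{\mu_s} and standard deviation
#' \eqn{\sigma_s} on the log2 scale, every missing value is replaced by
#' an independent draw from
#' \eqn{Normal(\mu_s - shift \cdot \sigma_s, (width \cdot \sigma_s)^2)},
#' placing imputed values in the left tail of the observed distribution.
#' Observed values are untouched.
#'
#' @param matrix log2-scale abundance matrix (NA = missing).
#' @param shift downshift in sample standard deviations (default 1.8).
#' @param width spread of the imputation distribution in sample standard
#'   deviations (default 0.3).
#' @param seed integer seed making the draws reproducible.
#' @return matrix without NAs; logical attribute \code{"imputed"} marks
#'   the filled cells.
#' @export
impute_mnar <- function(matrix, shift = 1.8, width = 0.3, seed = 1L) {
  x <- matrix
  n_obs <- colSums(!is.na(x))
  if (any(n_obs < 2L))
    stop("sample(s) with <2 observed values cannot be imputed")
  mask <- is.na(x)
  if (any(mask)) {
    set.seed(seed)
    for (j in seq_len(ncol(x))) {
      miss <- which(mask[, j])
      if (!length(miss)) next
      mu <- mean(x[, j], na.rm = TRUE)
      sd <- stats::sd(x[, j], na.rm = TRUE)
      x[miss, j] <- stats::rnorm(length(miss), mu - shift * sd, width * sd)
    }
  }
  attr(x, "imputed") <- mask
  x
}

# Newton inversion of the trigamma function (psigamma deriv = 1), used by
# the moment-matching prior estimator.
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-8
  out[lo] <- 1 / sqrt(y[lo])
  hi <- y > 1e7
  out[hi] <- 1 / y[hi]
  mid <- !(lo | hi)
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:60) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, 2L)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

# Moment-matching estimate of the scaled-inverse-chi-square variance
# prior (d0, s0^2) from per-protein sample variances s2 with df residual
# degrees of freedom: s2 ~ s0^2 * F(df, d0), matched on log s2 using
# digamma/trigamma identities.
estimate_variance_prior <- function(s2, df) {
  ok <- df > 0 & is.finite(s2)
  s2 <- pmax(s2[ok], 1e-300)
  df <- df[ok]
  if (length(s2) < 2L)
    stop("need >= 2 proteins with positive residual df to estimate the prior")
  z <- log(s2) - digamma(df / 2) + log(df / 2)
  zbar <- mean(z)
  n <- length(z)
  evar <- sum((z - zbar)^2) / (n - 1L) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(zbar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond sampling noise: variances are
    # exchangeable, and the pooled mean is the natural common estimate
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Prior scale consistent with a fixed prior df: the moment-matched
# location of log s0^2 given d0; at d0 = Inf the pooled mean variance.
prior_s0_for_d0 <- function(s2, df, d0) {
  ok <- df > 0 & is.finite(s2)
  if (is.infinite(d0)) return(mean(s2[ok]))
  z <- log(pmax(s2[ok], 1e-300)) - digamma(df[ok] / 2) + log(df[ok] / 2)
  exp(mean(z) + digamma(d0 / 2) - log(d0 / 2))
}

#' Empirical-Bayes moderated two-group test
#'
#' Per-protein two-sample comparison on a log2 matrix with
#' empirical-Bayes variance moderation: per-protein pooled variances are
#' shrunk toward a global prior \eqn{(d_0, s_0^2)} estimated across
#' proteins by moment matching on \eqn{\log s^2}, and the moderated t
#' statistic gains \eqn{d_0} prior degrees of freedom. With
#' \eqn{d_0 = 0} the ordinary pooled two-sample t-test is recovered; with
#' \eqn{d_0 = \infty} the test becomes a z-test against \eqn{s_0}.
#'
#' @param matrix log2-scale matrix, proteins x samples.
#' @param groups character vector over samples, values \code{"control"} /
#'   \code{"treated"}; defaults to the matrix's \code{"groups"} attribute.
#' @param prior_df optional fixed prior degrees of freedom \eqn{d_0}
#'   (may be 0 or \code{Inf}); if \code{NULL} (default) the prior is
#'   estimated from the data.
#' @return data.frame per tested protein: \code{protein}, \code{log2fc}
#'   (treated minus control), \code{s2}, \code{df_residual}, \code{t_mod},
#'   \code{p}, \code{adj_p}; globals \code{d0} and \code{s0_sq} attached
#'   as attributes, together with \code{"n_skipped"} (proteins with <2
#'   observed values in either group).
#' @export
moderated_test <- function(matrix, groups = NULL, prior_df = NULL) {
  if (is.null(groups)) groups <- attr(matrix, "groups")
  if (is.null(groups)) stop("sample groups not given")
  stopifnot(length(groups) == ncol(matrix))
  ic <- which(groups == "control")
  it <- which(groups == "treated")
  x_c <- matrix[, ic, drop = FALSE]
  x_t <- matrix[, it, drop = FALSE]
  n_c <- rowSums(!is.na(x_c))
  n_t <- rowSums(!is.na(x_t))
  usable <- n_c >= 2L & n_t >= 2L
  n_skipped <- sum(!usable)

  m_c <- rowMeans(x_c, na.rm = TRUE)
  m_t <- rowMeans(x_t, na.rm = TRUE)
  ss_c <- rowSums((x_c - m_c)^2, na.rm = TRUE)
  ss_t <- rowSums((x_t - m_t)^2, na.rm = TRUE)
  df <- n_c + n_t - 2L
  s2 <- (ss_c + ss_t) / pmax(df, 1L)

  idx <- which(usable)
  if (length(idx) == 0L) stop("no protein has >=2 observed values per group")
  lfc <- (m_t - m_c)[idx]
  s2u <- s2[idx]
  dfu <- df[idx]

  prior <- if (is.null(prior_df)) {
    estimate_variance_prior(s2u, dfu)
  } else {
    list(d0 = prior_df,
         s0_sq = if (prior_df > 0)
           prior_s0_for_d0(s2u, dfu, prior_df) else NA_real_)
  }
  d0 <- prior$d0
  s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(idx)) else if (d0 == 0)
    s2u else (d0 * s0_sq + dfu * s2u) / (d0 + dfu)
  se <- sqrt(s2_post * (1 / n_c[idx] + 1 / n_t[idx]))
  t_mod <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- d0 + dfu
  p <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(t_mod)) else
    2 * stats::pt(-abs(t_mod), df_total)
  p[t_mod == 0] <- 1

  prot <- rownames(matrix)
  if (is.null(prot)) prot <- as.character(seq_len(nrow(matrix)))
  out <- data.frame(protein = prot[idx], log2fc = lfc, s2 = s2u,
                    df_residual = dfu, t_mod = t_mod, p = p,
                    adj_p = bh_adjust(p), stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1, ties preserved, original order restored.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, elementwise >= the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential proteins
#'
#' A protein is a differential protein (DP) when its adjusted p-value is
#' below \code{alpha} and its absolute log2 fold change exceeds
#' \code{min_abs_lfc}.
#'
#' @param fits result of \code{\link{moderated_test}}.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_abs_lfc absolute log2 fold-change threshold (default 1).
#' @return the fit table with added columns \code{is_dp} and
#'   \code{direction} ("up"/"down").
#' @export
call_dps <- function(fits, alpha = 0.05, min_abs_lfc = 1) {
  fits$is_dp <- fits$adj_p < alpha & abs(fits$log2fc) > min_abs_lfc
  fits$direction <- ifelse(fits$log2fc >= 0, "up", "down")
  fits
}

#' Summed-fraction differential workflow
#'
#' The full summed-intensity analysis: sum over fractions, log2
#' normalization, left-censored imputation, moderated test, BH
#' adjustment, DP calling.
#'
#' @param dataset preprocessed \code{ElutionDataset}.
#' @param alpha,min_abs_lfc DP thresholds (defaults 0.05 and 1).
#' @param normalization \code{"vsn_glog"} (default) or
#'   \code{"median_log2"}.
#' @param impute_shift,impute_width imputation parameters (defaults 1.8
#'   and 0.3).
#' @param seed seed for the imputation draws.
#' @return DP call table (see \code{\link{call_dps}}).
#' @export
summed_differential <- function(dataset, alpha = 0.05, min_abs_lfc = 1,
                                normalization = "vsn_glog",
                                impute_shift = 1.8, impute_width = 0.3,
                                seed = 1L) {
  mat <- sum_fractions(dataset)
  groups <- attr(mat, "groups")
  mat <- log2_normalize(mat, method = normalization)
  mat <- impute_mnar(mat, shift = impute_shift, width = impute_width,
                     seed = seed)
  fits <- moderated_test(mat, groups = groups)
  call_dps(fits, alpha = alpha, min_abs_lfc = min_abs_lfc)
}

#' Per-fraction differential workflow
#'
#' Treats each fraction as a separate control-vs-treated comparison: per
#' fraction, the protein x sample matrix of that fraction's intensities
#' is log2-normalized (no imputation), proteins with fewer than 2
#' observed values in either group are dropped from that fraction, a
#' moderated test is run, and BH adjustment is applied within the
#' fraction. The union of per-fraction DPs and the stringent set
#' (proteins differential in \code{stringency} or more fractions,
#' direction not required to agree) are reported.
#'
#' @param dataset preprocessed \code{ElutionDataset}.
#' @param alpha,min_abs_lfc DP thresholds (defaults 0.05 and 1).
#' @param stringency minimum number of significant fractions for the
#'   stringent set (default 2).
#' @param normalization normalization method for each fraction matrix.
#' @return list with \code{per_fraction} (DP tables by fraction),
#'   \code{n_dp_fractions} (named integer vector over proteins),
#'   \code{union_dps}, \code{stringent_dps}, and
#'   \code{skipped_fractions}.
#' @export
fractionwise_differential <- function(dataset, alpha = 0.05,
                                      min_abs_lfc = 1, stringency = 2L,
                                      normalization = "vsn_glog") {
  labels <- protein_labels(dataset)
  dp_count <- stats::setNames(integer(length(labels)), labels)
  per_fraction <- vector("list", dataset$n_fractions)
  names(per_fraction) <- sprintf("F%02d", seq_len(dataset$n_fractions))
  skipped <- integer()
  grid <- expand.grid(replicate = seq_len(dataset$n_replicates),
                      condition = .CONDITIONS, stringsAsFactors = FALSE)
  for (f in seq_len(dataset$n_fractions)) {
    mat <- matrix(NA_real_, nrow = length(labels), ncol = nrow(grid),
                  dimnames = list(labels, paste(grid$condition,
                                                grid$replicate, sep = "_")))
    for (i in seq_len(nrow(grid))) {
      col <- sample_cols(dataset, condition = grid$condition[i],
                         replicate = grid$replicate[i], fraction = f)
      v <- dataset$intensity[, col]
      v[v == 0] <- NA_real_
      mat[, i] <- v
    }
    groups <- grid$condition
    n_c <- rowSums(!is.na(mat[, groups == "control", drop = FALSE]))
    n_t <- rowSums(!is.na(mat[, groups == "treated", drop = FALSE]))
    testable <- n_c >= 2L & n_t >= 2L
    if (sum(testable) < 2L || any(colSums(!is.na(mat[testable, , drop = FALSE])) < 2L)) {
      warning(sprintf("fraction %d skipped: too few observed values", f))
      skipped <- c(skipped, f)
      next
    }
    sub <- mat[testable, , drop = FALSE]
    fits <- tryCatch({
      norm <- log2_normalize(sub, method = normalization)
      moderated_test(norm, groups = groups)
    }, error = function(e) {
      warning(sprintf("fraction %d skipped: %s", f, conditionMessage(e)))
      NULL
    })
    if (is.null(fits)) {
      skipped <- c(skipped, f)
      next
    }
    calls <- call_dps(fits, alpha = alpha, min_abs_lfc = min_abs_lfc)
    per_fraction[[f]] <- calls
    dps <- calls$protein[calls$is_dp]
    dp_count[dps] <- dp_count[dps] + 1L
  }
  list(per_fraction = per_fraction,
       n_dp_fractions = dp_count,
       union_dps = names(dp_count)[dp_count >= 1L],
       stringent_dps = names(dp_count)[dp_count >= stringency],
       skipped_fractions = skipped)
}
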