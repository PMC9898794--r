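# Complex-centric coelution analysis: protein traces, sliding-window
# correlation, candidate feature detection against complex hypotheses,
# decoy-based FDR, molecular-weight consistency, and a
# differential-complex report.

#' Build aggregate protein elution traces
#'
#' Per-sample log2 intensity profiles are cross-normalized, transformed
#' back to the intensity scale, and summed across all conditions and
#' replicates per fraction, giving one length-F trace per protein.
#' Internal missing runs of length <= 2 are then filled by cubic spline
#' interpolation over the fraction index (clamped at 0, so interpolation
#' only adds signal); leading and trailing missing stretches stay at 0.
#'
#' @param dataset preprocessed \code{ElutionDataset}.
#' @param normalize cross-sample normalization: \code{"cyclic_loess"}
#'   (pairwise MA lowess over shared observed protein/fraction cells,
#'   default), \code{"median"} (per-sample median scaling), or
#'   \code{"none"}.
#' @return numeric matrix proteins x fractions (rownames = protein
#'   labels); the logical attribute \code{"interpolated"} marks filled
#'   cells.
#' @export
build_traces <- function(dataset,
                         normalize = c("cyclic_loess", "median", "none")) {
  normalize <- match.arg(normalize)
  n <- n_proteins(dataset)
  f_n <- dataset$n_fractions
  grid <- expand.grid(replicate = seq_len(dataset$n_replicates),
                      condition = .CONDITIONS, stringsAsFactors = FALSE)
  # one column per (condition, replicate) sample; rows = protein x fraction
  L <- matrix(NA_real_, nrow = n * f_n, ncol = nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cols <- sample_cols(dataset, condition = grid$condition[i],
                        replicate = grid$replicate[i])
    ord <- order(dataset$design$fraction[cols])
    block <- dataset$intensity[, cols[ord], drop = FALSE]
    v <- as.vector(block)
    v[v == 0] <- NA_real_
    L[, i] <- log2(v)
  }
  if (normalize == "median") {
    med <- apply(L, 2L, stats::median, na.rm = TRUE)
    L <- sweep(L, 2L, med - mean(med))
  } else if (normalize == "cyclic_loess") {
    L <- cyclic_loess_normalize(L)
  }
  raw <- 2^L
  raw[is.na(raw)] <- 0
  traces <- matrix(0, nrow = n, ncol = f_n)
  for (i in seq_len(ncol(L)))
    traces <- traces + matrix(raw[, i], nrow = n, ncol = f_n)
  rownames(traces) <- protein_labels(dataset)
  colnames(traces) <- sprintf("F%02d", seq_len(f_n))
  fill_internal_gaps(traces, max_gap = 2L)
}

# Cyclic pairwise lowess normalization on the log2 scale. For every
# sample pair, a lowess curve of M = li - lj against A = (li + lj)/2 is
# fitted on cells observed in both samples and half the fitted offset is
# subtracted/added; cycles over all pairs three times. Large pairs are
# subsampled for curve fitting and the curve interpolated back.
cyclic_loess_normalize <- function(L, iterations = 3L, span = 0.4,
                                   max_fit_points = 20000L) {
  k <- ncol(L)
  if (k < 2L) return(L)
  for (it in seq_len(iterations)) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        ok <- which(!is.na(L[, i]) & !is.na(L[, j]))
        if (length(ok) < 10L) next
        A <- (L[ok, i] + L[ok, j]) / 2
        M <- L[ok, i] - L[ok, j]
        fit_idx <- if (length(ok) > max_fit_points)
          sort(sample.int(length(ok), max_fit_points)) else seq_along(ok)
        lw <- stats::lowess(A[fit_idx], M[fit_idx], f = span)
        adj <- stats::approx(lw$x, lw$y, xout = A, rule = 2)$y
        L[ok, i] <- L[ok, i] - adj / 2
        L[ok, j] <- L[ok, j] + adj / 2
      }
    }
  }
  L
}

# Fill internal zero-runs of length <= max_gap by natural cubic spline
# over the observed fractions; never below 0, never at the edges.
fill_internal_gaps <- function(traces, max_gap = 2L) {
  interp <- matrix(FALSE, nrow = nrow(traces), ncol = ncol(traces))
  f_n <- ncol(traces)
  for (p in seq_len(nrow(traces))) {
    v <- traces[p, ]
    obs <- which(v > 0)
    if (length(obs) < 2L) next
    r <- rle(v == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      if (starts[g] == 1L || ends[g] == f_n) next    # leading/trailing
      if (r$lengths[g] > max_gap) next
      at <- starts[g]:ends[g]
      val <- stats::spline(obs, v[obs], xout = at, method = "natural")$y
      traces[p, at] <- pmax(val, 0)
      interp[p, at] <- TRUE
    }
  }
  attr(traces, "interpolated") <- interp
  traces
}

#' Moving-average smoothing of elution traces
#'
#' Centered moving average with edge truncation (windows are shortened
#' at the chromatogram ends rather than padded).
#'
#' @param traces numeric matrix proteins x fractions, or a single trace
#'   vector.
#' @param smoothing_length odd window length >= 1 (default 5).
#' @return smoothed traces, same shape as the input.
#' @export
smooth_traces <- function(traces, smoothing_length = 5L) {
  if (smoothing_length %% 2L == 0L || smoothing_length < 1L)
    stop("smoothing_length must be odd and >= 1")
  vec <- is.null(dim(traces))
  x <- if (vec) matrix(traces, nrow = 1L) else traces
  h <- (smoothing_length - 1L) %/% 2L
  f_n <- ncol(x)
  out <- x
  if (h > 0L) {
    for (t in seq_len(f_n)) {
      w <- max(1L, t - h):min(f_n, t + h)
      out[, t] <- rowMeans(x[, w, drop = FALSE])
    }
  }
  if (vec) drop(out) else out
}

#' Sliding-window mean pairwise correlation
#'
#' At each fraction position, Pearson correlation of every pair of
#' traces over the centered window (truncated at the chromatogram
#' edges), averaged over pairs. Pairs in which either trace is constant
#' within the window contribute a correlation of 0.
#'
#' @param traces numeric matrix, >= 2 traces in rows, fractions in
#'   columns.
#' @param window_size odd window length (default 5).
#' @return numeric vector of length \code{ncol(traces)}.
#' @export
sliding_correlation <- function(traces, window_size = 5L) {
  if (is.null(dim(traces)) || nrow(traces) < 2L)
    stop("sliding correlation needs >= 2 traces")
  h <- (window_size - 1L) %/% 2L
  f_n <- ncol(traces)
  out <- numeric(f_n)
  for (t in seq_len(f_n)) {
    w <- max(1L, t - h):min(f_n, t + h)
    if (length(w) < 2L) { out[t] <- 0; next }
    cm <- suppressWarnings(stats::cor(t(traces[, w, drop = FALSE])))
    cm[!is.finite(cm)] <- 0
    out[t] <- mean(cm[upper.tri(cm)])
  }
  out
}

# Windowed Pearson correlation of one trace against the mean of the
# others, centered at `at`.
subunit_corr_at <- function(traces, sub, at, window_size) {
  h <- (window_size - 1L) %/% 2L
  w <- max(1L, at - h):min(ncol(traces), at + h)
  a <- traces[sub, w]
  b <- colMeans(traces[-sub, w, drop = FALSE])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Detect coelution feature candidates for one complex hypothesis
#'
#' Candidate regions are maximal runs of fractions where the mean
#' sliding-window correlation of the hypothesis's traced subunits
#' reaches \code{corr_cutoff}. Within each region the apex is the
#' fraction of maximal summed subunit signal; a subunit counts as
#' coeluting when its windowed correlation against the mean of the other
#' subunits at the apex reaches \code{corr_cutoff}. Candidates whose
#' apexes lie within \code{rt_height} fractions of each other and share
#' a coeluting subunit are collapsed (wider bounds, union of subunits).
#' The feature score is completeness (coeluting / annotated subunits)
#' times the mean pairwise apex correlation of the coeluting subunits.
#'
#' @param hypothesis a complex hypothesis
#'   (see \code{\link{complex_hypothesis}}).
#' @param traces smoothed trace matrix (rownames = protein identifiers
#'   in the hypothesis id space).
#' @param corr_cutoff detection correlation cutoff (default 0.9).
#' @param window_size sliding window length (default 5).
#' @param rt_height apex collapse distance in fractions (default 1).
#' @param support_traces optional unsmoothed trace matrix used to demand
#'   real elution support: a coeluting subunit must carry nonzero
#'   unsmoothed signal in at least 2 of the 3 fractions around the apex,
#'   which suppresses sparse detection-floor traces whose isolated
#'   spikes correlate spuriously after smoothing.
#' @return list of candidate features; each has \code{complex_id},
#'   \code{complex_name}, \code{apex}, \code{left}, \code{right},
#'   \code{coeluting}, \code{n_subunits_annotated}, \code{mean_corr},
#'   \code{completeness}, \code{score}.
#' @export
detect_candidates <- function(hypothesis, traces, corr_cutoff = 0.9,
                              window_size = 5L, rt_height = 1L,
                              support_traces = NULL) {
  subs <- intersect(hypothesis$subunits, rownames(traces))
  if (length(subs) < 2L) return(list())
  sub_tr <- traces[subs, , drop = FALSE]
  corr <- sliding_correlation(sub_tr, window_size = window_size)
  above <- corr >= corr_cutoff
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  total <- colSums(sub_tr)
  # elution peaks of the summed subunit signal: interior local maxima
  # (or chromatogram-edge maxima); a correlated stretch without a peak
  # is a shared flank, not a coelution feature
  n_f <- length(total)
  is_peak <- vapply(seq_len(n_f), function(i) {
    left_ok <- i == 1L || total[i] >= total[i - 1L]
    right_ok <- i == n_f || total[i] >= total[i + 1L]
    left_ok && right_ok && total[i] > 0
  }, logical(1))
  cands <- list()
  for (g in which(r$values)) {
    reg <- starts[g]:ends[g]
    peaks <- reg[is_peak[reg]]
    if (!length(peaks)) next
    apex <- peaks[which.max(total[peaks])]
    coel_idx <- which(vapply(seq_along(subs), function(s)
      subunit_corr_at(sub_tr, s, apex, window_size), numeric(1)) >= corr_cutoff)
    if (!is.null(support_traces)) {
      around <- max(1L, apex - 1L):min(ncol(traces), apex + 1L)
      supported <- vapply(coel_idx, function(s)
        sum(support_traces[subs[s], around] > 0) >= 2L, logical(1))
      coel_idx <- coel_idx[supported]
    }
    if (length(coel_idx) < 2L) next
    mc <- mean_apex_corr(sub_tr[coel_idx, , drop = FALSE], apex, window_size)
    completeness <- length(coel_idx) / length(hypothesis$subunits)
    cands[[length(cands) + 1L]] <- list(
      complex_id = hypothesis$complex_id,
      complex_name = hypothesis$complex_name,
      apex = apex, left = starts[g], right = ends[g],
      coeluting = subs[coel_idx],
      n_subunits_annotated = length(hypothesis$subunits),
      mean_corr = mc, completeness = completeness,
      score = completeness * mc)
  }
  collapse_candidates(cands, rt_height = rt_height)
}

mean_apex_corr <- function(sub_tr, apex, window_size) {
  h <- (window_size - 1L) %/% 2L
  w <- max(1L, apex - h):min(ncol(sub_tr), apex + h)
  cm <- suppressWarnings(stats::cor(t(sub_tr[, w, drop = FALSE])))
  cm[!is.finite(cm)] <- 0
  mean(cm[upper.tri(cm)])
}

# Merge candidates whose apexes are within rt_height fractions and that
# share at least one coeluting subunit. Merging keeps the wider bounds
# and the union of subunits, and recomputes completeness and score from
# the retained apex correlation.
collapse_candidates <- function(cands, rt_height = 1L) {
  if (length(cands) < 2L) return(cands)
  repeat {
    merged <- FALSE
    for (i in seq_along(cands)) {
      for (j in seq_along(cands)) {
        if (j <= i) next
        a <- cands[[i]]; b <- cands[[j]]
        if (abs(a$apex - b$apex) <= rt_height &&
            length(intersect(a$coeluting, b$coeluting)) > 0L) {
          keep <- if (length(b$coeluting) > length(a$coeluting) ||
                      (length(b$coeluting) == length(a$coeluting) &&
                       b$score > a$score)) b else a
          keep$left <- min(a$left, b$left)
          keep$right <- max(a$right, b$right)
          keep$coeluting <- union(a$coeluting, b$coeluting)
          keep$completeness <- length(keep$coeluting) / keep$n_subunits_annotated
          keep$score <- keep$completeness * keep$mean_corr
          cands[[i]] <- keep
          cands[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  cands
}

#' Detect coelution features for a list of hypotheses
#'
#' Convenience wrapper: smooths the traces once and runs
#' \code{\link{detect_candidates}} for each hypothesis.
#'
#' @param hypotheses list of complex hypotheses.
#' @param traces raw trace matrix from \code{\link{build_traces}}.
#' @param corr_cutoff,window_size,rt_height,smoothing_length detection
#'   parameters (defaults 0.9, 5, 1, 5).
#' @return flat list of candidate features over all hypotheses.
#' @export
detect_features <- function(hypotheses, traces, corr_cutoff = 0.9,
                            window_size = 5L, rt_height = 1L,
                            smoothing_length = 5L) {
  sm <- smooth_traces(traces, smoothing_length = smoothing_length)
  out <- list()
  for (h in hypotheses)
    out <- c(out, detect_candidates(h, sm, corr_cutoff = corr_cutoff,
                                    window_size = window_size,
                                    rt_height = rt_height,
                                    support_traces = traces))
  out
}

#' Molecular-weight consistency filter
#'
#' Keeps features whose apex maps to an apparent MW at least
#' \code{factor} times the largest monomer MW among the feature's
#' coeluting subunits, discarding apparent monomer peaks. Subunits with
#' unknown monomer MW do not constrain the filter.
#'
#' @param features list of candidate features.
#' @param model a \code{CalibrationModel}.
#' @param monomer_mw named numeric vector, monomer MW (kDa) per protein
#'   identifier.
#' @param factor minimum apparent-to-monomer MW ratio (default 1.2; 0
#'   disables the filter).
#' @return filtered feature list, each feature gaining
#'   \code{apparent_mw_kda}; removed count in attribute
#'   \code{"n_removed"}.
#' @export
mw_consistency_filter <- function(features, model, monomer_mw,
                                  factor = 1.2) {
  keep <- logical(length(features))
  for (i in seq_along(features)) {
    ft <- features[[i]]
    app <- unname(apparent_mw(model, ft$apex))
    features[[i]]$apparent_mw_kda <- app
    mws <- monomer_mw[ft$coeluting]
    mws <- mws[!is.na(mws)]
    keep[i] <- !length(mws) || app >= factor * max(mws)
  }
  out <- features[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Generate decoy complex hypotheses
#'
#' One decoy per target hypothesis with the same subunit count, members
#' sampled without replacement from the detected proteins such that no
#' two decoy members co-occur in any reference complex (the
#' co-membership interpretation of a minimum graph distance of 2).
#' Decoys that cannot be assembled in 1000 attempts are skipped with a
#' warning.
#'
#' @param hypotheses reference (target) hypotheses.
#' @param detected_ids character vector of proteins with traces.
#' @param min_distance minimum co-membership graph distance between
#'   decoy members (default 2; values < 2 disable the constraint).
#' @param seed integer seed.
#' @return list of decoy hypotheses (ids prefixed \code{"DECOY_"}).
#' @export
generate_decoys <- function(hypotheses, detected_ids, min_distance = 2L,
                            seed = 1L) {
  set.seed(seed)
  membership <- new.env(parent = emptyenv())
  for (h in hypotheses)
    for (s in h$subunits)
      assign(s, c(if (exists(s, membership)) get(s, membership), h$complex_id),
             envir = membership)
  pool <- unique(detected_ids)
  decoys <- list()
  for (h in hypotheses) {
    k <- length(h$subunits)
    if (k > length(pool)) {
      warning("decoy skipped for ", h$complex_id, ": pool too small")
      next
    }
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      cand <- sample(pool, k)
      if (min_distance < 2L || !comembers(cand, membership)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      warning("decoy skipped for ", h$complex_id,
              ": no valid member set in 1000 attempts")
      next
    }
    decoys[[length(decoys) + 1L]] <- list(
      complex_id = paste0("DECOY_", h$complex_id),
      complex_name = paste0("DECOY_", h$complex_name),
      subunits = cand)
  }
  decoys
}

# TRUE if any pair of `ids` shares membership in a reference complex.
comembers <- function(ids, membership) {
  seen <- character()
  for (id in ids) {
    if (!exists(id, membership)) next
    cx <- get(id, membership)
    if (any(cx %in% seen)) return(TRUE)
    seen <- c(seen, cx)
  }
  FALSE
}

#' Score coelution features with decoy-based FDR
#'
#' Keeps the best feature per complex (most coeluting subunits, ties
#' broken by higher score), then estimates each target score's q-value
#' from the decoy score distribution:
#' \code{q(s) = #decoys >= s / max(1, #targets >= s)}, monotonized to be
#' non-increasing in the score. Features with \code{q <= fdr} that are
#' not decoys are accepted.
#'
#' @param target_features,decoy_features feature lists from
#'   \code{\link{detect_features}} run on target and decoy hypotheses.
#' @param fdr acceptance threshold on the q-value (default 0.05).
#' @return data.frame with one row per best feature (targets and
#'   decoys): complex, apex, bounds, subunit list, score, q-value,
#'   acceptance.
#' @export
score_and_fdr <- function(target_features, decoy_features, fdr = 0.05) {
  if (is.null(decoy_features))
    stop("no decoy queries were run: FDR is undefined")
  if (!length(decoy_features))
    message("no decoy features detected; all target q-values are 0")
  best <- function(features, is_decoy) {
    if (!length(features)) return(NULL)
    tab <- data.frame(
      complex_id = vapply(features, `[[`, character(1), "complex_id"),
      complex_name = vapply(features, `[[`, character(1), "complex_name"),
      apex = vapply(features, `[[`, numeric(1), "apex"),
      left = vapply(features, `[[`, numeric(1), "left"),
      right = vapply(features, `[[`, numeric(1), "right"),
      n_coeluting = vapply(features, function(f) length(f$coeluting),
                           integer(1)),
      subunits = vapply(features, function(f)
        paste(f$coeluting, collapse = ";"), character(1)),
      completeness = vapply(features, `[[`, numeric(1), "completeness"),
      mean_corr = vapply(features, `[[`, numeric(1), "mean_corr"),
      score = vapply(features, `[[`, numeric(1), "score"),
      apparent_mw_kda = vapply(features, function(f)
        if (is.null(f$apparent_mw_kda)) NA_real_ else f$apparent_mw_kda,
        numeric(1)),
      is_decoy = is_decoy, stringsAsFactors = FALSE)
    ord <- order(-tab$n_coeluting, -tab$score)
    tab <- tab[ord, , drop = FALSE]
    tab[!duplicated(tab$complex_id), , drop = FALSE]
  }
  tt <- best(target_features, FALSE)
  dt <- best(decoy_features, TRUE)
  if (is.null(tt))
    return(cbind(dt, q_value = NA_real_, accepted = FALSE))
  d_scores <- if (is.null(dt)) numeric() else dt$score
  fdr_at <- vapply(tt$score, function(s)
    sum(d_scores >= s) / max(1L, sum(tt$score >= s)), numeric(1))
  # q(s) = min FDR over thresholds <= s (accepting s implies accepting
  # everything above any lower threshold); non-increasing in s
  ord <- order(tt$score)
  q <- fdr_at
  q[ord] <- cummin(fdr_at[ord])
  q <- pmin(q, 1)
  tt$q_value <- q
  tt$accepted <- tt$q_value <= fdr
  if (!is.null(dt)) {
    dt$q_value <- NA_real_
    dt$accepted <- FALSE
    tt <- rbind(tt, dt)
  }
  rownames(tt) <- NULL
  tt
}

#' Differential-complex report
#'
#' For each accepted coelution feature, sums the member subunit
#' intensities within the feature's fraction bounds per condition
#' (over all replicates) and reports the treated/control log2 ratio,
#' which member subunits are stringent fraction-level differential
#' proteins, and how many members are differential in a fraction inside
#' the feature bounds. A condition with zero within-feature signal is
#' floored (\code{log2_ratio = +/- floor}) and flagged.
#'
#' @param scored data.frame from \code{\link{score_and_fdr}} (only
#'   accepted rows are reported).
#' @param fractionwise result of \code{\link{fractionwise_differential}}
#'   on the same dataset.
#' @param dataset the \code{ElutionDataset}.
#' @param floor magnitude used in place of an infinite log2 ratio
#'   (default 30).
#' @return data.frame, one row per accepted complex feature.
#' @export
differential_complex_report <- function(scored, fractionwise, dataset,
                                        floor = 30) {
  acc <- scored[scored$accepted, , drop = FALSE]
  labels <- protein_labels(dataset)
  rows <- lapply(seq_len(nrow(acc)), function(i) {
    ft <- acc[i, ]
    subs <- strsplit(ft$subunits, ";", fixed = TRUE)[[1]]
    ridx <- match(subs, labels)
    ridx <- ridx[!is.na(ridx)]
    frs <- ft$left:ft$right
    tot <- vapply(.CONDITIONS, function(cond) {
      cols <- sample_cols(dataset, condition = cond, fraction = frs)
      sum(dataset$intensity[ridx, cols, drop = FALSE])
    }, numeric(1))
    flagged <- any(tot == 0)
    lr <- if (all(tot > 0)) log2(tot[["treated"]] / tot[["control"]]) else
      if (tot[["treated"]] == 0 && tot[["control"]] == 0) 0 else
        if (tot[["treated"]] == 0) -floor else floor
    stringent_members <- intersect(subs, fractionwise$stringent_dps)
    n_dp_in_bounds <- sum(vapply(subs, function(s) {
      any(vapply(frs, function(f) {
        tab <- fractionwise$per_fraction[[f]]
        !is.null(tab) && s %in% tab$protein[tab$is_dp]
      }, logical(1)))
    }, logical(1)))
    data.frame(complex_id = ft$complex_id, complex_name = ft$complex_name,
               apex = ft$apex, left = ft$left, right = ft$right,
               control_intensity = tot[["control"]],
               treated_intensity = tot[["treated"]],
               log2_ratio = lr, ratio_floored = flagged,
               stringent_dp_members = paste(stringent_members,
                                            collapse = ";"),
               n_members_dp_in_bounds = n_dp_in_bounds,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(complex_id = character(), complex_name = character(),
                      apex = numeric(), left = numeric(), right = numeric(),
                      control_intensity = numeric(),
                      treated_intensity = numeric(), log2_ratio = numeric(),
                      ratio_floored = logical(),
                      stringent_dp_members = character(),
                      n_members_dp_in_bounds = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
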