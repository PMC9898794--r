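# Independent brute-force oracles, coded directly from the defining
# formulas with plain loops. They deliberately share no code with the
# package internals they check.

# Moderated two-group t-test: per-row pooled variances, a global
# scaled-inverse-chi-square prior matched on log s^2 (trigamma inverted
# by root finding, not Newton), posterior variances, t and p.
oracle_moderated <- function(X, groups) {
  ic <- groups == "control"
  it <- groups == "treated"
  n <- nrow(X)
  lfc <- s2 <- df <- numeric(n)
  nc <- nt <- integer(n)
  for (g in seq_len(n)) {
    a <- X[g, ic][!is.na(X[g, ic])]
    b <- X[g, it][!is.na(X[g, it])]
    nc[g] <- length(a); nt[g] <- length(b)
    lfc[g] <- mean(b) - mean(a)
    df[g] <- nc[g] + nt[g] - 2L
    s2[g] <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df[g]
  }
  z <- numeric(n)
  for (g in seq_len(n)) z[g] <- log(s2[g]) - digamma(df[g] / 2) + log(df[g] / 2)
  zbar <- mean(z)
  evar <- sum((z - zbar)^2) / (n - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    half_d0 <- stats::uniroot(function(x) trigamma(x) - evar,
                              lower = 1e-6, upper = 1e8, tol = 1e-14)$root
    d0 <- 2 * half_d0
    s0_sq <- exp(zbar + digamma(half_d0) - log(half_d0))
  } else {
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  t_mod <- p <- numeric(n)
  for (g in seq_len(n)) {
    s2_post <- if (is.infinite(d0)) s0_sq else
      (d0 * s0_sq + df[g] * s2[g]) / (d0 + df[g])
    t_mod[g] <- lfc[g] / sqrt(s2_post * (1 / nc[g] + 1 / nt[g]))
    p[g] <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(t_mod[g])) else
      2 * stats::pt(-abs(t_mod[g]), d0 + df[g])
  }
  list(log2fc = lfc, t_mod = t_mod, p = p, d0 = d0, s0_sq = s0_sq)
}

# Benjamini-Hochberg by the step-up definition: for each p_i, the
# minimum over tail values p_j >= p_i of m * p_j / rank(p_j), capped.
oracle_bh <- function(p) {
  m <- length(p)
  out <- numeric(m)
  for (i in seq_len(m)) {
    best <- 1
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) {
        cand <- m * p[j] / sum(p <= p[j])
        if (cand < best) best <- cand
      }
    }
    out[i] <- min(best, 1)
  }
  out
}

# Windowed Pearson correlation of two traces, straight from the
# definition (truncated centered windows).
oracle_windowed_corr <- function(a, b, window_size) {
  h <- (window_size - 1) %/% 2
  f_n <- length(a)
  out <- numeric(f_n)
  for (t in seq_len(f_n)) {
    w <- max(1, t - h):min(f_n, t + h)
    x <- a[w]; y <- b[w]
    sx <- sqrt(sum((x - mean(x))^2)); sy <- sqrt(sum((y - mean(y))^2))
    out[t] <- if (sx == 0 || sy == 0) 0 else
      sum((x - mean(x)) * (y - mean(y))) / (sx * sy)
  }
  out
}

# Minimal dataset builder for unit tests: intensity given as a
# protein x (condition, replicate, fraction) array.
make_dataset <- function(arr, monomer_mw = NULL, gene = NULL,
                         n_peptides = NULL, contaminant = NULL,
                         reverse = NULL, site = NULL) {
  stopifnot(length(dim(arr)) == 4L)   # protein x cond x rep x fraction
  n <- dim(arr)[1]; n_r <- dim(arr)[3]; n_f <- dim(arr)[4]
  grid <- expand.grid(condition = c("control", "treated"),
                      replicate = seq_len(n_r), fraction = seq_len(n_f),
                      stringsAsFactors = FALSE)
  ints <- matrix(0, n, nrow(grid))
  for (j in seq_len(nrow(grid)))
    ints[, j] <- arr[, match(grid$condition[j], c("control", "treated")),
                     grid$replicate[j], grid$fraction[j]]
  meta <- data.frame(
    protein_ids = if (is.null(gene)) sprintf("P%03d", seq_len(n)) else
      sprintf("P%03d", seq_len(n)),
    gene_name = if (is.null(gene)) sprintf("G%03d", seq_len(n)) else gene,
    n_peptides = if (is.null(n_peptides)) rep(5L, n) else n_peptides,
    is_contaminant = if (is.null(contaminant)) rep(FALSE, n) else contaminant,
    is_reverse = if (is.null(reverse)) rep(FALSE, n) else reverse,
    only_by_site = if (is.null(site)) rep(FALSE, n) else site,
    monomer_mw_kda = if (is.null(monomer_mw)) rep(NA_real_, n) else monomer_mw,
    stringsAsFactors = FALSE)
  elution_dataset(ints, grid, meta)
}

# Gaussian elution peak; values below `floor` x height are 0, emulating
# the instrument detection limit on real traces.
gaussian_trace <- function(center, f_n = 24, sd = 1, height = 1,
                           floor = 1e-3) {
  v <- height * exp(-(seq_len(f_n) - center)^2 / (2 * sd^2))
  v[v < floor * height] <- 0
  v
}
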