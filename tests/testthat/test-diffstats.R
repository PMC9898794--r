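# Summed and per-fraction differential statistics

test_that("sum_fractions collapses the elution dimension and flags empties", {
  arr <- array(0, dim = c(2, 2, 2, 6))
  arr[1, 1, 1, c(2, 4)] <- c(10, 20)    # control rep1: 30
  arr[1, 2, 1, 3] <- 5
  arr[2, 1, , ] <- 1                    # absent everywhere in treated
  ds <- make_dataset(arr)
  m <- sum_fractions(ds)
  expect_equal(m["G001", "control_1"], 30)
  expect_equal(m["G001", "treated_1"], 5)
  expect_true(all(is.na(m["G002", c("treated_1", "treated_2")])))
  expect_equal(sum(m, na.rm = TRUE), sum(ds$intensity))
})

test_that("median_log2 normalization equalizes proportional samples", {
  set.seed(1)
  a <- 2^stats::rnorm(50, 20, 2)
  m <- cbind(s1 = a, s2 = 2 * a, s3 = a)
  out <- log2_normalize(m, method = "median_log2")
  expect_equal(out[, "s1"], out[, "s2"], ignore_attr = TRUE)
  expect_equal(out[, "s1"], out[, "s3"], ignore_attr = TRUE)
})

test_that("vsn_glog behaves like log2 plus a constant for large values", {
  set.seed(2)
  # with the glog width pinned near a detection floor of ~16 counts,
  # values around 1e6 are far into the log-linear regime
  m <- matrix(2^stats::runif(300, 19, 24), ncol = 3)
  out <- log2_normalize(m, method = "vsn_glog", glog_c = 16)
  shift <- out - log2(m)
  # per-sample shift is an additive constant up to glog curvature
  for (j in 1:3)
    expect_lt(diff(range(shift[, j])), 1e-3)
  # closed form at x = 1e6: glog2(x, 16) equals log2(x) to well under 1e-3
  expect_equal(log2((1e6 + sqrt(1e12 + 16^2)) / 2), log2(1e6),
               tolerance = 1e-6)
  # the default width sits at the low end of the data, so the bulk of
  # the matrix is still ~log2 + constant
  wide <- matrix(2^stats::runif(600, 10, 24), ncol = 3)
  out_d <- log2_normalize(wide, method = "vsn_glog")
  for (j in 1:3) {
    top <- wide[, j] > stats::quantile(wide[, j], 0.5)
    shift_d <- out_d[top, j] - log2(wide[top, j])
    expect_lt(diff(range(shift_d)), 0.02)
  }
  # constant all-observed matrix stays constant
  const <- matrix(1000, nrow = 5, ncol = 3)
  outc <- log2_normalize(const, method = "vsn_glog")
  expect_lt(diff(range(outc)), 1e-9)
  # a sample with <2 observed values is a hard error
  bad <- m
  bad[2:100, 2] <- NA
  expect_error(log2_normalize(bad), "<2 observed")
})

test_that("left-censored imputation follows the shifted-Gaussian contract", {
  set.seed(3)
  m <- matrix(stats::rnorm(400, 25, 2), ncol = 4)
  full <- impute_mnar(m, seed = 9)
  expect_equal(unclass(full), m, ignore_attr = TRUE)  # nothing to impute
  m2 <- m
  m2[sample(length(m2), 120)] <- NA
  a <- impute_mnar(m2, seed = 9)
  b <- impute_mnar(m2, seed = 9)
  expect_identical(a, b)                     # determinism
  c_ <- impute_mnar(m2, seed = 10)
  expect_false(identical(a, c_))
  mask <- attr(a, "imputed")
  expect_identical(mask, is.na(m2))
  expect_equal(a[!mask], m2[!mask])          # observed untouched
  # imputed values sit in the left tail of the observed distribution
  expect_lt(mean(a[mask]), mean(m2[!mask], na.rm = TRUE))
})

test_that("moderated test reduces to the classical t-test at d0 = 0", {
  set.seed(4)
  m <- matrix(stats::rnorm(80, 20, 1), nrow = 10)
  groups <- rep(c("control", "treated"), each = 4)
  fit <- moderated_test(m, groups, prior_df = 0)
  for (g in c(1, 5, 10)) {
    tt <- stats::t.test(m[g, 5:8], m[g, 1:4], var.equal = TRUE)
    expect_equal(fit$t_mod[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(fit$p[g], tt$p.value, tolerance = 1e-12)
  }
  # identical group means -> zero effect, p = 1
  m[3, ] <- rep(c(1, 2, 3, 4), 2)
  fit2 <- moderated_test(m, groups)
  expect_equal(fit2$log2fc[3], 0)
  expect_equal(fit2$t_mod[3], 0)
  expect_equal(fit2$p[3], 1)
})

test_that("large prior df converges to the z-test against the prior variance", {
  set.seed(5)
  m <- matrix(stats::rnorm(160, 20, 1), nrow = 20)
  groups <- rep(c("control", "treated"), each = 4)
  # at huge prior df the posterior variance collapses onto the prior
  big <- moderated_test(m, groups, prior_df = 1e9)
  s0_big <- attr(big, "s0_sq")
  expect_equal(big$t_mod, big$log2fc / sqrt(s0_big * (1 / 4 + 1 / 4)),
               tolerance = 1e-6)
  expect_equal(big$p, 2 * stats::pnorm(-abs(big$t_mod)), tolerance = 1e-6)
  # and the infinite-prior z-test is exactly that closed form
  inf <- moderated_test(m, groups, prior_df = Inf)
  s0 <- attr(inf, "s0_sq")
  expect_equal(inf$t_mod, inf$log2fc / sqrt(s0 * (1 / 4 + 1 / 4)),
               tolerance = 1e-12)
  expect_equal(inf$p, 2 * stats::pnorm(-abs(inf$t_mod)), tolerance = 1e-12)
})

test_that("moderated test agrees with limma's empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  set.seed(6)
  m <- matrix(stats::rnorm(600, 22, 1.5), nrow = 75)
  m[1:10, 5:8] <- m[1:10, 5:8] + 2
  groups <- rep(c("control", "treated"), each = 4)
  fit <- moderated_test(m, groups)
  design <- cbind(1, groups == "treated")
  lf <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(fit$log2fc, unname(lf$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(attr(fit, "d0"), unname(lf$df.prior), tolerance = 1e-6)
  expect_equal(attr(fit, "s0_sq"), unname(lf$s2.prior), tolerance = 1e-6)
  expect_equal(fit$t_mod, unname(lf$t[, 2]), tolerance = 1e-6)
  # p-values: with an infinite estimated prior this package uses the
  # normal reference while limma caps the t df at the pooled residual
  # df, so agreement is close but not exact
  expect_equal(fit$p, unname(lf$p.value[, 2]), tolerance = 0.05)
})

test_that("proteins with too few observations are skipped, not imputed", {
  set.seed(7)
  m <- matrix(stats::rnorm(40, 20, 1), nrow = 5)
  m[2, 1:3] <- NA   # one control value left
  groups <- rep(c("control", "treated"), each = 4)
  fit <- moderated_test(m, groups)
  expect_equal(nrow(fit), 4L)
  expect_equal(attr(fit, "n_skipped"), 1L)
})

test_that("BH adjustment matches small worked examples and its bounds", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(8)
  p <- stats::runif(200)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p & adj <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DP calls require both significance and fold-change thresholds", {
  fits <- data.frame(protein = c("a", "b", "c", "d"),
                     log2fc = c(2, 0.86, 3, -1.4),
                     adj_p = c(0.01, 0.01, 0.06, 0.001))
  calls <- call_dps(fits)
  expect_equal(calls$is_dp, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(calls$direction, c("up", "up", "up", "down"))
})

test_that("fraction-level analysis finds nothing when conditions are identical", {
  sim <- generate_secms(synthetic_spec(n_proteins = 120), seed = 12)
  ds <- sim$dataset
  # duplicate control into treated so the two conditions are identical
  for (r in seq_len(ds$n_replicates)) for (f in seq_len(ds$n_fractions)) {
    jc <- sample_cols(ds, "control", r, f)
    jt <- sample_cols(ds, "treated", r, f)
    ds$intensity[, jt] <- ds$intensity[, jc]
  }
  fr <- suppressWarnings(fractionwise_differential(ds))
  expect_length(fr$union_dps, 0L)
  summed <- summed_differential(ds)
  expect_equal(sum(summed$is_dp), 0L)
})

test_that("a localized planted fold change lands in the stringent set", {
  spec <- synthetic_spec(n_proteins = 150, n_shifted = 1, noise_cv = 0.1,
                         missingness = FALSE)
  sim <- generate_secms(spec, seed = 21)
  fr <- suppressWarnings(fractionwise_differential(sim$dataset))
  shifted <- sim$truth$protein[sim$truth$label == "shifted"]
  expect_true(shifted %in% fr$stringent_dps)
  expect_true(all(fr$stringent_dps %in% fr$union_dps))
  expect_gte(fr$n_dp_fractions[[shifted]], 2L)
})
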