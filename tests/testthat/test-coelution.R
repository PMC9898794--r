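# Trace building, smoothing, sliding correlation, feature detection,
# decoys and FDR

test_that("internal gaps are spline-filled; edges are left at zero", {
  arr <- array(0, dim = c(2, 2, 2, 8))
  # protein 1: observed 0,10,missing,10,0 pattern inside the run
  for (cc in 1:2) for (r in 1:2) {
    arr[1, cc, r, c(2, 3, 5, 6)] <- c(5, 10, 10, 5)
    arr[2, cc, r, 1:8] <- 3
  }
  ds <- make_dataset(arr)
  tr <- build_traces(ds, normalize = "none")
  mask <- attr(tr, "interpolated")
  expect_true(mask[1, 4])
  expect_gt(tr[1, 4], 0)
  expect_equal(tr[1, 1], 0)          # leading gap untouched
  expect_equal(tr[1, 8], 0)          # trailing gap untouched
  expect_false(any(mask[2, ]))
  # interpolation only adds signal
  expect_gte(sum(tr), sum(ds$intensity))
})

test_that("without normalization the aggregate trace is the raw fraction sum", {
  set.seed(31)
  arr <- array(stats::runif(3 * 2 * 2 * 10, 10, 100), dim = c(3, 2, 2, 10))
  ds <- make_dataset(arr)
  tr <- build_traces(ds, normalize = "none")
  for (f in 1:10) {
    j <- sample_cols(ds, fraction = f)
    expect_equal(unname(tr[, f]), unname(rowSums(ds$intensity[, j])),
                 tolerance = 1e-9)
  }
})

test_that("trace totals never fall below raw totals on random fixtures", {
  for (seed in 1:5) {
    sim <- generate_secms(synthetic_spec(n_proteins = 60), seed = seed)
    tr <- build_traces(sim$dataset, normalize = "none")
    expect_gte(sum(tr) + 1e-9, sum(sim$dataset$intensity))
  }
})

test_that("moving-average smoothing conserves shape contracts", {
  expect_equal(smooth_traces(rep(4, 20)), rep(4, 20))      # constant unchanged
  imp <- c(rep(0, 9), 1, rep(0, 14))
  sm <- smooth_traces(imp, smoothing_length = 5)
  expect_equal(sm[8:12], rep(0.2, 5))
  expect_equal(sum(sm[-(8:12)]), 0)
  expect_equal(smooth_traces(imp, smoothing_length = 1), imp)  # identity
  expect_error(smooth_traces(imp, smoothing_length = 4), "odd")
})

test_that("sliding correlation matches the direct windowed Pearson oracle", {
  a <- gaussian_trace(8)
  b <- gaussian_trace(8, height = 7)          # same shape, different scale
  sc <- sliding_correlation(rbind(a, b), window_size = 5)
  expect_equal(sc[3:13], rep(1, 11), tolerance = 1e-12)
  # two peaks 6 fractions apart never reach the 0.9 cutoff
  c_ <- gaussian_trace(14)
  sc2 <- sliding_correlation(rbind(a, c_), window_size = 5)
  expect_lt(max(sc2), 0.9)
  expect_equal(sc2, oracle_windowed_corr(a, c_, 5), tolerance = 1e-12)
  # scale invariance
  expect_equal(sliding_correlation(rbind(3.7 * a, c_), window_size = 5), sc2,
               tolerance = 1e-12)
  expect_error(sliding_correlation(a), ">= 2 traces")
})

test_that("coeluting Gaussians yield a single well-scored candidate", {
  tr <- rbind(A = gaussian_trace(8), B = gaussian_trace(8, height = 4),
              C = gaussian_trace(8, height = 0.5))
  hyp <- complex_hypothesis("cx1", c("A", "B", "C"))
  cands <- detect_candidates(hyp, tr)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$apex, 8)
  expect_setequal(cands[[1]]$coeluting, c("A", "B", "C"))
  expect_equal(cands[[1]]$completeness, 1)
  expect_gt(cands[[1]]$score, 0.99)
  # no coelution -> empty list
  tr2 <- rbind(A = gaussian_trace(4), B = gaussian_trace(18))
  expect_length(detect_candidates(complex_hypothesis("cx2", c("A", "B")), tr2),
                0L)
  # detection invariant to positive rescaling and subunit order
  cands_s <- detect_candidates(hyp, tr * c(10, 0.1, 3))
  expect_equal(cands_s[[1]]$apex, cands[[1]]$apex)
  expect_setequal(cands_s[[1]]$coeluting, cands[[1]]$coeluting)
  cands_p <- detect_candidates(complex_hypothesis("cx1", c("C", "A", "B")),
                               tr[c(3, 1, 2), ])
  expect_equal(cands_p[[1]]$score, cands[[1]]$score, tolerance = 1e-12)
})

test_that("nearby candidates sharing subunits collapse without losing members", {
  c1 <- list(complex_id = "x", complex_name = "x", apex = 8, left = 6,
             right = 9, coeluting = c("A", "B"), n_subunits_annotated = 4L,
             mean_corr = 0.95, completeness = 0.5, score = 0.475)
  c2 <- list(complex_id = "x", complex_name = "x", apex = 9, left = 8,
             right = 11, coeluting = c("B", "C", "D"),
             n_subunits_annotated = 4L, mean_corr = 0.92,
             completeness = 0.75, score = 0.69)
  merged <- collapse_candidates(list(c1, c2), rt_height = 1)
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$left, 6)
  expect_equal(merged[[1]]$right, 11)
  expect_setequal(merged[[1]]$coeluting, c("A", "B", "C", "D"))
  expect_equal(merged[[1]]$completeness, 1)
  # apexes too far apart: no merge
  c2$apex <- 12
  expect_length(collapse_candidates(list(c1, c2), rt_height = 1), 2L)
})

test_that("MW-consistency filter keeps assembled features only", {
  model <- fit_calibration(data.frame(fraction = c(5, 15),
                                      mw_kda = c(1000, 10)))
  mk <- function(apex) list(complex_id = "x", complex_name = "x",
                            apex = apex, left = apex - 1, right = apex + 1,
                            coeluting = c("A", "B"),
                            n_subunits_annotated = 2L, mean_corr = 1,
                            completeness = 1, score = 1)
  mw <- c(A = 40, B = 20)
  # fraction 7.5 ~ 316 kDa >= 1.2 * 40 -> kept; fraction ~13.7 (45 kDa) kept
  # too, but a monomer-level apex is removed
  f_at <- function(kda) round(mw_to_fraction(model, kda))
  kept <- mw_consistency_filter(list(mk(f_at(300))), model, mw)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$apparent_mw_kda,
               unname(apparent_mw(model, f_at(300))))
  removed <- mw_consistency_filter(list(mk(f_at(45))), model, mw)
  expect_length(removed, 0L)
  expect_equal(attr(removed, "n_removed"), 1L)
  # factor 0 disables the filter
  expect_length(mw_consistency_filter(list(mk(f_at(45))), model, mw,
                                      factor = 0), 1L)
})

test_that("decoy complexes are size-matched and never share a reference complex", {
  hyps <- list(complex_hypothesis("c1", c("A", "B", "C")),
               complex_hypothesis("c2", c("C", "D")),
               complex_hypothesis("c3", c("E", "F", "G", "H")))
  pool <- c(LETTERS[1:12], paste0("Z", 1:8))
  d1 <- generate_decoys(hyps, pool, seed = 5)
  d2 <- generate_decoys(hyps, pool, seed = 5)
  expect_identical(d1, d2)
  expect_equal(sort(vapply(d1, function(h) length(h$subunits), integer(1))),
               sort(vapply(hyps, function(h) length(h$subunits), integer(1))))
  member_of <- function(id) vapply(hyps, function(h) id %in% h$subunits,
                                   logical(1))
  for (d in d1) {
    mm <- vapply(d$subunits, member_of, logical(length(hyps)))
    expect_true(all(rowSums(mm) <= 1))   # no complex holds two decoy members
  }
})

test_that("decoy-based q-values accept clear signal and control the null", {
  mk <- function(id, score, n_coel = 3L)
    list(complex_id = id, complex_name = id, apex = 8, left = 6, right = 10,
         coeluting = paste0(id, "_", seq_len(n_coel)),
         n_subunits_annotated = n_coel, mean_corr = score,
         completeness = 1, score = score)
  targets <- lapply(1:6, function(i) mk(paste0("t", i), 0.9 + i / 100))
  decoys <- lapply(1:6, function(i) mk(paste0("d", i), 0.3 + i / 100))
  sc <- score_and_fdr(targets, decoys, fdr = 0.05)
  tt <- sc[!sc$is_decoy, ]
  expect_equal(tt$q_value, rep(0, 6))
  expect_true(all(tt$accepted))
  # q-values are non-increasing in score
  mixed <- score_and_fdr(c(targets, lapply(1:4, function(i)
    mk(paste0("w", i), 0.35 + i / 100))), decoys, fdr = 0.05)
  mt <- mixed[!mixed$is_decoy, ]
  ord <- order(mt$score)
  expect_true(all(diff(mt$q_value[ord]) <= 1e-12))
  expect_error(score_and_fdr(targets, NULL), "decoy")
  # decoy queries that yield no features: clean targets keep q = 0
  none <- suppressMessages(score_and_fdr(targets, list(), fdr = 0.05))
  expect_true(all(none$q_value == 0))
  expect_true(all(none$accepted))
  # best-feature selection: most coeluting subunits wins over score
  two <- list(mk("t1", 0.99, n_coel = 2L), mk("t1", 0.80, n_coel = 4L))
  best <- score_and_fdr(two, decoys, fdr = 0.05)
  expect_equal(best$n_coeluting[best$complex_id == "t1"], 4L)
})

test_that("targets drawn from the decoy null are almost never accepted", {
  accepted <- 0; total <- 0
  for (seed in 1:5) {
    set.seed(seed)
    mk_rand <- function(id) {
      tr <- matrix(stats::runif(3 * 24), nrow = 3)
      sc <- max(sliding_correlation(smooth_traces(tr)))
      list(complex_id = id, complex_name = id, apex = 8, left = 6,
           right = 10, coeluting = paste0(id, 1:3),
           n_subunits_annotated = 3L, mean_corr = sc, completeness = 1,
           score = sc)
    }
    targets <- lapply(sprintf("t%02d", 1:30), mk_rand)
    decoys <- lapply(sprintf("d%02d", 1:30), mk_rand)
    sc <- score_and_fdr(targets, decoys, fdr = 0.05)
    accepted <- accepted + sum(sc$accepted)
    total <- total + 30
  }
  expect_lte(accepted / total, 0.07)
})

test_that("differential-complex report flags dissociation and degenerate ratios", {
  spec <- synthetic_spec(n_proteins = 60, n_complexes = 4, complex_size = 3,
                         n_dissociated = 2, missingness = FALSE,
                         noise_cv = 0.05)
  sim <- generate_secms(spec, seed = 41)
  ds <- sim$dataset
  fr <- suppressWarnings(fractionwise_differential(ds))
  model <- fit_calibration(default_calibration_standards())
  hyps <- lapply(sim$complexes, function(cx)
    complex_hypothesis(cx$complex_id, cx$subunits))
  tr <- build_traces(ds, normalize = "none")
  feats <- detect_features(hyps, tr)
  decoys <- generate_decoys(hyps, rownames(tr), seed = 2)
  dfeats <- detect_features(decoys, tr)
  # force acceptance of everything detected for report testing
  sc <- score_and_fdr(feats, if (length(dfeats)) dfeats else
    list(list(complex_id = "DECOY_x", complex_name = "x", apex = 2,
              left = 1, right = 3, coeluting = c("a", "b"),
              n_subunits_annotated = 2L, mean_corr = 0, completeness = 1,
              score = 0)), fdr = 1)
  rep_tab <- differential_complex_report(sc, fr, ds)
  dis_ids <- vapply(sim$complexes[vapply(sim$complexes, `[[`, logical(1),
                                         "dissociated")],
                    `[[`, character(1), "complex_id")
  hit <- rep_tab[rep_tab$complex_id %in% dis_ids, ]
  expect_gt(nrow(hit), 0)
  expect_true(all(hit$log2_ratio < -1))
  # complex fully absent in treated within bounds -> floored ratio
  ds2 <- ds
  first_cx <- sim$complexes[[1]]
  ridx <- first_cx$member_idx
  jt <- sample_cols(ds2, condition = "treated")
  ds2$intensity[ridx, jt] <- 0
  rep2 <- differential_complex_report(sc[sc$complex_id == "CPX001", , drop = FALSE],
                                      fr, ds2)
  if (nrow(rep2)) {
    expect_true(all(rep2$ratio_floored))
    expect_true(all(rep2$log2_ratio <= -30))
  }
})
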