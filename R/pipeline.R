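# Pipeline orchestration: a validated run configuration, a one-call
# driver over all stages, and a full-study reproduction entry point for
# a deposited proteinGroups table.

#' Build and validate a run configuration
#'
#' All stage parameters in one place, each defaulting to the pipeline's
#' standard value. Validation happens up front, before any stage runs.
#'
#' @param min_peptides,min_replicates preprocessing thresholds
#'   (defaults 2, 3).
#' @param alpha,lfc differential-protein thresholds (defaults 0.05, 1).
#' @param impute_shift,impute_width left-censored imputation parameters
#'   (defaults 1.8, 0.3).
#' @param stringency minimum significant fractions for the stringent DP
#'   set (default 2).
#' @param normalization \code{"vsn_glog"} or \code{"median_log2"}.
#' @param corr_cutoff,window_size,rt_height,smoothing_length coelution
#'   detection parameters (defaults 0.9, 5, 1, 5).
#' @param fdr coelution acceptance FDR (default 0.05).
#' @param min_distance decoy co-membership distance (default 2).
#' @param assembled_factor monomer distance factor for the MW filter and
#'   mass split (default 1.2).
#' @param trace_normalization trace cross-normalization
#'   (\code{"cyclic_loess"}, \code{"median"}, \code{"none"}).
#' @param seed root seed; stage seeds are derived from it (default 1).
#' @return validated list of class \code{RunConfig}.
#' @export
run_config <- function(min_peptides = 2L, min_replicates = 3L,
                       alpha = 0.05, lfc = 1,
                       impute_shift = 1.8, impute_width = 0.3,
                       stringency = 2L,
                       normalization = c("vsn_glog", "median_log2"),
                       corr_cutoff = 0.9, window_size = 5L,
                       rt_height = 1L, smoothing_length = 5L,
                       fdr = 0.05, min_distance = 2L,
                       assembled_factor = 1.2,
                       trace_normalization = c("cyclic_loess", "median",
                                               "none"),
                       seed = 1L) {
  normalization <- match.arg(normalization)
  trace_normalization <- match.arg(trace_normalization)
  cfg <- as.list(environment())
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stop("fdr must lie in (0, 1)")
  if (cfg$lfc < 0) stop("lfc must be nonnegative")
  if (cfg$impute_width <= 0) stop("impute_width must be positive")
  if (cfg$corr_cutoff < -1 || cfg$corr_cutoff > 1)
    stop("corr_cutoff must lie in [-1, 1]")
  if (cfg$window_size %% 2L == 0L || cfg$smoothing_length %% 2L == 0L)
    stop("window_size and smoothing_length must be odd")
  if (cfg$stringency < 1L) stop("stringency must be >= 1")
  if (cfg$seed < 0L || cfg$seed > 2^31 - 100) stop("seed out of range")
  class(cfg) <- "RunConfig"
  cfg
}

# Deterministic per-stage seeds derived from the root seed.
stage_seed <- function(cfg, stage) {
  offsets <- c(impute = 11L, decoy = 29L, simulate = 47L)
  (as.integer(cfg$seed) + offsets[[stage]]) %% (2^31 - 1)
}

#' Default molecular-weight calibration standards
#'
#' An editable example standards table lying on the package's default
#' synthetic calibration line (\code{log10(kDa) = 4.1 - 0.12 f}); real
#' analyses should supply the standards measured on their own column
#' via \code{\link{read_calibration_standards}}.
#'
#' @return data.frame with columns \code{fraction}, \code{mw_kda}.
#' @export
default_calibration_standards <- function() {
  f <- c(2, 6, 10, 14, 18, 22)
  data.frame(fraction = f, mw_kda = 10^(4.1 - 0.12 * f))
}

#' Run the full differential SEC-MS pipeline
#'
#' Executes preprocess, calibration, summed differential, per-fraction
#' differential, coelution detection with decoy FDR, and the
#' differential-complex report. Writes result tables plus a JSON summary
#' if \code{out_dir} is given; always returns all stage results.
#'
#' @param dataset an \code{ElutionDataset} (raw, as read).
#' @param hypotheses list of complex hypotheses (may be empty to skip
#'   the coelution stage).
#' @param standards calibration standards data.frame; default
#'   \code{\link{default_calibration_standards}()}.
#' @param config a \code{RunConfig}.
#' @param out_dir optional output directory.
#' @return list with \code{filter_report}, \code{dataset} (preprocessed),
#'   \code{calibration}, \code{mass_split}, \code{summed},
#'   \code{fractionwise}, \code{traces}, \code{features} (scored table),
#'   \code{complex_report}, \code{summary}.
#' @export
run_all <- function(dataset, hypotheses = list(),
                    standards = default_calibration_standards(),
                    config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- Sys.time()

  fc <- filter_cascade(dataset, min_peptides = config$min_peptides)
  ds <- consolidate(fc$dataset)
  n_consolidated <- n_proteins(ds)
  rp <- replicate_presence_filter(ds, min_replicates = config$min_replicates)
  ds <- rp$dataset
  filter_report <- c(fc$report,
                     n_after_consolidation = n_consolidated,
                     n_after_replicate_filter = rp$report$n_after_replicate_filter)

  model <- fit_calibration(standards)
  mass_split <- tryCatch(
    assembled_mass_split(ds, model, factor = config$assembled_factor),
    error = function(e) NULL)

  summed <- summed_differential(
    ds, alpha = config$alpha, min_abs_lfc = config$lfc,
    normalization = config$normalization,
    impute_shift = config$impute_shift, impute_width = config$impute_width,
    seed = stage_seed(config, "impute"))

  fractionwise <- fractionwise_differential(
    ds, alpha = config$alpha, min_abs_lfc = config$lfc,
    stringency = config$stringency, normalization = config$normalization)

  traces <- NULL; scored <- NULL; complex_report <- NULL
  if (length(hypotheses)) {
    traces <- build_traces(ds, normalize = config$trace_normalization)
    target_feats <- detect_features(
      hypotheses, traces, corr_cutoff = config$corr_cutoff,
      window_size = config$window_size, rt_height = config$rt_height,
      smoothing_length = config$smoothing_length)
    mono_mw <- stats::setNames(ds$meta$monomer_mw_kda, protein_labels(ds))
    target_feats <- mw_consistency_filter(target_feats, model, mono_mw,
                                          factor = config$assembled_factor)
    decoys <- generate_decoys(hypotheses, rownames(traces),
                              min_distance = config$min_distance,
                              seed = stage_seed(config, "decoy"))
    decoy_feats <- detect_features(
      decoys, traces, corr_cutoff = config$corr_cutoff,
      window_size = config$window_size, rt_height = config$rt_height,
      smoothing_length = config$smoothing_length)
    decoy_feats <- mw_consistency_filter(decoy_feats, model, mono_mw,
                                         factor = config$assembled_factor)
    scored <- if (length(decoys))
      suppressMessages(score_and_fdr(target_feats, decoy_feats,
                                     fdr = config$fdr))
    else NULL
    if (!is.null(scored))
      complex_report <- differential_complex_report(scored, fractionwise, ds)
  }

  summary <- list(
    config = unclass(config),
    filter_report = filter_report,
    n_proteins_analyzed = n_proteins(ds),
    n_summed_dps = sum(summed$is_dp),
    n_summed_dps_up = sum(summed$is_dp & summed$direction == "up"),
    n_summed_dps_down = sum(summed$is_dp & summed$direction == "down"),
    n_fraction_union_dps = length(fractionwise$union_dps),
    n_stringent_dps = length(fractionwise$stringent_dps),
    n_hypotheses = length(hypotheses),
    n_accepted_complexes = if (!is.null(scored))
      sum(scored$accepted) else 0L,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(summed, file.path(out_dir, "summed_differential.tsv"))
    write_table(
      data.frame(protein = names(fractionwise$n_dp_fractions),
                 n_dp_fractions = as.integer(fractionwise$n_dp_fractions),
                 stringent = names(fractionwise$n_dp_fractions) %in%
                   fractionwise$stringent_dps),
      file.path(out_dir, "fraction_dps.tsv"))
    if (!is.null(mass_split))
      write_table(mass_split, file.path(out_dir, "assembled_mass_split.tsv"))
    if (!is.null(scored))
      write_table(scored, file.path(out_dir, "complex_features.tsv"))
    if (!is.null(complex_report))
      write_table(complex_report,
                  file.path(out_dir, "differential_complexes.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(filter_report = filter_report, dataset = ds, calibration = model,
       mass_split = mass_split, summed = summed,
       fractionwise = fractionwise, traces = traces, features = scored,
       complex_report = complex_report, summary = summary)
}

#' Reproduce the full analysis from a deposited proteinGroups table
#'
#' Runs the complete preprocessing and differential workflow on a
#' MaxQuant proteinGroups.txt export of a 2-condition x 4-replicate x
#' 24-fraction SEC-MS study and returns the headline counts: records
#' after the filter cascade, unique proteins after consolidation,
#' proteins passing the replicate-presence filter, summed DPs,
#' all-fraction DPs, and stringent fraction DPs.
#'
#' @param path path to the proteinGroups.txt table.
#' @param control_token,treated_token condition tokens inside the LFQ
#'   intensity column names.
#' @param config a \code{RunConfig}.
#' @return list of counts plus the underlying stage results.
#' @export
reproduce_study <- function(path, control_token = "Ctrl",
                            treated_token = "HSP90i",
                            config = run_config()) {
  header <- names(utils::read.delim(path, nrows = 1, check.names = FALSE))
  cmap <- auto_column_map(header, control_token = control_token,
                          treated_token = treated_token)
  raw <- read_proteingroups(path, cmap)
  res <- run_all(raw, hypotheses = list(), config = config)
  list(n_input = res$filter_report$n_input,
       n_after_cascade = res$filter_report$n_after_cascade,
       n_after_consolidation = res$filter_report$n_after_consolidation,
       n_after_replicate_filter = res$filter_report$n_after_replicate_filter,
       n_summed_dps = res$summary$n_summed_dps,
       n_fraction_union_dps = res$summary$n_fraction_union_dps,
       n_stringent_dps = res$summary$n_stringent_dps,
       results = res)
}
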