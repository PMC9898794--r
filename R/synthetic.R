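# Synthetic SEC-MS generator: Gaussian elution peaks placed by a
# log-linear MW calibration, monomer + assembled subpopulations,
# multiplicative replicate noise, intensity-dependent (left-censored)
# missingness, and planted condition effects with ground-truth labels.

#' Specification of a synthetic SEC-MS experiment
#'
#' Collects the generator parameters. Elution peaks are Gaussian in the
#' fraction index with centers placed by the log-linear calibration
#' \code{log10(mw) = calibration_intercept + calibration_slope * f}.
#' Proteins carry a monomer component at their monomer MW and,
#' optionally, an assembled component at a higher MW; planted effects
#' multiply expected intensities in the treated condition.
#'
#' @param n_proteins number of proteins (default 1000).
#' @param n_fractions,n_replicates design size (defaults 24 and 4).
#' @param calibration_slope,calibration_intercept log-linear calibration
#'   used to place peak centers (defaults -0.12 and 4.1, spanning
#'   roughly 10 to 10000 kDa over 24 fractions).
#' @param abundance_meanlog2,abundance_sdlog2 log2-normal protein
#'   abundance distribution (defaults 24 and 1.5).
#' @param monomer_mw_meanlog,monomer_mw_sdlog log-normal monomer MW in
#'   kDa (defaults log(60) and 0.9, matching the spread of annotated
#'   human protein masses: median ~55-60 kDa, 5th-95th percentile
#'   roughly 15-250 kDa).
#' @param peak_sd Gaussian peak width in fractions (default 1.0).
#' @param assembled_fraction probability that an unperturbed protein
#'   carries an assembled component (default 0.4).
#' @param assembled_weight weight of the assembled component when
#'   present (default 0.5).
#' @param noise_cv multiplicative replicate noise coefficient of
#'   variation (default 0.2; log-normal with
#'   \code{sdlog = sqrt(log(1 + cv^2))}).
#' @param missingness logical: apply intensity-dependent missingness
#'   (default TRUE).
#' @param missing_midpoint,missing_width logistic missingness in log2
#'   intensity: a cell of log2 value v is missing with probability
#'   \code{plogis((missing_midpoint - v) / missing_width)} (defaults 17
#'   and 1.5).
#' @param n_induced,n_depleted,n_shifted planted effect counts
#'   (defaults 0).
#' @param effect_factor fold change for induction/depletion (default 4,
#'   i.e. |log2FC| = 2, comfortably above the DP threshold of 1).
#' @param n_complexes,complex_size,n_dissociated planted coeluting
#'   complexes: total count, members each, and how many lose their
#'   assembled component in the treated condition (defaults 0, 3, 0).
#' @param complex_stoichiometries candidate copy numbers per complex
#'   (default \code{c(1, 2, 4, 8)}, drawn uniformly): the complex MW is
#'   the summed member MW times the drawn stoichiometry, reflecting the
#'   prevalence of higher-order oligomers among real assemblies.
#' @return object of class \code{SyntheticSpec}.
#' @export
synthetic_spec <- function(n_proteins = 1000L, n_fractions = 24L,
                           n_replicates = 4L,
                           calibration_slope = -0.12,
                           calibration_intercept = 4.1,
                           abundance_meanlog2 = 24,
                           abundance_sdlog2 = 1.5,
                           monomer_mw_meanlog = log(60),
                           monomer_mw_sdlog = 0.9,
                           peak_sd = 1.0,
                           assembled_fraction = 0.4,
                           assembled_weight = 0.5,
                           noise_cv = 0.2,
                           missingness = TRUE,
                           missing_midpoint = 17,
                           missing_width = 1.5,
                           n_induced = 0L, n_depleted = 0L,
                           n_shifted = 0L, effect_factor = 4,
                           n_complexes = 0L, complex_size = 3L,
                           n_dissociated = 0L,
                           complex_stoichiometries = c(1, 2, 4, 8)) {
  spec <- as.list(environment())
  if (spec$effect_factor <= 0) stop("effect_factor must be positive")
  if (spec$peak_sd <= 0) stop("peak_sd must be positive")
  if (spec$noise_cv < 0) stop("noise_cv must be nonnegative")
  if (spec$n_dissociated > spec$n_complexes)
    stop("n_dissociated cannot exceed n_complexes")
  n_eff <- spec$n_induced + spec$n_depleted + spec$n_shifted +
    spec$n_complexes * spec$complex_size
  if (n_eff > spec$n_proteins)
    stop("planted effects require more proteins than n_proteins")
  class(spec) <- "SyntheticSpec"
  spec
}

#' Generate a synthetic SEC-MS dataset with ground truth
#'
#' Expected intensity of protein p in fraction f is
#' \code{A_p * sum_k w_k * exp(-(f - mu_k)^2 / (2 * sd_k^2))}; condition
#' effects multiply expected intensities, replicate values multiply in
#' log-normal noise, and each cell is independently set missing with the
#' logistic left-censoring probability. Zeros encode missing. The output
#' is deterministic given the seed.
#'
#' Planted effect classes: \emph{induced} proteins are multiplied by
#' \code{effect_factor} in all fractions of the treated condition;
#' \emph{depleted} proteins (monomer-only) are divided by it;
#' \emph{shifted} proteins move mass between their monomer and assembled
#' components (weights 0.8/0.2 in control, 0.2/0.8 in treated);
#' \emph{dissociated} complexes lose their assembled component in the
#' treated condition. Complex members share an assembled peak at the
#' summed MW of their members.
#'
#' @param spec a \code{SyntheticSpec}.
#' @param seed integer seed.
#' @return list with \code{dataset} (an \code{ElutionDataset}),
#'   \code{truth} (data.frame \code{protein}, \code{label},
#'   \code{complex_id}), \code{complexes} (planted hypotheses with a
#'   \code{dissociated} flag), \code{expected_log2_effect} (proteins x
#'   fractions matrix of planted log2 treated/control expectation
#'   ratios), and \code{calibration} (the generating model parameters).
#' @export
generate_secms <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(seed)
  n <- spec$n_proteins
  f_n <- spec$n_fractions
  fr <- seq_len(f_n)
  mw_to_f <- function(mw)
    (log10(mw) - spec$calibration_intercept) / spec$calibration_slope

  acc <- sprintf("SP%05d", seq_len(n))
  gene <- sprintf("SIM%05d", seq_len(n))
  mono_mw <- stats::rlnorm(n, spec$monomer_mw_meanlog, spec$monomer_mw_sdlog)
  abun <- 2^stats::rnorm(n, spec$abundance_meanlog2, spec$abundance_sdlog2)

  label <- rep("null", n)
  cx_id <- rep(NA_character_, n)
  idx <- seq_len(n)
  take <- function(k) {
    out <- idx[seq_len(k)]
    idx <<- idx[-seq_len(k)]
    out
  }
  i_ind <- if (spec$n_induced) take(spec$n_induced) else integer()
  i_dep <- if (spec$n_depleted) take(spec$n_depleted) else integer()
  i_shf <- if (spec$n_shifted) take(spec$n_shifted) else integer()
  label[i_ind] <- "induced"
  label[i_dep] <- "depleted"
  label[i_shf] <- "shifted"
  complexes <- list()
  if (spec$n_complexes) {
    stoich <- sample(spec$complex_stoichiometries, spec$n_complexes,
                     replace = TRUE)
    for (c_i in seq_len(spec$n_complexes)) {
      members <- take(spec$complex_size)
      label[members] <- "complex_member"
      id <- sprintf("CPX%03d", c_i)
      cx_id[members] <- id
      complexes[[c_i]] <- list(
        complex_id = id, complex_name = id,
        subunits = gene[members], member_idx = members,
        stoichiometry = stoich[c_i],
        dissociated = c_i <= spec$n_dissociated)
    }
  }

  # per-protein component table: weights per condition, centers, widths
  gaussian <- function(mu) exp(-(outer(mu, fr, `-`))^2 / (2 * spec$peak_sd^2))
  mono_centers <- mw_to_f(mono_mw)
  has_asm <- rep(FALSE, n)
  asm_centers <- rep(NA_real_, n)
  w_mono_ctl <- rep(1, n); w_asm_ctl <- rep(0, n)
  w_mono_trt <- rep(1, n); w_asm_trt <- rep(0, n)

  null_idx <- which(label == "null")
  asm_draw <- null_idx[stats::runif(length(null_idx)) < spec$assembled_fraction]
  has_asm[asm_draw] <- TRUE
  asm_centers[asm_draw] <- mw_to_f(mono_mw[asm_draw] *
                                     stats::runif(length(asm_draw), 4, 12))
  w_mono_ctl[asm_draw] <- w_mono_trt[asm_draw] <- 1 - spec$assembled_weight
  w_asm_ctl[asm_draw] <- w_asm_trt[asm_draw] <- spec$assembled_weight

  if (length(i_shf)) {
    has_asm[i_shf] <- TRUE
    asm_centers[i_shf] <- mw_to_f(mono_mw[i_shf] *
                                    stats::runif(length(i_shf), 6, 12))
    w_mono_ctl[i_shf] <- 0.8; w_asm_ctl[i_shf] <- 0.2
    w_mono_trt[i_shf] <- 0.2; w_asm_trt[i_shf] <- 0.8
  }
  for (cx in complexes) {
    m <- cx$member_idx
    has_asm[m] <- TRUE
    asm_centers[m] <- mw_to_f(sum(mono_mw[m]) * cx$stoichiometry)
    w_mono_ctl[m] <- w_mono_trt[m] <- 0.5
    w_asm_ctl[m] <- 0.5
    w_asm_trt[m] <- if (cx$dissociated) 0 else 0.5
  }

  g_mono <- gaussian(mono_centers)
  g_asm <- gaussian(ifelse(is.na(asm_centers), 1, asm_centers))
  g_asm[!has_asm, ] <- 0
  e_ctl <- abun * (w_mono_ctl * g_mono + w_asm_ctl * g_asm)
  e_trt <- abun * (w_mono_trt * g_mono + w_asm_trt * g_asm)
  if (length(i_ind)) e_trt[i_ind, ] <- e_trt[i_ind, ] * spec$effect_factor
  if (length(i_dep)) e_trt[i_dep, ] <- e_trt[i_dep, ] / spec$effect_factor
  expected_log2_effect <- log2((e_trt + 1e-300) / (e_ctl + 1e-300))

  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  grid <- expand.grid(condition = .CONDITIONS,
                      replicate = seq_len(spec$n_replicates),
                      fraction = fr, stringsAsFactors = FALSE)
  # canonical design ordering: condition, replicate, fraction
  grid <- grid[order(grid$condition, grid$replicate, grid$fraction), ]
  rownames(grid) <- NULL
  intens <- matrix(0, nrow = n, ncol = nrow(grid))
  for (j in seq_len(nrow(grid))) {
    e <- if (grid$condition[j] == "control") e_ctl[, grid$fraction[j]] else
      e_trt[, grid$fraction[j]]
    v <- e * exp(stats::rnorm(n, 0, sdlog))
    if (spec$missingness) {
      p_miss <- stats::plogis((spec$missing_midpoint - log2(pmax(v, 1e-300))) /
                                spec$missing_width)
      v[stats::runif(n) < p_miss] <- 0
    }
    intens[, j] <- v
  }

  meta <- data.frame(protein_ids = acc, gene_name = gene,
                     n_peptides = 2L + stats::rpois(n, 8),
                     is_contaminant = FALSE, is_reverse = FALSE,
                     only_by_site = FALSE, monomer_mw_kda = mono_mw,
                     stringsAsFactors = FALSE)
  ds <- elution_dataset(intens, grid[, c("condition", "replicate", "fraction")],
                        meta,
                        provenance = sprintf("generate_secms(seed = %d)", seed))
  truth <- data.frame(protein = gene, label = label, complex_id = cx_id,
                      stringsAsFactors = FALSE)
  list(dataset = ds, truth = truth, complexes = complexes,
       expected_log2_effect = expected_log2_effect,
       calibration = list(slope = spec$calibration_slope,
                          intercept = spec$calibration_intercept))
}

#' Write a generated dataset as a proteinGroups-like table
#'
#' Emits a tab-delimited table with MaxQuant-style columns readable by
#' \code{\link{read_proteingroups}} with \code{\link{auto_column_map}}:
#' LFQ intensity columns named
#' \code{"LFQ intensity <condition>_<replicate>_F<fraction>"}, peptide
#' counts >= 2, flags unset, monomer MW column filled. Optionally spikes
#' in flagged contaminant rows for filter testing.
#'
#' @param dataset an \code{ElutionDataset}.
#' @param path destination path.
#' @param n_contaminants number of synthetic contaminant-flagged rows to
#'   append (default 0).
#' @export
write_proteingroups_like <- function(dataset, path, n_contaminants = 0L) {
  m <- dataset$meta
  tab <- data.frame(
    `Protein IDs` = m$protein_ids,
    `Gene names` = m$gene_name,
    `Peptides` = pmax(m$n_peptides, 2L),
    `Mol. weight [kDa]` = m$monomer_mw_kda,
    `Potential contaminant` = "",
    `Reverse` = "",
    `Only identified by site` = "",
    check.names = FALSE, stringsAsFactors = FALSE)
  ints <- as.data.frame(dataset$intensity)
  names(ints) <- sprintf("LFQ intensity %s_%d_F%02d",
                         dataset$design$condition,
                         dataset$design$replicate,
                         dataset$design$fraction)
  tab <- cbind(tab, ints)
  if (n_contaminants > 0L) {
    spike <- tab[rep(1L, n_contaminants), , drop = FALSE]
    spike$`Protein IDs` <- sprintf("CON__%04d", seq_len(n_contaminants))
    spike$`Gene names` <- ""
    spike$`Potential contaminant` <- "+"
    tab <- rbind(tab, spike)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Recovery metrics against planted ground truth
#'
#' Compares a set of called proteins with the generator's truth labels:
#' per effect class, sensitivity and counts; overall, the empirical
#' false discovery rate (calls whose truth label is not a positive
#' class, over all calls; 0 when there are no calls).
#'
#' @param calls character vector of called protein identifiers.
#' @param truth truth data.frame from \code{\link{generate_secms}}.
#' @param positive_classes truth labels counted as true positives
#'   (default \code{c("induced", "depleted")}).
#' @return list with \code{per_class} (data.frame class, n_true,
#'   n_recovered, sensitivity), \code{n_calls}, \code{n_false},
#'   \code{fdr}, \code{sensitivity} (pooled over positive classes).
#' @export
evaluate_recovery <- function(calls, truth,
                              positive_classes = c("induced", "depleted")) {
  calls <- unique(as.character(calls))
  unknown <- setdiff(calls, truth$protein)
  if (length(unknown))
    stop("calls outside the truth protein universe: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  per_class <- do.call(rbind, lapply(positive_classes, function(cl) {
    tp_set <- truth$protein[truth$label == cl]
    data.frame(class = cl, n_true = length(tp_set),
               n_recovered = sum(calls %in% tp_set),
               sensitivity = if (length(tp_set))
                 sum(calls %in% tp_set) / length(tp_set) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pos_set <- truth$protein[truth$label %in% positive_classes]
  n_false <- sum(!calls %in% pos_set)
  list(per_class = per_class,
       n_calls = length(calls),
       n_false = n_false,
       fdr = if (length(calls)) n_false / length(calls) else 0,
       sensitivity = if (length(pos_set))
         sum(calls %in% pos_set) / length(pos_set) else NA_real_)
}
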