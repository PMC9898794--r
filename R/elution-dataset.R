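#' @keywords internal
"_PACKAGE"

# Conditions are fixed labels throughout: the untreated reference is
# "control", the perturbed condition "treated".
.CONDITIONS <- c("control", "treated")

#' Construct an ElutionDataset
#'
#' The central container of the package: a protein x sample intensity
#' matrix over the full factorial design condition x replicate x fraction,
#' together with per-protein identity metadata. Following the MaxQuant LFQ
#' convention, an intensity of exactly 0 means "not observed"; all stored
#' values are nonnegative.
#'
#' @param intensity numeric matrix, proteins in rows, one column per
#'   (condition, replicate, fraction) cell of the design; nonnegative,
#'   0 = missing.
#' @param design data.frame with columns \code{condition} ("control" or
#'   "treated"), \code{replicate} (1..R) and \code{fraction} (1..F), one
#'   row per column of \code{intensity}, covering the full grid exactly
#'   once.
#' @param meta data.frame with one row per protein: \code{protein_ids}
#'   (";"-separated accessions), \code{gene_name}, \code{n_peptides},
#'   logical flags \code{is_contaminant}, \code{is_reverse},
#'   \code{only_by_site}, and \code{monomer_mw_kda} (NA if unknown).
#' @param provenance character vector: free-text processing log.
#'
#' @return An object of class \code{ElutionDataset}.
#' @export
elution_dataset <- function(intensity, design, meta, provenance = character()) {
  intensity <- as.matrix(intensity)
  if (!is.numeric(intensity)) stop("intensity must be numeric")
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be nonnegative")
  intensity[is.na(intensity)] <- 0
  design$condition <- as.character(design$condition)
  if (!all(design$condition %in% .CONDITIONS))
    stop("design conditions must be 'control'/'treated'")
  design$replicate <- as.integer(design$replicate)
  design$fraction <- as.integer(design$fraction)
  n_f <- max(design$fraction)
  n_r <- max(design$replicate)
  if (n_f < 2L || n_r < 2L)
    stop("design requires at least 2 fractions and 2 replicates")
  key <- with(design, paste(condition, replicate, fraction))
  full <- with(
    expand.grid(condition = .CONDITIONS, replicate = seq_len(n_r),
                fraction = seq_len(n_f), stringsAsFactors = FALSE),
    paste(condition, replicate, fraction))
  if (anyDuplicated(key) || !setequal(key, full))
    stop("design must cover the full condition x replicate x fraction grid exactly once")
  if (nrow(design) != ncol(intensity))
    stop("design rows must match intensity columns")
  if (nrow(meta) != nrow(intensity))
    stop("meta rows must match intensity rows")
  meta$protein_ids <- as.character(meta$protein_ids)
  if (any(!nzchar(meta$protein_ids))) stop("protein_ids must be non-empty")
  for (fl in c("is_contaminant", "is_reverse", "only_by_site"))
    if (is.null(meta[[fl]])) meta[[fl]] <- FALSE
  if (is.null(meta$monomer_mw_kda)) meta$monomer_mw_kda <- NA_real_
  if (is.null(meta$gene_name)) meta$gene_name <- ""
  if (is.null(meta$n_peptides)) meta$n_peptides <- 0L
  colnames(intensity) <- with(design, sprintf("%s_%d_F%02d", condition,
                                              replicate, fraction))
  rownames(meta) <- NULL
  structure(
    list(intensity = intensity, design = design, meta = meta,
         n_fractions = n_f, n_replicates = n_r,
         provenance = as.character(provenance)),
    class = "ElutionDataset")
}

#' @export
print.ElutionDataset <- function(x, ...) {
  cat(sprintf(
    "ElutionDataset: %d proteins x (%d conditions x %d replicates x %d fractions)\n",
    nrow(x$intensity), length(.CONDITIONS), x$n_replicates, x$n_fractions))
  obs <- mean(x$intensity > 0)
  cat(sprintf("  observed cells: %.1f%%\n", 100 * obs))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' @export
dim.ElutionDataset <- function(x) dim(x$intensity)

#' Number of proteins in a dataset
#' @param dataset an \code{ElutionDataset}.
#' @return integer count of protein records.
#' @export
n_proteins <- function(dataset) nrow(dataset$intensity)

# Column selector over the design grid; any argument may be NULL (= all).
sample_cols <- function(dataset, condition = NULL, replicate = NULL,
                        fraction = NULL) {
  d <- dataset$design
  keep <- rep(TRUE, nrow(d))
  if (!is.null(condition)) keep <- keep & d$condition %in% condition
  if (!is.null(replicate)) keep <- keep & d$replicate %in% replicate
  if (!is.null(fraction)) keep <- keep & d$fraction %in% fraction
  which(keep)
}

# Subset records (rows), keeping the design intact.
subset_proteins <- function(dataset, idx, note = NULL) {
  dataset$intensity <- dataset$intensity[idx, , drop = FALSE]
  dataset$meta <- dataset$meta[idx, , drop = FALSE]
  rownames(dataset$meta) <- NULL
  if (!is.null(note)) dataset$provenance <- c(dataset$provenance, note)
  dataset
}

# Stable per-record display identifier: gene name when present, else the
# leading accession.
protein_labels <- function(dataset) {
  g <- dataset$meta$gene_name
  acc <- vapply(strsplit(dataset$meta$protein_ids, ";", fixed = TRUE),
                `[`, character(1), 1L)
  lab <- ifelse(is.na(g) | !nzchar(g), acc, g)
  make.unique(lab, sep = "#")
}
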