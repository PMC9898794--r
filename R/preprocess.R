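# Filter cascade, isoform/gene consolidation, replicate-presence filter
# and per-experiment scaling applied ahead of any statistics.

#' Sequential quality filter cascade
#'
#' Removes records in a fixed order: potential contaminants, reverse
#' (decoy) matches, entries only identified by site, then entries with
#' fewer than \code{min_peptides} peptides. Counts are sequential and
#' disjoint: a record that is both a contaminant and single-peptide is
#' counted once, as a contaminant.
#'
#' @param dataset an \code{ElutionDataset} with flags and peptide counts.
#' @param min_peptides minimum peptide evidence to retain a record
#'   (default 2).
#' @return list with \code{dataset} (filtered) and \code{report}, a named
#'   list of stage counts satisfying
#'   \code{n_input - contaminant - reverse - only_by_site - single_peptide
#'   = n_after_cascade}.
#' @export
filter_cascade <- function(dataset, min_peptides = 2L) {
  m <- dataset$meta
  n_input <- nrow(m)
  keep <- rep(TRUE, n_input)
  n_cont <- sum(keep & m$is_contaminant)
  keep <- keep & !m$is_contaminant
  n_rev <- sum(keep & m$is_reverse)
  keep <- keep & !m$is_reverse
  n_site <- sum(keep & m$only_by_site)
  keep <- keep & !m$only_by_site
  n_pep <- sum(keep & m$n_peptides < min_peptides)
  keep <- keep & m$n_peptides >= min_peptides
  report <- list(
    n_input = n_input,
    n_removed_contaminant = n_cont,
    n_removed_reverse = n_rev,
    n_removed_only_by_site = n_site,
    n_removed_single_peptide = n_pep,
    n_after_cascade = sum(keep))
  ds <- subset_proteins(dataset, which(keep),
                        note = sprintf("filter_cascade: %d -> %d",
                                       n_input, sum(keep)))
  list(dataset = ds, report = report)
}

# Leading accession with any isoform suffix ("-n") removed.
base_accession <- function(protein_ids) {
  lead <- vapply(strsplit(protein_ids, ";", fixed = TRUE), `[`,
                 character(1), 1L)
  sub("-\\d+$", "", lead)
}

#' Consolidate splice variants and duplicated gene entries
#'
#' Groups records that share a base accession (leading accession with any
#' isoform suffix removed) or a non-empty gene name, merging transitively.
#' Within a group, per-sample intensities are summed (missing treated as
#' 0; an all-zero result stays missing), peptide counts take the maximum,
#' accession lists take the union, and the monomer MW of the record with
#' the most peptides is kept.
#'
#' @param dataset an \code{ElutionDataset}, normally after
#'   \code{\link{filter_cascade}}.
#' @return consolidated \code{ElutionDataset}; record count never grows.
#' @export
consolidate <- function(dataset) {
  m <- dataset$meta
  n <- nrow(m)
  if (n == 0L) return(dataset)

  # union-find over records linked by shared base accession or gene name
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  link_by <- function(keys) {
    ok <- !is.na(keys) & nzchar(keys)
    for (grp in split(which(ok), keys[ok])) {
      if (length(grp) > 1L)
        for (k in grp[-1L]) unite(grp[1L], k)
    }
  }
  link_by(base_accession(m$protein_ids))
  link_by(m$gene_name)
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)

  ints <- dataset$intensity
  new_int <- matrix(0, nrow = length(groups), ncol = ncol(ints))
  new_meta <- m[rep(1L, length(groups)), , drop = FALSE]
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    if (length(idx) == 1L) {
      new_int[g, ] <- ints[idx, ]
      new_meta[g, ] <- m[idx, ]
    } else {
      new_int[g, ] <- colSums(ints[idx, , drop = FALSE])
      ids <- unique(unlist(strsplit(m$protein_ids[idx], ";", fixed = TRUE)))
      best <- idx[which.max(m$n_peptides[idx])]
      gn <- m$gene_name[idx]
      gn <- gn[!is.na(gn) & nzchar(gn)]
      new_meta$protein_ids[g] <- paste(ids, collapse = ";")
      new_meta$gene_name[g] <- if (length(gn)) gn[1L] else ""
      new_meta$n_peptides[g] <- max(m$n_peptides[idx])
      new_meta$is_contaminant[g] <- any(m$is_contaminant[idx])
      new_meta$is_reverse[g] <- any(m$is_reverse[idx])
      new_meta$only_by_site[g] <- any(m$only_by_site[idx])
      new_meta$monomer_mw_kda[g] <- m$monomer_mw_kda[best]
    }
  }
  rownames(new_meta) <- NULL
  out <- dataset
  out$intensity <- new_int
  colnames(out$intensity) <- colnames(ints)
  out$meta <- new_meta
  out$provenance <- c(dataset$provenance,
                      sprintf("consolidate: %d -> %d", n, length(groups)))
  out
}

#' Replicate-presence filter
#'
#' A protein is "present in replicate r" if any of its intensities in
#' replicate r — either condition, any fraction — is nonzero. Proteins
#' present in fewer than \code{min_replicates} replicates are removed.
#'
#' @param dataset consolidated \code{ElutionDataset}.
#' @param min_replicates minimum replicate presence (default 3).
#' @return list with \code{dataset} and \code{report}
#'   (\code{n_input}, \code{n_after_replicate_filter}).
#' @export
replicate_presence_filter <- function(dataset, min_replicates = 3L) {
  if (min_replicates > dataset$n_replicates)
    stop("min_replicates exceeds the number of replicates in the design")
  present <- matrix(FALSE, nrow = n_proteins(dataset),
                    ncol = dataset$n_replicates)
  for (r in seq_len(dataset$n_replicates)) {
    cols <- sample_cols(dataset, replicate = r)
    present[, r] <- rowSums(dataset$intensity[, cols, drop = FALSE] > 0) > 0
  }
  keep <- rowSums(present) >= min_replicates
  report <- list(n_input = n_proteins(dataset),
                 n_after_replicate_filter = sum(keep))
  ds <- subset_proteins(dataset, which(keep),
                        note = sprintf("replicate_presence_filter(>=%d): %d -> %d",
                                       min_replicates, length(keep), sum(keep)))
  list(dataset = ds, report = report)
}

#' Per-experiment profile scaling for visualization
#'
#' For each protein and each replicate experiment, divides all fraction
#' intensities of both conditions jointly by their maximum, so the
#' highest fraction value becomes 1 regardless of condition. All-missing
#' profiles stay all-missing. Intended for heatmaps and line graphs only,
#' never as input to statistics.
#'
#' @param dataset an \code{ElutionDataset}.
#' @return numeric matrix shaped like \code{dataset$intensity} with
#'   values in [0, 1] and \code{NA} for missing cells.
#' @export
scale_per_experiment <- function(dataset) {
  out <- dataset$intensity
  out[out == 0] <- NA
  for (r in seq_len(dataset$n_replicates)) {
    cols <- sample_cols(dataset, replicate = r)
    block <- out[, cols, drop = FALSE]
    mx <- apply(block, 1L, function(v) if (all(is.na(v))) NA_real_ else
      max(v, na.rm = TRUE))
    out[, cols] <- block / mx
  }
  out
}
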