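# Readers and writers for the tabular formats the pipeline touches:
# MaxQuant proteinGroups.txt, CORUM coreComplexes.txt, calibration
# standards, and plain TSV result tables.

#' Map LFQ intensity columns to design cells by name pattern
#'
#' Scans a proteinGroups header for label-free quantification columns of
#' the form \code{"LFQ intensity <cond>_<rep>_F<fraction>"} and builds the
#' column map that \code{\link{read_proteingroups}} needs. The condition
#' tokens are study-specific, so they are passed explicitly.
#'
#' @param header character vector of column names.
#' @param control_token,treated_token the condition labels used inside the
#'   intensity column names (e.g. \code{"Ctrl"} and \code{"HSP90i"}).
#' @param prefix column prefix, default \code{"LFQ intensity "}.
#' @return data.frame with columns \code{column}, \code{condition},
#'   \code{replicate}, \code{fraction}.
#' @export
auto_column_map <- function(header, control_token = "control",
                            treated_token = "treated",
                            prefix = "LFQ intensity ") {
  pat <- paste0("^", gsub("([][(){}.*+?^$\\\\|])", "\\\\\\1", prefix),
                "(\\S+)_(\\d+)_F(\\d+)$")
  hit <- grepl(pat, header)
  cond <- sub(pat, "\\1", header[hit])
  keep <- cond %in% c(control_token, treated_token)
  cols <- header[hit][keep]
  cond <- cond[keep]
  data.frame(
    column = cols,
    condition = ifelse(cond == control_token, "control", "treated"),
    replicate = as.integer(sub(pat, "\\2", cols)),
    fraction = as.integer(sub(pat, "\\3", cols)),
    stringsAsFactors = FALSE)
}

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses a tab-delimited proteinGroups file into an
#' \code{\link{elution_dataset}}. Zero and empty intensity cells are both
#' stored as missing (LFQ convention). Row order is preserved; one record
#' per data row.
#'
#' @param path file path to the tab-delimited table.
#' @param column_map data.frame mapping intensity column names to design
#'   cells (see \code{\link{auto_column_map}}); must cover the full
#'   condition x replicate x fraction grid.
#' @param id_col,gene_col,peptides_col,mw_col names of the identifier,
#'   gene-name, peptide-count and monomer molecular-weight columns;
#'   \code{gene_col}, \code{peptides_col} and \code{mw_col} may be
#'   \code{NA} to mark them as absent.
#' @param contaminant_col,reverse_col,site_col names of the "+"-marked
#'   flag columns, or \code{NA} if absent.
#' @return An \code{ElutionDataset}.
#' @export
read_proteingroups <- function(path, column_map,
                               id_col = "Protein IDs",
                               gene_col = "Gene names",
                               peptides_col = "Peptides",
                               mw_col = "Mol. weight [kDa]",
                               contaminant_col = "Potential contaminant",
                               reverse_col = "Reverse",
                               site_col = "Only identified by site") {
  tab <- utils::read.delim(path, check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (anyDuplicated(column_map$column))
    stop("duplicate mapped columns: ",
         paste(unique(column_map$column[duplicated(column_map$column)]),
               collapse = ", "))
  missing_cols <- setdiff(column_map$column, names(tab))
  if (length(missing_cols))
    stop("mapped column(s) not found in file: ",
         paste(missing_cols, collapse = ", "))
  if (!id_col %in% names(tab))
    stop("identifier column not found in file: ", id_col)

  n <- nrow(tab)
  intens <- matrix(0, nrow = n, ncol = nrow(column_map))
  for (j in seq_len(nrow(column_map))) {
    raw <- tab[[column_map$column[j]]]
    raw[is.na(raw) | !nzchar(trimws(raw))] <- "0"
    v <- suppressWarnings(as.numeric(raw))
    if (anyNA(v))
      stop(sprintf("non-numeric intensity in column '%s', row(s) %s",
                   column_map$column[j],
                   paste(utils::head(which(is.na(v)), 5), collapse = ", ")))
    intens[, j] <- v
  }

  flag <- function(col) {
    if (is.na(col) || !col %in% names(tab)) return(rep(FALSE, n))
    trimws(tab[[col]]) == "+"
  }
  num_col <- function(col, default) {
    if (is.na(col) || !col %in% names(tab)) return(rep(default, n))
    suppressWarnings(as.numeric(tab[[col]]))
  }
  meta <- data.frame(
    protein_ids = tab[[id_col]],
    gene_name = if (!is.na(gene_col) && gene_col %in% names(tab))
      tab[[gene_col]] else "",
    n_peptides = as.integer(round(num_col(peptides_col, 0))),
    is_contaminant = flag(contaminant_col),
    is_reverse = flag(reverse_col),
    only_by_site = flag(site_col),
    monomer_mw_kda = num_col(mw_col, NA_real_),
    stringsAsFactors = FALSE)

  design <- column_map[, c("condition", "replicate", "fraction")]
  elution_dataset(intens, design, meta,
                  provenance = sprintf("read %d records from %s", n, path))
}

#' Read CORUM-style complex hypotheses
#'
#' Reads a tab-delimited complex table in the coreComplexes.txt dialect:
#' a complex identifier, a complex name, and a semicolon-delimited subunit
#' column. Subunits are trimmed and de-duplicated; hypotheses with fewer
#' than two unique subunits are dropped (count reported as an attribute
#' \code{"n_dropped"} and via a message).
#'
#' @param path file path.
#' @param id_space which subunit identifier column to use:
#'   \code{"accession"} (UniProt IDs) or \code{"gene_name"}.
#' @param id_col,name_col,accession_col,gene_col column names of the
#'   CORUM dialect.
#' @return list of complex hypotheses, each a list with
#'   \code{complex_id}, \code{complex_name}, \code{subunits}.
#' @export
read_complex_hypotheses <- function(path, id_space = c("gene_name", "accession"),
                                    id_col = "ComplexID",
                                    name_col = "ComplexName",
                                    accession_col = "subunits(UniProt IDs)",
                                    gene_col = "subunits(Gene name)") {
  id_space <- match.arg(id_space)
  tab <- utils::read.delim(path, check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  sub_col <- if (id_space == "accession") accession_col else gene_col
  for (col in c(id_col, name_col, sub_col))
    if (!col %in% names(tab))
      stop("required column not found in complex table: ", col)
  hyps <- lapply(seq_len(nrow(tab)), function(i) {
    subs <- unique(trimws(strsplit(tab[[sub_col]][i], ";", fixed = TRUE)[[1]]))
    subs <- subs[nzchar(subs)]
    list(complex_id = as.character(tab[[id_col]][i]),
         complex_name = as.character(tab[[name_col]][i]),
         subunits = subs)
  })
  sizes <- vapply(hyps, function(h) length(h$subunits), integer(1))
  n_dropped <- sum(sizes < 2L)
  if (n_dropped)
    message(n_dropped, " complex hypothesis(es) with <2 unique subunits dropped")
  out <- hyps[sizes >= 2L]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Build complex hypotheses in code
#'
#' @param complex_id,complex_name,subunits identifier, display name and
#'   character vector of >= 2 unique subunit identifiers.
#' @return a single complex hypothesis (list).
#' @export
complex_hypothesis <- function(complex_id, subunits,
                               complex_name = complex_id) {
  subunits <- unique(as.character(subunits))
  if (length(subunits) < 2L) stop("a complex hypothesis needs >= 2 unique subunits")
  list(complex_id = as.character(complex_id),
       complex_name = as.character(complex_name), subunits = subunits)
}

#' Write a result table as TSV
#'
#' Tab-delimited UTF-8 output with a header row; missing values written
#' as \code{"NA"}; numeric columns formatted with 6 significant digits.
#' Round-trips through \code{\link{read_table_tsv}}.
#'
#' @param rows data.frame to write.
#' @param path destination path.
#' @export
write_table <- function(rows, path) {
  out <- as.data.frame(rows, stringsAsFactors = FALSE)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- out[[j]]
      s <- ifelse(is.na(v), NA_character_,
                  formatC(signif(v, 6), format = "g", digits = 6))
      out[[j]] <- s
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Read a result table written by \code{\link{write_table}}
#' @param path file path.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, quote = "",
                    stringsAsFactors = FALSE)
}

#' Read molecular-weight calibration standards
#'
#' Two-column TSV with one row per protein standard: the apex fraction of
#' its elution peak and its molecular weight in kDa.
#'
#' @param path file path; columns \code{fraction} and \code{mw_kda}.
#' @return data.frame with columns \code{fraction}, \code{mw_kda}.
#' @export
read_calibration_standards <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  for (col in c("fraction", "mw_kda"))
    if (!col %in% names(tab))
      stop("calibration standards need column: ", col)
  data.frame(fraction = as.numeric(tab$fraction),
             mw_kda = as.numeric(tab$mw_kda))
}
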