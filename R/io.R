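#' @keywords internal
"_PACKAGE"

PSM_COLUMNS <- c("peptide_sequence", "assigned_accession",
                 "peptide_probability", "ion_score", "parent_mass_error",
                 "mass_error_unit", "sample_label", "replicate_id")

PROTEIN_COLUMNS <- c("accession", "description", "length",
                     "protein_probability", "spectral_count",
                     "unique_peptides", "sample_label", "replicate_id")

validate_psm_table <- function(matches) {
  missing <- setdiff(PSM_COLUMNS, names(matches))
  if (length(missing) > 0L) {
    stop("PSM table is missing column(s): ", paste(missing, collapse = ", "))
  }
  check_numeric_column(matches, "peptide_probability", 0, 1)
  check_numeric_column(matches, "ion_score")
  check_numeric_column(matches, "parent_mass_error")
  bad_unit <- which(!matches$mass_error_unit %in% c("Da", "ppm"))
  if (length(bad_unit) > 0L) {
    stop(sprintf("row %d: mass_error_unit must be 'Da' or 'ppm' (got '%s')",
                 bad_unit[1L], matches$mass_error_unit[bad_unit[1L]]))
  }
  bad_label <- which(!matches$sample_label %in% c("treated", "control"))
  if (length(bad_label) > 0L) {
    stop(sprintf("row %d: sample_label must be 'treated' or 'control'",
                 bad_label[1L]))
  }
  matches
}

validate_protein_table <- function(records) {
  missing <- setdiff(PROTEIN_COLUMNS, names(records))
  if (length(missing) > 0L) {
    stop("protein table is missing column(s): ", paste(missing, collapse = ", "))
  }
  check_numeric_column(records, "protein_probability", 0, 1)
  check_numeric_column(records, "length", lower = 1)
  check_numeric_column(records, "spectral_count", lower = 0)
  check_numeric_column(records, "unique_peptides", lower = 0)
  bad <- which(records$spectral_count < records$unique_peptides)
  if (length(bad) > 0L) {
    stop(sprintf("row %d: spectral_count (%g) < unique_peptides (%g)",
                 bad[1L], records$spectral_count[bad[1L]],
                 records$unique_peptides[bad[1L]]))
  }
  records
}

check_numeric_column <- function(df, col, lower = -Inf, upper = Inf) {
  x <- df[[col]]
  if (!is.numeric(x)) {
    stop(sprintf("column '%s' must be numeric", col))
  }
  bad <- which(!is.finite(x) | x < lower | x > upper)
  if (length(bad) > 0L) {
    stop(sprintf("row %d: column '%s' value %s outside [%g, %g]",
                 bad[1L], col, format(x[bad[1L]]), lower, upper))
  }
  invisible(df)
}

#' Read a protein identification table
#'
#' Reads the tab-separated protein table dialect used throughout the
#' pipeline (one row per protein per run) and validates every field:
#' probabilities in [0,1], lengths at least 1, spectral counts at least the
#' unique-peptide count. Parse errors name the offending row and column.
#'
#' @param path Path to a TSV file with columns \code{accession},
#'   \code{description}, \code{length}, \code{protein_probability},
#'   \code{spectral_count}, \code{unique_peptides}, \code{sample_label},
#'   \code{replicate_id}.
#' @return Validated data frame.
#' @seealso [write_protein_table()]
#' @export
read_protein_table <- function(path) {
  records <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_protein_table(records)
}

#' Write a protein identification table
#'
#' Deterministic TSV writer: fixed column order, numeric fields formatted at
#' 6 significant digits so repeated runs produce byte-identical files.
#'
#' @param records Protein-record data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_protein_table <- function(records, path) {
  records <- validate_protein_table(records)
  extra <- setdiff(names(records), PROTEIN_COLUMNS)
  write_tsv_deterministic(records[c(PROTEIN_COLUMNS, extra)], path)
}

#' Read a PSM table
#'
#' @param path Path to a TSV with the PSM schema (see
#'   [filter_spectrum_matches()] for columns).
#' @return Validated data frame.
#' @export
read_psm_table <- function(path) {
  validate_psm_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_psm_table
#' @param matches PSM data frame.
#' @export
write_psm_table <- function(matches, path) {
  matches <- validate_psm_table(matches)
  write_tsv_deterministic(matches[PSM_COLUMNS], path)
}

#' Deterministic TSV writer
#'
#' Writes any data frame as tab-separated text with doubles formatted at 6
#' significant digits, so identical inputs always produce byte-identical
#' files (the convention every artifact writer in the package follows).
#'
#' @param df Data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  write_tsv_deterministic(df, path)
}

write_tsv_deterministic <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Protein lengths from a FASTA file
#'
#' Residue counts per accession, taken as the first whitespace-delimited
#' token of each header. Duplicate accessions and empty files are errors.
#' FASTA-derived lengths override any length column in tabular input (the
#' sequence database is authoritative for SAF denominators).
#'
#' @param path Path to a protein FASTA file.
#' @return Named integer vector, accession -> length (residues).
#' @export
read_fasta_lengths <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(acc)) {
    stop("duplicate FASTA accession: ", acc[duplicated(acc)][1L])
  }
  stats::setNames(Biostrings::width(seqs), acc)
}

#' Apply FASTA lengths to a protein table
#'
#' Replaces the \code{length} column with FASTA-derived residue counts
#' wherever the accession is present in \code{lengths}; mismatching table
#' values trigger a warning naming the accession.
#'
#' @param records Protein-record data frame.
#' @param lengths Named vector from [read_fasta_lengths()].
#' @return Updated data frame.
#' @export
apply_fasta_lengths <- function(records, lengths) {
  hit <- records$accession %in% names(lengths)
  new_len <- unname(lengths[records$accession[hit]])
  old_len <- records$length[hit]
  diff <- which(old_len != new_len)
  if (length(diff) > 0L) {
    warning("table length differs from FASTA for: ",
            paste(records$accession[hit][diff], collapse = ", "),
            " (FASTA value used)")
  }
  records$length[hit] <- new_len
  records
}

#' Read a category map
#'
#' Two-column TSV assigning each accession to a recruitment category:
#' \code{receptor}, \code{FADD}, \code{DED_only} or \code{other}.
#'
#' @param path Path to a TSV with columns \code{accession}, \code{category}.
#' @return Named character vector, accession -> category.
#' @export
read_category_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("accession", "category") %in% names(tab))) {
    stop("category map needs columns 'accession' and 'category'")
  }
  as_category_map(stats::setNames(tab$category, tab$accession))
}

as_category_map <- function(categories) {
  categories <- unlist(categories)
  if (is.null(names(categories)) || any(!nzchar(names(categories)))) {
    stop("category map must be named by accession")
  }
  if (anyDuplicated(names(categories))) {
    stop("duplicate accession in category map: ",
         names(categories)[duplicated(names(categories))][1L])
  }
  bad <- setdiff(unique(categories), c("receptor", "FADD", "DED_only", "other"))
  if (length(bad) > 0L) {
    stop("unknown category: ", paste(bad, collapse = ", "))
  }
  categories
}
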