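#' Filter peptide-spectrum matches on probability, ion score and mass error
#'
#' Applies the PSM-level retention criteria: peptide posterior probability at
#' least \code{min_peptide_probability}, Mascot ion score strictly greater
#' than \code{min_ion_score}, and absolute parent-ion mass error at most
#' \code{max_parent_mass_error}. Record order is preserved; the input is not
#' modified.
#'
#' @param matches Data frame of peptide-spectrum matches with columns
#'   \code{peptide_sequence}, \code{assigned_accession},
#'   \code{peptide_probability}, \code{ion_score}, \code{parent_mass_error},
#'   \code{mass_error_unit} ("Da" or "ppm"), \code{sample_label}
#'   ("treated"/"control"), \code{replicate_id}.
#' @param criteria A [filter_criteria()] object.
#' @return The retained rows of \code{matches}, order preserved.
#' @export
filter_spectrum_matches <- function(matches, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  matches <- validate_psm_table(matches)
  if (nrow(matches) == 0L) return(matches)
  units <- unique(matches$mass_error_unit)
  if (length(units) != 1L) {
    stop("mixed parent-ion mass-error units in PSM table: ",
         paste(units, collapse = ", "))
  }
  if (units != criteria$mass_error_unit) {
    stop(sprintf("PSM mass-error unit '%s' does not match criteria unit '%s'",
                 units, criteria$mass_error_unit))
  }
  keep <- matches$peptide_probability >= criteria$min_peptide_probability &
    matches$ion_score > criteria$min_ion_score &
    abs(matches$parent_mass_error) <= criteria$max_parent_mass_error
  matches[keep, , drop = FALSE]
}

#' Aggregate retained PSMs into spectral counts
#'
#' Counts PSMs per accession within each (sample_label, replicate_id) run.
#' Each PSM row is one acquired spectrum and contributes exactly one count,
#' so counts sum to the number of retained matches. Shared peptides —
#' the same (peptide_sequence, run) reported under several accessions — are
#' resolved by razor assignment: all of that peptide's PSMs in that run are
#' credited to the accession with the highest protein probability (supplied
#' via \code{protein_probabilities}), ties broken lexicographically by
#' accession; without probabilities the lexicographic rule alone applies.
#'
#' @param matches Filtered PSM data frame (see [filter_spectrum_matches()]).
#' @param protein_probabilities Optional named numeric vector,
#'   accession -> protein probability, used for razor assignment.
#' @return Data frame with columns \code{accession}, \code{sample_label},
#'   \code{replicate_id}, \code{spectral_count}, \code{unique_peptides}.
#' @export
compute_spectral_counts <- function(matches, protein_probabilities = NULL) {
  matches <- validate_psm_table(matches)
  if (nrow(matches) == 0L) {
    return(data.frame(accession = character(), sample_label = character(),
                      replicate_id = integer(), spectral_count = integer(),
                      unique_peptides = integer(),
                      stringsAsFactors = FALSE))
  }
  run <- paste(matches$sample_label, matches$replicate_id, sep = "\r")
  pep_run <- paste(matches$peptide_sequence, run, sep = "\r")
  # razor: one accession per (peptide, run)
  razor_for <- function(accs) {
    accs <- unique(accs)
    if (length(accs) == 1L) return(accs)
    if (!is.null(protein_probabilities)) {
      p <- protein_probabilities[accs]
      p[is.na(p)] <- -Inf
      accs <- accs[order(-p, accs)]
    } else {
      accs <- sort(accs)
    }
    accs[1L]
  }
  razor <- vapply(split(matches$assigned_accession, pep_run), razor_for, "")
  acc <- razor[pep_run]
  key <- data.frame(accession = unname(acc),
                    sample_label = matches$sample_label,
                    replicate_id = matches$replicate_id,
                    peptide_sequence = matches$peptide_sequence,
                    stringsAsFactors = FALSE)
  counts <- stats::aggregate(cbind(spectral_count = rep(1L, nrow(key))),
                             by = key[c("accession", "sample_label", "replicate_id")],
                             FUN = sum)
  uniq <- stats::aggregate(
    cbind(unique_peptides = key$peptide_sequence),
    by = key[c("accession", "sample_label", "replicate_id")],
    FUN = function(p) length(unique(p))
  )
  out <- merge(counts, uniq,
               by = c("accession", "sample_label", "replicate_id"), sort = TRUE)
  out$spectral_count <- as.integer(out$spectral_count)
  out$unique_peptides <- as.integer(out$unique_peptides)
  out[order(out$sample_label, out$replicate_id, out$accession), , drop = FALSE]
}

#' Subtract the unstimulated-receptor control from a treated run
#'
#' A treated protein is retained iff it is (a) absent from the paired
#' control, or (b) present at dramatically lower abundance in the control —
#' treated:control count ratio at least \code{control_fold_threshold} and
#' control count at most \code{control_max_count} — or (c) whitelisted.
#' Whitelist retentions are flagged in the \code{whitelisted} column.
#'
#' @param treated,control Protein-record data frames from the same replicate
#'   pairing (columns as in [read_protein_table()]).
#' @param criteria A [filter_criteria()] object.
#' @return \code{treated} rows retained, with added logical column
#'   \code{whitelisted} and character column \code{control_rule}
#'   (one of "absent_from_control", "lower_abundance", "whitelist").
#' @export
subtract_control <- function(treated, control, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  treated <- validate_protein_table(treated)
  control <- validate_protein_table(control)
  check_unique_per_run(treated, "treated")
  check_unique_per_run(control, "control")
  ctl_counts <- stats::setNames(control$spectral_count, control$accession)
  in_control <- treated$accession %in% control$accession
  ctl <- ifelse(in_control, ctl_counts[treated$accession], 0L)
  fold_ok <- treated$spectral_count / pmax(ctl, 1L) >= criteria$control_fold_threshold &
    ctl <= criteria$control_max_count
  whitelisted <- treated$accession %in% criteria$whitelist_accessions
  keep <- !in_control | fold_ok | whitelisted
  out <- treated[keep, , drop = FALSE]
  rule <- character(nrow(treated))
  rule[!in_control] <- "absent_from_control"
  rule[in_control & fold_ok] <- "lower_abundance"
  rule[in_control & !fold_ok & whitelisted] <- "whitelist"
  out$control_rule <- rule[keep]
  out$whitelisted <- (in_control & !fold_ok & whitelisted)[keep]
  out
}

#' Remove known contaminants and low-probability identifications
#'
#' Retains exactly the records whose accession is not in the contaminant set
#' and whose protein probability meets \code{min_protein_probability}.
#' Removed records are reported with a removal reason.
#'
#' @param records Protein-record data frame.
#' @param criteria A [filter_criteria()] object.
#' @return List with elements \code{retained} (data frame) and
#'   \code{removed} (data frame with added \code{reason} column, one of
#'   "contaminant", "protein probability").
#' @export
exclude_contaminants <- function(records, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  records <- validate_protein_table(records)
  is_cont <- records$accession %in% criteria$contaminant_accessions
  low_pp <- records$protein_probability < criteria$min_protein_probability
  reason <- ifelse(is_cont, "contaminant",
                   ifelse(low_pp, "protein probability", NA_character_))
  removed <- records[!is.na(reason), , drop = FALSE]
  removed$reason <- reason[!is.na(reason)]
  list(retained = records[is.na(reason), , drop = FALSE], removed = removed)
}

#' Full protein-level retention filter with removal audit
#'
#' Composes contaminant/probability exclusion with control subtraction for
#' one replicate pairing, partitioning the treated input into retained and
#' removed sets with exhaustive removal reasons.
#'
#' @param treated,control Protein-record data frames for one replicate.
#' @param criteria A [filter_criteria()] object.
#' @return List with \code{retained} (with \code{whitelisted} flag and
#'   \code{control_rule}) and \code{removed} (with \code{reason}: one of
#'   "contaminant", "protein probability", "control").
#' @export
filter_proteins <- function(treated, control, criteria = filter_criteria()) {
  step1 <- exclude_contaminants(treated, criteria)
  kept <- subtract_control(step1$retained, control, criteria)
  dropped_ctl <- step1$retained[!step1$retained$accession %in% kept$accession, ,
                                drop = FALSE]
  removed <- step1$removed
  if (nrow(dropped_ctl) > 0L) {
    dropped_ctl$reason <- "control"
    removed <- rbind(removed, dropped_ctl)
  }
  list(retained = kept, removed = removed)
}

check_unique_per_run <- function(records, label) {
  key <- paste(records$accession, records$sample_label, records$replicate_id)
  if (anyDuplicated(key)) {
    dup <- records$accession[duplicated(key)][1L]
    stop(sprintf("duplicate accession '%s' within one %s run", dup, label))
  }
  invisible(records)
}
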