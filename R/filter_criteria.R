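#' Retention criteria for DISC identification filtering
#'
#' Bundles every threshold applied to raw identification tables before
#' quantitation: peptide- and protein-level posterior probabilities, the
#' Mascot ion-score cutoff, the parent-ion mass-error window, the
#' control-subtraction rule, the contaminant table and the whitelist.
#'
#' The control-subtraction rule retains a treated protein seen in the
#' matched control only when its treated:control spectral-count ratio is at
#' least \code{control_fold_threshold} *and* the control count is at most
#' \code{control_max_count} ("dramatically lower abundance" in the control).
#' The whitelist generalizes the FADD-in-Jurkat exception: whitelisted
#' accessions survive control subtraction but are always flagged.
#'
#' @param min_peptide_probability Minimum peptide posterior probability
#'   (inclusive). Default 0.95.
#' @param min_protein_probability Minimum protein posterior probability
#'   (inclusive). Default 0.50.
#' @param min_ion_score Mascot ion score must strictly exceed this value.
#'   Default 30.
#' @param max_parent_mass_error Largest tolerated absolute parent-ion mass
#'   error, in \code{mass_error_unit}. Default 0.2 Da (QTof-class accuracy).
#' @param mass_error_unit Unit the mass-error threshold is expressed in,
#'   \code{"Da"} or \code{"ppm"}. All records must carry the same unit.
#' @param control_fold_threshold Minimum treated:control count ratio for a
#'   control-detected protein to survive subtraction. Default 5.
#' @param control_max_count Maximum control spectral count compatible with
#'   "dramatically lower abundance". Default 2.
#' @param contaminant_accessions Character vector of accessions removed as
#'   known contaminants (biotin-dependent carboxylases, bead background).
#'   Defaults to [default_contaminants()].
#' @param whitelist_accessions Accessions exempt from control subtraction;
#'   retentions via the whitelist are flagged in all outputs.
#'
#' @return An object of class \code{"filter_criteria"} (a validated list).
#' @examples
#' crit <- filter_criteria(control_fold_threshold = 10)
#' crit$min_ion_score
#' @export
filter_criteria <- function(min_peptide_probability = 0.95,
                            min_protein_probability = 0.50,
                            min_ion_score = 30,
                            max_parent_mass_error = 0.2,
                            mass_error_unit = c("Da", "ppm"),
                            control_fold_threshold = 5,
                            control_max_count = 2,
                            contaminant_accessions = default_contaminants(),
                            whitelist_accessions = character()) {
  mass_error_unit <- match.arg(mass_error_unit)
  stopifnot(
    is.numeric(min_peptide_probability), length(min_peptide_probability) == 1,
    min_peptide_probability >= 0, min_peptide_probability <= 1,
    is.numeric(min_protein_probability), length(min_protein_probability) == 1,
    min_protein_probability >= 0, min_protein_probability <= 1,
    is.numeric(min_ion_score), length(min_ion_score) == 1, min_ion_score >= 0,
    is.numeric(max_parent_mass_error), length(max_parent_mass_error) == 1,
    max_parent_mass_error >= 0,
    is.numeric(control_fold_threshold), control_fold_threshold >= 0,
    is.numeric(control_max_count), control_max_count >= 0
  )
  structure(
    list(
      min_peptide_probability = min_peptide_probability,
      min_protein_probability = min_protein_probability,
      min_ion_score = min_ion_score,
      max_parent_mass_error = max_parent_mass_error,
      mass_error_unit = mass_error_unit,
      control_fold_threshold = control_fold_threshold,
      control_max_count = control_max_count,
      contaminant_accessions = as.character(contaminant_accessions),
      whitelist_accessions = as.character(whitelist_accessions)
    ),
    class = "filter_criteria"
  )
}

#' Default contaminant accession table
#'
#' Biotin-dependent carboxylases (which bind streptavidin beads through
#' their biotin cofactor) plus common bead-binding background proteins.
#' The set ships as a plain TSV under \code{inst/extdata/contaminants.tsv}
#' and is user-extensible: pass any character vector of accessions to
#' [filter_criteria()].
#'
#' @return Character vector of contaminant accessions.
#' @export
default_contaminants <- function() {
  path <- system.file("extdata", "contaminants.tsv", package = "discstoich")
  if (!nzchar(path)) stop("bundled contaminant table not found")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  tab$accession
}

#' @export
print.filter_criteria <- function(x, ...) {
  cat("DISC identification filter criteria\n")
  cat(sprintf("  peptide probability >= %.2f, protein probability >= %.2f\n",
              x$min_peptide_probability, x$min_protein_probability))
  cat(sprintf("  ion score > %g, |parent mass error| <= %g %s\n",
              x$min_ion_score, x$max_parent_mass_error, x$mass_error_unit))
  cat(sprintf("  control rule: fold >= %g and control count <= %g\n",
              x$control_fold_threshold, x$control_max_count))
  cat(sprintf("  %d contaminant accession(s), %d whitelisted\n",
              length(x$contaminant_accessions), length(x$whitelist_accessions)))
  invisible(x)
}
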