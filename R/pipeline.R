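#' Run filter + quantitation + stoichiometry on a replicate dataset
#'
#' In-memory composition of the analysis chain over one dataset of paired
#' treated/control protein tables: per-replicate retention filtering
#' (contaminant/probability exclusion, control subtraction), SAF/NSAF
#' quantitation, replicate aggregation, and FADD-normalized grouped
#' stoichiometry.
#'
#' @param replicates List of replicate pairs, each a list with elements
#'   \code{treated} and \code{control} (protein data frames), e.g.
#'   \code{simulate_counts(...)$replicates}.
#' @param categories Named character vector accession -> category.
#' @param criteria A [filter_criteria()] object.
#' @param normalization_set Accessions forming the NSAF denominator;
#'   default: every retained accession (over all replicates).
#' @param reference_accession Optional reference for relative SAF (enables
#'   the probability/abundance scatter table).
#' @param length_overrides Optional named per-accession length overrides.
#' @return List: \code{quant} (per-replicate quant table with NSAF),
#'   \code{summary} (per-accession aggregate), \code{stoichiometry}
#'   (a [group_stoichiometry()] result), \code{retained}, \code{removed}
#'   (audit tables over all replicates), \code{scatter} (NULL unless a
#'   reference was declared).
#' @export
estimate_stoichiometry <- function(replicates, categories,
                                   criteria = filter_criteria(),
                                   normalization_set = NULL,
                                   reference_accession = NULL,
                                   length_overrides = NULL) {
  stopifnot(length(replicates) >= 1)
  filtered <- lapply(replicates, function(pair) {
    filter_proteins(pair$treated, pair$control, criteria)
  })
  retained <- do.call(rbind, lapply(filtered, `[[`, "retained"))
  removed <- do.call(rbind, lapply(filtered, `[[`, "removed"))
  rownames(retained) <- rownames(removed) <- NULL
  if (nrow(retained) == 0L) stop("no proteins retained by the filter")
  quant <- quant_table(retained, length_overrides)
  if (!is.null(reference_accession)) {
    quant <- compute_relative_saf(quant, reference_accession)
  }
  quant <- compute_nsaf(quant, normalization_set)
  summary <- aggregate_replicates(quant)
  stoich <- group_stoichiometry(quant, categories)
  list(
    quant = quant,
    summary = summary,
    stoichiometry = stoich,
    retained = retained,
    removed = removed,
    scatter = if (!is.null(reference_accession))
      probability_abundance_table(summary) else NULL
  )
}

#' End-to-end pipeline run with on-disk artifacts
#'
#' Simulates (or loads) a dataset, runs [estimate_stoichiometry()], and
#' writes every artifact deterministically under \code{out_dir}: filtered
#' and removal-audit TSVs, per-replicate quant TSV, aggregated summary TSV,
#' the stoichiometry JSON report, and a provenance block echoing the
#' configuration and seed, so any output can be regenerated exactly.
#'
#' @param out_dir Output directory (created if needed).
#' @param truth A [synthetic_truth()] object (e.g. [disc_preset()]), used
#'   when \code{replicates} is NULL.
#' @param replicates Optional pre-loaded replicate list (overrides
#'   simulation).
#' @param categories Named accession -> category vector; defaults to the
#'   truth's component categories.
#' @param criteria A [filter_criteria()] object.
#' @param seed Integer seed for the simulation.
#' @param reference_accession,normalization_set Passed through.
#' @return The [estimate_stoichiometry()] result, invisibly, with an added
#'   \code{paths} element.
#' @export
run_pipeline <- function(out_dir, truth = disc_preset(), replicates = NULL,
                         categories = NULL, criteria = filter_criteria(),
                         seed = 1L, reference_accession = NULL,
                         normalization_set = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(replicates)) {
    dataset <- simulate_counts(truth, seed = seed)
    replicates <- dataset$replicates
  }
  if (is.null(categories)) {
    if (is.null(truth)) stop("config error: need a category map when no truth is given")
    categories <- stats::setNames(truth$components$category,
                                  truth$components$accession)
  }
  res <- estimate_stoichiometry(replicates, categories, criteria,
                                normalization_set, reference_accession)
  paths <- list(
    retained = file.path(out_dir, "filtered_proteins.tsv"),
    removed = file.path(out_dir, "removal_audit.tsv"),
    quant = file.path(out_dir, "quant_per_replicate.tsv"),
    summary = file.path(out_dir, "summary.tsv"),
    stoichiometry = file.path(out_dir, "stoichiometry.json"),
    provenance = file.path(out_dir, "provenance.json")
  )
  write_protein_table(res$retained, paths$retained)
  write_tsv_deterministic(res$removed[c("accession", "replicate_id", "reason")],
                          paths$removed)
  write_tsv_deterministic(res$quant, paths$quant)
  write_tsv_deterministic(res$summary, paths$summary)
  jsonlite::write_json(
    list(categories = as.data.frame(res$stoichiometry)),
    paths$stoichiometry, digits = 10, auto_unbox = TRUE, pretty = TRUE
  )
  jsonlite::write_json(
    list(
      seed = seed,
      criteria = unclass(criteria),
      truth = if (!is.null(truth)) list(
        depth = truth$depth, n_replicates = truth$n_replicates,
        detectability = truth$detectability, count_law = truth$count_law,
        components = truth$components, contaminants = truth$contaminants
      ),
      normalization_set = normalization_set,
      reference_accession = reference_accession,
      package_version = as.character(utils::packageVersion("discstoich"))
    ),
    paths$provenance, digits = 10, auto_unbox = TRUE, pretty = TRUE
  )
  if (!is.null(res$scatter)) {
    paths$scatter <- file.path(out_dir, "probability_abundance.tsv")
    write_tsv_deterministic(res$scatter, paths$scatter)
  }
  res$paths <- paths
  invisible(res)
}
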