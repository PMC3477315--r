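#' Spectral abundance factor
#'
#' SAF = SpC / L: the spectral count divided by the protein length in
#' residues, correcting the count for the number of observable tryptic
#' peptides a longer protein contributes.
#'
#' @param spectral_count Nonnegative spectral count(s).
#' @param length Protein length(s) in residues, at least 1.
#' @return \code{spectral_count / length} (counts per residue).
#' @examples
#' compute_saf(10, 100) # 0.1
#' @export
compute_saf <- function(spectral_count, length) {
  if (any(!is.finite(length) | length < 1)) {
    stop("protein length must be >= 1 residue")
  }
  if (any(!is.finite(spectral_count) | spectral_count < 0)) {
    stop("spectral_count must be nonnegative")
  }
  spectral_count / length
}

#' Build a per-replicate quantitation table
#'
#' Attaches SAF values to a filtered protein table, one row per protein per
#' treated replicate.
#'
#' @param records Filtered protein-record data frame (treated rows).
#' @param length_overrides Optional named vector of per-accession lengths
#'   (e.g., for cleaved species quantified against a truncated sequence);
#'   overrides the table/FASTA length before SAF.
#' @return Data frame with columns \code{accession}, \code{replicate_id},
#'   \code{spectral_count}, \code{length}, \code{protein_probability},
#'   \code{saf}.
#' @export
quant_table <- function(records, length_overrides = NULL) {
  records <- validate_protein_table(records)
  records <- records[records$sample_label == "treated", , drop = FALSE]
  if (!is.null(length_overrides)) {
    hit <- records$accession %in% names(length_overrides)
    records$length[hit] <- unname(length_overrides[records$accession[hit]])
  }
  out <- records[c("accession", "replicate_id", "spectral_count", "length",
                   "protein_probability")]
  out$saf <- compute_saf(out$spectral_count, out$length)
  out <- out[order(out$replicate_id, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SAF relative to a reference protein
#'
#' Divides each protein's SAF by the SAF of a declared reference accession
#' within the same replicate (the reference's relative SAF is 1). Used for
#' probability-vs-abundance scatter views where abundance is expressed
#' relative to the bait-proximal receptor.
#'
#' @param table Quantitation table from [quant_table()].
#' @param reference_accession Accession of the reference protein; must be
#'   present with SAF > 0 in every replicate.
#' @return \code{table} with added column \code{relative_saf}.
#' @export
compute_relative_saf <- function(table, reference_accession) {
  stopifnot(is.character(reference_accession), length(reference_accession) == 1)
  out <- lapply(split(table, table$replicate_id), function(rep_tab) {
    ref <- rep_tab$saf[rep_tab$accession == reference_accession]
    if (length(ref) == 0L || ref[1L] <= 0) {
      stop(sprintf(
        "reference accession '%s' missing or zero-SAF in replicate %s",
        reference_accession, rep_tab$replicate_id[1L]))
    }
    rep_tab$relative_saf <- rep_tab$saf / ref[1L]
    rep_tab
  })
  out <- do.call(rbind, out)
  out <- out[order(out$replicate_id, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalized spectral abundance factor
#'
#' NSAF_i = SAF_i / sum of SAF over the normalization set, computed within
#' each replicate, so NSAF values over the set sum to 1 per replicate and
#' estimate each protein's mole fraction of the complex.
#'
#' @param table Quantitation table from [quant_table()].
#' @param normalization_set Accessions forming the NSAF denominator; default
#'   all accessions present in \code{table}. Proteins outside the set get an
#'   NSAF relative to the same denominator (their values are not part of the
#'   sum-to-one guarantee).
#' @return \code{table} with added column \code{nsaf}.
#' @export
compute_nsaf <- function(table, normalization_set = NULL) {
  if (is.null(normalization_set)) normalization_set <- unique(table$accession)
  out <- lapply(split(table, table$replicate_id), function(rep_tab) {
    denom <- sum(rep_tab$saf[rep_tab$accession %in% normalization_set])
    if (denom <= 0) {
      stop(sprintf("replicate %s: all-zero SAF over the normalization set",
                   rep_tab$replicate_id[1L]))
    }
    rep_tab$nsaf <- rep_tab$saf / denom
    rep_tab
  })
  out <- do.call(rbind, out)
  out <- out[order(out$replicate_id, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate per-replicate quantitation across replicates
#'
#' Per accession: median protein probability, median relative SAF (when
#' present), mean NSAF and its dispersion. An accession absent from a
#' replicate contributes NSAF 0 to that replicate (non-detection is treated
#' as zero abundance, flagged by \code{n_detected}). The dispersion
#' convention mirrors figure-legend practice: SEM for n >= 3 replicates,
#' range (max - min) for n = 2, NA for n = 1 (\code{dispersion_type}
#' records which was used).
#'
#' @param table Quantitation table with \code{nsaf} (and optionally
#'   \code{relative_saf}) over one or more replicates.
#' @return Data frame with one row per accession: \code{accession},
#'   \code{n_replicates}, \code{n_detected}, \code{median_protein_probability},
#'   \code{median_relative_saf} (NA when not computed), \code{mean_nsaf},
#'   \code{dispersion}, \code{dispersion_type}.
#' @export
aggregate_replicates <- function(table) {
  if (nrow(table) == 0L) stop("no replicates to aggregate")
  stopifnot("nsaf" %in% names(table))
  reps <- sort(unique(table$replicate_id))
  n <- length(reps)
  accs <- sort(unique(table$accession))
  nsaf_mat <- matrix(0, nrow = length(accs), ncol = n,
                     dimnames = list(accs, as.character(reps)))
  idx <- cbind(match(table$accession, accs), match(table$replicate_id, reps))
  nsaf_mat[idx] <- table$nsaf
  per_acc <- function(acc, col, fun) {
    x <- table[[col]][table$accession == acc]
    if (length(x) == 0L) NA_real_ else fun(x)
  }
  mean_nsaf <- rowMeans(nsaf_mat)
  disp <- apply(nsaf_mat, 1L, dispersion_stat, n = n)
  data.frame(
    accession = accs,
    n_replicates = n,
    n_detected = vapply(accs, function(a)
      length(unique(table$replicate_id[table$accession == a])), 0L),
    median_protein_probability = vapply(accs, per_acc, 0.0,
                                        col = "protein_probability",
                                        fun = stats::median),
    median_relative_saf = if ("relative_saf" %in% names(table)) {
      vapply(accs, per_acc, 0.0, col = "relative_saf", fun = stats::median)
    } else NA_real_,
    mean_nsaf = unname(mean_nsaf),
    dispersion = unname(disp),
    dispersion_type = dispersion_label(n),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

dispersion_stat <- function(x, n) {
  if (n >= 3L) stats::sd(x) / sqrt(n)
  else if (n == 2L) max(x) - min(x)
  else NA_real_
}

dispersion_label <- function(n) {
  if (n >= 3L) "sem" else if (n == 2L) "range" else "none"
}

#' FADD-normalized grouped stoichiometry
#'
#' Assigns each protein to a recruitment category (receptor, FADD, DED_only,
#' other), sums NSAF over category members within each replicate, averages
#' over replicates, and expresses each category relative to FADD — the only
#' adaptor linking receptors to DED-only proteins, hence the natural
#' per-complex unit. The FADD ratio is 1 by construction. Dispersion of the
#' per-replicate ratios is reported as SEM (n >= 3) or range (n = 2).
#'
#' @param table Quantitation table with \code{nsaf} over replicates.
#' @param categories Named character vector accession -> category
#'   (\code{receptor}, \code{FADD}, \code{DED_only}, \code{other}), e.g.
#'   from [read_category_map()]. Accessions missing from the map are
#'   treated as \code{other}.
#' @return Object of class \code{"stoichiometry_result"}: data frame with
#'   columns \code{category}, \code{combined_nsaf}, \code{ratio_to_fadd},
#'   \code{dispersion}, \code{dispersion_type}, \code{n_replicates}.
#' @export
group_stoichiometry <- function(table, categories) {
  categories <- as_category_map(categories)
  stopifnot("nsaf" %in% names(table))
  cat_of <- categories[table$accession]
  cat_of[is.na(cat_of)] <- "other"
  reps <- sort(unique(table$replicate_id))
  n <- length(reps)
  cats <- intersect(c("receptor", "FADD", "DED_only", "other"), unique(cat_of))
  # per-replicate category sums (absent category contributes 0)
  sums <- sapply(reps, function(r) {
    sel <- table$replicate_id == r
    vapply(cats, function(cc) sum(table$nsaf[sel & cat_of == cc]), 0.0)
  })
  sums <- matrix(sums, nrow = length(cats), dimnames = list(cats, NULL))
  if (!"FADD" %in% cats || any(sums["FADD", ] <= 0)) {
    stop("stoichiometry undefined: FADD combined NSAF is zero in at least one replicate")
  }
  combined <- rowMeans(sums)
  ratio <- combined / combined[["FADD"]]
  per_rep_ratio <- sweep(sums, 2L, sums["FADD", ], "/")
  disp <- apply(per_rep_ratio, 1L, dispersion_stat, n = n)
  structure(
    data.frame(
      category = cats,
      combined_nsaf = unname(combined),
      ratio_to_fadd = unname(ratio),
      dispersion = unname(disp),
      dispersion_type = dispersion_label(n),
      n_replicates = n,
      stringsAsFactors = FALSE,
      row.names = NULL
    ),
    class = c("stoichiometry_result", "data.frame")
  )
}

#' Combine gradient fractions before quantitation
#'
#' For analyses where one biological replicate was acquired as several
#' gradient fractions, spectral counts (and unique peptides) are summed per
#' accession across the fraction tables before SAF — an explicit combining
#' step rather than an implicit merge. Protein probability is taken as the
#' maximum across fractions; length and description must agree.
#'
#' @param fractions List of protein-record data frames, one per fraction,
#'   all from the same replicate and sample label.
#' @return One combined protein-record data frame.
#' @export
combine_fractions <- function(fractions) {
  stopifnot(length(fractions) >= 1)
  tab <- do.call(rbind, lapply(fractions, validate_protein_table))
  if (length(unique(tab$sample_label)) > 1 ||
      length(unique(tab$replicate_id)) > 1) {
    stop("fractions must come from one replicate and one sample label")
  }
  len <- tapply(tab$length, tab$accession, unique, simplify = FALSE)
  bad <- names(len)[lengths(len) > 1]
  if (length(bad) > 0L) stop("length differs across fractions for: ", bad[1L])
  agg <- function(x, f) as.vector(tapply(x, tab$accession, f))
  accs <- sort(unique(tab$accession))
  data.frame(
    accession = accs,
    description = agg(tab$description, function(d) d[1L]),
    length = agg(tab$length, function(l) l[1L]),
    protein_probability = agg(tab$protein_probability, max),
    spectral_count = as.integer(agg(tab$spectral_count, sum)),
    unique_peptides = as.integer(agg(tab$unique_peptides, sum)),
    sample_label = tab$sample_label[1L],
    replicate_id = tab$replicate_id[1L],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Plot-ready probability/abundance scatter table
#'
#' Emits one row per protein with its median protein probability and median
#' relative SAF, the two axes of the identification-confidence versus
#' abundance scatter view.
#'
#' @param summary Aggregated summary from [aggregate_replicates()] computed
#'   on a table carrying \code{relative_saf}.
#' @return Data frame with columns \code{accession},
#'   \code{median_protein_probability}, \code{median_relative_saf}.
#' @export
probability_abundance_table <- function(summary) {
  need <- c("accession", "median_protein_probability", "median_relative_saf")
  stopifnot(all(need %in% names(summary)))
  out <- summary[need]
  rownames(out) <- NULL
  out
}
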