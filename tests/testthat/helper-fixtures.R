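# Shared fixtures and independent oracles used across test files.

protein_row <- function(accession, spectral_count, replicate_id = 1L,
                        sample_label = "treated", length = 200,
                        protein_probability = 1.0,
                        unique_peptides = min(spectral_count, 2L)) {
  data.frame(accession = accession,
             description = paste("fixture", accession),
             length = length,
             protein_probability = protein_probability,
             spectral_count = as.integer(spectral_count),
             unique_peptides = as.integer(unique_peptides),
             sample_label = sample_label,
             replicate_id = as.integer(replicate_id),
             stringsAsFactors = FALSE)
}

protein_table <- function(...) do.call(rbind, list(...))

psm_row <- function(accession = "P01", peptide = "ACDEFGKL",
                    peptide_probability = 1.0, ion_score = 100,
                    parent_mass_error = 0, mass_error_unit = "Da",
                    sample_label = "treated", replicate_id = 1L) {
  data.frame(peptide_sequence = peptide, assigned_accession = accession,
             peptide_probability = peptide_probability, ion_score = ion_score,
             parent_mass_error = parent_mass_error,
             mass_error_unit = mass_error_unit, sample_label = sample_label,
             replicate_id = as.integer(replicate_id),
             stringsAsFactors = FALSE)
}

# a quant table straight from counts/lengths, one replicate
quant_fixture <- function(counts, lengths,
                          accessions = sprintf("P%02d", seq_along(counts)),
                          replicate_id = 1L) {
  tab <- do.call(rbind, Map(function(a, cnt, len)
    protein_row(a, cnt, replicate_id = replicate_id, length = len),
    accessions, counts, lengths))
  quant_table(tab)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_rotation(q)
}

quat_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_transform <- function() {
  rigid_transform(random_rotation(), stats::rnorm(3, sd = 5))
}

# Independent superposition oracle: dense quaternion sampling plus
# Nelder-Mead polish of the quaternion; translation is the closed-form
# centroid match for each candidate rotation. No SVD anywhere.
oracle_superpose_rmsd <- function(X, Y, n_samples = 4000) {
  rmsd_for <- function(R) {
    t_vec <- colMeans(Y) - as.numeric(R %*% colMeans(X))
    fitted <- X %*% t(R) + rep(t_vec, each = nrow(X))
    sqrt(mean(rowSums((fitted - Y)^2)))
  }
  best_q <- c(1, 0, 0, 0)
  best <- rmsd_for(quat_to_rotation(best_q))
  for (i in seq_len(n_samples)) {
    q <- stats::rnorm(4)
    r <- rmsd_for(quat_to_rotation(q))
    if (r < best) {
      best <- r
      best_q <- q
    }
  }
  opt <- stats::optim(best_q, function(q) rmsd_for(quat_to_rotation(q)),
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-15))
  opt$value
}

# Brute-force single-record re-check of the PSM retention predicates.
psm_predicate_oracle <- function(matches, criteria) {
  keep <- logical(nrow(matches))
  for (i in seq_len(nrow(matches))) {
    keep[i] <- matches$peptide_probability[i] >= criteria$min_peptide_probability &&
      matches$ion_score[i] > criteria$min_ion_score &&
      abs(matches$parent_mass_error[i]) <= criteria$max_parent_mass_error
  }
  keep
}

# Brute-force protein-level retention oracle (conjunction of all predicates,
# evaluated record by record against the paired control run).
protein_filter_oracle <- function(treated, control, criteria) {
  keep <- logical(nrow(treated))
  for (i in seq_len(nrow(treated))) {
    rec <- treated[i, ]
    if (rec$accession %in% criteria$contaminant_accessions) next
    if (rec$protein_probability < criteria$min_protein_probability) next
    ctl <- control$spectral_count[control$accession == rec$accession]
    if (length(ctl) == 0L) {
      keep[i] <- TRUE
    } else if (rec$spectral_count / max(ctl, 1) >= criteria$control_fold_threshold &&
               ctl <= criteria$control_max_count) {
      keep[i] <- TRUE
    } else if (rec$accession %in% criteria$whitelist_accessions) {
      keep[i] <- TRUE
    }
  }
  keep
}
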