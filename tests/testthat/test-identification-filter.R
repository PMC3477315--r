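crit <- filter_criteria()

test_that("PSM retention thresholds act at the documented boundaries", {
  # score exactly at 30 fails (strict >); probability exactly 0.95 passes
  at_boundary <- psm_row(peptide_probability = 0.95, ion_score = 30.0)
  expect_equal(nrow(filter_spectrum_matches(at_boundary, crit)), 0L)
  above <- psm_row(peptide_probability = 0.95, ion_score = 30.0001)
  expect_equal(nrow(filter_spectrum_matches(above, crit)), 1L)
  clean <- psm_row(peptide_probability = 1.0, ion_score = 100,
                   parent_mass_error = 0)
  expect_equal(filter_spectrum_matches(clean, crit), clean)
  # mass error window is inclusive and two-sided
  expect_equal(nrow(filter_spectrum_matches(
    psm_row(parent_mass_error = -0.2), crit)), 1L)
  expect_equal(nrow(filter_spectrum_matches(
    psm_row(parent_mass_error = 0.2001), crit)), 0L)
})

test_that("PSM filter rejects mixed mass-error units and passes empty input through", {
  mixed <- rbind(psm_row(mass_error_unit = "Da"),
                 psm_row(mass_error_unit = "ppm"))
  expect_error(filter_spectrum_matches(mixed, crit), "mixed")
  empty <- psm_row()[0, ]
  expect_equal(nrow(filter_spectrum_matches(empty, crit)), 0L)
  # unit must also match the criteria's unit
  expect_error(
    filter_spectrum_matches(psm_row(mass_error_unit = "ppm"), crit),
    "unit")
})

test_that("PSM filter equals a brute-force predicate oracle on random tables", {
  matches <- simulate_psm_table(1000, seed = 7)
  got <- filter_spectrum_matches(matches, crit)
  want <- matches[psm_predicate_oracle(matches, crit), ]
  expect_equal(got, want)
  # order preserved, input unmodified
  expect_true(all(diff(as.integer(rownames(got))) > 0))
  expect_equal(matches, simulate_psm_table(1000, seed = 7))
})

test_that("spectral counts equal an independent histogram and sum to the PSM count", {
  m <- rbind(psm_row("P1", "AAAAKAAA"), psm_row("P1", "CCCCKCCC"),
             psm_row("P1", "DDDDKDDD"), psm_row("P2", "EEEEKEEE"),
             psm_row("P2", "FFFFKFFF"))
  counts <- compute_spectral_counts(m)
  expect_equal(counts$spectral_count[counts$accession == "P1"], 3L)
  expect_equal(counts$spectral_count[counts$accession == "P2"], 2L)

  set.seed(11)
  accs <- sprintf("P%02d", 1:10)
  big <- do.call(rbind, lapply(seq_len(500), function(i)
    psm_row(sample(accs, 1), peptide = paste0("PEP", i))))
  got <- compute_spectral_counts(big)
  hist <- table(big$assigned_accession)
  expect_equal(stats::setNames(got$spectral_count, got$accession),
               stats::setNames(as.integer(hist), names(hist)))
  expect_equal(sum(got$spectral_count), nrow(big))
  expect_equal(nrow(compute_spectral_counts(psm_row()[0, ])), 0L)
})

test_that("shared peptides are razor-assigned once, to the most probable protein", {
  shared <- rbind(psm_row("P2", "SHAREDPEP"), psm_row("P1", "SHAREDPEP"),
                  psm_row("P3", "OWNPEPTID"))
  # with probabilities: all shared PSMs go to the higher-probability protein
  got <- compute_spectral_counts(shared, c(P1 = 0.7, P2 = 0.99, P3 = 1.0))
  expect_equal(stats::setNames(got$spectral_count, got$accession),
               c(P2 = 2L, P3 = 1L))
  # without probabilities: deterministic lexicographic tie-break
  got2 <- compute_spectral_counts(shared)
  expect_equal(stats::setNames(got2$spectral_count, got2$accession),
               c(P1 = 2L, P3 = 1L))
  expect_equal(sum(got$spectral_count), nrow(shared))
})

test_that("control subtraction follows the dramatically-lower-abundance rule", {
  treated <- protein_table(protein_row("A", 10), protein_row("B", 10),
                           protein_row("C", 10), protein_row("D", 10))
  control <- protein_table(
    protein_row("B", 2, sample_label = "control"),   # 10/2 = 5x, ctl <= 2: keep
    protein_row("C", 3, sample_label = "control"),   # ctl > 2: drop
    protein_row("D", 4, sample_label = "control"))   # fold < 5 and ctl > 2: drop
  kept <- subtract_control(treated, control, crit)
  expect_setequal(kept$accession, c("A", "B"))
  expect_equal(kept$control_rule[kept$accession == "A"], "absent_from_control")
  expect_equal(kept$control_rule[kept$accession == "B"], "lower_abundance")
  expect_false(any(kept$whitelisted))
})

test_that("whitelisted proteins survive control evidence and are flagged", {
  treated <- protein_table(protein_row("FADD_X", 3))
  control <- protein_table(protein_row("FADD_X", 3, sample_label = "control"))
  wl_crit <- filter_criteria(whitelist_accessions = "FADD_X")
  expect_equal(nrow(subtract_control(treated, control, crit)), 0L)
  kept <- subtract_control(treated, control, wl_crit)
  expect_equal(kept$accession, "FADD_X")
  expect_true(kept$whitelisted)
  expect_equal(kept$control_rule, "whitelist")
})

test_that("duplicate accessions within one run are an error, not a merge", {
  dup <- protein_table(protein_row("A", 5), protein_row("A", 7))
  expect_error(subtract_control(dup, protein_row("B", 1, sample_label = "control"), crit),
               "duplicate accession")
})

test_that("contaminant exclusion removes by table and by protein probability, with reasons", {
  recs <- protein_table(
    protein_row("PC_HUMAN", 50),                       # biotin carboxylase
    protein_row("GOOD", 10),
    protein_row("LOWPP", 10, protein_probability = 0.49))
  res <- exclude_contaminants(recs, crit)
  expect_equal(res$retained$accession, "GOOD")
  expect_equal(stats::setNames(res$removed$reason, res$removed$accession),
               c(PC_HUMAN = "contaminant", LOWPP = "protein probability"))
  # empty contaminant set + perfect probabilities = identity
  loose <- filter_criteria(contaminant_accessions = character())
  res2 <- exclude_contaminants(protein_table(protein_row("PC_HUMAN", 50),
                                             protein_row("GOOD", 10)), loose)
  expect_equal(nrow(res2$retained), 2L)
  expect_equal(nrow(res2$removed), 0L)
})

test_that("full filter partitions input with exhaustive reasons and is idempotent", {
  treated <- protein_table(
    protein_row("A", 20), protein_row("PC_HUMAN", 40),
    protein_row("B", 10, protein_probability = 0.3),
    protein_row("C", 4), protein_row("D", 25))
  control <- protein_table(
    protein_row("C", 4, sample_label = "control"),
    protein_row("D", 1, sample_label = "control"))
  res <- filter_proteins(treated, control, crit)
  # partition: every input accession appears exactly once across the two sets
  expect_setequal(c(res$retained$accession, res$removed$accession),
                  treated$accession)
  expect_equal(nrow(res$retained) + nrow(res$removed), nrow(treated))
  expect_setequal(unique(res$removed$reason),
                  c("contaminant", "protein probability", "control"))
  # idempotence: filtering the retained set again changes nothing
  res2 <- filter_proteins(res$retained[names(treated)], control, crit)
  expect_equal(res2$retained$accession, res$retained$accession)
  expect_equal(nrow(res2$removed), 0L)
})

test_that("raising any threshold never enlarges the retained set", {
  matches <- simulate_psm_table(800, seed = 3)
  base_keep <- nrow(filter_spectrum_matches(matches, crit))
  for (tweak in list(filter_criteria(min_peptide_probability = 0.99),
                     filter_criteria(min_ion_score = 50),
                     filter_criteria(max_parent_mass_error = 0.05))) {
    expect_lte(nrow(filter_spectrum_matches(matches, tweak)), base_keep)
  }
  set.seed(5)
  treated <- do.call(rbind, lapply(1:30, function(i)
    protein_row(sprintf("T%02d", i), sample(1:40, 1),
                protein_probability = stats::runif(1))))
  control <- do.call(rbind, lapply(1:15, function(i)
    protein_row(sprintf("T%02d", i), sample(1:10, 1),
                sample_label = "control")))
  base <- nrow(filter_proteins(treated, control, crit)$retained)
  stricter <- list(
    filter_criteria(min_protein_probability = 0.9),
    filter_criteria(control_fold_threshold = 20),
    filter_criteria(control_max_count = 0),
    filter_criteria(contaminant_accessions = c(default_contaminants(), "T01", "T02")))
  for (s in stricter) {
    expect_lte(nrow(filter_proteins(treated, control, s)$retained), base)
  }
})
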