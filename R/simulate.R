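#' Ground truth for a synthetic spectral-count experiment
#'
#' Defines a known complex composition (copy numbers per complex and
#' recruitment categories), a contaminant background, replicate structure,
#' sampling depth, detectability model and count law, from which
#' [simulate_counts()] draws treated/control protein tables. Under the
#' length-proportional detectability model a component's expected spectral
#' count is proportional to copy_number x length — the assumption under
#' which NSAF-derived mole ratios recover copy-number ratios.
#'
#' @param components Data frame with columns \code{accession},
#'   \code{length} (residues), \code{copy_number} (per complex),
#'   \code{category} (receptor/FADD/DED_only/other).
#' @param contaminants Data frame with columns \code{accession},
#'   \code{length}, \code{intensity} (sampling weight on the same scale as
#'   copy_number x length); may have zero rows.
#' @param n_replicates Number of treated/control replicate pairs.
#' @param depth Expected total spectral counts per run.
#' @param detectability \code{"length_proportional"} (weight = copy_number
#'   x length) or \code{"uniform"} (weight = copy_number).
#' @param count_law \code{"poisson"} or \code{"negbin"}.
#' @param negbin_size Dispersion parameter when \code{count_law = "negbin"}
#'   (smaller = more overdispersed).
#' @param control_leakage Fraction of a component's treated mean leaking
#'   into the control run (default 0).
#' @param contaminant_probability Protein probability emitted for
#'   contaminant identifications (components get 1.0).
#' @return Object of class \code{"synthetic_truth"}.
#' @export
synthetic_truth <- function(components,
                            contaminants = empty_contaminants(),
                            n_replicates = 3L,
                            depth = 5000,
                            detectability = c("length_proportional", "uniform"),
                            count_law = c("poisson", "negbin"),
                            negbin_size = 10,
                            control_leakage = 0,
                            contaminant_probability = 0.97) {
  detectability <- match.arg(detectability)
  count_law <- match.arg(count_law)
  stopifnot(
    all(c("accession", "length", "copy_number", "category") %in% names(components)),
    all(components$length >= 1), all(components$copy_number >= 0),
    all(c("accession", "length", "intensity") %in% names(contaminants)),
    n_replicates >= 1, depth > 0, control_leakage >= 0, control_leakage <= 1
  )
  as_category_map(stats::setNames(components$category, components$accession))
  structure(
    list(components = components, contaminants = contaminants,
         n_replicates = as.integer(n_replicates), depth = depth,
         detectability = detectability, count_law = count_law,
         negbin_size = negbin_size, control_leakage = control_leakage,
         contaminant_probability = contaminant_probability),
    class = "synthetic_truth"
  )
}

empty_contaminants <- function() {
  data.frame(accession = character(), length = numeric(),
             intensity = numeric(), stringsAsFactors = FALSE)
}

#' The 3:1:9 DISC preset
#'
#' Synthetic TRAIL-DISC composition with ground-truth mole ratios
#' receptor:FADD:DED_only = 3:1:9 — two TRAIL-R1 plus one TRAIL-R2 copy per
#' FADD, and nine DED-only copies (procaspase-8 dominant, with minor
#' procaspase-10 and c-FLIP). Lengths are canonical full-length residue
#' counts. The contaminant background is a set of biotin-dependent
#' carboxylases plus a bead binder at intensities that put them clearly
#' above detection in both treated and control runs, the regime the
#' control-subtraction rule addresses.
#'
#' @param n_replicates,depth,detectability,count_law,control_leakage Passed
#'   to [synthetic_truth()].
#' @param ... Further arguments to [synthetic_truth()].
#' @return A \code{"synthetic_truth"} object.
#' @export
disc_preset <- function(n_replicates = 3L, depth = 5000,
                        detectability = "length_proportional",
                        count_law = "poisson", control_leakage = 0, ...) {
  components <- data.frame(
    accession = c("TR10A_SYN", "TR10B_SYN", "FADD_SYN",
                  "CASP8_SYN", "CASP10_SYN", "CFLAR_SYN"),
    length = c(468, 440, 208, 479, 521, 480),
    copy_number = c(2, 1, 1, 7, 1, 1),
    category = c("receptor", "receptor", "FADD",
                 "DED_only", "DED_only", "DED_only"),
    stringsAsFactors = FALSE
  )
  contaminants <- data.frame(
    accession = c("PC_HUMAN", "MCCA_HUMAN", "ACACA_HUMAN", "ALBU_HUMAN"),
    length = c(1178, 725, 2346, 609),
    intensity = c(1800, 900, 600, 300),
    stringsAsFactors = FALSE
  )
  synthetic_truth(components, contaminants, n_replicates = n_replicates,
                  depth = depth, detectability = detectability,
                  count_law = count_law, control_leakage = control_leakage,
                  ...)
}

truth_weights <- function(truth) {
  comp <- truth$components
  w_comp <- if (truth$detectability == "length_proportional") {
    comp$copy_number * comp$length
  } else {
    comp$copy_number
  }
  w_cont <- truth$contaminants$intensity
  total <- sum(w_comp) + sum(w_cont)
  if (total <= 0) stop("degenerate truth: zero total sampling weight")
  list(component = w_comp / total, contaminant = w_cont / total)
}

#' Simulate treated/control spectral-count tables
#'
#' Per replicate, treated spectral counts are drawn per protein from the
#' stated count law with mean depth x weight, weights proportional to
#' copy_number x length for components (under length-proportional
#' detectability) and to the stated background intensity for contaminants.
#' Control runs contain the contaminants at the same expected level, plus
#' optional low-level component leakage. Protein probabilities are 1.0 for
#' components and \code{contaminant_probability} for contaminants. Fully
#' reproducible from the seed.
#'
#' @param truth A [synthetic_truth()] object.
#' @param seed Integer seed.
#' @return List of class \code{"synthetic_dataset"}: \code{replicates}
#'   (list of lists with \code{treated} and \code{control} protein data
#'   frames), \code{truth}, \code{seed}.
#' @export
simulate_counts <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(as.integer(seed))
  w <- truth_weights(truth)
  comp <- truth$components
  cont <- truth$contaminants
  draw <- function(mu) {
    mu <- pmax(mu, 0)
    if (truth$count_law == "poisson") {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), size = truth$negbin_size, mu = mu)
    }
  }
  make_run <- function(counts, accs, lens, probs, label, rep_id) {
    keep <- counts > 0
    data.frame(
      accession = accs[keep],
      description = sprintf("synthetic %s", accs[keep]),
      length = lens[keep],
      protein_probability = probs[keep],
      spectral_count = as.integer(counts[keep]),
      unique_peptides = pmax(1L, as.integer(ceiling(counts[keep] / 2))),
      sample_label = rep(label, sum(keep)),
      replicate_id = rep(rep_id, sum(keep)),
      stringsAsFactors = FALSE
    )
  }
  replicates <- lapply(seq_len(truth$n_replicates), function(r) {
    treated_counts <- c(draw(truth$depth * w$component),
                        draw(truth$depth * w$contaminant))
    control_counts <- c(draw(truth$depth * w$component * truth$control_leakage),
                        draw(truth$depth * w$contaminant))
    accs <- c(comp$accession, cont$accession)
    lens <- c(comp$length, cont$length)
    probs <- c(rep(1.0, nrow(comp)),
               rep(truth$contaminant_probability, nrow(cont)))
    list(
      treated = make_run(treated_counts, accs, lens, probs, "treated", r),
      control = make_run(control_counts, accs, lens, probs, "control", r)
    )
  })
  structure(list(replicates = replicates, truth = truth,
                 seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' Simulate a random PSM table
#'
#' Draws peptide-spectrum matches with uniform probabilities, gamma ion
#' scores and normal mass errors over a set of accessions — fixture-grade
#' input for exercising the PSM filter against brute-force oracles.
#'
#' @param n Number of PSMs.
#' @param accessions Accession pool.
#' @param seed Integer seed.
#' @return PSM data frame (see [filter_spectrum_matches()] for columns).
#' @export
simulate_psm_table <- function(n, accessions = sprintf("P%02d", 1:10),
                               seed = 1L) {
  set.seed(as.integer(seed))
  data.frame(
    peptide_sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "D", "E", "F", "G", "K", "L", "R"),
                   8, replace = TRUE), collapse = ""), ""),
    assigned_accession = sample(accessions, n, replace = TRUE),
    peptide_probability = stats::runif(n),
    ion_score = stats::rgamma(n, shape = 2, scale = 20),
    parent_mass_error = stats::rnorm(n, 0, 0.15),
    mass_error_unit = "Da",
    sample_label = sample(c("treated", "control"), n, replace = TRUE),
    replicate_id = sample(1:3, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Toy death-effector-domain coordinates
#'
#' A compact alpha-helix-like coil of \code{n_res} alpha-carbon positions
#' (rise 1.5 A, 100 degrees per residue, radius 2.3 A) bent into a globular
#' footprint — enough geometric structure for well-conditioned
#' superpositions without shipping any real structure.
#'
#' @param n_res Number of residues; default 20.
#' @return Domain coordinate data frame (\code{resno}, \code{atom},
#'   \code{x}, \code{y}, \code{z}).
#' @export
make_toy_domain <- function(n_res = 20L) {
  i <- seq_len(n_res)
  theta <- i * 100 * pi / 180
  # helical coil with a slow superhelical bend to break axial symmetry
  bend <- 0.15 * i
  data.frame(
    resno = i,
    atom = "CA",
    x = 2.3 * cos(theta) + bend * sin(i / 5),
    y = 2.3 * sin(theta) + bend * cos(i / 5),
    z = 1.5 * i,
    stringsAsFactors = FALSE
  )
}

#' Build a toy tandem-domain structure with a known interface transform
#'
#' Emits a two-domain structure where domain 2 is a known ground-truth
#' rigid transform applied to domain 1 (plus optional Gaussian coordinate
#' jitter), together with the identity residue correspondence — a complete
#' fixture for interface-transform recovery.
#'
#' @param transform Ground-truth [rigid_transform()]; default: 60 degrees
#'   about z with a (12, 3, 8) A offset (domain-sized displacement).
#' @param n_res Residues per domain.
#' @param jitter_sd Gaussian coordinate noise sd (Angstrom) on domain 2.
#' @param seed Integer seed.
#' @return List of class \code{"toy_tandem"}: \code{ded1}, \code{ded2}
#'   (coordinate data frames), \code{pairing} (resno1/resno2), \code{truth}
#'   (the transform), \code{jitter_sd}, \code{seed}.
#' @export
make_toy_tandem <- function(transform = rotation_about_axis(c(0, 0, 1), 60,
                                                            c(12, 3, 8)),
                            n_res = 20L, jitter_sd = 0, seed = 1L) {
  stopifnot(inherits(transform, "rigid_transform"), jitter_sd >= 0)
  set.seed(as.integer(seed))
  ded1 <- make_toy_domain(n_res)
  ded2 <- apply_transform(transform, ded1)
  if (jitter_sd > 0) {
    ded2[c("x", "y", "z")] <- ded2[c("x", "y", "z")] +
      matrix(stats::rnorm(3L * n_res, 0, jitter_sd), ncol = 3L)
  }
  ded2$resno <- ded2$resno + n_res  # distinct residue numbering downstream
  structure(
    list(ded1 = ded1, ded2 = ded2,
         pairing = data.frame(resno1 = ded1$resno, resno2 = ded2$resno),
         truth = transform, jitter_sd = jitter_sd, seed = as.integer(seed)),
    class = "toy_tandem"
  )
}
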