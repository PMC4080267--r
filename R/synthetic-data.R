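#' Parameters of the paired-array simulator
#'
#' Bundles and validates the knobs of [generate_paired_dataset()].  The
#' defaults emulate the study design the pipeline targets: 30 subjects,
#' each contributing a blood, a normal-tissue and a tumor sample (90
#' samples per modality), measured on the same probes by two coupled
#' modalities (genotype and DNA-methylation signal).  A planted subset of
#' probes carries class-ordered mean shifts, identical in both
#' modalities except that planted methylation values sit
#' `modality_offset` intensity units below the genotype values.
#'
#' Default intensity scales put planted genotype class means near
#' 1.33 / 2.43 / 2.83 for blood / normal / tumor (the 1.2--2.9 range
#' typical of normalized SNP-array summaries): probe baselines are
#' uniform on `baseline_range`, class shifts (added to planted probes
#' only) are 0 / 1.1 / 1.5, and the cell-level noise s.d. is 0.25.  The
#' baseline spread is kept modest; a wide spread would, after downstream
#' zero substitution of missing cells, give high-baseline probes inflated
#' outlier scores in both modalities at once and break the hypergeometric
#' null for the cross-modality intersection.  Probe baselines and
#' subject-level offsets are shared between the two modalities,
#' reflecting that both assays interrogate the same probes on the same
#' physical samples; cell-level noise is independent.
#'
#' @param n_subjects Number of subjects; each yields three samples.
#' @param n_probes Number of probes per modality.
#' @param n_signal Number of planted (class-ordered) probes; must not
#'   exceed `n_probes`.
#' @param class_effect Named or positional numeric vector of length 3,
#'   mean shifts for blood, normal, tumor; must be strictly increasing.
#' @param modality_offset Nonnegative amount by which planted methylation
#'   means sit below the corresponding genotype means.
#' @param noise_sd Cell-level Gaussian noise s.d. (> 0).
#' @param missing_rate Fraction of cells set to missing, in \[0, 1\].
#' @param baseline_range Range of the per-probe baseline intensity.
#' @param subject_sd S.d. of the subject-level offset shared by the three
#'   tissues of a subject (and by both modalities).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_subjects = 30,
                              n_probes = 20000,
                              n_signal = 100,
                              class_effect = c(blood = 0, normal = 1.1,
                                               tumor = 1.5),
                              modality_offset = 0.4,
                              noise_sd = 0.25,
                              missing_rate = 0.05,
                              baseline_range = c(1.25, 1.40),
                              subject_sd = 0.1,
                              seed = 1L) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid '", field, "': ", msg, call. = FALSE)
  chk(is.numeric(n_subjects) && length(n_subjects) == 1 && n_subjects >= 1,
      "n_subjects", "need a positive count")
  chk(is.numeric(n_probes) && length(n_probes) == 1 && n_probes >= 1,
      "n_probes", "need a positive count")
  chk(is.numeric(n_signal) && length(n_signal) == 1 && n_signal >= 0,
      "n_signal", "need a nonnegative count")
  chk(n_signal <= n_probes, "n_signal", "must not exceed n_probes")
  chk(is.numeric(class_effect) && length(class_effect) == 3,
      "class_effect", "need three per-class shifts")
  chk(all(diff(class_effect) > 0), "class_effect",
      "must be strictly increasing over (blood, normal, tumor)")
  chk(is.numeric(modality_offset) && length(modality_offset) == 1 &&
        modality_offset >= 0, "modality_offset", "must be nonnegative")
  chk(is.numeric(noise_sd) && length(noise_sd) == 1 && noise_sd > 0,
      "noise_sd", "must be positive")
  chk(is.numeric(missing_rate) && length(missing_rate) == 1 &&
        missing_rate >= 0 && missing_rate <= 1,
      "missing_rate", "must lie in [0, 1]")
  chk(is.numeric(baseline_range) && length(baseline_range) == 2 &&
        diff(baseline_range) >= 0, "baseline_range", "need a range")
  chk(is.numeric(subject_sd) && length(subject_sd) == 1 && subject_sd >= 0,
      "subject_sd", "must be nonnegative")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
      "seed", "need an integer")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_probes = as.integer(n_probes),
                 n_signal = as.integer(n_signal),
                 class_effect = stats::setNames(as.numeric(class_effect),
                                                tissue_levels()),
                 modality_offset = modality_offset,
                 noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 baseline_range = baseline_range,
                 subject_sd = subject_sd,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Generate a paired genotype/methylation dataset
#'
#' Simulates two probe-by-sample matrices over identical probe and sample
#' universes, a matching sample design, and the ground truth needed to
#' score recovery.  Sample columns are laid out tissue-major (all blood
#' samples, then all normal, then all tumor), with the same subject order
#' in each block, mirroring the paired layout of the study design.
#'
#' Model per cell: baseline(probe) + subject offset + class shift (planted
#' probes only; methylation shifted down by `modality_offset`) + Gaussian
#' noise.  Baselines and subject offsets are shared between modalities;
#' noise is modality-specific.  Cells are then masked missing (`NA`)
#' independently at `missing_rate`.
#'
#' @param params A [simulation_params()] object.
#' @return List with elements `genotype`, `methylation` (both
#'   [omics_matrix()]), `design` ([sample_design()]) and `truth`, a list
#'   holding `signal_probe_ids` (sorted) and the planted per-class mean
#'   matrices `class_means_genotype`, `class_means_methylation`.
#' @examples
#' d <- generate_paired_dataset(simulation_params(n_probes = 200,
#'                                                n_signal = 10))
#' ncol(d$genotype$values)  # 90 samples
#' @export
generate_paired_dataset <- function(params) {
  if (!inherits(params, "simulation_params"))
    params <- do.call(simulation_params, as.list(params))
  p <- params
  withr::with_seed(p$seed, {
    probes <- sprintf("SNP_%06d", seq_len(p$n_probes))
    subjects <- sprintf("subj%03d", seq_len(p$n_subjects))
    tissues <- rep(tissue_levels(), each = p$n_subjects)
    samples <- paste0(rep(subjects, times = 3), "_", tissues)
    design <- sample_design(samples, rep(subjects, times = 3), tissues)

    signal <- sort(sample(probes, p$n_signal))
    baseline <- stats::runif(p$n_probes, p$baseline_range[1],
                             p$baseline_range[2])
    names(baseline) <- probes
    subj_off <- stats::rnorm(p$n_subjects, 0, p$subject_sd)
    sample_off <- rep(subj_off, times = 3)

    mu <- outer(baseline, rep(1, length(samples))) +
      outer(rep(1, p$n_probes), sample_off)
    dimnames(mu) <- list(probes, samples)
    shift <- p$class_effect[tissues]            # per-sample planted shift
    mu_g <- mu
    mu_g[signal, ] <- mu_g[signal, , drop = FALSE] +
      outer(rep(1, length(signal)), shift)
    mu_m <- mu
    mu_m[signal, ] <- mu_m[signal, , drop = FALSE] +
      outer(rep(1, length(signal)), shift) - p$modality_offset

    noise <- function() matrix(stats::rnorm(length(mu), 0, p$noise_sd),
                               nrow(mu), ncol(mu))
    g <- mu_g + noise()
    m <- mu_m + noise()
    if (p$missing_rate > 0) {
      g[stats::runif(length(g)) < p$missing_rate] <- NA_real_
      m[stats::runif(length(m)) < p$missing_rate] <- NA_real_
    }

    cm <- function(base) {
      out <- outer(baseline[signal], rep(1, 3)) +
        outer(rep(1, length(signal)), p$class_effect) + base
      dimnames(out) <- list(signal, tissue_levels())
      out
    }
    list(genotype = omics_matrix(g, "genotype"),
         methylation = omics_matrix(m, "methylation"),
         design = design,
         truth = list(signal_probe_ids = signal,
                      class_means_genotype = cm(0),
                      class_means_methylation = cm(-p$modality_offset)))
  })
}

#' Generate correlated ranked score trials
#'
#' Simulates repeated scoring runs over the same compound library (a
#' stand-in for repeated docking-score computations).  Each trial's score
#' is a concordance-weighted mixture of a shared latent compound score and
#' trial-specific noise, so that the pairwise Pearson correlation between
#' trials equals `concordance` in expectation: 0 gives independent
#' rankings, 1 identical rankings.
#'
#' @param n_compounds Number of compounds (>= 2).
#' @param n_trials Number of trials (>= 2).
#' @param concordance Share of score variance from the common latent
#'   score, in \[0, 1\].
#' @param seed Integer seed.
#' @return A [rank_trial_set()].
#' @export
generate_rank_trials <- function(n_compounds, n_trials = 3,
                                 concordance = 0.95, seed = 1L) {
  if (!is.numeric(concordance) || length(concordance) != 1 ||
      concordance < 0 || concordance > 1)
    stop("invalid 'concordance': must lie in [0, 1]", call. = FALSE)
  if (n_trials < 2) stop("invalid 'n_trials': need >= 2", call. = FALSE)
  if (n_compounds < 2) stop("invalid 'n_compounds': need >= 2",
                            call. = FALSE)
  withr::with_seed(seed, {
    ids <- sprintf("CMP%05d", seq_len(n_compounds))
    latent <- stats::rnorm(n_compounds)
    scores <- t(vapply(seq_len(n_trials), function(n) {
      sqrt(concordance) * latent +
        sqrt(1 - concordance) * stats::rnorm(n_compounds)
    }, numeric(n_compounds)))
    dimnames(scores) <- list(paste0("trial", seq_len(n_trials)), ids)
    rank_trial_set(scores)
  })
}

#' Generate random binary compound fingerprints
#'
#' Bits are independent Bernoulli(`density`); the expected fraction of set
#' bits in each fingerprint equals `density`.
#'
#' @param n_compounds Number of compounds (0 gives an empty collection).
#' @param n_bits Fingerprint length (>= 1).
#' @param density Probability that a bit is set, in (0, 1).
#' @param seed Integer seed.
#' @return A [fingerprint_set()].
#' @export
generate_fingerprints <- function(n_compounds, n_bits = 1024,
                                  density = 0.3, seed = 1L) {
  if (!is.numeric(density) || length(density) != 1 ||
      density <= 0 || density >= 1)
    stop("invalid 'density': must lie in (0, 1)", call. = FALSE)
  if (n_bits < 1) stop("invalid 'n_bits': need >= 1", call. = FALSE)
  if (n_compounds == 0)
    return(fingerprint_set(matrix(0L, 0, n_bits,
                                  dimnames = list(character(0), NULL))))
  withr::with_seed(seed, {
    bits <- matrix(stats::rbinom(n_compounds * n_bits, 1L, density),
                   n_compounds, n_bits)
    rownames(bits) <- sprintf("CMP%05d", seq_len(n_compounds))
    fingerprint_set(bits)
  })
}
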