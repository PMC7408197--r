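## Small in-code fixtures shared across test files.

## A 3-transition method table matching published MRM notation.
tiny_transitions <- function() {
  TransitionTable(
    precursor_mz = c(800.6, 666.4, 484.4),
    product_mz = c(184.1, 264.3, 85.1),
    polarity = "positive",
    collision_energy = c(20, 22, 30),
    attribution = c("PC(37:2)", "Cer[AS](d18:1/24:0)2OH",
                    "O-behenoylcarnitine"),
    category = c("phospholipid", "sphingolipid", "acylcarnitine")
  )
}

tiny_sample_data <- function(n = 4L) {
  geno <- rep(c("WT", "cpdm"), length.out = n)
  S4Vectors::DataFrame(
    sex = rep(c("F", "M"), length.out = n),
    genotype = geno,
    age_weeks = rep(5L, n),
    stage = ifelse(geno == "WT", "control", "non-lesional"),
    row.names = sprintf("S%02d", seq_len(n))
  )
}

tiny_intensity_matrix <- function(values = NULL, n_samples = 4L) {
  tt <- tiny_transitions()
  if (is.null(values)) {
    values <- matrix(seq_len(3L * n_samples) * 10, nrow = 3L,
                     dimnames = list(tt$transition_id,
                                     sprintf("S%02d", seq_len(n_samples))))
  }
  IntensityMatrix(values, tt, tiny_sample_data(ncol(values)))
}

## Reduced-scale simulation used where full 1030-ion scale is not needed.
small_sim <- function(seed = 1L, nIons = 200L, effects = defaultEffects(),
                      zeroRate = 0.02) {
  simulateLipidomics(simConfig(nIons = nIons, effects = effects,
                               zeroRate = zeroRate, seed = seed))
}

## Effect specs planting genotype-only and sex-only ions on explicit,
## disjoint targets; used by the recovery tests.
planted_effects <- function(tt, n_geno = 40L, n_sex = 40L, eta2 = 0.6) {
  ids <- tt$transition_id
  list(
    effectSpec("genotype", targetEta2 = eta2, style = "concentrated",
               transitions = ids[seq_len(n_geno)]),
    effectSpec("sex", targetEta2 = eta2, style = "concentrated",
               transitions = ids[n_geno + seq_len(n_sex)])
  )
}
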