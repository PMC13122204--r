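# Synthetic qPCR plate generation from ZZ/Z0 genotypes under an explicit
# exponential-amplification model. All randomness is confined to this file;
# the genotyping pipeline itself is deterministic.

#' Amplification model for one qPCR assay
#'
#' Describes an assay by its amplification efficiency E (per-cycle fold
#' increase minus one; E = 1 is perfect doubling) and the reference Cq
#' observed for a single template copy at reference input. Expected Cq for
#' `c` copies is `cq_ref - log(c) / log(1 + E)`, so at E = 1 a 2-fold dosage
#' difference is exactly one cycle.
#'
#' @param target_role `"autosome"` or `"sex"`.
#' @param efficiency Amplification efficiency as a fraction; assays are
#'   conventionally accepted within 0.9--1.1 (90--110%).
#' @param cq_ref Cq of a single copy at reference input, in `(0, 45)`.
#' @return Object of class `"assay_model"`.
#' @export
assay_model <- function(target_role = c("autosome", "sex"), efficiency = 1.0,
                        cq_ref = 25) {
  target_role <- match.arg(target_role)
  stopifnot(efficiency > 0, cq_ref > 0, cq_ref < 45)
  structure(list(target_role = target_role, efficiency = efficiency,
                 cq_ref = cq_ref), class = "assay_model")
}

#' Expected quantification cycle for a given template copy number
#'
#' @param copies Template copy number (>= 1; 0 returns `NA`, no
#'   amplification).
#' @param model An [assay_model()].
#' @return Expected Cq in cycles.
#' @examples
#' m <- assay_model("sex", efficiency = 1.0, cq_ref = 25)
#' expected_cq(2, m)  # one cycle below cq_ref
#' @export
expected_cq <- function(copies, model) {
  stopifnot(inherits(model, "assay_model"), all(copies >= 0))
  out <- model$cq_ref - log(copies) / log1p(model$efficiency)
  out[copies == 0] <- NA_real_
  out
}

#' Simulation settings for a synthetic genotyping cohort
#'
#' Defaults describe a realistic swab-qPCR run: quadruplicate technical
#' replicates, Gaussian replicate noise of 0.12 cycles, and a per-sample
#' input-amount offset (SD 0.5 cycles) shared by both assays of a sample,
#' reflecting widely varying DNA yields. Outlier wells can be injected with
#' probability `outlier_prob` by shifting a replicate by `outlier_shift`
#' cycles (random sign).
#'
#' @param n_male,n_female Numbers of ZZ and Z0 animals.
#' @param replicates Technical replicates per assay; default 4.
#' @param noise_sd Per-replicate Gaussian Cq noise SD, cycles.
#' @param sample_offset_sd SD of the per-sample input-amount Cq offset.
#' @param outlier_prob,outlier_shift Probability and magnitude of injected
#'   outlier wells.
#' @param seed Integer seed; the whole plate is reproducible from it.
#' @param autosome,sex [assay_model()]s for the two assays.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_male, n_female, replicates = 4, noise_sd = 0.12,
                       sample_offset_sd = 0.5, outlier_prob = 0,
                       outlier_shift = 3, seed = 1,
                       autosome = assay_model("autosome", 1.0, 24),
                       sex = assay_model("sex", 1.0, 25)) {
  stopifnot(n_male >= 0, n_female >= 0, n_male + n_female >= 1,
            replicates >= 1, noise_sd >= 0, sample_offset_sd >= 0,
            outlier_prob >= 0, outlier_prob <= 1,
            inherits(autosome, "assay_model"), inherits(sex, "assay_model"))
  structure(list(n_male = as.integer(n_male), n_female = as.integer(n_female),
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 sample_offset_sd = sample_offset_sd,
                 outlier_prob = outlier_prob, outlier_shift = outlier_shift,
                 seed = as.integer(seed), autosome = autosome, sex = sex),
            class = "sim_config")
}

# run code with a private RNG stream, leaving the caller's RNG untouched
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate the Cq measurements of one animal
#'
#' Autosomal copy number is 2 for both genotypes; the Z-linked target has 2
#' copies in ZZ males and 1 in Z0 females. Each replicate draws
#' `expected_cq + sample_offset + N(0, noise_sd)`, with optional outlier
#' shifts. Uses the current RNG state; see [simulate_cohort()] for seeded
#' plate generation.
#'
#' @param sample_id Identifier for the animal.
#' @param genotype `"ZZ"` or `"Z0"`.
#' @param config A [sim_config()].
#' @return Data frame of measurements (`sample_id`, `target_role`, `well_id`,
#'   `cq`).
#' @export
simulate_sample <- function(sample_id, genotype = c("ZZ", "Z0"), config) {
  genotype <- match.arg(genotype)
  stopifnot(inherits(config, "sim_config"))
  offset <- if (config$sample_offset_sd > 0) stats::rnorm(1, 0, config$sample_offset_sd) else 0
  sex_copies <- if (genotype == "ZZ") 2 else 1
  one_target <- function(model, copies, role) {
    mu <- expected_cq(copies, model) + offset
    cq <- mu + if (config$noise_sd > 0) stats::rnorm(config$replicates, 0, config$noise_sd) else 0
    if (config$outlier_prob > 0) {
      hit <- stats::runif(config$replicates) < config$outlier_prob
      cq[hit] <- cq[hit] + sample(c(-1, 1), sum(hit), replace = TRUE) * config$outlier_shift
    }
    data.frame(sample_id = sample_id, target_role = role,
               well_id = paste0(sample_id, "_", role, "_", seq_len(config$replicates)),
               cq = cq, stringsAsFactors = FALSE)
  }
  rbind(one_target(config$autosome, 2, "autosome"),
        one_target(config$sex, sex_copies, "sex"))
}

#' Simulate a full genotyping plate with known ground truth
#'
#' Generates measurements for `n_male` ZZ and `n_female` Z0 animals under the
#' configured amplification model and noise, deterministically from
#' `config$seed`. The caller's RNG state is preserved.
#'
#' @param config A [sim_config()].
#' @return Object of class `"sim_cohort"`: list with `measurements` (Cq table
#'   in the dialect read by [genotype_cohort()]) and `truth` (data frame of
#'   `sample_id`, `genotype`, `sex`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- c(if (config$n_male > 0) sprintf("M%03d", seq_len(config$n_male)),
           if (config$n_female > 0) sprintf("F%03d", seq_len(config$n_female)))
  genos <- c(rep("ZZ", config$n_male), rep("Z0", config$n_female))
  meas <- with_seed(config$seed, {
    do.call(rbind, lapply(seq_along(ids), function(i) {
      simulate_sample(ids[i], genos[i], config)
    }))
  })
  structure(list(
    measurements = meas,
    truth = data.frame(sample_id = ids, genotype = genos,
                       sex = ifelse(genos == "ZZ", "male", "female"),
                       stringsAsFactors = FALSE),
    config = config
  ), class = "sim_cohort")
}

#' Simulate a dilution series for efficiency estimation
#'
#' Produces (log10 input, Cq) pairs from serial dilutions of a template under
#' an assay's amplification model, for standard-curve efficiency estimation
#' with [estimate_efficiency()].
#'
#' @param model An [assay_model()].
#' @param dilution_factors Relative input amounts, e.g. `10^-(0:4)` for a
#'   10-fold series (>= 3 points).
#' @param start_copies Copy number at dilution factor 1.
#' @param noise_sd Gaussian Cq noise SD; 0 for a noiseless series.
#' @return Data frame with `log10_input` and `cq`.
#' @export
simulate_dilution_series <- function(model, dilution_factors = 10^-(0:4),
                                     start_copies = 1e6, noise_sd = 0) {
  stopifnot(inherits(model, "assay_model"), length(dilution_factors) >= 3,
            all(dilution_factors > 0), noise_sd >= 0)
  copies <- start_copies * dilution_factors
  stopifnot(all(copies >= 1))
  cq <- expected_cq(copies, model)
  if (noise_sd > 0) cq <- cq + stats::rnorm(length(cq), 0, noise_sd)
  data.frame(log10_input = log10(dilution_factors), cq = cq)
}
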