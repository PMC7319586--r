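#' Noise model for synthetic gel densitometry
#'
#' Band intensities receive independent multiplicative lognormal noise
#' (median factor 1, log-sd `multiplicative_sigma`) plus an optional additive
#' background offset. Multiplicative lognormal noise keeps intensities
#' positive and mimics the error structure of gel densitometry; the default
#' 5% sigma is a realistic per-band quantification error for well-exposed
#' fluorescent gels.
#'
#' @param multiplicative_sigma lognormal sd on each band intensity
#'   (default 0.05; 0 disables noise).
#' @param background additive offset per band (default 0).
#' @param seed RNG seed; identical seeds reproduce identical outputs
#'   bit-for-bit. NULL uses the caller's RNG stream.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_sigma = 0.05, background = 0,
                        seed = NULL) {
  cf_assert(is_scalar_number(multiplicative_sigma) && multiplicative_sigma >= 0,
            "multiplicative_sigma must be >= 0")
  cf_assert(is_scalar_number(background) && background >= 0,
            "background must be >= 0")
  structure(list(multiplicative_sigma = multiplicative_sigma,
                 background = background, seed = seed),
            class = "noise_model")
}

#' Titration design for a synthetic EMSA
#'
#' A zero-protein lane plus `n_lanes` log-spaced concentrations spanning
#' `decades` decades either side of `center` (typically the Kd under study),
#' replicated `replicates` times. Mirrors the titration layout of a gel-shift
#' experiment: protein titrated from zero to an upper limit well past
#' saturation, in triplicate.
#'
#' @param center concentration the grid is centred on, uM.
#' @param n_lanes number of non-zero lanes (default 12).
#' @param decades half-width of the grid in decades (default 2).
#' @param replicates replicate gels (default 3).
#' @param total_probe_intensity summed band intensity per lane, arbitrary
#'   densitometry units.
#' @param concentrations optional explicit non-zero concentration vector
#'   overriding the log grid (distinct, > 0).
#' @return object of class `titration_design` with `concentrations`
#'   (including the 0 lane), `replicates`, `total_probe_intensity`.
#' @export
titration_design <- function(center = 1, n_lanes = 12L, decades = 2,
                             replicates = 3L, total_probe_intensity = 1000,
                             concentrations = NULL) {
  if (is.null(concentrations)) {
    cf_assert(is_scalar_number(center) && center > 0, "center must be > 0")
    concentrations <- 10^seq(log10(center) - decades, log10(center) + decades,
                             length.out = n_lanes)
  }
  cf_assert(all(concentrations > 0) && !anyDuplicated(concentrations),
            "non-zero concentrations must be distinct and > 0")
  cf_assert(replicates >= 1L, "need at least one replicate")
  cf_assert(total_probe_intensity > 0, "total_probe_intensity must be > 0")
  structure(list(concentrations = c(0, sort(concentrations)),
                 replicates = as.integer(replicates),
                 total_probe_intensity = total_probe_intensity),
            class = "titration_design")
}

#' Simulate an EMSA band table from a binding model
#'
#' For each lane the expected band intensities are
#' `total_probe_intensity * band_distribution(model, conc)`; each band then
#' receives an independent lognormal factor and the background offset from
#' the noise model. With `multiplicative_sigma = 0` and `background = 0` the
#' simulated band fractions equal the model's distribution exactly.
#'
#' @param model a [promoter_model()].
#' @param design a [titration_design()].
#' @param noise a [noise_model()].
#' @return a [band_table()] with one row per lane and replicate.
#' @export
simulate_emsa <- function(model, design = titration_design(),
                          noise = noise_model()) {
  .check_model(model)
  cf_assert(inherits(design, "titration_design"), "design must be a titration_design")
  cf_assert(inherits(noise, "noise_model"), "noise must be a noise_model")
  n <- length(model$kds)
  conc <- design$concentrations
  expected <- t(vapply(conc, function(cc) {
    design$total_probe_intensity * band_distribution(model, cc)$probs
  }, numeric(n + 1L)))

  with_local_seed(noise$seed, {
    all_conc <- rep(conc, times = design$replicates)
    reps <- rep(seq_len(design$replicates), each = length(conc))
    intens <- expected[rep(seq_along(conc), times = design$replicates), ,
                       drop = FALSE]
    if (noise$multiplicative_sigma > 0) {
      intens <- intens * matrix(
        stats::rlnorm(length(intens), meanlog = 0,
                      sdlog = noise$multiplicative_sigma),
        nrow = nrow(intens))
    }
    intens <- intens + noise$background
    band_table(all_conc, intens, replicate = reps)
  })
}

#' Knock operator sites out of a model (polyC mutant probe)
#'
#' Models the mutant-probe design in which an inverted repeat is replaced by
#' a polyC tract: the replaced site contributes no binding event, so it is
#' removed from the model while the remaining sites keep their order and
#' affinities. Knocking out every site yields a zero-site model whose band
#' distribution is always "0 bound".
#'
#' @param model a [promoter_model()].
#' @param knocked_out_sites character vector of site ids to remove (may be
#'   empty, returning the model unchanged).
#' @return a [promoter_model()] over the surviving sites.
#' @export
mutate_probe <- function(model, knocked_out_sites = character()) {
  .check_model(model)
  if (!length(knocked_out_sites)) return(model)
  unknown <- setdiff(knocked_out_sites, model$site_ids)
  if (length(unknown)) {
    cf_stop(paste0("unknown site id(s): ", paste(unknown, collapse = ", ")),
            "coopfit_input_error")
  }
  keep <- !(model$site_ids %in% knocked_out_sites)
  promoter_model(model$kds[keep],
                 coupling = model$omega[keep, keep, drop = FALSE])
}

#' Generate a promoter sequence with planted inverted repeats
#'
#' Background bases are drawn uniformly at random (seeded); each planted pair
#' consists of a random left arm and, after the stated spacer, the reverse
#' complement of that arm carrying the stated number of random point
#' mutations (each mutated position changed to a different base, so the
#' pair's Hamming mismatch count equals `mutations` exactly). Ground-truth
#' coordinates are returned alongside the sequence so downstream tests never
#' re-derive them.
#'
#' @param length total sequence length, bp.
#' @param plan list of placements, each a list with `arm_length`, `spacer`,
#'   `position` (1-based left-arm start) and optional `mutations` (default 0).
#' @param seed RNG seed.
#' @param id,anchor passed to [promoter_sequence()].
#' @return list with `sequence` (a [promoter_sequence()]) and `truth`
#'   (data.frame of planted coordinates: `left_start`, `left_end`,
#'   `right_start`, `right_end`, `arm_length`, `spacer`, `mismatches`).
#' @export
plant_inverted_repeats <- function(length, plan, seed = NULL,
                                   id = "synthetic_promoter", anchor = NULL) {
  cf_assert(is_scalar_number(length) && length >= 1, "length must be >= 1")
  spans <- lapply(plan, function(p) {
    arm <- p$arm_length
    cf_assert(is_scalar_number(arm) && arm >= 4, "arm_length must be >= 4")
    cf_assert(is_scalar_number(p$spacer) && p$spacer >= 0, "spacer must be >= 0")
    cf_assert(is_scalar_number(p$position) && p$position >= 1,
              "position must be >= 1")
    c(p$position, p$position + 2 * arm + p$spacer - 1)
  })
  for (sp in spans) {
    if (sp[2] > length) cf_stop("planted pair does not fit in the sequence",
                                "coopfit_design_error")
  }
  if (base::length(spans) > 1L) {
    iv <- do.call(rbind, spans)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
      cf_stop("planted pairs overlap", "coopfit_design_error")
    }
  }

  with_local_seed(seed, {
    bases <- sample(.DNA_BASES, length, replace = TRUE)
    truth <- vector("list", base::length(plan))
    for (k in seq_along(plan)) {
      p <- plan[[k]]
      arm_len <- as.integer(p$arm_length)
      mut <- if (is.null(p$mutations)) 0L else as.integer(p$mutations)
      cf_assert(mut <= arm_len, "more mutations than arm positions")
      left <- sample(.DNA_BASES, arm_len, replace = TRUE)
      right <- rev(c(A = "T", C = "G", G = "C", T = "A")[left])
      if (mut > 0L) {
        pos <- sample.int(arm_len, mut)
        for (q in pos) {
          right[q] <- sample(setdiff(.DNA_BASES, right[q]), 1L)
        }
      }
      ls <- as.integer(p$position)
      rs <- ls + arm_len + as.integer(p$spacer)
      bases[ls:(ls + arm_len - 1L)] <- left
      bases[rs:(rs + arm_len - 1L)] <- right
      truth[[k]] <- data.frame(left_start = ls, left_end = ls + arm_len - 1L,
                               right_start = rs, right_end = rs + arm_len - 1L,
                               arm_length = arm_len,
                               spacer = as.integer(p$spacer),
                               mismatches = mut)
    }
    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$left_start), , drop = FALSE]
    rownames(truth) <- NULL
    list(sequence = promoter_sequence(paste(bases, collapse = ""), id = id,
                                      anchor = anchor),
         truth = truth)
  })
}

#' Simulate a kinetic reporter read under occupancy-based repression
#'
#' Links the occupancy model to the reporter readout: transcription is
#' assumed proportional to the probability that the promoter is completely
#' free of repressor, so the OD420 development slope is
#' `basal_slope * P(0 sites bound at repressor_conc)`. The OD420 series is a
#' linear ramp at that slope with additive Gaussian noise; the first-point
#' OD600 is drawn near 0.5 (Normal, sd 0.02), the typical mid-log density at
#' which the assay is run.
#'
#' @param model a [promoter_model()] of the repressor's operators.
#' @param repressor_conc free repressor concentration, uM.
#' @param basal_slope unrepressed OD420 development rate, OD420/min (>= 0).
#' @param noise_sd additive Gaussian sd on each OD420 reading (default 0).
#' @param seed RNG seed.
#' @param duration_min,interval_s sampling schedule (default 60 min at 90 s).
#' @param od600_first optional fixed OD600 (skips the random draw).
#' @param well_id,condition passed to [kinetic_plate_read()].
#' @return a [kinetic_plate_read()].
#' @export
simulate_reporter <- function(model, repressor_conc, basal_slope = 0.01,
                              noise_sd = 0, seed = NULL, duration_min = 60,
                              interval_s = 90, od600_first = NULL,
                              well_id = "sim_well", condition = list()) {
  .check_model(model)
  .check_conc(repressor_conc)
  cf_assert(is_scalar_number(basal_slope) && basal_slope >= 0,
            "basal_slope must be >= 0")
  p_free <- unname(band_distribution(model, repressor_conc)$probs[1])
  activity <- basal_slope * p_free
  times <- seq(0, duration_min, by = interval_s / 60)
  with_local_seed(seed, {
    od420 <- activity * times
    if (noise_sd > 0) od420 <- od420 + stats::rnorm(length(times), 0, noise_sd)
    if (is.null(od600_first)) od600_first <- stats::rnorm(1, 0.5, 0.02)
    kinetic_plate_read(times, od420, od600_first, well_id = well_id,
                       condition = condition)
  })
}
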