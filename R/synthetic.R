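#' Sample geometry of a tissue strip
#'
#' Rectangular strip dimensions used to convert between stress and force.
#' Defaults reflect the tested plantar aponeurosis strips: width about
#' 5 mm, thickness about 2.4-2.57 mm, gauge length 10 mm.
#'
#' @param width_mm,thickness_mm,gauge_length_mm Positive dimensions (mm).
#' @return A list of class `sample_geometry`.
#' @export
sample_geometry <- function(width_mm = 5, thickness_mm = 2.47,
                            gauge_length_mm = 10) {
  stopifnot(width_mm > 0, thickness_mm > 0, gauge_length_mm > 0)
  structure(list(width_mm = width_mm, thickness_mm = thickness_mm,
                 gauge_length_mm = gauge_length_mm),
            class = "sample_geometry")
}

#' Stress-relaxation testing protocol
#'
#' Strain levels, ramp rate and hold duration of the virtual experiment.
#' Defaults mirror the tissue protocol: consecutive relaxation tests at
#' nominal strains of 4, 6 and 8% reached by a 120%/s ramp and held for
#' 240 s, with full viscous recovery between tests.
#'
#' @param strain_levels Nominal strains, each in (0, 0.1].
#' @param ramp_rate Nominal strain rate of the loading ramp (1/s).
#' @param hold_duration Hold length (s).
#' @param ramp `"true"` simulates the finite-rate ramp before the hold;
#'   `"step"` idealizes it as instantaneous (closed-form relaxation).
#' @param hold_times Sampling instants of the hold (s since ramp end).
#' @return A list of class `relax_protocol`.
#' @export
relax_protocol <- function(strain_levels = c(0.04, 0.06, 0.08),
                           ramp_rate = 1.2,
                           hold_duration = 240,
                           ramp = c("true", "step"),
                           hold_times = hold_time_grid(0.01, hold_duration)) {
  ramp <- match.arg(ramp)
  stopifnot(all(strain_levels > 0), all(strain_levels <= 0.1),
            ramp_rate > 0, hold_duration > 0, all(hold_times > 0))
  structure(list(strain_levels = strain_levels, ramp_rate = ramp_rate,
                 hold_duration = hold_duration, ramp = ramp,
                 hold_times = sort(unique(hold_times))),
            class = "relax_protocol")
}

#' Measurement and population noise model
#'
#' `stress_cv` is the multiplicative Gaussian coefficient of variation of
#' the recorded stress (point-wise measurement noise). `sample_scatter`
#' is the SD, on the log scale, of per-sample log-normal perturbations of
#' the relative stiffnesses — between-sample variability of relaxation
#' shape. Instrument resolutions quantize force and imposed displacement.
#'
#' @param stress_cv Coefficient of variation of stress noise (default 0.03).
#' @param sample_scatter Log-scale SD of per-sample gamma perturbation
#'   (default 0.15).
#' @param force_resolution_N Load-cell resolution (N), default 0.2.
#' @param displacement_resolution_mm Actuator resolution (mm), default 0.001.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(stress_cv = 0.03, sample_scatter = 0.15,
                        force_resolution_N = 0.2,
                        displacement_resolution_mm = 0.001) {
  stopifnot(stress_cv >= 0, sample_scatter >= 0,
            force_resolution_N >= 0, displacement_resolution_mm >= 0)
  structure(list(stress_cv = stress_cv, sample_scatter = sample_scatter,
                 force_resolution_N = force_resolution_N,
                 displacement_resolution_mm = displacement_resolution_mm),
            class = "noise_model")
}

#' Generate a virtual sample population
#'
#' Draws per-sample geometries and per-sample material parameters around
#' the supplied truth. Geometries vary mildly around the strip dimensions
#' (donor-specific mean thickness); relative stiffnesses are perturbed
#' log-normally per sample and rescaled if their sum exceeds 1; relaxation
#' times are shared (relaxation-shape variability is carried by the
#' stiffnesses). With all noise off every sample carries the truth exactly.
#'
#' @param n_donors Number of donors.
#' @param samples_per_donor Integer vector (recycled) of samples per donor;
#'   default `c(7, 8, 9)` giving the study's 24 samples for 3 donors.
#' @param true_hp True `hyperelastic_params`.
#' @param true_ps True `prony_series`.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param donor_thickness_mm Mean strip thickness per donor (recycled).
#' @return A tibble of class `sample_population`: one row per sample with
#'   donor_id, sample_id, geometry columns and a `params` list-column
#'   holding each sample's `hp` and `ps`.
#' @export
generate_population <- function(n_donors = 3, samples_per_donor = c(7, 8, 9),
                                true_hp = ref_hyperelastic(),
                                true_ps = ref_prony(3),
                                noise = noise_model(), seed = 1L,
                                donor_thickness_mm = c(2.4, 2.41, 2.57)) {
  stopifnot(n_donors >= 1, all(samples_per_donor >= 1))
  counts <- rep_len(samples_per_donor, n_donors)
  thick <- rep_len(donor_thickness_mm, n_donors)
  withr::with_seed(as.integer(seed), {
    rows <- list()
    sid <- 0L
    for (d in seq_len(n_donors)) {
      for (j in seq_len(counts[d])) {
        sid <- sid + 1L
        width <- max(stats::rnorm(1, 5, 0.25), 2)
        th <- max(stats::rnorm(1, thick[d], 0.05), 0.5)
        if (noise$sample_scatter > 0 && true_ps$m > 0) {
          g <- true_ps$gamma *
            exp(stats::rnorm(true_ps$m, 0, noise$sample_scatter))
          if (sum(g) > 1) g <- g * (0.995 / sum(g))
          ps_s <- prony_series(g, true_ps$tau)
        } else {
          ps_s <- true_ps
        }
        rows[[sid]] <- tibble::tibble(
          donor_id = sprintf("D%d", d),
          sample_id = sprintf("D%d_S%02d", d, j),
          width_mm = width, thickness_mm = th, gauge_length_mm = 10,
          params = list(list(hp = true_hp, ps = ps_s)))
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(hp = true_hp, ps = true_ps, noise = noise,
                               seed = as.integer(seed))
    class(out) <- c("sample_population", class(out))
    out
  })
}

# Simulate one sample x strain hold trace (noise-free, second-PK measure).
.simulate_hold <- function(hp, ps, strain, protocol) {
  if (protocol$ramp == "step") {
    return(step_relaxation(hp, ps, strain, protocol$hold_times,
                           measure = "second_pk"))
  }
  t_ramp <- strain / protocol$ramp_rate
  ramp_grid <- seq(0, t_ramp, length.out = 501)
  grid <- c(ramp_grid, t_ramp + protocol$hold_times)
  tr <- integrate_history(
    hp, ps, function(t) pmin(protocol$ramp_rate * t, strain),
    t_end = max(grid), times = grid, measure = "second_pk")
  hold <- tr[tr$time_s > t_ramp, ]
  stress_trace(hold$time_s - t_ramp, hold$strain, hold$stress_MPa,
               "second_pk")
}

#' Simulate a full stress-relaxation experiment
#'
#' Runs the protocol on every sample of the population: for each strain
#' level, a loading ramp at the protocol rate (or an ideal step) followed
#' by the hold, sampled on the log-time grid. Consecutive tests on a
#' sample are independent (full viscous recovery during the rest period).
#' The nominal stress is converted to force through the strip
#' cross-section, quantized at the instrument resolutions, perturbed by
#' multiplicative measurement noise and converted back.
#'
#' @param population A `sample_population` from [generate_population()].
#' @param protocol A [relax_protocol()].
#' @param noise A [noise_model()]; defaults to the one recorded in the
#'   population.
#' @param seed Integer seed for the measurement noise.
#' @return A tibble of class `relaxation_dataset`, one row per time sample,
#'   columns donor_id, sample_id, strain_level, time_s, strain, stress_MPa
#'   (nominal measure), with the generating truth in `attr(, "truth")`.
#' @export
simulate_experiment <- function(population, protocol = relax_protocol(),
                                noise = NULL, seed = 1L) {
  stopifnot(inherits(population, "sample_population"),
            inherits(protocol, "relax_protocol"))
  truth <- attr(population, "truth")
  if (is.null(noise)) noise <- truth$noise
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (i in seq_len(nrow(population))) {
      smp <- population[i, ]
      pars <- smp$params[[1]]
      area <- smp$width_mm * smp$thickness_mm  # mm^2; MPa * mm^2 = N
      for (strain in protocol$strain_levels) {
        # displacement resolution quantizes the imposed strain
        if (noise$displacement_resolution_mm > 0) {
          disp <- round(strain * smp$gauge_length_mm /
                          noise$displacement_resolution_mm) *
            noise$displacement_resolution_mm
          strain_q <- disp / smp$gauge_length_mm
        } else strain_q <- strain
        tr <- .simulate_hold(pars$hp, pars$ps, strain_q, protocol)
        nominal <- convert_stress(tr$stress_MPa, 1 + tr$strain,
                                  "second_pk", "nominal")
        force <- nominal * area
        if (noise$force_resolution_N > 0) {
          force <- round(force / noise$force_resolution_N) *
            noise$force_resolution_N
        }
        if (noise$stress_cv > 0) {
          force <- force * (1 + stats::rnorm(length(force), 0,
                                             noise$stress_cv))
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          donor_id = smp$donor_id, sample_id = smp$sample_id,
          strain_level = strain, time_s = tr$time_s, strain = tr$strain,
          stress_MPa = force / area)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "measure") <- "nominal"
    attr(out, "truth") <- truth
    attr(out, "protocol") <- protocol
    attr(out, "noise") <- noise
    attr(out, "seed") <- as.integer(seed)
    class(out) <- c("relaxation_dataset", class(out))
    out
  })
}

#' Split a relaxation dataset into individual traces
#'
#' @param dataset A `relaxation_dataset` (long tibble).
#' @param keep_meta Attach donor/sample/strain attributes to each trace.
#' @return A named list of `stress_trace` objects, one per
#'   sample x strain-level combination.
#' @export
dataset_traces <- function(dataset, keep_meta = FALSE) {
  stopifnot(all(c("sample_id", "strain_level", "time_s",
                  "stress_MPa") %in% names(dataset)))
  measure <- attr(dataset, "measure")
  if (is.null(measure)) measure <- "nominal"
  key <- interaction(dataset$sample_id, dataset$strain_level, drop = TRUE)
  parts <- split(seq_len(nrow(dataset)), key)
  out <- lapply(parts, function(idx) {
    g <- dataset[idx, ]
    g <- g[order(g$time_s), ]
    tr <- stress_trace(g$time_s, g$strain, g$stress_MPa, measure)
    if (keep_meta) {
      attr(tr, "donor_id") <- g$donor_id[1]
      attr(tr, "sample_id") <- g$sample_id[1]
      attr(tr, "strain_level") <- g$strain_level[1]
    }
    tr
  })
  out
}
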