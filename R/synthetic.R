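# Synthetic study-design generator: batch growth curves, dilution-corrected
# OD measurement, saturating sensor responses, and the 8-batch x 19-time-point
# sampling grid.  Everything downstream (feature extraction, BPNN, ACO) is
# exercised against data from this module.

#' Dye labels of the 4x3 colorimetric sensor array
#'
#' Eleven porphyrins and one pH indicator, in row-major array order.  Feature
#' vectors are ordered dye-major with channels R, G, B within each dye, giving
#' 36 color components per sample.
#'
#' @return character vector of 12 dye labels.
#' @export
#' @examples
#' sensor_dyes()
sensor_dyes <- function() {
  c("TPP", "TPPMnCl", "FTPPFeCl", "TPPFeCl", "TPPCu", "FTPPCo",
    "TPPZn", "MTPPTE", "MTPPNiCl", "OEPPNi", "MTPP", "BTB")
}

#' Names of the 36 color components
#'
#' @return character vector `"<dye>:<channel>"`, dye-major, channels R, G, B.
#' @export
#' @examples
#' feature_names()[1:6]
feature_names <- function() {
  paste0(rep(sensor_dyes(), each = 3L), ":", rep(c("R", "G", "B"), times = 12L))
}

#' Logistic batch-growth parameters
#'
#' Defaults are calibrated so that a 0--72 h culture sampled every 4 h spans
#' optical densities from about 0.001 to 9.12, the range a dense yeast batch
#' culture covers.
#'
#' @param carrying_capacity plateau OD gained over the run (dimensionless
#'   absorbance units).
#' @param growth_rate logistic rate, per hour.
#' @param midpoint_time inflection time, hours.
#' @param baseline_od OD at inoculation.
#' @return object of class `growth_params`.
#' @export
#' @examples
#' growth_params()
growth_params <- function(carrying_capacity = 9.119, growth_rate = 0.25,
                          midpoint_time = 36, baseline_od = 0.001) {
  stopifnot_finite(c(carrying_capacity, growth_rate, midpoint_time, baseline_od),
                   "growth parameters")
  if (carrying_capacity <= 0) stop("'carrying_capacity' must be > 0")
  if (growth_rate <= 0) stop("'growth_rate' must be > 0")
  if (baseline_od < 0) stop("'baseline_od' must be >= 0")
  structure(list(carrying_capacity = carrying_capacity,
                 growth_rate = growth_rate,
                 midpoint_time = midpoint_time,
                 baseline_od = baseline_od),
            class = "growth_params")
}

#' Sensor response model linking OD to color-component changes
#'
#' Each of the 36 components responds to cell concentration through a
#' saturating (Michaelis-type) link,
#' `delta_c = coef_c * od / (od + K_c)` plus Gaussian read noise, where `K_c`
#' is the component's `saturation_half_od`.  Components with zero coefficient
#' carry noise only.  The default mimics the cross-sensitivity structure of a
#' porphyrin array in which a small number of dyes dominate: two strongly
#' informative components (FTPPFeCl:B, MTPPTE:B), two weakly informative
#' ones (TPPMnCl:B, BTB:B), and 32 noise-only components.
#'
#' @param coefficients numeric 36-vector of saturated response amplitudes in
#'   gray levels; zero means non-informative.  Default described above.
#' @param saturation_half_od OD at which a response reaches half its
#'   amplitude; scalar or per-component 36-vector.
#' @param noise_sd standard deviation of additive gray-level noise.
#' @return object of class `response_model` with an `informative_indices`
#'   field (indices of nonzero coefficients).
#' @export
#' @examples
#' m <- response_model()
#' feature_names()[m$informative_indices]
response_model <- function(coefficients = NULL, saturation_half_od = NULL,
                           noise_sd = 2) {
  if (is.null(coefficients)) {
    coefficients <- numeric(36L)
    coefficients[9L] <- -90   # FTPPFeCl:B  (strong)
    coefficients[24L] <- 81   # MTPPTE:B    (strong)
    coefficients[6L] <- -4    # TPPMnCl:B   (weak)
    coefficients[36L] <- 3.5  # BTB:B       (weak)
  }
  if (is.null(saturation_half_od)) saturation_half_od <- 4
  if (length(coefficients) != 36L) stop("'coefficients' must have length 36")
  stopifnot_finite(coefficients, "coefficients")
  if (!length(saturation_half_od) %in% c(1L, 36L))
    stop("'saturation_half_od' must have length 1 or 36")
  if (any(saturation_half_od <= 0)) stop("'saturation_half_od' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (any(abs(coefficients) + 5 * noise_sd > 255))
    stop("responses would exceed the 8-bit gray range")
  structure(list(coefficients = coefficients,
                 saturation_half_od = saturation_half_od,
                 noise_sd = noise_sd,
                 informative_indices = which(coefficients != 0)),
            class = "response_model")
}

#' Simulate a logistic growth curve
#'
#' `od(t) = baseline_od + K / (1 + exp(-r (t - t0)))` with carrying capacity
#' `K`, rate `r` and midpoint `t0`.
#'
#' @param times sampling times in hours (non-negative).
#' @param params a [growth_params()] object.
#' @return numeric vector of true OD values, one per time.
#' @export
#' @examples
#' simulate_growth_curve(seq(0, 72, by = 4), growth_params())
simulate_growth_curve <- function(times, params = growth_params()) {
  if (length(times) == 0L) stop("'times' must be non-empty")
  stopifnot_finite(times, "times")
  if (any(times < 0)) stop("'times' must be non-negative")
  params$baseline_od + params$carrying_capacity /
    (1 + exp(-params$growth_rate * (times - params$midpoint_time)))
}

#' Dilution ladder used for dense suspensions
#'
#' Factors 1, 2, 5, 10, 20, 50, ... (the 1-2-5 decade series).
#' @keywords internal
#' @noRd
dilution_ladder <- function() {
  as.vector(outer(c(1, 2, 5), 10^(0:3)))
}

#' Simulate a spectrophotometer OD measurement with dilution
#'
#' Absorbance is linear in cell concentration only for reads between 0.1 and
#' 0.65, so dense suspensions are diluted by the smallest 1-2-5 ladder factor
#' bringing the read at or below 0.65; the reported value is the dilution
#' factor times the mean of three noisy reads of the diluted sample.  Samples
#' already at or below 0.65 (including very dilute ones below 0.1, which no
#' dilution could raise) are read undiluted.
#'
#' @param od_true true optical density (>= 0).
#' @param read_noise_sd standard deviation of a single diluted read, OD units.
#' @param seed optional integer seed for the three reads.
#' @return list with `od_measured` and `dilution_factor`.
#' @export
#' @examples
#' simulate_od_measurement(9.12, read_noise_sd = 0)
simulate_od_measurement <- function(od_true, read_noise_sd = 0.005, seed = NULL) {
  if (!is.finite(od_true) || od_true < 0) stop("'od_true' must be >= 0")
  ladder <- dilution_ladder()
  ok <- which(od_true / ladder <= 0.65)
  if (length(ok) == 0L) stop("'od_true' exceeds the dilution ladder range")
  f <- ladder[ok[1L]]
  with_seed(seed, {
    reads <- od_true / f + rnorm(3L, 0, read_noise_sd)
    list(od_measured = f * mean(reads), dilution_factor = f)
  })
}

#' Simulate the 36-component sensor response of one sample
#'
#' @param od_true true optical density.
#' @param model a [response_model()].
#' @param seed optional integer seed for the read noise.
#' @return numeric 36-vector of signed gray-level differences, named after
#'   [feature_names()].
#' @export
#' @examples
#' simulate_feature_vector(1, response_model(), seed = 1)
simulate_feature_vector <- function(od_true, model = response_model(),
                                    seed = NULL) {
  sat <- od_true / (od_true + model$saturation_half_od)
  with_seed(seed, {
    v <- model$coefficients * sat + rnorm(36L, 0, model$noise_sd)
    names(v) <- feature_names()
    v
  })
}

#' Generate a full synthetic culture study
#'
#' Emulates the study design: `n_batches` independent batch cultures sampled
#' at 19 time points (0--72 h, every 4 h).  Batch-to-batch variability enters
#' as multiplicative jitter on carrying capacity and growth rate and additive
#' jitter on the midpoint time.  Each sample carries a true OD from the batch
#' growth curve, a dilution-corrected measured OD, and a 36-component sensor
#' response.
#'
#' @param n_batches number of culture batches (default 8).
#' @param times sampling times in hours (default `seq(0, 72, by = 4)`).
#' @param growth a [growth_params()] object (batch means).
#' @param response a [response_model()].
#' @param batch_jitter list with `capacity_cv`, `rate_cv` (log-normal
#'   coefficients of variation) and `midpoint_sd` (hours).
#' @param batch_feature_sd standard deviation (gray levels) of a per-batch,
#'   per-component offset added to every sample of a batch.  This emulates
#'   sensor drift and dye cross-sensitivity to uncontrolled batch conditions:
#'   a component's baseline response shifts between cultures, so components
#'   carrying no concentration signal do not generalize across batches.
#' @param read_noise_sd spectrophotometer read noise, OD units.
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return data.frame with columns `sample_id`, `batch_id`, `time_h`,
#'   `od_true`, `od_measured`, `dilution_factor` and 36 feature columns named
#'   `<dye>:<channel>`.
#' @export
#' @examples
#' d <- generate_dataset(n_batches = 2, seed = 1)
#' dim(d)
generate_dataset <- function(n_batches = 8, times = seq(0, 72, by = 4),
                             growth = growth_params(),
                             response = response_model(),
                             batch_jitter = list(capacity_cv = 0.03,
                                                 rate_cv = 0.08,
                                                 midpoint_sd = 1.5),
                             batch_feature_sd = 4,
                             read_noise_sd = 0.005, seed = NULL) {
  if (n_batches < 1) stop("'n_batches' must be >= 1")
  with_seed(seed, {
    rows <- vector("list", n_batches)
    for (b in seq_len(n_batches)) {
      gp <- growth_params(
        carrying_capacity = growth$carrying_capacity *
          exp(rnorm(1L, 0, batch_jitter$capacity_cv)),
        growth_rate = growth$growth_rate * exp(rnorm(1L, 0, batch_jitter$rate_cv)),
        midpoint_time = growth$midpoint_time + rnorm(1L, 0, batch_jitter$midpoint_sd),
        baseline_od = growth$baseline_od)
      od <- simulate_growth_curve(times, gp)
      meas <- lapply(od, simulate_od_measurement, read_noise_sd = read_noise_sd)
      feats <- t(vapply(od, simulate_feature_vector, numeric(36L),
                        model = response))
      feats <- sweep(feats, 2L, rnorm(36L, 0, batch_feature_sd), "+")
      df <- data.frame(batch_id = b, time_h = times, od_true = od,
                       od_measured = vapply(meas, `[[`, numeric(1L), "od_measured"),
                       dilution_factor = vapply(meas, `[[`, numeric(1L),
                                                "dilution_factor"),
                       check.names = FALSE)
      rows[[b]] <- cbind(df, as.data.frame(feats, check.names = FALSE))
    }
    out <- do.call(rbind, rows)
    out <- cbind(sample_id = sprintf("S%03d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}

#' Extract the 36-column feature matrix from a dataset
#'
#' @param data a data.frame from [generate_dataset()] or a feature CSV.
#' @return numeric matrix, samples x 36 components.
#' @export
feature_matrix <- function(data) {
  cols <- feature_names()
  missing <- setdiff(cols, names(data))
  if (length(missing)) stop("missing feature columns: ",
                            paste(head(missing, 3L), collapse = ", "))
  as.matrix(data[, cols, drop = FALSE])
}
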