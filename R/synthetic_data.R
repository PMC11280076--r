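#' Noise model for synthetic studies
#'
#' Inter-animal variability for generated datasets. Lognormal noise is
#' used because tissue concentrations are strictly positive and observed
#' standard deviations frequently exceed the means, implying right skew.
#' Under `"destructive"` sampling each timepoint draws independent
#' subjects (each animal contributes one terminal sample); under
#' `"serial"` sampling the same subjects are followed, implemented as one
#' multiplicative deviate per subject shared across timepoints.
#'
#' @param cv Coefficient of variation of the lognormal deviates (>= 0).
#' @param n_subjects_per_timepoint Subjects per timepoint (>= 1).
#' @param sampling `"destructive"` or `"serial"`.
#' @param distribution Only `"lognormal"` is supported.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.3, n_subjects_per_timepoint = 4,
                        sampling = c("destructive", "serial"),
                        distribution = "lognormal") {
  sampling <- match.arg(sampling)
  distribution <- match.arg(distribution, "lognormal")
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (n_subjects_per_timepoint < 1) stop("need n >= 1 subjects", call. = FALSE)
  structure(
    list(distribution = distribution, cv = cv,
         n_subjects_per_timepoint = as.integer(n_subjects_per_timepoint),
         sampling = sampling),
    class = "noise_model"
  )
}

# mean-preserving lognormal multipliers: E[m] = 1, CV[m] = cv
lognormal_multipliers <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic observed study
#'
#' Simulates the true tissue profiles for a protocol, then emulates a
#' destructively sampled animal study: at each timepoint and tissue, `n`
#' lognormal deviates are drawn around the true concentration with the
#' stated CV, and the per-timepoint mean, SD and n are reported in the
#' tidy observed-dataset layout. With `cv = 0` the reported means equal
#' the simulated truths exactly. Fully reproducible given the seed.
#'
#' @param drug,formulation,physiology,protocol Passed to
#'   [simulate_ocular()].
#' @param timepoints Sampling times (h); must not exceed `t_end`.
#' @param tissues Tissues to sample (see [tissue_concentration()]).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param study_code Label recorded in the dataset.
#' @param t_end Simulation horizon (default: last timepoint).
#' @return A tibble with columns `study_code`, `species_label`, `tissue`,
#'   `time` (h), `mean_conc` (ug/mL), `sd`, `n`.
#' @examples
#' ds <- generate_study(
#'   besifloxacin_parameters(), besivance_formulation(),
#'   builtin_physiology("NZ_rabbit"),
#'   timepoints = c(0.5, 1, 2, 4, 8, 24), tissues = "cornea",
#'   noise = noise_model(cv = 0.3, n_subjects_per_timepoint = 4), seed = 7
#' )
#' @export
generate_study <- function(drug, formulation, physiology,
                           protocol = dosing_protocol(0, formulation),
                           timepoints = c(0.25, 0.5, 1, 2, 4, 8, 12, 24),
                           tissues = c("tears", "cornea", "conjunctiva",
                                       "aqueous_humor", "plasma"),
                           noise = noise_model(), seed = 1,
                           study_code = "synthetic",
                           t_end = max(timepoints)) {
  if (any(timepoints < 0)) stop("timepoints must be >= 0", call. = FALSE)
  if (max(timepoints) > t_end) {
    stop("timepoints beyond the simulation horizon", call. = FALSE)
  }
  sim <- simulate_ocular(drug, formulation, physiology, protocol,
                         t_end = t_end)
  n <- noise$n_subjects_per_timepoint

  set.seed(seed)
  rows <- list()
  for (tt in tissues) {
    prof <- tissue_concentration(sim, tt)
    truth <- stats::approx(prof$time, prof$conc, xout = timepoints, rule = 2)$y
    if (noise$sampling == "serial") {
      subj <- lognormal_multipliers(n, noise$cv)
    }
    for (i in seq_along(timepoints)) {
      mult <- if (noise$sampling == "destructive") {
        lognormal_multipliers(n, noise$cv)
      } else {
        subj
      }
      obs <- truth[i] * mult
      rows[[length(rows) + 1]] <- tibble::tibble(
        study_code = study_code,
        species_label = physiology$species_label,
        tissue = tt, time = timepoints[i],
        mean_conc = mean(obs),
        sd = if (n > 1) stats::sd(obs) else 0,
        n = n
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$tissue, .data$time)
}

#' Read / write observed datasets
#'
#' Observed concentration-time tables are exchanged as delimited text
#' with the documented header
#' `study_code, species_label, tissue, time, mean_conc, sd, n`
#' (tab-separated). The same reader ingests user-supplied real data.
#'
#' @param path File path.
#' @return `read_observed_dataset()` returns the dataset tibble;
#'   `write_observed_dataset()` returns `path` invisibly.
#' @export
read_observed_dataset <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("study_code", "species_label", "tissue", "time",
                "mean_conc", "sd", "n")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("observed dataset is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  if (any(df$time < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(df$n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(df$sd < 0)) stop("sd must be >= 0", call. = FALSE)
  dplyr::arrange(df, .data$tissue, .data$time)
}

#' @rdname read_observed_dataset
#' @param dataset An observed-dataset tibble.
#' @export
write_observed_dataset <- function(dataset, path) {
  utils::write.table(dataset, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
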