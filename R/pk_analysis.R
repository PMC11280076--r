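#' Summary PK metrics for a concentration-time profile
#'
#' Computes Cmax, Tmax and the linear-trapezoidal AUC from the grid of a
#' simulated or observed profile. For an `ocular_simulation` the profile
#' of the requested tissue is extracted with [tissue_concentration()]; for
#' an observed dataset the `mean_conc` rows of that tissue are used. An
#' extrapolated AUC to infinity is reported when the terminal log-linear
#' slope (last `n_terminal` points) is negative.
#'
#' @param x An `ocular_simulation`, an observed-dataset tibble, or a
#'   two-column data frame `time`/`conc`.
#' @param tissue Tissue to summarise (ignored for a bare profile).
#' @param n_terminal Points used for the terminal slope (>= 2).
#' @return A one-row tibble: `tissue`, `cmax` (ug/mL), `tmax` (h),
#'   `auc_0_t` (ug*h/mL), `auc_0_inf` (NA when no terminal decline),
#'   `t_last`.
#' @examples
#' prof <- data.frame(time = c(0, 1, 2), conc = c(0, 2, 0))
#' compute_pk_metrics(prof) # AUC 2, Cmax 2, Tmax 1
#' @export
compute_pk_metrics <- function(x, tissue = NULL, n_terminal = 3) {
  prof <- extract_profile(x, tissue)
  if (nrow(prof) < 2) stop("need at least two timepoints", call. = FALSE)
  if (is.unsorted(prof$time, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  t <- prof$time
  c_ <- prof$conc
  auc <- sum(diff(t) * (utils::head(c_, -1) + utils::tail(c_, -1)) / 2)
  imax <- which.max(c_)

  auc_inf <- NA_real_
  k <- min(n_terminal, nrow(prof))
  tail_idx <- seq(nrow(prof) - k + 1, nrow(prof))
  ct <- c_[tail_idx]
  if (all(ct > 0)) {
    slope <- unname(stats::coef(stats::lm(log(ct) ~ t[tail_idx]))[2])
    if (is.finite(slope) && slope < 0) {
      auc_inf <- auc + c_[length(c_)] / (-slope)
    }
  }

  tibble::tibble(
    tissue = if (is.null(tissue)) NA_character_ else tissue,
    cmax = c_[imax], tmax = t[imax],
    auc_0_t = auc, auc_0_inf = auc_inf,
    t_last = t[length(t)]
  )
}

extract_profile <- function(x, tissue) {
  if (inherits(x, "ocular_simulation")) {
    if (is.null(tissue)) stop("tissue is required for a simulation", call. = FALSE)
    return(tissue_concentration(x, tissue))
  }
  df <- tibble::as_tibble(x)
  if ("mean_conc" %in% names(df)) {
    if (!is.null(tissue)) df <- df[df$tissue == tissue, ]
    return(tibble::tibble(time = df$time, conc = df$mean_conc))
  }
  stopifnot(all(c("time", "conc") %in% names(df)))
  df[c("time", "conc")]
}

#' Fold errors between simulated and observed profiles
#'
#' The fold error at each matched point is `max(sim/obs, obs/sim)` (always
#' >= 1, symmetric under swapping the two profiles). The summary reports
#' the geometric mean and maximum fold error, and whether every point is
#' within `k`-fold (boundary inclusive — a common acceptability criterion
#' for physiologically based model predictions). Points where the observed
#' value is zero cannot define a ratio; they are excluded and counted.
#'
#' @param simulated,observed Matched numeric vectors, or data frames with
#'   `time` and `conc`/`mean_conc` columns (matched on time).
#' @param k Fold threshold for the `within_k_fold` predicate.
#' @return A list with `per_point` (tibble: `time` when available, `sim`,
#'   `obs`, `fold`) and `summary` (tibble: `geomean_fold`, `max_fold`,
#'   `within_k_fold`, `k`, `n_used`, `n_excluded`).
#' @examples
#' fold_error(c(2, 0.5), c(1, 1))$summary$geomean_fold # 2
#' @export
fold_error <- function(simulated, observed, k = 3) {
  as_vec <- function(x) {
    if (is.data.frame(x)) {
      cn <- intersect(c("conc", "mean_conc"), names(x))[1]
      list(time = if ("time" %in% names(x)) x$time else NULL, v = x[[cn]])
    } else {
      list(time = NULL, v = as.numeric(x))
    }
  }
  s <- as_vec(simulated)
  o <- as_vec(observed)
  if (length(s$v) != length(o$v)) {
    stop("simulated and observed must be matched (equal length)", call. = FALSE)
  }
  usable <- o$v > 0 & s$v > 0
  n_excluded <- sum(!usable)
  fold <- pmax(s$v[usable] / o$v[usable], o$v[usable] / s$v[usable])
  per_point <- tibble::tibble(
    time = if (is.null(s$time)) NA_real_ else s$time[usable],
    sim = s$v[usable], obs = o$v[usable], fold = fold)
  summary <- tibble::tibble(
    geomean_fold = if (length(fold) > 0) exp(mean(log(fold))) else NA_real_,
    max_fold = if (length(fold) > 0) max(fold) else NA_real_,
    within_k_fold = if (length(fold) > 0) all(fold <= k) else NA,
    k = k, n_used = length(fold), n_excluded = n_excluded)
  list(per_point = per_point, summary = summary)
}

#' PK metrics table across tissues
#'
#' @param sim An `ocular_simulation`.
#' @param tissues Tissues to summarise.
#' @return A tibble with one row per tissue (see [compute_pk_metrics()]).
#' @export
pk_metrics_table <- function(sim, tissues = c("tears", "cornea",
                                              "conjunctiva", "aqueous_humor",
                                              "plasma")) {
  purrr::map_dfr(tissues, function(tt) compute_pk_metrics(sim, tt))
}
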