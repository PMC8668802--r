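#' Mean copies per partition from droplet counts
#'
#' The Poisson occupancy estimator: with k positive droplets out of n
#' accepted, the mean number of target copies per droplet is
#' `lambda = -ln(1 - k/n)`. Exactly zero when `k = 0`. Saturation (`k = n`)
#' is an error — every droplet positive means the concentration is above
#' the dynamic range and the estimator diverges; pipelines should fail
#' loudly rather than report infinity.
#'
#' @param n Total accepted droplets (> 0). Vectorised.
#' @param k Positive droplets, `0 <= k < n`. Vectorised.
#' @return Mean copies per partition (dimensionless), same length as `k`.
#' @examples
#' lambda_from_counts(n = 11272, k = 10)   # 8.87e-4
#' @export
lambda_from_counts <- function(n, k) {
  if (inherits(n, "well_counts") || (is.data.frame(n) &&
                                     all(c("n", "k") %in% names(n)))) {
    k <- n$k; n <- n$n
  }
  stopifnot(length(n) == length(k))
  if (any(n <= 0))
    stop("lambda_from_counts: n must be positive", call. = FALSE)
  if (any(k < 0) || any(k > n))
    stop("lambda_from_counts: require 0 <= k <= n", call. = FALSE)
  if (any(k == n))
    stop("lambda_from_counts: all droplets positive (k = n); concentration above dynamic range",
         call. = FALSE)
  ifelse(k == 0, 0, -log1p(-k / n))
}

#' Absolute concentration of the 1x reaction
#'
#' `lambda / droplet_volume_ul`, in target copies per microlitre of the
#' assembled reaction. Conversion to the DNA-sample scale is a separate
#' step ([copies_per_ng()]).
#'
#' @inheritParams lambda_from_counts
#' @param cfg A [quant_config()].
#' @return Copies/µl of the 1x reaction.
#' @examples
#' concentration(n = 11272, k = 10)   # 1.04 copies/ul
#' @export
concentration <- function(n, k, cfg = quant_config()) {
  lambda_from_counts(n, k) / cfg$droplet_volume_ul
}

#' Poisson confidence interval for a well concentration
#'
#' Exact (Garwood) two-sided interval on the positive-droplet count via
#' chi-square quantiles — `low_k = qchisq(alpha/2, 2k)/2`,
#' `high_k = qchisq(1 - alpha/2, 2k + 2)/2`, with `low_k = 0` at `k = 0` —
#' each bound pushed through the occupancy transform and the droplet
#' volume. A normal approximation (`ci_method = "normal"` in the config)
#' is provided for large counts: `k ± z * sqrt(k)` on the count scale,
#' clamped to `[0, n)`.
#'
#' Vendor software prints its own (unpublished) intervals; Garwood bounds
#' bracket the point estimate and agree with them approximately.
#'
#' @inheritParams concentration
#' @return A data.frame with columns `ci_low` and `ci_high` (copies/µl).
#' @export
poisson_ci <- function(n, k, cfg = quant_config()) {
  if (inherits(n, "well_counts") || (is.data.frame(n) &&
                                     all(c("n", "k") %in% names(n)))) {
    k <- n$k; n <- n$n
  }
  stopifnot(length(n) == length(k))
  if (any(k < 0) || any(n <= 0))
    stop("poisson_ci: require n > 0 and k >= 0", call. = FALSE)
  if (any(k == n))
    stop("poisson_ci: all droplets positive (k = n); concentration above dynamic range",
         call. = FALSE)
  alpha <- 1 - cfg$ci_level
  if (cfg$ci_method == "garwood") {
    low_k <- ifelse(k == 0, 0, stats::qchisq(alpha / 2, 2 * k) / 2)
    high_k <- stats::qchisq(1 - alpha / 2, 2 * k + 2) / 2
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    low_k <- pmax(0, k - z * sqrt(k))
    high_k <- pmin(k + z * sqrt(k), n - 0.5)
  }
  high_k <- pmin(high_k, n - 0.5)  # keep the occupancy transform finite
  to_conc <- function(kk) -log1p(-kk / n) / cfg$droplet_volume_ul
  data.frame(ci_low = to_conc(low_k), ci_high = to_conc(high_k))
}

#' Infection load: target copies per nanogram of total DNA
#'
#' Scales the reaction concentration back to the DNA extract:
#' `C_ng = C_ddPCR * (V_r / V_s) / C_DNA`, with reaction volume V_r and
#' template volume V_s from the config (defaults 22 µl and 2 µl).
#'
#' @param c_ddpcr Reaction concentration, copies/µl of the 1x reaction.
#'   Vectorised.
#' @param c_dna Total-DNA concentration of the extract, ng/µl (> 0).
#' @param cfg A [quant_config()].
#' @return Copies per ng of total DNA.
#' @examples
#' copies_per_ng(10, 5)   # 22
#' @export
copies_per_ng <- function(c_ddpcr, c_dna, cfg = quant_config()) {
  if (any(is.na(c_dna)) || any(c_dna <= 0))
    stop("copies_per_ng: total-DNA concentration must be > 0", call. = FALSE)
  if (any(c_ddpcr < 0))
    stop("copies_per_ng: reaction concentration must be >= 0", call. = FALSE)
  c_ddpcr * (cfg$reaction_volume_ul / cfg$sample_volume_ul) / c_dna
}

#' Droplet-count quality control
#'
#' A well passes when it has at least `min_droplets` accepted droplets
#' (default 10,000, boundary inclusive); wells below the floor are excluded
#' from all downstream statistics.
#'
#' @inheritParams concentration
#' @return Logical vector.
#' @export
well_qc <- function(n, cfg = quant_config()) {
  if (is.data.frame(n)) n <- n$n
  n >= cfg$min_droplets
}

#' Quantify a table of wells
#'
#' Applies the full per-well chain — occupancy estimator, concentration,
#' confidence interval, QC flag — to a `well_counts` table. Saturated wells
#' (`k = n`) error; callers that want to tolerate them should filter first.
#'
#' @param counts A `well_counts` data.frame (e.g. from
#'   [read_well_counts_csv()]).
#' @param cfg A [quant_config()].
#' @return A data.frame of class `well_quant`: the input columns plus
#'   `lambda`, `conc_copies_ul`, `ci_low`, `ci_high`, `qc_pass`.
#' @export
quantify_wells <- function(counts, cfg = quant_config()) {
  counts <- validate_counts_df(as.data.frame(counts), "quantify_wells")
  out <- counts
  out$lambda <- lambda_from_counts(counts$n, counts$k)
  out$conc_copies_ul <- out$lambda / cfg$droplet_volume_ul
  ci <- poisson_ci(counts$n, counts$k, cfg)
  out$ci_low <- ci$ci_low
  out$ci_high <- ci$ci_high
  out$qc_pass <- well_qc(counts$n, cfg)
  class(out) <- c("well_quant", "data.frame")
  out
}
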