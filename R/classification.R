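#' Classify droplets against a fluorescence threshold
#'
#' A droplet is positive when its amplitude is strictly greater than the
#' threshold, so a threshold placed exactly on the ceiling of the negative
#' cluster excludes it. Droplets in the "rain" region between the clusters
#' are classified by the threshold alone.
#'
#' @param well A [droplet_well()].
#' @param threshold Finite fluorescence threshold.
#' @return A `well_counts` row with `n = length(amplitudes)` and
#'   `k = sum(amplitudes > threshold)`.
#' @export
classify_droplets <- function(well, threshold) {
  stopifnot(inherits(well, "droplet_well"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold))
    stop("classify_droplets: 'threshold' must be a single finite number",
         call. = FALSE)
  well_counts(well$well_id, n = length(well$amplitudes),
              k = sum(well$amplitudes > threshold))
}

#' Automatic two-cluster threshold
#'
#' Pools the amplitudes of all supplied wells, partitions them with a
#' deterministic one-dimensional 2-means (centres initialised at the pooled
#' minimum and maximum, Lloyd iterations to convergence), and places the
#' threshold at the midpoint of the two cluster centres — mimicking the
#' usual manual placement between the negative and positive bands.
#'
#' Separability guard: if the centre separation is less than four times the
#' pooled within-cluster standard deviation the data are treated as a single
#' cluster and an error is raised; supply a manual threshold instead.
#'
#' @param wells A `droplet_well` or list of them.
#' @return A list of class `threshold_result` with fields `threshold`,
#'   `method` and `cluster_means` (negative mean, positive mean).
#' @export
auto_threshold <- function(wells) {
  if (inherits(wells, "droplet_well")) wells <- list(wells)
  stopifnot(length(wells) > 0L,
            all(vapply(wells, inherits, logical(1), "droplet_well")))
  amp <- unlist(lapply(wells, `[[`, "amplitudes"), use.names = FALSE)
  if (length(amp) < 2L || min(amp) == max(amp))
    stop("auto_threshold: no separation between droplet clusters",
         call. = FALSE)
  centres <- c(min(amp), max(amp))
  for (i in 1:100) {
    assign_hi <- abs(amp - centres[2]) < abs(amp - centres[1])
    new <- c(mean(amp[!assign_hi]), mean(amp[assign_hi]))
    if (anyNA(new)) break   # one cluster empty: degenerate
    if (max(abs(new - centres)) < 1e-9) { centres <- new; break }
    centres <- new
  }
  assign_hi <- abs(amp - centres[2]) < abs(amp - centres[1])
  if (!any(assign_hi) || all(assign_hi))
    stop("auto_threshold: no separation between droplet clusters",
         call. = FALSE)
  within_sd <- sqrt(
    (sum((amp[!assign_hi] - centres[1])^2) +
       sum((amp[assign_hi] - centres[2])^2)) / length(amp))
  if (diff(centres) < 4 * within_sd)
    stop("auto_threshold: no separation between droplet clusters (centre gap < 4x within-cluster spread)",
         call. = FALSE)
  structure(
    list(threshold = mean(centres), method = "two_cluster_midpoint",
         cluster_means = centres),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s at %.1f (cluster means %.1f / %.1f)\n",
              x$method, x$threshold, x$cluster_means[1], x$cluster_means[2]))
  invisible(x)
}

#' Manual threshold record
#'
#' @param threshold Fluorescence threshold set by inspection.
#' @return A `threshold_result` with `method = "manual"`.
#' @export
manual_threshold <- function(threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  structure(list(threshold = as.numeric(threshold), method = "manual",
                 cluster_means = NULL),
            class = "threshold_result")
}
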