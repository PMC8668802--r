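#' Quantification configuration
#'
#' Bundles the constants of the partition-quantification chain: the effective
#' droplet volume, the reaction and sample volumes used when converting a
#' reaction concentration to an infection load, the droplet-count QC floor,
#' the confidence level, and the positive-droplet floor used by the
#' limit-of-detection rule.
#'
#' The droplet volume default (0.85 nl) is the effective partition volume
#' that reproduces the printed lambda/concentration pairs of QX200-style
#' instruments; it is configurable because readers calibrate it per assay.
#'
#' @param droplet_volume_ul Effective droplet (partition) volume in
#'   microlitres. Default `0.00085` (0.85 nl).
#' @param reaction_volume_ul Reaction mix volume V_r in microlitres
#'   (default 22).
#' @param sample_volume_ul Template volume V_s added to the reaction, in
#'   microlitres (default 2).
#' @param min_droplets Minimum accepted droplets for a well to pass QC
#'   (default 10000).
#' @param ci_level Two-sided confidence level for Poisson intervals
#'   (default 0.95).
#' @param min_positive_droplets_lod Minimum positive droplets per replicate
#'   for a dilution level to count as detected (default 3).
#' @param ci_method `"garwood"` for the exact chi-square interval or
#'   `"normal"` for the large-count normal approximation.
#' @return An object of class `quant_config`.
#' @examples
#' cfg <- quant_config()
#' cfg$droplet_volume_ul
#' @export
quant_config <- function(droplet_volume_ul = 0.00085,
                         reaction_volume_ul = 22,
                         sample_volume_ul = 2,
                         min_droplets = 10000L,
                         ci_level = 0.95,
                         min_positive_droplets_lod = 3L,
                         ci_method = c("garwood", "normal")) {
  ci_method <- match.arg(ci_method)
  stopifnot(
    is.numeric(droplet_volume_ul), droplet_volume_ul > 0,
    is.numeric(reaction_volume_ul), reaction_volume_ul > 0,
    is.numeric(sample_volume_ul), sample_volume_ul > 0,
    is.numeric(min_droplets), min_droplets >= 0,
    is.numeric(ci_level), ci_level > 0, ci_level < 1,
    is.numeric(min_positive_droplets_lod), min_positive_droplets_lod >= 0
  )
  structure(
    list(
      droplet_volume_ul = as.numeric(droplet_volume_ul),
      reaction_volume_ul = as.numeric(reaction_volume_ul),
      sample_volume_ul = as.numeric(sample_volume_ul),
      min_droplets = as.integer(min_droplets),
      ci_level = as.numeric(ci_level),
      min_positive_droplets_lod = as.integer(min_positive_droplets_lod),
      ci_method = ci_method
    ),
    class = "quant_config"
  )
}

#' @export
print.quant_config <- function(x, ...) {
  cat("ddPCR quantification config\n")
  cat(sprintf("  droplet volume: %.5f ul (%.2f nl)\n",
              x$droplet_volume_ul, x$droplet_volume_ul * 1000))
  cat(sprintf("  reaction / sample volume: %g / %g ul\n",
              x$reaction_volume_ul, x$sample_volume_ul))
  cat(sprintf("  QC: >= %d droplets; LOD rule: >= %d positives per replicate\n",
              x$min_droplets, x$min_positive_droplets_lod))
  cat(sprintf("  CI: %s, level %.2f\n", x$ci_method, x$ci_level))
  invisible(x)
}

#' Full run configuration
#'
#' A serialisable bundle of every tunable the workflows use: the
#' [quant_config()] fields plus thresholding, imputation settings, and the
#' random seed. Round-trips losslessly through JSON via [write_run_config()] /
#' [read_run_config()].
#'
#' @param quant A [quant_config()].
#' @param threshold Manual fluorescence threshold, or `NA` for automatic
#'   two-cluster placement.
#' @param impute_m Number of multiple imputations (default 5).
#' @param impute_iters Chained-equation sweeps per imputation (default 50).
#' @param impute_donors Donor-pool size for predictive mean matching
#'   (default 5).
#' @param seed Integer seed governing all randomness in a run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(quant = quant_config(), threshold = NA_real_,
                       impute_m = 5L, impute_iters = 50L, impute_donors = 5L,
                       seed = 1L) {
  stopifnot(inherits(quant, "quant_config"),
            impute_m >= 1, impute_iters >= 1, impute_donors >= 1)
  structure(
    list(quant = quant, threshold = as.numeric(threshold),
         impute_m = as.integer(impute_m),
         impute_iters = as.integer(impute_iters),
         impute_donors = as.integer(impute_donors),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path File path for the JSON serialisation.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$quant <- unclass(x$quant)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  q <- x$quant
  run_config(
    quant = quant_config(q$droplet_volume_ul, q$reaction_volume_ul,
                         q$sample_volume_ul, q$min_droplets, q$ci_level,
                         q$min_positive_droplets_lod, q$ci_method),
    threshold = if (is.null(x$threshold)) NA_real_ else x$threshold,
    impute_m = x$impute_m, impute_iters = x$impute_iters,
    impute_donors = x$impute_donors, seed = x$seed
  )
}
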