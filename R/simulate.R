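#' Two-cluster droplet amplitude model
#'
#' Forward model of an end-point ddPCR amplitude plot: occupied droplets
#' fluoresce around a saturated positive mean irrespective of their exact
#' copy number, empty droplets around a low negative mean, and a small
#' "rain" fraction is re-drawn uniformly between the two cluster means
#' (primer dimer / partial amplification). Default cluster means are
#' instrument-realistic (negatives ~5,028, positives ~16,788); the spreads
#' are assumptions chosen to keep the clusters visually separable.
#'
#' @param neg_mean,neg_sd Negative-cluster mean and SD (defaults 5028, 300).
#' @param pos_mean,pos_sd Positive-cluster mean and SD (defaults 16788,
#'   400).
#' @param rain_fraction Fraction of droplets re-drawn uniformly between the
#'   cluster means (default 0.02).
#' @return An object of class `amplitude_model`.
#' @export
amplitude_model <- function(neg_mean = 5028, neg_sd = 300,
                            pos_mean = 16788, pos_sd = 400,
                            rain_fraction = 0.02) {
  stopifnot(neg_sd > 0, pos_sd > 0, rain_fraction >= 0, rain_fraction < 1,
            neg_mean < pos_mean)
  if (neg_mean + 3 * neg_sd >= pos_mean - 3 * pos_sd)
    warning("amplitude_model: clusters are not 3-sigma separable; auto thresholding may fail")
  structure(list(neg_mean = neg_mean, neg_sd = neg_sd, pos_mean = pos_mean,
                 pos_sd = pos_sd, rain_fraction = rain_fraction),
            class = "amplitude_model")
}

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  expr
}

#' Simulate one droplet-level well
#'
#' Per droplet the target copy number is Poisson with mean
#' `true_conc * droplet_volume_ul`; droplets holding at least one copy draw
#' their amplitude from the positive cluster, the rest from the negative
#' cluster, and a `rain_fraction` of droplets is re-drawn uniformly between
#' the cluster means. The attached `true_positive` attribute records the
#' occupancy labels, so classification error can be measured exactly.
#'
#' @param true_conc True concentration, copies/µl of the reaction (>= 0).
#' @param n_droplets Number of droplets (> 0).
#' @param cfg A [quant_config()] (droplet volume).
#' @param amp An [amplitude_model()].
#' @param seed Integer seed; same seed, same well.
#' @param well_id,sample_id,dilution_fold Identifiers for the output.
#' @return A [droplet_well()] with attribute `true_positive` (logical).
#' @export
simulate_well <- function(true_conc, n_droplets, cfg = quant_config(),
                          amp = amplitude_model(), seed = 1L,
                          well_id = "sim", sample_id = well_id,
                          dilution_fold = NA_real_) {
  if (true_conc < 0)
    stop("simulate_well: concentration must be >= 0", call. = FALSE)
  stopifnot(n_droplets > 0)
  with_seed(seed, {
    copies <- stats::rpois(n_droplets, true_conc * cfg$droplet_volume_ul)
    occupied <- copies > 0
    a <- ifelse(occupied,
                stats::rnorm(n_droplets, amp$pos_mean, amp$pos_sd),
                stats::rnorm(n_droplets, amp$neg_mean, amp$neg_sd))
    n_rain <- stats::rbinom(1, n_droplets, amp$rain_fraction)
    if (n_rain > 0) {
      idx <- sample.int(n_droplets, n_rain)
      a[idx] <- stats::runif(n_rain, amp$neg_mean, amp$pos_mean)
    }
    w <- droplet_well(well_id, pmax(a, 0), sample_id = sample_id,
                      dilution_fold = dilution_fold)
    attr(w, "true_positive") <- occupied
    w
  })
}

#' Simulate well counts directly (fast path)
#'
#' Counts-level shortcut used by coverage studies: the positive-droplet
#' count is Binomial(n, 1 - exp(-lambda)) with
#' `lambda = true_conc * droplet_volume_ul` — the same occupancy law as
#' [simulate_well()] without materialising amplitudes.
#'
#' @inheritParams simulate_well
#' @param n_wells Number of independent wells.
#' @return A `well_counts` data.frame with `n_wells` rows.
#' @export
simulate_well_counts <- function(true_conc, n_droplets, n_wells = 1L,
                                 cfg = quant_config(), seed = 1L) {
  if (true_conc < 0)
    stop("simulate_well_counts: concentration must be >= 0", call. = FALSE)
  with_seed(seed, {
    p <- 1 - exp(-true_conc * cfg$droplet_volume_ul)
    df <- data.frame(
      well_id = sprintf("sim%04d", seq_len(n_wells)),
      n = as.integer(rep(n_droplets, length.out = n_wells)),
      k = stats::rbinom(n_wells, rep(n_droplets, length.out = n_wells), p))
    class(df) <- c("well_counts", "data.frame")
    df
  })
}

#' Simulate a replicated dilution series
#'
#' Wells at true concentration `top_conc * fold` for each fold, with
#' droplet counts drawn uniformly within `n_droplet_range` (default
#' 10,000–17,500, a realistic reader range).
#'
#' @param top_conc Concentration of the undiluted sample, copies/µl.
#' @param folds Positive dilution folds, descending (default
#'   `c(1, 0.1, 0.01, 0.001)`).
#' @param replicates Replicates per level (default 10).
#' @param n_droplet_range Inclusive range for per-well droplet counts.
#' @param cfg A [quant_config()].
#' @param seed Integer seed.
#' @return A `well_counts` data.frame with `dilution_fold` and `true_conc`
#'   columns.
#' @export
simulate_dilution_series <- function(top_conc, folds = c(1, 0.1, 0.01, 0.001),
                                     replicates = 10L,
                                     n_droplet_range = c(10000L, 17500L),
                                     cfg = quant_config(), seed = 1L) {
  stopifnot(all(folds > 0), !is.unsorted(rev(folds)),
            replicates >= 1, n_droplet_range[1] <= n_droplet_range[2])
  with_seed(seed, {
    rows <- lapply(seq_along(folds), function(i) {
      tc <- top_conc * folds[i]
      n <- sample(seq(n_droplet_range[1], n_droplet_range[2]), replicates,
                  replace = TRUE)
      p <- 1 - exp(-tc * cfg$droplet_volume_ul)
      data.frame(
        well_id = sprintf("f%g_rep%d", folds[i], seq_len(replicates)),
        dilution_fold = folds[i], true_conc = tc,
        n = as.integer(n), k = stats::rbinom(replicates, n, p))
    })
    df <- do.call(rbind, rows)
    class(df) <- c("well_counts", "data.frame")
    df
  })
}

#' Host-survey generative model
#'
#' Infection status is Bernoulli under a logistic model in population,
#' month, host length and host density; infected hosts receive lognormal
#' infection loads (continuous copies/ng, variance-to-mean ratio >> 1 for
#' `sdlog` above ~0.7 at the default means); covariates are drawn from
#' configurable ranges, and missingness is applied completely at random.
#'
#' @param intercept Logistic intercept on the log-odds scale (reference
#'   population/month).
#' @param population_effects,month_effects Named log-odds offsets for the
#'   non-reference levels.
#' @param beta_length,beta_density Log-odds per µm of length / per
#'   individual/m² of density.
#' @param load_meanlog,load_sdlog Lognormal parameters of infected-host
#'   loads.
#' @param length_mean,length_sd Host length distribution (µm).
#' @param density_range Uniform range of population densities (ind/m²).
#' @param organic_range Uniform range of sediment organic content (%).
#' @param dna_range Uniform range of total-DNA concentrations (ng/µl).
#' @param missing_length,missing_organic MCAR missingness rates.
#' @return An object of class `survey_model`.
#' @export
survey_model <- function(intercept = 1.76,
                         population_effects = c(Lammefjord = -3.0,
                                                Vellerup = -1.8,
                                                Lynaes = -2.8),
                         month_effects = c(May = 0.7, August = 0.0,
                                           October = 0.3, November = 0.6),
                         beta_length = 0.001, beta_density = -0.0003,
                         load_meanlog = 3, load_sdlog = 1.5,
                         length_mean = 5000, length_sd = 1200,
                         density_range = c(1000, 30000),
                         organic_range = c(0.3, 3),
                         dna_range = c(2, 30),
                         missing_length = 0, missing_organic = 0) {
  structure(as.list(environment()), class = "survey_model")
}

#' Simulate a host survey table
#'
#' @param model A [survey_model()].
#' @param hosts_per_cell Hosts per population-month cell (default 25).
#' @param cfg A [quant_config()] (used to back-compute the reaction
#'   concentration each host would have produced).
#' @param seed Integer seed.
#' @return A `host_survey` data.frame with the reader schema plus
#'   `load_copies_ng`; the generating truth is attached as attribute
#'   `truth` (list of coefficients on the model scale).
#' @export
simulate_survey <- function(model = survey_model(), hosts_per_cell = 25L,
                            cfg = quant_config(), seed = 1L) {
  stopifnot(inherits(model, "survey_model"), hosts_per_cell > 0)
  pops <- c("Herslev", names(model$population_effects))
  months <- c("March", names(model$month_effects))
  with_seed(seed, {
    grid <- expand.grid(population = pops, month = months,
                        stringsAsFactors = FALSE)
    df <- grid[rep(seq_len(nrow(grid)), each = hosts_per_cell), ]
    n <- nrow(df)
    df$host_id <- sprintf("H%05d", seq_len(n))
    df$length_um <- pmax(stats::rnorm(n, model$length_mean, model$length_sd),
                         500)
    df$density_ind_m2 <- stats::runif(n, model$density_range[1],
                                      model$density_range[2])
    df$organic_content_pct <- stats::runif(n, model$organic_range[1],
                                           model$organic_range[2])
    df$dna_conc_ng_ul <- stats::runif(n, model$dna_range[1],
                                      model$dna_range[2])
    eta <- model$intercept +
      ifelse(df$population == "Herslev", 0,
             model$population_effects[df$population]) +
      ifelse(df$month == "March", 0, model$month_effects[df$month]) +
      model$beta_length * df$length_um +
      model$beta_density * df$density_ind_m2
    df$infected_true <- stats::rbinom(n, 1, stats::plogis(eta)) == 1L
    df$load_copies_ng <- ifelse(
      df$infected_true,
      stats::rlnorm(n, model$load_meanlog, model$load_sdlog), 0)
    # reaction concentration that would have produced this load (Eq. chain
    # inverted): C_ddPCR = load * C_DNA / (V_r / V_s)
    df$conc_copies_ul <- df$load_copies_ng * df$dna_conc_ng_ul /
      (cfg$reaction_volume_ul / cfg$sample_volume_ul)
    if (model$missing_length > 0)
      df$length_um[stats::runif(n) < model$missing_length] <- NA_real_
    if (model$missing_organic > 0)
      df$organic_content_pct[stats::runif(n) < model$missing_organic] <-
        NA_real_
    truth <- list(intercept = model$intercept,
                  population_effects = model$population_effects,
                  month_effects = model$month_effects,
                  beta_length = model$beta_length,
                  beta_density = model$beta_density,
                  load_meanlog = model$load_meanlog,
                  load_sdlog = model$load_sdlog)
    rownames(df) <- NULL
    df <- df[, c("host_id", "population", "month", "length_um",
                 "density_ind_m2", "organic_content_pct", "dna_conc_ng_ul",
                 "conc_copies_ul", "load_copies_ng", "infected_true")]
    class(df) <- c("host_survey", "data.frame")
    attr(df, "truth") <- truth
    df
  })
}
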