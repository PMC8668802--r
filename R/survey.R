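#' Infection status from an infection load
#'
#' A host is infected when more than zero target copies per ng of total DNA
#' were detected.
#'
#' @param load Infection load, copies/ng, `>= 0`. Vectorised; `NA` stays
#'   `NA`.
#' @return Logical vector.
#' @export
infected_flag <- function(load) {
  if (any(!is.na(load) & load < 0))
    stop("infected_flag: negative infection load", call. = FALSE)
  load > 0
}

# Wilson score interval for a binomial proportion; good behaviour at the
# extreme proportions (0%, 100%) that field prevalence data hit.
wilson_interval <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Prevalence of infection, by group
#'
#' Proportion of infected hosts (load > 0) per group, with a 95% Wilson
#' score interval. Hosts with missing load are dropped from the
#' denominator.
#'
#' @param hosts A `host_survey` data.frame carrying a `load_copies_ng`
#'   column (see [survey_loads()]), or any data.frame with one.
#' @param by Character vector of grouping column names (default
#'   `c("population", "month")`); use `character(0)` for a single overall
#'   group.
#' @param level Confidence level (default 0.95).
#' @return A data.frame with one row per group: grouping columns,
#'   `n_hosts`, `n_infected`, `prevalence_pct`, `ci_low_pct`, `ci_high_pct`.
#' @export
prevalence <- function(hosts, by = c("population", "month"), level = 0.95) {
  df <- as.data.frame(hosts)
  stopifnot("load_copies_ng" %in% names(df))
  df <- df[!is.na(df$load_copies_ng), , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("prevalence: no hosts with measured load; empty result")
    return(data.frame())
  }
  key <- if (length(by)) interaction(df[by], drop = TRUE, sep = " / ")
  else factor(rep("all", nrow(df)))
  res <- lapply(levels(key), function(g) {
    sub <- df[key == g, , drop = FALSE]
    n <- nrow(sub)
    ki <- sum(infected_flag(sub$load_copies_ng))
    ci <- wilson_interval(ki, n, level)
    out <- if (length(by)) sub[1, by, drop = FALSE]
    else data.frame(group = "all")
    cbind(out,
          data.frame(n_hosts = n, n_infected = ki,
                     prevalence_pct = 100 * ki / n,
                     ci_low_pct = 100 * ci[["low"]],
                     ci_high_pct = 100 * ci[["high"]]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Aggregation (variance-to-mean ratio) of infection loads
#'
#' Mean, variance and variance-to-mean ratio of the infection loads of
#' *infected* hosts; a ratio much greater than one means few hosts carry
#' most of the symbionts. Loads of zero (uninfected hosts) must be filtered
#' out first — the function enforces this.
#'
#' @param loads Infection loads of infected hosts (all > 0), length >= 2.
#' @param var_mode `"sample"` (divisor m - 1, default) or `"population"`.
#' @return A list of class `aggregation_result` with `mean`, `se`,
#'   `variance`, `vmr` and `m`.
#' @export
aggregation_index <- function(loads, var_mode = c("sample", "population")) {
  var_mode <- match.arg(var_mode)
  loads <- as.numeric(loads)
  loads <- loads[!is.na(loads)]
  if (length(loads) < 2L)
    stop("aggregation_index: need >= 2 infected-host loads", call. = FALSE)
  if (any(loads <= 0))
    stop("aggregation_index: loads must come from infected hosts only (all > 0)",
         call. = FALSE)
  m <- length(loads)
  v <- stats::var(loads)
  if (var_mode == "population") v <- v * (m - 1) / m
  mu <- mean(loads)
  structure(
    list(mean = mu, se = stats::sd(loads) / sqrt(m), variance = v,
         vmr = v / mu, m = m, var_mode = var_mode),
    class = "aggregation_result"
  )
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat(sprintf("<aggregation> m=%d mean=%.4g s2=%.4g s2/mean=%.4g\n",
              x$m, x$mean, x$variance, x$vmr))
  invisible(x)
}

#' Attach infection loads to a survey table
#'
#' Computes `load_copies_ng` from the measured reaction concentration and
#' the total-DNA concentration of each host via [copies_per_ng()].
#'
#' @param hosts A `host_survey` data.frame (see [read_survey_csv()]).
#' @param cfg A [quant_config()].
#' @return The input with a `load_copies_ng` column appended.
#' @export
survey_loads <- function(hosts, cfg = quant_config()) {
  df <- as.data.frame(hosts)
  stopifnot(all(c("conc_copies_ul", "dna_conc_ng_ul") %in% names(df)))
  ok <- !is.na(df$conc_copies_ul) & !is.na(df$dna_conc_ng_ul)
  df$load_copies_ng <- NA_real_
  df$load_copies_ng[ok] <- copies_per_ng(df$conc_copies_ul[ok],
                                         df$dna_conc_ng_ul[ok], cfg)
  class(df) <- unique(c("host_survey", class(df)))
  df
}

#' Survey summary table
#'
#' One row per group mirroring the standard survey report: prevalence (%)
#' with the number infected, and — over infected hosts only — mean load,
#' its standard error, variance and variance-to-mean ratio.
#'
#' @inheritParams prevalence
#' @return A data.frame, one row per group.
#' @export
survey_summary <- function(hosts, by = c("population", "month")) {
  prev <- prevalence(hosts, by = by)
  df <- as.data.frame(hosts)
  df <- df[!is.na(df$load_copies_ng) & df$load_copies_ng > 0, , drop = FALSE]
  key_all <- if (length(by)) interaction(prev[by], drop = FALSE, sep = " / ")
  else factor("all")
  key_inf <- if (length(by)) interaction(df[by], sep = " / ")
  else factor(rep("all", nrow(df)))
  agg <- t(vapply(seq_len(nrow(prev)), function(i) {
    loads <- df$load_copies_ng[key_inf == as.character(key_all[i])]
    if (length(loads) >= 2) {
      a <- aggregation_index(loads)
      c(a$mean, a$se, a$variance, a$vmr)
    } else if (length(loads) == 1) c(loads, NA, NA, NA)
    else rep(NA_real_, 4)
  }, numeric(4)))
  prev$mean_load <- agg[, 1]
  prev$se_load <- agg[, 2]
  prev$variance <- agg[, 3]
  prev$vmr <- agg[, 4]
  prev
}
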