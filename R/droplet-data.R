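#' Droplet-level data for one ddPCR well
#'
#' Holds the raw fluorescence amplitudes of one reaction together with its
#' identifiers. Amplitudes are in the reader's arbitrary fluorescence units.
#'
#' @param well_id Well identifier (e.g. `"A01"`).
#' @param amplitudes Numeric vector of droplet fluorescence amplitudes; must
#'   be non-empty and finite.
#' @param sample_id Sample identifier.
#' @param cartridge_id Droplet-generation batch identifier.
#' @param dilution_fold Relative quantity of the template (1 = undiluted),
#'   or `NA`.
#' @return An object of class `droplet_well`.
#' @export
droplet_well <- function(well_id, amplitudes, sample_id = well_id,
                         cartridge_id = NA_character_,
                         dilution_fold = NA_real_) {
  if (length(amplitudes) == 0L)
    stop("droplet_well: 'amplitudes' must be non-empty", call. = FALSE)
  amplitudes <- as.numeric(amplitudes)
  if (any(!is.finite(amplitudes)))
    stop("droplet_well: all amplitudes must be finite", call. = FALSE)
  if (!is.na(dilution_fold) && dilution_fold <= 0)
    stop("droplet_well: 'dilution_fold' must be positive", call. = FALSE)
  structure(
    list(well_id = as.character(well_id), sample_id = as.character(sample_id),
         cartridge_id = as.character(cartridge_id),
         dilution_fold = as.numeric(dilution_fold), amplitudes = amplitudes),
    class = "droplet_well"
  )
}

#' @export
print.droplet_well <- function(x, ...) {
  cat(sprintf("<droplet_well %s> sample %s, %d droplets, amplitude range [%g, %g]\n",
              x$well_id, x$sample_id, length(x$amplitudes),
              min(x$amplitudes), max(x$amplitudes)))
  invisible(x)
}

#' Positive/total droplet counts for one well
#'
#' @param well_id Well identifier.
#' @param n Total accepted droplets (non-negative integer).
#' @param k Positive droplets, `0 <= k <= n`.
#' @return An object of class `well_counts`: a one-row data.frame with
#'   columns `well_id`, `n`, `k`.
#' @export
well_counts <- function(well_id, n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (is.na(n) || is.na(k) || n < 0L || k < 0L)
    stop("well_counts: 'n' and 'k' must be non-negative integers",
         call. = FALSE)
  if (k > n)
    stop(sprintf("well_counts: k (%d) exceeds n (%d) for well '%s'",
                 k, n, well_id), call. = FALSE)
  structure(data.frame(well_id = as.character(well_id), n = n, k = k,
                       stringsAsFactors = FALSE),
            class = c("well_counts", "data.frame"))
}

validate_counts_df <- function(df, context = "well counts") {
  req <- c("well_id", "n", "k")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", context,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (anyNA(df$n) || anyNA(df$k))
    stop(sprintf("%s: 'n' and 'k' must be numeric and non-missing", context),
         call. = FALSE)
  if (any(df$n < 0) || any(df$k < 0))
    stop(sprintf("%s: negative counts are invalid", context), call. = FALSE)
  bad <- which(df$k > df$n)
  if (length(bad))
    stop(sprintf("%s: k > n in row(s) %s", context,
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(df$well_id))
    stop(sprintf("%s: duplicated well_id within one file", context),
         call. = FALSE)
  df$n <- as.integer(round(df$n)); df$k <- as.integer(round(df$k))
  df
}

# Printed tables carry thousands separators ("14,522"); accept them on read.
parse_count <- function(x) {
  as.numeric(gsub(",", "", trimws(as.character(x)), fixed = TRUE))
}

read_csv_strict <- function(path, required, context) {
  if (!file.exists(path))
    stop(sprintf("%s: file not found: %s", context, path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s in %s", context,
                 paste(miss, collapse = ", "), path), call. = FALSE)
  df
}

num_or_na <- function(x, col, context) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "na", "NaN")] <- NA_character_
  x <- gsub(",", "", x, fixed = TRUE)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("%s: non-numeric value '%s' in column '%s' at data row %d",
                 context, x[bad[1]], col, bad[1]), call. = FALSE)
  out
}

#' Read a droplet-level amplitude CSV
#'
#' Expects one row per droplet with header columns `well_id`, `sample_id`,
#' `cartridge_id`, `amplitude` and optionally `dilution_fold`. Returns one
#' [droplet_well()] per distinct `well_id`, amplitudes kept in file order.
#'
#' @param path Path to the CSV file.
#' @return A list of `droplet_well` objects (possibly empty).
#' @export
read_droplet_csv <- function(path) {
  df <- read_csv_strict(path, c("well_id", "sample_id", "cartridge_id",
                                "amplitude"), "read_droplet_csv")
  if (nrow(df) == 0L) return(list())
  amp <- num_or_na(df$amplitude, "amplitude", "read_droplet_csv")
  if (anyNA(amp))
    stop("read_droplet_csv: missing amplitude value", call. = FALSE)
  fold <- if ("dilution_fold" %in% names(df))
    num_or_na(df$dilution_fold, "dilution_fold", "read_droplet_csv")
  else rep(NA_real_, nrow(df))
  ids <- unique(df$well_id)
  lapply(ids, function(w) {
    i <- which(df$well_id == w)
    droplet_well(w, amp[i], sample_id = df$sample_id[i[1]],
                 cartridge_id = df$cartridge_id[i[1]],
                 dilution_fold = fold[i[1]])
  })
}

#' Read a well-count CSV
#'
#' Columns `well_id`, `n` (accepted droplets) and `k` (positive droplets);
#' any further columns (e.g. `dilution_fold`, `sample_id`) are carried
#' through. Thousands separators in counts are accepted.
#'
#' @param path Path to the CSV file.
#' @return A data.frame of class `well_counts`.
#' @export
read_well_counts_csv <- function(path) {
  df <- read_csv_strict(path, c("well_id", "n", "k"), "read_well_counts_csv")
  df$n <- num_or_na(df$n, "n", "read_well_counts_csv")
  df$k <- num_or_na(df$k, "k", "read_well_counts_csv")
  for (col in setdiff(names(df), c("well_id", "n", "k", "sample_id")))
    df[[col]] <- num_or_na(df[[col]], col, "read_well_counts_csv")
  df <- validate_counts_df(df, "read_well_counts_csv")
  class(df) <- c("well_counts", "data.frame")
  df
}

#' Write a well-count table
#'
#' Strict inverse of [read_well_counts_csv()]: plain integers, empty cells
#' for missing values.
#'
#' @param counts A `well_counts` data.frame.
#' @param path Output path.
#' @export
write_well_counts_csv <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE, na = "")
  invisible(path)
}

survey_numeric_cols <- c("length_um", "density_ind_m2", "organic_content_pct",
                         "dna_conc_ng_ul", "conc_copies_ul")

#' Read a host survey CSV
#'
#' One row per host with columns `host_id`, `population`, `month`,
#' `length_um`, `density_ind_m2`, `organic_content_pct`, `dna_conc_ng_ul`
#' (total-DNA concentration) and `conc_copies_ul` (measured reaction
#' concentration). Empty cells and `"NA"` mark missing covariates; they are
#' kept missing, never coerced to zero.
#'
#' @param path Path to the CSV file.
#' @return A data.frame of class `host_survey`.
#' @export
read_survey_csv <- function(path) {
  req <- c("host_id", "population", "month", survey_numeric_cols)
  df <- read_csv_strict(path, req, "read_survey_csv")
  for (col in survey_numeric_cols)
    df[[col]] <- num_or_na(df[[col]], col, "read_survey_csv")
  bad <- which(!is.na(df$dna_conc_ng_ul) & df$dna_conc_ng_ul <= 0)
  if (length(bad))
    stop(sprintf("read_survey_csv: dna_conc_ng_ul must be > 0 (row %d)",
                 bad[1]), call. = FALSE)
  if (any(!is.na(df$conc_copies_ul) & df$conc_copies_ul < 0))
    stop("read_survey_csv: conc_copies_ul must be >= 0", call. = FALSE)
  if (anyDuplicated(df$host_id))
    stop("read_survey_csv: duplicated host_id", call. = FALSE)
  class(df) <- c("host_survey", "data.frame")
  df
}

#' @rdname read_survey_csv
#' @param hosts A `host_survey` data.frame.
#' @param path Output path.
#' @export
write_survey_csv <- function(hosts, path) {
  utils::write.csv(as.data.frame(hosts), path, row.names = FALSE, na = "")
  invisible(path)
}
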