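# Shared fixture accessors and small builders used across the suite.

table4 <- function() read_well_counts_csv(ddquant_example("table4_dilution.csv"))
table3 <- function() utils::read.csv(ddquant_example("table3_wells.csv"),
                                     stringsAsFactors = FALSE)
table7 <- function() utils::read.csv(ddquant_example("table7_survey_summary.csv"),
                                     stringsAsFactors = FALSE)

# cartridge-1 / cartridge-2 concentration groups of the reproducibility table
cartridge_groups <- function() {
  t3 <- table3()
  list(x = t3$conc_copies_ul[t3$cartridge_id == 1],
       y = t3$conc_copies_ul[t3$cartridge_id == 2])
}

write_temp_csv <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, na = "", ...)
  path
}

# tiny survey table with a known infected/uninfected split
toy_survey <- function(n_inf, n_tot, population = "A", month = "March") {
  data.frame(
    host_id = sprintf("%s%03d", population, seq_len(n_tot)),
    population = population, month = month,
    length_um = 5000, density_ind_m2 = 1000, organic_content_pct = 1,
    dna_conc_ng_ul = 10,
    conc_copies_ul = c(rep(5, n_inf), rep(0, n_tot - n_inf)),
    stringsAsFactors = FALSE
  )
}
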