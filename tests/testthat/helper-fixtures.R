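# Small programmatic fixtures shared across test files.

make_meas <- function(specimen_id, well_id, treatment, analyte, time_h,
                      concentration, censor = "within") {
  tibble::tibble(
    specimen_id = specimen_id, well_id = well_id, treatment = treatment,
    analyte = analyte, time_h = time_h,
    concentration_pg_ml = concentration, censor = censor
  )
}

# Panel with limits so wide that censoring never bites; used when a test
# targets arithmetic rather than censoring.
wide_panel <- function(analytes = c("A", "B", "C")) {
  analyte_panel(analytes, lloq = 1e-9, uloq = 1e12)
}

# A three-time-point sequential well as one measurement table.
make_sequential_well <- function(conc, specimen = "S1", well = "S1_seq_r1",
                                 analyte = "A", times = c(4, 20, 48),
                                 censor = "within") {
  make_meas(specimen, well, "sequential", analyte, times, conc, censor)
}
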