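# Shared fixtures: tiny sample data frames built in code.

make_samples <- function(conc, sbgc = "01",
                         dwelling_id = NULL, supply_id = NULL,
                         below_lod = FALSE) {
  n <- length(conc)
  data.frame(
    dwelling_id = if (is.null(dwelling_id)) sprintf("d%03d", seq_len(n))
                  else dwelling_id,
    supply_id = if (is.null(supply_id)) sprintf("s%03d", seq_len(n))
                else supply_id,
    sbgc = rep_len(sbgc, n),
    arsenic_ugL = conc,
    below_lod = rep_len(below_lod, n),
    water_type = "drinking_water",
    treated = NA,
    stringsAsFactors = FALSE
  )
}

write_samples_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Published per-stratum model parameters, inlined for oracle arithmetic
# independent of the packaged JSON fixture.
table_params <- data.frame(
  sbgc = sprintf("%02d", 1:10),
  gm = c(0.885, 0.575, 0.086, 1.213, 0.622, 0.441, 0.175, 0.083, 0.665, 0.141),
  sigma_log = c(1.805, 1.214, 0.885, 2.542, 1.819, 1.577, 1.109, 1.040,
                2.024, 0.977),
  n = c(140L, 93L, 11L, 19L, 73L, 69L, 66L, 3L, 18L, 16L),
  stringsAsFactors = FALSE
)
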