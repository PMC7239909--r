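# regenerate the shipped synthetic fixture (text CSVs) from the master seed
devtools::load_all(".", quiet = TRUE)
st <- snowfinch_synthetic_study(seed = 2003)
utils::write.csv(st$records, "inst/extdata/snowfinch_synthetic_records.csv",
                 row.names = FALSE, quote = FALSE)
utils::write.csv(
  dplyr::mutate(st$covs, dplyr::across(!year, ~ round(.x, 6))),
  "inst/extdata/snowfinch_synthetic_covariates.csv",
  row.names = FALSE, quote = FALSE)
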