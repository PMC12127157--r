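# Published summary values shipped as small reference tables: the
# reagent-wise MFI group parameters (used as generator defaults) and the
# per-allele reporter-assay EC50 values.

#' Published per-type MFI parameters of the four Luminex reagents
#'
#' Mean and sample SD of the per-allele MFI of the 18 Type-I and 11
#' Type-II panel alleles for each reagent: the two allosera (S001, S002),
#' the discriminating monoclonal antibody 5.2G1, and the NKG2D-Ig fusion
#' protein. These are the default parameters of [simulate_mfi_panel()].
#'
#' @return A tibble: `reagent`, `mean_I`, `sd_I`, `mean_II`, `sd_II`.
#' @export
mica_mfi_params <- function() {
  tibble::tribble(
    ~reagent,   ~mean_I, ~sd_I,   ~mean_II, ~sd_II,
    "S001",     8380.48, 351.01,  680.64,   93.54,
    "S002",     307.89,  55.45,   7806.39,  498.21,
    "5.2G1",    1405.06, 223.11,  597.55,   73.54,
    "NKG2D-Ig", 1977.52, 446.00,  655.70,   175.68
  )
}

#' Published reporter-assay EC50 values of 11 MICA molecules
#'
#' The concentration (µg/mL) at which each molecule drives 50% of NKG2D
#' reporter cells GFP-positive, for six Type-I and five Type-II alleles.
#'
#' @return A tibble: `allele`, `type`, `ec50`.
#' @export
mica_ec50 <- function() {
  tibble::tribble(
    ~allele,     ~type,     ~ec50,
    "MICA*001",  "type_I",  26.35,
    "MICA*002",  "type_I",  21.96,
    "MICA*007",  "type_I",  25.16,
    "MICA*012",  "type_I",  28.61,
    "MICA*017",  "type_I",  21.55,
    "MICA*018",  "type_I",  26.04,
    "MICA*004",  "type_II", 39.54,
    "MICA*006",  "type_II", 38.67,
    "MICA*008",  "type_II", 41.84,
    "MICA*009",  "type_II", 34.84,
    "MICA*019",  "type_II", 43.49
  )
}
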