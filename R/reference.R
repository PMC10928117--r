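#' Published reference estimates of HWLE for England at age 50
#'
#' Point estimates, from a published national study of healthy working life
#' expectancy in England based on a 3-state multi-state model of ageing-survey
#' data, of the expected years from age 50 spent healthy and in work
#' (`hwle`), not healthy and/or not in work (`nonhw`), and their sum, life
#' expectancy (`le`), overall (`age_only`) and by the presence/absence of
#' single binary factors.  These printed values serve two purposes in the
#' package: arithmetic-consistency checks (the decomposition
#' `hwle + nonhw = le` must hold up to printed rounding, and differences
#' between groups reproduce the headline HWLE gaps) and calibration targets
#' for the synthetic-cohort scenario.  They are inputs, not outputs, of this
#' package.
#'
#' @return data.frame with columns `model`, `group`, `hwle`, `nonhw`, `le`
#'   (years).
#' @export
hwle_reference <- function() {
  read.csv(system.file("extdata", "england_hwle_reference.csv",
                       package = "hwle", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
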