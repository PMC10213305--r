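#' Packaged smoking/Alzheimer's worked-example datasets
#'
#' Returns the per-SNP exposure (cigarettes per day, CPD, from BioBank Japan)
#' and outcome (Alzheimer's disease case-control GWAS) summary statistics for
#' the two East Asian MR analyses shipped with the package: a Chinese cohort
#' (5 instruments) and a Japanese cohort (4 instruments, two of them LD
#' proxies: rs3825845 replaces rs13329271 and rs12151139 replaces
#' rs56129017). Exposure betas are per-allele effects on smoking quantity;
#' outcome betas are log-odds of AD.
#'
#' @param name `"chinese"` or `"japanese"`.
#' @return Named list with elements `exposure` and `outcome`, each an
#'   `mr_sumstats` tibble sharing the same SNPs in the same order.
#' @examples
#' fx <- mr_fixture("chinese")
#' fx$exposure
#' @export
mr_fixture <- function(name) {
  fixtures <- list(
    chinese = list(
      snp_id = c("rs78277894", "rs2435355", "rs79105258", "rs13329271",
                 "rs56129017"),
      effect_allele = c("A", "C", "A", "C", "T"),
      other_allele  = c("G", "T", "C", "A", "C"),
      eaf    = c(0.336, 0.195, 0.257, 0.516, 0.260),
      beta_x = c(0.040, -0.036, 0.055, -0.044, 0.131),
      se_x   = c(0.006, 0.007, 0.007, 0.005, 0.006),
      p_x    = c(5.63e-13, 3.62e-08, 4.76e-17, 2.71e-16, 2.18e-96),
      beta_y = c(0.080, 0.093, -0.104, -0.108, -0.122),
      se_y   = c(0.101, 0.096, 0.093, 0.084, 0.088),
      p_y    = c(0.428, 0.334, 0.262, 0.200, 0.164),
      outcome_label = "AD (Chinese cohort)"
    ),
    japanese = list(
      snp_id = c("rs78277894", "rs2435355", "rs3825845", "rs12151139"),
      effect_allele = c("A", "C", "T", "T"),
      other_allele  = c("G", "T", "C", "C"),
      eaf    = c(0.336, 0.195, 0.503, 0.256),
      beta_x = c(0.040, -0.036, -0.041, 0.122),
      se_x   = c(0.006, 0.007, 0.005, 0.006),
      p_x    = c(5.63e-13, 3.62e-08, 6.95e-15, 4.83e-92),
      beta_y = c(-0.007, -0.055, 0.007, 0.018),
      se_y   = c(0.035, 0.042, 0.033, 0.038),
      p_y    = c(0.845, 0.190, 0.842, 0.636),
      outcome_label = "AD (Japanese cohort)"
    )
  )
  if (!is.character(name) || length(name) != 1 || !name %in% names(fixtures)) {
    abort(paste0("unknown fixture '", paste(name, collapse = ","),
                 "'; valid fixtures: ",
                 paste(names(fixtures), collapse = ", ")),
          class = "mrkit_validation_error")
  }
  f <- fixtures[[name]]
  exposure <- summary_stats(
    tibble::tibble(snp_id = f$snp_id, effect_allele = f$effect_allele,
                   other_allele = f$other_allele, eaf = f$eaf,
                   beta = f$beta_x, se = f$se_x, pval = f$p_x,
                   n = 72655),
    trait_label = "CPD", trait_type = "quantitative")
  outcome <- summary_stats(
    tibble::tibble(snp_id = f$snp_id, effect_allele = f$effect_allele,
                   other_allele = f$other_allele, eaf = f$eaf,
                   beta = f$beta_y, se = f$se_y, pval = f$p_y),
    trait_label = f$outcome_label, trait_type = "binary")
  list(exposure = exposure, outcome = outcome)
}
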