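#' Simulation configuration for two-sample summary statistics
#'
#' Parameters of the standard two-sample generating model
#' `beta_x_j ~ N(gamma_j, se_xj^2)`,
#' `beta_y_j ~ N(theta * gamma_j + alpha_j, se_yj^2)`,
#' where `gamma_j` are true SNP-exposure effects, `theta` the causal effect
#' and `alpha_j` direct (pleiotropic) SNP-outcome effects. Defaults put the
#' simulated effects and sampling errors at the scale of the packaged
#' smoking/AD datasets: gamma magnitudes around 0.03-0.13, exposure SEs
#' 0.005-0.007 (a biobank-sized quantitative GWAS) and outcome SEs
#' 0.08-0.10 (a case-control GWAS of ~1,500 subjects).
#'
#' @param k Number of instruments.
#' @param theta True causal effect (log-odds of outcome per unit exposure).
#' @param gamma_mean,gamma_sd Mean and SD of the true exposure effects;
#'   draws are taken positive (orientation convention).
#' @param pleiotropy `"none"` (all `alpha_j = 0`), `"balanced"`
#'   (`alpha_j ~ N(0, alpha_sd)`), or `"directional"`
#'   (`alpha_j ~ N(alpha_mean, alpha_sd)`).
#' @param alpha_mean,alpha_sd Mean/SD of direct effects (used per
#'   `pleiotropy`).
#' @param inside_violation Correlation between `gamma_j` and `alpha_j`;
#'   0 (default) satisfies the InSIDE assumption.
#' @param se_x_range,se_y_range Ranges the per-SNP sampling SEs are drawn
#'   from (uniform).
#' @param eaf_range Range of effect-allele frequencies (uniform).
#' @param n_x,n_y Nominal sample sizes recorded in the output tables.
#' @return A validated list of class `mr_sim_config`.
#' @export
sim_config <- function(k = 10, theta = 0,
                       gamma_mean = 0.08, gamma_sd = 0.03,
                       pleiotropy = c("none", "balanced", "directional"),
                       alpha_mean = 0.05, alpha_sd = 0.02,
                       inside_violation = 0,
                       se_x_range = c(0.005, 0.007),
                       se_y_range = c(0.08, 0.10),
                       eaf_range = c(0.1, 0.9),
                       n_x = 72655, n_y = 1500) {
  pleiotropy <- match.arg(pleiotropy)
  check <- function(ok, field) {
    if (!ok) abort(paste0("invalid simulation config field: ", field),
                   class = "mrkit_validation_error")
  }
  check(is.numeric(k) && length(k) == 1 && k >= 1, "k")
  check(is.numeric(theta) && length(theta) == 1, "theta")
  check(gamma_sd >= 0, "gamma_sd")
  check(alpha_sd >= 0, "alpha_sd")
  check(inside_violation >= -1 && inside_violation <= 1, "inside_violation")
  check(length(se_x_range) == 2 && all(se_x_range >= 0) &&
          se_x_range[1] <= se_x_range[2], "se_x_range")
  check(length(se_y_range) == 2 && all(se_y_range >= 0) &&
          se_y_range[1] <= se_y_range[2], "se_y_range")
  check(length(eaf_range) == 2 && all(eaf_range > 0) &&
          all(eaf_range < 1) && eaf_range[1] <= eaf_range[2], "eaf_range")
  check(n_x >= 1, "n_x"); check(n_y >= 1, "n_y")
  structure(list(k = as.integer(k), theta = theta, gamma_mean = gamma_mean,
                 gamma_sd = gamma_sd, pleiotropy = pleiotropy,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 inside_violation = inside_violation,
                 se_x_range = se_x_range, se_y_range = se_y_range,
                 eaf_range = eaf_range, n_x = n_x, n_y = n_y),
            class = "mr_sim_config")
}

#' Generate synthetic two-sample GWAS summary statistics
#'
#' Draws exposure and outcome association tables under the two-sample MR
#' generating model of [sim_config()], together with the ground truth, so
#' estimator calibration and parameter recovery can be tested without any
#' external data. Alleles are assigned from non-palindromic pairs so
#' harmonization retains every SNP; both tables share ids, alleles and
#' EAFs. Fully reproducible by `seed`.
#'
#' @param config An [sim_config()].
#' @param seed Integer seed (required for reproducibility).
#' @return List with `exposure` and `outcome` (`mr_sumstats` tables) and
#'   `truth`, a tibble (`snp_id`, `gamma`, `alpha`, `is_outlier`) carrying
#'   `theta` as an attribute.
#' @examples
#' sim <- simulate_mr(sim_config(k = 5, theta = 0.3), seed = 1)
#' mr_ivw(harmonize(sim$exposure, sim$outcome))
#' @export
simulate_mr <- function(config = sim_config(), seed = 1) {
  if (!inherits(config, "mr_sim_config")) {
    abort("config must come from sim_config()",
          class = "mrkit_validation_error")
  }
  withr::with_seed(seed, simulate_mr_impl(config))
}

simulate_mr_impl <- function(config, outlier_idx = integer(),
                             outlier_shift = 0) {
  k <- config$k
  gamma <- abs(rnorm(k, config$gamma_mean, config$gamma_sd))
  gamma <- pmax(gamma, 1e-4)   # instruments must have non-null effects
  alpha <- switch(config$pleiotropy,
    none = rep(0, k),
    balanced = rnorm(k, 0, config$alpha_sd),
    directional = {
      z <- rnorm(k)
      rho <- config$inside_violation
      gs <- if (stats::sd(gamma) > 0) as.numeric(scale(gamma)) else rep(0, k)
      config$alpha_mean + config$alpha_sd * (rho * gs + sqrt(1 - rho^2) * z)
    })
  if (length(outlier_idx) > 0) alpha[outlier_idx] <- alpha[outlier_idx] +
    outlier_shift
  se_x <- runif(k, config$se_x_range[1], config$se_x_range[2])
  se_y <- runif(k, config$se_y_range[1], config$se_y_range[2])
  eaf <- runif(k, config$eaf_range[1], config$eaf_range[2])
  bx <- rnorm(k, gamma, se_x)
  by <- rnorm(k, config$theta * gamma + alpha, se_y)
  # non-palindromic allele pairs only, so strand is always resolvable
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  al <- pairs[sample.int(4, k, replace = TRUE)]
  ids <- sprintf("rs%07d", seq_len(k))
  se_x_pos <- pmax(se_x, .Machine$double.xmin)
  se_y_pos <- pmax(se_y, .Machine$double.xmin)
  exposure <- summary_stats(tibble::tibble(
    snp_id = ids,
    effect_allele = vapply(al, `[`, "", 1),
    other_allele = vapply(al, `[`, "", 2),
    eaf = eaf, beta = bx, se = se_x_pos,
    pval = pmax(2 * pnorm(-abs(bx / se_x_pos)), .Machine$double.xmin),
    n = config$n_x),
    trait_label = "simulated exposure", trait_type = "quantitative")
  outcome <- summary_stats(tibble::tibble(
    snp_id = ids,
    effect_allele = vapply(al, `[`, "", 1),
    other_allele = vapply(al, `[`, "", 2),
    eaf = eaf, beta = by, se = se_y_pos,
    pval = pmax(2 * pnorm(-abs(by / se_y_pos)), .Machine$double.xmin),
    n = config$n_y),
    trait_label = "simulated outcome", trait_type = "binary")
  truth <- tibble::tibble(snp_id = ids, gamma = gamma, alpha = alpha,
                          is_outlier = seq_len(k) %in% outlier_idx)
  attr(truth, "theta") <- config$theta
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Generate synthetic data with injected pleiotropic outliers
#'
#' As [simulate_mr()], but shifts the direct effect of `n_outliers`
#' randomly chosen SNPs by `outlier_shift`, marking them in the truth
#' record. With `n_outliers = 0` the output is identical to
#' [simulate_mr()] under the same seed.
#'
#' @inheritParams simulate_mr
#' @param n_outliers Number of SNPs to contaminate (must be `< k`).
#' @param outlier_shift Added to the chosen SNPs' direct effects.
#' @return As [simulate_mr()].
#' @export
simulate_mr_outliers <- function(config = sim_config(), n_outliers = 1,
                                 outlier_shift = 0.5, seed = 1) {
  if (!inherits(config, "mr_sim_config")) {
    abort("config must come from sim_config()",
          class = "mrkit_validation_error")
  }
  if (n_outliers >= config$k) {
    abort("n_outliers must be smaller than k",
          class = "mrkit_validation_error")
  }
  withr::with_seed(seed, {
    idx <- if (n_outliers > 0) sample.int(config$k, n_outliers) else integer()
    simulate_mr_impl(config, outlier_idx = idx, outlier_shift = outlier_shift)
  })
}
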