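#' Modified Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j * (ratio_j - beta_IVW)^2` over the per-SNP Wald ratios,
#' with an upper-tail chi-square p-value on `k - 1` degrees of freedom.
#' Excess heterogeneity among the per-SNP estimates signals pleiotropy or
#' otherwise invalid instruments. The default (`"first_order"`) weights are
#' the IVW weights `(beta_x / se_y)^2`; `"second_order"` additionally
#' propagates the exposure sampling error into the weights.
#'
#' @param set An `mr_harmonized` table with at least 2 SNPs.
#' @param weights Weighting variant; default `"first_order"`.
#' @return A list of class `mr_heterogeneity`: `q_stat`, `df`, `pval`.
#' @examples
#' fx <- mr_fixture("chinese")
#' cochran_q(harmonize(fx$exposure, fx$outcome))
#' @export
cochran_q <- function(set, weights = c("first_order", "second_order")) {
  weights <- match.arg(weights)
  set <- as_harmonized(set)
  k <- nrow(set)
  if (k < 2) abort("Q test needs >= 2 SNPs", class = "mrkit_estimator_error")
  wr <- wald_ratios(set)
  w <- if (weights == "first_order") wr$weight else
    1 / (set$se_y^2 / set$beta_x^2 +
           set$beta_y^2 * set$se_x^2 / set$beta_x^4)
  beta <- sum(w * wr$ratio) / sum(w)
  q <- sum(w * (wr$ratio - beta)^2)
  structure(list(q_stat = q, df = k - 1L,
                 pval = pchisq(q, k - 1, lower.tail = FALSE),
                 weights = weights),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3f (%s weights)\n",
              x$q_stat, x$df, x$pval, x$weights))
  invisible(x)
}

#' @method glance mr_heterogeneity
#' @export
glance.mr_heterogeneity <- function(x, ...) {
  tibble::tibble(q_stat = x$q_stat, df = x$df, pval = x$pval)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW effect with each SNP omitted in turn, appending the
#' full-set estimate. An omission is flagged "influential" when it moves
#' the point estimate across the null or
#' outside the full-set confidence interval — a package convention for the
#' usual qualitative check that no single variant drives the result.
#'
#' @param set An `mr_harmonized` table with at least 2 SNPs.
#' @param model IVW model for the reduced fits; a reduced set of one SNP
#'   degrades to that SNP's Wald ratio (fixed-effect) rather than erroring.
#' @return Tibble of class `mr_loo`: one row per omitted SNP plus a final
#'   `"(all)"` row, with `or`, `ci_low`, `ci_high`, `pval`, `influential`.
#' @export
leave_one_out <- function(set, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  set <- as_harmonized(set)
  k <- nrow(set)
  if (k < 2) abort("leave-one-out needs >= 2 SNPs",
                   class = "mrkit_estimator_error")
  fit_ivw <- function(s) {
    if (nrow(s) == 1) mr_ivw(s, model = "fixed") else mr_ivw(s, model = model)
  }
  full <- fit_ivw(set)
  rows <- purrr::map_dfr(seq_len(k), function(j) {
    fit <- fit_ivw(set[-j, , drop = FALSE])
    g <- glance(fit)
    g$method <- NULL
    dplyr::bind_cols(tibble::tibble(omitted = set$snp_id[j]), g)
  })
  rows$influential <-
    sign(rows$beta) != sign(full$beta) |           # omission crosses the null
    rows$beta < full$beta - Z95 * full$se |        # or exits the full-set CI
    rows$beta > full$beta + Z95 * full$se
  gfull <- glance(full); gfull$method <- NULL
  out <- dplyr::bind_rows(
    rows,
    dplyr::bind_cols(tibble::tibble(omitted = "(all)"), gfull,
                     tibble::tibble(influential = FALSE)))
  structure(out, class = c("mr_loo", class(tibble::tibble())))
}

# leave-one-out IVW point estimates from running totals (vector form)
loo_ivw_beta <- function(w, ratio) {
  (sum(w * ratio) - w * ratio) / (sum(w) - w)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Tests for horizontal pleiotropy via the leave-one-out weighted residual
#' sum of squares: `RSS = sum_j w_j * (beta_yj - b_(-j) * beta_xj)^2`,
#' where `b_(-j)` is the IVW estimate without SNP j and `w_j = 1 / se_yj^2`.
#' The null distribution is simulated parametrically: in each of `n_sim`
#' draws, `beta_x*_j ~ N(beta_xj, se_xj)` and
#' `beta_y*_j ~ N(b_(-j) * beta_xj, se_yj)`, and the RSS is recomputed with
#' the simulated leave-one-out estimates. The global p-value is
#' `(1 + #[RSS* >= RSS_obs]) / (n_sim + 1)`. Each SNP's observed residual
#' is compared with its own simulated residual distribution for the outlier
#' test (Bonferroni-adjusted across the k SNPs); when outliers are found, a
#' distortion test compares the full-set IVW estimate with the
#' outlier-removed one against a bootstrap distribution built from the
#' non-outlying SNPs.
#'
#' @param set An `mr_harmonized` table with at least 4 SNPs.
#' @param n_sim Number of null simulations (default 10000).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param outlier_significance Per-test level before Bonferroni adjustment
#'   by k (default 0.05).
#' @return A list of class `mr_presso`: `global_rss`, `global_pval`,
#'   `per_snp` (tibble `snp_id`, `rss`, `pval`, `outlier`), `outliers`,
#'   `distortion` (`NULL` when no outliers), `n_sim`, `seed`.
#' @examples
#' fx <- mr_fixture("chinese")
#' mr_presso(harmonize(fx$exposure, fx$outcome), n_sim = 1000, seed = 1)
#' @export
mr_presso <- function(set, n_sim = 10000, seed = NULL,
                      outlier_significance = 0.05) {
  set <- as_harmonized(set)
  k <- nrow(set)
  if (k < 4) abort("too few SNPs for MR-PRESSO (need >= 4)",
                   class = "mrkit_estimator_error")
  wr <- wald_ratios(set)
  loo <- loo_ivw_beta(wr$weight, wr$ratio)
  w <- 1 / set$se_y^2
  resid_obs <- w * (set$beta_y - loo * set$beta_x)^2
  rss_obs <- sum(resid_obs)

  simulate <- function() {
    bxs <- matrix(rnorm(n_sim * k, rep(set$beta_x, each = n_sim),
                        rep(set$se_x, each = n_sim)), n_sim, k)
    bys <- matrix(rnorm(n_sim * k, rep(loo * set$beta_x, each = n_sim),
                        rep(set$se_y, each = n_sim)), n_sim, k)
    ws <- sweep(bxs, 2, set$se_y, "/")^2
    rs <- bys / bxs
    swr <- rowSums(ws * rs)
    sw <- rowSums(ws)
    loos <- (swr - ws * rs) / (sw - ws)
    t(w * t((bys - loos * bxs)^2))   # n_sim x k simulated residuals
  }
  resid_sim <- if (is.null(seed)) simulate() else
    withr::with_seed(seed, simulate())
  rss_sim <- rowSums(resid_sim)
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  per_snp_pval <- vapply(seq_len(k), function(j) {
    (1 + sum(resid_sim[, j] >= resid_obs[j])) / (n_sim + 1)
  }, numeric(1))
  is_outlier <- per_snp_pval < outlier_significance / k
  per_snp <- tibble::tibble(snp_id = set$snp_id, rss = resid_obs,
                            pval = per_snp_pval, outlier = is_outlier)
  outliers <- set$snp_id[is_outlier]

  distortion <- NULL
  if (length(outliers) > 0 && sum(!is_outlier) >= 2) {
    distortion <- presso_distortion(set, is_outlier, n_sim, seed)
  }
  structure(list(global_rss = rss_obs, global_pval = global_pval,
                 per_snp = per_snp, outliers = outliers,
                 distortion = distortion, n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

# distortion of the causal estimate attributable to the flagged outliers:
# observed distortion vs a bootstrap of outlier-free subsets
presso_distortion <- function(set, is_outlier, n_sim, seed) {
  ivw_beta <- function(s) {
    wr <- wald_ratios(s)
    sum(wr$weight * wr$ratio) / sum(wr$weight)
  }
  beta_full <- ivw_beta(set)
  clean <- set[!is_outlier, , drop = FALSE]
  beta_clean <- ivw_beta(clean)
  d_obs <- beta_full - beta_clean
  boot <- function() {
    replicate(n_sim, {
      idx <- sample(nrow(clean), nrow(set), replace = TRUE)
      ivw_beta(clean[idx, , drop = FALSE]) - beta_clean
    })
  }
  d_sim <- if (is.null(seed)) boot() else withr::with_seed(seed + 1L, boot())
  list(beta_full = beta_full, beta_outlier_removed = beta_clean,
       distortion = d_obs,
       distortion_pct = 100 * d_obs / abs(beta_clean),
       pval = (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1))
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.3f, p = %.4g (n_sim = %d)\n",
              x$global_rss, x$global_pval, x$n_sim))
  if (length(x$outliers) > 0) {
    cat("Outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$distortion)) {
      cat(sprintf("Distortion: %.1f%% (p = %.3g)\n",
                  x$distortion$distortion_pct, x$distortion$pval))
    }
  } else {
    cat("No outlier SNPs detected\n")
  }
  invisible(x)
}

#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(global_rss = x$global_rss, global_pval = x$global_pval,
                 n_outliers = length(x$outliers), n_sim = x$n_sim)
}

#' Funnel-plot coordinates
#'
#' One point per SNP: the Wald ratio against its precision (the reciprocal
#' of the ratio standard error), with a vertical reference line at the
#' pooled IVW estimate. Asymmetry about the reference suggests directional
#' pleiotropy.
#'
#' @param set An `mr_harmonized` table.
#' @param model IVW model for the reference line.
#' @return Tibble of class `mr_funnel` (`snp_id`, `ratio`, `precision`)
#'   with the reference estimate in attribute `"reference"`.
#' @export
funnel_data <- function(set, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  set <- as_harmonized(set)
  wr <- wald_ratios(set)
  ref <- if (nrow(set) == 1) wr$ratio else mr_ivw(set, model = model)$beta
  structure(tibble::tibble(snp_id = wr$snp_id, ratio = wr$ratio,
                           precision = 1 / wr$se_ratio),
            reference = ref,
            class = c("mr_funnel", class(tibble::tibble())))
}

#' Forest-plot coordinates
#'
#' Per-SNP Wald ratio odds ratios with 95% confidence intervals, followed
#' by the pooled estimates of each method in `results`.
#'
#' @param set An `mr_harmonized` table.
#' @param results Optional tibble from [mr_all()] to append as summary rows.
#' @return Tibble of class `mr_forest` (`label`, `or`, `ci_low`, `ci_high`,
#'   `kind`).
#' @export
forest_data <- function(set, results = NULL) {
  set <- as_harmonized(set)
  wr <- wald_ratios(set)
  out <- tibble::tibble(
    label = wr$snp_id,
    or = exp(wr$ratio),
    ci_low = exp(wr$ratio - Z95 * wr$se_ratio),
    ci_high = exp(wr$ratio + Z95 * wr$se_ratio),
    kind = "snp")
  if (!is.null(results)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      label = results$method, or = results$or,
      ci_low = results$ci_low, ci_high = results$ci_high,
      kind = "summary"))
  }
  structure(out, class = c("mr_forest", class(tibble::tibble())))
}

#' Full sensitivity report
#'
#' Bundles the heterogeneity, leave-one-out, MR-PRESSO (when k >= 4) and
#' funnel/forest outputs for one harmonized set.
#'
#' @inheritParams mr_presso
#' @param results Optional [mr_all()] table for the forest summary rows.
#' @return Named list of class `mr_sensitivity`.
#' @export
sensitivity_report <- function(set, results = NULL, n_sim = 10000,
                               seed = NULL, outlier_significance = 0.05) {
  set <- as_harmonized(set)
  k <- nrow(set)
  structure(list(
    heterogeneity = if (k >= 2) cochran_q(set) else NULL,
    leave_one_out = if (k >= 2) leave_one_out(set) else NULL,
    presso = if (k >= 4) mr_presso(set, n_sim = n_sim, seed = seed,
                                   outlier_significance = outlier_significance)
             else NULL,
    funnel = funnel_data(set),
    forest = forest_data(set, results)
  ), class = "mr_sensitivity")
}
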