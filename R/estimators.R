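#' Per-SNP Wald ratio estimates
#'
#' The Wald ratio is the per-SNP causal estimate `beta_y / beta_x`, with the
#' first-order standard error `se_y / |beta_x|` (the exposure sampling error
#' is ignored, the standard approximation for strong instruments in
#' two-sample MR). The inverse-variance weight is `1 / se_ratio^2 =
#' (beta_x / se_y)^2`.
#'
#' @param set An `mr_harmonized` table (or compatible data frame).
#' @return Tibble with columns `snp_id`, `ratio`, `se_ratio`, `weight`.
#' @examples
#' fx <- mr_fixture("chinese")
#' wald_ratios(harmonize(fx$exposure, fx$outcome))
#' @export
wald_ratios <- function(set) {
  set <- as_harmonized(set)
  if (any(set$beta_x == 0)) {
    abort(paste0("null instrument (beta_x = 0): ",
                 paste(set$snp_id[set$beta_x == 0], collapse = ", ")),
          class = "mrkit_estimator_error")
  }
  tibble::tibble(
    snp_id = set$snp_id,
    ratio = set$beta_y / set$beta_x,
    se_ratio = set$se_y / abs(set$beta_x),
    weight = (set$beta_x / set$se_y)^2
  )
}

new_mr_result <- function(method, beta, se, pval, n_snp, extra = list()) {
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 or = exp(beta),
                 ci_low = exp(beta - Z95 * se),
                 ci_high = exp(beta + Z95 * se),
                 n_snp = n_snp, extra = extra),
            class = "mr_result")
}

#' Inverse-variance weighted (IVW) estimator
#'
#' Pools the per-SNP Wald ratios with inverse-variance weights
#' `w_j = (beta_xj / se_yj)^2`, equivalent to a zero-intercept weighted
#' regression of `beta_y` on `beta_x` with weights `1 / se_y^2`. The
#' fixed-effect standard error is `(sum w_j)^(-1/2)`; the multiplicative
#' random-effects model (the default) scales it by the residual dispersion
#' `sigma_hat = sqrt(Q / (k - 1))`, left unconstrained so it may also
#' shrink the SE when the instruments are less heterogeneous than chance
#' (`sigma_hat < 1`). Two-sided p-values come from the standard normal.
#'
#' @param set An `mr_harmonized` table.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An object of class `mr_result` with elements `beta`, `se`,
#'   `pval`, `or`, `ci_low`, `ci_high` (95% CI on the odds-ratio scale),
#'   `n_snp`, and `extra$sigma` (the residual scale; `NA` for fixed).
#'   Methods: [tidy()], [glance()], `print()`.
#' @examples
#' fx <- mr_fixture("chinese")
#' mr_ivw(harmonize(fx$exposure, fx$outcome))
#' @export
mr_ivw <- function(set, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  set <- as_harmonized(set)
  wr <- wald_ratios(set)
  k <- nrow(wr)
  if (k < 1) abort("need at least one SNP", class = "mrkit_estimator_error")
  if (model == "multiplicative_random" && k < 2) {
    abort("multiplicative random-effects IVW needs at least 2 SNPs",
          class = "mrkit_estimator_error")
  }
  beta <- sum(wr$weight * wr$ratio) / sum(wr$weight)
  se_fixed <- 1 / sqrt(sum(wr$weight))
  sigma <- NA_real_
  se <- se_fixed
  if (model == "multiplicative_random") {
    q <- sum(wr$weight * (wr$ratio - beta)^2)
    sigma <- sqrt(q / (k - 1))
    se <- se_fixed * sigma
  }
  pval <- 2 * pnorm(-abs(beta / se))
  new_mr_result("IVW", beta, se, pval, k,
                extra = list(model = model, sigma = sigma))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an unconstrained intercept (weights `1 / se_y^2`). The slope is a
#' causal estimate robust to directional pleiotropy under the InSIDE
#' assumption; a non-zero intercept indicates directional pleiotropy (the
#' Egger intercept test). The intercept is only identified once all
#' exposure effects point the same way, so the set is first passed through
#' [orient_positive_exposure()] (a no-op on already-oriented sets).
#' Standard errors carry the unconstrained multiplicative residual scale;
#' slope and intercept p-values are two-sided from the t-distribution with
#' `k - 2` degrees of freedom.
#'
#' @param set An `mr_harmonized` table with at least 3 SNPs.
#' @return An `mr_result` for the slope; `extra$intercept` holds the
#'   intercept block (`estimate`, `se`, `pval`) and `extra$sigma` the
#'   residual scale.
#' @examples
#' fx <- mr_fixture("chinese")
#' fit <- mr_egger(harmonize(fx$exposure, fx$outcome))
#' fit$extra$intercept
#' @export
mr_egger <- function(set) {
  set <- orient_positive_exposure(as_harmonized(set))
  k <- nrow(set)
  if (k < 3) {
    abort("insufficient instruments for Egger (need >= 3 SNPs)",
          class = "mrkit_estimator_error")
  }
  fit <- lm(beta_y ~ beta_x, data = set, weights = 1 / set$se_y^2)
  sm <- summary(fit)
  co <- coef(sm)   # SEs already scaled by sigma_hat; p from t(k - 2)
  res <- new_mr_result("MR-Egger", co["beta_x", 1], co["beta_x", 2],
                       co["beta_x", 4], k,
                       extra = list(
                         intercept = list(estimate = co["(Intercept)", 1],
                                          se = co["(Intercept)", 2],
                                          pval = co["(Intercept)", 4]),
                         sigma = sm$sigma))
  res
}

# interpolated weighted median of ratios at cumulative weight 0.5
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator (WME)
#'
#' Orders the per-SNP Wald ratios and interpolates them at cumulative
#' inverse-variance weight 0.5. The estimate is consistent as long as at
#' least half the total weight comes from valid instruments. The standard
#' error comes from a parametric bootstrap: effects are resampled from
#' normals centred on the observed `(beta_x, beta_y)` with SDs
#' `(se_x, se_y)`, the weighted median recomputed each time, and the SE
#' taken as the SD of the resampled estimates. Two-sided normal p-value.
#'
#' @param set An `mr_harmonized` table with at least 3 SNPs.
#' @param n_boot Number of bootstrap resamples (default 1000; fewer than
#'   100 triggers a warning).
#' @param seed Integer seed making the bootstrap reproducible; `NULL` uses
#'   the current RNG state.
#' @return An `mr_result`; `extra` records `n_boot` and `seed`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = NULL) {
  set <- as_harmonized(set)
  wr <- wald_ratios(set)
  k <- nrow(wr)
  if (k < 3) {
    abort("weighted median needs >= 3 SNPs", class = "mrkit_estimator_error")
  }
  if (n_boot < 100) {
    warn("n_boot < 100 gives an unstable bootstrap SE",
         class = "mrkit_small_bootstrap")
  }
  beta <- weighted_median_point(wr$ratio, wr$weight)
  boot_fun <- function() {
    replicate(n_boot, {
      bx <- rnorm(k, set$beta_x, set$se_x)
      by <- rnorm(k, set$beta_y, set$se_y)
      weighted_median_point(by / bx, (bx / set$se_y)^2)
    })
  }
  boots <- if (is.null(seed)) boot_fun() else
    withr::with_seed(seed, boot_fun())
  se <- sd(boots)
  pval <- 2 * pnorm(-abs(beta / se))
  new_mr_result("WME", beta, se, pval, k,
                extra = list(n_boot = n_boot, seed = seed))
}

#' Run the full estimator panel
#'
#' Convenience wrapper running IVW, MR-Egger and the weighted median on one
#' harmonized set and binding their [glance()] rows, the shape of a
#' standard MR results table.
#'
#' @inheritParams mr_weighted_median
#' @param ivw_model Passed to [mr_ivw()].
#' @return Tibble with one row per method: `method`, `beta`, `se`, `pval`,
#'   `or`, `ci_low`, `ci_high`, `n_snp`.
#' @examples
#' fx <- mr_fixture("chinese")
#' mr_all(harmonize(fx$exposure, fx$outcome), seed = 1)
#' @export
mr_all <- function(set, ivw_model = c("multiplicative_random", "fixed"),
                   n_boot = 1000, seed = NULL) {
  ivw_model <- match.arg(ivw_model)
  fits <- list(mr_ivw(set, model = ivw_model),
               mr_egger(set),
               mr_weighted_median(set, n_boot = n_boot, seed = seed))
  purrr::map_dfr(fits, glance)
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: OR %.3f (95%% CI %.3f-%.3f), p = %.3f, n SNP = %d\n",
              x$method, x$or, x$ci_low, x$ci_high, x$pval, x$n_snp))
  if (!is.null(x$extra$intercept)) {
    ic <- x$extra$intercept
    cat(sprintf("  intercept %.3f (se %.3f), p = %.3f\n",
                ic$estimate, ic$se, ic$pval))
  }
  invisible(x)
}

#' @rdname mr_ivw
#' @param x An `mr_result`.
#' @param ... Unused.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  out <- tibble::tibble(term = x$method, estimate = x$beta,
                        std.error = x$se, p.value = x$pval)
  if (!is.null(x$extra$intercept)) {
    ic <- x$extra$intercept
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "(Intercept)", estimate = ic$estimate,
      std.error = ic$se, p.value = ic$pval))
  }
  out
}

#' @rdname mr_ivw
#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(method = x$method, beta = x$beta, se = x$se, pval = x$pval,
                 or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_snp = x$n_snp)
}

#' Format an MR results table for display
#'
#' Renders the output of [mr_all()] in the conventional published layout:
#' `Method`, `OR (95% CI)`, `p`, `n SNP`, rounded to three decimals.
#'
#' @param results Tibble from [mr_all()] (or [glance()] rows).
#' @return Tibble of formatted character columns.
#' @export
format_mr_table <- function(results) {
  tibble::tibble(
    Method = results$method,
    `OR (95% CI)` = sprintf("%.3f (%.3f-%.3f)", results$or,
                            results$ci_low, results$ci_high),
    p = sprintf("%.3f", results$pval),
    `n SNP` = results$n_snp
  )
}
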