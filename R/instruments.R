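#' Instrument selection configuration
#'
#' Bundles the thresholds of the instrument-selection pipeline: genome-wide
#' significance for the exposure, the LD-clumping ceiling and window, the
#' minimum r-squared for proxy substitution, and the outcome-association
#' screen threshold.
#'
#' @param p_threshold Exposure genome-wide significance threshold (strict
#'   `<`); default `5e-8`.
#' @param clump_r2 r-squared above which two SNPs are considered in LD during
#'   clumping; default `0.001`.
#' @param clump_window_kb Window (kilobases) within which the r-squared
#'   constraint applies; SNPs further apart (or on different chromosomes)
#'   are treated as independent. Default `10000`; use `Inf` to apply the
#'   r-squared rule to all pairs regardless of position.
#' @param proxy_r2_floor Minimum r-squared for a proxy SNP; default `0.8`.
#' @param outcome_p_threshold Outcome-association screen threshold; default
#'   `5e-8`.
#' @param missing_ld_policy How to treat an unknown r-squared between two
#'   SNPs inside the window: `"conservative"` (default) assumes LD and
#'   removes the SNP; `"permissive"` assumes independence.
#' @return A list of class `mr_selection_config`.
#' @export
selection_config <- function(p_threshold = 5e-8,
                             clump_r2 = 0.001,
                             clump_window_kb = 10000,
                             proxy_r2_floor = 0.8,
                             outcome_p_threshold = 5e-8,
                             missing_ld_policy = c("conservative",
                                                   "permissive")) {
  missing_ld_policy <- match.arg(missing_ld_policy)
  stopifnot(p_threshold > 0, p_threshold <= 1,
            clump_r2 >= 0, clump_r2 <= 1,
            clump_window_kb > 0,
            proxy_r2_floor > 0, proxy_r2_floor <= 1,
            outcome_p_threshold > 0, outcome_p_threshold <= 1)
  if (clump_r2 >= proxy_r2_floor) {
    abort("clump_r2 must be below proxy_r2_floor",
          class = "mrkit_validation_error")
  }
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb,
                 proxy_r2_floor = proxy_r2_floor,
                 outcome_p_threshold = outcome_p_threshold,
                 missing_ld_policy = missing_ld_policy),
            class = "mr_selection_config")
}

#' Keep genome-wide significant SNPs
#'
#' Retains SNPs whose exposure p-value is strictly below the threshold,
#' preserving row order. Idempotent.
#'
#' @param stats An `mr_sumstats` table.
#' @param p_threshold Significance threshold (default `5e-8`).
#' @return The filtered `mr_sumstats` table (possibly empty).
#' @export
filter_significant <- function(stats, p_threshold = 5e-8) {
  keep <- stats$pval < p_threshold
  out <- stats[keep, , drop = FALSE]
  new_sumstats(out, attr(stats, "trait_label") %||% "trait",
               attr(stats, "trait_type") %||% "quantitative")
}

#' Greedy LD clumping
#'
#' Selects approximately independent index SNPs: repeatedly take the
#' remaining SNP with the smallest p-value, then remove every other
#' remaining SNP within `clump_window_kb` whose r-squared with it exceeds
#' `clump_r2`. Pairs outside the window (or on different chromosomes) are
#' treated as independent; an unknown r-squared inside the window is handled
#' per `missing_ld_policy`. Equal p-values are broken by smaller genomic
#' position, then lexicographic id, so the result does not depend on input
#' row order.
#'
#' @param stats An `mr_sumstats` table; must carry `chrom`/`pos` when a
#'   finite window is requested.
#' @param ld An `mr_ld` table of pairwise r-squared values.
#' @param config A [selection_config()].
#' @return The index SNPs as an `mr_sumstats` table, in selection order.
#' @export
clump_instruments <- function(stats, ld, config = selection_config()) {
  if (nrow(stats) == 0) return(stats)
  finite_window <- is.finite(config$clump_window_kb)
  if (finite_window && !all(c("chrom", "pos") %in% names(stats))) {
    abort(paste0("clumping with a finite window requires chrom/pos columns; ",
                 "set clump_window_kb = Inf to clump on r2 alone"),
          class = "mrkit_format_error")
  }
  pos <- if ("pos" %in% names(stats)) stats$pos else rep(0, nrow(stats))
  remaining <- seq_len(nrow(stats))
  picked <- integer()
  while (length(remaining) > 0) {
    ord <- order(stats$pval[remaining], pos[remaining],
                 stats$snp_id[remaining])
    idx <- remaining[ord[1]]
    picked <- c(picked, idx)
    remaining <- setdiff(remaining, idx)
    if (length(remaining) == 0) break
    in_window <- if (finite_window) {
      stats$chrom[remaining] == stats$chrom[idx] &
        abs(pos[remaining] - pos[idx]) <= config$clump_window_kb * 1000
    } else rep(TRUE, length(remaining))
    r2 <- ld_r2(ld, stats$snp_id[idx], stats$snp_id[remaining])
    linked <- ifelse(is.na(r2),
                     config$missing_ld_policy == "conservative",
                     r2 > config$clump_r2)
    remove <- in_window & linked
    remaining <- remaining[!remove]
  }
  out <- stats[picked, , drop = FALSE]
  new_sumstats(out, attr(stats, "trait_label") %||% "trait",
               attr(stats, "trait_type") %||% "quantitative")
}

#' Screen instruments for direct outcome association
#'
#' Drops candidate instruments that are themselves genome-wide associated
#' with the outcome in a prior GWAS (a direct association suggests the SNP
#' affects the outcome other than through the exposure).
#'
#' @param stats Candidate instruments (`mr_sumstats` for the exposure).
#' @param outcome Outcome `mr_sumstats`; SNPs absent from it are retained.
#' @param p_threshold Removal threshold (strict `<`); default `5e-8`.
#' @return The screened table, with the removals recorded in attribute
#'   `"exclusions"` (columns `snp_id`, `reason`, `detail`).
#' @export
screen_outcome_association <- function(stats, outcome, p_threshold = 5e-8) {
  p_out <- outcome$pval[match(stats$snp_id, outcome$snp_id)]
  drop <- !is.na(p_out) & p_out < p_threshold
  excl <- tibble::tibble(
    snp_id = stats$snp_id[drop],
    reason = "outcome_associated",
    detail = sprintf("outcome p = %.3g < %.3g", p_out[drop], p_threshold))
  out <- new_sumstats(stats[!drop, , drop = FALSE],
                      attr(stats, "trait_label") %||% "trait",
                      attr(stats, "trait_type") %||% "quantitative")
  attr(out, "exclusions") <- excl
  out
}

#' Screen instruments against confounder GWAS tables
#'
#' Removes instruments associated with any supplied confounder trait (e.g.
#' hypertension, type 2 diabetes, depression) below the threshold. The
#' confounder tables are user-supplied summary statistics; SNPs absent from
#' a table are unconstrained by it.
#'
#' @param stats Candidate instruments.
#' @param confounders Named list of `mr_sumstats` tables, one per confounder
#'   trait; names are used in the exclusion log.
#' @param p_threshold Removal threshold (strict `<`); default `5e-8`.
#' @return The screened table with attribute `"exclusions"` naming the
#'   confounder responsible for each removal.
#' @export
screen_confounders <- function(stats, confounders = list(),
                               p_threshold = 5e-8) {
  excl <- list()
  drop <- rep(FALSE, nrow(stats))
  if (length(confounders) > 0 && is.null(names(confounders))) {
    names(confounders) <- paste0("confounder_", seq_along(confounders))
  }
  for (nm in names(confounders)) {
    tab <- confounders[[nm]]
    p_conf <- tab$pval[match(stats$snp_id, tab$snp_id)]
    hit <- !is.na(p_conf) & p_conf < p_threshold & !drop
    if (any(hit)) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        snp_id = stats$snp_id[hit],
        reason = "confounder_associated",
        detail = sprintf("%s p = %.3g < %.3g", nm, p_conf[hit], p_threshold))
      drop <- drop | hit
    }
  }
  out <- new_sumstats(stats[!drop, , drop = FALSE],
                      attr(stats, "trait_label") %||% "trait",
                      attr(stats, "trait_type") %||% "quantitative")
  attr(out, "exclusions") <- if (length(excl) > 0) dplyr::bind_rows(excl) else
    tibble::tibble(snp_id = character(), reason = character(),
                   detail = character())
  out
}

#' Find proxy SNPs for instruments missing from the outcome dataset
#'
#' For each missing instrument, chooses the outcome-present SNP with the
#' highest r-squared at or above `proxy_r2_floor`. Ties are broken by the
#' smaller outcome p-value, then lexicographic id. Instruments with no
#' qualifying proxy are reported as unresolved (to be excluded).
#'
#' @param missing Character vector of instrument ids absent from the outcome.
#' @param outcome Outcome `mr_sumstats` providing the candidate proxies.
#' @param ld An `mr_ld` table covering the candidate pairs.
#' @param proxy_r2_floor Minimum acceptable r-squared; default `0.8`.
#' @return List with `proxies` (tibble `snp_id`, `proxy_id`, `r2`) and
#'   `unresolved` (character vector).
#' @export
substitute_proxies <- function(missing, outcome, ld, proxy_r2_floor = 0.8) {
  rows <- list()
  unresolved <- character()
  for (id in missing) {
    cand <- setdiff(outcome$snp_id, id)
    if (length(cand) == 0) {
      unresolved <- c(unresolved, id)
      next
    }
    r2 <- ld_r2(ld, id, cand)
    ok <- !is.na(r2) & r2 >= proxy_r2_floor
    if (!any(ok)) {
      unresolved <- c(unresolved, id)
      next
    }
    cand <- cand[ok]; r2 <- r2[ok]
    p_out <- outcome$pval[match(cand, outcome$snp_id)]
    best <- order(-r2, p_out, cand)[1]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      snp_id = id, proxy_id = cand[best], r2 = r2[best])
  }
  proxies <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(snp_id = character(), proxy_id = character(),
                   r2 = numeric())
  list(proxies = proxies, unresolved = unresolved)
}

#' Instrument strength: variance explained and F-statistic
#'
#' Per-SNP exposure variance explained is
#' `R2_j = 2 * EAF_j * (1 - EAF_j) * (beta_xj / SD)^2`, summed over the
#' instruments, and the F-statistic is
#' `F = ((N - k - 1) / k) * (R2 / (1 - R2))` with `k` instruments and
#' exposure sample size `N`. `F > 10` is the conventional guard against
#' weak-instrument bias.
#'
#' @param set An `mr_harmonized` table with non-missing `eaf`.
#' @param n Exposure GWAS sample size.
#' @param sd Exposure trait standard deviation in the units of `beta_x`;
#'   default `1` (betas assumed standardized). The published variance
#'   explained depends on this choice, so it is exposed rather than hidden.
#' @param r2_total Optionally override the summed variance explained (e.g.
#'   a value reported by the source GWAS) while still computing F from it.
#' @return A list of class `mr_strength`: `r2_total`, `f_stat`, `n`, `k`,
#'   `per_snp` (tibble `snp_id`, `r2`). See also [f_statistic()].
#' @examples
#' set <- harmonize(mr_fixture("chinese")$exposure, mr_fixture("chinese")$outcome)
#' instrument_strength(set, n = 72655, r2_total = 0.0036)
#' @export
instrument_strength <- function(set, n, sd = 1, r2_total = NULL) {
  k <- nrow(set)
  if (any(is.na(set$eaf))) {
    abort(paste0("eaf missing for SNP(s): ",
                 paste(set$snp_id[is.na(set$eaf)], collapse = ", ")),
          class = "mrkit_validation_error")
  }
  if (n <= k + 1) {
    abort("sample size n must exceed k + 1", class = "mrkit_validation_error")
  }
  if (sd <= 0) abort("sd must be positive", class = "mrkit_validation_error")
  per_snp <- 2 * set$eaf * (1 - set$eaf) * (set$beta_x / sd)^2
  total <- r2_total %||% sum(per_snp)
  structure(list(r2_total = total,
                 f_stat = f_statistic(total, n, k),
                 n = n, k = k,
                 per_snp = tibble::tibble(snp_id = set$snp_id, r2 = per_snp)),
            class = "mr_strength")
}

#' F-statistic from variance explained
#'
#' @param r2 Total exposure variance explained by the instruments.
#' @param n Exposure GWAS sample size.
#' @param k Number of instruments.
#' @return `((n - k - 1) / k) * (r2 / (1 - r2))`.
#' @export
f_statistic <- function(r2, n, k) {
  stopifnot(r2 >= 0, r2 < 1, k >= 1, n > k + 1)
  ((n - k - 1) / k) * (r2 / (1 - r2))
}

#' @export
print.mr_strength <- function(x, ...) {
  cat(sprintf("Instrument strength: k = %d, N = %d, R2 = %.4g, F = %.1f\n",
              x$k, x$n, x$r2_total, x$f_stat))
  invisible(x)
}

#' @method glance mr_strength
#' @export
glance.mr_strength <- function(x, ...) {
  tibble::tibble(r2_total = x$r2_total, f_stat = x$f_stat, n = x$n, k = x$k)
}
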