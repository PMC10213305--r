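#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome associations onto each SNP's exposure effect allele,
#' producing the paired-effect table every MR estimator consumes. For SNPs
#' present in both tables: if the outcome alleles are swapped relative to the
#' exposure, the outcome beta is sign-flipped and its EAF complemented; if
#' the alleles match only after strand complementation (A<->T, C<->G), the
#' outcome alleles are complemented first. Palindromic SNPs (allele pair A/T
#' or C/G), whose strand cannot be resolved from the alleles alone, are
#' handled per `palindrome_policy`. Every exclusion and flip is logged.
#'
#' @param exposure,outcome `mr_sumstats` tables (or compatible data frames).
#' @param palindrome_policy One of:
#'   * `"infer_by_eaf"` (default): use the effect-allele frequencies to match
#'     orientation, dropping SNPs whose EAF falls in the ambiguity band
#'     `[0.42, 0.58]` on either side (frequency cannot resolve the strand
#'     near 0.5);
#'   * `"drop"`: exclude all palindromic SNPs;
#'   * `"keep"`: align by allele letters, assuming both studies report the
#'     same strand.
#' @return A tibble of class `mr_harmonized` with columns `snp_id`,
#'   `beta_x`, `se_x`, `beta_y`, `se_y`, `eaf` (exposure EAF), `pval_x`,
#'   `pval_y`, `flipped` (audit flag), `proxy_for`. The exclusion log (one
#'   row per dropped SNP: `snp_id`, `reason`, `detail`) is available via
#'   [exclusion_log()].
#' @examples
#' fx <- mr_fixture("chinese")
#' harmonize(fx$exposure, fx$outcome)
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop", "keep")) {
  palindrome_policy <- match.arg(palindrome_policy)
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0) {
    abort("no shared SNPs between exposure and outcome",
          class = "mrkit_harmonize_error")
  }
  ex <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  excl <- list()
  drop_snp <- function(id, reason, detail = "") {
    excl[[length(excl) + 1L]] <<-
      tibble::tibble(snp_id = id, reason = reason, detail = detail)
  }

  rows <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    id <- shared[i]
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    beta_y <- ou$beta[i]
    eaf_y <- if ("eaf" %in% names(ou)) ou$eaf[i] else NA_real_
    eaf_x <- if ("eaf" %in% names(ex)) ex$eaf[i] else NA_real_
    flipped <- FALSE

    if (is_palindromic(ea_x, oa_x)) {
      if (palindrome_policy == "drop") {
        drop_snp(id, "palindromic", paste0(ea_x, "/", oa_x))
        next
      }
      if (palindrome_policy == "infer_by_eaf") {
        if (is.na(eaf_x) || is.na(eaf_y)) {
          drop_snp(id, "palindromic", "eaf missing, cannot infer strand")
          next
        }
        if (ambiguous_eaf(eaf_x) || ambiguous_eaf(eaf_y)) {
          drop_snp(id, "palindromic",
                   sprintf("eaf ambiguous (x=%.3f, y=%.3f)", eaf_x, eaf_y))
          next
        }
        # frequency resolves orientation: mismatched minor/major status
        # means the outcome effect allele is really the other allele
        if ((eaf_x < 0.5) != (eaf_y < 0.5)) {
          beta_y <- -beta_y
          eaf_y <- 1 - eaf_y
          flipped <- TRUE
        }
        rows[[i]] <- harmonized_row(ex, ou, i, beta_y, eaf_x, flipped)
        next
      }
      # policy "keep" falls through to letter matching
    }

    aligned <- align_alleles(ea_x, oa_x, ea_y, oa_y)
    if (is.na(aligned)) {
      drop_snp(id, "allele_mismatch",
               paste0("exposure ", ea_x, "/", oa_x,
                      " vs outcome ", ea_y, "/", oa_y))
      next
    }
    if (aligned == "swap") {
      beta_y <- -beta_y
      flipped <- TRUE
    }
    rows[[i]] <- harmonized_row(ex, ou, i, beta_y, eaf_x, flipped)
  }

  kept <- dplyr::bind_rows(rows)
  exclusions <- if (length(excl) > 0) dplyr::bind_rows(excl) else
    tibble::tibble(snp_id = character(), reason = character(),
                   detail = character())
  if (nrow(kept) == 0) {
    abort("no SNPs left after harmonization", class = "mrkit_harmonize_error")
  }
  new_harmonized(kept,
                 exposure_label = attr(exposure, "trait_label") %||% "exposure",
                 outcome_label = attr(outcome, "trait_label") %||% "outcome",
                 exclusions = exclusions)
}

harmonized_row <- function(ex, ou, i, beta_y, eaf, flipped) {
  tibble::tibble(
    snp_id = ex$snp_id[i],
    beta_x = ex$beta[i], se_x = ex$se[i],
    beta_y = beta_y, se_y = ou$se[i],
    eaf = eaf,
    pval_x = ex$pval[i], pval_y = ou$pval[i],
    flipped = flipped,
    proxy_for = NA_character_
  )
}

new_harmonized <- function(data, exposure_label, outcome_label, exclusions) {
  structure(tibble::as_tibble(data),
            exposure_label = exposure_label,
            outcome_label = outcome_label,
            exclusions = exclusions,
            class = c("mr_harmonized", class(tibble::tibble())))
}

is_palindromic <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

ambiguous_eaf <- function(eaf, band = c(0.42, 0.58)) {
  eaf >= band[1] & eaf <= band[2]
}

complement_allele <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}

# How do the outcome alleles relate to the exposure pair?
# "same", "swap", or NA when irreconcilable even after strand complementation.
align_alleles <- function(ea_x, oa_x, ea_y, oa_y) {
  if (ea_y == ea_x && oa_y == oa_x) return("same")
  if (ea_y == oa_x && oa_y == ea_x) return("swap")
  ea_yc <- unname(complement_allele(ea_y))
  oa_yc <- unname(complement_allele(oa_y))
  if (ea_yc == ea_x && oa_yc == oa_x) return("same")
  if (ea_yc == oa_x && oa_yc == ea_x) return("swap")
  NA_character_
}

#' Retrieve the exclusion log of a harmonized set
#'
#' @param x An `mr_harmonized` table.
#' @return Tibble with columns `snp_id`, `reason`, `detail`.
#' @export
exclusion_log <- function(x) {
  attr(x, "exclusions") %||%
    tibble::tibble(snp_id = character(), reason = character(),
                   detail = character())
}

#' Write an exclusion log as TSV
#'
#' @param x An `mr_harmonized` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(x, path) {
  readr::write_tsv(exclusion_log(x), path)
  invisible(path)
}

#' Orient a harmonized set to positive exposure effects
#'
#' Sign-flips both the exposure and outcome betas of every SNP whose
#' exposure effect is negative, so that all instruments point in the
#' exposure-increasing direction. Wald ratios are unchanged; MR-Egger's
#' intercept is only meaningful under this convention. SNPs with a null
#' exposure effect (`beta_x == 0`) cannot be oriented and are excluded with
#' reason `"null_instrument"`. Idempotent.
#'
#' @param set An `mr_harmonized` table.
#' @return The oriented `mr_harmonized` table.
#' @export
orient_positive_exposure <- function(set) {
  excl <- exclusion_log(set)
  null_ix <- which(set$beta_x == 0)
  if (length(null_ix) > 0) {
    excl <- dplyr::bind_rows(excl, tibble::tibble(
      snp_id = set$snp_id[null_ix], reason = "null_instrument",
      detail = "beta_x = 0 cannot be oriented"))
    set <- set[-null_ix, , drop = FALSE]
  }
  if (nrow(set) == 0) {
    abort("no SNPs left after removing null instruments",
          class = "mrkit_harmonize_error")
  }
  neg <- set$beta_x < 0
  set$beta_y[neg] <- -set$beta_y[neg]
  set$beta_x[neg] <- -set$beta_x[neg]
  new_harmonized(set,
                 exposure_label = attr(set, "exposure_label"),
                 outcome_label = attr(set, "outcome_label"),
                 exclusions = excl)
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("# Harmonized MR set: %s -> %s, %d SNP(s), %d excluded\n",
              attr(x, "exposure_label") %||% "exposure",
              attr(x, "outcome_label") %||% "outcome",
              nrow(x), nrow(exclusion_log(x))))
  NextMethod()
}

as_harmonized <- function(data, exposure_label = "exposure",
                          outcome_label = "outcome") {
  if (inherits(data, "mr_harmonized")) return(data)
  required <- c("snp_id", "beta_x", "se_x", "beta_y", "se_y")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("not a harmonized set; missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mrkit_format_error")
  }
  if (any(data$se_x <= 0) || any(data$se_y <= 0)) {
    abort("standard errors must be positive", class = "mrkit_validation_error")
  }
  new_harmonized(tibble::as_tibble(data), exposure_label, outcome_label,
                 exclusions = tibble::tibble(snp_id = character(),
                                             reason = character(),
                                             detail = character()))
}
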