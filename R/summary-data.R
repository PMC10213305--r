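#' Construct a GWAS summary-statistics table
#'
#' Builds a validated per-SNP association table, the basic currency of
#' two-sample Mendelian randomization: one row per variant with its effect
#' allele (EA), other allele, effect-allele frequency (EAF), effect size
#' `beta` (log-odds for binary traits, trait units for quantitative traits),
#' standard error and p-value.
#'
#' @param data Data frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, and optionally `n`,
#'   `chrom`, `pos`.
#' @param trait_label Short label for the trait (e.g. `"CPD"`).
#' @param trait_type `"quantitative"` or `"binary"`; binary traits carry
#'   log-odds betas.
#' @return A tibble of class `mr_sumstats` with attributes `trait_label` and
#'   `trait_type`. Row order is preserved.
#' @examples
#' summary_stats(
#'   tibble::tibble(
#'     snp_id = "rs1", effect_allele = "A", other_allele = "G",
#'     eaf = 0.3, beta = 0.04, se = 0.006, pval = 1e-12
#'   ),
#'   trait_label = "CPD", trait_type = "quantitative"
#' )
#' @export
summary_stats <- function(data, trait_label = "trait",
                          trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mrkit_format_error")
  }
  out <- tibble::as_tibble(data)
  if (!"eaf" %in% names(out)) out$eaf <- NA_real_
  problems <- validate_summary_stats(out)
  if (nrow(problems) > 0) {
    abort(paste0("invalid summary statistics:\n",
                 paste0("  row ", problems$row, " (", problems$snp_id, "): ",
                        problems$problem, collapse = "\n")),
          class = "mrkit_validation_error")
  }
  dups <- unique(out$snp_id[duplicated(out$snp_id)])
  if (length(dups) > 0) {
    abort(paste0("duplicate snp_id: ", paste(dups, collapse = ", ")),
          class = "mrkit_validation_error")
  }
  new_sumstats(out, trait_label, trait_type)
}

new_sumstats <- function(data, trait_label, trait_type) {
  structure(tibble::as_tibble(data),
            trait_label = trait_label,
            trait_type = trait_type,
            class = c("mr_sumstats", class(tibble::tibble())))
}

#' Row-level validation of a summary-statistics table
#'
#' Checks each row against the invariants a usable MR input must satisfy:
#' ACGT alleles, effect allele distinct from the other allele, `se > 0`,
#' `eaf` strictly inside (0, 1) when present, and `pval` in (0, 1].
#'
#' @param data Data frame with summary-statistic columns (see
#'   [summary_stats()]).
#' @return A tibble with one row per problem: `row` (1-based data row),
#'   `snp_id`, and `problem`. Zero rows means the table is valid.
#' @export
validate_summary_stats <- function(data) {
  probs <- list()
  note <- function(rows, msg) {
    if (any(rows, na.rm = TRUE)) {
      idx <- which(rows)
      probs[[length(probs) + 1L]] <<-
        tibble::tibble(row = idx, snp_id = as.character(data$snp_id[idx]),
                       problem = msg)
    }
  }
  acgt <- c("A", "C", "G", "T")
  note(is.na(data$snp_id) | data$snp_id == "", "missing snp_id")
  note(!(data$effect_allele %in% acgt), "effect_allele not one of A/C/G/T")
  note(!(data$other_allele %in% acgt), "other_allele not one of A/C/G/T")
  note(data$effect_allele == data$other_allele,
       "effect_allele equals other_allele")
  note(is.na(data$beta), "missing beta")
  note(is.na(data$se) | data$se <= 0, "se must be > 0")
  note(is.na(data$pval) | data$pval <= 0 | data$pval > 1,
       "pval must be in (0, 1]")
  if ("eaf" %in% names(data)) {
    note(!is.na(data$eaf) & (data$eaf <= 0 | data$eaf >= 1),
         "eaf must be in (0, 1)")
  }
  if (length(probs) == 0) {
    return(tibble::tibble(row = integer(), snp_id = character(),
                          problem = character()))
  }
  dplyr::arrange(dplyr::bind_rows(probs), .data$row)
}

#' Default column mapping for summary-statistic files
#'
#' Maps the package's internal column names to the header names conventional
#' in GWAS summary-statistic files. Override individual entries in
#' [read_summary_stats()] for files with different headers.
#'
#' @return Named character vector `internal name -> file header`.
#' @export
default_column_map <- function() {
  c(snp_id = "SNP", effect_allele = "EA", other_allele = "NEA",
    eaf = "EAF", beta = "BETA", se = "SE", pval = "P", n = "N",
    chrom = "CHR", pos = "POS")
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-bearing TSV or CSV (delimiter auto-detected from the
#' header line), maps columns to the internal schema, and validates every
#' row. Rows violating the invariants are rejected with row-level
#' diagnostics; scientific-notation p-values (`5.63E-13`) are parsed
#' case-insensitively.
#'
#' @param path Path to the file.
#' @param column_map Named vector mapping internal names to file headers;
#'   defaults to [default_column_map()]. `eaf`, `n`, `chrom`, `pos` are
#'   optional in the file.
#' @param trait_label,trait_type Passed to [summary_stats()].
#' @param on_invalid `"drop"` (default) rejects offending rows with a
#'   warning citing their row numbers; `"error"` aborts instead.
#' @return An `mr_sumstats` tibble; rejected rows (if any) are attached as
#'   attribute `"rejected"` together with their diagnostics.
#' @export
read_summary_stats <- function(path, column_map = default_column_map(),
                               trait_label = "trait",
                               trait_type = c("quantitative", "binary"),
                               on_invalid = c("drop", "error")) {
  trait_type <- match.arg(trait_type)
  on_invalid <- match.arg(on_invalid)
  column_map <- utils::modifyList(as.list(default_column_map()),
                                  as.list(column_map))
  delim <- sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  required <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")
  for (nm in required) {
    if (!column_map[[nm]] %in% names(raw)) {
      abort(paste0("mapped column '", column_map[[nm]], "' (", nm,
                   ") not found in ", path),
            class = "mrkit_format_error")
    }
  }
  optional <- c("eaf", "n", "chrom", "pos")
  present <- c(required, optional[vapply(optional, function(nm)
    column_map[[nm]] %in% names(raw), logical(1))])
  out <- tibble::as_tibble(
    setNames(lapply(present, function(nm) raw[[column_map[[nm]]]]), present)
  )
  numcols <- intersect(c("eaf", "beta", "se", "pval", "n", "pos"), names(out))
  out[numcols] <- lapply(out[numcols], function(x) as.numeric(x))
  if (nrow(out) == 0) {
    return(new_sumstats(out, trait_label, trait_type))
  }
  dups <- unique(out$snp_id[duplicated(out$snp_id)])
  if (length(dups) > 0) {
    abort(paste0("duplicate snp_id in ", path, ": ",
                 paste(dups, collapse = ", ")),
          class = "mrkit_validation_error")
  }
  problems <- validate_summary_stats(out)
  if (nrow(problems) > 0) {
    msg <- paste0("  row ", problems$row, " (", problems$snp_id, "): ",
                  problems$problem, collapse = "\n")
    if (on_invalid == "error") {
      abort(paste0("invalid rows in ", path, ":\n", msg),
            class = "mrkit_validation_error")
    }
    warn(paste0("rejected ", length(unique(problems$row)), " invalid row(s) in ",
                path, ":\n", msg), class = "mrkit_rejected_rows")
    rejected <- out[unique(problems$row), , drop = FALSE]
    out <- out[-unique(problems$row), , drop = FALSE]
    res <- new_sumstats(out, trait_label, trait_type)
    attr(res, "rejected") <- list(rows = rejected, problems = problems)
    return(res)
  }
  new_sumstats(out, trait_label, trait_type)
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) {
    abort(paste0("empty file: ", path), class = "mrkit_format_error")
  }
  ntab <- lengths(regmatches(header, gregexpr("\t", header)))
  ncom <- lengths(regmatches(header, gregexpr(",", header)))
  if (ntab >= ncom) "\t" else ","
}

#' Write summary statistics to TSV
#'
#' Writes the standard header dialect read back by [read_summary_stats()]
#' (round-trip safe at full double precision).
#'
#' @param stats An `mr_sumstats` tibble or compatible data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  map <- default_column_map()
  keep <- intersect(names(map), names(stats))
  out <- setNames(stats[keep], map[keep])
  readr::write_tsv(tibble::as_tibble(out), path)
  invisible(path)
}

#' Read a pairwise LD table
#'
#' Reads a three-column delimited file (`SNP_A`, `SNP_B`, `R2`) into a
#' symmetric r-squared lookup, the format emitted by standard LD-calculation
#' tools. Absent pairs are "unknown" (`NA`), which is distinct from r2 = 0.
#'
#' @param path Path to the file.
#' @return A tibble of class `mr_ld` with columns `snp_a`, `snp_b`, `r2`.
#' @export
read_ld_table <- function(path) {
  delim <- sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = "ccd",
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 3) {
    abort("LD table must have three columns: SNP_A, SNP_B, R2",
          class = "mrkit_format_error")
  }
  out <- tibble::tibble(snp_a = raw[[1]], snp_b = raw[[2]], r2 = raw[[3]])
  ld_table(out)
}

#' Construct an LD reference from a data frame
#'
#' @param data Data frame with columns `snp_a`, `snp_b`, `r2` (r-squared in
#'   \[0, 1\]). The lookup is symmetric; each pair need only appear once.
#' @return A tibble of class `mr_ld`.
#' @export
ld_table <- function(data) {
  out <- tibble::as_tibble(data[c("snp_a", "snp_b", "r2")])
  bad <- which(is.na(out$r2) | out$r2 < 0 | out$r2 > 1)
  if (length(bad) > 0) {
    abort(paste0("r2 outside [0, 1] at row(s) ",
                 paste(bad, collapse = ", ")),
          class = "mrkit_validation_error")
  }
  structure(out, class = c("mr_ld", class(tibble::tibble())))
}

#' Symmetric LD lookup
#'
#' @param ld An `mr_ld` table.
#' @param a,b SNP identifiers (vectorized, recycled).
#' @return Numeric vector of r-squared values; `1` when `a == b`, `NA`
#'   ("unknown") for pairs absent from the table.
#' @export
ld_r2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  key <- paste(pmin(a, b), pmax(a, b))
  tab_key <- paste(pmin(ld$snp_a, ld$snp_b), pmax(ld$snp_a, ld$snp_b))
  out <- ld$r2[match(key, tab_key)]
  out[a == b] <- 1
  out
}

#' @export
print.mr_sumstats <- function(x, ...) {
  cat(sprintf("# GWAS summary statistics: %s (%s), %d SNP(s)\n",
              attr(x, "trait_label") %||% "trait",
              attr(x, "trait_type") %||% "quantitative", nrow(x)))
  NextMethod()
}
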