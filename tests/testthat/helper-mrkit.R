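# Shared builders for the test suite. Everything is constructed in code;
# no stored binary fixtures.

# minimal valid summary-stats tibble, overridable per test
make_stats <- function(n = 3, ids = sprintf("rs%d", seq_len(n)),
                       beta = seq(0.02, by = 0.01, length.out = n),
                       se = rep(0.005, n),
                       pval = rep(1e-10, n),
                       eaf = rep(0.3, n), ...) {
  summary_stats(tibble::tibble(
    snp_id = ids,
    effect_allele = rep("A", n), other_allele = rep("G", n),
    eaf = eaf, beta = beta, se = se, pval = pval, ...))
}

# harmonized set straight from paired effects
make_set <- function(beta_x, beta_y, se_x = rep(0.006, length(beta_x)),
                     se_y = rep(0.09, length(beta_x)),
                     eaf = rep(0.3, length(beta_x)),
                     ids = sprintf("rs%d", seq_along(beta_x))) {
  mrkit:::as_harmonized(tibble::tibble(
    snp_id = ids, beta_x = beta_x, se_x = se_x,
    beta_y = beta_y, se_y = se_y, eaf = eaf,
    flipped = FALSE, proxy_for = NA_character_))
}

# independent re-statement of the greedy clumping procedure, written as a
# naive repeated scan over data frames (oracle for clump_instruments)
oracle_clump <- function(df, ld_df, r2_max, window_kb, missing_policy) {
  picked <- character()
  pool <- df
  get_r2 <- function(a, b) {
    hit <- (ld_df$snp_a == a & ld_df$snp_b == b) |
      (ld_df$snp_a == b & ld_df$snp_b == a)
    if (any(hit)) ld_df$r2[which(hit)[1]] else NA_real_
  }
  while (nrow(pool) > 0) {
    pool <- pool[order(pool$pval, pool$pos, pool$snp_id), , drop = FALSE]
    index <- pool[1, ]
    picked <- c(picked, index$snp_id)
    pool <- pool[-1, , drop = FALSE]
    keep <- rep(TRUE, nrow(pool))
    for (i in seq_len(nrow(pool))) {
      same_window <- pool$chrom[i] == index$chrom &&
        abs(pool$pos[i] - index$pos) <= window_kb * 1000
      if (!same_window) next
      r2 <- get_r2(index$snp_id, pool$snp_id[i])
      if (is.na(r2)) {
        if (missing_policy == "conservative") keep[i] <- FALSE
      } else if (r2 > r2_max) {
        keep[i] <- FALSE
      }
    }
    pool <- pool[keep, , drop = FALSE]
  }
  picked
}

# write a sumstats tibble to a temp TSV and return the path
tmp_sumstats_file <- function(stats, dir = withr::local_tempdir(.local_envir =
                                                                  parent.frame())) {
  path <- file.path(dir, "stats.tsv")
  write_summary_stats(stats, path)
  path
}
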