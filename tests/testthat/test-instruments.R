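test_that("genome-wide significance filter uses a strict threshold and keeps order", {
  fx <- mr_fixture("chinese")$exposure
  expect_equal(filter_significant(fx, 5e-8)$snp_id, fx$snp_id)
  expect_equal(filter_significant(fx, 1e-16)$snp_id,
               c("rs79105258", "rs56129017"))
  expect_equal(nrow(filter_significant(fx, 1e-100)), 0)
  # strictness: a p exactly at the threshold is excluded
  at <- make_stats(1, pval = 5e-8)
  expect_equal(nrow(filter_significant(at, 5e-8)), 0)
  # idempotence
  once <- filter_significant(fx, 5e-8)
  expect_equal(tibble::as_tibble(filter_significant(once, 5e-8)),
               tibble::as_tibble(once))
})

test_that("greedy clumping keeps index SNPs per the documented procedure", {
  stats <- make_stats(3, pval = c(1e-10, 1e-9, 1e-8),
                      chrom = rep("1", 3), pos = c(100, 200, 300) * 1000)
  ld <- ld_table(tibble::tibble(
    snp_a = c("rs1", "rs1", "rs2"), snp_b = c("rs2", "rs3", "rs3"),
    r2 = c(0.5, 0.0, 0.0)))
  out <- clump_instruments(stats, ld)
  expect_equal(out$snp_id, c("rs1", "rs3"))

  # all independent: identity (selection order = p order)
  ld0 <- ld_table(tibble::tibble(
    snp_a = c("rs1", "rs1", "rs2"), snp_b = c("rs2", "rs3", "rs3"),
    r2 = c(0, 0, 0)))
  expect_setequal(clump_instruments(stats, ld0)$snp_id, stats$snp_id)

  # perfect LD: only the smaller-p SNP survives
  two <- make_stats(2, pval = c(1e-9, 1e-12), chrom = c("1", "1"),
                    pos = c(1e5, 2e5))
  ld1 <- ld_table(tibble::tibble(snp_a = "rs1", snp_b = "rs2", r2 = 1))
  expect_equal(clump_instruments(two, ld1)$snp_id, "rs2")

  # window: SNPs beyond the window are independent regardless of r2
  far <- make_stats(2, pval = c(1e-12, 1e-9), chrom = c("1", "1"),
                    pos = c(0, 2e7))  # 20,000 kb apart
  expect_equal(nrow(clump_instruments(far, ld1)), 2)

  # missing positions with a finite window is an error
  nopos <- make_stats(2, pval = c(1e-12, 1e-9))
  expect_error(clump_instruments(nopos, ld1), "chrom/pos",
               class = "mrkit_format_error")
  # ... but clumping on r2 alone works with an infinite window
  cfg <- selection_config(clump_window_kb = Inf)
  expect_equal(clump_instruments(nopos, ld1, cfg)$snp_id, "rs1")
})

test_that("unknown within-window r2 follows the missing-LD policy", {
  stats <- make_stats(2, pval = c(1e-12, 1e-9), chrom = c("1", "1"),
                      pos = c(1e5, 2e5))
  no_info <- ld_table(tibble::tibble(snp_a = character(),
                                     snp_b = character(), r2 = numeric()))
  cons <- clump_instruments(stats, no_info, selection_config())
  expect_equal(cons$snp_id, "rs1")
  perm <- clump_instruments(
    stats, no_info, selection_config(missing_ld_policy = "permissive"))
  expect_equal(nrow(perm), 2)
})

test_that("clumping is row-order invariant and matches a brute-force oracle", {
  cfg <- selection_config()
  for (case in 1:30) {
    withr::with_seed(1000 + case, {
      k <- sample(2:6, 1)
      df <- tibble::tibble(
        snp_id = sprintf("rs%d", sample(100, k)),
        effect_allele = "A", other_allele = "G", eaf = 0.3,
        beta = runif(k, 0.01, 0.1), se = 0.006,
        # draw p-values from few distinct values so ties occur
        pval = sample(c(1e-10, 1e-9, 1e-8), k, replace = TRUE),
        chrom = sample(c("1", "2"), k, replace = TRUE),
        pos = sample.int(2e7, k))
      pairs <- t(utils::combn(df$snp_id, 2))
      keep <- runif(nrow(pairs)) < 0.6   # some pairs unknown
      ld_df <- tibble::tibble(snp_a = pairs[keep, 1],
                              snp_b = pairs[keep, 2],
                              r2 = runif(sum(keep)))
      stats <- summary_stats(df)
      got <- clump_instruments(stats, ld_table(ld_df), cfg)$snp_id
      want <- oracle_clump(df, ld_df, cfg$clump_r2, cfg$clump_window_kb,
                           cfg$missing_ld_policy)
      expect_equal(got, want)
      # row-order invariance
      shuffled <- summary_stats(df[sample(nrow(df)), ])
      expect_equal(clump_instruments(shuffled, ld_table(ld_df), cfg)$snp_id,
                   want)
    })
  }
})

test_that("outcome-association screen removes only outcome-significant SNPs", {
  fx <- mr_fixture("chinese")
  kept <- screen_outcome_association(fx$exposure, fx$outcome)
  expect_equal(nrow(kept), 5)   # min outcome p = 0.164
  expect_equal(nrow(attr(kept, "exclusions")), 0)

  hot <- fx$outcome
  hot$pval[1] <- 1e-9
  kept2 <- screen_outcome_association(fx$exposure, hot)
  expect_equal(nrow(kept2), 4)
  expect_equal(attr(kept2, "exclusions")$snp_id, "rs78277894")
  # boundary: threshold 1 removes everything
  expect_equal(nrow(screen_outcome_association(fx$exposure, fx$outcome, 1)), 0)
})

test_that("confounder screen names the offending trait and passes absentees", {
  fx <- mr_fixture("chinese")$exposure
  expect_equal(nrow(screen_confounders(fx, list())), 5)
  htn <- make_stats(1, ids = "rs79105258", pval = 1e-12)
  kept <- screen_confounders(fx, list(hypertension = htn))
  expect_equal(nrow(kept), 4)
  excl <- attr(kept, "exclusions")
  expect_equal(excl$snp_id, "rs79105258")
  expect_match(excl$detail, "hypertension")
  # instrument absent from every confounder table is retained
  other <- make_stats(1, ids = "rs999", pval = 1e-12)
  expect_equal(nrow(screen_confounders(fx, list(obesity = other))), 5)
})

test_that("proxy substitution picks the best qualifying proxy deterministically", {
  fx <- mr_fixture("japanese")
  ld <- read_ld_table(system.file("extdata", "ld_proxies.tsv",
                                  package = "mrkit"))
  res <- substitute_proxies("rs13329271", fx$outcome, ld)
  expect_equal(res$proxies$proxy_id, "rs3825845")
  expect_equal(res$proxies$r2, 0.91)
  expect_equal(res$unresolved, character())

  # below the floor: unresolved
  weak <- ld_table(tibble::tibble(snp_a = "rsX", snp_b = "rs3825845",
                                  r2 = 0.5))
  expect_equal(substitute_proxies("rsX", fx$outcome, weak)$unresolved, "rsX")

  # tie on r2 broken by smaller outcome p
  outcome <- make_stats(2, ids = c("rsA", "rsB"), pval = c(0.1, 0.9))
  tie <- ld_table(tibble::tibble(snp_a = c("rsQ", "rsQ"),
                                 snp_b = c("rsA", "rsB"), r2 = c(0.9, 0.9)))
  expect_equal(substitute_proxies("rsQ", outcome, tie)$proxies$proxy_id, "rsA")
  # full tie broken lexicographically
  outcome2 <- make_stats(2, ids = c("rsB", "rsA"), pval = c(0.5, 0.5))
  expect_equal(substitute_proxies("rsQ", outcome2, tie)$proxies$proxy_id,
               "rsA")
})

test_that("variance explained and F follow the published formulas", {
  # single SNP: R2 = 2 * 0.26 * 0.74 * 0.131^2
  set <- make_set(beta_x = 0.131, beta_y = -0.122, eaf = 0.260)
  st <- instrument_strength(set, n = 72655)
  expect_equal(st$per_snp$r2, 2 * 0.26 * 0.74 * 0.131^2, tolerance = 1e-12)
  expect_equal(st$per_snp$r2, 0.006603, tolerance = 1e-4)

  # the study-scale computation: published R2 used as the input constant
  fx <- mr_fixture("chinese")
  h <- harmonize(fx$exposure, fx$outcome)
  st2 <- instrument_strength(h, n = 72655, r2_total = 0.0036)
  expect_equal(st2$k, 5)
  expect_equal(st2$f_stat, ((72655 - 5 - 1) / 5) * (0.0036 / 0.9964),
               tolerance = 1e-12)
  expect_equal(st2$f_stat, 52.5, tolerance = 0.01)
  expect_equal(f_statistic(0, 1000, 5), 0)

  # trait SD rescales the per-SNP contributions quadratically
  st_sd <- instrument_strength(h, n = 72655, sd = 2)
  st_1 <- instrument_strength(h, n = 72655, sd = 1)
  expect_equal(st_sd$r2_total, st_1$r2_total / 4, tolerance = 1e-12)

  # monotonicity of F in R2 and k
  expect_true(f_statistic(0.02, 1e4, 5) > f_statistic(0.01, 1e4, 5))
  expect_true(f_statistic(0.01, 1e4, 5) > f_statistic(0.01, 1e4, 10))

  # guard rails
  noeaf <- make_set(beta_x = 0.1, beta_y = 0.1)
  noeaf$eaf <- NA_real_
  expect_error(instrument_strength(noeaf, n = 1000), "rs1")
  expect_error(instrument_strength(set, n = 2), "exceed")
  expect_equal(glance(st2)$f_stat, st2$f_stat)
})
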