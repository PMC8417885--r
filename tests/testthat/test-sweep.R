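test_that("four-way classification follows the strict-threshold rule", {
  expect_equal(as.character(classify_assembly(0.975, 0.000, 0.05)),
               "MSN-only")
  expect_equal(as.character(classify_assembly(0.686, 0.996, 0.05)),
               "both")
  expect_equal(as.character(classify_assembly(0.000, 0.000, 0.05)),
               "neither")
  expect_equal(as.character(classify_assembly(0.04, 0.04, 0.05)),
               "neither")
  expect_equal(as.character(classify_assembly(0.04, 0.5, 0.05)),
               "NNH-only")
  # passing is strictly greater than the threshold
  expect_equal(as.character(classify_assembly(0.05, 0.5, 0.05)),
               "NNH-only")
  expect_error(classify_assembly(0.5, 0.5, 0), "P_t")
  expect_error(classify_assembly(1.5, 0.5, 0.05), "0, 1")
})

# build an mn_results table with engineered P-values
fake_results <- function(n_msn_only, n_nnh_only, n_both, n_neither,
                         group = "HEA-2") {
  n <- n_msn_only + n_nnh_only + n_both + n_neither
  P_M <- c(rep(0.9, n_msn_only), rep(0.01, n_nnh_only),
           rep(0.9, n_both), rep(0.01, n_neither))
  P_nnh <- c(rep(0.01, n_msn_only), rep(0.9, n_nnh_only),
             rep(0.9, n_both), rep(0.01, n_neither))
  collate_results(subject_id = sprintf("s%02d", seq_len(n)),
                  group = rep_len(group, n),
                  P_M = P_M, P_L = P_M, P_nnh = P_nnh,
                  local_P = replicate(n, runif(5), simplify = FALSE))
}

test_that("category table reproduces percentage arithmetic on known
           counts", {
  set.seed(1)
  res <- fake_results(54, 0, 23, 2)
  sw <- sweep_tables(res, thresholds = 0.05)
  ov <- sw$categories[sw$categories$group == "Overall", ]
  expect_equal(ov$n, 79L)
  expect_equal(c(ov$msn_only, ov$nnh_only, ov$both, ov$neither),
               c(54L, 0L, 23L, 2L))
  expect_equal(c(ov$msn_only_pct, ov$nnh_only_pct, ov$both_pct,
                 ov$neither_pct), c(68.4, 0.0, 29.1, 2.5))
})

test_that("passing sets are nested across rising thresholds", {
  set.seed(2)
  n <- 30
  res <- collate_results(sprintf("s%02d", 1:n),
                         rep(c("ABV", "HEA-2"), length.out = n),
                         P_M = runif(n), P_L = runif(n),
                         P_nnh = runif(n),
                         local_P = replicate(n, runif(8),
                                             simplify = FALSE))
  sw <- sweep_tables(res)
  ov <- sw$passing[sw$passing$group == "Overall", ]
  for (mod in c("MSN", "NNH")) {
    for (lev in c("metacommunity", "local")) {
      p <- ov$pct[ov$model == mod & ov$level == lev]
      expect_true(all(diff(p) <= 0))
    }
  }
  cats <- sw$categories[sw$categories$group == "Overall", ]
  expect_true(all(diff(cats$both_pct) <= 0))
  # counts always sum to n at every threshold
  expect_true(all(cats$msn_only + cats$nnh_only + cats$both +
                    cats$neither == n))
})

test_that("single subject and single threshold degenerate cleanly", {
  res <- fake_results(1, 0, 0, 0, group = "PREG")
  sw <- sweep_tables(res, thresholds = 0.05)
  ov <- sw$categories[sw$categories$group == "Overall", ]
  expect_equal(ov$msn_only_pct, 100)
  expect_equal(ov$n, 1L)
})

test_that("empty factor levels are dropped with a warning", {
  res <- fake_results(2, 0, 1, 0)
  res$group <- factor(res$group, levels = c("HEA-2", "PREG"))
  expect_warning(sweep_tables(res, 0.05), "PREG")
})

test_that("Fisher comparisons match hypergeometric enumeration and
           t-tests handle identical samples", {
  # perfectly separated 2x2: P = 2 / C(12,6)
  tab <- matrix(c(6, 0, 0, 6), 2, byrow = TRUE)
  expect_equal(fisher.test(tab)$p.value, 2 / choose(12, 6),
               tolerance = 1e-12)
  expect_equal(fisher_enum(tab), 2 / choose(12, 6), tolerance = 1e-12)

  # agreement with the enumeration oracle across small margins
  set.seed(3)
  for (r in 1:20) {
    tab <- matrix(rbinom(4, 7, 0.5), 2)
    expect_equal(fisher.test(tab)$p.value, fisher_enum(tab),
                 tolerance = 1e-9)
  }

  # identical pass proportions: Fisher P = 1
  res <- rbind(fake_results(3, 0, 0, 3, group = "ABV"),
               fake_results(3, 0, 0, 3, group = "SBV"))
  class(res) <- c("mn_results", "data.frame")
  cmp <- group_compare(res, thresholds = 0.05, merges = list())
  msn <- cmp[cmp$model == "MSN" & cmp$group1 == "ABV" &
               cmp$group2 == "SBV", ]
  expect_equal(msn$fisher_P, 1)
  # identical local-rate samples: t-test P = 1 (or NA on zero variance)
  expect_true(is.na(msn$t_P) || msn$t_P == 1)

  # merged labels appear in the comparison set, but never against their
  # own member groups
  res3 <- rbind(res, fake_results(2, 0, 2, 0, group = "HEA-1"))
  class(res3) <- c("mn_results", "data.frame")
  cmp2 <- group_compare(res3, thresholds = 0.05,
                        merges = list(BV = c("ABV", "SBV")))
  expect_true("BV" %in% c(cmp2$group1, cmp2$group2))
  expect_false(any(cmp2$group1 == "BV" & cmp2$group2 %in% c("ABV", "SBV")) ||
               any(cmp2$group2 == "BV" & cmp2$group1 %in% c("ABV", "SBV")))
})
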