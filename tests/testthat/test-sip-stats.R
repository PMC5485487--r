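test_that("odds ratio matches hand arithmetic and flags undefined tables", {
  expect_equal(odds_ratio(10, 100, 10, 100), 1.0)
  expect_equal(odds_ratio(20, 100, 10, 100), 2.25)  # (20/80)/(10/90)
  expect_true(is.na(odds_ratio(5, 5, 3, 10)))   # H_narc = 0
  expect_true(is.na(odds_ratio(3, 10, 0, 10)))  # L_arc = 0
  expect_equal(odds_ratio(0, 10, 3, 10), 0)     # zero numerator is defined
  expect_error(odds_ratio(5, 3, 1, 10), "exceed", class = "sip_validation_error")
  expect_error(odds_ratio(-1, 3, 1, 10), "negative", class = "sip_validation_error")
})

test_that("Haldane correction touches only zero-cell tables", {
  # fully populated table: exact Eq-style value regardless of correction
  expect_equal(odds_ratio(20, 100, 10, 100, correction = 0.5), 2.25)
  # zero light cell becomes defined under the correction
  expect_equal(odds_ratio(10, 20, 0, 30, correction = 0.5),
               (10.5 / 10.5) / (0.5 / 30.5))
  expect_true(is.na(odds_ratio(10, 20, 0, 30, correction = 0)))
})

test_that("odds ratio properties: depth invariance, monotonicity, symmetry", {
  sipcall:::with_seed(11, {
    for (i in 1:50) {
      h <- sample(1:50, 1); hn <- sample(1:50, 1)
      l <- sample(1:50, 1); ln <- sample(1:50, 1)
      or <- odds_ratio(h, h + hn, l, l + ln)
      k <- sample(2:9, 1)
      expect_equal(odds_ratio(k * h, k * (h + hn), k * l, k * (l + ln)), or)
      expect_equal(odds_ratio(l, l + ln, h, h + hn), 1 / or)
      expect_gt(odds_ratio(h + 1, h + hn + 1, l, l + ln), or)
    }
  })
})

test_that("eligibility is >= min_reads in both pools, taxon-level", {
  expect_true(eligible(5, 5))
  expect_false(eligible(4, 100))
  expect_false(eligible(0, 0))
  expect_equal(eligible(c(10, 3), c(2, 10), min_reads = 3),
               c(FALSE, TRUE))
})

test_that("RoOR divides the two ORs and propagates undefined members", {
  expect_equal(ratio_of_odds_ratios(2.25, 1.5), 1.5)
  expect_equal(ratio_of_odds_ratios(3.2, 3.2), 1.0)
  expect_true(is.na(ratio_of_odds_ratios(2.0, NA_real_)))
})

test_that("labeling analysis reproduces per-cell arithmetic on a fixture", {
  # 2 taxa, 2 13C bottles + control; numbers chosen so every OR is defined
  m <- matrix(c(30L, 70L,  10L, 90L,   # B13C_1 heavy | light
                25L, 75L,  12L, 88L,   # B13C_2
                10L, 90L,  10L, 90L),  # B12C_1
              nrow = 2)
  colnames(m) <- c("B13C_1|heavy", "B13C_1|light", "B13C_2|heavy",
                   "B13C_2|light", "B12C_1|heavy", "B12C_1|light")
  rownames(m) <- c("tA", "tB")
  pooled <- make_pooled(m)
  lab <- labeling_analysis(pooled, demo_design())
  expect_equal(nrow(lab), 4L)  # 2 taxa x 2 13C bottles
  r <- lab[lab$taxon == "tA" & lab$bottle_13c == "B13C_1", ]
  expect_equal(r$or_13c, (30 / 70) / (10 / 90))
  expect_equal(r$or_12c, 1.0)
  expect_equal(r$roor, (30 / 70) / (10 / 90))
  expect_true(r$labeled)
  # tB is depleted heavy in the 13C bottles: RoOR < 1, not labeled
  expect_false(any(lab$labeled[lab$taxon == "tB"]))
  expect_true(all(lab$labeled_all[lab$taxon == "tA"]))
  expect_false(any(lab$labeled_all[lab$taxon == "tB"]))
})

test_that("taxon-level scope reports low-count replicates as ineligible", {
  m <- matrix(c(4L, 96L, 100L, 100L,   # taxon t1: 4 heavy reads in B13C_1
                20L, 80L, 100L, 100L,
                10L, 90L, 100L, 100L),
              nrow = 2)
  colnames(m) <- c("B13C_1|heavy", "B13C_1|light", "B13C_2|heavy",
                   "B13C_2|light", "B12C_1|heavy", "B12C_1|light")
  rownames(m) <- c("t1", "t2")
  lab <- labeling_analysis(make_pooled(m), demo_design(), scope = "taxon")
  r1 <- lab[lab$taxon == "t1" & lab$bottle_13c == "B13C_1", ]
  expect_false(r1$eligible_13c)
  expect_true(is.na(r1$roor))          # ineligible, not a number
  r2 <- lab[lab$taxon == "t1" & lab$bottle_13c == "B13C_2", ]
  expect_false(is.na(r2$roor))         # the other replicate is eligible
  # labeled_all uses only replicates with defined RoOR
  expect_equal(unique(lab$labeled_all[lab$taxon == "t1"]), r2$labeled)
})

test_that("ties at the threshold are not labeled (strict inequality)", {
  m <- matrix(c(10L, 90L, 10L, 90L, 10L, 90L), nrow = 1)
  colnames(m) <- c("B13C_1|heavy", "B13C_1|light", "B13C_2|heavy",
                   "B13C_2|light", "B12C_1|heavy", "B12C_1|light")
  rownames(m) <- "t1"
  lab <- labeling_analysis(make_pooled(m), demo_design())
  expect_equal(lab$roor, c(1, 1))
  expect_false(any(lab$labeled))
})

test_that("design without pooled bottles and mismatches are caught", {
  m <- matrix(c(5L, 5L, 5L, 5L), nrow = 1,
              dimnames = list("t1", c("B13C_1|heavy", "B13C_1|light",
                                      "B12C_1|heavy", "B12C_1|light")))
  pooled <- make_pooled(m)
  d <- demo_design()  # mentions B13C_2, absent from pools
  expect_error(labeling_analysis(pooled, d), "B13C_2",
               class = "sip_validation_error")
})

test_that("permutation rate is ~0.5 on exchangeable null bottles", {
  ex <- simulate_experiment(default_scenario(seed = 3, n_labeled = 0))
  pr <- roor_permutation_rate(ex$pooled, ex$design)
  expect_gt(pr$n, 50)
  expect_gt(pr$rate, 0.3)
  expect_lt(pr$rate, 0.7)
})
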