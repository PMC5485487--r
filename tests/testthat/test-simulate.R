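quad_mass <- function(mean, sd, lo, hi) {
  stats::integrate(stats::dnorm, lo, hi, mean = mean, sd = sd,
                   rel.tol = 1e-12)$value
}

test_that("fraction composition matches a quadrature oracle", {
  sc <- sim_scenario(taxa = c("light_t", "heavy_t"),
                     base_abundance = c(0.5, 0.5),
                     density_mean = c(1.695, 1.731),
                     density_sd = 0.005,
                     fraction_edges = c(1.68, 1.72, 1.76))
  comp <- simulate_fraction_composition(sc, "12C")
  m1 <- 0.5 * quad_mass(1.695, 0.005, 1.72, 1.76)
  m2 <- 0.5 * quad_mass(1.731, 0.005, 1.72, 1.76)
  expect_equal(unname(comp["heavy_t", 2]), m2 / (m1 + m2), tolerance = 1e-9)
  expect_equal(unname(colSums(comp)), c(1, 1), tolerance = 1e-12)
})

test_that("zero labeling makes 13C and 12C compositions identical", {
  sc <- default_scenario(seed = 2, n_labeled = 0)
  expect_identical(simulate_fraction_composition(sc, "13C"),
                   simulate_fraction_composition(sc, "12C"))
})

test_that("a single taxon owns every non-empty fraction", {
  sc <- sim_scenario("only", 1, 1.70)
  comp <- simulate_fraction_composition(sc, "13C")
  empty <- attr(comp, "empty")
  expect_true(all(comp[1, !empty] == 1))
  expect_true(all(comp[1, empty] == 0))
})

test_that("labeling shifts mass monotonically into the heavy fractions", {
  # expected share of the taxon's DNA mass in the heavy zone: weight each
  # fraction's composition by its total DNA mass (the unpooled analogue of
  # the heavy pool's expected composition)
  heavy_share <- function(ae) {
    sc <- sim_scenario(c("a", "b"), c(0.3, 0.7), c(1.70, 1.705),
                       atom_excess = c(ae, 0))
    comp <- simulate_fraction_composition(sc, "13C")
    mids <- (sc$fraction_edges[-1] + sc$fraction_edges[-13]) / 2
    heavy <- classify_fraction(mids) == "heavy"
    mass <- attr(comp, "mass")
    sum(comp["a", heavy] * mass[heavy]) / sum(mass[heavy])
  }
  shares <- vapply(seq(0, 1, by = 0.25), heavy_share, 0)
  expect_false(is.unsorted(shares))
  expect_gt(shares[5], shares[1])
})

test_that("multinomial draws conserve depth and respect zero proportions", {
  comp <- matrix(c(0.3, 0.7, 0, 0.2, 0.8, 0), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("F1", "F2")))
  ct <- simulate_reads(comp, depth = 500, seed = 9)
  expect_equal(unname(colSums(ct)), c(500, 500))
  expect_equal(unname(unclass(ct)["c", ]), c(0L, 0L))
  expect_error(simulate_reads(comp * 1.5, 500, 9), "sums to",
               class = "sip_validation_error")
})

test_that("draw mean agrees with binomial moments over 200 seeded draws", {
  comp <- matrix(c(0.3, 0.7), 2, 1, dimnames = list(c("a", "b"), "F1"))
  counts <- vapply(1:200, function(s) {
    unclass(simulate_reads(comp, 10000, seed = s))["a", 1]
  }, 0L)
  se_mean <- sqrt(10000 * 0.3 * 0.7) / sqrt(200)
  expect_lt(abs(mean(counts) - 3000), 3 * se_mean)
})

test_that("identical scenario and seed reproduce byte-identical counts", {
  sc <- default_scenario(seed = 5, depth = 2000)
  e1 <- simulate_experiment(sc)
  e2 <- simulate_experiment(sc)
  expect_identical(e1$counts, e2$counts)
  # per-bottle sub-seeding: adding a replicate leaves earlier bottles alone
  sc3 <- default_scenario(seed = 5, depth = 2000, n_label_replicates = 3)
  e3 <- simulate_experiment(sc3)
  shared <- grep("^B13C_[12]_|^B12C_1_", colnames(e1$counts), value = TRUE)
  expect_identical(unclass(e1$counts)[, shared], unclass(e3$counts)[, shared])
})

test_that("experiment layout and ground truth follow the design arithmetic", {
  sc <- default_scenario(seed = 4, depth = 2000)
  ex <- simulate_experiment(sc)
  expect_equal(nrow(ex$design), 3L)          # 2 x 13C + 1 x 12C
  expect_equal(nrow(ex$pooled$pools), 6L)    # light + heavy per bottle
  expect_setequal(ex$truth, sc$taxa[sc$atom_excess > 0])
  expect_equal(length(ex$truth), 2L)
  expect_equal(nrow(ex$fractions), 3L * 12L)
  # fraction densities are bin midpoints inside the gradient span
  expect_true(all(ex$fractions$density > 1.68 & ex$fractions$density < 1.76))
})

test_that("cut-offs that exclude a pool class abort the experiment", {
  sc <- default_scenario(seed = 1, depth = 500)
  expect_error(simulate_experiment(sc, light_max = 1.60, heavy_min = 1.61),
               "classifies as light", class = "sip_undefined_error")
})

test_that("default-scenario recovery regression: both planted taxa called", {
  ex <- simulate_experiment(default_scenario(seed = 1))
  lab <- labeling_analysis(ex$pooled, ex$design)
  called_all <- unique(lab$taxon[lab$labeled_all])
  expect_setequal(intersect(called_all, ex$truth), ex$truth)
  # and per replicate, as observed on first verified execution
  for (b in unique(lab$bottle_13c)) {
    expect_true(all(lab$labeled[lab$taxon %in% ex$truth & lab$bottle_13c == b]))
  }
})

test_that("scenario invariants are enforced", {
  expect_error(sim_scenario(character(0), 1, 1.7), "empty",
               class = "sip_validation_error")
  expect_error(sim_scenario("a", 0.9, 1.7), "sum to 1",
               class = "sip_validation_error")
  expect_error(sim_scenario("a", 1, 1.7, fraction_edges = c(1.7, 1.7)),
               "increasing", class = "sip_validation_error")
  expect_error(sim_scenario("a", 1, 1.7, atom_excess = 1.2), "0, 1",
               class = "sip_validation_error")
})
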