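# Synthetic CsCl-gradient generator. The forward model: each taxon's DNA
# forms a Gaussian band along the buoyant-density axis (isopycnic band
# approximation) centered at its unlabeled density; assimilating a 13C
# substrate shifts the center by atom_excess * label_shift. Fractions are
# density bins; within a fraction, a taxon's expected read proportion is
# its base abundance weighted by the band mass falling in the bin,
# renormalized over taxa (amplicon sequencing sees composition, not
# absolute DNA amounts). Reads are multinomial draws at a fixed depth per
# fraction.

#' Construct a simulation scenario
#'
#' Bundles everything the synthetic-gradient generator needs. Invariants
#' are validated here: base abundances non-negative summing to 1 (1e-9),
#' strictly increasing fraction edges, atom excess in [0, 1].
#'
#' @param taxa character vector of taxon labels (unique).
#' @param base_abundance per-taxon relative abundance, summing to 1.
#' @param density_mean per-taxon unlabeled buoyant density, g/mL.
#' @param density_sd per-taxon band spread along the gradient, g/mL
#'   (recycled; default 0.005).
#' @param label_shift density increase at full 13C labeling, g/mL (default
#'   0.036, the literature-typical CsCl shift of fully 13C-labeled DNA).
#' @param atom_excess per-taxon labeling level in [0, 1] (recycled;
#'   0 = unlabeled). Always treated as 0 when simulating a 12C bottle.
#' @param fraction_edges ordered density bin edges, g/mL. The canonical
#'   gradient uses 13 edges spanning 1.68-1.76 g/mL (12 fractions,
#'   matching the 11-12 fractions collected from real gradients); smaller
#'   toy gradients are permitted for testing.
#' @param depth reads sequenced per fraction (multinomial size).
#' @param n_label_replicates number of 13C bottles (default 2; one 12C
#'   control bottle is always simulated).
#' @param seed RNG seed for the experiment; per-bottle streams are derived
#'   from it (see [simulate_experiment()]).
#' @return a validated `sim_scenario` list.
#' @export
sim_scenario <- function(taxa, base_abundance, density_mean,
                         density_sd = 0.005, label_shift = 0.036,
                         atom_excess = 0,
                         fraction_edges = seq(1.68, 1.76, length.out = 13L),
                         depth = 10000L, n_label_replicates = 2L, seed = 1L) {
  if (length(taxa) < 1L) sip_stop("empty taxon set")
  if (anyDuplicated(taxa)) sip_stop("duplicate taxon labels")
  nt <- length(taxa)
  if (length(base_abundance) != nt) sip_stop("base_abundance length mismatch")
  if (any(base_abundance < 0)) sip_stop("base_abundance must be non-negative")
  if (abs(sum(base_abundance) - 1) > 1e-9) {
    sip_stop("base_abundance must sum to 1 (within 1e-9)")
  }
  if (length(density_mean) != nt) sip_stop("density_mean length mismatch")
  density_sd <- rep_len(density_sd, nt)
  if (any(density_sd <= 0)) sip_stop("density_sd must be positive")
  atom_excess <- rep_len(atom_excess, nt)
  if (any(atom_excess < 0 | atom_excess > 1)) {
    sip_stop("atom_excess must lie in [0, 1]")
  }
  if (length(fraction_edges) < 2L || any(diff(fraction_edges) <= 0)) {
    sip_stop("fraction_edges must be strictly increasing (>= 2 edges)")
  }
  if (depth < 1) sip_stop("depth must be >= 1")
  if (n_label_replicates < 1) sip_stop("need at least one 13C replicate")
  structure(list(taxa = as.character(taxa),
                 base_abundance = as.numeric(base_abundance),
                 density_mean = as.numeric(density_mean),
                 density_sd = density_sd,
                 label_shift = label_shift,
                 atom_excess = atom_excess,
                 fraction_edges = as.numeric(fraction_edges),
                 depth = as.integer(depth),
                 n_label_replicates = as.integer(n_label_replicates),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Default labeled-community scenario
#'
#' The reference world used throughout the tests: `n_taxa` taxa at uniform
#' base abundance, unlabeled band centers drawn uniformly in
#' [1.69, 1.71] g/mL (so unlabeled DNA sits in the light zone and fully
#' labeled DNA reaches >= 1.72 g/mL), band sd 0.005 g/mL, and `n_labeled`
#' randomly chosen taxa at `atom_excess` (default fully labeled). The
#' scenario-level draws (band centers, labeled set) use their own stream
#' derived from `seed`.
#'
#' @param n_taxa number of taxa (default 20).
#' @param n_labeled number of labeled taxa (default 2).
#' @param atom_excess labeling level of the labeled taxa (default 1).
#' @param depth reads per fraction (default 10000).
#' @param n_label_replicates number of 13C bottles (default 2).
#' @param seed RNG seed.
#' @return a `sim_scenario`.
#' @export
default_scenario <- function(n_taxa = 20L, n_labeled = 2L, atom_excess = 1.0,
                             depth = 10000L, n_label_replicates = 2L,
                             seed = 1L) {
  if (n_labeled > n_taxa) sip_stop("n_labeled exceeds n_taxa")
  with_seed(seed, {
    means <- stats::runif(n_taxa, 1.69, 1.71)
    labeled <- sample.int(n_taxa, n_labeled)
    ae <- rep(0, n_taxa)
    ae[labeled] <- atom_excess
    sim_scenario(taxa = sprintf("T%02d", seq_len(n_taxa)),
                 base_abundance = rep(1 / n_taxa, n_taxa),
                 density_mean = means, atom_excess = ae,
                 depth = depth, n_label_replicates = n_label_replicates,
                 seed = seed)
  })
}

#' Expected per-fraction taxon composition of one bottle
#'
#' For each density bin, each taxon's proportion is its base abundance
#' times the Gaussian band mass falling in the bin (band center shifted by
#' `atom_excess * label_shift` in a 13C bottle), renormalized across taxa
#' within the bin. Bins whose total unnormalized mass is below 1e-12 are
#' flagged empty (attribute `empty`) and returned as all-zero columns.
#' The unnormalized per-bin total mass — the synthetic analogue of a
#' per-fraction DNA concentration curve — is attached as attribute `mass`.
#'
#' @param scenario a [sim_scenario()].
#' @param bottle_isotope `"13C"` or `"12C"`; in a 12C bottle every band
#'   sits at its unlabeled center regardless of `atom_excess`.
#' @return taxa x fractions matrix of proportions; non-empty columns sum
#'   to 1.
#' @export
simulate_fraction_composition <- function(scenario,
                                          bottle_isotope = c("13C", "12C")) {
  bottle_isotope <- match.arg(bottle_isotope)
  if (!inherits(scenario, "sim_scenario")) sip_stop("not a sim_scenario")
  edges <- scenario$fraction_edges
  nf <- length(edges) - 1L
  shift <- if (bottle_isotope == "13C") scenario$atom_excess * scenario$label_shift else 0
  centers <- scenario$density_mean + shift
  mass <- matrix(0, length(scenario$taxa), nf)
  for (f in seq_len(nf)) {
    mass[, f] <- scenario$base_abundance *
      (stats::pnorm(edges[f + 1L], centers, scenario$density_sd) -
         stats::pnorm(edges[f], centers, scenario$density_sd))
  }
  tot <- colSums(mass)
  empty <- tot < 1e-12
  prop <- mass
  prop[, !empty] <- sweep(mass[, !empty, drop = FALSE], 2L, tot[!empty], "/")
  prop[, empty] <- 0
  dimnames(prop) <- list(scenario$taxa, sprintf("F%d", seq_len(nf)))
  attr(prop, "empty") <- stats::setNames(empty, colnames(prop))
  attr(prop, "mass") <- stats::setNames(tot, colnames(prop))
  prop
}

#' Draw multinomial reads from a composition matrix
#'
#' One multinomial draw of size `depth` per fraction column; all-zero
#' (empty) columns yield all-zero counts. Identical inputs and seed give
#' byte-identical counts; the RNG stream is private to the call.
#'
#' @param composition taxa x fractions proportion matrix (columns sum to 1
#'   within 1e-6, or to 0 for empty fractions).
#' @param depth multinomial size (reads per fraction).
#' @param seed RNG seed.
#' @return a [count_table()].
#' @export
simulate_reads <- function(composition, depth, seed) {
  m <- unclass(composition)
  if (depth < 1) sip_stop("depth must be >= 1")
  cs <- colSums(m)
  bad <- abs(cs - 1) > 1e-6 & cs != 0
  if (any(bad)) {
    sip_stop(sprintf("composition column '%s' sums to %.8g, not 1",
                     colnames(m)[bad][1L], cs[bad][1L]))
  }
  counts <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  with_seed(seed, {
    for (f in seq_len(ncol(m))) {
      if (cs[f] == 0) next
      counts[, f] <- as.integer(stats::rmultinom(1L, size = depth,
                                                 prob = m[, f]))
    }
  })
  count_table(counts)
}

#' Simulate a full SIP experiment with known ground truth
#'
#' Emits `n_label_replicates` 13C bottles plus one 12C control bottle under
#' a shared experimental condition. For each bottle, fraction-level reads
#' are drawn at `depth` reads per non-empty fraction and then pooled into
#' one light and one heavy sample via [pool_fractions()], using the
#' density cut-offs applied to each fraction's midpoint density. Per-bottle
#' RNG streams are sub-seeded deterministically (13C replicate r uses
#' `seed + 1000*r`, the control uses `seed + 500`), so adding a replicate
#' does not perturb the other bottles' counts.
#'
#' @param scenario a [sim_scenario()].
#' @param light_max,heavy_min density cut-offs for pooling
#'   (see [classify_fraction()]).
#' @return a `sip_experiment` list: `counts` (fraction-level
#'   [count_table()], columns `<bottle>_F<k>`), `fractions` (metadata with
#'   midpoint densities and simulated DNA-concentration analogue),
#'   `design` (incubation manifest), `pooled` (a `pooled_counts`), `truth`
#'   (labels of taxa with `atom_excess > 0`) and the scenario itself.
#' @export
simulate_experiment <- function(scenario, light_max = 1.715, heavy_min = 1.72) {
  if (!inherits(scenario, "sim_scenario")) sip_stop("not a sim_scenario")
  edges <- scenario$fraction_edges
  nf <- length(edges) - 1L
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  cls <- classify_fraction(mids, light_max, heavy_min)
  for (pool in c("light", "heavy")) {
    if (!any(cls == pool)) {
      sip_undefined(sprintf(
        "no fraction classifies as %s under cut-offs (light < %.4g, heavy >= %.4g); RoOR undefined",
        pool, light_max, heavy_min))
    }
  }
  nrep <- scenario$n_label_replicates
  bottles <- c(sprintf("B13C_%d", seq_len(nrep)), "B12C_1")
  isotopes <- c(rep("13C", nrep), "12C")
  subseeds <- c(scenario$seed + 1000L * seq_len(nrep), scenario$seed + 500L)

  comp13 <- simulate_fraction_composition(scenario, "13C")
  comp12 <- simulate_fraction_composition(scenario, "12C")
  tabs <- vector("list", length(bottles))
  fracs <- vector("list", length(bottles))
  for (b in seq_along(bottles)) {
    comp <- if (isotopes[b] == "13C") comp13 else comp12
    tab <- simulate_reads(comp, scenario$depth, subseeds[b])
    colnames(tab) <- sprintf("%s_F%d", bottles[b], seq_len(nf))
    tabs[[b]] <- unclass(tab)
    fracs[[b]] <- data.frame(bottle_id = bottles[b],
                             fraction_index = seq_len(nf),
                             density = mids,
                             dna_conc = as.numeric(attr(comp, "mass")),
                             stringsAsFactors = FALSE)
  }
  counts <- count_table(do.call(cbind, tabs))
  fractions <- validate_fractions(do.call(rbind, fracs))
  design <- validate_design(data.frame(
    bottle_id = bottles, isotope = isotopes, substrate = "CO2-bicarbonate",
    replicate = c(seq_len(nrep), 1L), oxygen = "anoxic",
    source_well = "SIM", weeks = 4, stringsAsFactors = FALSE))
  pooled <- pool_fractions(counts, fractions,
                           light_max = light_max, heavy_min = heavy_min)
  structure(list(counts = counts, fractions = fractions, design = design,
                 pooled = pooled,
                 truth = scenario$taxa[scenario$atom_excess > 0],
                 scenario = scenario),
            class = "sip_experiment")
}

#' @export
print.sip_experiment <- function(x, ...) {
  cat(sprintf("sip_experiment: %d taxa, %d 13C + 1 12C bottles, %d fractions/bottle, depth %d\n",
              length(x$scenario$taxa), x$scenario$n_label_replicates,
              length(x$scenario$fraction_edges) - 1L, x$scenario$depth))
  cat(sprintf("ground-truth labeled taxa: %s\n",
              if (length(x$truth)) paste(x$truth, collapse = ", ") else "(none)"))
  invisible(x)
}
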