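# Fixture builders and independent oracles shared across test files.
# Oracles deliberately take their own computational route (direct
# arithmetic, quadrature, exhaustive search) rather than calling the code
# they check.

make_counts <- function(m, taxa = sprintf("T%02d", seq_len(nrow(m))),
                        samples = sprintf("S%d", seq_len(ncol(m)))) {
  dimnames(m) <- list(taxa, samples)
  count_table(m)
}

# four fractions of one bottle: two light, one intermediate, one heavy
demo_fractions <- function(bottle = "B1",
                           densities = c(1.69, 1.705, 1.717, 1.73)) {
  data.frame(bottle_id = bottle,
             fraction_index = seq_along(densities),
             density = densities,
             dna_conc = NA_real_,
             sample_id = sprintf("%s_F%d", bottle, seq_along(densities)),
             stringsAsFactors = FALSE)
}

demo_design <- function(bottles = c("B13C_1", "B13C_2", "B12C_1"),
                        isotopes = c("13C", "13C", "12C")) {
  data.frame(bottle_id = bottles, isotope = isotopes,
             substrate = "CO2-bicarbonate",
             replicate = ave(seq_along(bottles), isotopes, FUN = seq_along),
             oxygen = "anoxic", source_well = "W1", weeks = 4,
             stringsAsFactors = FALSE)
}

# hand-assembled pooled_counts (bypasses pool_fractions) for stats tests
make_pooled <- function(counts_by_pool) {
  ids <- colnames(counts_by_pool)
  parts <- strsplit(ids, "|", fixed = TRUE)
  pools <- data.frame(sample_id = ids,
                      bottle_id = vapply(parts, `[[`, "", 1L),
                      pool = vapply(parts, `[[`, "", 2L),
                      n_fractions = 1L, member_fractions = "1",
                      stringsAsFactors = FALSE)
  structure(list(counts = count_table(counts_by_pool), pools = pools,
                 excluded = setNames(rep(0L, nrow(counts_by_pool)),
                                     rownames(counts_by_pool))),
            class = "pooled_counts")
}

# direct-arithmetic odds-ratio reference (acceptance criterion oracle)
or_reference <- function(h, ht, l, lt) {
  hn <- ht - h
  ln <- lt - l
  if (hn == 0 || l == 0) return(NA_real_)
  (h / hn) / (l / ln)
}

# exhaustive minimum-variance agglomeration: cluster-pair merge costs are
# recomputed from the ORIGINAL squared distances via the centroid identity
# at every step (no Lance-Williams updates), all pairs evaluated, ties
# broken by lowest creation-order pair
ward_oracle <- function(D) {
  D2 <- unclass(D)^2
  n <- nrow(D2)
  members <- as.list(seq_len(n))
  code <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  cost <- function(A, B) {
    na <- length(A); nb <- length(B)
    cc <- sum(D2[A, B]) / (na * nb) -
      sum(D2[A, A]) / (2 * na^2) - sum(D2[B, B]) / (2 * nb^2)
    2 * na * nb / (na + nb) * cc
  }
  for (k in seq_len(n - 1L)) {
    m <- length(members)
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        co <- cost(members[[i]], members[[j]])
        if (co < best) { best <- co; bi <- i; bj <- j }
      }
    }
    height[k] <- sqrt(max(best, 0))
    merge[k, ] <- sort(c(code[bi], code[bj]))
    members <- c(members[-c(bi, bj)], list(c(members[[bi]], members[[bj]])))
    code <- c(code[-c(bi, bj)], k)
  }
  list(merge = merge, height = height)
}

# random abundance profile with n samples (taxa x n, columns sum to 100)
random_profile <- function(n_samples, n_taxa = 12L) {
  m <- matrix(rexp(n_taxa * n_samples), n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("S%d", seq_len(n_samples))))
  relative_abundance(make_counts(round(m * 500) + 1L))
}

# two planted blocks of samples with near-1 within-block correlation
two_block_profile <- function(n_taxa = 12L, per_block = 3L, noise = 0.02,
                              seed = 99L) {
  sipcall:::with_seed(seed, {
    uA <- c(rep(10, n_taxa / 2), rep(1, n_taxa / 2))
    uB <- rev(uA)
    cols <- cbind(
      sapply(seq_len(per_block), function(i) uA * exp(rnorm(n_taxa, 0, noise))),
      sapply(seq_len(per_block), function(i) uB * exp(rnorm(n_taxa, 0, noise))))
    colnames(cols) <- c(sprintf("A%d", seq_len(per_block)),
                        sprintf("B%d", seq_len(per_block)))
    rownames(cols) <- sprintf("t%02d", seq_len(n_taxa))
    structure(sweep(cols, 2, colSums(cols), "/") * 100,
              class = c("abundance_profile", "matrix", "array"))
  })
}

# test-side RoOR with the package's published rules (bottle-level filter,
# Haldane 0.5 on zero-cell tables), written as straight arithmetic
roor_direct <- function(h13, H13, l13, L13, h12, H12, l12, L12, corr = 0.5) {
  or1 <- function(h, ht, l, lt) {
    hn <- ht - h; ln <- lt - l
    if (h == 0 || hn == 0 || l == 0 || ln == 0) {
      h <- h + corr; hn <- hn + corr; l <- l + corr; ln <- ln + corr
    }
    if (hn == 0 || l == 0) return(NA_real_)
    (h / hn) / (l / ln)
  }
  a <- or1(h13, H13, l13, L13)
  b <- or1(h12, H12, l12, L12)
  if (is.na(a) || is.na(b)) NA_real_ else a / b
}
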