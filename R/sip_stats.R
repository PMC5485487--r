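#' Heavy-versus-light odds ratio for one taxon in one bottle
#'
#' The enrichment statistic of a two-pool DNA-SIP contrast. With `H_arc` the
#' taxon's reads in the heavy pool, `H_narc` the remaining heavy reads,
#' `L_arc` and `L_narc` the same for the light pool,
#' \deqn{OR = (H_{arc}/H_{narc}) / (L_{arc}/L_{narc}).}
#' An OR > 1 means the taxon is relatively more abundant in the heavy pool
#' than in the light pool of that bottle.
#'
#' The ratio is undefined (returned as `NA`) when `H_narc = 0` or
#' `L_arc = 0` and no continuity correction is applied; this is a property
#' of the data, distinct from invalid input (negative counts, taxon counts
#' exceeding totals), which is an error. The read-count eligibility filter
#' ([eligible()]) guarantees all four cells are positive, so `NA` never
#' occurs for eligible taxa under the canonical analysis.
#'
#' @param h_taxon,h_total taxon reads and total reads in the heavy pool.
#' @param l_taxon,l_total taxon reads and total reads in the light pool.
#' @param correction Haldane–Anscombe continuity correction: when a table
#'   contains at least one zero cell, `correction` is added to all four
#'   cells (tables without zeros are never touched, so defined ratios are
#'   exact). Off (`0`) by default here; [labeling_analysis()] enables it
#'   under the bottle-level filter, where zero cells can occur.
#' @return numeric vector of odds ratios (`NA` where undefined).
#' @examples
#' odds_ratio(20, 100, 10, 100)  # (20/80)/(10/90) = 2.25
#' @export
odds_ratio <- function(h_taxon, h_total, l_taxon, l_total, correction = 0) {
  n <- max(length(h_taxon), length(h_total), length(l_taxon), length(l_total))
  h_taxon <- rep_len(h_taxon, n); h_total <- rep_len(h_total, n)
  l_taxon <- rep_len(l_taxon, n); l_total <- rep_len(l_total, n)
  if (anyNA(c(h_taxon, h_total, l_taxon, l_total))) sip_stop("counts contain NA")
  if (any(c(h_taxon, l_taxon) < 0)) sip_stop("negative counts")
  if (any(h_total < h_taxon) || any(l_total < l_taxon)) {
    sip_stop("taxon reads exceed pool total")
  }
  if (correction < 0) sip_stop("correction must be >= 0")
  h_narc <- h_total - h_taxon
  l_narc <- l_total - l_taxon
  h <- h_taxon
  l <- l_taxon
  zero_cell <- h == 0 | h_narc == 0 | l == 0 | l_narc == 0
  if (correction > 0) {
    h[zero_cell] <- h[zero_cell] + correction
    h_narc[zero_cell] <- h_narc[zero_cell] + correction
    l[zero_cell] <- l[zero_cell] + correction
    l_narc[zero_cell] <- l_narc[zero_cell] + correction
  }
  undefined <- h_narc == 0 | l == 0
  out <- rep(NA_real_, n)
  ok <- !undefined
  # l_narc = 0 with l > 0 gives l/l_narc = Inf and OR = 0: the taxon is the
  # entire light pool, so it cannot be *more* enriched heavy than light.
  out[ok] <- (h[ok] / h_narc[ok]) / (l[ok] / l_narc[ok])
  out
}

#' Read-count eligibility filter
#'
#' A (taxon, bottle) pair enters the labeling analysis only when the taxon
#' has at least `min_reads` reads in both the heavy and the light pool of
#' that bottle (default 5). This taxon-level reading also guarantees all
#' four odds-ratio cells are positive, so no OR is ever division-by-zero
#' for eligible taxa. See [labeling_analysis()] for the alternative
#' bottle-total reading.
#'
#' @param h_taxon,l_taxon taxon reads in the heavy and light pool.
#' @param min_reads minimum reads required in each pool.
#' @return logical vector.
#' @examples
#' eligible(c(5, 4, 0), c(5, 100, 0))  # TRUE FALSE FALSE
#' @export
eligible <- function(h_taxon, l_taxon, min_reads = 5) {
  if (any(c(h_taxon, l_taxon) < 0, na.rm = TRUE)) sip_stop("negative counts")
  if (min_reads < 1) sip_stop("min_reads must be >= 1")
  h_taxon >= min_reads & l_taxon >= min_reads
}

#' Ratio of odds ratios between a 13C bottle and its 12C control
#'
#' `RoOR = OR_13C / OR_12C`. Dividing out the control bottle's OR removes
#' the heavy-pool enrichment a taxon shows for reasons other than isotope
#' incorporation (GC content, gradient artifacts): RoOR > 1 indicates the
#' taxon is more enriched in the heavy pool of the 13C incubation than in
#' the paired 12C control, i.e. that it assimilated the labeled substrate.
#' An undefined member OR (`NA`) propagates to an undefined RoOR.
#'
#' @param or_13c,or_12c odds ratios of the 13C bottle and 12C control.
#' @return numeric vector of RoOR values (`NA` where undefined).
#' @export
ratio_of_odds_ratios <- function(or_13c, or_12c) {
  n <- max(length(or_13c), length(or_12c))
  or_13c <- rep_len(or_13c, n); or_12c <- rep_len(or_12c, n)
  if (any(or_13c < 0 | or_12c < 0, na.rm = TRUE)) sip_stop("odds ratios must be >= 0")
  ifelse(is.na(or_13c) | is.na(or_12c), NA_real_, or_13c / or_12c)
}

#' Full labeling analysis over pooled samples and an incubation design
#'
#' For every taxon and every 13C bottle, computes the Eq.-style odds ratio
#' in the 13C bottle and in its paired 12C control, their ratio (RoOR), the
#' eligibility of each bottle, and the per-replicate labeling call
#' `RoOR > threshold` (strict inequality; a tie at the threshold is "not
#' labeled"). RoOR is reported only when both the 13C bottle and its control
#' are eligible for that taxon. Two consensus columns are emitted and
#' neither is "the" result: `labeled_any` (RoOR above threshold in at least
#' one replicate) and `labeled_all` (above threshold in every replicate with
#' a defined RoOR, and at least one defined).
#'
#' @param pooled a `pooled_counts` object from [pool_fractions()] or
#'   [read_pooled()].
#' @param design a validated design data.frame from [read_design()] (or a
#'   data.frame with the same columns).
#' @param min_reads eligibility threshold, reads per pool (default 5).
#' @param threshold RoOR labeling threshold (default 1; no multiple-testing
#'   adjustment is applied — use [roor_permutation_rate()] to quantify the
#'   chance rate of `RoOR > 1`).
#' @param scope how to read the "min_reads in both fractions" filter.
#'   `"fraction_total"` (default) requires each *pool's total* reads to
#'   reach `min_reads` — the bottle-level reading, which keeps strongly
#'   labeled taxa (absent from the light pool of a 13C bottle precisely
#'   because all their DNA moved heavy) in the analysis. `"taxon"` requires
#'   the taxon's own reads in each pool to reach `min_reads`; it guarantees
#'   all four OR cells are positive but silently discards fully labeled
#'   taxa, so it is offered as the stricter alternative, not the default.
#' @param correction Haldane–Anscombe correction passed to [odds_ratio()]
#'   for tables containing a zero cell (default 0.5 under the bottle-level
#'   filter, where zero cells occur; tables without zeros are unaffected).
#'   Set to 0 to report such ratios as undefined (`NA`) instead.
#' @return a data.frame of class `labeling_table`, one row per
#'   (taxon, 13C bottle), sorted by taxon then replicate, with all four
#'   odds-ratio cells for both bottles, `or_13c`, `or_12c`, `roor`,
#'   eligibility flags and the labeling calls.
#' @export
labeling_analysis <- function(pooled, design, min_reads = 5, threshold = 1.0,
                              scope = c("fraction_total", "taxon"),
                              correction = 0.5) {
  scope <- match.arg(scope)
  if (!inherits(pooled, "pooled_counts")) {
    sip_stop("`pooled` must be a pooled_counts object (see pool_fractions())")
  }
  design <- validate_design(design)
  counts <- unclass(pooled$counts)
  pools <- pooled$pools
  missing_bottles <- setdiff(design$bottle_id, pools$bottle_id)
  if (length(missing_bottles)) {
    sip_stop(sprintf("design bottle(s) without pooled samples: %s",
                     paste(missing_bottles, collapse = ", ")))
  }
  col_of <- function(bottle, pool) {
    id <- pools$sample_id[pools$bottle_id == bottle & pools$pool == pool]
    if (length(id) != 1L) {
      sip_undefined(sprintf("bottle '%s' lacks a %s pool", bottle, pool))
    }
    counts[, id]
  }
  totals <- colSums(counts)
  tot_of <- function(bottle, pool) {
    totals[[pools$sample_id[pools$bottle_id == bottle & pools$pool == pool]]]
  }

  d13 <- design[design$isotope == "13C", , drop = FALSE]
  rows <- vector("list", nrow(d13))
  for (i in seq_len(nrow(d13))) {
    b <- d13$bottle_id[i]
    ctrl <- design$bottle_id[design$group == d13$group[i] & design$isotope == "12C"]
    h13 <- col_of(b, "heavy");    l13 <- col_of(b, "light")
    h12 <- col_of(ctrl, "heavy"); l12 <- col_of(ctrl, "light")
    th13 <- tot_of(b, "heavy");    tl13 <- tot_of(b, "light")
    th12 <- tot_of(ctrl, "heavy"); tl12 <- tot_of(ctrl, "light")
    if (scope == "taxon") {
      e13 <- eligible(h13, l13, min_reads)
      e12 <- eligible(h12, l12, min_reads)
    } else {
      e13 <- rep(th13 >= min_reads & tl13 >= min_reads, nrow(counts))
      e12 <- rep(th12 >= min_reads & tl12 >= min_reads, nrow(counts))
    }
    or13 <- odds_ratio(h13, th13, l13, tl13, correction)
    or12 <- odds_ratio(h12, th12, l12, tl12, correction)
    roor <- ratio_of_odds_ratios(or13, or12)
    roor[!(e13 & e12)] <- NA_real_
    rows[[i]] <- data.frame(
      taxon = rownames(counts), bottle_13c = b, bottle_12c = ctrl,
      replicate = d13$replicate[i], group = d13$group[i],
      h_arc_13c = h13, h_narc_13c = th13 - h13,
      l_arc_13c = l13, l_narc_13c = tl13 - l13,
      h_arc_12c = h12, h_narc_12c = th12 - h12,
      l_arc_12c = l12, l_narc_12c = tl12 - l12,
      or_13c = or13, or_12c = or12,
      eligible_13c = e13, eligible_12c = e12,
      roor = roor,
      labeled = !is.na(roor) & roor > threshold,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$taxon, out$group, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  # consensus over 13C replicates, per (taxon, condition)
  key <- paste(out$taxon, out$group, sep = "\r")
  any_by <- tapply(out$labeled, key, any)
  all_by <- tapply(seq_len(nrow(out)), key, function(ii) {
    defined <- !is.na(out$roor[ii])
    any(defined) && all(out$labeled[ii][defined])
  })
  out$labeled_any <- as.logical(any_by[key])
  out$labeled_all <- as.logical(all_by[key])
  attr(out, "min_reads") <- min_reads
  attr(out, "threshold") <- threshold
  attr(out, "scope") <- scope
  class(out) <- c("labeling_table", "data.frame")
  out
}

#' Chance rate of RoOR > 1 by bottle-role permutation
#'
#' Estimates how often `RoOR > 1` arises with no labeling at all, by
#' exploiting that under the null every bottle of a condition is
#' exchangeable: each bottle in turn plays the 12C control while each other
#' bottle plays the 13C role, and the rate of RoOR > 1 among eligible,
#' defined (taxon, pair) combinations is returned. A rate near 0.5
#' documents that `RoOR > 1` on its own is a coin-flip criterion for an
#' unlabeled taxon; the labeling call gains its meaning from replication
#' and from effect size, not from the bare inequality.
#'
#' @inheritParams labeling_analysis
#' @return a list with `rate` (proportion of RoOR > 1), `n` (number of
#'   eligible defined pairs) and `per_pair` (the underlying logical vector).
#' @export
roor_permutation_rate <- function(pooled, design, min_reads = 5,
                                  scope = c("fraction_total", "taxon"),
                                  correction = 0.5) {
  scope <- match.arg(scope)
  design <- validate_design(design)
  counts <- unclass(pooled$counts)
  pools <- pooled$pools
  totals <- colSums(counts)
  hits <- logical(0)
  for (g in unique(design$group)) {
    bottles <- design$bottle_id[design$group == g]
    if (length(bottles) < 2L) next
    for (ctrl in bottles) {
      for (b in setdiff(bottles, ctrl)) {
        id_h <- pools$sample_id[pools$bottle_id == b & pools$pool == "heavy"]
        id_l <- pools$sample_id[pools$bottle_id == b & pools$pool == "light"]
        id_hc <- pools$sample_id[pools$bottle_id == ctrl & pools$pool == "heavy"]
        id_lc <- pools$sample_id[pools$bottle_id == ctrl & pools$pool == "light"]
        h <- counts[, id_h]; l <- counts[, id_l]
        hc <- counts[, id_hc]; lc <- counts[, id_lc]
        if (scope == "taxon") {
          el <- eligible(h, l, min_reads) & eligible(hc, lc, min_reads)
        } else {
          el <- rep(totals[[id_h]] >= min_reads & totals[[id_l]] >= min_reads &
                    totals[[id_hc]] >= min_reads & totals[[id_lc]] >= min_reads,
                    length(h))
        }
        roor <- ratio_of_odds_ratios(
          odds_ratio(h, totals[[id_h]], l, totals[[id_l]], correction),
          odds_ratio(hc, totals[[id_hc]], lc, totals[[id_lc]], correction))
        keep <- el & !is.na(roor)
        hits <- c(hits, roor[keep] > 1)
      }
    }
  }
  list(rate = if (length(hits)) mean(hits) else NA_real_,
       n = length(hits), per_pair = hits)
}

#' @export
print.labeling_table <- function(x, ...) {
  lab <- unique(x$taxon[x$labeled_all])
  cat(sprintf("labeling_table: %d taxa x %d 13C bottles (min_reads=%s, RoOR threshold=%s, scope=%s)\n",
              length(unique(x$taxon)), length(unique(x$bottle_13c)),
              attr(x, "min_reads"), attr(x, "threshold"), attr(x, "scope")))
  cat(sprintf("labeled in all replicates with defined RoOR: %s\n",
              if (length(lab)) paste(lab, collapse = ", ") else "(none)"))
  print.data.frame(utils::head(x, 12L))
  invisible(x)
}

#' Write a labeling table as tab-separated text
#'
#' One row per (taxon, 13C bottle), mirroring the layout of published
#' SIP supplementary tables: all four contingency cells for both bottles,
#' both ORs, the RoOR, eligibility and the calls. `NA` marks ineligible or
#' undefined entries.
#'
#' @param labeling a `labeling_table` from [labeling_analysis()].
#' @param path file path.
#' @param comment optional `#` comment lines.
#' @export
write_labeling <- function(labeling, path, comment = NULL) {
  df <- as.data.frame(labeling)
  num <- vapply(df, is.numeric, TRUE)
  for (cn in names(df)[num]) {
    df[[cn]] <- ifelse(is.na(df[[cn]]), "NA",
                       formatC(df[[cn]], format = "g", digits = 12))
  }
  write_plain_tsv(df, path, comment)
}
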