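#' Classify a gradient fraction as light, heavy or intermediate
#'
#' Buoyant-density cut-offs for CsCl gradient fractions: a fraction is
#' *light* when its density is strictly below `light_max` and *heavy* when
#' its density is at or above `heavy_min` (boundary inclusive). Densities in
#' the gap `[light_max, heavy_min)` are *intermediate* and are excluded from
#' the labeling statistic under the default pooling policy.
#'
#' The defaults are the cut-offs used for archaeal DNA-SIP gradients:
#' light < 1.715 g/mL, heavy >= 1.72 g/mL.
#'
#' @param density numeric vector of buoyant densities, g/mL.
#' @param light_max upper (exclusive) density bound of the light class, g/mL.
#' @param heavy_min lower (inclusive) density bound of the heavy class, g/mL.
#' @return character vector in `c("light", "intermediate", "heavy")`.
#' @examples
#' classify_fraction(c(1.70, 1.715, 1.717, 1.72))
#' @export
classify_fraction <- function(density, light_max = 1.715, heavy_min = 1.72) {
  if (!is.numeric(light_max) || !is.numeric(heavy_min) || light_max >= heavy_min) {
    sip_stop("thresholds inverted: light_max must be < heavy_min")
  }
  if (!is.numeric(density)) sip_stop("density must be numeric")
  out <- rep("intermediate", length(density))
  out[density < light_max] <- "light"
  out[density >= heavy_min] <- "heavy"
  out
}

#' Pool fraction-level counts into one light and one heavy sample per bottle
#'
#' Sums each bottle's fraction columns into a light and a heavy pooled
#' sample according to [classify_fraction()]. The default policy pools *all*
#' fractions of a class (deterministic and data-independent; the original
#' studies chose representative fractions by DGGE screening, which is not
#' recoverable) and drops intermediate fractions; `intermediate` can instead
#' assign them to either class. Counts are conserved exactly: pooled counts
#' plus excluded counts equal the fraction totals, taxon by taxon.
#'
#' @param table a [count_table()] whose columns are fraction-level samples.
#' @param fractions fraction metadata (see [read_fractions()]); every column
#'   of `table` must match a `sample_id` here.
#' @param intermediate what to do with intermediate-density fractions:
#'   `"drop"` (default), `"light"` or `"heavy"`.
#' @param light_max,heavy_min density cut-offs, see [classify_fraction()].
#' @return an object of class `pooled_counts`: a list with
#'   \describe{
#'     \item{counts}{[count_table()] of pooled samples, ids `<bottle>|light`
#'       and `<bottle>|heavy`;}
#'     \item{pools}{data.frame mapping pooled sample id to bottle, pool and
#'       member fraction indices;}
#'     \item{excluded}{per-taxon counts in excluded (intermediate) fractions.}
#'   }
#' @export
pool_fractions <- function(table, fractions,
                           intermediate = c("drop", "light", "heavy"),
                           light_max = 1.715, heavy_min = 1.72) {
  intermediate <- match.arg(intermediate)
  if (!inherits(table, "count_table")) table <- count_table(table)
  fractions <- validate_fractions(fractions)
  unmatched <- setdiff(colnames(table), fractions$sample_id)
  if (length(unmatched)) {
    sip_stop(sprintf("count-table sample(s) with no fraction record: %s",
                     paste(unmatched, collapse = ", ")))
  }
  fr <- fractions[match(colnames(table), fractions$sample_id), ]
  cls <- classify_fraction(fr$density, light_max, heavy_min)
  if (intermediate != "drop") cls[cls == "intermediate"] <- intermediate

  bottles <- unique(fr$bottle_id)
  pooled <- matrix(0L, nrow(table), 2L * length(bottles))
  pool_ids <- character(2L * length(bottles))
  pools <- vector("list", 2L * length(bottles))
  k <- 0L
  for (b in bottles) {
    for (pool in c("light", "heavy")) {
      sel <- fr$bottle_id == b & cls == pool
      if (!any(sel)) {
        sip_undefined(sprintf(
          "bottle '%s' has no %s fraction under cut-offs (light < %.4g, heavy >= %.4g); labeling is undefined",
          b, pool, light_max, heavy_min))
      }
      k <- k + 1L
      pooled[, k] <- as.integer(rowSums(unclass(table)[, sel, drop = FALSE]))
      pool_ids[k] <- paste(b, pool, sep = "|")
      pools[[k]] <- data.frame(
        sample_id = pool_ids[k], bottle_id = b, pool = pool,
        n_fractions = sum(sel),
        member_fractions = paste(fr$fraction_index[sel], collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  dimnames(pooled) <- list(rownames(table), pool_ids)
  excluded_sel <- cls == "intermediate"
  excluded <- as.integer(rowSums(unclass(table)[, excluded_sel, drop = FALSE]))
  names(excluded) <- rownames(table)
  structure(list(counts = count_table(pooled),
                 pools = do.call(rbind, pools),
                 excluded = excluded),
            class = "pooled_counts")
}

#' @export
print.pooled_counts <- function(x, ...) {
  cat(sprintf("pooled_counts: %d taxa, %d bottles (%d excluded intermediate reads)\n",
              nrow(x$counts), nrow(x$pools) / 2L, sum(x$excluded)))
  print(x$pools, row.names = FALSE)
  invisible(x)
}

#' Write / read pooled samples
#'
#' Pooled samples are serialized as an ordinary count table whose sample ids
#' are `<bottle_id>|<pool>`; bottle ids therefore must not contain `|`.
#'
#' @param pooled a `pooled_counts` object (or its `counts` table).
#' @param path file path.
#' @param comment optional `#` comment lines.
#' @export
write_pooled <- function(pooled, path, comment = NULL) {
  counts <- if (inherits(pooled, "pooled_counts")) pooled$counts else pooled
  write_count_table(counts, path, comment)
}

#' @rdname write_pooled
#' @export
read_pooled <- function(path) {
  counts <- read_count_table(path)
  parts <- strsplit(colnames(counts), "|", fixed = TRUE)
  ok <- lengths(parts) == 2L & vapply(parts, function(p) p[2L] %in% c("light", "heavy"), TRUE)
  if (!all(ok)) {
    sip_stop(sprintf("%s: sample id '%s' is not of the form <bottle>|light or <bottle>|heavy",
                     path, colnames(counts)[!ok][1L]))
  }
  pools <- data.frame(
    sample_id = colnames(counts),
    bottle_id = vapply(parts, `[[`, "", 1L),
    pool = vapply(parts, `[[`, "", 2L),
    n_fractions = NA_integer_, member_fractions = NA_character_,
    stringsAsFactors = FALSE)
  structure(list(counts = counts, pools = pools,
                 excluded = stats::setNames(rep(NA_integer_, nrow(counts)),
                                            rownames(counts))),
            class = "pooled_counts")
}
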