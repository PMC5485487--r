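#' Relative-abundance profile (percent of total reads per sample)
#'
#' Converts a count table into per-sample percentages: each column is
#' `100 * count / column total`, so columns sum to 100. Percentages are
#' always computed per sample, never over the whole dataset.
#'
#' @param table a [count_table()]; every sample must have at least one read.
#' @return an `abundance_profile`: a numeric matrix of percentages with the
#'   same dimnames, columns summing to 100.
#' @export
relative_abundance <- function(table) {
  if (!inherits(table, "count_table")) table <- count_table(table)
  tot <- colSums(table)
  if (any(tot == 0)) {
    sip_stop(sprintf("sample '%s' has zero reads; relative abundance undefined",
                     colnames(table)[tot == 0][1L]))
  }
  pct <- sweep(unclass(table) * 100, 2L, tot, "/")
  structure(pct, class = c("abundance_profile", "matrix", "array"))
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("abundance_profile: %d taxa x %d samples (percent of reads per sample)\n",
              nrow(x), ncol(x)))
  print(round(utils::head(unclass(x), 10L), 2L))
  invisible(x)
}

#' Aggregate taxa into higher-level groups
#'
#' Sums the counts of taxa sharing a group label (e.g. collapsing OTUs into
#' clades such as MG-I, SCG or RC-V before profiling). The mapping must
#' cover every taxon in the table; the grand total of reads is conserved.
#' Groups appear in order of first appearance among the input taxa.
#'
#' @param table a [count_table()].
#' @param mapping named character vector `taxon -> group`, or a two-column
#'   data.frame `(taxon, group)`.
#' @return a [count_table()] with one row per group.
#' @export
aggregate_taxa <- function(table, mapping) {
  if (!inherits(table, "count_table")) table <- count_table(table)
  if (is.data.frame(mapping)) {
    mapping <- stats::setNames(as.character(mapping[[2L]]),
                               as.character(mapping[[1L]]))
  }
  unmapped <- setdiff(rownames(table), names(mapping))
  if (length(unmapped)) {
    sip_stop(sprintf("taxon without group mapping: %s",
                     paste(unmapped, collapse = ", ")))
  }
  grp <- mapping[rownames(table)]
  agg <- rowsum(unclass(table), group = grp, reorder = FALSE)
  count_table(agg)
}

#' Taxa shared between two abundance profiles
#'
#' Returns the taxa that reach at least `min_pct` percent (and are nonzero)
#' in at least one sample of *each* profile — the "present in both habitats"
#' comparison used when contrasting e.g. groundwater against soil
#' communities. With `min_pct = 0` this is the intersection of taxa with
#' any nonzero reads.
#'
#' @param profile_a,profile_b `abundance_profile` objects
#'   (see [relative_abundance()]).
#' @param min_pct detection threshold in percent (>= 0).
#' @return sorted character vector of shared taxon labels.
#' @export
shared_taxa <- function(profile_a, profile_b, min_pct = 0) {
  if (min_pct < 0) sip_stop("min_pct must be >= 0")
  present <- function(p) {
    hit <- apply(unclass(p), 1L, function(v) any(v > 0 & v >= min_pct))
    rownames(p)[hit]
  }
  sort(intersect(present(profile_a), present(profile_b)))
}

#' Write an abundance profile as tab-separated text
#'
#' @param profile an `abundance_profile`.
#' @param path file path.
#' @param comment optional `#` comment lines.
#' @param digits significant digits for the percentages.
#' @export
write_profile <- function(profile, path, comment = NULL, digits = 10) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("taxon", colnames(profile)), collapse = "\t"), con)
  body <- apply(unclass(profile), 1L, function(v) {
    paste(formatC(v, format = "g", digits = digits), collapse = "\t")
  })
  writeLines(paste(rownames(profile), body, sep = "\t"), con)
  invisible(path)
}

#' Read an abundance profile written by [write_profile()]
#'
#' @param path file path.
#' @return an `abundance_profile`.
#' @export
read_profile <- function(path) {
  tl <- read_tsv_lines(path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  taxa <- vapply(body, `[[`, "", 1L)
  m <- t(vapply(body, function(f) as.numeric(f[-1L]),
                numeric(length(header) - 1L)))
  if (length(header) == 2L) m <- matrix(vapply(body, function(f) as.numeric(f[2L]), 0), ncol = 1L)
  dimnames(m) <- list(taxa, header[-1L])
  bad <- abs(colSums(m) - 100) > 1e-6
  if (any(bad)) {
    sip_stop(sprintf("%s: column '%s' does not sum to 100 — not a percentage profile",
                     path, colnames(m)[bad][1L]))
  }
  structure(m, class = c("abundance_profile", "matrix", "array"))
}
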