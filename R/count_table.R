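#' Taxon-by-sample read-count table
#'
#' The basic data container of the package: a non-negative integer matrix of
#' amplicon read counts with taxa as rows and samples (gradient fractions,
#' pooled fractions, bulk samples, ...) as columns. Labels must be unique and
#' non-empty on both margins.
#'
#' @param counts a numeric matrix (or object coercible to one) of
#'   non-negative integers, with taxon labels as rownames and sample ids as
#'   colnames.
#' @return an object of class `count_table` (an integer matrix).
#' @examples
#' ct <- count_table(matrix(c(10L, 0L, 3L, 7L), 2, 2,
#'   dimnames = list(c("MG-I", "SCG"), c("S1", "S2"))))
#' colSums(ct)
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L || nrow(counts) < 1L || ncol(counts) < 1L) {
    sip_stop("count table needs at least 1 taxon and 1 sample")
  }
  if (!is.numeric(counts)) sip_stop("counts must be numeric")
  if (anyNA(counts)) sip_stop("counts contain NA")
  if (any(counts < 0)) sip_stop("counts contain negative entries")
  if (any(counts != round(counts))) sip_stop("counts must be integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    sip_stop("count table needs taxon rownames and sample colnames")
  }
  if (any(!nzchar(rownames(counts))) || any(!nzchar(colnames(counts)))) {
    sip_stop("empty taxon or sample label")
  }
  if (anyDuplicated(rownames(counts))) {
    sip_stop(sprintf("duplicate taxon label: %s",
                     rownames(counts)[duplicated(rownames(counts))][1L]))
  }
  if (anyDuplicated(colnames(counts))) {
    sip_stop(sprintf("duplicate sample id: %s",
                     colnames(counts)[duplicated(colnames(counts))][1L]))
  }
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_table", class(counts))
  counts
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples, %d reads total\n",
              nrow(x), ncol(x), sum(x)))
  print(utils::head(unclass(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more taxa\n", nrow(x) - 10L))
  invisible(x)
}

taxon_labels <- function(table) rownames(table)
sample_ids <- function(table) colnames(table)
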