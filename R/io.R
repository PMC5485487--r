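# Tab-separated readers/writers for the three on-disk formats:
#   counts.tsv    taxon \t <sample ids...>  (integer cells)
#   fractions.tsv bottle_id, fraction_index, density, dna_conc[, sample_id]
#   design.tsv    bottle_id, isotope, substrate, replicate, oxygen,
#                 source_well, weeks
# Lines starting with '#' are comments (used for config-hash stamps) and are
# skipped by every reader. Errors name the offending line of the file.

read_tsv_lines <- function(path) {
  if (!file.exists(path)) sip_stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a taxon-by-sample count table
#'
#' Expects tab-separated text with a header row of sample ids and the taxon
#' label in the first column. Cells must be non-negative integers; duplicate
#' taxon rows, ragged rows and non-integer cells are errors reported with
#' their line number (no silent merging or coercion).
#'
#' @param path path to a tab-separated count table.
#' @return a [count_table()].
#' @seealso [write_count_table()]
#' @export
read_count_table <- function(path) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) < 2L) sip_stop(sprintf("%s: need a header and at least one taxon row", path))
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) sip_stop(sprintf("%s:%d: header needs at least one sample id", path, tl$lineno[1L]))
  samples <- header[-1L]
  p <- length(header)
  body <- fields[-1L]
  linenos <- tl$lineno[-1L]
  nfield <- lengths(body)
  if (any(nfield != p)) {
    bad <- which(nfield != p)[1L]
    sip_stop(sprintf("%s:%d: ragged row (%d fields, expected %d)",
                     path, linenos[bad], nfield[bad], p))
  }
  taxa <- vapply(body, `[[`, "", 1L)
  cells <- t(vapply(body, function(f) f[-1L], character(p - 1L)))
  if (p == 2L) cells <- matrix(vapply(body, `[[`, "", 2L), ncol = 1L)
  bad_cell <- matrix(!grepl("^[0-9]+$", cells), nrow = nrow(cells))
  if (any(bad_cell)) {
    idx <- which(bad_cell, arr.ind = TRUE)[1L, ]
    sip_stop(sprintf("%s:%d: non-integer count '%s' in column '%s'",
                     path, linenos[idx[1L]], cells[idx[1L], idx[2L]],
                     samples[idx[2L]]))
  }
  if (anyDuplicated(taxa)) {
    dup <- taxa[duplicated(taxa)][1L]
    sip_stop(sprintf("%s:%d: duplicate taxon row '%s'",
                     path, linenos[which(taxa == dup)[2L]], dup))
  }
  m <- matrix(as.integer(cells), nrow = length(taxa),
              dimnames = list(taxa, samples))
  count_table(m)
}

#' Write a count table
#'
#' Inverse of [read_count_table()]: stable row and column order, so a
#' write/read round trip reproduces the table exactly.
#'
#' @param table a [count_table()].
#' @param path output path.
#' @param comment optional character vector written as leading `#` lines.
#' @export
write_count_table <- function(table, path, comment = NULL) {
  if (!inherits(table, "count_table")) table <- count_table(table)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("taxon", colnames(table)), collapse = "\t"), con)
  body <- apply(unclass(table), 1L, paste, collapse = "\t")
  writeLines(paste(rownames(table), body, sep = "\t"), con)
  invisible(path)
}

read_tsv_df <- function(path, required, numeric_cols = character()) {
  tl <- read_tsv_lines(path)
  if (length(tl$lines) < 2L) sip_stop(sprintf("%s: need a header and at least one row", path))
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  miss <- setdiff(required, header)
  if (length(miss)) sip_stop(sprintf("%s: missing required column(s): %s",
                                     path, paste(miss, collapse = ", ")))
  p <- length(header)
  body <- fields[-1L]
  linenos <- tl$lineno[-1L]
  nfield <- lengths(body)
  if (any(nfield != p)) {
    bad <- which(nfield != p)[1L]
    sip_stop(sprintf("%s:%d: ragged row", path, linenos[bad]))
  }
  df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(df) <- header
  for (cn in intersect(numeric_cols, header)) {
    val <- suppressWarnings(as.numeric(ifelse(df[[cn]] %in% c("", "NA"),
                                              NA, df[[cn]])))
    conv_bad <- is.na(val) & !(df[[cn]] %in% c("", "NA"))
    if (any(conv_bad)) {
      sip_stop(sprintf("%s:%d: non-numeric value '%s' in column '%s'",
                       path, linenos[which(conv_bad)[1L]],
                       df[[cn]][which(conv_bad)[1L]], cn))
    }
    df[[cn]] <- val
  }
  attr(df, "linenos") <- linenos
  df
}

#' Read gradient-fraction metadata
#'
#' One row per collected CsCl fraction: `bottle_id`, `fraction_index`
#' (1-based), `density` in g/mL, optional `dna_conc` (ng/uL, used only for
#' plotting gradient profiles) and optional `sample_id` linking the fraction
#' to a count-table column (default `<bottle_id>_F<fraction_index>`).
#' Densities must fall inside the (1.60, 1.85) g/mL sanity window of a CsCl
#' gradient; `(bottle_id, fraction_index)` pairs must be unique.
#'
#' @param path path to a tab-separated fraction table.
#' @return a data.frame of validated fraction records.
#' @export
read_fractions <- function(path) {
  df <- read_tsv_df(path, c("bottle_id", "fraction_index", "density"),
                    numeric_cols = c("fraction_index", "density", "dna_conc"))
  validate_fractions(df, where = path)
}

validate_fractions <- function(df, where = "fractions") {
  linenos <- attr(df, "linenos")
  ln <- function(i) if (is.null(linenos)) i else linenos[i]
  if (anyNA(df$density)) {
    sip_stop(sprintf("%s:%d: missing density", where, ln(which(is.na(df$density))[1L])))
  }
  bad <- df$density <= 1.60 | df$density >= 1.85
  if (any(bad)) {
    i <- which(bad)[1L]
    sip_stop(sprintf("%s:%d: density %.4g g/mL outside the (1.60, 1.85) CsCl sanity window",
                     where, ln(i), df$density[i]))
  }
  if (anyNA(df$fraction_index) || any(df$fraction_index < 1) ||
      any(df$fraction_index != round(df$fraction_index))) {
    sip_stop(sprintf("%s: fraction_index must be integers >= 1", where))
  }
  df$fraction_index <- as.integer(df$fraction_index)
  key <- paste(df$bottle_id, df$fraction_index)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    sip_stop(sprintf("%s:%d: duplicate (bottle_id, fraction_index) = (%s, %d)",
                     where, ln(i), df$bottle_id[i], df$fraction_index[i]))
  }
  if (is.null(df$dna_conc)) df$dna_conc <- NA_real_
  if (is.null(df$sample_id)) {
    df$sample_id <- sprintf("%s_F%d", df$bottle_id, df$fraction_index)
  }
  if (anyDuplicated(df$sample_id)) sip_stop(sprintf("%s: duplicate sample_id", where))
  attr(df, "linenos") <- NULL
  df[c("bottle_id", "fraction_index", "density", "dna_conc", "sample_id")]
}

#' @rdname read_fractions
#' @param fractions a fraction data.frame as returned by [read_fractions()].
#' @param comment optional `#` comment lines.
#' @export
write_fractions <- function(fractions, path, comment = NULL) {
  fractions <- validate_fractions(fractions)
  write_plain_tsv(fractions, path, comment)
}

write_plain_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  rows <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) ifelse(is.na(col), "NA", formatC(col, format = "g", digits = 15))
    else as.character(col)
  }), sep = "\t"))
  writeLines(rows, con)
  invisible(path)
}

#' Read an incubation-design manifest
#'
#' One row per incubation bottle: `bottle_id`, `isotope` (`13C` or `12C`),
#' `substrate`, `replicate`, `oxygen` (`oxic`/`anoxic`), `source_well`,
#' `weeks`. Bottles sharing (substrate, oxygen, source_well, weeks) form one
#' experimental condition; every condition containing a 13C bottle must
#' contain exactly one 12C control bottle, because the ratio of odds ratios
#' is undefined without a paired control. Replicate indices must be unique
#' within (condition, isotope).
#'
#' @param path path to a tab-separated design manifest.
#' @return a data.frame of validated design rows with a `group` key column.
#' @export
read_design <- function(path) {
  df <- read_tsv_df(path, c("bottle_id", "isotope", "substrate", "replicate",
                            "oxygen", "source_well", "weeks"),
                    numeric_cols = c("replicate", "weeks"))
  validate_design(df, where = path)
}

validate_design <- function(df, where = "design") {
  if (anyDuplicated(df$bottle_id)) sip_stop(sprintf("%s: duplicate bottle_id", where))
  bad <- !df$isotope %in% c("13C", "12C")
  if (any(bad)) {
    sip_stop(sprintf("%s: isotope must be '13C' or '12C' (got '%s' for bottle %s)",
                     where, df$isotope[bad][1L], df$bottle_id[bad][1L]))
  }
  if (!all(df$oxygen %in% c("oxic", "anoxic"))) {
    sip_stop(sprintf("%s: oxygen must be 'oxic' or 'anoxic'", where))
  }
  df$group <- paste(df$substrate, df$oxygen, df$source_well, df$weeks, sep = "|")
  for (g in unique(df$group[df$isotope == "13C"])) {
    n12 <- sum(df$group == g & df$isotope == "12C")
    if (n12 != 1L) {
      sip_stop(sprintf(
        "%s: condition '%s' has %d 12C control bottle(s); exactly one is required to compute RoOR",
        where, g, n12))
    }
  }
  key <- paste(df$group, df$isotope, df$replicate)
  if (anyDuplicated(key)) {
    sip_stop(sprintf("%s: duplicate replicate index within a condition", where))
  }
  attr(df, "linenos") <- NULL
  df[c("bottle_id", "isotope", "substrate", "replicate", "oxygen",
       "source_well", "weeks", "group")]
}

#' @rdname read_design
#' @param design a design data.frame as returned by [read_design()].
#' @param comment optional `#` comment lines.
#' @export
write_design <- function(design, path, comment = NULL) {
  design <- validate_design(design)
  write_plain_tsv(design[setdiff(names(design), "group")], path, comment)
}
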