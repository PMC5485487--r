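# Pipeline driver and command-line interface.
# Stages: simulate -> pool -> label -> profile -> cluster. Each stage reads
# and writes the package's plain-text formats, so running the stages one at
# a time over intermediate files is identical to running `run_pipeline()`
# end to end. Outputs carry a `# sipcall config=<md5> seed=<n>` stamp and
# contain no timestamps, so a rerun under the same config is byte-identical.

#' Read a pipeline run configuration
#'
#' Plain-text `key = value` lines (`#` comments allowed). Recognized keys:
#' input paths `counts`, `fractions`, `design`; thresholds `light_max`,
#' `heavy_min`, `min_reads`, `roor_threshold`, `correction`, `scope`,
#' `intermediate`; clustering `boot`; `seed`; and a simulator block
#' `sim.n_taxa`, `sim.n_labeled`, `sim.atom_excess`, `sim.depth`,
#' `sim.n_label_replicates` that, when present, generates the inputs
#' instead of reading them. Validation (`light_max < heavy_min`,
#' `min_reads >= 1`) happens here, before any stage runs.
#'
#' @param path path to a config file, or a named list of the same keys.
#' @return a validated `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  raw <- if (is.list(path)) {
    lapply(path, as.character)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    bad <- !grepl("=", lines, fixed = TRUE)
    if (any(bad)) sip_stop(sprintf("config: not a key = value line: '%s'", lines[bad][1L]))
    keys <- trimws(sub("=.*$", "", lines))
    vals <- trimws(sub("^[^=]*=", "", lines))
    if (anyDuplicated(keys)) sip_stop("config: duplicate key")
    stats::setNames(as.list(vals), keys)
  }
  defaults <- list(light_max = 1.715, heavy_min = 1.72, min_reads = 5,
                   roor_threshold = 1.0, correction = 0.5,
                   scope = "fraction_total", intermediate = "drop",
                   boot = 200, seed = 1)
  num_keys <- c("light_max", "heavy_min", "min_reads", "roor_threshold",
                "correction", "boot", "seed", "sim.n_taxa", "sim.n_labeled",
                "sim.atom_excess", "sim.depth", "sim.n_label_replicates")
  known <- c(names(defaults), num_keys, "counts", "fractions", "design", "scope",
             "intermediate")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    sip_stop(sprintf("config: unknown key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, raw)
  for (k in intersect(num_keys, names(cfg))) {
    v <- suppressWarnings(as.numeric(cfg[[k]]))
    if (is.na(v)) sip_stop(sprintf("config: key '%s' must be numeric", k))
    cfg[[k]] <- v
  }
  if (cfg$light_max >= cfg$heavy_min) {
    sip_stop("config: light_max must be < heavy_min")
  }
  if (cfg$min_reads < 1) sip_stop("config: min_reads must be >= 1")
  if (!cfg$scope %in% c("fraction_total", "taxon")) {
    sip_stop("config: scope must be 'fraction_total' or 'taxon'")
  }
  if (!cfg$intermediate %in% c("drop", "light", "heavy")) {
    sip_stop("config: intermediate must be drop/light/heavy")
  }
  has_sim <- any(startsWith(names(cfg), "sim."))
  has_files <- all(c("counts", "fractions", "design") %in% names(cfg))
  if (!has_sim && !has_files) {
    sip_stop("config: provide counts/fractions/design paths or a sim.* block")
  }
  cfg$use_sim <- has_sim
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg <- cfg[order(names(cfg))]
  txt <- paste(names(cfg), vapply(cfg, paste, "", collapse = ","),
               sep = "=", collapse = "\n")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the whole SIP analysis pipeline
#'
#' Executes simulate (or load) -> pool -> label -> profile -> cluster and
#' writes `counts.tsv`, `fractions.tsv`, `design.tsv`, `pooled.tsv`,
#' `labeling.tsv`, `profile.tsv`, `tree.nwk` and `run_log.txt` into
#' `out_dir`. Every tab-separated output is stamped with the config md5
#' hash and seed; the log records an md5 checksum per output. A failure in
#' any stage removes the partial outputs of this run before the classed
#' condition is rethrown with the stage name.
#'
#' @param config a `run_config` from [read_run_config()], a path to a
#'   config file, or a named list.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory results: `experiment` (if
#'   simulated), `pooled`, `labeling`, `profile`, `tree`, `newick`, and the
#'   output `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(cfg)
  stamp <- sprintf("sipcall config=%s seed=%d", hash, as.integer(cfg$seed))
  outs <- file.path(out_dir, c(counts = "counts.tsv", fractions = "fractions.tsv",
                               design = "design.tsv", pooled = "pooled.tsv",
                               labeling = "labeling.tsv", profile = "profile.tsv",
                               tree = "tree.nwk", log = "run_log.txt"))
  names(outs) <- c("counts", "fractions", "design", "pooled", "labeling",
                   "profile", "tree", "log")
  written <- character(0)
  stage <- "setup"
  res <- tryCatch({
    if (cfg$use_sim) {
      stage <- "simulate"
      sc <- default_scenario(
        n_taxa = as.integer(cfg[["sim.n_taxa"]] %||% 20),
        n_labeled = as.integer(cfg[["sim.n_labeled"]] %||% 2),
        atom_excess = cfg[["sim.atom_excess"]] %||% 1.0,
        depth = as.integer(cfg[["sim.depth"]] %||% 10000),
        n_label_replicates = as.integer(cfg[["sim.n_label_replicates"]] %||% 2),
        seed = as.integer(cfg$seed))
      ex <- simulate_experiment(sc, cfg$light_max, cfg$heavy_min)
      write_count_table(ex$counts, outs[["counts"]], comment = stamp)
      write_fractions(ex$fractions, outs[["fractions"]], comment = stamp)
      write_design(ex$design, outs[["design"]], comment = stamp)
      written <- c(written, outs[c("counts", "fractions", "design")])
      counts <- ex$counts; fractions <- ex$fractions; design <- ex$design
    } else {
      stage <- "load"
      ex <- NULL
      counts <- read_count_table(cfg$counts)
      fractions <- read_fractions(cfg$fractions)
      design <- read_design(cfg$design)
    }
    stage <- "pool"
    pooled <- pool_fractions(counts, fractions, intermediate = cfg$intermediate,
                             light_max = cfg$light_max, heavy_min = cfg$heavy_min)
    write_pooled(pooled, outs[["pooled"]], comment = stamp)
    written <- c(written, outs[["pooled"]])
    stage <- "label"
    labeling <- labeling_analysis(pooled, design, min_reads = cfg$min_reads,
                                  threshold = cfg$roor_threshold,
                                  scope = cfg$scope, correction = cfg$correction)
    write_labeling(labeling, outs[["labeling"]], comment = stamp)
    written <- c(written, outs[["labeling"]])
    stage <- "profile"
    profile <- relative_abundance(pooled$counts)
    write_profile(profile, outs[["profile"]], comment = stamp)
    written <- c(written, outs[["profile"]])
    stage <- "cluster"
    tree <- bootstrap_support(profile, n_boot = as.integer(cfg$boot),
                              seed = as.integer(cfg$seed))
    nwk <- to_newick(tree)
    writeLines(nwk, outs[["tree"]])
    written <- c(written, outs[["tree"]])
    stage <- "log"
    sums <- tools::md5sum(written)
    log_lines <- c(paste0("# ", stamp),
                   sprintf("%s\t%s", basename(names(sums)), unname(sums)))
    writeLines(log_lines, outs[["log"]])
    list(experiment = ex, pooled = pooled, labeling = labeling,
         profile = profile, tree = tree, newick = nwk, paths = outs)
  }, sipError = function(e) {
    unlink(written)
    e$message <- sprintf("[stage %s] %s", stage, e$message)
    stop(e)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_usage <- "usage: sipcall <simulate|pool|label|profile|cluster|all> [--key value ...]
  all       --config run.cfg --out DIR
  simulate  --out DIR [--seed N --n-taxa N --n-labeled N --depth N --replicates N --atom-excess X]
  pool      --counts counts.tsv --fractions fractions.tsv --out pooled.tsv
            [--light-max 1.715 --heavy-min 1.72 --intermediate drop]
  label     --pooled pooled.tsv --design design.tsv --out labeling.tsv
            [--min-reads 5 --threshold 1.0 --scope fraction_total --correction 0.5]
  profile   --counts counts.tsv --out profile.tsv [--map clades.tsv]
  cluster   --profile profile.tsv --out tree.nwk [--boot 1000 --seed 42]
exit codes: 0 ok, 2 validation error, 3 undefined statistic"

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) sip_stop(sprintf("unexpected argument '%s'", args[i]))
    if (i == length(args)) sip_stop(sprintf("flag %s needs a value", args[i]))
    flags[[sub("^--", "", args[i])]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

need <- function(flags, key) {
  if (is.null(flags[[key]])) sip_stop(sprintf("missing required flag --%s", key))
  flags[[key]]
}

#' Command-line entry point
#'
#' Dispatches the `sipcall` subcommands (`simulate`, `pool`, `label`,
#' `profile`, `cluster`, `all`). Intended to be driven by the wrapper
#' script in `inst/cli/sipcall`, but callable in-process with a character
#' vector of arguments. Returns the process exit code instead of calling
#' `quit()`: 0 on success, 2 on a validation error, 3 when a statistic is
#' undefined for the input (e.g. a bottle with no heavy fractions).
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
sipcall <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(args) == 0L || args[1L] %in% c("-h", "--help", "help")) {
      message(cli_usage)
      return(invisible(0L))
    }
    cmd <- args[1L]
    flags <- parse_flags(args[-1L])
    switch(cmd,
      all = {
        run_pipeline(need(flags, "config"), need(flags, "out"))
        message(sprintf("sipcall all: outputs in %s", flags$out))
      },
      simulate = {
        sc <- default_scenario(
          n_taxa = as.integer(flags[["n-taxa"]] %||% 20),
          n_labeled = as.integer(flags[["n-labeled"]] %||% 2),
          atom_excess = as.numeric(flags[["atom-excess"]] %||% 1),
          depth = as.integer(flags[["depth"]] %||% 10000),
          n_label_replicates = as.integer(flags[["replicates"]] %||% 2),
          seed = as.integer(flags[["seed"]] %||% 1))
        ex <- simulate_experiment(sc)
        out <- need(flags, "out")
        if (!dir.exists(out)) dir.create(out, recursive = TRUE)
        write_count_table(ex$counts, file.path(out, "counts.tsv"))
        write_fractions(ex$fractions, file.path(out, "fractions.tsv"))
        write_design(ex$design, file.path(out, "design.tsv"))
        message(sprintf("simulated %d taxa (%d labeled) into %s",
                        length(sc$taxa), length(ex$truth), out))
      },
      pool = {
        pooled <- pool_fractions(
          read_count_table(need(flags, "counts")),
          read_fractions(need(flags, "fractions")),
          intermediate = flags[["intermediate"]] %||% "drop",
          light_max = as.numeric(flags[["light-max"]] %||% 1.715),
          heavy_min = as.numeric(flags[["heavy-min"]] %||% 1.72))
        write_pooled(pooled, need(flags, "out"))
      },
      label = {
        lab <- labeling_analysis(
          read_pooled(need(flags, "pooled")),
          read_design(need(flags, "design")),
          min_reads = as.numeric(flags[["min-reads"]] %||% 5),
          threshold = as.numeric(flags[["threshold"]] %||% 1),
          scope = flags[["scope"]] %||% "fraction_total",
          correction = as.numeric(flags[["correction"]] %||% 0.5))
        write_labeling(lab, need(flags, "out"))
      },
      profile = {
        tab <- read_count_table(need(flags, "counts"))
        if (!is.null(flags[["map"]])) {
          mp <- read_tsv_df(flags[["map"]], c("taxon", "group"))
          tab <- aggregate_taxa(tab, mp)
        }
        write_profile(relative_abundance(tab), need(flags, "out"))
      },
      cluster = {
        prof <- read_profile(need(flags, "profile"))
        tree <- bootstrap_support(prof,
                                  n_boot = as.integer(flags[["boot"]] %||% 1000),
                                  seed = as.integer(flags[["seed"]] %||% 42))
        writeLines(to_newick(tree), need(flags, "out"))
      },
      sip_stop(sprintf("unknown subcommand '%s'\n%s", cmd, cli_usage))
    )
    0L
  },
  sip_undefined_error = function(e) { message("sipcall error: ", conditionMessage(e)); 3L },
  sip_validation_error = function(e) { message("sipcall error: ", conditionMessage(e)); 2L })
  invisible(code)
}
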