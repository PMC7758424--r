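# Scenario files are declarative YAML; save/load round-trips losslessly
# (doubles are written with 17 significant digits). Every CLI run writes a
# machine-readable manifest (arguments, scenario hash, seed, versions)
# from which the run can be reconstructed.

#' Save a scenario to a YAML file
#'
#' @param scn A [scenario()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(scn, path) {
  validate_scenario(scn)
  rep <- list(
    feature_dim = scn$scene$feature_dim,
    objects = lapply(scn$scene$objects, function(ob) {
      list(id = ob$id, location = ob$location, salience = ob$salience,
           attributes = lapply(ob$attributes, function(at) {
             list(id = at$id, features = as.integer(at$features))
           }))
    }),
    patterns = lapply(scn$assoc$patterns, as.integer),
    semantic = apply(scn$assoc$semantic, 1, as.numeric, simplify = FALSE),
    episodic = apply(scn$assoc$episodic, 1, as.numeric, simplify = FALSE),
    value_map = as.numeric(scn$vmap),
    memory = unclass(scn$mem),
    accumulators = scn$acc,
    attention = unclass(scn$att),
    input_gain = scn$input_gain,
    dwell_attr = scn$dwell_attr,
    max_steps = scn$max_steps)
  writeLines(yaml::as.yaml(rep, precision = 17L), path)
  invisible(path)
}

need_field <- function(rep, field, where = "scenario file") {
  if (is.null(rep[[field]])) {
    stop("schema error: missing required field '", field, "' in ", where,
         call. = FALSE)
  }
  rep[[field]]
}

as_matrix_rows <- function(rows, field) {
  m <- try(do.call(rbind, lapply(rows, as.numeric)), silent = TRUE)
  if (inherits(m, "try-error") || is.null(dim(m))) {
    stop("schema error: field '", field, "' is not a numeric matrix",
         call. = FALSE)
  }
  m
}

#' Load a scenario from a YAML file
#'
#' All scenario invariants are checked at load; schema violations produce
#' an error naming the offending field.
#'
#' @param path Scenario file written by [save_scenario()].
#' @return A validated [scenario()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  rep <- yaml::read_yaml(path)
  feature_dim <- need_field(rep, "feature_dim")
  objs <- need_field(rep, "objects")
  objects <- lapply(objs, function(ob) {
    atts <- lapply(need_field(ob, "attributes", "object"), function(at) {
      attribute(need_field(at, "id", "attribute"),
                feature_vector(need_field(at, "features", "attribute")))
    })
    scene_object(need_field(ob, "id", "object"),
                 need_field(ob, "location", "object"),
                 atts,
                 salience = if (is.null(ob$salience)) 1 else ob$salience)
  })
  semantic <- as_matrix_rows(need_field(rep, "semantic"), "semantic")
  episodic <- as_matrix_rows(need_field(rep, "episodic"), "episodic")
  vmap <- value_map(need_field(rep, "value_map"))
  mem <- do.call(memory_config, need_field(rep, "memory"))
  att <- do.call(attention_config, need_field(rep, "attention"))
  patterns <- lapply(if (is.null(rep$patterns)) list() else rep$patterns,
                     as.numeric)
  scenario(scene = scene(objects, feature_dim),
           assoc = association_set(semantic, episodic, patterns),
           vmap = vmap, mem = mem,
           acc = need_field(rep, "accumulators"),
           att = att,
           input_gain = need_field(rep, "input_gain"),
           dwell_attr = need_field(rep, "dwell_attr"),
           max_steps = need_field(rep, "max_steps"))
}

write_manifest <- function(out_dir, command, args, scenario_path, seed) {
  manifest <- list(
    command = command,
    arguments = args,
    scenario = scenario_path,
    scenario_md5 = if (!is.null(scenario_path) && file.exists(scenario_path))
      unname(tools::md5sum(scenario_path)) else NULL,
    seed = seed,
    package_version = as.character(utils::packageVersion("accumem")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3))
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

cli_usage <- function() {
  paste(
    "usage: accumem-sim <command> [options]",
    "",
    "commands:",
    "  trial       run one trial        (--scenario|--preset, --seed, --trace)",
    "  trials      run a trial batch    (--scenario|--preset, --n, --seed)",
    "  sweep       parameter sweep      (+ --param, --grid 0.01,0.02,...)",
    "  breakpoint  discounting break    (--v-immediate, --v-delayed,",
    "              --max-chain, --n, --seed)",
    "",
    "common options:",
    "  --scenario PATH   scenario YAML file",
    "  --preset NAME     bundled preset (see ?preset_scenario)",
    "  --out DIR         output directory (default '.')",
    "  --seed INT        base seed (default 1)",
    "  --n INT           trials per condition (default 100)",
    sep = "\n")
}

#' Command-line entry point
#'
#' Dispatches the `trial`, `trials`, `sweep` and `breakpoint` commands,
#' writes delimited result tables plus a JSON run manifest to the output
#' directory, and returns an exit status. The installed script
#' `inst/cli/accumem-sim` wraps this function for shell use.
#'
#' @param args Character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 on success, 2 on usage error.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L || args[1] %in% c("-h", "--help", "help")) {
    message(cli_usage())
    return(invisible(if (length(args) < 1L) 2L else 0L))
  }
  command <- args[1]
  if (!command %in% c("trial", "trials", "sweep", "breakpoint")) {
    message("unknown command: ", command, "\n\n", cli_usage())
    return(invisible(2L))
  }
  opt <- try(parse_cli_args(args[-1]), silent = TRUE)
  if (inherits(opt, "try-error")) {
    message(attr(opt, "condition")$message, "\n\n", cli_usage())
    return(invisible(2L))
  }
  out_dir <- if (is.null(opt$out)) "." else opt$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(opt$seed)) 1L else as.integer(opt$seed)
  n <- if (is.null(opt$n)) 100L else as.integer(opt$n)

  status <- try({
    scn <- NULL
    scenario_path <- opt$scenario
    if (command %in% c("trial", "trials", "sweep")) {
      if (!is.null(opt$scenario)) {
        scn <- load_scenario(opt$scenario)
      } else if (!is.null(opt$preset)) {
        scn <- preset_scenario(opt$preset)
        scenario_path <- file.path(out_dir, "scenario.yaml")
        save_scenario(scn, scenario_path)
      } else {
        stop("one of --scenario or --preset is required", call. = FALSE)
      }
    }
    if (command == "trial") {
      tr <- run_trial(scn, seed = seed, traces = !is.null(opt$trace))
      print(tr)
      utils::write.table(
        data.frame(seed = seed, choice = tr$choice, rt = tr$rt,
                   steps = tr$steps),
        file.path(out_dir, "trial.tsv"), sep = "\t", row.names = FALSE,
        quote = FALSE)
      if (!is.null(opt$trace)) {
        utils::write.table(
          data.frame(step = seq_len(tr$steps), tr$acc_trace,
                     attended = tr$att_trace, value = tr$v_trace),
          file.path(out_dir, "trace.tsv"), sep = "\t", row.names = FALSE,
          quote = FALSE)
      }
    } else if (command == "trials") {
      sm <- run_trials(scn, n = n, base_seed = seed)
      print(sm)
      utils::write.table(sm$summary, file.path(out_dir, "summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(sm$trials, file.path(out_dir, "trials.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    } else if (command == "sweep") {
      if (is.null(opt$param) || is.null(opt$grid)) {
        stop("sweep requires --param and --grid", call. = FALSE)
      }
      grid <- as.numeric(strsplit(opt$grid, ",")[[1]])
      if (!length(grid) || anyNA(grid)) {
        stop("--grid must be a comma-separated numeric list", call. = FALSE)
      }
      sw <- sweep_parameter(scn, opt$param, grid, n = n, base_seed = seed)
      print(sw)
      utils::write.table(sweep_table(sw), file.path(out_dir, "sweep.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    } else if (command == "breakpoint") {
      bp <- discounting_breakpoint(
        value_immediate = if (is.null(opt$v_immediate)) 0.9 else
          as.numeric(opt$v_immediate),
        value_delayed = if (is.null(opt$v_delayed)) 1.0 else
          as.numeric(opt$v_delayed),
        max_chain = if (is.null(opt$max_chain)) 9L else
          as.integer(opt$max_chain),
        n = n, base_seed = seed,
        scenario_args = delayed_reward_calibration())
      print(bp)
      utils::write.table(bp$table, file.path(out_dir, "breakpoint.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write_manifest(out_dir, command, as.list(opt), scenario_path, seed)
    0L
  }, silent = TRUE)
  if (inherits(status, "try-error")) {
    message("error: ", attr(status, "condition")$message)
    return(invisible(1L))
  }
  invisible(0L)
}
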