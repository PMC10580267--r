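# Index/quant command surface: manifest persistence, backend auto-chaining,
# and deterministic argv assembly behind a pluggable executor.
#
# External tools (salmon, piscem, alevin-fry) are never reimplemented; the
# package ships argv templates for them as configuration data
# (inst/extdata/argv_templates.json) and only assembles fully resolved
# command lines. The manifest written at index time records the backend and
# file locations, so later quantification runs self-configure without the
# user restating anything.

MANIFEST_FILE <- "index_info.json"

argv_templates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- jsonlite::read_json(
        system.file("extdata", "argv_templates.json", package = "screadkit"),
        simplifyVector = TRUE)
    }
    cache
  }
})

fill_template <- function(argv, values) {
  for (key in names(values)) {
    argv <- gsub(paste0("{", key, "}"), values[[key]], argv, fixed = TRUE)
  }
  left <- grep("\\{[a-z0-9_]+\\}", argv, value = TRUE)
  if (length(left)) {
    stop(sprintf("unresolved argv placeholder(s): %s",
                 paste(left, collapse = ", ")))
  }
  argv
}

new_command_plan <- function(stages, provenance = NULL) {
  structure(list(stages = stages, provenance = provenance),
            class = "command_plan")
}

plan_stage <- function(name, argv, io = list()) {
  list(name = name, argv = argv, io = io)
}

#' @export
print.command_plan <- function(x, ...) {
  cat(sprintf("<command_plan> %d stage(s)\n", length(x$stages)))
  for (s in x$stages) {
    cat(sprintf("  [%s] %s\n", s$name, paste(s$argv, collapse = " ")))
  }
  invisible(x)
}

write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  if (!file.rename(tmp, path)) {
    stop(sprintf("could not move manifest into place at '%s'", path))
  }
  invisible(path)
}

#' Read an index manifest
#'
#' @param index_dir Directory given to [cmd_index()].
#' @return The manifest as a list.
#' @export
read_manifest <- function(index_dir) {
  path <- file.path(index_dir, MANIFEST_FILE)
  if (!file.exists(path)) {
    stop(sprintf("no index manifest found at '%s'", path))
  }
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Plan (and stage) reference indexing
#'
#' Builds the augmented reference requested by `config[["ref_type"]]`
#' (`"splici"`, `"spliceu"`, or `"direct"` passthrough of a user FASTA and
#' two-column t2g), writes it with [write_reference()], persists the index
#' manifest (`index_info.json`, written atomically), and returns the
#' command plan whose single stage invokes the chosen backend's indexer.
#' The backend is piscem iff `config[["use_piscem"]]` is set, salmon otherwise;
#' this choice is recorded in the manifest so that subsequent
#' quantification runs pick it up automatically.
#'
#' @param config A list: `out_dir`; `ref_type`; for splici/spliceu
#'   `genome_fasta` + `gtf` (paths) or `genome` + `models` (in-memory),
#'   plus `rlen` and optional `flank_trim` (splici); for direct `ref_seq`
#'   and `t2g`; optional `use_piscem`, `geometry_hint`, `threads`,
#'   `tool_versions`.
#' @return List with `manifest` and `plan` (a `command_plan`).
#' @export
cmd_index <- function(config) {
  out_dir <- config[["out_dir"]]
  if (is.null(out_dir)) stop("config$out_dir is required")
  ref_type <- config[["ref_type"]] %||% "splici"
  if (!ref_type %in% c("splici", "spliceu", "direct")) {
    stop(sprintf("unknown ref_type '%s'", ref_type))
  }
  has_direct <- !is.null(config[["ref_seq"]])
  has_genome <- !is.null(config[["genome_fasta"]]) || !is.null(config[["genome"]])
  if (has_direct && has_genome) {
    stop("conflicting inputs: give either a direct reference or genome+GTF, not both")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ref_dir <- file.path(out_dir, "ref")

  if (ref_type == "direct") {
    if (!has_direct || is.null(config[["t2g"]])) {
      stop("direct ref_type requires config$ref_seq and config$t2g")
    }
    paths <- write_direct_reference(config[["ref_seq"]], config[["t2g"]], ref_dir)
  } else {
    if (!has_genome) stop("splici/spliceu require a genome and annotation")
    genome <- config[["genome"]] %||%
      Biostrings::readDNAStringSet(config[["genome_fasta"]])
    models <- config[["models"]] %||% load_annotation(config[["gtf"]])
    ref <- if (ref_type == "splici") {
      if (is.null(config[["rlen"]])) stop("splici requires config$rlen")
      build_splici(genome, models, read_length = config[["rlen"]],
                   flank_trim = config[["flank_trim"]] %||% 5L)
    } else {
      build_spliceu(genome, models)
    }
    paths <- write_reference(ref, ref_dir)
  }

  backend <- if (isTRUE(config[["use_piscem"]])) "piscem" else "salmon"
  index_dir <- file.path(out_dir, "index")
  dir.create(index_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    ref_type = ref_type,
    backend = backend,
    geometry_hint = config[["geometry_hint"]],
    paths = list(reference_fasta = paths$fasta, t2g = paths$t2g,
                 index_dir = index_dir),
    tool_versions = config[["tool_versions"]] %||% stats::setNames(list(), character(0)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_json_atomic(manifest, file.path(out_dir, MANIFEST_FILE))

  argv <- fill_template(
    argv_templates()[[backend]][["index"]],
    list(ref_fasta = paths$fasta, index_dir = index_dir,
         threads = as.character(config[["threads"]] %||% 1L)))
  plan <- new_command_plan(
    list(plan_stage("index", argv,
                    io = list(inputs = paths$fasta, outputs = index_dir))),
    provenance = file.path(out_dir, MANIFEST_FILE))
  list(manifest = manifest, plan = plan)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plan quantification against an existing index
#'
#' Assembles the ordered stage list
#' `[xform?] -> map -> generate-permit-list -> collate -> quant` with
#' fully resolved argv. The mapper backend and the transcript-to-gene map
#' are taken from the index manifest — the user never restates them. If
#' the fragment geometry is complex, an `xform` stage is prepended: it
#' streams the reads through geometry normalization into named-pipe paths
#' that feed the mapper, and the mapper receives
#' [simplified_geometry()]`(g)` instead of the original description.
#' With `config[["map_dir"]]` set, mapping (and any xform) is skipped and the
#' plan starts from the existing mapping results.
#'
#' Plans are pure functions of `(config, manifest)`: identical inputs give
#' byte-identical argv.
#'
#' @param config A list: `index_dir` (unless `map_dir` is given),
#'   `geometry` (string), `reads1`/`reads2` (FASTQ paths), `out_dir`,
#'   optional `map_dir`, `t2g` (required with `map_dir`), `threads`.
#' @return A `command_plan`.
#' @export
cmd_quant <- function(config) {
  out_dir <- config[["out_dir"]]
  if (is.null(out_dir)) stop("config$out_dir is required")
  threads <- as.character(config[["threads"]] %||% 1L)
  quant_dir <- file.path(out_dir, "quant")
  af <- argv_templates()[["alevin-fry"]]

  if (!is.null(config[["map_dir"]])) {
    t2g <- config[["t2g"]]
    if (is.null(t2g)) {
      stop("starting from map_dir requires config$t2g")
    }
    vals <- list(map_dir = config[["map_dir"]], quant_dir = quant_dir,
                 t2g = t2g, threads = threads)
    stages <- list(
      plan_stage("generate-permit-list",
                 fill_template(af[["generate-permit-list"]], vals)),
      plan_stage("collate", fill_template(af[["collate"]], vals)),
      plan_stage("quant", fill_template(af[["quant"]], vals)))
    return(new_command_plan(stages, provenance = NULL))
  }

  if (is.null(config[["index_dir"]])) {
    stop("either config$index_dir or config$map_dir is required")
  }
  manifest <- read_manifest(config[["index_dir"]])
  geometry <- config[["geometry"]] %||% manifest$geometry_hint
  if (is.null(geometry)) {
    stop("a fragment geometry is required (config$geometry or manifest geometry_hint)")
  }
  g <- parse_geometry(geometry)
  backend <- manifest$backend
  map_dir <- file.path(out_dir, "map")
  stages <- list()

  reads1 <- paste(config[["reads1"]], collapse = ",")
  reads2 <- paste(config[["reads2"]], collapse = ",")
  mapper_geometry <- render_geometry(g)

  if (classify_geometry(g) == "complex") {
    fifo1 <- file.path(out_dir, "xform_r1.pipe")
    fifo2 <- file.path(out_dir, "xform_r2.pipe")
    stages[[length(stages) + 1L]] <- plan_stage(
      "xform",
      c("xform", "--geometry", render_geometry(g),
        "-1", reads1, "-2", reads2,
        "--out-1", fifo1, "--out-2", fifo2, "--fifo"),
      io = list(inputs = c(config[["reads1"]], config[["reads2"]]),
                outputs = c(fifo1, fifo2)))
    reads1 <- fifo1
    reads2 <- fifo2
    mapper_geometry <- render_geometry(simplified_geometry(g))
  }

  vals <- list(index_dir = manifest$paths$index_dir,
               reads1 = reads1, reads2 = reads2,
               geometry = mapper_geometry, map_dir = map_dir,
               quant_dir = quant_dir, t2g = manifest$paths$t2g,
               threads = threads)
  stages[[length(stages) + 1L]] <- plan_stage(
    "map", fill_template(argv_templates()[[backend]][["map"]], vals))
  stages[[length(stages) + 1L]] <- plan_stage(
    "generate-permit-list", fill_template(af[["generate-permit-list"]], vals))
  stages[[length(stages) + 1L]] <- plan_stage(
    "collate", fill_template(af[["collate"]], vals))
  stages[[length(stages) + 1L]] <- plan_stage(
    "quant", fill_template(af[["quant"]], vals))

  new_command_plan(stages,
                   provenance = file.path(config[["index_dir"]], MANIFEST_FILE))
}

#' Executors
#'
#' An executor is a list with a `run(argv, io)` function returning an exit
#' status. `shell_executor()` invokes the command via [system2()];
#' `recording_executor()` records every invocation without running
#' anything (optionally failing at a given call index), which is how all
#' tests exercise command plans.
#'
#' @param fail_at Optional call index at which the recording executor
#'   returns a non-zero status.
#' @return An executor list; the recording executor additionally exposes
#'   `calls()` returning the list of recorded argv vectors.
#' @name executors
NULL

#' @rdname executors
#' @export
shell_executor <- function() {
  list(run = function(argv, io = NULL) {
    status <- system2(argv[[1L]], argv[-1L])
    as.integer(status)
  })
}

#' @rdname executors
#' @export
recording_executor <- function(fail_at = NULL) {
  env <- new.env(parent = emptyenv())
  env$calls <- list()
  list(
    run = function(argv, io = NULL) {
      env$calls[[length(env$calls) + 1L]] <- argv
      if (!is.null(fail_at) && length(env$calls) == fail_at) 1L else 0L
    },
    calls = function() env$calls)
}

#' Execute a command plan
#'
#' Runs the stages in order through the executor. A non-zero exit status
#' aborts the run, naming the failed stage; stages after it are not
#' invoked. The returned log records the verbatim argv, status and timing
#' of every executed stage.
#'
#' @param plan A `command_plan`.
#' @param executor An executor (see [shell_executor()]); defaults to the
#'   shell executor.
#' @return A data.frame run log (`stage`, `argv`, `status`,
#'   `elapsed_sec`).
#' @export
execute_plan <- function(plan, executor = shell_executor()) {
  stopifnot(inherits(plan, "command_plan"))
  log <- list()
  for (s in plan$stages) {
    t0 <- proc.time()[["elapsed"]]
    status <- executor$run(s$argv, s$io)
    elapsed <- proc.time()[["elapsed"]] - t0
    log[[length(log) + 1L]] <- data.frame(
      stage = s$name, argv = paste(s$argv, collapse = " "),
      status = as.integer(status), elapsed_sec = elapsed,
      stringsAsFactors = FALSE)
    if (status != 0L) {
      res <- do.call(rbind, log)
      cond <- structure(
        class = c("stage_failure", "error", "condition"),
        list(message = sprintf("stage '%s' failed with status %d", s$name,
                               status),
             call = NULL, stage = s$name, log = res))
      stop(cond)
    }
  }
  do.call(rbind, log)
}
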