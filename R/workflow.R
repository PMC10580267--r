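# Workflow templates: a JSON dialect with `${params.path}` interpolation,
# a required-value sentinel, ordered command records, and resumable
# execution.
#
# Template schema:
#   {
#     "meta": {"name": ..., "version": ...},
#     "params": { nested maps whose leaves are values or "__REQUIRED__" },
#     "commands": [
#       {"program": ..., "arguments": [...], "active": true, "order": 1},
#       ...
#     ]
#   }
# Placeholders `${params.a.b}` may appear in command arguments and in
# param leaves themselves; references among params are resolved in
# topological order and reference cycles are rejected. Every error names
# the offending JSON path.

#' The sentinel marking a template parameter the user must fill
#' @export
REQUIRED <- "__REQUIRED__"

#' Load a workflow template from JSON
#'
#' @param path Path to a template JSON file.
#' @return A `workflow_template` list (`meta`, `params`, `commands`).
#' @export
load_workflow_template <- function(path) {
  t <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_workflow_template(t)
}

#' Validate a workflow template list
#'
#' @param t A list following the template schema.
#' @return The template, classed `workflow_template`.
#' @export
as_workflow_template <- function(t) {
  if (is.null(t$commands) || length(t$commands) == 0L) {
    stop("template has no commands")
  }
  orders <- vapply(t$commands, function(cmd) {
    if (is.null(cmd$order)) stop("every command needs an 'order' field")
    as.integer(cmd$order)
  }, integer(1))
  if (any(orders < 1L)) stop("command order indices must be >= 1")
  if (anyDuplicated(orders)) {
    stop(sprintf("duplicate command order indices: %s",
                 paste(orders[duplicated(orders)], collapse = ", ")))
  }
  for (cmd in t$commands) {
    if (is.null(cmd$program) || !nzchar(cmd$program)) {
      stop("every command needs a non-empty 'program'")
    }
  }
  t$params <- t$params %||% list()
  structure(t, class = "workflow_template")
}

flatten_params <- function(params, prefix = "params") {
  out <- list()
  for (key in names(params)) {
    path <- paste0(prefix, ".", key)
    v <- params[[key]]
    if (is.list(v)) {
      out <- c(out, flatten_params(v, path))
    } else {
      out[[path]] <- v
    }
  }
  out
}

set_by_path <- function(params, path, value) {
  keys <- strsplit(sub("^params\\.", "", path), ".", fixed = TRUE)[[1L]]
  rec <- function(node, keys) {
    if (length(keys) == 1L) {
      node[[keys]] <- value
      return(node)
    }
    if (is.null(node[[keys[[1L]]]])) node[[keys[[1L]]]] <- list()
    node[[keys[[1L]]]] <- rec(node[[keys[[1L]]]], keys[-1L])
    node
  }
  rec(params, keys)
}

placeholder_refs <- function(s) {
  if (!is.character(s)) return(character(0))
  m <- gregexpr("\\$\\{([^}]+)\\}", s)[[1L]]
  if (m[1L] == -1L) return(character(0))
  raw <- regmatches(s, gregexpr("\\$\\{([^}]+)\\}", s))[[1L]]
  sub("^\\$\\{", "", sub("\\}$", "", raw))
}

substitute_placeholders <- function(s, values, context) {
  for (ref in placeholder_refs(s)) {
    if (is.null(values[[ref]])) {
      stop(sprintf("dangling placeholder '${%s}' in %s", ref, context))
    }
    s <- gsub(paste0("${", ref, "}"), as.character(values[[ref]]), s,
              fixed = TRUE)
  }
  s
}

#' Required parameter paths of a template
#'
#' Lists the JSON paths (e.g. `params.sample.r1`) whose leaves carry the
#' required sentinel and therefore must be filled at instantiation. This
#' is what `workflow inspect` prints.
#'
#' @param t A `workflow_template`.
#' @return Character vector of parameter paths.
#' @export
workflow_required_leaves <- function(t) {
  flat <- flatten_params(t$params)
  names(flat)[vapply(flat, identical, logical(1), REQUIRED)]
}

#' Instantiate a workflow template
#'
#' Overlays `fills` onto the template parameters, verifies that every
#' required leaf is filled, resolves `${params.path}` references among
#' parameters in topological order (cycles are an error), substitutes
#' placeholders into the command arguments, and returns the execution
#' plan: active commands sorted by their order index, inactive commands
#' listed as skipped. Instantiation is deterministic, and idempotent in
#' the sense that re-instantiating with the resolved parameters as fills
#' reproduces the same plan.
#'
#' @param t A `workflow_template`.
#' @param fills Named list/vector of parameter fills keyed by path, e.g.
#'   `list("params.sample.r1" = "a_R1.fastq")`.
#' @return A `workflow_plan`: list with `commands` (resolved, ascending
#'   order), `skipped`, and the resolved `params`.
#' @export
instantiate_template <- function(t, fills = list()) {
  t <- as_workflow_template(unclass(t))
  params <- t$params
  for (path in names(fills)) {
    if (!startsWith(path, "params.")) {
      stop(sprintf("fill key '%s' must start with 'params.'", path))
    }
    flat <- flatten_params(params)
    if (is.null(flat[[path]])) {
      stop(sprintf("fill key '%s' does not name a template parameter", path))
    }
    params <- set_by_path(params, path, fills[[path]])
  }

  flat <- flatten_params(params)
  required <- names(flat)[vapply(flat, identical, logical(1), REQUIRED)]
  if (length(required)) {
    stop(sprintf("required parameter(s) not filled: %s",
                 paste(required, collapse = ", ")))
  }

  # Resolve references among params in topological order.
  deps <- lapply(flat, placeholder_refs)
  for (path in names(deps)) {
    missing <- setdiff(deps[[path]], names(flat))
    if (length(missing)) {
      stop(sprintf("dangling placeholder '${%s}' in %s", missing[[1L]],
                   path))
    }
  }
  resolved <- list()
  pending <- names(flat)
  while (length(pending)) {
    ready <- pending[vapply(pending, function(p) {
      length(setdiff(deps[[p]], names(resolved))) == 0L
    }, logical(1))]
    if (length(ready) == 0L) {
      stop(sprintf("parameter reference cycle involving: %s",
                   paste(sort(pending), collapse = ", ")))
    }
    for (p in ready) {
      v <- flat[[p]]
      if (is.character(v)) {
        v <- substitute_placeholders(v, resolved, context = p)
      }
      resolved[[p]] <- v
    }
    pending <- setdiff(pending, ready)
  }

  active <- list()
  skipped <- list()
  for (cmd in t$commands) {
    is_active <- is.null(cmd$active) || isTRUE(cmd$active)
    rec <- list(program = cmd$program,
                arguments = vapply(cmd$arguments %||% list(), function(a) {
                  substitute_placeholders(
                    as.character(a), resolved,
                    context = sprintf("command order %d", as.integer(cmd$order)))
                }, character(1)),
                order = as.integer(cmd$order))
    if (is_active) {
      active[[length(active) + 1L]] <- rec
    } else {
      skipped[[length(skipped) + 1L]] <- rec
    }
  }
  active <- active[order(vapply(active, `[[`, integer(1), "order"))]

  params_resolved <- params
  for (p in names(resolved)) {
    params_resolved <- set_by_path(params_resolved, p, resolved[[p]])
  }
  structure(list(commands = active, skipped = skipped,
                 params = params_resolved,
                 meta = t$meta %||% list()),
            class = "workflow_plan")
}

#' @export
print.workflow_plan <- function(x, ...) {
  cat(sprintf("<workflow_plan> %d command(s), %d skipped\n",
              length(x$commands), length(x$skipped)))
  for (cmd in x$commands) {
    cat(sprintf("  [%d] %s %s\n", cmd$order, cmd$program,
                paste(cmd$arguments, collapse = " ")))
  }
  invisible(x)
}

default_internal_dispatch <- function() {
  list(
    xform = function(args) { cli_xform(args); 0L },
    index = function(args) { cli_index(args); 0L },
    quant = function(args) { cli_quant(args); 0L },
    fixtures = function(args) { cli_fixtures(args); 0L })
}

#' Execute an instantiated workflow
#'
#' Runs the plan's commands in ascending order. Programs named like the
#' package's own subcommands (`xform`, `index`, `quant`, `fixtures`) are
#' dispatched in-process; anything else is handed to the executor (by
#' default a shell). When `marker_dir` is given, a per-command completion
#' marker (`<order>.done`) is written after each success; with
#' `resume = TRUE`, commands whose marker already exists are not
#' re-executed. A failing command aborts the run.
#'
#' @param plan A `workflow_plan` from [instantiate_template()].
#' @param executor Executor for external programs (see
#'   [shell_executor()]).
#' @param marker_dir Directory for completion markers; required when
#'   `resume = TRUE`.
#' @param resume Skip commands with an existing completion marker.
#' @param internal Named list of in-process handlers
#'   (`function(arguments) -> status`); defaults to the package's
#'   subcommand handlers.
#' @return A data.frame run log (`order`, `program`, `dispatch`,
#'   `status`), where `dispatch` is `internal`, `external`, or
#'   `resumed`.
#' @export
execute_workflow <- function(plan, executor = shell_executor(),
                             marker_dir = NULL, resume = FALSE,
                             internal = default_internal_dispatch()) {
  stopifnot(inherits(plan, "workflow_plan"))
  if (resume && is.null(marker_dir)) {
    stop("resume requires marker_dir")
  }
  if (!is.null(marker_dir)) {
    dir.create(marker_dir, recursive = TRUE, showWarnings = FALSE)
  }
  log <- list()
  for (cmd in plan$commands) {
    marker <- if (!is.null(marker_dir)) {
      file.path(marker_dir, sprintf("%d.done", cmd$order))
    }
    if (resume && !is.null(marker) && file.exists(marker)) {
      log[[length(log) + 1L]] <- data.frame(
        order = cmd$order, program = cmd$program, dispatch = "resumed",
        status = 0L, stringsAsFactors = FALSE)
      next
    }
    if (cmd$program %in% names(internal)) {
      status <- internal[[cmd$program]](cmd$arguments)
      dispatch <- "internal"
    } else {
      status <- executor$run(c(cmd$program, cmd$arguments))
      dispatch <- "external"
    }
    log[[length(log) + 1L]] <- data.frame(
      order = cmd$order, program = cmd$program, dispatch = dispatch,
      status = as.integer(status), stringsAsFactors = FALSE)
    if (status != 0L) {
      stop(sprintf("workflow command %d ('%s') failed with status %d",
                   cmd$order, cmd$program, status))
    }
    if (!is.null(marker)) file.create(marker)
  }
  do.call(rbind, log)
}
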