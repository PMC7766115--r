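TRACE_SCHEMA_VERSION <- 1L

#' Write / read ejection traces (JSON-lines)
#'
#' One trace per file: a header record (schema version, condition, seed,
#' completion summary) followed by one record per entrance-plane crossing
#' and one per `(t, m)` sample.  The format is plain text, diffable, and
#' round-trips exactly: `read_trace(write_trace(x)) == x`.
#'
#' @param trace An [ejection_trace()].
#' @param path File path (conventionally `run-<id>.jsonl`).
#' @return `write_trace()` returns `path` invisibly; `read_trace()`
#'   returns the [ejection_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ejection_trace"))
  header <- list(
    type = "header", schema_version = TRACE_SCHEMA_VERSION,
    run_id = trace$run_id, seed = trace$seed,
    N = trace$N, D = if (is.infinite(trace$D)) "Inf" else trace$D,
    phi0 = trace$phi0, Lp = trace$Lp, m0 = trace$m0,
    tau_total = trace$tau_total, head_exit_time = trace$head_exit_time,
    completed = trace$completed, provenance = trace$provenance
  )
  lines <- c(
    jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, null = "null",
                     na = "null"),
    vapply(seq_len(nrow(trace$events)), function(i) {
      jsonlite::toJSON(list(type = "event", time = trace$events$time[i],
                            bead = trace$events$bead[i],
                            dir = trace$events$dir[i]),
                       auto_unbox = TRUE, digits = NA)
    }, character(1)),
    vapply(seq_len(nrow(trace$samples)), function(i) {
      jsonlite::toJSON(list(type = "sample", time = trace$samples$time[i],
                            m = trace$samples$m[i]),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty trace file: ", path, call. = FALSE)
  recs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i]),
             error = function(e) {
               stop(sprintf("partial or corrupt trace %s at line %d: %s",
                            path, i, conditionMessage(e)), call. = FALSE)
             })
  })
  hd <- recs[[1]]
  if (!identical(hd$type, "header")) {
    stop("trace file must start with a header record: ", path, call. = FALSE)
  }
  if (!identical(as.integer(hd$schema_version), TRACE_SCHEMA_VERSION)) {
    stop(sprintf("trace schema version %s unsupported (expected %d): %s",
                 hd$schema_version, TRACE_SCHEMA_VERSION, path), call. = FALSE)
  }
  types <- vapply(recs[-1], function(r) r$type %||% "", character(1))
  ev <- recs[-1][types == "event"]
  sm <- recs[-1][types == "sample"]
  events <- tibble::tibble(
    time = vapply(ev, function(r) as.numeric(r$time), numeric(1)),
    bead = vapply(ev, function(r) as.integer(r$bead), integer(1)),
    dir = vapply(ev, function(r) as.character(r$dir), character(1))
  )
  samples <- tibble::tibble(
    time = vapply(sm, function(r) as.numeric(r$time), numeric(1)),
    m = vapply(sm, function(r) as.integer(r$m), integer(1))
  )
  ejection_trace(
    run_id = hd$run_id, seed = hd$seed %||% NA_integer_,
    N = hd$N, D = as.numeric(hd$D), phi0 = hd$phi0, Lp = hd$Lp,
    events = events, samples = samples, m0 = hd$m0,
    tau_total = hd$tau_total %||% NA_real_,
    head_exit_time = hd$head_exit_time %||% NA_real_,
    completed = isTRUE(hd$completed),
    provenance = hd$provenance %||% "simulation"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an ensemble directory
#'
#' `write_ensemble()` writes one `run-<id>.jsonl` per trace plus a
#' `manifest.csv` indexing the runs; `read_ensemble()` loads every trace
#' file in a directory.
#'
#' @param traces An [ejection_ensemble()].
#' @param dir Directory (created if needed).
#' @return `write_ensemble()` the manifest tibble (invisibly);
#'   `read_ensemble()` an [ejection_ensemble()].
#' @export
write_ensemble <- function(traces, dir) {
  stopifnot(inherits(traces, "ejection_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mani <- purrr::map_dfr(traces, function(tr) {
    file <- sprintf("run-%04d.jsonl", tr$run_id)
    write_trace(tr, file.path(dir, file))
    tibble::tibble(
      run_id = tr$run_id, seed = tr$seed, N = tr$N,
      D = tr$D, phi0 = tr$phi0, Lp = tr$Lp,
      completed = tr$completed, tau_total = tr$tau_total,
      n_events = nrow(tr$events), file = file
    )
  })
  utils::write.csv(mani, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(mani)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.jsonl$", full.names = TRUE))
  if (length(files) == 0) stop("no trace files in ", dir, call. = FALSE)
  ejection_ensemble(lapply(files, read_trace))
}

#' Stable configuration hash
#'
#' FNV-1a hash of the canonical (name-sorted, formatted) representation of
#' a configuration list; invariant under key reordering, used to tie trace
#' files to the configuration that produced them.
#'
#' @param config A list (e.g. a [sim_config()]).
#' @return An 8-hex-digit character scalar.
#' @export
config_hash <- function(config) {
  config <- unclass(config)
  config <- config[order(names(config))]
  canon <- paste(names(config),
                 vapply(config, function(v) paste(format(v, digits = 15),
                                                  collapse = ","),
                        character(1)),
                 sep = "=", collapse = ";")
  bytes <- utf8ToInt(canon)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (byte-sized input), arithmetic kept in
    # doubles to stay clear of 32-bit integer overflow
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime, split to keep every
    # intermediate below 2^53
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
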