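#' Read and write current traces as CSV
#'
#' Traces are written as two-column CSV (`time_ms`, `current_pA`) preceded by
#' a sidecar metadata block of `# key: value` comment lines carrying the
#' capacitance, seed and stimulus protocol, so a trace round-trips through
#' disk with its provenance.
#'
#' @param trace a [new_current_trace()].
#' @param path file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns a
#'   `current_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  meta <- c(capacitance = attr(trace, "capacitance"),
            seed = attr(trace, "seed"))
  proto <- attr(trace, "protocol")
  if (!is.null(proto)) {
    meta <- c(meta, unlist(unclass(proto)))
  }
  meta <- meta[!vapply(meta, is.null, logical(1))]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), ": ", unname(meta)), con)
  writeLines("time_ms,current_pA", con)
  writeLines(paste(trace$time_ms, trace$current_pA, sep = ","), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- suppressWarnings(as.numeric(kv[2]))
  }
  df <- utils::read.csv(text = lines[!grepl("^#", lines)])
  proto_fields <- c("gaba_concentration", "pulse_start", "pulse_duration",
                    "record_duration", "zinc_concentration",
                    "zinc_preapplication", "exchange_time", "sample_rate_khz")
  proto <- NULL
  if (all(proto_fields %in% names(meta))) {
    proto <- do.call(stimulus_protocol, meta[proto_fields])
  }
  new_current_trace(df$time_ms, df$current_pA,
                    capacitance = meta$capacitance %||% NA_real_,
                    protocol = proto,
                    seed = as.integer(meta$seed %||% NA_integer_))
}

#' Read a kinetic scheme and stimulus protocol from a config file
#'
#' The config is YAML key/value pairs with two optional top-level sections,
#' `scheme:` and `protocol:`, whose entries are passed to [kinetic_scheme()]
#' and [stimulus_protocol()]; unknown keys are rejected.
#'
#' @param path path to a YAML file.
#' @return A list with `scheme` and `protocol`.
#' @export
read_scheme_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys <- function(x, fn, what) {
    bad <- setdiff(names(x), names(formals(fn)))
    if (length(bad)) {
      abort(paste0("unknown ", what, " key(s): ", paste(bad, collapse = ", ")),
            class = "gabrisk_bad_config")
    }
  }
  sch <- cfg$scheme %||% list()
  prt <- cfg$protocol %||% list()
  check_keys(sch, kinetic_scheme, "scheme")
  check_keys(prt, stimulus_protocol, "protocol")
  list(scheme = do.call(kinetic_scheme, sch),
       protocol = do.call(stimulus_protocol, prt))
}
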