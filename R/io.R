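#' Plain-text raster, trace and bundle I/O
#'
#' The raster format is two whitespace-separated columns
#' `unit_index spike_time_ms` with 0-based unit indices, preceded by a
#' comment header (`# key value`) carrying `n_units`, `t_total`, `dt`,
#' `lambda` and `p`, plus one `types` line listing the per-unit labels as an
#' `E`/`I` string. Traces and drive series are written as CSV.
#' `write_bundle()` stores a whole simulation as a directory of these
#' plain-text files plus a JSON metadata/config file.
#'
#' @param raster a `lif_raster`.
#' @param path output file / directory path.
#' @param dt,p optional header metadata stored alongside the raster.
#' @return readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_raster <- function(raster, path, dt = NA, p = NA) {
  stopifnot(inherits(raster, "lif_raster"))
  lam <- mean(raster$unit_type == "excitatory")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# n_units", raster$n_units),
    paste("# t_total", format(raster$t_total, digits = 17)),
    paste("# dt", format(dt, digits = 17)),
    paste("# lambda", format(lam, digits = 17)),
    paste("# p", format(p, digits = 17)),
    paste0("# types ", paste(ifelse(raster$unit_type == "excitatory",
                                    "E", "I"), collapse = ""))
  ), con)
  if (length(raster$time)) {
    writeLines(paste(raster$unit - 1L, format(raster$time, digits = 17)), con)
  }
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  kv <- strsplit(sub("^#\\s*", "", lines[hdr]), "\\s+")
  meta <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = " "),
                                 character(1)),
                          vapply(kv, `[[`, character(1), 1))
  types <- strsplit(meta[["types"]], "")[[1]]
  body <- lines[!hdr]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, "\\s+")
    unit <- as.integer(vapply(parts, `[[`, character(1), 1)) + 1L
    time <- as.numeric(vapply(parts, `[[`, character(1), 2))
  } else {
    unit <- integer(0); time <- numeric(0)
  }
  spike_raster(unit, time,
               ifelse(types == "E", "excitatory", "inhibitory"),
               as.numeric(meta[["t_total"]]))
}

#' @rdname write_raster
#' @param trace a `lif_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "lif_trace"))
  df <- data.frame(time_ms = seq_along(trace$values) * trace$dt,
                   potential_mv = trace$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @param label trace label for `read_trace()`.
#' @param t_transient transient marker for `read_trace()`.
#' @export
read_trace <- function(path, label = "LIF", t_transient = 0) {
  df <- utils::read.csv(path)
  dt <- df$time_ms[1]
  potential_trace(df$potential_mv, dt, label, t_transient)
}

#' @rdname write_raster
#' @param drive a `lif_drive`.
#' @export
write_drive <- function(drive, path) {
  stopifnot(inherits(drive, "lif_drive"))
  df <- data.frame(time_ms = seq_len(drive$n_bins) * drive$dt,
                   phi_exc = drive$phi_exc, phi_inh = drive$phi_inh,
                   phi_ext = drive$phi_ext)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_drive <- function(path, t_transient = 0) {
  df <- utils::read.csv(path)
  d <- drive_series(df$phi_exc, df$phi_inh, df$phi_ext, dt = df$time_ms[1])
  attr(d, "t_transient") <- t_transient
  d
}

#' @rdname write_raster
#' @param sim a `lif_simulation`.
#' @param dir bundle directory (created if missing).
#' @export
write_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "lif_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster(sim$raster, file.path(dir, "raster.txt"),
               dt = sim$config$dt, p = sim$config$p_internal)
  write_drive(sim$drive, file.path(dir, "drive.csv"))
  write_trace(sim$trace, file.path(dir, "trace_lif.csv"))
  write_config(sim$config, file.path(dir, "config.json"))
  invisible(dir)
}

#' @rdname write_raster
#' @export
read_bundle <- function(dir) {
  cfg <- read_config(file.path(dir, "config.json"))
  list(raster = read_raster(file.path(dir, "raster.txt")),
       drive = read_drive(file.path(dir, "drive.csv"), cfg$t_transient),
       trace = read_trace(file.path(dir, "trace_lif.csv"), "LIF",
                          cfg$t_transient),
       config = cfg)
}
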