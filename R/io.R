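# File formats -----------------------------------------------------------
#
# Spike table: tab-separated text, one spike per row, header
#   well_id  electrode_id  spike_time_s
# Times are written in seconds with 7 decimals so a written table re-reads
# to well below microsecond accuracy while staying human-diffable.
#
# Raw/sweep container: annotated plain text, one block per trace.  Each block
# is a set of "@key<TAB>value" attribute lines followed by a single "!samples"
# line holding the tab-separated sample values at full (17 significant digit)
# precision, so that a write/read round trip is bit-exact.

#' Write a plate of spike trains to a tab-separated table
#'
#' Rows are ordered deterministically by (well, electrode, time); a header
#' line is always present, so an empty plate produces a header-only file.
#'
#' @param plate A [plate_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_spike_table()]
#' @export
write_spike_table <- function(plate, path) {
  stopifnot(inherits(plate, "plate_recording"))
  rows <- lapply(plate$wells, function(w) {
    trains <- w$trains[order(names(w$trains))]
    do.call(rbind, lapply(trains, function(tr) {
      if (length(tr$spike_times) == 0L) return(NULL)
      data.frame(
        well_id = w$well_id,
        electrode_id = tr$electrode_id,
        spike_time_s = sprintf("%.7f", tr$spike_times),
        stringsAsFactors = FALSE
      )
    }))
  })
  rows <- rows[order(names(plate$wells))]
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(well_id = character(), electrode_id = character(),
                      spike_time_s = character())
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spike table into a plate recording
#'
#' Wells with no rows in the file are absent from the result; an electrode
#' present in the file always yields a train, and spike times are sorted.
#'
#' @param path Path to a tab-separated spike table with columns `well_id`,
#'   `electrode_id`, `spike_time_s`.
#' @param duration Recording duration in seconds, shared by all wells.  Any
#'   spike time outside `[0, duration]` is a validation error naming the
#'   offending line.
#' @param plate_id Identifier given to the returned plate.
#' @return A [plate_recording()].
#' @export
read_spike_table <- function(path, duration, plate_id = "P01") {
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  needed <- c("well_id", "electrode_id", "spike_time_s")
  if (!all(needed %in% names(tab))) {
    stop("spike table must have columns well_id, electrode_id, spike_time_s",
         call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    return(plate_recording(list(), plate_id = plate_id))
  }
  t_s <- suppressWarnings(as.numeric(tab$spike_time_s))
  bad <- which(is.na(t_s) | tab$well_id == "" | tab$electrode_id == "")
  if (length(bad)) {
    stop(sprintf("malformed spike table row at line %d of %s",
                 bad[1L] + 1L, path), call. = FALSE)
  }
  out_of_range <- which(t_s < 0 | t_s > duration)
  if (length(out_of_range)) {
    stop(sprintf(
      "spike time %.7f at line %d of %s outside [0, %g]",
      t_s[out_of_range[1L]], out_of_range[1L] + 1L, path, duration
    ), call. = FALSE)
  }
  wells <- lapply(split(seq_len(nrow(tab)), tab$well_id), function(idx) {
    wid <- tab$well_id[idx[1L]]
    trains <- lapply(split(idx, tab$electrode_id[idx]), function(j) {
      # the table stores times at 0.1 us resolution; rows that coincide at
      # that resolution collapse to one spike
      spike_train(unique(sort(t_s[j])), duration = duration,
                  electrode_id = tab$electrode_id[j[1L]], well_id = wid)
    })
    well_recording(unname(trains), well_id = wid,
                   n_electrodes = max(12L, length(trains)))
  })
  plate_recording(unname(wells), plate_id = plate_id)
}

# shared writer for the annotated text container
write_container_blocks <- function(blocks, path, kind) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# netburst %s container v1", kind), con)
  for (b in blocks) {
    for (k in names(b$attrs)) {
      writeLines(sprintf("@%s\t%s", k, b$attrs[[k]]), con)
    }
    writeLines(paste0("!samples\t",
                      paste(sprintf("%.17g", b$samples), collapse = "\t")),
               con)
  }
  invisible(path)
}

read_container_blocks <- function(path, kind) {
  lines <- readLines(path)
  if (length(lines) == 0L ||
      !grepl(sprintf("^# netburst %s container", kind), lines[1L])) {
    stop(sprintf("not a netburst %s container: %s", kind, path), call. = FALSE)
  }
  blocks <- list()
  attrs <- list()
  for (ln in lines[-1L]) {
    if (startsWith(ln, "@")) {
      kv <- strsplit(sub("^@", "", ln), "\t", fixed = TRUE)[[1L]]
      attrs[[kv[1L]]] <- kv[2L]
    } else if (startsWith(ln, "!samples")) {
      vals <- strsplit(ln, "\t", fixed = TRUE)[[1L]][-1L]
      blocks[[length(blocks) + 1L]] <-
        list(attrs = attrs, samples = as.numeric(vals))
      attrs <- list()
    }
  }
  blocks
}

#' Write raw extracellular traces to the annotated text container
#'
#' One block per electrode carrying `electrode_id` and `sampling_rate`
#' attributes; samples are stored at 17 significant digits so the round trip
#' is bit-exact.
#'
#' @param traces A list of [raw_trace()] objects (a single trace is accepted).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raw_recording <- function(traces, path) {
  if (inherits(traces, "raw_trace")) traces <- list(traces)
  stopifnot(all(vapply(traces, inherits, TRUE, "raw_trace")))
  blocks <- lapply(traces, function(tr) {
    list(attrs = list(electrode_id = tr$electrode_id,
                      sampling_rate = sprintf("%.17g", tr$sampling_rate)),
         samples = tr$samples)
  })
  write_container_blocks(blocks, path, "raw")
}

#' Read raw extracellular traces from the annotated text container
#'
#' @param path Path written by [write_raw_recording()].
#' @return A named list of [raw_trace()] objects (names are electrode ids).
#' @export
read_raw_recording <- function(path) {
  blocks <- read_container_blocks(path, "raw")
  traces <- lapply(blocks, function(b) {
    if (is.null(b$attrs$sampling_rate)) {
      stop("trace block missing sampling_rate attribute", call. = FALSE)
    }
    if (is.null(b$attrs$electrode_id)) {
      stop("trace block missing electrode_id attribute", call. = FALSE)
    }
    raw_trace(b$samples, as.numeric(b$attrs$sampling_rate),
              electrode_id = b$attrs$electrode_id)
  })
  names(traces) <- vapply(traces, function(t) t$electrode_id, "")
  traces
}

#' Write patch-clamp sweeps to the annotated text container
#'
#' @param sweeps List of [ephys_sweep()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_set <- function(sweeps, path) {
  if (inherits(sweeps, "sweep")) sweeps <- list(sweeps)
  stopifnot(all(vapply(sweeps, inherits, TRUE, "sweep")))
  blocks <- lapply(sweeps, function(s) {
    list(attrs = list(sampling_rate = sprintf("%.17g", s$sampling_rate),
                      stim_time = sprintf("%.17g", s$stim_time),
                      holding_potential = sprintf("%.17g", s$holding_potential)),
         samples = s$samples)
  })
  write_container_blocks(blocks, path, "sweep")
}

#' Read patch-clamp sweeps from the annotated text container
#'
#' @param path Path written by [write_sweep_set()].
#' @return A list of [ephys_sweep()] objects.
#' @export
read_sweep_set <- function(path) {
  blocks <- read_container_blocks(path, "sweep")
  lapply(blocks, function(b) {
    if (is.null(b$attrs$sampling_rate)) {
      stop("sweep block missing sampling_rate attribute", call. = FALSE)
    }
    ephys_sweep(b$samples, as.numeric(b$attrs$sampling_rate),
          stim_time = as.numeric(b$attrs$stim_time),
          holding_potential = as.numeric(b$attrs$holding_potential))
  })
}
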