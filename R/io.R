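# Delimited-table interchange for every input/output class. Traces travel as
# long-format CSV with their sampling metadata in columns.

#' Write / read isotopomer samples as a long-format table
#'
#' Columns: `subject`, `tissue`, `kind` (`conc` | `enrich` | `glc_c1`),
#' `key`, `value`.
#'
#' @param samples list of [isotopomer_sample()] objects.
#' @param path CSV path.
#' @return `read_isotopomer_table()` returns a list of samples;
#'   `write_isotopomer_table()` the path, invisibly.
#' @export
write_isotopomer_table <- function(samples, path) {
  rows <- do.call(rbind, lapply(samples, function(s) {
    rbind(
      data.frame(subject = s$id, tissue = s$tissue, kind = "conc",
                 key = names(s$conc), value = unname(s$conc)),
      data.frame(subject = s$id, tissue = s$tissue, kind = "enrich",
                 key = names(s$enrich), value = unname(s$enrich)),
      data.frame(subject = s$id, tissue = s$tissue, kind = "glc_c1",
                 key = "glc_c1", value = s$glc_c1))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_isotopomer_table
#' @export
read_isotopomer_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "tissue", "kind", "key", "value")
  if (!all(need %in% names(d))) {
    stop("expected columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  lapply(split(d, d$subject), function(ds) {
    conc <- ds$value[ds$kind == "conc"]
    names(conc) <- ds$key[ds$kind == "conc"]
    enr <- ds$value[ds$kind == "enrich"]
    names(enr) <- ds$key[ds$kind == "enrich"]
    isotopomer_sample(conc, enr, glc_c1 = ds$value[ds$kind == "glc_c1"][1],
                      tissue = ds$tissue[1], id = ds$subject[1])
  })
}

#' Write a flux table to CSV
#'
#' @param ft data.frame from [flux_table()].
#' @param path CSV path.
#' @export
write_flux_table <- function(ft, path) {
  utils::write.csv(ft, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a sweep set as long-format CSV
#'
#' Columns `sweep`, `current`, `t`, `v`; sampling metadata rides in the
#' first rows' attributes columns (`fs`, `onset`, `offset`).
#'
#' @param ss a [sweep_set()].
#' @param path CSV path.
#' @export
write_sweeps <- function(ss, path) {
  long <- do.call(rbind, lapply(seq_along(ss$currents), function(j) {
    data.frame(sweep = j, current = ss$currents[j], t = ss$time,
               v = ss$voltage[, j], fs = ss$fs, onset = ss$onset,
               offset = ss$offset)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(path) {
  d <- utils::read.csv(path)
  sweeps <- split(d, d$sweep)
  t0 <- sweeps[[1]]$t
  v <- vapply(sweeps, function(s) s$v, numeric(length(t0)))
  currents <- vapply(sweeps, function(s) s$current[1], numeric(1))
  sweep_set(t0, v, currents, fs = d$fs[1], onset = d$onset[1],
            offset = d$offset[1])
}

#' Write / read an event series as CSV
#'
#' @param es an [event_series()].
#' @param path CSV path.
#' @export
write_event_series <- function(es, path) {
  d <- as.data.frame(es)
  d$cell <- attr(es, "cell")
  d$condition <- attr(es, "condition")
  d$duration <- attr(es, "duration")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_series
#' @export
read_event_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_series(d$onset, d$amplitude, cell = d$cell[1],
               condition = d$condition[1], duration = d$duration[1])
}

#' Read a trajectory CSV into a track
#'
#' @param path CSV with columns `t`, `x`, `y`.
#' @param arena the arena the track was recorded in.
#' @param fs frame rate, Hz; inferred from the time base when omitted.
#' @export
read_track <- function(path, arena, fs = NULL) {
  d <- utils::read.csv(path)
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$t))
  track(d$t, d$x, d$y, fs = fs, arena = arena)
}

#' Read a Ct table CSV
#'
#' @param path CSV with columns `subject`, `group`, `gene`, `ct`.
#' @param housekeeping housekeeping gene name to attach.
#' @export
read_ct_table <- function(path, housekeeping) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(d, housekeeping = housekeeping,
            class = c("ct_table", "data.frame"))
}
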