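#' Persist a simulation record to a directory
#'
#' Writes a plain-text, replayable representation of a record: the
#' resolved configuration (`config.yaml`), run metadata including the
#' seed (`metadata.json`), one CSV per probe under `probes/`, and
#' optionally long-format CSV snapshot stacks under `snapshots/` (large;
#' off by default).
#'
#' @param record A `sim_record`.
#' @param dir Output directory (created if needed).
#' @param snapshot_fields Snapshot fields to export as CSV (e.g.
#'   `"K_o"`); empty by default.
#' @return `dir`, invisibly.
#' @export
write_record <- function(record, dir, snapshot_fields = character(0)) {
  dir.create(file.path(dir, "probes"), recursive = TRUE, showWarnings = FALSE)
  write_config(record$config, file.path(dir, "config.yaml"))
  meta <- list(seed = record$seed, model_variant = record$model_variant,
               nx = record$domain$nx, ny = record$domain$ny,
               dx = record$domain$dx, probe_dt = record$probe_dt,
               snapshot_dt = record$snapshot_dt,
               total_time = record$config$total_time,
               probes = as.list(setNames(nm = names(record$probes))))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(record$probes)) {
    utils::write.csv(record$probes[[nm]],
                     file.path(dir, "probes", paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (length(snapshot_fields) > 0 && !is.null(record$snapshots)) {
    dir.create(file.path(dir, "snapshots"), showWarnings = FALSE)
    for (f in snapshot_fields) {
      arr <- record$snapshots[[f]]
      long <- tidyr::expand_grid(k = seq_along(record$snapshots$t),
                                 i = seq_len(dim(arr)[1]),
                                 j = seq_len(dim(arr)[2])) |>
        mutate(t = record$snapshots$t[.data$k],
               value = arr[cbind(.data$i, .data$j, .data$k)]) |>
        select("t", "i", "j", "value")
      utils::write.csv(long, file.path(dir, "snapshots", paste0(f, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read back a persisted record
#'
#' Restores the probe series and metadata written by [write_record()]
#' (snapshots are not reloaded). The result supports the probe-level
#' analysis functions ([detect_discharges()], [burst_synchrony()], ...).
#'
#' @param dir Directory written by [write_record()].
#' @return A list of class `sim_record_io` with `probes`, `config`,
#'   `seed` and `metadata`.
#' @export
read_record <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  files <- list.files(file.path(dir, "probes"), pattern = "\\.csv$",
                      full.names = TRUE)
  probes <- lapply(files, function(f) as_tibble(utils::read.csv(f)))
  names(probes) <- sub("\\.csv$", "", basename(files))
  structure(list(probes = probes,
                 config = load_config(file.path(dir, "config.yaml")),
                 seed = meta$seed, metadata = meta),
            class = "sim_record_io")
}
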