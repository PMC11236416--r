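#' Session bundles in the phy/Kilosort convention
#'
#' A session directory holds the spike-sorter outputs needed for tracking,
#' using the phy file semantics with plain-text payloads:
#' \describe{
#'   \item{channel_positions.csv}{`x,z` site coordinates in um, one row per
#'     site in channel order.}
#'   \item{channel_shanks.csv}{optional single `shank` column (0-based).}
#'   \item{cluster_group.tsv}{`cluster_id`, `group` (\"good\" or \"mua\").}
#'   \item{spike_times.csv}{single `time_s` column, seconds.}
#'   \item{spike_clusters.csv}{single `cluster_id` column, parallel to
#'     spike_times.csv.}
#'   \item{mean_waveforms.csv}{long format: `cluster_id`, `channel`, then one
#'     column per sample (`s1`..`sN`), values in uV.}
#'   \item{session.json}{`session_id`, `sample_rate`, optional
#'     `recording_date`.}
#'   \item{stim_table.csv}{optional `image_id`, `trial`, `onset_s` stimulus
#'     presentation table.}
#' }
#'
#' @param session_id character scalar.
#' @param channel_map a [channel_map()].
#' @param cluster_labels data.frame with `cluster_id` and `quality`
#'   (\"good\"/\"mua\").
#' @param mean_waveforms numeric array `[n_clusters, n_channels, n_samples]`
#'   in uV, with cluster ids as first dimnames.
#' @param spike_times named list (by cluster id) of spike times in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param recording_date optional `Date` or string.
#' @param stim_table optional stimulus table.
#' @return an object of class `session_bundle`.
#' @export
session_bundle <- function(session_id, channel_map, cluster_labels,
                           mean_waveforms, spike_times, sample_rate = 30000,
                           recording_date = NULL, stim_table = NULL) {
  allowed <- c("good", "mua")
  cluster_labels$cluster_id <- as.integer(cluster_labels$cluster_id)
  bad <- setdiff(unique(cluster_labels$quality), allowed)
  if (length(bad) > 0) {
    stop(sprintf("unknown quality label(s) %s; allowed labels: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(sQuote(allowed), collapse = ", ")))
  }
  if (nrow(cluster_labels) == 0L) {
    warning(sprintf("session %s has an empty cluster table", session_id))
  }
  if (length(dim(mean_waveforms)) != 3L) {
    stop("mean_waveforms must be a [clusters x channels x samples] array")
  }
  if (dim(mean_waveforms)[2] != nrow(channel_map)) {
    stop(sprintf("waveform array has %d channels but channel map has %d sites",
                 dim(mean_waveforms)[2], nrow(channel_map)))
  }
  wf_ids <- as.integer(dimnames(mean_waveforms)[[1]])
  if (is.null(wf_ids) && dim(mean_waveforms)[1] > 0) {
    stop("mean_waveforms must carry cluster ids as first dimnames")
  }
  missing_lab <- setdiff(wf_ids, cluster_labels$cluster_id)
  if (length(missing_lab) > 0) {
    stop(sprintf("waveform clusters absent from cluster table: %s",
                 paste(missing_lab, collapse = ", ")))
  }
  # clusters without waveforms cannot be localized or matched
  no_wf <- setdiff(cluster_labels$cluster_id, wf_ids)
  if (length(no_wf) > 0) {
    warning(sprintf("dropping %d cluster(s) without mean waveforms", length(no_wf)))
    cluster_labels <- cluster_labels[cluster_labels$cluster_id %in% wf_ids, , drop = FALSE]
  }

  n_samples <- dim(mean_waveforms)[3]
  expected <- round(0.0027 * sample_rate)
  window_deviation <- if (dim(mean_waveforms)[1] > 0) n_samples - expected else 0L
  if (abs(window_deviation) > 1) {
    warning(sprintf(
      "waveform window is %d samples; expected %d (2.7 ms at %g Hz)",
      n_samples, expected, sample_rate))
  }

  structure(list(session_id = as.character(session_id),
                 channel_map = channel_map,
                 cluster_labels = cluster_labels,
                 mean_waveforms = mean_waveforms,
                 spike_times = spike_times,
                 sample_rate = sample_rate,
                 recording_date = recording_date,
                 stim_table = stim_table,
                 window_deviation = window_deviation),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("session %s: %d clusters (%d good), %d channels, %d samples @ %g Hz\n",
              x$session_id, nrow(x$cluster_labels),
              sum(x$cluster_labels$quality == "good"),
              nrow(x$channel_map), dim(x$mean_waveforms)[3], x$sample_rate))
  invisible(x)
}

#' Load a channel map file
#'
#' Reads an `[n_sites x 2]` coordinate table (um) plus an optional shank
#' vector, and applies the origin convention (see [channel_map()]). `path`
#' may be the positions file itself or a session directory containing
#' `channel_positions.csv`.
#'
#' @param path file or session directory.
#' @return a [channel_map()].
#' @export
load_channel_map <- function(path) {
  file <- if (dir.exists(path)) file.path(path, "channel_positions.csv") else path
  if (!file.exists(file)) stop(sprintf("channel map file not found: %s", file))
  pos <- utils::read.csv(file)
  if (ncol(pos) != 2L) {
    stop(sprintf("channel positions must have 2 columns (x, z); got %d", ncol(pos)))
  }
  shank_file <- file.path(dirname(file), "channel_shanks.csv")
  shank <- NULL
  if (file.exists(shank_file)) {
    shank <- utils::read.csv(shank_file)[[1]]
    if (length(shank) != nrow(pos)) stop("channel_shanks.csv length mismatch")
  }
  channel_map(pos[[1]], pos[[2]], shank)
}

#' Load a session directory
#'
#' @param dir session directory written by [write_session()] or any tool
#'   following the same layout.
#' @return a [session_bundle()].
#' @export
load_session <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("session directory not found: %s", dir))
  cm <- load_channel_map(dir)

  meta_file <- file.path(dir, "session.json")
  meta <- if (file.exists(meta_file)) jsonlite::read_json(meta_file, simplifyVector = TRUE)
          else list(session_id = basename(dir), sample_rate = 30000)

  cg_file <- file.path(dir, "cluster_group.tsv")
  if (!file.exists(cg_file)) stop(sprintf("missing cluster_group.tsv in %s", dir))
  cg <- utils::read.delim(cg_file)
  names(cg) <- c("cluster_id", "quality")

  wf_file <- file.path(dir, "mean_waveforms.csv")
  if (!file.exists(wf_file)) stop(sprintf("missing mean_waveforms.csv in %s", dir))
  wf_long <- data.table::fread(wf_file, data.table = FALSE)
  mw <- waveforms_from_long(wf_long, nrow(cm))

  st <- utils::read.csv(file.path(dir, "spike_times.csv"))[[1]]
  sc <- utils::read.csv(file.path(dir, "spike_clusters.csv"))[[1]]
  if (length(st) != length(sc)) stop("spike_times and spike_clusters length mismatch")
  spikes <- split(st, factor(sc, levels = sort(unique(cg$cluster_id))))
  spikes <- lapply(spikes, sort)

  stim_file <- file.path(dir, "stim_table.csv")
  stim <- if (file.exists(stim_file)) utils::read.csv(stim_file) else NULL

  session_bundle(session_id = meta$session_id, channel_map = cm,
                 cluster_labels = cg, mean_waveforms = mw,
                 spike_times = spikes, sample_rate = meta$sample_rate,
                 recording_date = meta$recording_date, stim_table = stim)
}

#' Write a session bundle to a directory
#'
#' @param bundle a [session_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- bundle$channel_map
  data.table::fwrite(data.frame(x = cm$x, z = cm$z),
                     file.path(dir, "channel_positions.csv"))
  data.table::fwrite(data.frame(shank = cm$shank_id),
                     file.path(dir, "channel_shanks.csv"))
  utils::write.table(
    data.frame(cluster_id = bundle$cluster_labels$cluster_id,
               group = bundle$cluster_labels$quality),
    file.path(dir, "cluster_group.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)

  data.table::fwrite(waveforms_to_long(bundle$mean_waveforms),
                     file.path(dir, "mean_waveforms.csv"))

  ids <- rep(as.integer(names(bundle$spike_times)),
             vapply(bundle$spike_times, length, 1L))
  times <- unlist(bundle$spike_times, use.names = FALSE)
  o <- order(times, ids)
  data.table::fwrite(data.frame(time_s = times[o]), file.path(dir, "spike_times.csv"))
  data.table::fwrite(data.frame(cluster_id = ids[o]), file.path(dir, "spike_clusters.csv"))

  meta <- list(session_id = bundle$session_id, sample_rate = bundle$sample_rate)
  if (!is.null(bundle$recording_date)) meta$recording_date <- as.character(bundle$recording_date)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$stim_table)) {
    data.table::fwrite(bundle$stim_table, file.path(dir, "stim_table.csv"))
  }
  invisible(dir)
}

waveforms_to_long <- function(mw) {
  d <- dim(mw)
  if (d[1] == 0L) {
    out <- data.frame(cluster_id = integer(0), channel = integer(0))
    for (s in seq_len(d[3])) out[[paste0("s", s)]] <- numeric(0)
    return(out)
  }
  ids <- as.integer(dimnames(mw)[[1]])
  # rows: cluster-major, then channel
  flat <- matrix(aperm(mw, c(3, 2, 1)), ncol = d[3], byrow = TRUE)
  out <- data.frame(cluster_id = rep(ids, each = d[2]),
                    channel = rep(seq_len(d[2]) - 1L, times = d[1]))
  colnames(flat) <- paste0("s", seq_len(d[3]))
  cbind(out, as.data.frame(flat))
}

waveforms_from_long <- function(wf_long, n_channels) {
  s_cols <- grep("^s[0-9]+$", names(wf_long), value = TRUE)
  n_samples <- length(s_cols)
  ids <- unique(wf_long$cluster_id)
  mw <- array(0, dim = c(length(ids), n_channels, n_samples),
              dimnames = list(as.character(ids), NULL, NULL))
  if (length(ids) == 0L) return(mw)
  # loading must be order independent: index rows explicitly
  ci <- match(wf_long$cluster_id, ids)
  ch <- wf_long$channel + 1L
  if (any(ch < 1L | ch > n_channels)) {
    stop("waveform table references channels outside the channel map")
  }
  vals <- as.matrix(wf_long[, s_cols, drop = FALSE])
  for (r in seq_len(nrow(wf_long))) mw[ci[r], ch[r], ] <- vals[r, ]
  # reorder clusters by id for a canonical in-memory layout
  o <- order(ids)
  mw[o, , , drop = FALSE]
}

#' Save / load a match table
#'
#' Writes one CSV row per matched pair (session ids, unit ids, location,
#' waveform and combined distances, signed z-distance, threshold flag) plus a
#' JSON sidecar (`<path>.json`) holding the run parameters: omega, the z
#' threshold, the drift estimate, and pre/post-correction total EMD costs.
#' Output is bit-stable for identical input.
#'
#' @param match a `unit_match` from [match_sessions()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_matches <- function(match, path) {
  stopifnot(inherits(match, "unit_match"))
  tab <- match$pairs
  tab <- cbind(data.frame(session1 = match$session_ids[1],
                          session2 = match$session_ids[2]), tab)
  data.table::fwrite(tab, path)
  meta <- list(session1 = match$session_ids[1], session2 = match$session_ids[2],
               omega = match$omega, threshold = match$threshold,
               drift_um = if (is.null(match$drift)) NA else match$drift$z_mode,
               total_cost_pre = match$total_cost_pre,
               total_cost_post = match$total_cost_post,
               n_units = c(match$n1, match$n2))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_matches
#' @export
load_matches <- function(path) {
  tab <- data.table::fread(path, data.table = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(tab, "params") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  tab
}

#' Save traced chains as a link table
#'
#' One row per chain link (pair of consecutive sessions), sharing a
#' `chain_id`; a chain spanning k sessions yields k-1 rows.
#'
#' @param chains a chain table from [trace_chains()].
#' @param path output CSV path.
#' @export
save_chains <- function(chains, path) {
  links <- list()
  for (id in unique(chains$chain_id)) {
    ch <- chains[chains$chain_id == id, ]
    ch <- ch[order(ch$position), ]
    if (nrow(ch) < 2L) next
    idx <- seq_len(nrow(ch) - 1L)
    links[[length(links) + 1L]] <- data.frame(
      chain_id = id,
      session1 = ch$session_id[idx], unit1 = ch$unit_id[idx],
      session2 = ch$session_id[idx + 1L], unit2 = ch$unit_id[idx + 1L],
      length = nrow(ch),
      classification = if ("classification" %in% names(ch)) ch$classification[1] else NA_character_)
  }
  out <- if (length(links) > 0) do.call(rbind, links) else
    data.frame(chain_id = integer(0), session1 = character(0), unit1 = integer(0),
               session2 = character(0), unit2 = integer(0), length = integer(0),
               classification = character(0))
  data.table::fwrite(out, path)
  invisible(path)
}
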