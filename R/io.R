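# Readers and writers for the pipeline's external formats: DeepLabCut-dialect
# landmark CSV, Kilosort/Phy spike exports, BED-like bout tables, tidy CSV.

#' Read and write DeepLabCut-dialect landmark CSV
#'
#' The dialect has three header rows — `scorer`, `bodyparts`, `coords` — above
#' a frame-index column and `x`, `y`, `likelihood` triplets per bodypart.
#' Frames map to seconds at `frame_rate` (299 Hz video unless metadata says
#' otherwise). Malformed headers raise an error naming the offending row.
#'
#' @param path CSV path.
#' @param frame_rate Video rate, Hz.
#' @param landmarks Tidy landmark tibble (`frame`, `bodypart`, `x`, `y`,
#'   `likelihood`).
#' @param scorer Scorer name written into the header.
#' @return `read_dlc_landmarks`: tidy tibble `frame`, `time`, `bodypart`,
#'   `x`, `y`, `likelihood`; `write_dlc_landmarks`: `path`, invisibly.
#' @export
read_dlc_landmarks <- function(path, frame_rate = 299) {
  lines <- readLines(path, n = 3)
  if (length(lines) < 3) rlang::abort(sprintf("%s: truncated header (< 3 rows)", path))
  h <- strsplit(lines, ",")
  labels <- c("scorer", "bodyparts", "coords")
  for (i in 1:3) {
    if (!identical(h[[i]][1], labels[i])) {
      rlang::abort(sprintf("%s: header row %d must start with '%s', found '%s'",
                           path, i, labels[i], h[[i]][1]))
    }
  }
  bodyparts <- h[[2]][-1]; coords <- h[[3]][-1]
  if (length(bodyparts) == 0 || length(bodyparts) %% 3 != 0 ||
      !all(coords %in% c("x", "y", "likelihood"))) {
    rlang::abort(sprintf("%s: header rows 2-3 malformed (need x,y,likelihood per bodypart)", path))
  }
  body <- utils::read.csv(path, skip = 3, header = FALSE)
  if (ncol(body) != length(bodyparts) + 1) {
    rlang::abort(sprintf("%s: %d data columns but %d declared in header row 2",
                         path, ncol(body) - 1, length(bodyparts)))
  }
  frame <- as.integer(body[[1]])
  purrr::map_dfr(seq(1, length(bodyparts), by = 3), function(j) {
    tibble::tibble(frame = frame, time = frame / frame_rate,
                   bodypart = bodyparts[j],
                   x = body[[j + 1]], y = body[[j + 2]],
                   likelihood = body[[j + 3]])
  }) |>
    dplyr::arrange(.data$frame, .data$bodypart)
}

#' @rdname read_dlc_landmarks
#' @export
write_dlc_landmarks <- function(landmarks, path, scorer = "synthetic") {
  parts <- unique(landmarks$bodypart)
  wide <- landmarks |>
    tidyr::pivot_wider(id_cols = "frame", names_from = "bodypart",
                       values_from = c("x", "y", "likelihood")) |>
    dplyr::arrange(.data$frame)
  cols <- as.vector(t(outer(parts, c("x", "y", "likelihood"),
                            function(p, c) paste0(c, "_", p))))
  header <- c(
    paste(c("scorer", rep(scorer, 3 * length(parts))), collapse = ","),
    paste(c("bodyparts", rep(parts, each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))), collapse = ",")
  )
  body <- cbind(wide$frame, as.data.frame(wide[, cols]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(body, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and write Kilosort/Phy-style spike exports
#'
#' The export layout is a directory with `spike_times.npy` (per-spike sample
#' indices at the acquisition rate, 30 kHz for Neuropixels),
#' `spike_clusters.npy` (per-spike cluster ids) and `cluster_group.tsv`
#' (curation labels: good / mua / noise). Only well-isolated ("good") units
#' enter analyses by default; a missing curation table keeps every unit with
#' a warning. Spike times are returned in seconds, sorted within unit.
#'
#' @param dir Export directory.
#' @param sample_rate Acquisition rate, Hz (default 30000).
#' @param good_only Keep only "good" units?
#' @param spikes Tibble `unit_id`, `time` (s).
#' @param labels Named character vector of curation labels per unit id;
#'   defaults to "good" for all units in `spikes`.
#' @return `read_phy_spikes`: tibble `unit_id`, `time`, `label`;
#'   `write_phy_spikes`: `dir`, invisibly.
#' @export
read_phy_spikes <- function(dir, sample_rate = 30000, good_only = TRUE) {
  st_path <- file.path(dir, "spike_times.npy")
  sc_path <- file.path(dir, "spike_clusters.npy")
  if (!file.exists(st_path) || !file.exists(sc_path)) {
    rlang::abort(sprintf("%s: missing spike_times.npy / spike_clusters.npy", dir))
  }
  samples <- read_npy(st_path)
  clusters <- read_npy(sc_path)
  if (length(samples) != length(clusters)) {
    rlang::abort(sprintf("%s: %d spike times but %d cluster ids", dir,
                         length(samples), length(clusters)))
  }
  cg_path <- file.path(dir, "cluster_group.tsv")
  if (file.exists(cg_path)) {
    cg <- utils::read.delim(cg_path)
    labels <- stats::setNames(cg$group, cg$cluster_id)
  } else {
    rlang::warn(sprintf("%s: no cluster_group.tsv; treating all units as uncurated", dir))
    labels <- NULL
  }
  out <- tibble::tibble(
    unit_id = as.integer(clusters),
    time = samples / sample_rate,
    label = if (is.null(labels)) "uncurated"
            else as.character(labels[as.character(clusters)])
  ) |>
    dplyr::arrange(.data$unit_id, .data$time)
  if (good_only && !is.null(labels)) {
    out <- dplyr::filter(out, .data$label == "good")
  }
  out
}

#' @rdname read_phy_spikes
#' @export
write_phy_spikes <- function(spikes, dir, sample_rate = 30000, labels = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_npy(round(spikes$time * sample_rate), file.path(dir, "spike_times.npy"),
            dtype = "<i8")
  write_npy(as.integer(spikes$unit_id), file.path(dir, "spike_clusters.npy"),
            dtype = "<u4")
  ids <- sort(unique(spikes$unit_id))
  labels <- labels %||% stats::setNames(rep("good", length(ids)), ids)
  utils::write.table(
    data.frame(cluster_id = as.integer(names(labels)), group = unname(labels)),
    file.path(dir, "cluster_group.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read and write bout tables (BED-like two-column CSV)
#'
#' @param bouts Tibble `onset`, `offset` (s).
#' @param path CSV path.
#' @return `read_bout_table`: tibble `onset`, `offset`; `write_bout_table`:
#'   `path`, invisibly.
#' @export
read_bout_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("onset", "offset") %in% names(df))) {
    rlang::abort(sprintf("%s: bout table needs 'onset' and 'offset' columns", path))
  }
  tibble::as_tibble(df[, c("onset", "offset")])
}

#' @rdname read_bout_table
#' @export
write_bout_table <- function(bouts, path) {
  utils::write.csv(bouts[, c("onset", "offset")], path, row.names = FALSE)
  invisible(path)
}
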