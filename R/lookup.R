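# Project-tree navigation. Wearable trackers store studies and recordings
# under randomly named directories; the lookup table indexes them into
# human-readable rows and is serialized both as a canonical TSV and a
# spreadsheet-compatible CSV.

.lookup_cols <- c("project_id", "project_name", "participant_id",
                  "participant_name", "recording_id", "recording_name",
                  "start_time", "duration_s", "calibration_status", "path")

.empty_lookup <- function() {
  df <- data.frame(matrix(character(), 0L, length(.lookup_cols)),
                   stringsAsFactors = FALSE)
  names(df) <- .lookup_cols
  df$duration_s <- numeric()
  df
}

#' Build a lookup table of all recordings under a directory
#'
#' Scans a project tree for recording directories (any directory holding at
#' least one `segments/<k>/livedata.json.gz`), reads each recording's
#' metadata file, and returns one row per recording sorted by project,
#' participant and recording name. Recordings with unreadable or absent
#' metadata are still included, with fields set to unknown and a warning.
#' The table is serialized beside the data as `lookup.tsv` (canonical) and
#' `lookup.csv` (spreadsheet-compatible).
#'
#' @param root_dir Root of the project tree.
#' @param write Serialize the table into `root_dir` (default `TRUE`).
#' @return A `wg_lookup` data.frame with columns `project_id`,
#'   `project_name`, `participant_id`, `participant_name`, `recording_id`,
#'   `recording_name`, `start_time`, `duration_s`, `calibration_status` and
#'   `path` (relative to `root_dir`). An empty tree yields zero rows.
#' @export
build_lookup <- function(root_dir, write = TRUE) {
  if (!dir.exists(root_dir))
    wg_missing_input(sprintf("root directory not found: %s", root_dir))
  seg_files <- list.files(root_dir, pattern = "^livedata\\.json\\.gz$",
                          recursive = TRUE, full.names = FALSE)
  seg_files <- seg_files[basename(dirname(dirname(seg_files))) == "segments"]
  rec_dirs <- unique(dirname(dirname(dirname(seg_files))))
  if (length(rec_dirs) == 0L) {
    lk <- .empty_lookup()
  } else {
    rows <- lapply(sort(rec_dirs), function(rel) {
      full <- file.path(root_dir, rel)
      mj <- file.path(full, "recording.json")
      meta <- if (file.exists(mj)) .read_meta_json(mj) else {
        warning(sprintf("no readable metadata for recording at %s", rel))
        NULL
      }
      data.frame(
        project_id = as.character(meta$project_id %||% basename(dirname(rel))),
        project_name = as.character(meta$project_name %||% "unknown"),
        participant_id = as.character(meta$participant_id %||% "unknown"),
        participant_name = as.character(meta$participant_name %||% "unknown"),
        recording_id = as.character(meta$recording_id %||% basename(rel)),
        recording_name = as.character(meta$recording_name %||% "unknown"),
        start_time = as.character(meta$start_time %||% "unknown"),
        duration_s = as.numeric(meta$duration_s %||% NA_real_),
        calibration_status = as.character(meta$calibration_status %||% "none"),
        path = rel,
        stringsAsFactors = FALSE
      )
    })
    lk <- do.call(rbind, rows)
    lk <- lk[order(lk$project_name, lk$participant_name, lk$recording_name,
                   lk$recording_id), , drop = FALSE]
    rownames(lk) <- NULL
  }
  class(lk) <- c("wg_lookup", "data.frame")
  attr(lk, "root") <- normalizePath(root_dir)
  if (write) write_lookup(lk, root_dir)
  lk
}

#' Serialize / read a lookup table
#'
#' `write_lookup` writes `lookup.tsv` (canonical: UTF-8, LF, header row)
#' and `lookup.csv` into the directory; `read_lookup` reads the TSV back.
#'
#' @param lookup A `wg_lookup`.
#' @param dir Directory receiving `lookup.tsv` / `lookup.csv`.
#' @export
write_lookup <- function(lookup, dir) {
  num <- function(x) ifelse(is.na(x), "unknown", .num_str(x))
  body <- apply(cbind(lookup[.lookup_cols[1:7]],
                      duration_s = num(lookup$duration_s),
                      lookup[.lookup_cols[9:10]]), 1L, paste,
                collapse = "\t")
  writeLines(c(paste(.lookup_cols, collapse = "\t"), body),
             file.path(dir, "lookup.tsv"), sep = "\n", useBytes = TRUE)
  utils::write.csv(as.data.frame(lookup), file.path(dir, "lookup.csv"),
                   row.names = FALSE, na = "unknown")
  invisible(dir)
}

#' @rdname write_lookup
#' @param path Path to a `lookup.tsv`.
#' @export
read_lookup <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$duration_s <- suppressWarnings(as.numeric(df$duration_s))
  class(df) <- c("wg_lookup", "data.frame")
  attr(df, "root") <- dirname(normalizePath(path))
  df
}

#' Locate a recording through the lookup table
#'
#' Matches `project` against project id or name and `recording` against
#' recording id or name. Exactly one matching row returns that recording's
#' path; no match raises a lookup-miss error listing near matches, and
#' several matches raise an ambiguity error.
#'
#' @param lookup A non-empty `wg_lookup`.
#' @param project Project id or name.
#' @param recording Recording id or name.
#' @return The recording directory path (absolute when the lookup knows its
#'   root, else relative).
#' @export
select_recording <- function(lookup, project, recording) {
  if (nrow(lookup) == 0L) wg_missing_input("lookup table is empty")
  hit <- (lookup$project_id == project | lookup$project_name == project) &
         (lookup$recording_id == recording |
          lookup$recording_name == recording)
  if (sum(hit) == 0L) {
    pool <- unique(c(lookup$recording_id, lookup$recording_name))
    near <- unique(unlist(lapply(c(project, recording), function(q)
      agrep(q, pool, max.distance = 0.3, value = TRUE))))
    wg_missing_input(sprintf(
      "no recording matches project '%s', recording '%s'%s",
      project, recording,
      if (length(near)) paste0("; near matches: ",
                               paste(near, collapse = ", ")) else ""))
  }
  if (sum(hit) > 1L)
    wg_validation_error(sprintf(
      "ambiguous selection: %d recordings match project '%s', recording '%s'",
      sum(hit), project, recording))
  root <- attr(lookup, "root")
  p <- lookup$path[hit]
  if (is.null(root)) p else file.path(root, p)
}

#' @export
print.wg_lookup <- function(x, ...) {
  cat(sprintf("<wg_lookup> %d recording(s) in %d project(s)\n",
              nrow(x), length(unique(x$project_id))))
  if (nrow(x)) print.data.frame(x[, c("project_name", "participant_name",
                                      "recording_name", "recording_id",
                                      "calibration_status", "path")])
  invisible(x)
}
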