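# Event streams: named, contiguous, non-overlapping sequences of labeled
# time intervals annotating a recording, with optional per-label flags.
# Streams come from manual editing, TTL activity, text files, or classifier
# plugins. Manual streams may leave uncoded spans; classifier output must
# cover the full timeline.

.ann_df <- function(start = numeric(), end = numeric(),
                    label = character(), flags = character()) {
  if (length(flags) == 0L) flags <- rep("", length(start))
  data.frame(start = start, end = end, label = label, flags = flags,
             stringsAsFactors = FALSE)
}

.norm_categories <- function(categories) {
  if (is.character(categories))
    categories <- lapply(categories, function(l) list(label = l,
                                                      flags = character()))
  lapply(categories, function(cc)
    list(label = cc$label, flags = as.character(cc$flags %||% character())))
}

.cat_labels <- function(stream)
  vapply(stream$categories, `[[`, "", "label")

.cat_flags <- function(stream, label) {
  i <- match(label, .cat_labels(stream))
  if (is.na(i)) character() else stream$categories[[i]]$flags
}

.split_flags <- function(s) {
  if (!nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1L]]
}

#' Create an event stream
#'
#' @param name Stream name.
#' @param categories Character vector of labels, or a list of
#'   `list(label =, flags =)` entries where `flags` names the flag labels
#'   allowed on annotations of that category.
#' @param source One of `"manual"`, `"ttl"`, `"file"`, `"classifier"`.
#' @param duration_s Recording duration bounding all annotations
#'   (`Inf` when unknown).
#' @param annotations Optional initial annotation data.frame
#'   (`start`, `end`, `label`, `flags`).
#' @param locked Locked streams reject manual edits (TTL-derived streams).
#' @return An `event_stream`.
#' @export
event_stream <- function(name, categories, source = "manual",
                         duration_s = Inf, annotations = .ann_df(),
                         locked = FALSE) {
  stopifnot(source %in% c("manual", "ttl", "file", "classifier"))
  s <- structure(list(
    name = name,
    categories = .norm_categories(categories),
    annotations = annotations,
    source = source,
    locked = locked,
    duration_s = duration_s
  ), class = "event_stream")
  validate_stream(s)
}

#' Validate event-stream invariants
#'
#' Checks that annotations are non-overlapping, ordered by start, lie within
#' `[0, duration_s]`, have `end > start`, carry known labels and only flags
#' valid for their label.
#'
#' @param stream An `event_stream`.
#' @return The stream, invisibly-validated (errors on violation).
#' @export
validate_stream <- function(stream) {
  a <- stream$annotations
  if (nrow(a) == 0L) return(stream)
  o <- order(a$start)
  a <- a[o, , drop = FALSE]
  rownames(a) <- NULL
  if (any(a$end <= a$start))
    wg_validation_error(sprintf("stream '%s': annotation end <= start",
                                stream$name))
  if (any(a$start < 0) || any(a$end > stream$duration_s + 1e-9))
    wg_validation_error(sprintf(
      "stream '%s': annotation outside [0, %g]", stream$name,
      stream$duration_s))
  if (nrow(a) > 1L && any(a$start[-1L] < a$end[-nrow(a)] - 1e-12))
    wg_validation_error(sprintf("stream '%s': overlapping annotations",
                                stream$name))
  labs <- .cat_labels(stream)
  if (!all(a$label %in% labs))
    wg_validation_error(sprintf(
      "stream '%s': unknown label(s) %s", stream$name,
      paste(setdiff(a$label, labs), collapse = ", ")))
  for (i in seq_len(nrow(a))) {
    fl <- .split_flags(a$flags[i])
    bad <- setdiff(fl, .cat_flags(stream, a$label[i]))
    if (length(bad))
      wg_validation_error(sprintf(
        "stream '%s': flag(s) %s not valid for label '%s'",
        stream$name, paste(bad, collapse = ", "), a$label[i]))
  }
  stream$annotations <- a
  stream
}

.check_unlocked <- function(stream) {
  if (isTRUE(stream$locked))
    wg_validation_error(sprintf("stream '%s' is locked", stream$name))
}

#' Add an annotation ending at a clicked time
#'
#' The new annotation spans from the end of the latest annotation ending at
#' or before `t_click` (or from 0 when there is none) up to `t_click`,
#' mirroring timeline-click coding: each click closes the episode that
#' started where the previous one ended.
#'
#' @param stream An unlocked `event_stream`.
#' @param t_click Click time in seconds, inside the recording.
#' @param label Category label for the new annotation.
#' @param flags Optional character vector of flags valid for `label`.
#' @return The updated stream.
#' @export
add_annotation <- function(stream, t_click, label, flags = character()) {
  .check_unlocked(stream)
  if (t_click <= 0 || t_click > stream$duration_s)
    wg_validation_error("t_click outside the recording")
  a <- stream$annotations
  inside <- which(a$start < t_click & t_click < a$end)
  if (length(inside))
    wg_validation_error(sprintf(
      "t_click = %g lies inside annotation [%g, %g)", t_click,
      a$start[inside[1L]], a$end[inside[1L]]))
  prev_end <- a$end[a$end <= t_click]
  start <- if (length(prev_end)) max(prev_end) else 0
  stream$annotations <- rbind(a, .ann_df(start, t_click, label,
                                         paste(flags, collapse = ";")))
  validate_stream(stream)
}

#' Split an annotation at a time
#'
#' The annotation containing `t` strictly in its interior becomes two
#' annotations sharing its label and flags.
#'
#' @param stream An unlocked `event_stream`.
#' @param t Split time, strictly inside an annotation.
#' @return The updated stream.
#' @export
split_annotation <- function(stream, t) {
  .check_unlocked(stream)
  a <- stream$annotations
  i <- which(a$start < t & t < a$end)
  if (length(i) != 1L)
    wg_validation_error("split time is on a boundary or outside all annotations")
  piece <- a[i, , drop = FALSE]
  left <- piece; left$end <- t
  right <- piece; right$start <- t
  stream$annotations <- rbind(a[-i, , drop = FALSE], left, right)
  validate_stream(stream)
}

#' Relabel, remove, or move annotations
#'
#' `relabel_annotation` changes an annotation's category and flags;
#' `remove_annotation` deletes it; `merge_adjacent_equal` fuses touching
#' annotations with equal label and flags; `move_boundary` drags one edge
#' from the sorted set of annotation edges, shifting the shared edge of two
#' adjacent annotations or growing/shrinking a lone annotation against
#' uncoded time. The new position must stay strictly between the
#' neighboring fixed edges.
#'
#' @param stream An unlocked `event_stream`.
#' @param index Annotation index (in start order).
#' @param new_label,new_flags Replacement category and flags.
#' @return The updated stream.
#' @export
relabel_annotation <- function(stream, index, new_label,
                               new_flags = character()) {
  .check_unlocked(stream)
  a <- stream$annotations
  if (index < 1L || index > nrow(a)) wg_validation_error("bad annotation index")
  a$label[index] <- new_label
  a$flags[index] <- paste(new_flags, collapse = ";")
  stream$annotations <- a
  validate_stream(stream)
}

#' @rdname relabel_annotation
#' @export
remove_annotation <- function(stream, index) {
  .check_unlocked(stream)
  a <- stream$annotations
  if (index < 1L || index > nrow(a)) wg_validation_error("bad annotation index")
  stream$annotations <- a[-index, , drop = FALSE]
  validate_stream(stream)
}

#' @rdname relabel_annotation
#' @export
merge_adjacent_equal <- function(stream) {
  a <- stream$annotations
  i <- 1L
  while (i < nrow(a)) {
    if (abs(a$start[i + 1L] - a$end[i]) < 1e-12 &&
        a$label[i + 1L] == a$label[i] && a$flags[i + 1L] == a$flags[i]) {
      a$end[i] <- a$end[i + 1L]
      a <- a[-(i + 1L), , drop = FALSE]
    } else i <- i + 1L
  }
  stream$annotations <- a
  validate_stream(stream)
}

#' @rdname relabel_annotation
#' @param boundary_index Index into the sorted unique set of annotation
#'   edges (starts and ends).
#' @param new_t New edge time in seconds.
#' @export
move_boundary <- function(stream, boundary_index, new_t) {
  .check_unlocked(stream)
  a <- stream$annotations
  edges <- sort(unique(c(a$start, a$end)))
  if (boundary_index < 1L || boundary_index > length(edges))
    wg_validation_error("bad boundary index")
  old <- edges[boundary_index]
  # fixed neighbors: the adjacent distinct edges (or recording limits)
  lo <- if (boundary_index > 1L) edges[boundary_index - 1L] else 0
  hi <- if (boundary_index < length(edges)) edges[boundary_index + 1L]
        else stream$duration_s
  if (new_t <= lo || new_t >= hi)
    wg_validation_error(sprintf(
      "new boundary %g crosses neighboring edge (allowed (%g, %g))",
      new_t, lo, hi))
  a$start[abs(a$start - old) < 1e-12] <- new_t
  a$end[abs(a$end - old) < 1e-12] <- new_t
  stream$annotations <- a
  validate_stream(stream)
}

#' Event stream from TTL activity
#'
#' Under the `"edges"` scheme every TTL event (e.g. a button press) becomes
#' one short annotation starting at the event and lasting one gaze interval
#' (zero-duration edges are widened so the `end > start` invariant holds);
#' under `"levels"` the held signal level spans from each event to the next
#' change, the last level extending to the end of the recording.
#'
#' @param ttl Data.frame with columns `t` (seconds) and `value`, sorted.
#' @param scheme `"edges"` or `"levels"`.
#' @param tick_s One gaze sampling interval in seconds (edge width).
#' @param duration_s Recording duration in seconds.
#' @param name Stream name.
#' @return A locked `event_stream` with `source = "ttl"`; empty when there
#'   is no TTL activity.
#' @export
ttl_stream <- function(ttl, scheme = c("edges", "levels"), tick_s,
                       duration_s, name = "ttl") {
  scheme <- match.arg(scheme)
  if (nrow(ttl) == 0L)
    return(event_stream(name, character(), source = "ttl",
                        duration_s = duration_s, locked = TRUE))
  lab <- as.character(ttl$value)
  if (scheme == "edges") {
    start <- ttl$t
    end <- pmin(start + tick_s, c(start[-1L], duration_s))
    keep <- end > start
    ann <- .ann_df(start[keep], end[keep], lab[keep])
  } else {
    change <- c(TRUE, lab[-1L] != lab[-length(lab)])
    start <- ttl$t[change]
    labv <- lab[change]
    end <- c(start[-1L], duration_s)
    keep <- end > start
    ann <- .ann_df(start[keep], end[keep], labv[keep])
  }
  event_stream(name, unique(ann$label), source = "ttl",
               duration_s = duration_s, annotations = ann, locked = TRUE)
}

# --- text-file import ------------------------------------------------------

#' Load an event stream from a text file
#'
#' Reads a TSV with header `start_s`, `end_s`, `label` and optional `flags`
#' (semicolon-separated). The returned stream remembers the file contents:
#' after manual edits, [reset_stream()] restores exactly the loaded
#' annotations.
#'
#' @param file Path to the TSV.
#' @param categories Allowed categories; derived from the file's labels
#'   when `NULL`.
#' @param duration_s Recording duration bound.
#' @param name Stream name; defaults to the file's base name.
#' @return An `event_stream` with `source = "file"`.
#' @export
load_events_from_text <- function(file, categories = NULL,
                                  duration_s = Inf, name = NULL) {
  if (!file.exists(file)) wg_missing_input(sprintf("event file not found: %s",
                                                   file))
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(df)))
    wg_parse_error(sprintf(
      "event file %s must have header start_s, end_s, label[, flags]", file))
  start <- as.numeric(df$start_s)
  end <- as.numeric(df$end_s)
  if (anyNA(start) || anyNA(end))
    wg_parse_error(sprintf("non-numeric times in event file %s", file))
  o <- order(start)
  if (any(start[o][-1L] < end[o][-length(end)] - 1e-12)) {
    bad <- which(start[o][-1L] < end[o][-length(end)] - 1e-12)
    wg_parse_error(sprintf("overlapping rows in %s (rows %s)", file,
                           paste(sort(c(o[bad], o[bad + 1L])),
                                 collapse = ", ")))
  }
  flags <- if ("flags" %in% names(df)) df$flags else rep("", nrow(df))
  ann <- .ann_df(start, end, df$label, flags)
  if (is.null(categories)) {
    categories <- lapply(unique(ann$label), function(l)
      list(label = l,
           flags = unique(unlist(lapply(
             ann$flags[ann$label == l], .split_flags)))))
  } else {
    categories <- .norm_categories(categories)
    unknown <- setdiff(unique(ann$label),
                       vapply(categories, `[[`, "", "label"))
    if (length(unknown))
      wg_validation_error(sprintf("label(s) not in categories: %s",
                                  paste(unknown, collapse = ", ")))
  }
  s <- event_stream(name %||% tools::file_path_sans_ext(basename(file)),
                    categories, source = "file", duration_s = duration_s,
                    annotations = ann, locked = FALSE)
  attr(s, "file_annotations") <- s$annotations
  s
}

#' Reset a file-derived stream to its loaded annotations
#'
#' @param stream An `event_stream` loaded with [load_events_from_text()].
#' @return The stream with all manual edits discarded.
#' @export
reset_stream <- function(stream) {
  orig <- attr(stream, "file_annotations")
  if (is.null(orig))
    wg_validation_error("stream was not loaded from a file; nothing to reset")
  stream$annotations <- orig
  validate_stream(stream)
}

#' Write an event stream as a text file
#'
#' Serializes in the format read by [load_events_from_text()], with a
#' canonical, deterministic number format.
#'
#' @param stream An `event_stream`.
#' @param file Output TSV path.
#' @export
write_events_text <- function(stream, file) {
  a <- stream$annotations
  num <- .num_str
  lines <- c("start_s\tend_s\tlabel\tflags",
             sprintf("%s\t%s\t%s\t%s", num(a$start), num(a$end),
                     a$label, a$flags))
  writeLines(lines, file, sep = "\n", useBytes = TRUE)
  invisible(file)
}

# --- classifier plugins ----------------------------------------------------

.classifiers <- new.env(parent = emptyenv())

#' Register an event-classification algorithm
#'
#' A classifier is a function taking the full recording plus a named list of
#' parameter values and returning an `event_stream` covering the recording
#' timeline. Registered classifiers can then be invoked through
#' [run_classifier()] with user-settable parameters validated against their
#' allowed ranges.
#'
#' @param name Entry-point name.
#' @param fun `function(recording, params)` returning an `event_stream`.
#' @export
register_classifier <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .classifiers)
  invisible(name)
}

#' @rdname register_classifier
#' @export
list_classifiers <- function() sort(ls(.classifiers))

#' Classifier specification
#'
#' @param id Stream name for the classifier's output.
#' @param entry_point Name of a registered classifier.
#' @param parameters List of `list(name, value, min, max, user_settable)`
#'   entries; each value must lie within `[min, max]`.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(id, entry_point, parameters = list()) {
  for (p in parameters) {
    if (is.null(p$name) || is.null(p$value))
      wg_validation_error("classifier parameter needs name and value")
    if (!is.null(p$min) && p$value < p$min ||
        !is.null(p$max) && p$value > p$max)
      wg_validation_error(sprintf(
        "classifier '%s': parameter '%s' = %g outside [%g, %g]",
        id, p$name, p$value, p$min %||% -Inf, p$max %||% Inf))
  }
  structure(list(id = id, entry_point = entry_point,
                 parameters = parameters),
            class = "classifier_spec")
}

#' Run a registered classifier on a recording
#'
#' Invokes the entry point with the recording and the parameter values of
#' the given [classifier_spec()], validates the returned stream's
#' invariants, and stamps it with `source = "classifier"` and the
#' configured id. Rerunning with changed
#' parameters simply replaces the stream.
#'
#' @param recording A `wg_recording`.
#' @param spec A [classifier_spec()].
#' @return A validated `event_stream`.
#' @export
run_classifier <- function(recording, spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (!exists(spec$entry_point, envir = .classifiers, inherits = FALSE))
    wg_validation_error(sprintf("no classifier registered under '%s'",
                                spec$entry_point))
  fun <- get(spec$entry_point, envir = .classifiers)
  params <- stats::setNames(lapply(spec$parameters, `[[`, "value"),
                            vapply(spec$parameters, `[[`, "", "name"))
  out <- fun(recording, params)
  if (!inherits(out, "event_stream"))
    wg_validation_error(sprintf("classifier '%s' did not return an event stream",
                                spec$entry_point))
  out$name <- spec$id
  out$source <- "classifier"
  tryCatch(validate_stream(out), error = function(e)
    wg_validation_error(sprintf("classifier '%s' returned an invalid stream: %s",
                                spec$entry_point, conditionMessage(e))))
}

#' Built-in slow/fast-phase classifier
#'
#' Splits the gaze timeline into episodes where the eye rotates slowly
#' (fixation, pursuit, VOR) versus rapidly (saccades), by thresholding the
#' smoothed eye speed. Eye speed is the binocular mean of the per-eye
#' [eye_velocity()] traces where both are finite, otherwise the one finite
#' eye; samples with no finite speed are labeled `"missing"`. Runs shorter
#' than the minimum duration for their phase are merged into a neighboring
#' phase (shortest run first; into the longer neighbor, ties to the earlier
#' one); missing spans are never merged. This is a deliberately simple,
#' fully documented velocity-threshold classifier; domain-specific
#' algorithms can be added through [register_classifier()].
#'
#' @param recording A `wg_recording` (kinematics are computed with default
#'   settings if absent).
#' @param velocity_threshold_dps Speed threshold separating slow from fast,
#'   deg/s.
#' @param min_fast_ms,min_slow_ms Minimum episode durations, milliseconds.
#' @return An `event_stream` named `"slow_fast"` covering the full
#'   timeline with labels `slow`, `fast`, `missing`.
#' @export
classify_slow_fast <- function(recording, velocity_threshold_dps = 100,
                               min_fast_ms = 10, min_slow_ms = 40) {
  stopifnot(inherits(recording, "wg_recording"))
  if (is.null(recording$derived))
    recording <- compute_kinematics(recording)
  v <- recording$derived$velocity
  lo <- v$l_omega; ro <- v$r_omega
  omega <- ifelse(is.finite(lo) & is.finite(ro), (lo + ro) / 2,
           ifelse(is.finite(lo), lo, ro))
  lab <- ifelse(!is.finite(omega), "missing",
         ifelse(omega > velocity_threshold_dps, "fast", "slow"))
  dt <- 1 / recording$meta$nominal_gaze_rate_hz
  min_ms <- c(fast = min_fast_ms, slow = min_slow_ms)
  lab <- .merge_short_runs(lab, dt, min_ms)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  ann <- .ann_df(starts * dt, ends * dt, r$values)
  event_stream("slow_fast", c("slow", "fast", "missing"),
               source = "classifier",
               duration_s = length(lab) * dt, annotations = ann)
}

# merge sub-minimum-duration runs into neighbors; missing never participates
.merge_short_runs <- function(lab, dt, min_ms) {
  frozen <- numeric()                        # run start times we gave up on
  repeat {
    r <- rle(lab)
    n <- length(r$values)
    ends <- cumsum(r$lengths)
    starts <- c(0L, ends[-n]) + 1L
    dur_ms <- r$lengths * dt * 1000
    cand <- which(r$values %in% names(min_ms) &
                  dur_ms < min_ms[r$values] - 1e-9 &
                  !(starts %in% frozen))
    if (length(cand) == 0L) break
    cand <- cand[order(dur_ms[cand], starts[cand])]
    i <- cand[1L]
    nb <- c(if (i > 1L && r$values[i - 1L] != "missing") i - 1L,
            if (i < n && r$values[i + 1L] != "missing") i + 1L)
    if (length(nb) == 0L) { frozen <- c(frozen, starts[i]); next }
    j <- nb[which.max(r$lengths[nb])]        # longer neighbor, ties earlier
    lab[starts[i]:ends[i]] <- r$values[j]
  }
  lab
}

# --- coding persistence ----------------------------------------------------

#' Save and load event-stream codings
#'
#' The coding for a recording lives in a single open `coding.json` file in
#' the recording directory; save then load is an identity, and streams
#' added to the file by external tools (e.g. a manual-mapping coder)
#' appear on reload.
#'
#' @param streams A list of `event_stream` objects.
#' @param dir Recording directory.
#' @return `load_coding` returns the list of streams (empty when no coding
#'   file exists).
#' @export
save_coding <- function(streams, dir) {
  payload <- list(streams = lapply(streams, function(s) list(
    name = s$name,
    source = s$source,
    locked = s$locked,
    duration_s = s$duration_s,
    categories = lapply(s$categories, function(cc)
      list(label = cc$label, flags = I(as.character(cc$flags)))),
    annotations = lapply(seq_len(nrow(s$annotations)), function(i) list(
      start_s = s$annotations$start[i],
      end_s = s$annotations$end[i],
      label = s$annotations$label[i],
      flags = I(.split_flags(s$annotations$flags[i]))))
  )))
  jsonlite::write_json(payload, file.path(dir, "coding.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "coding.json"))
}

#' @rdname save_coding
#' @export
load_coding <- function(dir) {
  path <- file.path(dir, "coding.json")
  if (!file.exists(path)) return(list())
  p <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  wg_parse_error(sprintf("corrupt coding file %s: %s", path,
                                         conditionMessage(e))))
  if (is.null(p$streams))
    wg_parse_error(sprintf("coding file %s lacks a 'streams' array", path))
  lapply(p$streams, function(s) {
    ann <- .ann_df(
      vapply(s$annotations, function(a) as.numeric(a$start_s), 0),
      vapply(s$annotations, function(a) as.numeric(a$end_s), 0),
      vapply(s$annotations, function(a) as.character(a$label), ""),
      vapply(s$annotations, function(a)
        paste(unlist(a$flags), collapse = ";"), ""))
    event_stream(s$name,
                 lapply(s$categories, function(cc)
                   list(label = cc$label, flags = unlist(cc$flags))),
                 source = s$source, duration_s = s$duration_s %||% Inf,
                 annotations = ann, locked = isTRUE(s$locked))
  })
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> '%s' (%s%s): %d annotations, %d categories\n",
              x$name, x$source, if (x$locked) ", locked" else "",
              nrow(x$annotations), length(x$categories)))
  if (nrow(x$annotations)) {
    tab <- table(x$annotations$label)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "  "),
        "\n", sep = "")
  }
  invisible(x)
}
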