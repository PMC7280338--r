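# Packet dialect: one JSON object per line, gzip-compressed, one file
# (livedata.json.gz) per segment directory. Keys: ts (microseconds, integer),
# s (status, 0 = valid), gidx (gaze-sample group index), eye ("left"/"right"),
# and exactly one payload key among gd, pc, pd, gp, gp3, gy, ac, vts, sig.

# payload key -> kind, and expected payload length per kind
.payload_key <- c(
  gd  = "gaze_dir",      pc  = "pupil_center", pd = "pupil_diameter",
  gp  = "gaze_point_2d", gp3 = "gaze_point_3d",
  gy  = "gyro",          ac  = "accel",        vts = "vts", sig = "ttl"
)
.payload_len <- c(
  gaze_dir = 3L, pupil_center = 3L, pupil_diameter = 1L,
  gaze_point_2d = 2L, gaze_point_3d = 3L, gyro = 3L, accel = 3L,
  vts = 1L, ttl = 1L
)
.eye_kinds <- c("gaze_dir", "pupil_center", "pupil_diameter")

#' Decode one packet line
#'
#' Parses a single line of the packet dialect into a raw packet. Unknown keys
#' are ignored. A line whose payload key is not recognized yields a skip
#' marker; malformed JSON or a payload of the wrong length yields a
#' recoverable error marker. Neither raises.
#'
#' @param line A length-1 character vector holding one JSON object.
#' @return A list of class `raw_packet` with elements `ts` (microseconds),
#'   `status`, `kind`, `eye` (`"left"`, `"right"` or `"none"`), `gidx`
#'   (`NA` for non-gaze packets) and `payload` (numeric vector); or a list of
#'   class `packet_skip` / `packet_error` describing why the line was not
#'   decodable.
#' @examples
#' decode_packet('{"ts":100000,"s":0,"gidx":7,"eye":"left","gd":[0,0,1]}')
#' @export
decode_packet <- function(line) {
  obj <- tryCatch(jsonlite::fromJSON(line, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(obj) || !is.list(obj))
    return(structure(list(reason = "malformed JSON", line = line),
                     class = "packet_error"))
  .decode_obj(obj, line)
}

# shared by decode_packet and the batch path of read_segment
.decode_obj <- function(obj, line = NULL) {
  pk <- intersect(names(.payload_key), names(obj))
  if (length(pk) != 1L)
    return(structure(list(reason = "unknown or missing payload key"),
                     class = "packet_skip"))
  kind <- .payload_key[[pk]]
  payload <- suppressWarnings(as.numeric(unlist(obj[[pk]], use.names = FALSE)))
  ts <- suppressWarnings(as.numeric(obj$ts))
  if (length(ts) != 1L || !is.finite(ts) || ts < 0 ||
      length(payload) != .payload_len[[kind]] || anyNA(payload))
    return(structure(list(reason = "bad ts or payload length", kind = kind),
                     class = "packet_error"))
  eye <- if (kind %in% .eye_kinds) as.character(obj$eye %||% NA_character_)
         else "none"
  if (kind %in% .eye_kinds && !isTRUE(eye %in% c("left", "right")))
    return(structure(list(reason = "missing eye on per-eye packet"),
                     class = "packet_error"))
  structure(list(
    ts = ts,
    status = as.integer(obj$s %||% 0L),
    kind = kind,
    eye = eye,
    gidx = suppressWarnings(as.numeric(obj$gidx %||% NA_real_)),
    payload = payload
  ), class = "raw_packet")
}

# Packets travel internally as a data.frame: ts, status, kind, eye, gidx,
# p1..p3 (payload, NA-padded). This keeps 10^4-10^5 packets fast in base R.
.packets_df <- function(plist) {
  n <- length(plist)
  p <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    pay <- plist[[i]]$payload
    p[i, seq_along(pay)] <- pay
  }
  data.frame(
    ts     = vapply(plist, `[[`, 0, "ts"),
    status = vapply(plist, `[[`, 0L, "status"),
    kind   = vapply(plist, `[[`, "", "kind"),
    eye    = vapply(plist, `[[`, "", "eye"),
    gidx   = vapply(plist, `[[`, 0, "gidx"),
    p1 = p[, 1L], p2 = p[, 2L], p3 = p[, 3L],
    stringsAsFactors = FALSE
  )
}

.empty_packets <- function() {
  data.frame(ts = numeric(), status = integer(), kind = character(),
             eye = character(), gidx = numeric(),
             p1 = numeric(), p2 = numeric(), p3 = numeric(),
             stringsAsFactors = FALSE)
}

#' Read one segment's packet file
#'
#' Reads a gzip-compressed (or plain) line-delimited JSON packet file and
#' decodes every line. Undecodable lines are dropped and counted, never
#' fatal; an unreadable file is.
#'
#' @param file Path to a `livedata.json.gz` (gzip or plain text).
#' @return A list of class `segment_packets`: `packets` (data.frame with
#'   columns `ts`, `status`, `kind`, `eye`, `gidx`, `p1`..`p3`), `n_total`,
#'   `n_dropped`, `n_skipped` and `per_kind` (named counts).
#' @export
read_segment <- function(file) {
  if (!file.exists(file))
    wg_missing_input(sprintf("packet file not found: %s", file))
  lines <- tryCatch({
    con <- gzfile(file, "rt", encoding = "UTF-8")
    on.exit(close(con))
    readLines(con, warn = FALSE)
  }, error = function(e)
    wg_parse_error(sprintf("cannot read packet file %s: %s",
                           file, conditionMessage(e))))
  lines <- lines[nzchar(lines)]
  n_total <- length(lines)
  if (n_total == 0L)
    return(structure(list(packets = .empty_packets(), n_total = 0L,
                          n_dropped = 0L, n_skipped = 0L,
                          per_kind = integer()),
                     class = "segment_packets"))
  # fast path: the whole file as one JSON array; fall back per line if any
  # line is malformed
  objs <- tryCatch(
    jsonlite::fromJSON(paste0("[", paste(lines, collapse = ","), "]"),
                       simplifyVector = FALSE),
    error = function(e) NULL)
  if (is.null(objs)) {
    decoded <- lapply(lines, decode_packet)
  } else {
    decoded <- lapply(objs, .decode_obj)
  }
  cls <- vapply(decoded, function(x) class(x)[1L], "")
  ok <- decoded[cls == "raw_packet"]
  pk <- if (length(ok)) .packets_df(ok) else .empty_packets()
  structure(list(
    packets   = pk,
    n_total   = n_total,
    n_dropped = sum(cls == "packet_error"),
    n_skipped = sum(cls == "packet_skip"),
    per_kind  = if (nrow(pk)) table(pk$kind) else integer()
  ), class = "segment_packets")
}

# deterministic double formatting that round-trips exactly
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  short <- sprintf("%.15g", x)
  exact <- as.numeric(short) == x
  out[exact] <- short[exact]
  out
}

#' Write a packet stream to a segment file
#'
#' Serializes packets in the dialect read by [read_segment()]. Writing then
#' reading reproduces the stream packet-for-packet, including exact integer
#' timestamps. Output bytes are deterministic (gzip with no embedded
#' timestamp), so identical inputs give identical files.
#'
#' @param packets A packet data.frame as returned in
#'   `read_segment(...)$packets`.
#' @param file Output path; written gzip-compressed.
#' @export
write_segment <- function(packets, file) {
  kinds <- packets$kind
  key <- names(.payload_key)[match(kinds, .payload_key)]
  lines <- character(nrow(packets))
  for (i in seq_len(nrow(packets))) {
    np <- .payload_len[[kinds[i]]]
    pay <- unlist(packets[i, c("p1", "p2", "p3")[seq_len(np)]],
                  use.names = FALSE)
    paystr <- if (np == 1L) .fmt_num(pay)
              else paste0("[", paste(.fmt_num(pay), collapse = ","), "]")
    parts <- c(
      sprintf('"ts":%.0f', packets$ts[i]),
      sprintf('"s":%d', packets$status[i]),
      if (!is.na(packets$gidx[i])) sprintf('"gidx":%.0f', packets$gidx[i]),
      if (packets$eye[i] %in% c("left", "right"))
        sprintf('"eye":"%s"', packets$eye[i]),
      sprintf('"%s":%s', key[i], paystr)
    )
    lines[i] <- paste0("{", paste(parts, collapse = ","), "}")
  }
  ok <- tryCatch({
    con <- gzfile(file, "wb")            # gzip with zeroed mtime: output
    on.exit(close(con))                  # bytes depend only on content
    if (length(lines))
      writeBin(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")), con)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) wg_missing_input(sprintf("cannot write packet file: %s", file))
  invisible(file)
}
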