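#' Calibrated walkway pressure recording
#'
#' A frames x rows x cols tensor of calibrated pressures (Pa) with the
#' frame interval and sensel size needed to integrate it into forces.
#'
#' @param tensor 3D numeric array, frames x rows x cols, pressures >= 0.
#' @param dt Frame interval in seconds.
#' @param cell_size Sensel edge length in metres.
#' @param units Pressure unit label.
#' @return An object of class `pressure_recording`.
#' @export
pressure_recording <- function(tensor, dt = 0.02, cell_size = 0.005,
                               units = "Pa") {
  stopifnot(is.array(tensor), length(dim(tensor)) == 3, dt > 0,
            cell_size > 0)
  if (any(tensor < 0)) stop("pressures must be non-negative")
  structure(list(tensor = tensor, dt = dt, cell_size = cell_size,
                 units = units),
            class = "pressure_recording")
}

#' @export
print.pressure_recording <- function(x, ...) {
  d <- dim(x$tensor)
  cat("<pressure_recording>", d[1], "frames x", d[2], "rows x", d[3],
      "cols @", x$dt, "s,", x$cell_size * 1000, "mm cells\n")
  invisible(x)
}

#' Write / read a pressure recording as a text frame file
#'
#' Plain-text dialect: a header line
#' `# dt=<s> cell=<m> rows=<R> cols=<C> frames=<F>`, then for each frame a
#' line `Frame <k>` followed by R comma-separated rows of C pressures.
#' The round trip is lossless to the 10 significant digits written
#' (exact for integer-scaled pressures).
#'
#' @param rec A [pressure_recording()].
#' @param path File path.
#' @return `write_frames_text` returns `path` invisibly;
#'   `read_frames_text` returns a `pressure_recording`.
#' @export
write_frames_text <- function(rec, path) {
  stopifnot(inherits(rec, "pressure_recording"))
  d <- dim(rec$tensor)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%s cell=%s rows=%d cols=%d frames=%d",
                     format(rec$dt, digits = 10),
                     format(rec$cell_size, digits = 10),
                     d[2], d[3], d[1]), con)
  for (k in seq_len(d[1])) {
    writeLines(paste("Frame", k), con)
    fr <- rec$tensor[k, , , drop = TRUE]
    writeLines(apply(matrix(fr, d[2], d[3]), 1, function(r) {
      paste(format(r, digits = 10, trim = TRUE, scientific = FALSE),
            collapse = ",")
    }), con)
  }
  invisible(path)
}

#' @rdname write_frames_text
#' @param path File path.
#' @export
read_frames_text <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path)
  hd <- lines[1]
  m <- regmatches(hd, regexec(
    "^# dt=([0-9.eE+-]+) cell=([0-9.eE+-]+) rows=(\\d+) cols=(\\d+) frames=(\\d+)$",
    hd))[[1]]
  if (length(m) != 6) stop("missing or malformed header line: ", hd)
  dt <- as.numeric(m[2]); cell <- as.numeric(m[3])
  R <- as.integer(m[4]); C <- as.integer(m[5]); F <- as.integer(m[6])
  expected <- 1 + F * (1 + R)
  if (length(lines) != expected) {
    stop("file has ", length(lines), " lines; expected ", expected,
         " for ", F, " frames of ", R, " rows")
  }
  tensor <- array(0, dim = c(F, R, C))
  pos <- 2L
  for (k in seq_len(F)) {
    if (!grepl("^Frame ", lines[pos])) {
      stop("parse error at frame ", k, ": expected 'Frame ' marker, got '",
           lines[pos], "'")
    }
    block <- lines[pos + seq_len(R)]
    vals <- strsplit(block, ",", fixed = TRUE)
    lens <- lengths(vals)
    if (any(lens != C)) {
      stop("parse error at frame ", k, ": row with ",
           lens[which(lens != C)[1]], " values, expected ", C)
    }
    tensor[k, , ] <- matrix(as.numeric(unlist(vals)), R, C, byrow = TRUE)
    pos <- pos + R + 1L
  }
  pressure_recording(tensor, dt = dt, cell_size = cell)
}

#' Segment a recording into walking passes
#'
#' Passes are maximal runs of frames bounded by runs of at least
#' `min_gap` all-zero frames (the instrument records zeros while the
#' walker steps off and turns around). Zero frames never belong to a
#' pass; short interior zero runs (< `min_gap`) are kept inside a pass.
#'
#' @param rec A [pressure_recording()].
#' @param min_gap Minimum all-zero run separating passes (frames, >= 1).
#' @return Tibble with one row per pass: `pass`, half-open frame range
#'   `start`, `end` (0-based), `n_frames`, `normalized` flag. An all-zero
#'   recording yields zero rows.
#' @export
segment_passes <- function(rec, min_gap = 5) {
  stopifnot(inherits(rec, "pressure_recording"), min_gap >= 1)
  active <- apply(rec$tensor, 1, function(fr) any(fr > 0))
  n <- length(active)
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  # merge active runs separated by zero runs shorter than min_gap
  segs <- list()
  cur <- NULL
  for (i in seq_along(runs$lengths)) {
    if (runs$values[i]) {
      if (is.null(cur)) cur <- c(starts[i], ends[i]) else cur[2] <- ends[i]
    } else if (!is.null(cur) && runs$lengths[i] >= min_gap) {
      segs[[length(segs) + 1]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) segs[[length(segs) + 1]] <- cur
  if (length(segs) == 0) {
    return(tibble::tibble(pass = integer(), start = integer(),
                          end = integer(), n_frames = integer(),
                          normalized = logical()))
  }
  tibble::tibble(
    pass = seq_along(segs),
    start = vapply(segs, function(s) as.integer(s[1] - 1), integer(1)),
    end = vapply(segs, function(s) as.integer(s[2]), integer(1)),
    n_frames = vapply(segs, function(s) as.integer(s[2] - s[1] + 1),
                      integer(1)),
    normalized = FALSE)
}

#' Normalize alternating walking direction across passes
#'
#' Every other pass is walked in the opposite direction, so the
#' instrument's frames for odd passes (0-based: pass indices 1, 3, ...)
#' are mirrored. Flipping those frames row- and column-wise restores a
#' single walking direction with the left foot in the higher columns.
#' The flip is an involution and conserves every frame's total pressure.
#'
#' @param rec A [pressure_recording()].
#' @param passes Pass table from [segment_passes()].
#' @return List with the direction-normalized `recording` and the
#'   updated `passes` table (`normalized = TRUE`).
#' @export
normalize_direction <- function(rec, passes) {
  stopifnot(inherits(rec, "pressure_recording"))
  if (any(passes$normalized)) {
    stop("passes already normalized; direction flip is not idempotent")
  }
  tensor <- rec$tensor
  d <- dim(tensor)
  for (i in seq_len(nrow(passes))) {
    if ((passes$pass[i] - 1) %% 2 == 1) {
      idx <- (passes$start[i] + 1):passes$end[i]
      tensor[idx, , ] <- tensor[idx, rev(seq_len(d[2])), rev(seq_len(d[3]))]
    }
  }
  out <- pressure_recording(tensor, dt = rec$dt, cell_size = rec$cell_size,
                            units = rec$units)
  attr(out, "truth") <- attr(rec, "truth")
  passes$normalized <- TRUE
  list(recording = out, passes = passes)
}

# 8-connected component labelling of a logical matrix (BFS flood fill)
.label8 <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  nextlab <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% d[1] + 1L
      c <- (cur - 1L) %/% d[1] + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= d[1] && cc >= 1 && cc <= d[2]) {
          j <- (cc - 1L) * d[1] + rr
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- nextlab
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  lab
}

#' Detect footstep regions in direction-normalized passes
#'
#' Integrates each pass over time, thresholds the resulting footprint
#' map, and takes 8-connected components of at least `min_area` cells as
#' footsteps. The foot side comes from the component's column centroid
#' relative to the walkway midline (left foot = higher columns); per-foot
#' cycle indices follow first-contact order. A step's frame window spans
#' the frames where the force inside its bounding box exceeds
#' `contact_rel` times that step's peak in-box force.
#'
#' @param rec Direction-normalized [pressure_recording()].
#' @param passes Normalized pass table (see [normalize_direction()]).
#' @param contact_rel Relative in-stance force threshold (default 0.005).
#' @param min_area Minimum component area in cells (default 20).
#' @param map_rel Relative threshold on the time-integrated footprint map
#'   (guards against numeric dust in renderings; real instruments write
#'   exact zeros off-contact).
#' @return Tibble with one row per detected step: `pass`, `foot`,
#'   `cycle`, bounding box `row0`, `row1`, `col0`, `col1` and frame
#'   window `frame0`, `frame1` (all 0-based, half-open), `area`.
#' @export
detect_steps <- function(rec, passes, contact_rel = 0.005, min_area = 20,
                         map_rel = 1e-3) {
  stopifnot(inherits(rec, "pressure_recording"))
  if (nrow(passes) > 0 && !all(passes$normalized)) {
    stop("passes must be direction-normalized before step detection")
  }
  d <- dim(rec$tensor)
  col_mid <- (d[3] + 1) / 2
  out <- list()
  for (i in seq_len(nrow(passes))) {
    frames <- (passes$start[i] + 1):passes$end[i]
    imap <- apply(rec$tensor[frames, , , drop = FALSE], c(2, 3), sum)
    if (max(imap) <= 0) next
    lab <- .label8(imap > map_rel * max(imap))
    for (l in seq_len(max(lab))) {
      cells <- which(lab == l, arr.ind = TRUE)
      if (nrow(cells) < min_area) next
      r0 <- min(cells[, 1]); r1 <- max(cells[, 1])
      c0 <- min(cells[, 2]); c1 <- max(cells[, 2])
      foot <- if (mean(cells[, 2]) > col_mid) "l" else "r"
      force <- apply(rec$tensor[frames, r0:r1, c0:c1, drop = FALSE], 1, sum)
      hot <- which(force > contact_rel * max(force))
      out[[length(out) + 1]] <- tibble::tibble(
        pass = passes$pass[i], foot = foot,
        row0 = r0 - 1L, row1 = r1, col0 = c0 - 1L, col1 = c1,
        frame0 = passes$start[i] + min(hot) - 1L,
        frame1 = passes$start[i] + max(hot),
        area = nrow(cells))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(pass = integer(), foot = character(),
                          cycle = integer(), row0 = integer(),
                          row1 = integer(), col0 = integer(),
                          col1 = integer(), frame0 = integer(),
                          frame1 = integer(), area = integer()))
  }
  steps <- dplyr::bind_rows(out)
  steps <- dplyr::arrange(steps, .data$frame0, .data$row0)
  steps <- dplyr::group_by(steps, .data$foot)
  steps <- dplyr::mutate(steps, cycle = dplyr::row_number())
  steps <- dplyr::ungroup(steps)
  dplyr::relocate(steps, "pass", "foot", "cycle")
}

#' Integrate one step region into its temporal force signal
#'
#' Sums the pressure over the step's bounding box at each frame of its
#' stance window, multiplies by the cell area (Pa * m^2 = N), re-indexes
#' so first contact is frame 0, and zero-pads to `pad_to` frames.
#'
#' @param rec Direction-normalized [pressure_recording()].
#' @param region One row of the [detect_steps()] table.
#' @param pad_to Padded signal length in frames (default 100).
#' @return A [step_signal()] with `stance_len = frame1 - frame0`.
#' @export
extract_step_signal <- function(rec, region, pad_to = 100) {
  stopifnot(inherits(rec, "pressure_recording"), nrow(region) == 1)
  stance <- region$frame1 - region$frame0
  if (stance > pad_to) {
    stop("stance of ", stance, " frames exceeds pad_to = ", pad_to,
         "; increase pad_to")
  }
  frames <- (region$frame0 + 1):region$frame1
  force <- apply(rec$tensor[frames, (region$row0 + 1):region$row1,
                            (region$col0 + 1):region$col1,
                            drop = FALSE], 1, sum) * rec$cell_size^2
  values <- numeric(pad_to)
  values[seq_len(stance)] <- force
  step_signal(values, dt = rec$dt, foot = region$foot,
              cycle = region$cycle, stance_len = stance)
}

#' Full preprocessing: recording to per-step force signals
#'
#' Convenience pipeline chaining [segment_passes()],
#' [normalize_direction()], [detect_steps()] and
#' [extract_step_signal()].
#'
#' @param rec A raw [pressure_recording()].
#' @param min_gap,contact_rel,min_area,pad_to Stage parameters.
#' @return The [detect_steps()] tibble with a `signal` list-column of
#'   [step_signal()] objects.
#' @export
extract_steps <- function(rec, min_gap = 5, contact_rel = 0.005,
                          min_area = 20, pad_to = 100) {
  passes <- segment_passes(rec, min_gap = min_gap)
  norm <- normalize_direction(rec, passes)
  steps <- detect_steps(norm$recording, norm$passes,
                        contact_rel = contact_rel, min_area = min_area)
  steps$signal <- lapply(seq_len(nrow(steps)), function(i) {
    extract_step_signal(norm$recording, steps[i, ], pad_to = pad_to)
  })
  steps
}
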