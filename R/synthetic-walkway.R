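#' Canonical mode triplets of the default synthetic walker
#'
#' Six conjugate-pair mode triplets (decay rate alpha in 1/s, frequency in
#' Hz, complex initial condition in N) whose damped-sinusoid expansion
#' renders a stylized vertical ground-reaction-force curve: a ~0.9 s
#' stance with the classic heel-strike and push-off bumps (peak ~680 N, a
#' mid-stance valley at ~80% of peak) decaying to zero afterwards. The
#' lowest-frequency pair dominates the initial-condition modulus, and the
#' two dominant pairs alone already carry the double-bump shape.
#'
#' The triplets were designed once, by weighted least squares of the
#' damped-sinusoid basis against a textbook force curve, and are frozen;
#' person-level and step-level variation is layered on top of them by
#' [make_cohort()] and [simulate_step_force()].
#'
#' @return A tibble with columns `mode`, `alpha` (1/s, negative), `freq`
#'   (Hz, strictly increasing), `s0_re`, `s0_im` (N).
#' @export
default_mode_params <- function() {
  tibble::tibble(
    mode = 1:6,
    alpha = c(-6.5, -6.5, -7.2, -7.6, -8.0, -8.5),
    freq = c(0.55, 1.60, 2.40, 3.60, 4.90, 6.20),
    s0_re = c(-1941.99458, 1780.04595, 293.59260, 702.08422,
              -796.13279, -23.21784),
    s0_im = c(-5493.35499, 738.01363, -743.12550, 1290.88334,
              309.41918, -330.19420)
  )
}

# extend or trim the canonical table to K modes; extra modes continue the
# frequency ladder with weak, fast-decaying content
.base_modes <- function(K) {
  base <- default_mode_params()
  if (K <= 6) return(base[seq_len(K), ])
  extra <- tibble::tibble(
    mode = 7:K,
    alpha = -8.5 - 0.3 * (7:K - 6),
    freq = 6.2 + 1.3 * (7:K - 6),
    s0_re = 15 * 0.6^(7:K - 6),
    s0_im = -10 * 0.6^(7:K - 6)
  )
  dplyr::bind_rows(base, extra)
}

#' Default step-to-step jitter and measurement noise
#'
#' Step-to-step variation is multiplicative Gaussian on the decay rate and
#' on the initial-condition modulus (relative sd) and additive Gaussian on
#' the frequency (Hz); measurement noise is additive Gaussian on the
#' force during stance. The magnitudes are chosen to reflect the
#' within-person variability of comfortable-pace walking: a few percent on
#' amplitude-like quantities and a few hundredths of a Hz on frequency.
#'
#' @return Named list with `alpha`, `freq`, `s0` jitter scales and
#'   `noise_sd` (N).
#' @export
default_jitter <- function() {
  list(alpha = 0.05, freq = 0.02, s0 = 0.05, noise_sd = 0.05)
}

#' Generate a cohort of synthetic walkers
#'
#' Draws `n_persons` walker profiles around the canonical mode triplets of
#' [default_mode_params()]. Between-person spread is controlled by
#' `separation`: each person's decay rates and initial-condition moduli
#' are scaled by independent lognormal-like factors and the frequencies
#' are shifted additively, all proportional to `separation`. At
#' `separation = 0` every profile equals the canonical walker.
#'
#' @param n_persons Number of walkers (>= 2, identification needs a
#'   gallery).
#' @param n_modes Number of conjugate mode pairs K per walker (default 6).
#' @param separation Non-negative scalar scaling between-person spread
#'   (default 1).
#' @param steps_per_person Default number of steps per person per foot
#'   used by [simulate_cohort_steps()] (>= 2).
#' @param seed RNG seed; the cohort is a pure function of the arguments.
#' @param jitter Step-to-step jitter scales, see [default_jitter()].
#' @return A tibble of class `gait_cohort` with one row per person and
#'   mode: columns `person`, `mode`, `alpha`, `freq`, `s0_re`, `s0_im`.
#'   Jitter scales, separation, seed and `steps_per_person` are carried
#'   as attributes.
#' @export
make_cohort <- function(n_persons = 16, n_modes = 6, separation = 1,
                        steps_per_person = 30, seed = 1,
                        jitter = default_jitter()) {
  if (!is.numeric(n_persons) || n_persons < 2)
    stop("invalid n_persons: need at least 2 walkers")
  if (!is.numeric(n_modes) || n_modes < 1)
    stop("invalid n_modes: need at least 1 mode pair")
  if (!is.numeric(separation) || separation < 0)
    stop("invalid separation: must be >= 0")
  if (!is.numeric(steps_per_person) || steps_per_person < 2)
    stop("invalid steps_per_person: need at least 2 steps")
  base <- .base_modes(as.integer(n_modes))
  nyq_margin <- 24  # keep all frequencies safely below Nyquist (25 Hz)
  cohort <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_persons), function(p) {
      K <- nrow(base)
      alpha <- base$alpha * (1 + separation * stats::rnorm(K, 0, 0.10))
      alpha <- pmin(alpha, -0.5)  # stay decaying
      freq <- base$freq + separation * stats::rnorm(K, 0, 0.05)
      freq <- pmin(pmax(freq, 0.05), nyq_margin)
      freq <- sort(freq)
      s0_mod <- Mod(complex(real = base$s0_re, imaginary = base$s0_im)) *
        (1 + separation * stats::rnorm(K, 0, 0.12))
      s0_arg <- Arg(complex(real = base$s0_re, imaginary = base$s0_im)) +
        separation * stats::rnorm(K, 0, 0.10)
      tibble::tibble(
        person = sprintf("P%02d", p), mode = base$mode,
        alpha = alpha, freq = freq,
        s0_re = s0_mod * cos(s0_arg), s0_im = s0_mod * sin(s0_arg))
    })
  })
  structure(cohort,
            class = c("gait_cohort", class(cohort)),
            jitter = jitter, separation = separation, seed = as.integer(seed),
            steps_per_person = as.integer(steps_per_person))
}

#' Extract one walker's profile from a cohort
#'
#' @param cohort A [make_cohort()] tibble.
#' @param person Person label (e.g. `"P01"`).
#' @return The person's mode-parameter tibble, carrying the cohort's
#'   jitter attributes.
#' @export
person_profile <- function(cohort, person) {
  rows <- cohort[cohort$person == person, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown person: ", person)
  structure(tibble::as_tibble(rows), jitter = attr(cohort, "jitter"))
}

#' Simulate one step's plantar force signal
#'
#' Evaluates the damped-sinusoid mode expansion
#' `s_n = sum_k 2 e^{alpha_k n dt} Re(s0_k e^{2 pi i f_k n dt})`
#' at per-step jittered copies of the profile parameters and adds
#' measurement noise during stance. With `jitter = NULL` (none) and
#' `noise_sd = 0` the output is the exact K-pair expansion, the analytic
#' oracle for the DMD layer.
#'
#' Uses the session RNG; seed the caller (or use
#' [simulate_cohort_steps()]) for reproducibility.
#'
#' @param profile Mode-parameter tibble with columns `alpha`, `freq`,
#'   `s0_re`, `s0_im` (one walker), e.g. from [person_profile()].
#' @param n_frames Number of frames to render (default 100).
#' @param dt Frame interval in seconds (default 0.02, i.e. 50 Hz).
#' @param jitter `NULL` for no jitter, `TRUE` for the profile's attached
#'   jitter scales (falling back to [default_jitter()]), or a list with
#'   elements `alpha`, `freq`, `s0`.
#' @param noise_sd Additive noise sd in N applied during stance; `NULL`
#'   takes the jitter list's `noise_sd` (0 when jitter is `NULL`).
#' @param speed_factor Time-compression factor; > 1 shortens the stance
#'   (fast pace). Scales decay rates and frequencies.
#' @param rectify Clamp the rendered signal at zero (off by default: the
#'   raw expansion is the linear-model oracle and rectification breaks
#'   it).
#' @return A [step_signal()].
#' @export
simulate_step_force <- function(profile, n_frames = 100, dt = 0.02,
                                jitter = NULL, noise_sd = NULL,
                                speed_factor = 1, rectify = FALSE) {
  stopifnot(n_frames >= 2, dt > 0)
  alpha <- profile$alpha
  freq <- profile$freq
  s0 <- complex(real = profile$s0_re, imaginary = profile$s0_im)
  if (isTRUE(jitter)) {
    jitter <- attr(profile, "jitter")
    if (is.null(jitter)) jitter <- default_jitter()
  }
  if (is.null(noise_sd)) {
    noise_sd <- if (is.list(jitter) && !is.null(jitter$noise_sd))
      jitter$noise_sd else 0
  }
  K <- length(alpha)
  if (is.list(jitter)) {
    alpha <- alpha * (1 + stats::rnorm(K, 0, jitter$alpha))
    alpha <- pmin(alpha, -0.1)
    freq <- pmax(freq + stats::rnorm(K, 0, jitter$freq), 0.01)
    s0 <- s0 * (1 + stats::rnorm(K, 0, jitter$s0))
  }
  alpha <- alpha * speed_factor
  freq <- pmin(freq * speed_factor, 1 / (2 * dt) - 0.5)
  n <- 0:(n_frames - 1)
  s <- numeric(n_frames)
  for (k in seq_len(K)) {
    s <- s + 2 * Re(s0[k] * exp((alpha[k] + 2i * pi * freq[k]) * n * dt))
  }
  stance <- .stance_length(s)
  if (noise_sd > 0 && stance > 0) {
    s[seq_len(stance)] <- s[seq_len(stance)] +
      stats::rnorm(stance, 0, noise_sd)
  }
  if (rectify) s <- pmax(s, 0)
  step_signal(s, dt = dt, stance_len = stance)
}

#' Simulate force signals for a whole cohort
#'
#' Renders `steps_per_person` jittered, noisy step signals per person,
#' foot and speed. Feet share the walker's mode parameters (asymmetry is
#' out of scope); the fast pace compresses time by `fast_factor`.
#'
#' @param cohort A [make_cohort()] cohort.
#' @param steps_per_person Steps per person/foot/speed; default from the
#'   cohort attribute.
#' @param feet Character subset of `c("l", "r")`.
#' @param speeds Character subset of `c("normal", "fast")`.
#' @param seed RNG seed for the jitter/noise draws.
#' @param n_frames,fast_factor Rendering controls.
#' @return Tibble with columns `person`, `foot`, `speed`, `cycle` and a
#'   list-column `signal` of [step_signal()] objects.
#' @export
simulate_cohort_steps <- function(cohort, steps_per_person = NULL,
                                  feet = c("l", "r"), speeds = "normal",
                                  seed = 1, n_frames = 100,
                                  fast_factor = 1.15) {
  stopifnot(inherits(cohort, "gait_cohort"))
  if (is.null(steps_per_person))
    steps_per_person <- attr(cohort, "steps_per_person")
  persons <- unique(cohort$person)
  grid <- tidyr::expand_grid(person = persons, foot = feet, speed = speeds,
                             cycle = seq_len(steps_per_person))
  withr::with_seed(as.integer(seed), {
    grid$signal <- purrr::pmap(grid, function(person, foot, speed, cycle) {
      prof <- person_profile(cohort, person)
      st <- simulate_step_force(
        prof, n_frames = n_frames, dt = 0.02, jitter = TRUE,
        speed_factor = if (speed == "fast") fast_factor else 1)
      st$person <- person; st$foot <- foot
      st$speed <- speed; st$cycle <- as.integer(cycle)
      st
    })
  })
  grid
}

#' Walkway sensor-grid geometry
#'
#' Describes the pressure-sensitive walkway: sensel grid, cell size and
#' frame interval. The default is a reduced 256 x 64 grid (rows along the
#' walking direction, columns across it, 5 mm cells, 50 Hz) sized for
#' fast tests; pass larger dimensions for full-scale instruments.
#'
#' @param n_rows Sensels along the walking direction.
#' @param n_cols Sensels across the walkway (the left foot lands in the
#'   higher columns once passes are direction-normalized).
#' @param cell_size Cell edge length in metres (> 0).
#' @param dt Frame interval in seconds (> 0).
#' @param frames Optional fixed frame count; `NULL` lets the simulator
#'   size the recording.
#' @export
walkway_geometry <- function(n_rows = 256, n_cols = 64, cell_size = 0.005,
                             dt = 0.02, frames = NULL) {
  stopifnot(n_rows >= 8, n_cols >= 8, cell_size > 0, dt > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, dt = dt,
                 frames = if (is.null(frames)) NULL else as.integer(frames)),
            class = "walkway_geometry")
}

# footprint layout constants (cells): length along walking axis, width,
# and centers/sds of the heel/metatarsal/toe Gaussian components
.footprint <- list(
  len = 38, wid = 14,
  centers_r = c(8, 26, 34),     # rows within footprint
  sd_r = c(4.5, 5, 3),
  sd_c = c(3.5, 4.5, 2.5)
)

# temporal envelopes of the three components over normalized stance time
.blob_weights <- function(u) {
  c(heel = exp(-((u - 0.20) / 0.26)^2),
    met = exp(-((u - 0.55) / 0.30)^2),
    toe = exp(-((u - 0.82) / 0.22)^2))
}

#' Simulate a multi-pass walkway pressure recording
#'
#' Renders one walker's passes over the walkway as a full frames x rows x
#' cols pressure tensor. Within a pass, steps alternate right/left with a
#' constant stride and overlapping stance windows (double support);
#' passes are separated by runs of all-zero frames and alternate walking
#' direction, odd passes being flipped row- and column-wise exactly as
#' the instrument records them. Each step is painted as heel, metatarsal
#' and toe Gaussian pressure blobs whose temporal envelopes shift weight
#' from heel to toe; every frame is normalized so the spatial integral
#' times the cell area equals that step's 1D force signal.
#'
#' @param profile One walker's mode-parameter tibble (see
#'   [person_profile()]); jitter attributes are honoured.
#' @param geometry A [walkway_geometry()].
#' @param n_passes Number of passes (0 gives an all-zero recording).
#' @param steps_per_pass Steps per pass (alternating feet).
#' @param seed RNG seed for step jitter.
#' @param gap_frames All-zero frames between passes (>= 5).
#' @param stride_rows,step_interval Spatial stride (rows) and temporal
#'   offset (frames) between consecutive steps.
#' @return A `pressure_recording` whose `truth` attribute tabulates, per
#'   rendered step: pass, foot, cycle, the bounding box and stance frame
#'   window in direction-normalized coordinates, and the ground-truth
#'   force series as a list-column.
#' @export
simulate_recording <- function(profile, geometry = walkway_geometry(),
                               n_passes = 4, steps_per_pass = 8, seed = 1,
                               gap_frames = 10, stride_rows = 26,
                               step_interval = 25) {
  stopifnot(inherits(geometry, "walkway_geometry"), n_passes >= 0,
            steps_per_pass >= 1, gap_frames >= 5)
  fp <- .footprint
  margin <- 6
  need_rows <- 2 * margin + (steps_per_pass - 1) * stride_rows + fp$len
  if (need_rows > geometry$n_rows) {
    stop("cannot place ", steps_per_pass, " steps on ", geometry$n_rows,
         " rows (need ", need_rows, "); use a larger walkway geometry")
  }
  if (geometry$n_cols < 2 * fp$wid + 8) {
    stop("walkway too narrow for two feet; need at least ",
         2 * fp$wid + 8, " columns")
  }
  n_frames_step <- 100L
  pass_len <- (steps_per_pass - 1) * step_interval + n_frames_step
  total <- if (n_passes == 0) gap_frames else
    n_passes * pass_len + (n_passes - 1) * gap_frames
  if (!is.null(geometry$frames)) {
    if (geometry$frames < total) {
      stop("geometry$frames = ", geometry$frames, " too small (need ",
           total, "); enlarge or leave NULL")
    }
    total <- geometry$frames
  }
  tensor <- array(0, dim = c(total, geometry$n_rows, geometry$n_cols))
  cell_area <- geometry$cell_size^2
  col_mid <- (geometry$n_cols + 1) / 2
  col_center <- c(r = col_mid - fp$wid * 0.85, l = col_mid + fp$wid * 0.85)
  truth <- NULL
  withr::with_seed(as.integer(seed), {
    for (p in seq_len(n_passes)) {
      pass_start <- (p - 1) * (pass_len + gap_frames)  # 0-based
      for (i in seq_len(steps_per_pass)) {
        foot <- if (i %% 2 == 1) "r" else "l"
        row0 <- margin + (i - 1) * stride_rows            # 0-based
        cc <- col_center[[foot]]
        st <- simulate_step_force(profile, n_frames = n_frames_step,
                                  dt = geometry$dt, jitter = TRUE)
        f <- pmax(st$values, 0)
        stance <- st$stance_len
        t0 <- pass_start + (i - 1) * step_interval        # 0-based frame
        rows <- row0 + seq_len(fp$len) - 1                # 0-based cells
        cols <- round(cc - fp$wid / 2) + seq_len(fp$wid) - 1
        for (n in seq_len(stance)) {
          u <- (n - 1) / max(stance - 1, 1)
          w <- .blob_weights(u)
          blob <- matrix(0, fp$len, fp$wid)
          for (jb in 1:3) {
            gr <- exp(-((seq_len(fp$len) - fp$centers_r[jb])^2) /
                        (2 * fp$sd_r[jb]^2))
            gc <- exp(-((seq_len(fp$wid) - (fp$wid + 1) / 2)^2) /
                        (2 * fp$sd_c[jb]^2))
            blob <- blob + w[jb] * outer(gr, gc)
          }
          tot <- sum(blob) * cell_area
          if (f[n] > 0 && tot > 0) {
            frame_idx <- t0 + n          # 1-based tensor frame = 0-based+1
            tensor[frame_idx, rows + 1, cols + 1] <-
              tensor[frame_idx, rows + 1, cols + 1] + blob * (f[n] / tot)
          }
        }
        # contact window by the same rule the detector uses: rendered
        # force above 0.5% of this step's peak
        hot <- which(f[seq_len(stance)] > 0.005 * max(f))
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          pass = p, foot = foot,
          row0 = min(rows), row1 = max(rows) + 1L,
          col0 = min(cols), col1 = max(cols) + 1L,
          start_frame = t0, render_len = stance,
          frame0 = t0 + min(hot) - 1L, frame1 = t0 + max(hot),
          stance_len = max(hot) - min(hot) + 1L, force = list(f)))
      }
      if (p %% 2 == 0) {
        # instrument view of an opposite-direction pass: flip rows+cols
        idx <- pass_start + seq_len(pass_len)
        tensor[idx, , ] <- tensor[idx, rev(seq_len(geometry$n_rows)),
                                  rev(seq_len(geometry$n_cols))]
      }
    }
  })
  if (!is.null(truth)) {
    truth <- dplyr::arrange(truth, .data$frame0)
    truth <- dplyr::group_by(truth, .data$foot)
    truth <- dplyr::mutate(truth, cycle = dplyr::row_number())
    truth <- dplyr::ungroup(truth)
  }
  rec <- pressure_recording(tensor, dt = geometry$dt,
                            cell_size = geometry$cell_size)
  attr(rec, "truth") <- truth
  rec
}
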