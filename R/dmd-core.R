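#' Build a Hankel (time-delay) matrix from a scalar series
#'
#' Stacks time-shifted copies of a scalar signal into a `rows` x `cols`
#' matrix with entry (i, j) = `series[i + j - 1]` (1-based), the standard
#' time-delay embedding used to give a univariate series the surrogate
#' spatial dimensions that SVD-based dynamic mode decomposition needs.
#'
#' @param series Numeric vector of length at least `rows + cols - 1`.
#' @param rows Number of delay rows (embedding dimension), at least 1.
#' @param cols Number of columns (snapshots), at least `rows` for a wide
#'   embedding; smaller values are allowed but unusual.
#' @return A `rows` x `cols` numeric matrix whose first row is
#'   `series[1:cols]`.
#' @examples
#' build_hankel(c(1, 2, 3, 4), rows = 2, cols = 3)
#' @export
build_hankel <- function(series, rows, cols) {
  stopifnot(is.numeric(series), rows >= 1, cols >= 1)
  need <- rows + cols - 1
  if (length(series) < need) {
    stop("series too short for Hankel embedding: need at least ", need,
         " samples, got ", length(series))
  }
  idx <- outer(seq_len(rows), seq_len(cols), function(i, j) i + j - 1)
  matrix(series[idx], nrow = rows, ncol = cols)
}

#' Snapshot pair for dynamic mode decomposition
#'
#' Splits a snapshot matrix `D = [D_0 D_1 ... D_{N-1}]` into the shifted
#' pair `X = [D_0 ... D_{N-2}]`, `Y = [D_1 ... D_{N-1}]` whose linear
#' relation `Y = A X` the DMD operator approximates.
#'
#' @param D Numeric matrix of snapshot columns (at least 2 columns).
#' @return A list of class `snapshot_pair` with elements `X`, `Y`.
#' @export
snapshot_pair <- function(D) {
  D <- as.matrix(D)
  if (ncol(D) < 2) stop("snapshot matrix needs at least 2 columns")
  structure(list(X = D[, -ncol(D), drop = FALSE],
                 Y = D[, -1, drop = FALSE]),
            class = "snapshot_pair")
}

#' Rank-selection rules for DMD truncation
#'
#' Three ways to pick the SVD truncation rank r: a fixed rank, the smallest
#' rank whose reduced model keeps the one-step residual `||Y - A X||_2`
#' under a tolerance, or the smallest rank retaining a fraction of the
#' total squared singular-value mass ("variance").
#'
#' For `rank_error()` the tolerance defaults to `coef * (rows + cols)` of
#' the data matrix, the scale-by-problem-size convention used with Hankel
#' embeddings of force signals; pass `epsilon` for an absolute tolerance.
#'
#' @param r Fixed truncation rank.
#' @param epsilon Absolute residual tolerance (spectral norm). When `NULL`
#'   the tolerance is `coef * (nrow(D) + ncol(D))`.
#' @param coef Multiplier for the problem-size-scaled tolerance.
#' @param q Fraction of squared singular-value mass to retain, in (0, 1].
#' @return An object of class `rank_rule`.
#' @name rank_rules
NULL

#' @rdname rank_rules
#' @export
rank_fixed <- function(r) {
  stopifnot(is.numeric(r), length(r) == 1, r >= 1)
  structure(list(kind = "fixed", r = as.integer(r)), class = "rank_rule")
}

#' @rdname rank_rules
#' @export
rank_error <- function(epsilon = NULL, coef = 1e-6) {
  stopifnot(is.null(epsilon) || (is.numeric(epsilon) && epsilon > 0),
            is.numeric(coef), coef > 0)
  structure(list(kind = "error", epsilon = epsilon, coef = coef),
            class = "rank_rule")
}

#' @rdname rank_rules
#' @export
rank_variance <- function(q = 0.999) {
  stopifnot(is.numeric(q), q > 0, q <= 1)
  structure(list(kind = "variance", q = q), class = "rank_rule")
}

# Spectral-norm residual of the rank-r reduced model: ||Y - Y V_r V_r'||_2.
# V must hold the right singular vectors of X as columns.
.dmd_residual <- function(Y, V, r) {
  if (r >= ncol(V)) r <- ncol(V)
  Vr <- V[, seq_len(r), drop = FALSE]
  R <- Y - (Y %*% Vr) %*% t(Vr)
  # norm(,"2") on a zero matrix is fine (returns 0)
  norm(R, type = "2")
}

#' Choose the SVD truncation rank for a snapshot pair
#'
#' Applies a [rank_rules] rule to the singular spectrum of `X`: the
#' variance rule keeps the smallest rank holding at least a fraction `q`
#' of the squared singular values, the error rule the smallest rank whose
#' reduced one-step model satisfies `||Y - A X||_2 <= epsilon`. Singular
#' values below `1e-12 * sigma_max` are always discarded first. Both rules
#' are monotone: loosening the tolerance never increases the rank.
#'
#' @param pair A [snapshot_pair()].
#' @param rule A [rank_rules] object.
#' @param sv Optional pre-computed `svd(pair$X)`.
#' @return Integer rank r.
#' @export
choose_truncation <- function(pair, rule, sv = NULL) {
  stopifnot(inherits(pair, "snapshot_pair"), inherits(rule, "rank_rule"))
  if (is.null(sv)) sv <- svd(pair$X)
  d <- sv$d
  nrank <- sum(d > 1e-12 * d[1])
  if (nrank == 0) stop("zero data matrix: no truncation rank exists")
  if (rule$kind == "fixed") {
    r <- rule$r
    if (r > nrank) {
      warning("requested rank ", r, " exceeds numerical rank ", nrank,
              "; clamping")
      r <- nrank
    }
    return(as.integer(r))
  }
  if (rule$kind == "variance") {
    mass <- cumsum(d^2) / sum(d^2)
    return(as.integer(min(which(mass >= rule$q - 1e-15))))
  }
  # error rule: binary search the smallest r meeting the tolerance
  # (residual is non-increasing in r)
  eps <- rule$epsilon
  if (is.null(eps)) eps <- rule$coef * (nrow(pair$X) + ncol(pair$X) + 1)
  if (.dmd_residual(pair$Y, sv$v, nrank) > eps) {
    warning("residual tolerance ", format(eps),
            " unattainable at full numerical rank ", nrank,
            "; returning full rank")
    return(as.integer(nrank))
  }
  lo <- 1L
  hi <- as.integer(nrank)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (.dmd_residual(pair$Y, sv$v, mid) <= eps) hi <- mid else lo <- mid + 1L
  }
  hi
}

#' Least-squares amplitudes of DMD modes
#'
#' Solves `modes %*% b = d0` in the least-squares sense, giving the
#' projection coefficients b(s0) of the initial snapshot onto the dynamic
#' modes. Degenerate (rank-deficient) mode sets fall back to the
#' minimum-norm solution with a warning.
#'
#' @param modes Complex (or numeric) matrix, one mode per column.
#' @param d0 Initial snapshot vector.
#' @return Complex vector of amplitudes, one per mode.
#' @export
compute_amplitudes <- function(modes, d0) {
  modes <- as.matrix(modes)
  stopifnot(nrow(modes) == length(d0))
  sv <- svd(modes)
  keep <- sv$d > 1e-12 * sv$d[1]
  if (!all(keep)) {
    warning("modes numerically degenerate; returning minimum-norm amplitudes")
  }
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]
  out <- as.vector(v %*% ((Conj(t(u)) %*% d0) / d))
  if (!is.complex(out)) out <- as.complex(out)
  out
}

#' Exact (SVD-based) dynamic mode decomposition
#'
#' The standard exact-DMD algorithm: thin SVD of `X = W S V*`, truncation
#' to rank r by `rank_rule`, eigendecomposition of the reduced operator
#' `A_hat = W* Y V S^-1`, exact dynamic modes `(1/mu) Y V S^-1 w`, and
#' least-squares amplitudes against the first snapshot.
#'
#' @param pair A [snapshot_pair()].
#' @param rank_rule A [rank_rules] object (default: the size-scaled error
#'   tolerance rule).
#' @param dt Sampling interval in seconds (stored for feature conversion).
#' @param projected If `TRUE`, also return the projected modes `W w`.
#' @return An object of class `dmd_model`: a list with complex `eigvals`,
#'   complex mode matrix `modes` (exact modes, columns), `mode_scalars`
#'   (first element of each exact mode), `amplitudes`, `rank`, `fit_error`
#'   (`||Y - A X||_2`), `dt`, and the embedding dimensions.
#' @export
exact_dmd <- function(pair, rank_rule = rank_error(), dt = 0.02,
                      projected = FALSE) {
  stopifnot(inherits(pair, "snapshot_pair"))
  X <- pair$X
  Y <- pair$Y
  if (all(X == 0)) stop("zero data matrix: DMD undefined")
  sv <- svd(X)
  r <- choose_truncation(pair, rank_rule, sv = sv)
  Wr <- sv$u[, seq_len(r), drop = FALSE]
  Vr <- sv$v[, seq_len(r), drop = FALSE]
  dr <- sv$d[seq_len(r)]
  YVs <- Y %*% Vr %*% diag(1 / dr, nrow = r)
  Ahat <- t(Wr) %*% YVs
  eig <- eigen(Ahat)
  mu <- as.complex(eig$values)
  w <- eig$vectors
  # exact dynamic modes: (1/mu_k) * Y V S^-1 w_k
  Phi <- (YVs %*% w) %*% diag(1 / mu, nrow = r)
  b <- compute_amplitudes(Phi, X[, 1])
  # energy ordering: descending |v_k * b_k| with v_k the mode first element
  v1 <- Phi[1, ]
  ord <- order(Mod(v1 * b), decreasing = TRUE)
  model <- structure(list(
    eigvals = mu[ord],
    modes = Phi[, ord, drop = FALSE],
    mode_scalars = v1[ord],
    amplitudes = b[ord],
    rank = as.integer(r),
    fit_error = .dmd_residual(Y, sv$v, r),
    dt = dt,
    rows = nrow(X),
    cols = ncol(X) + 1L
  ), class = "dmd_model")
  if (projected) model$projected_modes <- (Wr %*% w)[, ord, drop = FALSE]
  model
}

#' Hankel dynamic mode decomposition of one step signal
#'
#' Embeds a zero-padded per-step force signal in a Hankel matrix and runs
#' [exact_dmd()] on it. Only the first element of each exact mode enters
#' the model's scalar reconstruction, because every row of the Hankel
#' matrix is a shifted copy of the same signal.
#'
#' With `rows = "auto"` a small grid of embedding depths is searched --
#' the stance length (frames of genuine foot contact), half of it, and 25
#' -- and the embedding whose model minimises the one-step residual
#' (subject to the rank rule's tolerance when it uses one) is kept.
#' `rows = "stance"` uses the stance length directly, the natural depth
#' for a signal whose genuine content occupies the stance window; it is
#' the more robust choice on noisy steps, where the residual-minimising
#' search tends to reward shallow, overfitted embeddings.
#'
#' @param step A [step_signal()] (or plain numeric vector, in which case
#'   `dt` and stance length are taken from the arguments).
#' @param rows `"auto"`, `"stance"`, or an integer number of Hankel rows
#'   (>= 2).
#' @param rank_rule A [rank_rules] object.
#' @param dt Sampling interval, used only when `step` is a bare vector.
#' @return A `dmd_model` (see [exact_dmd()]) with the chosen `rows`
#'   recorded.
#' @export
hankel_dmd <- function(step, rows = "auto", rank_rule = rank_error(),
                       dt = 0.02) {
  if (inherits(step, "step_signal")) {
    series <- step$values
    dt <- step$dt
    stance <- step$stance_len
  } else {
    series <- as.numeric(step)
    stance <- .stance_length(series)
  }
  n <- length(series)
  # aspect condition: keep the embedding at least as wide as tall
  # (cols = n - rows + 1 >= rows)
  cap <- max((n + 1L) %/% 2L, 2L)
  if (identical(rows, "auto")) {
    grid <- unique(pmin(pmax(c(stance, ceiling(stance / 2), 25L), 2L), cap))
  } else if (identical(rows, "stance")) {
    grid <- min(max(stance, 2L), cap)
  } else {
    stopifnot(is.numeric(rows), rows >= 2)
    if (rows > n - 1) stop("stance too short: need rows <= length - 1")
    grid <- as.integer(rows)
  }
  best <- NULL
  for (m in grid) {
    D <- build_hankel(series, m, n - m + 1L)
    fit <- withCallingHandlers(
      exact_dmd(snapshot_pair(D), rank_rule = rank_rule, dt = dt),
      warning = function(w) {
        if (grepl("unattainable", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (is.null(best) || fit$fit_error < best$fit_error) best <- fit
  }
  best$series_len <- n
  best
}

# frames with signal above 0.5% of peak magnitude, counted to the last
# such frame (contact is contiguous in practice)
.stance_length <- function(values, rel = 0.005) {
  peak <- max(abs(values))
  if (peak == 0) return(0L)
  idx <- which(abs(values) > rel * peak)
  if (length(idx) == 0) 0L else as.integer(max(idx))
}

#' Reconstruct a scalar series from a DMD model
#'
#' Evaluates `s_n = sum_k mu_k^n v_k b_k` for `n = 0, ..., n_frames - 1`,
#' with `v_k` the first element of the k-th exact mode, and returns the
#' real part. For models of real signals the eigenvalues come in conjugate
#' pairs and the imaginary residual is at machine level; a warning is
#' raised if it exceeds 1e-9 of the signal scale.
#'
#' @param model A `dmd_model`.
#' @param n_frames Number of samples to generate.
#' @param n_modes Optional number of leading (energy-ordered) modes to
#'   keep; conjugate partners count separately. Default: all.
#' @return Numeric vector of length `n_frames`.
#' @export
reconstruct <- function(model, n_frames = model$series_len, n_modes = NULL) {
  stopifnot(inherits(model, "dmd_model"))
  if (is.null(n_frames)) n_frames <- model$cols
  keep <- seq_len(if (is.null(n_modes)) model$rank else min(n_modes, model$rank))
  mu <- model$eigvals[keep]
  coef <- model$mode_scalars[keep] * model$amplitudes[keep]
  powers <- outer(mu, 0:(n_frames - 1), `^`)
  s <- as.vector(coef %*% powers)
  scale <- max(Mod(s), .Machine$double.eps)
  if (max(abs(Im(s))) > 1e-9 * scale) {
    warning("reconstruction has non-negligible imaginary part (",
            format(max(abs(Im(s))) / scale), " of signal scale)")
  }
  Re(s)
}

#' Reconstruct keeping the leading conjugate pairs
#'
#' Convenience wrapper around [reconstruct()] that keeps the `n_pairs`
#' dominant conjugate pairs (by energy), i.e. `2 * n_pairs` modes.
#'
#' @inheritParams reconstruct
#' @param n_pairs Number of conjugate pairs to keep.
#' @export
reconstruct_pairs <- function(model, n_pairs, n_frames = model$series_len) {
  reconstruct(model, n_frames = n_frames, n_modes = 2L * n_pairs)
}

#' @export
print.dmd_model <- function(x, ...) {
  cat("<dmd_model> rank", x$rank, "| Hankel", x$rows, "x", x$cols,
      "| dt", x$dt, "s | fit error", format(x$fit_error, digits = 4), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DMD model into one row per mode
#'
#' @param x A `dmd_model`.
#' @param ... Unused.
#' @return A tibble with eigenvalue, decay rate (1/s), frequency (Hz),
#'   mode scalar and amplitude per mode, energy-ordered.
#' @export
tidy.dmd_model <- function(x, ...) {
  lmu <- log(x$eigvals)
  tibble::tibble(
    mode = seq_len(x$rank),
    eig_re = Re(x$eigvals),
    eig_im = Im(x$eigvals),
    alpha = Re(lmu) / x$dt,
    freq = Im(lmu) / (2 * pi * x$dt),
    s0_re = Re(x$mode_scalars * x$amplitudes),
    s0_im = Im(x$mode_scalars * x$amplitudes),
    energy = Mod(x$mode_scalars * x$amplitudes)
  )
}

#' One-row summary of a DMD model
#'
#' @param x A `dmd_model`.
#' @param ... Unused.
#' @export
glance.dmd_model <- function(x, ...) {
  tibble::tibble(rank = x$rank, rows = x$rows, cols = x$cols,
                 fit_error = x$fit_error, dt = x$dt,
                 max_mod = max(Mod(x$eigvals)))
}
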