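#' Convert a DMD eigenvalue to a mode feature triplet
#'
#' Maps a discrete-time eigenvalue mu (and its mode scalar v and
#' amplitude b) to continuous-time gait features via the principal
#' branch of the logarithm: decay rate `alpha = Re(log mu) / dt` (1/s),
#' frequency `freq = Im(log mu) / (2 pi dt)` (Hz), and the complex
#' initial condition `s0 = v * b` with modulus `|s0|` in force units.
#'
#' @param mu Complex eigenvalue(s), non-zero.
#' @param v Mode scalar(s): first element of the exact dynamic mode.
#' @param b Amplitude(s) b(s0).
#' @param dt Sampling interval in seconds.
#' @return Tibble with columns `mu`, `alpha`, `freq`, `s0_re`, `s0_im`,
#'   `s0`.
#' @export
eig_to_feature <- function(mu, v, b, dt) {
  stopifnot(dt > 0)
  mu <- as.complex(mu)
  if (any(mu == 0)) stop("eigenvalue 0 has no finite logarithm")
  lmu <- log(mu)
  s0c <- as.complex(v) * as.complex(b)
  tibble::tibble(
    mu = mu,
    alpha = Re(lmu) / dt,
    freq = Im(lmu) / (2 * pi * dt),
    s0_re = Re(s0c), s0_im = Im(s0c), s0 = Mod(s0c))
}

#' Pair conjugate modes into single representatives
#'
#' Modes of a real signal come in complex-conjugate pairs `(mu, mu*)`.
#' Each pair is collapsed to the representative with non-negative
#' frequency (`pair = TRUE`); real modes pass through as singletons with
#' `freq = 0` (or the Nyquist edge) and `pair = FALSE`. A complex mode
#' whose conjugate partner is missing beyond `tol` is kept as a
#' singleton with a warning.
#'
#' @param features Tibble from [eig_to_feature()] (must keep the `mu`
#'   column).
#' @param tol Absolute pairing tolerance on `|mu_i - Conj(mu_j)|`.
#' @return The representative rows with an added logical `pair` column;
#'   `ceiling(r / 2)` rows for a fully paired rank-r model.
#' @export
pair_conjugates <- function(features, tol = 1e-8) {
  mu <- features$mu
  n <- length(mu)
  used <- logical(n)
  reps <- integer(0)
  pairflag <- logical(0)
  for (i in seq_len(n)) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(mu[i])) <= tol) {   # real mode (incl. Nyquist edge mu < 0)
      reps <- c(reps, i)
      pairflag <- c(pairflag, FALSE)
      next
    }
    partner <- which(!used & Mod(mu - Conj(mu[i])) <= tol)
    if (length(partner) == 0) {
      warning("complex mode without conjugate partner (|mu| = ",
              format(Mod(mu[i]), digits = 4), "); kept as singleton")
      reps <- c(reps, i)
      pairflag <- c(pairflag, FALSE)
      next
    }
    partner <- partner[which.min(Mod(mu[partner] - Conj(mu[i])))]
    used[partner] <- TRUE
    keep <- if (features$freq[i] >= 0) i else partner
    reps <- c(reps, keep)
    pairflag <- c(pairflag, TRUE)
  }
  out <- features[reps, , drop = FALSE]
  out$pair <- pairflag
  out
}

#' Fixed-length, frequency-sorted feature set of one step
#'
#' Converts a fitted DMD model of one step into exactly `K` mode feature
#' triplets: eigenvalues become (alpha, freq, s0) triplets, conjugate
#' pairs are collapsed to their non-negative-frequency representatives,
#' and the representatives are sorted by ascending frequency (ties: more
#' negative alpha first, then larger s0). If more than `K` remain, the
#' K largest-s0 representatives are kept (then re-sorted by frequency);
#' if fewer, null rows flagged `missing` pad the set, so feature sets
#' are comparable across steps by mode rank.
#'
#' @param model A `dmd_model` from [hankel_dmd()].
#' @param K Number of mode-pair features (default 6).
#' @param tol Conjugate-pairing tolerance, see [pair_conjugates()].
#' @return Tibble with `K` rows: `mode_rank`, `alpha`, `freq`, `s0`,
#'   `s0_re`, `s0_im`, `pair`, `missing`.
#' @export
featurize_step <- function(model, K = 6, tol = 1e-8) {
  stopifnot(inherits(model, "dmd_model"), K >= 1)
  if (model$rank == 0) stop("empty model: no modes to featurize")
  feats <- eig_to_feature(model$eigvals, model$mode_scalars,
                          model$amplitudes, model$dt)
  reps <- pair_conjugates(feats, tol = tol)
  reps <- dplyr::arrange(reps, .data$freq, .data$alpha,
                         dplyr::desc(.data$s0))
  if (nrow(reps) > K) {
    keep <- order(reps$s0, decreasing = TRUE)[seq_len(K)]
    reps <- reps[sort(keep), , drop = FALSE]
  }
  reps$missing <- FALSE
  if (nrow(reps) < K) {
    pad <- tibble::tibble(
      mu = complex(real = rep(NA_real_, K - nrow(reps))),
      alpha = NA_real_, freq = NA_real_, s0_re = NA_real_,
      s0_im = NA_real_, s0 = NA_real_, pair = NA, missing = TRUE)
    reps <- dplyr::bind_rows(reps, pad)
  }
  reps$mode_rank <- seq_len(K)
  dplyr::select(reps, "mode_rank", "alpha", "freq", "s0",
                "s0_re", "s0_im", "pair", "missing")
}

#' Featurize a table of step signals
#'
#' Runs [hankel_dmd()] + [featurize_step()] over a tibble of steps (as
#' produced by [simulate_cohort_steps()] or [extract_steps()]) and binds
#' the resulting triplets with the step metadata.
#'
#' @param steps Tibble with a `signal` list-column of [step_signal()]
#'   objects; metadata columns (`person`, `foot`, `speed`, `cycle`, ...)
#'   are carried through.
#' @param K Mode pairs per step (default 6).
#' @param rows,rank_rule Passed to [hankel_dmd()]. The defaults -- a
#'   stance-deep Hankel matrix and a fixed rank `2 * K` -- mirror the
#'   construction and the r = 12 truncation that the tolerance rule
#'   selects on clean steps, and stay stable on noisy ones, where the
#'   residual-minimising depth search would overfit.
#' @return Long tibble: one row per step and mode rank.
#' @export
featurize_steps <- function(steps, K = 6, rows = "stance",
                            rank_rule = rank_fixed(2 * K)) {
  stopifnot(is.data.frame(steps), "signal" %in% names(steps))
  meta <- dplyr::select(steps, -dplyr::any_of("signal"))
  purrr::map_dfr(seq_len(nrow(steps)), function(i) {
    model <- hankel_dmd(steps$signal[[i]], rows = rows,
                        rank_rule = rank_rule)
    dplyr::bind_cols(meta[rep(i, K), , drop = FALSE],
                     featurize_step(model, K = K))
  })
}

#' Reconstruct a force series from feature triplets
#'
#' Evaluates the mode expansion
#' `s_n = sum_k 2 Re(s0_k e^{(alpha_k + 2 pi i f_k) n dt})` for paired
#' representatives (singleton real modes contribute without the factor
#' 2), the inverse of [featurize_step()]'s eigenvalue mapping. Missing
#' (padded) features are skipped.
#'
#' @param features Feature tibble of one step (from [featurize_step()]).
#' @param n_frames Number of samples.
#' @param dt Sampling interval in seconds.
#' @return Numeric series of length `n_frames`.
#' @export
reconstruct_from_features <- function(features, n_frames, dt) {
  stopifnot(dt > 0, n_frames >= 1)
  n <- 0:(n_frames - 1)
  s <- numeric(n_frames)
  for (i in seq_len(nrow(features))) {
    if (isTRUE(features$missing[i])) next
    s0c <- complex(real = features$s0_re[i], imaginary = features$s0_im[i])
    term <- s0c * exp((features$alpha[i] + 2i * pi * features$freq[i]) *
                        n * dt)
    s <- s + if (isTRUE(features$pair[i])) 2 * Re(term) else Re(term)
  }
  s
}

#' Write a long feature table as CSV
#'
#' @param features Feature tibble (any metadata columns plus the triplet
#'   columns).
#' @param path Output path.
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(dplyr::select(features, -dplyr::any_of("mu")), path)
  invisible(path)
}
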