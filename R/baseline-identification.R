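#' Per-person centroid baseline over step feature sets
#'
#' Averages a person's per-step mode triplets into centroids and computes
#' the spread weights used by the identification cost: per mode rank and
#' component (alpha, freq, s0), the centroid is the arithmetic mean over
#' steps and the spread is the reciprocal sample standard deviation
#' `S = [ (1/(C-1)) sum_c (F_c - <F>)^2 ]^{-1/2}`.
#'
#' @param steps Long feature tibble of one person/foot/speed (rows = step
#'   x mode rank), at least 2 steps.
#' @param spread_cap Ceiling for the spread when a component has zero
#'   within-person variance (degenerate, e.g. jitter-free synthetic
#'   steps); applied with a warning.
#' @return Tibble with one row per mode rank: centroid and spread per
#'   component, plus `n_steps` and any constant metadata columns
#'   (`person`, `foot`, `speed`).
#' @export
compute_baseline <- function(steps, spread_cap = 1e6) {
  stopifnot(is.data.frame(steps))
  for (col in c("person", "foot", "speed")) {
    if (col %in% names(steps) && dplyr::n_distinct(steps[[col]]) > 1) {
      stop("steps mix several values of '", col,
           "'; compute baselines per person/foot/speed")
    }
  }
  C <- dplyr::n_distinct(steps$cycle)
  if (C < 2) stop("need at least 2 steps to form a baseline, got ", C)
  inv_sd <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("zero within-person variance; spread capped at ",
              format(spread_cap))
      spread_cap
    } else min(1 / s, spread_cap)
  }
  out <- dplyr::summarise(
    dplyr::group_by(steps, .data$mode_rank),
    centroid_alpha = mean(.data$alpha), centroid_freq = mean(.data$freq),
    centroid_s0 = mean(.data$s0),
    spread_alpha = inv_sd(.data$alpha), spread_freq = inv_sd(.data$freq),
    spread_s0 = inv_sd(.data$s0),
    n_steps = C, .groups = "drop")
  for (col in c("person", "foot", "speed")) {
    if (col %in% names(steps)) out[[col]] <- steps[[col]][1]
  }
  out
}

#' Build an identification gallery of baselines
#'
#' One baseline per person (and per foot/speed stratum when those
#' columns are present).
#'
#' @param features Long feature tibble for several persons.
#' @param spread_cap See [compute_baseline()].
#' @return Tibble of stacked baselines; person order (enrollment order)
#'   is first appearance in `features` and is the deterministic
#'   tie-break order of [identify_person()].
#' @export
build_gallery <- function(features, spread_cap = 1e6) {
  strata <- intersect(c("person", "foot", "speed"), names(features))
  grp <- dplyr::group_by(features, dplyr::across(dplyr::all_of(strata)))
  keys <- dplyr::group_keys(grp)
  parts <- dplyr::group_split(grp)
  out <- purrr::map_dfr(parts, compute_baseline, spread_cap = spread_cap)
  # preserve enrollment order
  out[order(match(out$person, unique(features$person))), , drop = FALSE]
}

#' Identification cost of probe steps against one baseline
#'
#' The spread-weighted squared deviation of the probe's mode triplets
#' from a candidate's centroids,
#' `l = sum_k (1/Cs) sum_c S_k . (F_kc - <F_k>)^2`,
#' with `S_k` the baseline's reciprocal-standard-deviation vector and
#' `.` the componentwise dot product over (alpha, freq, s0). With
#' `standardized = TRUE` the weights are squared (`(d/sigma)^2`, a true
#' squared Mahalanobis distance with diagonal covariance).
#'
#' @param probe_steps Long feature tibble of the probe's steps.
#' @param baseline A [compute_baseline()] tibble.
#' @param standardized Use inverse-variance weights instead of the
#'   default inverse-standard-deviation weights.
#' @return Non-negative scalar; zero iff every probe step equals the
#'   centroids exactly.
#' @export
identification_cost <- function(probe_steps, baseline,
                                standardized = FALSE) {
  stopifnot(nrow(probe_steps) > 0)
  if (!setequal(unique(probe_steps$mode_rank), baseline$mode_rank)) {
    stop("mode-rank mismatch between probe steps and baseline")
  }
  j <- dplyr::inner_join(probe_steps, baseline, by = "mode_rank")
  pw <- if (standardized) 2 else 1
  dev <- j$spread_alpha^pw * (j$alpha - j$centroid_alpha)^2 +
    j$spread_freq^pw * (j$freq - j$centroid_freq)^2 +
    j$spread_s0^pw * (j$s0 - j$centroid_s0)^2
  Cs <- dplyr::n_distinct(probe_steps$cycle)
  sum(dev) / Cs
}

#' Identify a probe walker against a gallery
#'
#' Computes the identification cost against every enrolled baseline and
#' returns the argmin label. Ties break deterministically by enrollment
#' order (with a message when triggered).
#'
#' @param probe_steps Long feature tibble of the probe's steps.
#' @param gallery A [build_gallery()] tibble (single foot/speed stratum).
#' @param standardized See [identification_cost()].
#' @return List with `person` (estimated label) and `costs` (tibble
#'   person/cost in enrollment order).
#' @export
identify_person <- function(probe_steps, gallery, standardized = FALSE) {
  persons <- unique(gallery$person)
  if (length(persons) == 0) stop("empty gallery")
  costs <- vapply(persons, function(p) {
    identification_cost(probe_steps,
                        gallery[gallery$person == p, , drop = FALSE],
                        standardized = standardized)
  }, numeric(1))
  hit <- which(costs == min(costs))
  if (length(hit) > 1) message("cost tie; resolved by enrollment order")
  list(person = persons[hit[1]],
       costs = tibble::tibble(person = persons, cost = unname(costs)))
}

#' Monte-Carlo identification accuracy over random step subsets
#'
#' The validation protocol: per repeat, draw a person uniformly, draw
#' `ceiling(fraction * C)` of their steps uniformly without replacement,
#' score whether the minimum-cost baseline is theirs, and report the
#' fraction of correct identifications per foot/speed stratum. With
#' `holdout = TRUE` the probe person's baseline is recomputed without
#' the drawn steps, and every other candidate's baseline is subsampled
#' to the same step count, so that no probe/enrollment leakage remains
#' and all candidates are scored on equal footing (for indistinguishable
#' walkers this makes the protocol exactly exchangeable, i.e. a true
#' chance-level null).
#'
#' @param features Long feature tibble (persons x steps x mode ranks),
#'   with `foot`/`speed` columns defining strata when present.
#' @param fraction Probe subset fraction in (0, 1] (default 0.3).
#' @param n_repeats Monte-Carlo repeats per stratum.
#' @param seed RNG seed; reports are pure functions of inputs + seed.
#' @param holdout Recompute the probe's baseline excluding probe steps.
#' @param standardized See [identification_cost()].
#' @return Object of class `gait_eval`: list with `summary` (tibble:
#'   stratum, accuracy, n_repeats), `confusion` (tibble of true/predicted
#'   counts), `fraction`, `seed`, `holdout`.
#' @export
evaluate_identification <- function(features, fraction = 0.3,
                                    n_repeats = 1000, seed = 1,
                                    holdout = FALSE, standardized = FALSE) {
  stopifnot(fraction > 0, fraction <= 1, n_repeats >= 1)
  strata <- intersect(c("foot", "speed"), names(features))
  if (length(strata) == 0) {
    features$foot <- "all"
    strata <- "foot"
  }
  grp <- dplyr::group_by(features, dplyr::across(dplyr::all_of(strata)))
  keys <- dplyr::group_keys(grp)
  parts <- dplyr::group_split(grp)
  summaries <- list()
  confusions <- list()
  for (g in seq_along(parts)) {
    res <- .evaluate_stratum(parts[[g]], fraction, n_repeats,
                             seed + g - 1L, holdout, standardized)
    summaries[[g]] <- dplyr::bind_cols(keys[g, , drop = FALSE], res$summary)
    confusions[[g]] <- dplyr::bind_cols(keys[rep(g, nrow(res$confusion)), ,
                                             drop = FALSE], res$confusion)
  }
  structure(list(summary = dplyr::bind_rows(summaries),
                 confusion = dplyr::bind_rows(confusions),
                 fraction = fraction, seed = as.integer(seed),
                 holdout = holdout),
            class = "gait_eval")
}

.evaluate_stratum <- function(features, fraction, n_repeats, seed,
                              holdout, standardized) {
  persons <- unique(features$person)
  comp <- c("alpha", "freq", "s0")
  # per-person step x (mode, component) matrices, rank-aligned
  featmat <- lapply(persons, function(p) {
    f <- features[features$person == p, , drop = FALSE]
    f <- dplyr::arrange(f, .data$cycle, .data$mode_rank)
    K <- max(f$mode_rank)
    C <- nrow(f) / K
    m <- matrix(unlist(f[, comp]), nrow = nrow(f))
    do.call(rbind, lapply(seq_len(C), function(cix) {
      as.vector(m[(cix - 1) * K + seq_len(K), ])
    }))
  })
  names(featmat) <- persons
  need <- ceiling(1 / fraction)
  short <- persons[vapply(featmat, nrow, integer(1)) < need]
  if (length(short) > 0) {
    stop("not enough steps for fraction = ", fraction, ": ",
         paste(short, collapse = ", "))
  }
  bl <- function(M) {
    mu <- colMeans(M)
    sdv <- apply(M, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1e-6
    list(mu = mu, w = pmin(1 / sdv, 1e6))
  }
  base <- lapply(featmat, bl)
  pw <- if (standardized) 2 else 1
  counts <- matrix(0L, length(persons), length(persons),
                   dimnames = list(true = persons, predicted = persons))
  correct <- 0L
  withr::with_seed(as.integer(seed), {
    for (rep_i in seq_len(n_repeats)) {
      p <- sample(persons, 1)
      M <- featmat[[p]]
      Cs <- ceiling(fraction * nrow(M))
      pick <- sample(nrow(M), Cs)
      P <- M[pick, , drop = FALSE]
      costs <- vapply(persons, function(q) {
        b <- if (!holdout) {
          base[[q]]
        } else if (q == p) {
          bl(M[-pick, , drop = FALSE])
        } else {
          # equal-footing enrollment: same baseline size for everyone
          Mq <- featmat[[q]]
          keep_n <- nrow(Mq) - ceiling(fraction * nrow(Mq))
          bl(Mq[sample(nrow(Mq), keep_n), , drop = FALSE])
        }
        mean(as.vector((sweep(P, 2, b$mu)^2) %*% (b$w^pw)))
      }, numeric(1))
      pred <- persons[which.min(costs)]
      counts[p, pred] <- counts[p, pred] + 1L
      if (pred == p) correct <- correct + 1L
    }
  })
  conf <- as.data.frame.table(counts, responseName = "n",
                              stringsAsFactors = FALSE)
  conf <- tibble::as_tibble(conf[conf$n > 0, , drop = FALSE])
  list(summary = tibble::tibble(accuracy = correct / n_repeats,
                                n_repeats = as.integer(n_repeats),
                                n_persons = length(persons)),
       confusion = conf)
}

#' @export
print.gait_eval <- function(x, ...) {
  cat("<gait_eval>", x$summary$n_repeats[1], "repeats, probe fraction",
      x$fraction, if (x$holdout) "(held-out baselines)" else
        "(full baselines)", "\n")
  print(x$summary)
  invisible(x)
}

#' Tidy an identification evaluation report
#'
#' @param x A `gait_eval` object.
#' @param ... Unused.
#' @export
tidy.gait_eval <- function(x, ...) x$summary

#' One-row summary of an evaluation report
#'
#' @param x A `gait_eval` object.
#' @param ... Unused.
#' @export
glance.gait_eval <- function(x, ...) {
  tibble::tibble(mean_accuracy = mean(x$summary$accuracy),
                 n_strata = nrow(x$summary),
                 n_repeats = x$summary$n_repeats[1],
                 fraction = x$fraction, holdout = x$holdout,
                 seed = x$seed)
}
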