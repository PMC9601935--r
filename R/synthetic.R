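#' Specification for a synthetic risk-factor table
#'
#' Describes a UCI-schema-like table: a mix of right-skewed continuous
#' factors (age-like, years-like) and Bernoulli binary factors, four binary
#' screening-test targets with controllable prevalence, an optional planted
#' logistic factor-label signal per target, and optional missingness. The
#' defaults emulate the real screening table this pipeline family targets:
#' 858 patients, 30 factors (about two-thirds binary), and prevalences of
#' 4.5% (Hinselmann), 9.4% (Schiller), 5.8% (Cytology), 6.7% (Biopsy).
#'
#' @param n_rows Number of patients. Default 858.
#' @param n_factors Number of risk factors. Default 30.
#' @param binary_factor_ids Which factors are binary. Default: the
#'   indicator-style ids of the emulated schema (contraception, IUD, STD
#'   and diagnosis flags), intersected with `1:n_factors`.
#' @param prevalence Named probabilities in (0, 1), one per target.
#' @param signal_factors Named list: per target, a list with `ids` (factor
#'   numbers) and `effects` (log-odds coefficients per standardised factor).
#'   Default: no signal (`NULL` entries).
#' @param noise_scale Scale of the continuous factors. Default 1.
#' @param missing_rate Per-cell missingness probability for factor cells.
#'   Default 0.
#' @param seed Integer seed; generation is fully reproducible given it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_rows = 858L, n_factors = 30L,
                           binary_factor_ids = default_binary_ids(n_factors),
                           prevalence = c(Hinselmann = 0.045, Schiller = 0.094,
                                          Cytology = 0.058, Biopsy = 0.067),
                           signal_factors = NULL,
                           noise_scale = 1, missing_rate = 0, seed = 1L) {
  n_rows <- as.integer(n_rows)
  n_factors <- as.integer(n_factors)
  stopifnot(n_rows >= 2L, n_factors >= 1L,
            all(binary_factor_ids %in% seq_len(n_factors)),
            length(prevalence) >= 1L, !is.null(names(prevalence)),
            all(prevalence > 0 & prevalence < 1),
            noise_scale > 0, missing_rate >= 0, missing_rate < 1)
  if (!is.null(signal_factors)) {
    stopifnot(all(names(signal_factors) %in% names(prevalence)))
    for (sf in signal_factors) {
      if (is.null(sf)) next
      stopifnot(all(sf$ids %in% seq_len(n_factors)),
                length(sf$ids) == length(sf$effects))
    }
  }
  structure(list(n_rows = n_rows, n_factors = n_factors,
                 binary_factor_ids = as.integer(binary_factor_ids),
                 prevalence = prevalence, signal_factors = signal_factors,
                 noise_scale = noise_scale, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Indicator-style factors of the emulated schema (smoking, contraception,
# IUD, STD flags, diagnosis flags); everything else is continuous.
default_binary_ids <- function(n_factors) {
  intersect(c(5L, 8L, 10L, 12L, 14L:25L, 27L:32L), seq_len(n_factors))
}

#' Generate a synthetic risk-factor table
#'
#' Continuous factors are drawn from right-skewed non-negative
#' distributions (the first factor is age-like: 15 + a gamma draw; the rest
#' are years-like gamma draws scaled by `noise_scale`); binary factors are
#' Bernoulli. Each target is drawn from a logistic model on its planted
#' signal factors (standardised), with the intercept placed at the target
#' prevalence; the positive count is then adjusted to exactly
#' `round(n_rows * prevalence)` by flipping the labels of the rows whose
#' model probabilities sit closest to the decision boundary. Missing cells
#' are injected into factor columns at `missing_rate`.
#'
#' @param spec A [synthetic_spec()].
#' @return A `raw_table` (same class as [read_table()] returns) with
#'   `n_factors` factor columns named `factor_01`, ... and the four target
#'   columns. Targets missing from `spec$prevalence` are not emitted.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_rows
  p <- spec$n_factors
  with_seed(derive_seed(spec$seed, "synth"), {
    X <- matrix(0, n, p)
    for (j in seq_len(p)) {
      if (j %in% spec$binary_factor_ids) {
        X[, j] <- stats::rbinom(n, 1L, 0.2)
      } else if (j == 1L) {
        X[, j] <- round(15 + stats::rgamma(n, shape = 2.5, scale = 5))
      } else {
        X[, j] <- round(stats::rgamma(n, shape = 1.5, scale = 2 * spec$noise_scale), 2)
      }
    }
    targets <- matrix(0L, n, length(spec$prevalence))
    colnames(targets) <- names(spec$prevalence)
    for (t in names(spec$prevalence)) {
      prev <- spec$prevalence[[t]]
      m <- as.integer(round(n * prev))
      if (m < 1L || m >= n) {
        stop(sprintf("infeasible prevalence %.4f for target %s at n = %d", prev, t, n))
      }
      eta <- rep(stats::qlogis(prev), n)
      sf <- spec$signal_factors[[t]]
      if (!is.null(sf) && length(sf$ids) > 0L) {
        for (i in seq_along(sf$ids)) {
          col <- X[, sf$ids[[i]]]
          s <- stats::sd(col)
          z <- if (s > 0) (col - mean(col)) / s else col * 0
          eta <- eta + sf$effects[[i]] * z
        }
      }
      pr <- stats::plogis(eta)
      y <- stats::rbinom(n, 1L, pr)
      # exact-count adjustment: flip the labels nearest the boundary
      excess <- sum(y) - m
      if (excess > 0L) {
        pos <- which(y == 1L)
        y[pos[order(pr[pos], pos)][seq_len(excess)]] <- 0L
      } else if (excess < 0L) {
        neg <- which(y == 0L)
        y[neg[order(-pr[neg], neg)][seq_len(-excess)]] <- 1L
      }
      targets[, t] <- y
    }
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
      X[mask] <- NA_real_
    }
    values <- cbind(X, targets)
    colnames(values) <- c(sprintf("factor_%02d", seq_len(p)), colnames(targets))
    structure(list(values = values, n_rows = n,
                   factor_names = sprintf("factor_%02d", seq_len(p)),
                   target_names = colnames(targets)),
              class = "raw_table")
  })
}

#' Two separable Gaussian clouds
#'
#' A standard linearly separable fixture: balanced labels, standard-normal
#' features, and the class means pushed `margin` apart along one random
#' unit direction. With a large margin (e.g. 6) the classes are essentially
#' perfectly separable; with margin 0 they coincide and any classifier is
#' at chance.
#'
#' @param n_rows Even number of rows.
#' @param n_factors Number of feature columns. Default 30.
#' @param margin Distance between class means. Must be >= 0.
#' @param seed Integer seed.
#' @return List with `X` (matrix) and `y` (balanced 0/1 vector).
#' @export
make_separable <- function(n_rows, n_factors = 30L, margin = 6, seed = 1L) {
  n_rows <- as.integer(n_rows)
  if (n_rows < 2L || n_rows %% 2L != 0L) stop("n_rows must be an even integer >= 2")
  stopifnot(margin >= 0)
  with_seed(derive_seed(seed, "separable"), {
    u <- stats::rnorm(n_factors)
    u <- u / sqrt(sum(u^2))
    y <- sample(rep(c(0L, 1L), each = n_rows %/% 2L))
    X <- matrix(stats::rnorm(n_rows * n_factors), n_rows, n_factors) +
      outer(ifelse(y == 1L, margin / 2, -margin / 2), u)
    list(X = X, y = y)
  })
}
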