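# Empirical-Bayes variance moderation for paired tests. The per-site
# variance of pair differences is shrunk toward a prior via the standard
# scaled inverse-chi-square hierarchy: the posterior variance is
# (d0 * s0^2 + df * s2) / (d0 + df) and the moderated t gains d0 extra
# degrees of freedom. Hyperparameters (d0, s0^2) are fitted by moment
# matching on log(s2) across sites.

#' Variance-moderation hyperparameters
#'
#' @param prior_df Prior degrees of freedom `d0` (>= 0; 0 reduces the
#'   moderated test to the ordinary paired t-test; `Inf` pools all sites to
#'   the common prior variance).
#' @param prior_var Prior variance `s0^2` (> 0). Ignored (may be `NA`) when
#'   `prior_df` is 0.
#' @return Object of class `moderation_params`.
#' @export
moderation_params <- function(prior_df, prior_var = NA_real_) {
  if (!is.numeric(prior_df) || length(prior_df) != 1 || is.na(prior_df) ||
      prior_df < 0)
    stop("prior_df must be a single number >= 0", call. = FALSE)
  if (prior_df > 0 && (!is.numeric(prior_var) || is.na(prior_var) ||
                       prior_var <= 0))
    stop("prior_var must be > 0 when prior_df > 0", call. = FALSE)
  structure(list(prior_df = prior_df, prior_var = prior_var),
            class = "moderation_params")
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma, which
# is nearly linear; converges in a handful of steps for x > 0.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moment-matched moderation hyperparameters
#'
#' Fits the scaled-F model for observed per-site variances: with `e =
#' log(s2) - digamma(df/2) + log(df/2)`, the excess of `var(e)` over
#' `trigamma(df/2)` identifies `d0`, and the mean of `e` identifies `s0^2`.
#' Sites with zero or missing variance are excluded from the fit. When the
#' observed spread is no larger than the sampling spread, `d0 = Inf` and
#' `s0^2 = exp(mean(e))` (complete pooling).
#'
#' @param s2 Per-site sample variances of pair differences.
#' @param df Residual degrees of freedom (scalar or per-site).
#' @return A [moderation_params()].
#' @export
estimate_moderation <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- !is.na(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2)
    stop("too few positive variances to estimate moderation", call. = FALSE)
  s2 <- s2[ok]; df <- df[ok]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (is.na(evar) || evar <= 0)
    return(moderation_params(Inf, exp(emean)))
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  moderation_params(d0, s02)
}

# Core moderated paired statistics on a site x pair matrix of differences.
# Returns delta, s2, df (complete pairs - 1), t_mod, p and the moderation
# actually used. NA cells are pairwise-excluded; rows with < 2 complete
# pairs get NA statistics.
paired_stats_core <- function(dmat, moderation = "estimate") {
  n_pairs <- rowSums(!is.na(dmat))
  delta <- rowMeans(dmat, na.rm = TRUE)
  s2 <- row_vars_na(dmat)
  df <- n_pairs - 1L
  testable <- n_pairs >= 2L

  if (identical(moderation, "estimate")) {
    moderation <- estimate_moderation(s2[testable], df[testable])
  } else if (identical(moderation, "none")) {
    moderation <- moderation_params(0)
  }
  if (!inherits(moderation, "moderation_params"))
    stop("moderation must be 'estimate', 'none' or moderation_params()",
         call. = FALSE)
  d0 <- moderation$prior_df
  s02 <- moderation$prior_var

  post_var <- if (d0 == 0) s2
    else if (is.infinite(d0)) rep_len(s02, length(s2))
    else (d0 * s02 + df * s2) / (d0 + df)
  t_mod <- delta / sqrt(post_var / n_pairs)
  total_df <- d0 + df
  p <- 2 * pt(-abs(t_mod), df = pmin(total_df, .Machine$double.xmax))
  # Zero posterior variance (only possible without a prior): a nonzero
  # difference is then infinitely significant, an all-zero one is null.
  degenerate <- testable & !is.na(post_var) & post_var == 0
  t_mod[degenerate] <- ifelse(delta[degenerate] == 0, 0,
                              sign(delta[degenerate]) * Inf)
  p[degenerate] <- ifelse(delta[degenerate] == 0, 1, 0)
  p[testable & !is.na(t_mod) & t_mod == 0] <- 1

  list(delta = delta, s2 = s2, df = df, n_pairs = n_pairs, t_mod = t_mod,
       p = p, testable = testable, moderation = moderation)
}
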