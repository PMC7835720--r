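#' Percent-correct analysis of grasp-quality judgments
#'
#' The dependent measure throughout is percent correct: the percentage of
#' trials in which the model-optimal (near-optimal) grasp was judged the
#' better one, with chance at 50%. Frequentist inference uses one-sample and
#' paired t-tests against chance and bootstrapped confidence intervals of
#' the mean; Bayesian inference uses a robust (t-likelihood) estimation of
#' the group mean with 95% highest density intervals, standardized effect
#' sizes, and the posterior mass of the effect size inside a region of
#' practical equivalence of -0.4 to 0.4.
#'
#' @name analysis_stats
NULL

#' Percent correct per grouping cell
#'
#' @param records trial data.frame with a `chose_near_optimal` 0/1 column
#' @param by grouping columns (default participant x session)
#' @return data.frame with the grouping columns, `n_trials` and
#'   `percent_correct` (0-100). Cells absent from the records are simply not
#'   rows; requested-but-empty crossings are reported in the
#'   `"excluded"` attribute.
#' @export
percent_correct <- function(records, by = c("participant", "session")) {
  if (!nrow(records)) stopf("percent_correct: no records")
  f <- lapply(records[by], factor)
  agg <- stats::aggregate(records$chose_near_optimal, f, function(x) c(n = length(x), pc = 100 * mean(x)))
  out <- data.frame(agg[by], n_trials = agg$x[, "n"], percent_correct = agg$x[, "pc"],
                    stringsAsFactors = FALSE)
  for (b in by) out[[b]] <- type.convert(as.character(out[[b]]), as.is = TRUE)
  full <- Reduce(`*`, vapply(f, nlevels, 0L))
  if (nrow(out) < full) {
    attr(out, "excluded") <- full - nrow(out)
    message(sprintf("percent_correct: %d empty cell(s) excluded", full - nrow(out)))
  }
  out[do.call(order, out[by]), , drop = FALSE]
}

#' One-sample t-test of percent correct against chance
#'
#' @param values per-participant percent-correct values
#' @param chance null value (default 50)
#' @return list of class `grasp_test`: t, df, p, mean_diff, n
#' @export
one_sample_t <- function(values, chance = 50) {
  if (length(values) < 2) stopf("one_sample_t: need n >= 2")
  if (stats::sd(values) < 1e-12) stopf("one_sample_t: zero variance")
  tt <- stats::t.test(values, mu = chance)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = mean(values) - chance,
                 n = length(values), type = "one-sample"),
            class = "grasp_test")
}

#' Paired t-test between two sessions
#'
#' A one-sample t-test on within-participant differences against zero.
#'
#' @param a,b equal-length per-participant values, paired by position
#' @return `grasp_test`
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stopf("paired_t: length mismatch (%d vs %d)", length(a), length(b))
  one_sample_t(a - b, 0)
}

#' Unpaired (Welch) t-test between two groups
#'
#' @param a,b per-participant values from independent groups
#' @param pooled use the pooled-variance (classical) variant instead of Welch
#' @return `grasp_test`
#' @export
unpaired_t <- function(a, b, pooled = FALSE) {
  if (length(a) < 2 || length(b) < 2) stopf("unpaired_t: need n >= 2 per group")
  tt <- stats::t.test(a, b, var.equal = pooled)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = mean(a) - mean(b),
                 n = c(length(a), length(b)),
                 type = if (pooled) "pooled two-sample" else "Welch two-sample"),
            class = "grasp_test")
}

#' @export
print.grasp_test <- function(x, ...) {
  cat(sprintf("%s t-test: t(%.4g) = %.3f, p = %.3g, mean difference = %.2f\n",
              x$type, x$df, x$t, x$p, x$mean_diff))
  invisible(x)
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param values numeric sample, n >= 2
#' @param reps bootstrap resamples (default 10000)
#' @param level confidence level (default 0.95)
#' @param seed integer seed
#' @return length-2 numeric (low, high)
#' @export
bootstrap_ci <- function(values, reps = 10000, level = 0.95, seed = 1L) {
  if (length(values) < 2) stopf("bootstrap_ci: need n >= 2")
  set.seed(as.integer(seed) %% 2147483647L)
  n <- length(values)
  means <- colMeans(matrix(sample(values, n * reps, replace = TRUE), nrow = n))
  unname(stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Standardized effect sizes
#'
#' `(mean - chance) / sd` for a difference from chance, and
#' `mean(a - b) / sd(a - b)` for a paired difference between sessions.
#'
#' @param values per-participant values
#' @param chance null value (default 50)
#' @return dimensionless effect size
#' @export
effect_size <- function(values, chance = 50) {
  s <- stats::sd(values)
  if (s < 1e-12) stopf("effect_size: zero standard deviation")
  (mean(values) - chance) / s
}

#' @rdname effect_size
#' @param a,b paired per-participant values
#' @export
effect_size_paired <- function(a, b) {
  if (length(a) != length(b)) stopf("effect_size_paired: length mismatch")
  effect_size(a - b, 0)
}

#' Highest density interval of a sample
#'
#' Shortest window over the sorted draws containing `level` of them.
#'
#' @param samples numeric vector of (posterior) draws
#' @param level mass to cover (default 0.95)
#' @return length-2 numeric (low, high)
#' @export
hdi <- function(samples, level = 0.95) {
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(level * n)
  if (m >= n) return(c(x[1], x[n]))
  w <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(w)
  c(x[i], x[i + m])
}

#' Posterior mass inside a region of practical equivalence
#'
#' @param samples effect-size draws
#' @param rope length-2 bounds (default -0.4 to 0.4)
#' @return fraction in [0, 1]
#' @export
rope_fraction <- function(samples, rope = c(-0.4, 0.4)) {
  if (rope[1] > rope[2]) stopf("rope_fraction: bounds must be ordered")
  mean(samples >= rope[1] & samples <= rope[2])
}

## ---- BEST-style Bayesian estimation ----------------------------------------

# log posterior for the one-group robust model; theta = (mu, log sigma, log(nu - 1))
.lp_one <- function(theta, y, m0, s0, ls_lo, ls_hi) {
  mu <- theta[1]; ls <- theta[2]; lnu <- theta[3]
  if (ls < ls_lo || ls > ls_hi) return(-Inf)
  sigma <- exp(ls); nu <- exp(lnu) + 1
  sum(stats::dt((y - mu) / sigma, nu, log = TRUE) - ls) +
    stats::dnorm(mu, m0, s0, log = TRUE) +
    stats::dexp(nu - 1, 1 / 29, log = TRUE) + lnu
}

# seeded adaptive random-walk Metropolis; componentwise updates
.rw_metropolis <- function(lp, init, n_iter, burn, seed, scales) {
  set.seed(seed)
  d <- length(init)
  draws <- matrix(NA_real_, n_iter - burn, d)
  cur <- init; cur_lp <- lp(cur)
  acc <- numeric(d); win <- numeric(d)
  for (it in seq_len(n_iter)) {
    for (k in seq_len(d)) {
      prop <- cur
      prop[k] <- cur[k] + stats::rnorm(1, 0, scales[k])
      new_lp <- lp(prop)
      win[k] <- win[k] + 1
      if (is.finite(new_lp) && log(stats::runif(1)) < new_lp - cur_lp) {
        cur <- prop; cur_lp <- new_lp; acc[k] <- acc[k] + 1
      }
    }
    # tune proposal scales toward ~30% acceptance during burn-in
    if (it <= burn && it %% 100 == 0) {
      rate <- acc / pmax(win, 1)
      scales <- scales * exp((rate - 0.3))
      acc[] <- 0; win[] <- 0
    }
    if (it > burn) draws[it - burn, ] <- cur
  }
  draws
}

# split-chain potential scale reduction factor
.rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- floor(length(x) / 2)
    list(x[1:h], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Robust Bayesian estimation of percent-correct differences
#'
#' BEST-style estimation with a t-distributed likelihood and broad priors:
#' normal prior on the mean centered at the sample mean with a scale 1000
#' times the sample SD, a uniform-on-log prior on the scale within a factor
#' 1000 of the sample SD, and a shifted-exponential prior (mean 30) on the
#' normality parameter. Sampling is by seeded adaptive random-walk
#' Metropolis, 4 chains of 10,000 draws after 2,000 burn-in by default, with
#' a split-Rhat convergence gate at 1.1.
#'
#' One-group usage compares `values` with `chance` (effect size
#' `(mu - chance)/sigma`); `b` with `paired = TRUE` estimates the paired
#' difference `values - b` against zero; `b` with `paired = FALSE` fits the
#' two-group model with per-group means and scales, shared normality, and
#' effect size `(mu1 - mu2)/sqrt((sigma1^2 + sigma2^2)/2)`.
#'
#' @param values numeric sample (group 1)
#' @param chance null/reference value for the one-group form (default 50)
#' @param b optional second sample
#' @param paired treat `b` as paired with `values`
#' @param rope effect-size region of practical equivalence (default +/-0.4)
#' @param chains,draws,burn MCMC geometry (post-burn-in draws per chain)
#' @param seed integer seed
#' @return list of class `bayes_estimate`: posterior draws of `mu` (the mean
#'   difference, in percentage points), `sigma`, `nu` and `effect_size`;
#'   `hdi95` of the mean difference; `effect_hdi95`; `rope_fraction`;
#'   `rhat`
#' @export
bayes_estimate <- function(values, chance = 50, b = NULL, paired = FALSE,
                           rope = c(-0.4, 0.4), chains = 4, draws = 10000,
                           burn = 2000, seed = 1L) {
  if (!is.null(b) && paired) {
    if (length(values) != length(b)) stopf("bayes_estimate: paired length mismatch")
    values <- values - b; b <- NULL; chance <- 0
  }
  if (is.null(b)) {
    y <- values
    if (length(y) < 2 || stats::sd(y) < 1e-12) stopf("bayes_estimate: need n >= 2 with nonzero variance")
    m0 <- mean(y); s0 <- 1000 * stats::sd(y)
    ls_lo <- log(stats::sd(y) / 1000); ls_hi <- log(stats::sd(y) * 1000)
    lp <- function(th) .lp_one(th, y, m0, s0, ls_lo, ls_hi)
    init <- c(mean(y), log(stats::sd(y)), log(29))
    ch <- lapply(seq_len(chains), function(cc) {
      .rw_metropolis(lp, init, draws + burn, burn,
                     seed = (as.integer(seed) + 131 * cc) %% 2147483647L,
                     scales = c(stats::sd(y) / 2, 0.3, 0.5))
    })
    mu <- lapply(ch, function(m) m[, 1])
    rhat <- .rhat(mu)
    post_mu <- unlist(mu) - chance
    post_sigma <- exp(unlist(lapply(ch, function(m) m[, 2])))
    post_nu <- exp(unlist(lapply(ch, function(m) m[, 3]))) + 1
    eff <- post_mu / post_sigma
  } else {
    if (length(values) < 2 || length(b) < 2) stopf("bayes_estimate: need n >= 2 per group")
    # two-group model: independent (mu, log sigma) per group, shared nu
    y1 <- values; y2 <- b
    pri <- function(y) list(m0 = mean(y), s0 = 1000 * stats::sd(c(y1, y2)),
                            lo = log(stats::sd(c(y1, y2)) / 1000),
                            hi = log(stats::sd(c(y1, y2)) * 1000))
    p1 <- pri(y1); p2 <- pri(y2)
    lp <- function(th) {
      mu1 <- th[1]; ls1 <- th[2]; mu2 <- th[3]; ls2 <- th[4]; lnu <- th[5]
      if (ls1 < p1$lo || ls1 > p1$hi || ls2 < p2$lo || ls2 > p2$hi) return(-Inf)
      nu <- exp(lnu) + 1
      sum(stats::dt((y1 - mu1) / exp(ls1), nu, log = TRUE) - ls1) +
        sum(stats::dt((y2 - mu2) / exp(ls2), nu, log = TRUE) - ls2) +
        stats::dnorm(mu1, p1$m0, p1$s0, log = TRUE) +
        stats::dnorm(mu2, p2$m0, p2$s0, log = TRUE) +
        stats::dexp(nu - 1, 1 / 29, log = TRUE) + lnu
    }
    init <- c(mean(y1), log(stats::sd(y1)), mean(y2), log(stats::sd(y2)), log(29))
    ch <- lapply(seq_len(chains), function(cc) {
      .rw_metropolis(lp, init, draws + burn, burn,
                     seed = (as.integer(seed) + 131 * cc) %% 2147483647L,
                     scales = c(stats::sd(y1) / 2, 0.3, stats::sd(y2) / 2, 0.3, 0.5))
    })
    diff <- lapply(ch, function(m) m[, 1] - m[, 3])
    rhat <- .rhat(diff)
    post_mu <- unlist(diff)
    s1 <- exp(unlist(lapply(ch, function(m) m[, 2])))
    s2 <- exp(unlist(lapply(ch, function(m) m[, 4])))
    post_sigma <- sqrt((s1^2 + s2^2) / 2)
    post_nu <- exp(unlist(lapply(ch, function(m) m[, 5]))) + 1
    eff <- post_mu / post_sigma
  }
  if (rhat > 1.1) {
    chain_means <- vapply(ch, function(m) mean(m[, 1]), 0)
    stopf("bayes_estimate: chains did not converge (Rhat = %.3f; chain means: %s)",
          rhat, paste(sprintf("%.3f", chain_means), collapse = ", "))
  }
  structure(list(
    mu = post_mu, sigma = post_sigma, nu = post_nu, effect_size = eff,
    hdi95 = hdi(post_mu, 0.95), effect_hdi95 = hdi(eff, 0.95),
    rope = rope, rope_fraction = rope_fraction(eff, rope),
    rhat = rhat, n_draws = length(post_mu)
  ), class = "bayes_estimate")
}

#' @export
print.bayes_estimate <- function(x, ...) {
  cat(sprintf("Bayesian estimate (%d draws, Rhat %.3f)\n", x$n_draws, x$rhat))
  cat(sprintf("  mean difference: %.2f, 95%% HDI (%.2f, %.2f)\n",
              mean(x$mu), x$hdi95[1], x$hdi95[2]))
  cat(sprintf("  effect size: %.2f, 95%% HDI (%.2f, %.2f); %.0f%% in ROPE (%.1f, %.1f)\n",
              mean(x$effect_size), x$effect_hdi95[1], x$effect_hdi95[2],
              100 * x$rope_fraction, x$rope[1], x$rope[2]))
  invisible(x)
}

#' Select the replication subset of objects
#'
#' Objects on which the cohort is at chance in the vision session (the
#' bootstrap CI of mean percent correct contains 50) and significantly above
#' chance in the grasping session (two-sided one-sample t against 50 with
#' p < 0.05 and positive mean difference).
#'
#' @param records trial data.frame covering vision and grasping sessions
#' @param reps bootstrap resamples per object
#' @param alpha significance level for the grasping test
#' @param seed integer seed for the bootstrap
#' @return character vector of object ids (possibly empty)
#' @export
select_replication_subset <- function(records, reps = 2000, alpha = 0.05, seed = 1L) {
  pc <- percent_correct(records, by = c("participant", "session", "object"))
  objs <- sort(unique(pc$object))
  keep <- vapply(seq_along(objs), function(k) {
    v <- pc$percent_correct[pc$object == objs[k] & pc$session == "vision"]
    g <- pc$percent_correct[pc$object == objs[k] & pc$session == "grasping"]
    if (length(v) < 2 || length(g) < 2) return(FALSE)
    ci <- bootstrap_ci(v, reps = reps, seed = (as.integer(seed) + k) %% 2147483647L)
    at_chance <- ci[1] <= 50 && ci[2] >= 50
    above <- if (stats::sd(g) < 1e-12) mean(g) > 50 else {
      tt <- one_sample_t(g, 50); tt$p < alpha && tt$mean_diff > 0
    }
    at_chance && above
  }, TRUE)
  as.character(objs[keep])
}

#' Within-session learning trend
#'
#' Per participant and session, the least-squares slope of response
#' correctness on within-session trial index; then, per session, a
#' one-sample t-test of the participant slopes against zero. A stationary
#' observer should show slopes indistinguishable from zero.
#'
#' @param records trial data.frame with a `trial` index column
#' @return data.frame per session: mean slope, t, df, p, n
#' @export
learning_trend <- function(records) {
  if (is.null(records$trial)) stopf("learning_trend: records lack a trial index")
  out <- list()
  for (sess in unique(records$session)) {
    sub <- records[records$session == sess, ]
    slopes <- vapply(unique(sub$participant), function(p) {
      r <- sub[sub$participant == p, ]
      if (nrow(r) < 2) stopf("learning_trend: single-trial session for participant %s", p)
      x <- r$trial
      stats::cov(x, r$chose_near_optimal) / stats::var(x)
    }, 0)
    tt <- if (length(slopes) < 2 || stats::sd(slopes) < 1e-12) {
      list(t = NA_real_, df = length(slopes) - 1, p = NA_real_)
    } else one_sample_t(slopes, 0)
    out[[sess]] <- data.frame(session = sess, mean_slope = mean(slopes),
                              t = tt$t, df = tt$df, p = tt$p, n = length(slopes),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Session summary with bootstrap error bars
#'
#' Per-session mean percent correct across participants with 95% bootstrap
#' CIs of the mean; the standard session-level summary feeding the bar
#' plots.
#'
#' @param records trial data.frame
#' @param reps bootstrap resamples
#' @param seed integer seed
#' @return data.frame per session: n, mean, ci_low, ci_high
#' @export
session_summary <- function(records, reps = 10000, seed = 1L) {
  pc <- percent_correct(records)
  out <- list()
  for (sess in unique(pc$session)) {
    v <- pc$percent_correct[pc$session == sess]
    ci <- bootstrap_ci(v, reps = reps, seed = seed)
    out[[sess]] <- data.frame(session = sess, n = length(v), mean = mean(v),
                              ci_low = ci[1], ci_high = ci[2],
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Bar plot of session accuracy with bootstrap error bars
#'
#' @param summary data.frame from [session_summary()]
#' @param main plot title
#' @export
plot_session_summary <- function(summary, main = "Grasp optimality judgments") {
  bp <- graphics::barplot(summary$mean, names.arg = summary$session,
                          ylim = c(0, 100), ylab = "Percent correct", main = main,
                          col = "grey80")
  graphics::arrows(bp, summary$ci_low, bp, summary$ci_high,
                   angle = 90, code = 3, length = 0.08)
  graphics::abline(h = 50, lty = 3)
  invisible(bp)
}
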