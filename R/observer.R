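#' Parametric 2AFC observer
#'
#' Simulated participants judge, for each designed grasp pair, which of the
#' two marked grasps is better. The probability of choosing the near-optimal
#' grasp follows a lapse-contaminated logistic in the pair's target-criterion
#' optimality difference, with a sensitivity that depends on the session
#' (vision, video, grasping). The observer is scaffolding for generating data
#' with the experiment's structure, not a claim about human mechanism; it is
#' memoryless across trials by default, with an optional linear drift in
#' log-odds for power analyses of learning effects.
#'
#' @name synthetic_observer
NULL

.sessions <- c("vision", "video", "grasping")

#' Construct an observer model
#'
#' Default sensitivities emulate the experiments' qualitative pattern:
#' modest above-chance accuracy from vision alone and clearly higher,
#' mutually similar accuracy in the video and grasping sessions.
#'
#' @param sensitivity named nonnegative vector: log-odds of a correct
#'   judgment per unit of normalized optimality difference, one entry per
#'   session
#' @param lapse probability of an attention lapse (random response),
#'   in [0, 0.5]
#' @param seed master integer seed; per-participant streams are derived from
#'   it so adding participants never perturbs existing ones
#' @param object_effects optional named multiplier on sensitivity per object
#'   (default 1 for every object), giving per-object difficulty profiles
#' @param drift_per_trial optional additive log-odds drift per within-session
#'   trial index (default 0: no learning)
#' @return list of class `observer_model`
#' @export
observer_model <- function(sensitivity = c(vision = 1.0, video = 2.1, grasping = 2.2),
                           lapse = 0.02, seed = 1L,
                           object_effects = NULL, drift_per_trial = 0) {
  if (any(sensitivity < 0) || any(!is.finite(sensitivity))) {
    stopf("observer_model: sensitivities must be finite and >= 0")
  }
  if (lapse < 0 || lapse > 0.5) stopf("observer_model: lapse must be in [0, 0.5]")
  structure(list(sensitivity = sensitivity, lapse = lapse,
                 seed = as.integer(seed), object_effects = object_effects,
                 drift_per_trial = drift_per_trial),
            class = "observer_model")
}

#' Probability of choosing the near-optimal grasp
#'
#' `lapse/2 + (1 - lapse) * logistic(k * delta)`: 0.5 at zero sensitivity or
#' zero optimality difference, saturating toward `1 - lapse/2` for large
#' `k * delta`.
#'
#' @param delta target-criterion optimality difference (>= 0 by design)
#' @param k sensitivity (>= 0)
#' @param lapse lapse probability in [0, 0.5]
#' @return probability (vectorized)
#' @export
p_correct <- function(delta, k, lapse = 0) {
  if (any(lapse < 0) || any(lapse > 0.5)) stopf("p_correct: lapse must be in [0, 0.5]")
  if (any(k < 0)) stopf("p_correct: k must be >= 0")
  lapse / 2 + (1 - lapse) * stats::plogis(k * delta)
}

#' Simulate an experiment's trial table
#'
#' One Bernoulli trial per participant x session x grasp pair, with object
#' order and which grasp is presented first randomized per participant from
#' a per-participant seed stream. Fully reproducible given the observer's
#' master seed.
#'
#' @param design an `experiment_design`, or a data.frame with columns
#'   `object`, `criterion`, `delta`
#' @param observer an `observer_model`
#' @param n_participants number of simulated participants
#' @param sessions sessions to run, a subset of vision/video/grasping
#' @return data.frame of trial records: participant, session, trial (within
#'   session), object, criterion, order ("near_first"/"sub_first"),
#'   chose_near_optimal (0/1)
#' @export
simulate_experiment <- function(design, observer = observer_model(),
                                n_participants = 21,
                                sessions = c("vision", "grasping")) {
  df <- if (inherits(design, "experiment_design")) design$pairs else design
  if (!nrow(df)) stopf("simulate_experiment: empty design")
  sessions <- match.arg(sessions, .sessions, several.ok = TRUE)
  if (!all(sessions %in% names(observer$sensitivity))) {
    stopf("simulate_experiment: observer lacks sensitivity for session(s): %s",
          paste(setdiff(sessions, names(observer$sensitivity)), collapse = ", "))
  }
  if (n_participants < 1) stopf("simulate_experiment: need >= 1 participant")
  obj_eff <- rep(1, nrow(df))
  if (!is.null(observer$object_effects)) {
    m <- observer$object_effects[df$object]
    obj_eff <- ifelse(is.na(m), 1, m)
  }
  recs <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    set.seed(participant_seed(observer$seed, p))
    per_sess <- lapply(sessions, function(sess) {
      ord <- sample.int(nrow(df))                 # object order this session
      k <- observer$sensitivity[[sess]] * obj_eff[ord]
      drift <- observer$drift_per_trial * (seq_along(ord) - 1)
      pr <- observer$lapse / 2 +
        (1 - observer$lapse) * stats::plogis(k * df$delta[ord] + drift)
      data.frame(
        participant = p, session = sess, trial = seq_along(ord),
        object = df$object[ord], criterion = df$criterion[ord],
        order = sample(c("near_first", "sub_first"), length(ord), replace = TRUE),
        chose_near_optimal = stats::rbinom(length(ord), 1, pr),
        stringsAsFactors = FALSE
      )
    })
    recs[[p]] <- do.call(rbind, per_sess)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Write / read a trial table as CSV
#'
#' The interchange schema consumed by the analysis layer: participant,
#' session, trial, object, criterion, order, chose_near_optimal (0/1).
#'
#' @param records trial data.frame
#' @param path file path
#' @export
write_trials_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Fit the observer's sensitivity by maximum likelihood
#'
#' One-dimensional bounded likelihood maximization of the session sensitivity
#' `k` under the lapse-contaminated logistic response model, given each
#' trial's target-criterion optimality difference; the lapse is held fixed.
#' Sessions whose estimate lies at the search boundary (e.g. all-constant
#' responses) are flagged.
#'
#' @param records trial data.frame (see [simulate_experiment()])
#' @param design design providing per-object `delta` (an `experiment_design`
#'   or data.frame with `object` and `delta`)
#' @param lapse fixed lapse used in the likelihood (default 0)
#' @param upper upper search bound for k (default 50)
#' @return object of class `observer_fit`
#' @export
fit_observer <- function(records, design, lapse = 0, upper = 50) {
  df <- if (inherits(design, "experiment_design")) design$pairs else design
  delta <- df$delta[match(records$object, df$object)]
  if (any(is.na(delta))) stopf("fit_observer: records contain objects absent from the design")
  sessions <- unique(records$session)
  est <- setNames(numeric(length(sessions)), sessions)
  ll <- est; boundary <- setNames(logical(length(sessions)), sessions)
  for (sess in sessions) {
    sel <- records$session == sess
    y <- records$chose_near_optimal[sel]; d <- delta[sel]
    nll <- function(k) {
      pr <- pmin(pmax(p_correct(d, k, lapse), 1e-12), 1 - 1e-12)
      -sum(y * log(pr) + (1 - y) * log(1 - pr))
    }
    opt <- stats::optimize(nll, c(0, upper))
    est[sess] <- opt$minimum
    ll[sess] <- -opt$objective
    if (stats::var(y) == 0 || opt$minimum > upper * 0.999) boundary[sess] <- TRUE
  }
  structure(list(coefficients = est, logLik = ll, boundary = boundary,
                 lapse = lapse, n_trials = table(records$session),
                 call = match.call()),
            class = "observer_fit")
}

#' @export
print.observer_fit <- function(x, ...) {
  cat("2AFC observer sensitivity fit (lapse fixed at", x$lapse, ")\n")
  for (s in names(x$coefficients)) {
    cat(sprintf("  %-9s k = %6.3f%s\n", s, x$coefficients[[s]],
                if (x$boundary[[s]]) "  [boundary]" else ""))
  }
  invisible(x)
}

#' @export
coef.observer_fit <- function(object, ...) object$coefficients

#' @export
summary.observer_fit <- function(object, ...) {
  data.frame(session = names(object$coefficients),
             k = as.numeric(object$coefficients),
             logLik = as.numeric(object$logLik),
             n_trials = as.numeric(object$n_trials[names(object$coefficients)]),
             boundary = as.logical(object$boundary),
             row.names = NULL)
}

#' @export
predict.observer_fit <- function(object, newdata, ...) {
  k <- object$coefficients[newdata$session]
  p_correct(newdata$delta, as.numeric(k), object$lapse)
}
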