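#' Criterion-isolating grasp-pair selection
#'
#' For each object one near-optimal and one sub-optimal grasp are chosen so
#' that they differ strongly on a single target criterion while the other
#' three criteria stay approximately constant within the pair (or cancel, in
#' sign, across the objects of a criterion block). Optimality here is
#' `1 - normalized cost`, so the per-criterion optimality difference
#' `delta = optimality(near) - optimality(sub)` is positive exactly when the
#' near-optimal grasp is the better one on that criterion.
#'
#' @name stimulus_design
NULL

# optimality-difference matrix between all ordered candidate pairs on one
# criterion: delta[i, j] = cost_j - cost_i (positive when i is better)
.delta_mat <- function(norm_cost) outer(rep(1, length(norm_cost)), norm_cost) - norm_cost

#' Select a near-/sub-optimal grasp pair isolating one criterion
#'
#' Exhaustive search over ordered candidate pairs. Among pairs whose
#' off-target optimality differences are all within `epsilon` (normalized
#' units), the pair maximizing the target-criterion difference is returned.
#' If no pair satisfies the tolerance, the fallback takes the pairs in the
#' top decile of target difference and returns the one minimizing the worst
#' off-target difference, flagged `relaxed`.
#'
#' @param scores a `grasp_scores` data.frame with normalized costs (all rows
#'   already pass force closure)
#' @param criterion one of `"aperture"`, `"nga"`, `"torque"`, `"visibility"`
#' @param epsilon largest tolerated absolute off-target difference
#'   (default 0.2)
#' @return list of class `grasp_pair`: near/sub row indices and ids, `delta`
#'   (named length-4, near minus sub optimality), `relaxed` flag
#' @export
select_pair <- function(scores, criterion, epsilon = 0.2) {
  criterion <- match.arg(criterion, criterion_names)
  n <- nrow(scores)
  if (n < 2) stopf("select_pair: need at least 2 scored candidates")
  deltas <- lapply(criterion_names, function(cr) .delta_mat(scores[[paste0("norm_", cr)]]))
  names(deltas) <- criterion_names
  target <- deltas[[criterion]]
  off <- deltas[setdiff(criterion_names, criterion)]
  worst_off <- Reduce(pmax, lapply(off, abs))
  pos <- target > 1e-12
  if (!any(pos)) stopf("select_pair: no candidate pair differs on criterion '%s'", criterion)

  feasible <- pos & (worst_off <= epsilon)
  relaxed <- FALSE
  if (any(feasible)) {
    cand <- which(feasible, arr.ind = TRUE)
    best <- cand[which.max(target[feasible]), ]
  } else {
    relaxed <- TRUE
    thr <- stats::quantile(target[pos], 0.9)
    top <- pos & (target >= thr)
    cand <- which(top, arr.ind = TRUE)
    best <- cand[which.min(worst_off[top]), ]
  }
  i <- best[[1]]; j <- best[[2]]
  delta <- vapply(deltas, function(d) d[i, j], 0)
  structure(list(
    object = attr(scores, "object") %||% NA_character_,
    criterion = criterion,
    near_optimal = i, sub_optimal = j,
    near_id = scores$grasp_id[i], sub_id = scores$grasp_id[j],
    delta = delta, relaxed = relaxed
  ), class = "grasp_pair")
}

#' @export
print.grasp_pair <- function(x, ...) {
  cat(sprintf("<grasp_pair> object %s, criterion %s%s\n", x$object, x$criterion,
              if (x$relaxed) " (relaxed)" else ""))
  cat(sprintf("  near %s vs sub %s; delta: %s\n", x$near_id, x$sub_id,
              paste(sprintf("%s=%+.3f", names(x$delta), x$delta), collapse = ", ")))
  invisible(x)
}

#' Design a full experiment: one pair per object, criteria in blocks
#'
#' Objects are assigned to criteria in consecutive blocks of
#' `per_criterion_count` (the assignment is configuration, not optimization),
#' and [select_pair()] is run per object. The result carries the 4 x n
#' criteria-by-objects matrix of target-and-off-target optimality
#' differences, plus a random near/sub to sticker-color map drawn from
#' `seed` (mirroring random sticker assignment in the physical stimuli).
#'
#' @param scores_list named list of `grasp_scores`, one per object
#' @param per_criterion_count objects per criterion (default 4)
#' @param criteria criterion block order (default the four standard criteria)
#' @param epsilon off-target tolerance passed to [select_pair()]
#' @param seed integer seed for the sticker-color assignment
#' @return list of class `experiment_design` with elements `pairs`
#'   (data.frame), `delta_matrix` (criteria x objects) and `pair_objects`
#' @export
design_experiment <- function(scores_list, per_criterion_count = 4,
                              criteria = criterion_names, epsilon = 0.2,
                              seed = 1L) {
  need <- per_criterion_count * length(criteria)
  if (length(scores_list) < need) {
    stopf("design_experiment: need %d objects (%d per criterion x %d criteria), got %d",
          need, per_criterion_count, length(criteria), length(scores_list))
  }
  scores_list <- scores_list[seq_len(need)]
  assigned <- rep(criteria, each = per_criterion_count)
  pairs <- vector("list", need)
  for (k in seq_len(need)) {
    pairs[[k]] <- select_pair(scores_list[[k]], assigned[k], epsilon)
    if (is.na(pairs[[k]]$object)) pairs[[k]]$object <- names(scores_list)[k] %||% as.character(k)
  }
  set.seed(as.integer(seed) %% 2147483647L)
  near_color <- sample(c("blue", "green"), need, replace = TRUE)
  df <- data.frame(
    object = vapply(pairs, `[[`, "", "object"),
    criterion = assigned,
    near_id = vapply(pairs, `[[`, "", "near_id"),
    sub_id = vapply(pairs, `[[`, "", "sub_id"),
    delta_aperture = vapply(pairs, function(p) p$delta[["aperture"]], 0),
    delta_nga = vapply(pairs, function(p) p$delta[["nga"]], 0),
    delta_torque = vapply(pairs, function(p) p$delta[["torque"]], 0),
    delta_visibility = vapply(pairs, function(p) p$delta[["visibility"]], 0),
    relaxed = vapply(pairs, `[[`, TRUE, "relaxed"),
    near_color = near_color,
    stringsAsFactors = FALSE
  )
  df$delta <- vapply(seq_len(need), function(k) {
    df[[paste0("delta_", assigned[k])]][k]
  }, 0)
  dm <- t(as.matrix(df[, paste0("delta_", criterion_names)]))
  rownames(dm) <- criterion_names
  colnames(dm) <- df$object
  structure(list(pairs = df, delta_matrix = dm, grasp_pairs = pairs),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %d grasp pairs (%s)\n", nrow(x$pairs),
              paste(sprintf("%s x%d", names(table(x$pairs$criterion)),
                            table(x$pairs$criterion)), collapse = ", ")))
  cat(sprintf("  target delta: mean %.3f, range [%.3f, %.3f]; %d relaxed\n",
              mean(x$pairs$delta), min(x$pairs$delta), max(x$pairs$delta),
              sum(x$pairs$relaxed)))
  invisible(x)
}

#' Counterbalancing report of off-target differences
#'
#' For each criterion block, the signed sum of each off-target optimality
#' difference across the block's objects; values near zero indicate the
#' residual off-target differences cancel across objects.
#'
#' @param design an `experiment_design` (or its `pairs` data.frame)
#' @return data.frame: one row per (block criterion, off-target criterion)
#'   with the signed sum
#' @export
counterbalance_report <- function(design) {
  df <- if (inherits(design, "experiment_design")) design$pairs else design
  if (nrow(df) < 1) stopf("counterbalance_report: need at least one pair")
  out <- list()
  for (blk in unique(df$criterion)) {
    sub <- df[df$criterion == blk, , drop = FALSE]
    for (cr in setdiff(criterion_names, blk)) {
      out[[length(out) + 1L]] <- data.frame(
        block = blk, off_target = cr,
        signed_sum = sum(sub[[paste0("delta_", cr)]]),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Write the design table to CSV
#' @param design an `experiment_design`
#' @param path output path
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design$pairs, path, row.names = FALSE)
  invisible(path)
}
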