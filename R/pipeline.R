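#' End-to-end pipeline
#'
#' Ties the stages together: build (or load) the polycube objects, enumerate
#' and score admissible grasps, design criterion-isolating grasp pairs,
#' simulate the cohort's judgments, and run the statistical analysis. All
#' randomness flows from the seeds in the configuration, so a given
#' configuration reproduces its outputs byte for byte.
#'
#' @name cli_pipeline
NULL

# four deterministic 10-cube shapes: an L, a staircase, a cross, and a U
.fixture_shapes <- function() {
  list(
    L = rbind(c(0,0,0), c(1,0,0), c(2,0,0), c(3,0,0), c(4,0,0), c(5,0,0), c(6,0,0),
              c(6,0,1), c(6,0,2), c(6,0,3)),
    stair = rbind(c(0,0,0), c(1,0,0), c(2,0,0), c(2,0,1), c(3,0,1), c(4,0,1),
                  c(4,0,2), c(5,0,2), c(6,0,2), c(7,0,2)),
    cross = rbind(c(0,0,0), c(1,0,0), c(2,0,0), c(3,0,0), c(4,0,0),
                  c(2,1,0), c(2,2,0), c(2,3,0), c(2,4,0), c(2,2,1)),
    U = rbind(c(0,0,0), c(1,0,0), c(2,0,0), c(3,0,0), c(0,1,0), c(3,1,0),
              c(0,2,0), c(3,2,0), c(0,3,0), c(3,3,0))
  )
}

# four material configurations: all wood, brass on either half, brass ends
.fixture_materials <- function(n = 10) {
  list(
    wood = rep("wood", n),
    brass_head = c(rep("brass", 5), rep("wood", n - 5)),
    brass_tail = c(rep("wood", n - 5), rep("brass", 5)),
    brass_ends = c(rep("brass", 3), rep("wood", n - 6), rep("brass", 3))
  )
}

#' Generate the demo stimulus set
#'
#' Sixteen connected 10-cube objects: 4 shapes crossed with 4 material
#' configurations (all beech wood, brass on either half, brass at both
#' ends), each placed on the table at a turntable orientation drawn from the
#' seed. The exact shapes and material layouts of the original physical set
#' are not machine-readable, so these are plausible stand-ins with the same
#' structure; the all-wood variants weigh 96.875 g at the default densities.
#'
#' @param seed integer seed (drives the turntable yaws)
#' @param side_cm cube side (default 2.5)
#' @param densities density map
#' @return named list of 16 `rigid_object`s
#' @export
generate_fixtures <- function(seed = 1L, side_cm = 2.5,
                              densities = c(wood = 0.62, brass = 8.5)) {
  set.seed(as.integer(seed) %% 2147483647L)
  shapes <- .fixture_shapes()
  mats <- .fixture_materials()
  out <- list()
  for (sh in names(shapes)) {
    for (mc in names(mats)) {
      nm <- paste(sh, mc, sep = "_")
      yaw <- sample(c(0, 90, 180, 270), 1)
      out[[nm]] <- build_object(shapes[[sh]], mats[[mc]], side_cm = side_cm,
                                densities = densities,
                                pose = list(yaw_deg = yaw, translation_cm = c(0, 0, 0)),
                                name = nm)
    }
  }
  out
}

#' Assemble a pipeline configuration
#'
#' @param objects_path optional path to a directory of object-spec JSON files
#'   (default: use [generate_fixtures()])
#' @param densities named material density map (g/cm^3) used when building
#'   objects
#' @param model a `grasp_config`
#' @param per_criterion_count objects per criterion block (default 4)
#' @param epsilon off-target tolerance for pair selection
#' @param observer an `observer_model`
#' @param n_participants cohort size (default 21)
#' @param sessions sessions to simulate
#' @param bootstrap_reps,alpha,rope analysis options
#' @param bayes toggle the (slower) Bayesian estimation stage
#' @param bayes_draws,bayes_burn MCMC geometry for the analysis stage
#' @param seed master seed
#' @param out_dir output directory
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(objects_path = NULL,
                            densities = c(wood = 0.62, brass = 8.5),
                            model = grasp_config(),
                            per_criterion_count = 4,
                            epsilon = 0.2,
                            observer = observer_model(),
                            n_participants = 21,
                            sessions = c("vision", "grasping"),
                            bootstrap_reps = 10000,
                            alpha = 0.05,
                            rope = c(-0.4, 0.4),
                            bayes = FALSE,
                            bayes_draws = 4000,
                            bayes_burn = 1000,
                            seed = 1L,
                            out_dir = tempfile("grasp_run_")) {
  if (rope[1] > rope[2]) stopf("pipeline_config: ROPE bounds must be ordered")
  if (!is.numeric(densities) || is.null(names(densities)) || !length(densities)) {
    stopf("pipeline_config: field 'densities' must be a named numeric density map")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Recognized top-level blocks: `model`, `design`, `observer`, `analysis`,
#' plus `objects_path`, `n_participants`, `sessions`, `seed`, `out_dir`.
#' Unspecified fields fall back to the [pipeline_config()] defaults.
#'
#' @param path config file ending in .json, .yaml or .yml
#' @return `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  m <- raw$model %||% list()
  if (is.null(m$densities %||% NULL) && !is.null(raw$densities)) m$densities <- raw$densities
  model <- do.call(grasp_config, m[intersect(names(m), names(formals(grasp_config)))])
  ob <- raw$observer %||% list()
  if (!is.null(ob$sensitivity)) ob$sensitivity <- unlist(ob$sensitivity)
  observer <- do.call(observer_model, ob[intersect(names(ob), names(formals(observer_model)))])
  an <- raw$analysis %||% list()
  de <- raw$design %||% list()
  dens <- raw$densities %||% c(wood = 0.62, brass = 8.5)
  pipeline_config(
    objects_path = raw$objects_path %||% NULL,
    densities = unlist(dens),
    model = model,
    per_criterion_count = de$per_criterion_count %||% 4,
    epsilon = de$epsilon %||% 0.2,
    observer = observer,
    n_participants = raw$n_participants %||% 21,
    sessions = raw$sessions %||% c("vision", "grasping"),
    bootstrap_reps = an$bootstrap_reps %||% 10000,
    alpha = an$alpha %||% 0.05,
    rope = an$rope %||% c(-0.4, 0.4),
    bayes = an$bayes %||% FALSE,
    bayes_draws = an$bayes_draws %||% 4000,
    bayes_burn = an$bayes_burn %||% 1000,
    seed = raw$seed %||% 1L,
    out_dir = raw$out_dir %||% tempfile("grasp_run_")
  )
}

.stage <- function(name, expr, log) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stopf("[stage %s] %s", name, conditionMessage(e))
  })
  log(sprintf("stage %-14s %6.2f s", name, as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full pipeline
#'
#' Stages: build/load objects, score grasps, design stimuli, simulate
#' judgments, analyze. Writes `design.csv`, `trials.csv`, `report.json`,
#' `objects/*.json` and a session bar-plot `sessions.png` into the
#' configured output directory; every tabular output embeds the
#' configuration hash. Deterministic given the config's seeds.
#'
#' @param config a `pipeline_config`, or a path readable by
#'   [read_pipeline_config()]
#' @param quiet suppress progress logging to stderr
#' @return invisibly, a list with the design, trial records, analysis report
#'   and output paths
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  log <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
    if (!quiet) message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  cfg_hash <- fnv1a_hash(config[setdiff(names(config), "out_dir")])
  log(sprintf("run start (R %s.%s, graspquality %s, config %s)",
              R.version$major, R.version$minor,
              as.character(utils::packageVersion("graspquality")), cfg_hash))

  objects <- .stage("build-objects", {
    if (!is.null(config$objects_path)) {
      files <- sort(list.files(config$objects_path, "\\.json$", full.names = TRUE))
      if (!length(files)) stopf("no object specs under %s", config$objects_path)
      objs <- lapply(files, read_object_json, densities = config$densities)
      names(objs) <- vapply(objs, `[[`, "", "name")
      objs
    } else generate_fixtures(config$seed, densities = config$densities)
  }, log)

  scores <- .stage("score-grasps", {
    lapply(objects, function(o) enumerate_grasps(o, config = config$model))
  }, log)

  design <- .stage("design-stimuli", {
    design_experiment(scores, per_criterion_count = config$per_criterion_count,
                      epsilon = config$epsilon, seed = config$seed)
  }, log)

  records <- .stage("simulate", {
    simulate_experiment(design, config$observer, config$n_participants,
                        config$sessions)
  }, log)

  report <- .stage("analyze", {
    pc <- percent_correct(records)
    summ <- session_summary(records, reps = config$bootstrap_reps, seed = config$seed)
    contrasts <- list()
    for (sess in config$sessions) {
      v <- pc$percent_correct[pc$session == sess]
      tt <- one_sample_t(v, 50)
      entry <- list(contrast = paste0(sess, "_vs_chance"),
                    t = tt$t, df = tt$df, p = tt$p, mean_diff = tt$mean_diff,
                    ci95 = bootstrap_ci(v, config$bootstrap_reps, seed = config$seed),
                    effect_size = effect_size(v, 50))
      if (config$bayes) {
        be <- bayes_estimate(v, 50, rope = config$rope, draws = config$bayes_draws,
                             burn = config$bayes_burn, seed = config$seed)
        entry$hdi95 <- be$hdi95
        entry$rope_fraction <- be$rope_fraction
      }
      contrasts[[length(contrasts) + 1L]] <- entry
    }
    if (length(config$sessions) > 1) {
      cmb <- utils::combn(config$sessions, 2)
      for (ci in seq_len(ncol(cmb))) {
        s1 <- cmb[1, ci]; s2 <- cmb[2, ci]
        a <- pc$percent_correct[pc$session == s2][order(pc$participant[pc$session == s2])]
        b <- pc$percent_correct[pc$session == s1][order(pc$participant[pc$session == s1])]
        tt <- paired_t(a, b)
        entry <- list(contrast = paste0(s2, "_vs_", s1),
                      t = tt$t, df = tt$df, p = tt$p, mean_diff = tt$mean_diff,
                      effect_size = effect_size_paired(a, b))
        if (config$bayes) {
          be <- bayes_estimate(a, b = b, paired = TRUE, rope = config$rope,
                               draws = config$bayes_draws, burn = config$bayes_burn,
                               seed = config$seed)
          entry$hdi95 <- be$hdi95
          entry$rope_fraction <- be$rope_fraction
        }
        contrasts[[length(contrasts) + 1L]] <- entry
      }
    }
    per_object <- percent_correct(records, by = c("session", "object"))
    trend <- learning_trend(records)
    list(config_hash = cfg_hash, sessions = summ, contrasts = contrasts,
         per_object = per_object, learning_trend = trend)
  }, log)

  paths <- .stage("write-outputs", {
    obj_dir <- file.path(config$out_dir, "objects")
    dir.create(obj_dir, showWarnings = FALSE)
    for (o in objects) write_object_json(o, file.path(obj_dir, paste0(o$name, ".json")))
    design_out <- design$pairs
    design_out$config_hash <- cfg_hash
    utils::write.csv(design_out, file.path(config$out_dir, "design.csv"), row.names = FALSE)
    rec_out <- records
    rec_out$config_hash <- cfg_hash
    utils::write.csv(rec_out, file.path(config$out_dir, "trials.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    fig <- file.path(config$out_dir, "sessions.png")
    grDevices::png(fig, width = 600, height = 480)
    plot_session_summary(report$sessions)
    grDevices::dev.off()
    list(design = file.path(config$out_dir, "design.csv"),
         trials = file.path(config$out_dir, "trials.csv"),
         report = file.path(config$out_dir, "report.json"),
         figure = fig, log = log_path)
  }, log)

  log("run complete")
  invisible(list(objects = objects, scores = scores, design = design,
                 records = records, report = report, paths = paths))
}
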