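# Configuration and trajectory serialization. Configs are flat YAML
# mappings mirroring the constructor field names, SI units throughout,
# except that angles are stored in degrees in the file (converted on
# read/write, matching how joint ranges are usually quoted).

rad2deg <- function(x) x * 180 / pi
deg2rad <- function(x) x * pi / 180

#' Write / read the full study configuration as YAML
#'
#' Serializes plant parameters, task specification, reward weights and
#' (optionally) the PPO configuration into one YAML file with sections
#' `plant`, `task`, `reward` and `ppo`. Angle fields (`ankle_angle_range`,
#' `hip_angle_range`, `neutral_angles`) are written in degrees.
#'
#' @param path YAML file path.
#' @param params A `plant_params` object.
#' @param task A [task_spec()].
#' @param weights A [reward_weights()].
#' @param ppo Optional [ppo_config()].
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a list with elements `params`, `task`, `weights` and `ppo`
#'   (NULL if absent), reconstructed as their classed objects.
#' @export
write_config <- function(path, params, task = task_spec(),
                         weights = reward_weights(), ppo = NULL) {
  plant <- unclass(params)
  for (f in c("ankle_angle_range", "hip_angle_range", "neutral_angles"))
    plant[[f]] <- rad2deg(plant[[f]])
  cfg <- list(plant = plant, task = unclass(task), reward = unclass(weights))
  if (!is.null(ppo)) cfg$ppo <- unclass(ppo)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::yaml.load_file(path)
  plant <- cfg$plant
  for (f in c("ankle_angle_range", "hip_angle_range", "neutral_angles"))
    plant[[f]] <- deg2rad(unlist(plant[[f]]))
  params <- do.call(derive_segment_parameters, plant[
    intersect(names(plant), names(formals(derive_segment_parameters)))])
  task <- do.call(task_spec, cfg$task[
    intersect(names(cfg$task), names(formals(task_spec)))])
  weights <- do.call(reward_weights, cfg$reward[
    intersect(names(cfg$reward), names(formals(reward_weights)))])
  ppo <- NULL
  if (!is.null(cfg$ppo))
    ppo <- do.call(ppo_config, cfg$ppo[
      intersect(names(cfg$ppo), setdiff(names(formals(ppo_config)), "profile"))])
  list(params = params, task = task, weights = weights, ppo = ppo)
}

#' Write / read a trajectory log as CSV with a JSON sidecar
#'
#' The CSV holds the per-control-step record with a fixed, documented header
#' (see [run_episode()]); the sidecar `<path>.json` records the task
#' specification, reward weights, key plant parameters, seed and control
#' period so a log is self-describing.
#'
#' @param log A `trajectory_log`.
#' @param path CSV file path.
#' @return `write_trajectory_log()` returns `path` invisibly;
#'   `read_trajectory_log()` returns the `trajectory_log` with its spec and
#'   weights reattached.
#' @export
write_trajectory_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  spec <- attr(log, "spec"); w <- attr(log, "weights")
  params <- attr(log, "params")
  side <- list(
    spec = if (!is.null(spec)) unclass(spec),
    weights = if (!is.null(w)) unclass(w),
    plant = if (!is.null(params))
      unclass(params)[c("total_mass", "total_height", "standing_com_height",
                        "added_mass", "ankle_stiffness", "hip_stiffness",
                        "torque_limit")],
    seed = attr(log, "seed"),
    control_dt = attr(log, "control_dt")
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory_log
#' @export
read_trajectory_log <- function(path) {
  df <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  spec <- NULL; w <- NULL; seed <- NA; control_dt <- NULL; params <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$spec)) spec <- do.call(task_spec, side$spec[
      intersect(names(side$spec), names(formals(task_spec)))])
    if (!is.null(side$weights)) w <- do.call(reward_weights, side$weights[
      intersect(names(side$weights), names(formals(reward_weights)))])
    if (!is.null(side$plant)) params <- do.call(derive_segment_parameters,
      side$plant[intersect(names(side$plant),
                           names(formals(derive_segment_parameters)))])
    seed <- side$seed
    control_dt <- side$control_dt
  }
  trajectory_log(df, spec = spec, params = params, weights = w, seed = seed,
                 control_dt = control_dt)
}
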