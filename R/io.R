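# Trial-table and kernel I/O, experiment configuration, presets, and the
# end-to-end pipeline runner.

#' Write / read a trial table
#'
#' Trial tables are CSV (one row per trial: `trial`, `choice`,
#' `decision_time`, `rt`, `crossed`, plus any extra columns) with a JSON
#' sidecar (`<path>.json`) holding the metadata attributes (frame_dt, task,
#' censored count) so that a round trip is lossless.
#'
#' @param trials a `decision_trials` data frame.
#' @param path CSV file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns a
#'   `decision_trials` data frame.
#' @export
write_trials <- function(trials, path) {
  if (!is.data.frame(trials)) stop_invalid("'trials' must be a data frame")
  .check_trials(trials)
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  meta <- list(frame_dt = attr(trials, "frame_dt"),
               task = attr(trials, "task"),
               n_censored = attr(trials, "n_censored"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trials
#' @param path CSV file path written by [write_trials()].
#' @export
read_trials <- function(path) {
  tab <- utils::read.csv(path)
  .check_trials(tab)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(tab,
            frame_dt = meta$frame_dt, task = meta$task,
            n_censored = if (is.null(meta$n_censored)) 0L else meta$n_censored,
            class = c("decision_trials", "data.frame"))
}

.check_trials <- function(tab) {
  need <- c("choice", "rt")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop_invalid("trial table lacks column(s): ",
                 paste(missing_cols, collapse = ", "))
  }
  ok <- !is.na(tab$choice)
  if (!all(tab$choice[ok] %in% c(1, 2))) {
    stop_invalid("column 'choice' must be coded 1/2")
  }
  if (any(tab$rt[!is.na(tab$rt)] < 0)) stop_invalid("column 'rt' has negative values")
  invisible(tab)
}

#' Write / read a psychophysical kernel
#'
#' CSV columns `time`, `value`, `sem`, `n` plus a JSON sidecar with
#' alignment/normalization metadata.
#'
#' @param kernel a `psych_kernel`.
#' @param path CSV file path.
#' @export
write_kernel <- function(kernel, path) {
  if (!inherits(kernel, "psych_kernel")) stop_invalid("'kernel' must be a psych_kernel")
  utils::write.csv(as.data.frame(kernel), path, row.names = FALSE)
  meta <- list(alignment = attr(kernel, "alignment"),
               normalization = attr(kernel, "normalization"),
               frame_dt = attr(kernel, "frame_dt"),
               window_end = attr(kernel, "window_end"),
               median_rt = attr(kernel, "median_rt"),
               scale_value = attr(kernel, "scale_value"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(tab, alignment = meta$alignment,
            normalization = meta$normalization, frame_dt = meta$frame_dt,
            window_end = meta$window_end, median_rt = meta$median_rt,
            scale_value = meta$scale_value,
            class = c("psych_kernel", "data.frame"))
}

# Allowed configuration keys per section (strict validation).
.config_keys <- list(
  model = c("kind", "bound", "sigma_eta", "start_point", "drift_offset",
            "weight", "ndt", "urgency", "rho", "reflect", "leak",
            "inhibition", "v0", "max_time"),
  stimulus = c("n_trials", "n_frames", "frame_dt", "sigma_s", "conditions"),
  analysis = c("alignment", "normalization", "window", "inclusion"),
  top = c("model", "stimulus", "analysis", "seed", "name"))

#' Regime presets for the simulation studies
#'
#' Named, fully specified configurations reproducing the simulation regimes
#' explored in the package's validation studies: basic bounded/unbounded
#' integration, non-decision-time and urgency effects, and the
#' competing-accumulator manipulations (input correlation, reflective bound,
#' leak/inhibition imbalance).
#'
#' @param name one of `"rt-basic"`, `"fixed-unbounded"`, `"fixed-bounded"`,
#'   `"rt-ndt"`, `"rt-urgency"`, `"race-correlation"`, `"race-reflective"`,
#'   `"race-leak-inhibition"`; missing gives the list of names.
#' @param n_trials simulated trials (default 1e5; raise for figure-grade
#'   precision).
#' @return a configuration list accepted by [run_pipeline()].
#' @export
regime_preset <- function(name, n_trials = 1e5) {
  presets <- list(
    "rt-basic" = list(
      model = list(kind = "ddm", bound = 30, sigma_eta = 1),
      stimulus = list(n_trials = n_trials, n_frames = 525, frame_dt = 1 / 75,
                      sigma_s = 1),
      analysis = list(alignment = "stimulus", normalization = "bounded")),
    "fixed-unbounded" = list(
      model = list(kind = "unbounded", sigma_eta = 1),
      stimulus = list(n_trials = n_trials, n_frames = 75, frame_dt = 1 / 75,
                      sigma_s = 1),
      analysis = list(alignment = "stimulus", normalization = "unbounded")),
    "fixed-bounded" = list(
      model = list(kind = "ddm", bound = 30, sigma_eta = 1),
      stimulus = list(n_trials = n_trials, n_frames = 75, frame_dt = 1 / 75,
                      sigma_s = 1),
      analysis = list(alignment = "stimulus", normalization = "bounded")),
    "rt-ndt" = list(
      model = list(kind = "ddm", bound = 30, sigma_eta = 1,
                   ndt = list(mean_T0 = 0.3, sd_T0 = 0.1)),
      stimulus = list(n_trials = n_trials, n_frames = 525, frame_dt = 1 / 75,
                      sigma_s = 1),
      analysis = list(alignment = "stimulus", normalization = "bounded")),
    "rt-urgency" = list(
      model = list(kind = "ddm", sigma_eta = 1,
                   urgency = list(b = 60, u_inf = 60, tau_half = 0.4)),
      stimulus = list(n_trials = n_trials, n_frames = 300, frame_dt = 1 / 75,
                      sigma_s = 1),
      analysis = list(alignment = "stimulus", normalization = "bounded")),
    "race-correlation" = list(
      model = list(kind = "race", rho = -0.2, bound = 30, reflect = -Inf,
                   leak = 0, inhibition = 0, v0 = 0, sigma_eta = 1),
      stimulus = list(n_trials = n_trials, n_frames = 300, frame_dt = 1 / 75,
                      sigma_s = 1),
      analysis = list(alignment = "stimulus", normalization = "bounded")),
    "race-reflective" = list(
      model = list(kind = "race", rho = -1, bound = 30, reflect = -10,
                   leak = 0, inhibition = 0, v0 = 0, sigma_eta = 0),
      stimulus = list(n_trials = n_trials, n_frames = 600, frame_dt = 1 / 75,
                      sigma_s = 1),
      analysis = list(alignment = "stimulus", normalization = "bounded")),
    "race-leak-inhibition" = list(
      model = list(kind = "race", rho = -1, bound = 60, reflect = 0,
                   leak = 0.003, inhibition = 0.003, v0 = 30, sigma_eta = 0,
                   max_time = 30),
      stimulus = list(n_trials = n_trials, n_frames = 400, frame_dt = 1 / 75,
                      sigma_s = 1),
      analysis = list(alignment = "stimulus", normalization = "bounded")))
  if (missing(name)) return(names(presets))
  if (!name %in% names(presets)) {
    stop_invalid("unknown preset; available: ",
                 paste(names(presets), collapse = ", "))
  }
  c(presets[[name]], list(name = name))
}

.validate_config <- function(config) {
  unknown <- setdiff(names(config), .config_keys$top)
  if (length(unknown) > 0L) {
    stop_invalid("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in c("model", "stimulus")) {
    if (is.null(config[[sec]])) stop_invalid("config lacks section '", sec, "'")
    bad <- setdiff(names(config[[sec]]), .config_keys[[sec]])
    if (length(bad) > 0L) {
      stop_invalid("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
    }
  }
  if (!is.null(config$analysis)) {
    bad <- setdiff(names(config$analysis), .config_keys$analysis)
    if (length(bad) > 0L) {
      stop_invalid("unknown key(s) in 'analysis': ", paste(bad, collapse = ", "))
    }
  }
  invisible(config)
}

.config_weight <- function(w) {
  if (is.null(w)) weight_spec("constant") else do.call(weight_spec, w)
}

#' Run a simulate-then-analyze pipeline from a configuration
#'
#' Executes stimulus generation, model simulation, kernel estimation, and
#' normalization from one seeded configuration (a list, a preset name, or a
#' YAML/JSON file path), optionally writing all artifacts plus a
#' machine-readable run manifest.
#'
#' @param config configuration list (sections `model`, `stimulus`, optional
#'   `analysis`, `seed`), a [regime_preset()] name, or a path to a YAML/JSON
#'   config file. Unknown keys are rejected.
#' @param out_dir optional output directory; when given, writes `trials.csv`,
#'   `kernel.csv` (+ JSON sidecars), `config.yaml` and `manifest.json`.
#' @param seed overrides the config seed.
#' @return list with `stimulus`, `trials`, `kernel` (raw), `kernel_norm`
#'   (when the analysis section names a normalization), and `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (file.exists(config)) {
      if (grepl("\\.json$", config)) jsonlite::read_json(config) else
        yaml::read_yaml(config)
    } else regime_preset(config)
  }
  .validate_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1L
  seed <- as.integer(config$seed)

  st <- config$stimulus
  stim <- gaussian_stimulus(
    n_trials = st$n_trials, n_frames = st$n_frames,
    frame_dt = if (is.null(st$frame_dt)) 1 / 75 else st$frame_dt,
    sigma_s = if (is.null(st$sigma_s)) 1 else st$sigma_s,
    trial_means = if (is.null(st$conditions)) 0 else
      rep_len(unlist(st$conditions), st$n_trials),
    seed = seed)

  md <- config$model
  kind <- if (is.null(md$kind)) "ddm" else md$kind
  wspec <- .config_weight(md$weight)
  ndt <- if (is.null(md$ndt)) NULL else do.call(ndt_spec, md$ndt)
  urg <- if (is.null(md$urgency)) NULL else do.call(urgency_spec, md$urgency)
  max_time <- if (is.null(md$max_time)) 20 else md$max_time
  trials <- switch(kind,
    ddm = simulate_ddm(
      ddm_spec(bound = if (is.null(md$bound)) 30 else md$bound,
               sigma_eta = if (is.null(md$sigma_eta)) 1 else md$sigma_eta,
               weight = wspec, ndt = ndt, urgency = urg,
               start_point = if (is.null(md$start_point)) 0 else md$start_point,
               drift_offset = if (is.null(md$drift_offset)) 0 else md$drift_offset),
      stim, task = "rt", max_time = max_time, seed = seed + 1L),
    unbounded = simulate_unbounded_ddm(
      ddm_spec(bound = Inf,
               sigma_eta = if (is.null(md$sigma_eta)) 1 else md$sigma_eta,
               weight = wspec),
      stim, seed = seed + 1L),
    race = simulate_race(
      race_spec(rho = if (is.null(md$rho)) -1 else md$rho,
                bound = if (is.null(md$bound)) 30 else md$bound,
                reflect = if (is.null(md$reflect)) -Inf else md$reflect,
                leak = if (is.null(md$leak)) 0 else md$leak,
                inhibition = if (is.null(md$inhibition)) 0 else md$inhibition,
                v0 = if (is.null(md$v0)) 0 else md$v0,
                sigma_eta = if (is.null(md$sigma_eta)) 1 else md$sigma_eta,
                weight = wspec, ndt = ndt, urgency = urg),
      stim, max_time = max_time, seed = seed + 1L),
    stop_invalid("unknown model kind '", kind, "'"))

  an <- config$analysis
  align <- if (is.null(an$alignment)) "stimulus" else an$alignment
  kernel <- psych_kernel(stim, trials, align = align,
                         window = an$window,
                         inclusion = if (is.null(an$inclusion)) "onset"
                                     else an$inclusion)
  kernel_norm <- NULL
  if (!is.null(an$normalization) && an$normalization != "raw") {
    kernel_norm <- if (an$normalization == "bounded") {
      normalize_kernel(kernel, "bounded", sigma_s = stim$sigma_s,
                       bound = if (is.null(urg)) md$bound else NULL,
                       urgency = urg)
    } else {
      normalize_kernel(kernel, "unbounded", sigma_s = stim$sigma_s,
                       sigma_tot = sigma_tot(
                         st$n_frames, stim$frame_dt, stim$sigma_s,
                         if (is.null(md$sigma_eta)) 1 else md$sigma_eta, wspec))
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    write_kernel(if (is.null(kernel_norm)) kernel else kernel_norm,
                 file.path(out_dir, "kernel.csv"))
    cfg_path <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(config, cfg_path, precision = 12L)
    manifest <- list(
      package = "revkernel",
      version = as.character(utils::packageVersion("revkernel")),
      r_version = R.version.string,
      seed = seed,
      config_md5 = unname(tools::md5sum(cfg_path)),
      created = format(Sys.time(), tz = "UTC", usetz = TRUE),
      n_trials = nrow(trials), n_censored = attr(trials, "n_censored"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(stimulus = stim, trials = trials, kernel = kernel,
       kernel_norm = kernel_norm, config = config)
}
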