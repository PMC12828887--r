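#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> screen -> pseudopopulation -> decode ->
#' sharpening (-> dynamics) from a single configuration and writes every
#' stage's artifact plus a manifest with seeds and content hashes.
#' Re-running with the same configuration reproduces byte-identical CSVs.
#'
#' @param config Either a named list or a path to a YAML file with blocks:
#'   `simulation` (arguments to [sim_config()]; `transfer_family` /
#'   `transfer_gamma` may be given in place of a profile object),
#'   `screening` (`min_trials`, `min_modulation_pct`), `pseudopop`
#'   (`seed`, `target_nbacks`), `decoding` (`kind`, `n_iterations`,
#'   `window`, `seed`), `sharpening` (`dynamics` flag, `centers_ms`,
#'   `window_ms`, `threshold`, `n_iterations`).
#' @param out_dir Output directory.
#' @return The run manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    artifacts <<- c(artifacts, path)
    path
  }

  ## stage 1: simulate
  study <- with_stage("simulate", simulate_study(cfg$simulation))

  ## stage 2: screen
  screen <- with_stage("screen", {
    do.call(rbind, lapply(study$sessions, function(s) {
      inc <- session_inclusion(
        s, min_trials = cfg$screening$min_trials,
        min_modulation_pct = cfg$screening$min_modulation_pct)
      data.frame(session_id = s$session_id, included = inc$included,
                 t(inc$criteria), modulation_pct = inc$modulation_pct)
    }))
  })
  emit(screen, "screening.csv")
  kept <- study$sessions[screen$included]
  if (!length(kept)) stop("[screen] no session passed screening",
                          call. = FALSE)

  ## stage 3: pseudopopulation + unit d'
  pop <- with_stage("pseudopop", build_pseudopopulation(
    kept, target_nbacks = cfg$pseudopop$target_nbacks,
    seed = cfg$pseudopop$seed))
  dpr <- with_stage("pseudopop", {
    Xn <- spike_count_window(pop$blocks$novel_exact, pop$time_bins_ms,
                             300, 500)
    Xr <- spike_count_window(pop$blocks$repeat_exact, pop$time_bins_ms,
                             300, 500)
    data.frame(unit_id = pop$unit_ids, dprime = unit_dprimes(Xn, Xr))
  })
  emit(dpr, "unit_dprime.csv")

  ## stage 4: decode
  cv <- with_stage("decode", crossval_run(
    pop, kind = cfg$decoding$kind,
    n_iterations = cfg$decoding$n_iterations,
    window = cfg$decoding$window, seed = cfg$decoding$seed))
  emit(cv$iterations, "crossval_iterations.csv")

  ## stage 5: sharpening (+ behavior)
  sh <- with_stage("sharpen", sharpening_from_crossval(cv))
  behav <- with_stage("sharpen", behavioral_pcr_curve(kept))
  emit(behav$table, "behavior_pcr.csv")
  sharpen_summary <- list(
    classifier_sharpening_mean = sh$mean,
    classifier_sharpening_se = sh$se,
    peak_accuracy = sh$peak_accuracy,
    behavioral_sharpening = sharpening_metric(
      behav$curve,
      peak_accuracy = max(mean(c(behav$curve$novel_accuracy,
                                 behav$curve$repeat_accuracy)), 0.51))$value,
    generative_sharpening = study$ground_truth$sharpening)
  jsonlite::write_json(sharpen_summary, file.path(out_dir, "sharpening.json"),
                       auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, file.path(out_dir, "sharpening.json"))

  ## stage 6: dynamics (optional)
  latency_summary <- NULL
  if (isTRUE(cfg$sharpening$dynamics)) {
    tc <- with_stage("dynamics", sliding_window_sharpening(
      pop, kind = cfg$decoding$kind,
      window_ms = cfg$sharpening$window_ms,
      centers_ms = cfg$sharpening$centers_ms,
      n_iterations = cfg$sharpening$n_iterations,
      seed = cfg$decoding$seed))
    emit(data.frame(center_ms = tc$centers_ms, mean = tc$mean, se = tc$se,
                    accuracy = tc$accuracy), "dynamics.csv")
    lat <- sharpening_latency(tc, threshold = cfg$sharpening$threshold)
    latency_summary <- list(
      mean_ms = if (length(lat)) mean(lat) else NA,
      n = length(lat),
      n_excluded_preonset = attr(lat, "n_excluded_preonset"),
      n_never_crossed = attr(lat, "n_never_crossed"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mnemosharp")),
    config = serialize_config(cfg),
    n_sessions_simulated = length(study$sessions),
    n_sessions_included = length(kept),
    n_units = length(pop$unit_ids),
    sharpening = sharpen_summary,
    latency = latency_summary,
    artifact_md5 = as.list(tools::md5sum(sort(artifacts))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

pipeline_config <- function(config) {
  sim_args <- config$simulation %||% list()
  if (!inherits(sim_args, "sim_config")) {
    if (!is.null(sim_args$transfer_family)) {
      sim_args$transfer <- transfer_profile(
        sim_args$transfer_family, sim_args$transfer_gamma %||% 1)
      sim_args$transfer_family <- NULL
      sim_args$transfer_gamma <- NULL
    }
    sim_args <- do.call(sim_config, sim_args)
  }
  dec <- config$decoding %||% list()
  dec$kind <- dec$kind %||% "spike_count"
  dec$n_iterations <- dec$n_iterations %||% 100L
  dec$window <- dec$window %||% c(300, 500)
  dec$seed <- dec$seed %||% (sim_args$seed + 1L)
  if (dec$n_iterations < 1L) {
    stop("decoding n_iterations must be >= 1", call. = FALSE)
  }
  scr <- config$screening %||% list()
  scr$min_trials <- scr$min_trials %||% 1200L
  scr$min_modulation_pct <- scr$min_modulation_pct %||% 2
  pp <- config$pseudopop %||% list()
  pp$seed <- pp$seed %||% (sim_args$seed + 2L)
  shp <- config$sharpening %||% list()
  shp$dynamics <- shp$dynamics %||% FALSE
  shp$window_ms <- shp$window_ms %||% 200
  shp$centers_ms <- shp$centers_ms %||% seq(-100, 500, by = 30)
  shp$threshold <- shp$threshold %||% 0.1
  shp$n_iterations <- shp$n_iterations %||% dec$n_iterations
  list(simulation = sim_args, screening = scr, pseudopop = pp,
       decoding = dec, sharpening = shp)
}

serialize_config <- function(cfg) {
  sim <- unclass(cfg$simulation)
  sim$transfer <- list(family = sim$transfer$family,
                       gamma = sim$transfer$gamma)
  list(simulation = sim, screening = cfg$screening,
       pseudopop = cfg$pseudopop, decoding = cfg$decoding,
       sharpening = cfg$sharpening)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preset fixture configurations
#'
#' `"tiny"` is a seconds-scale end-to-end fixture (2 sessions of 20 units,
#' 50 exact and 30 lure pairs). `"paper_scale_m2"` mirrors a Monkey-2-scale
#' dataset: 17 sessions of 35 units (595 total), 142 exact and 80 lure
#' pairs per session at N-backs 7--10, 1,500 trials per session.
#'
#' @param preset `"tiny"` or `"paper_scale_m2"`.
#' @param dir Optional directory: when given, the study is simulated and
#'   each session written via [write_session_csv()] into
#'   `dir/session_<k>/`.
#' @param seed Master seed stored in the configuration.
#' @return The [sim_config()] (invisibly if `dir` is given).
#' @export
generate_fixtures <- function(preset = c("tiny", "paper_scale_m2"),
                              dir = NULL, seed = 1L) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    tiny = sim_config(
      n_sessions = 2L, units_per_session = 20L, trials = 180L,
      n_exact_pairs = 50L, n_lure_pairs = 30L,
      target_nback_set = c(7L, 8L, 9L, 10L), seed = seed),
    paper_scale_m2 = sim_config(
      n_sessions = 17L, units_per_session = 35L, trials = 1500L,
      n_exact_pairs = 142L, n_lure_pairs = 80L,
      target_nback_set = c(7L, 8L, 9L, 10L), seed = seed))
  if (is.null(dir)) return(cfg)
  study <- simulate_study(cfg)
  for (s in study$sessions) {
    write_session_csv(s, file.path(dir, sprintf("session_%02d", s$session_id)))
  }
  invisible(cfg)
}
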