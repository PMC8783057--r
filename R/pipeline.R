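#' Build a validated pipeline run configuration
#'
#' A run configuration bundles the kinetic scheme, the photophysics model,
#' the experiment size, stage toggles, and the per-stage analysis
#' parameters, plus a single master seed that fans out deterministically to
#' every stochastic stage. Configurations round-trip through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param scheme a [kinetic_scheme()] (or a plain list of its fields).
#' @param phys a [photophysics_model()] (or a plain list of its fields).
#' @param n_molecules molecules per field of view.
#' @param duration acquisition length (s).
#' @param contaminant_fraction,no_binding_fraction population structure
#'   (see [simulate_experiment()]).
#' @param stages character subset of
#'   `c("simulate", "detect", "segment", "kinetics", "ensemble")`.
#' @param detection list: `min_duration`, `threshold_window`,
#'   `threshold_factor`, `bridge_gap`.
#' @param hmm list: `max_states`, `fit_window`, `n_restarts`.
#' @param kinetics list: `censoring_policy`, `n_boot`, `start_tolerance`.
#' @param ensemble list: `low_binding_cutoff`, plus [group_rules()] fields.
#' @param master_seed integer master seed.
#' @param name configuration name (used in output paths/manifest).
#' @return list of class `run_config`.
#' @export
run_config <- function(scheme = kinetic_scheme(),
                       phys = photophysics_model(),
                       n_molecules = 300, duration = 160,
                       contaminant_fraction = 0.13,
                       no_binding_fraction = 0.32,
                       stages = c("simulate", "detect", "segment",
                                  "kinetics", "ensemble"),
                       detection = list(),
                       hmm = list(),
                       kinetics = list(),
                       ensemble = list(),
                       master_seed = 1,
                       name = "run") {
  if (!inherits(scheme, "kinetic_scheme")) scheme <- do.call(kinetic_scheme, scheme)
  if (!inherits(phys, "photophysics_model")) phys <- do.call(photophysics_model, phys)
  allowed <- c("simulate", "detect", "segment", "kinetics", "ensemble")
  bad <- setdiff(stages, allowed)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  merge_defaults <- function(user, defaults, block) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
      stop("unknown ", block, " keys: ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  detection <- merge_defaults(detection,
    list(min_duration = 0.5, threshold_window = c(400, 3000),
         threshold_factor = 0.5, bridge_gap = 1), "detection")
  hmm <- merge_defaults(hmm,
    list(max_states = 3, fit_window = 5, n_restarts = 5), "hmm")
  kinetics <- merge_defaults(kinetics,
    list(censoring_policy = "survival", n_boot = 1000,
         start_tolerance = 1), "kinetics")
  ensemble <- merge_defaults(ensemble,
    list(low_binding_cutoff = 0.05, persistence_cutoff = 0.5,
         tail_window = 20, bright_window = 10), "ensemble")
  if (n_molecules < 0 || duration <= 0) stop("invalid experiment size")
  structure(list(name = name, scheme = scheme, phys = phys,
                 n_molecules = n_molecules, duration = duration,
                 contaminant_fraction = contaminant_fraction,
                 no_binding_fraction = no_binding_fraction,
                 stages = stages, detection = detection, hmm = hmm,
                 kinetics = kinetics, ensemble = ensemble,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config '%s': %d molecules, %.0f s, stages: %s (seed %d)\n",
              x$name, x$n_molecules, x$duration,
              paste(x$stages, collapse = " -> "), x$master_seed))
  invisible(x)
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param file YAML path.
#' @return `write_config`: the path invisibly; `read_config`: a
#'   `run_config`.
#' @export
write_config <- function(config, file) {
  x <- unclass(config)
  x$scheme <- unclass(x$scheme)
  x$scheme$incorporation_rates <- as.list(x$scheme$incorporation_rates)
  x$phys <- unclass(x$phys)
  x$phys$label_fractions <- as.list(x$phys$label_fractions)
  # YAML has no Inf literal guaranteed across parsers; encode as string
  if (is.infinite(x$scheme$t_add)) x$scheme$t_add <- ".inf"
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- yaml::read_yaml(file)
  if (identical(x$scheme$t_add, ".inf")) x$scheme$t_add <- Inf
  x$scheme$incorporation_rates <- unlist(x$scheme$incorporation_rates)
  x$phys$label_fractions <- unlist(x$phys$label_fractions)
  run_config(scheme = x$scheme, phys = x$phys,
             n_molecules = x$n_molecules, duration = x$duration,
             contaminant_fraction = x$contaminant_fraction,
             no_binding_fraction = x$no_binding_fraction,
             stages = x$stages, detection = x$detection, hmm = x$hmm,
             kinetics = x$kinetics, ensemble = x$ensemble,
             master_seed = x$master_seed, name = x$name)
}

#' Run the simulate -> detect -> segment -> kinetics -> ensemble pipeline
#'
#' Executes the enabled stages of a [run_config()] and writes each stage's
#' outputs (CSV/JSON) into `out_dir`, together with a manifest recording
#' the configuration, the master seed, per-file MD5 hashes and the package
#' version. Reruns with an identical configuration are bit-identical for
#' all deterministic stages. Stage logging (molecule/event counts in and
#' out of each filter) goes to `message()`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (Invisibly) a list with the in-memory stage results
#'   (`experiment`, `events`, `segmentation`, `kinetics`, `ensemble`) and
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  res <- list()
  files <- character(0)
  seed <- config$master_seed

  if ("simulate" %in% config$stages) {
    say("[simulate] %d molecules, %.0f s", config$n_molecules, config$duration)
    res$experiment <- simulate_experiment(
      config$scheme, config$phys, config$n_molecules, config$duration,
      contaminant_fraction = config$contaminant_fraction,
      no_binding_fraction = config$no_binding_fraction,
      seed = fan_seed(seed, 1))
    files <- c(files,
               write_traces(res$experiment$traces,
                            file.path(out_dir, "traces.csv")),
               file.path(out_dir, "traces.csv.meta.json"),
               write_state_paths(res$experiment$paths,
                                 file.path(out_dir, "ground_truth.json")))
  }

  traces <- res$experiment$traces
  if (is.null(traces) && any(c("detect", "segment", "kinetics", "ensemble")
                             %in% config$stages)) {
    tf <- file.path(out_dir, "traces.csv")
    if (!file.exists(tf))
      stop("stage 'detect' needs traces: run 'simulate' or provide ", tf)
    traces <- read_traces(tf)
  }

  if ("detect" %in% config$stages) {
    res$events <- detect_events_set(
      traces, min_duration = config$detection$min_duration,
      bridge_gap = config$detection$bridge_gap)
    say("[detect] %d events (>= %.2g s) on %d molecules",
        nrow(res$events), config$detection$min_duration, length(traces))
    files <- c(files, write_events(res$events,
                                   file.path(out_dir, "events.csv")))
  }

  if ("segment" %in% config$stages) {
    if (is.null(res$events)) stop("stage 'segment' needs stage 'detect'")
    res$segmentation <- segment_events(
      traces, res$events, max_states = config$hmm$max_states,
      fit_window = config$hmm$fit_window,
      n_restarts = config$hmm$n_restarts, seed = fan_seed(seed, 2))
    say("[segment] %d dwells from %d events",
        nrow(res$segmentation$dwells), length(res$segmentation$models))
    files <- c(files, write_events(res$segmentation$dwells,
                                   file.path(out_dir, "dwells.csv")))
    mods <- lapply(res$segmentation$models, function(m)
      list(K = m$K, means = m$means, variances = m$variances,
           transition_matrix = m$transition_matrix,
           initial_probs = m$initial_probs, evidence = m$evidence,
           bic = m$bic))
    jsonlite::write_json(mods, file.path(out_dir, "hmm_models.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out_dir, "hmm_models.json"))
  }

  if ("kinetics" %in% config$stages) {
    if (is.null(res$segmentation)) stop("stage 'kinetics' needs stage 'segment'")
    dw <- res$segmentation$dwells
    dt <- attr(traces[[1]], "frame_dt")
    kin <- list()
    for (st in c("open", "closed")) {
      d <- dw[dw$state_label == st, , drop = FALSE]
      kin[[paste0("k_exit_", st)]] <- tryCatch(
        unclass(fit_exponential_rate(
          d, policy = config$kinetics$censoring_policy, frame_dt = dt,
          n_boot = config$kinetics$n_boot, seed = fan_seed(seed, 3))),
        error = function(e) list(error = conditionMessage(e)))
    }
    pt <- polymerisation_times(dw, dt,
                               start_tolerance = config$kinetics$start_tolerance)
    kin$polymerisation_times <- unclass(
      polymerisation_time_histogram(pt$duration))
    say("[kinetics] open/closed dwell fits on %d dwells; %d polymerisation times",
        nrow(dw), nrow(pt))
    kin$provenance <- list(master_seed = seed,
                           censoring_policy = config$kinetics$censoring_policy,
                           threshold_factor = config$detection$threshold_factor)
    jsonlite::write_json(kin, file.path(out_dir, "kinetics.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, file.path(out_dir, "kinetics.json"))
    res$kinetics <- kin
  }

  if ("ensemble" %in% config$stages) {
    if (is.null(res$events)) stop("stage 'ensemble' needs stage 'detect'")
    t_add <- attr(traces, "t_add") %||% config$scheme$t_add
    if (is.finite(t_add)) {
      res$ensemble <- build_heatmap(
        traces, res$events, t_add,
        low_binding_cutoff = config$ensemble$low_binding_cutoff,
        rules = group_rules(config$ensemble$persistence_cutoff,
                            config$ensemble$tail_window,
                            config$ensemble$bright_window))
      say("[ensemble] %d displayed / %d molecules; group c: %d",
          nrow(res$ensemble$matrix), length(traces),
          sum(res$ensemble$group_labels == "c_low_binding"))
      write.csv(res$ensemble$matrix,
                file.path(out_dir, "ensemble_matrix.csv"))
      jsonlite::write_json(
        list(sort_order = res$ensemble$sort_order,
             group_labels = as.list(res$ensemble$group_labels),
             t_add = t_add,
             thresholds = config$ensemble),
        file.path(out_dir, "ensemble_meta.json"), auto_unbox = TRUE,
        digits = NA)
      files <- c(files, file.path(out_dir, "ensemble_matrix.csv"),
                 file.path(out_dir, "ensemble_meta.json"))
    } else {
      say("[ensemble] skipped: no finite t_add")
    }
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_file)
  files <- unique(c(files, cfg_file))
  manifest <- list(
    name = config$name,
    master_seed = seed,
    stages = config$stages,
    package_version = as.character(utils::packageVersion("polfret")),
    files = lapply(setNames(nm = basename(files)), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Packaged demonstration configurations
#'
#' Desk-scale configurations (300 molecules, 160 s at 25 Hz by default)
#' reproducing the canonical experiment designs: binary complex on
#' extensible DNA, binary complex on dideoxy-terminated DNA, 5/10/15-nt
#' extensions at saturating dNTPs, single-dTTP incorporation, and the
#' no-nucleotide and mismatched-nucleotide controls (where closing is ~90%
#' rarer than with a complementary nucleotide).
#'
#' @param n_molecules,duration experiment size shared by all configs.
#' @param master_seed master seed shared by all configs.
#' @return Named list of [run_config()] objects.
#' @export
make_demo_configs <- function(n_molecules = 300, duration = 160,
                              master_seed = 1) {
  base_inc <- c(A = 2, C = 1, G = 1.5, T = 3.4)
  cfg <- function(name, ...) {
    run_config(scheme = kinetic_scheme(...), n_molecules = n_molecules,
               duration = duration, master_seed = master_seed, name = name)
  }
  list(
    binary_extensible = cfg("binary_extensible", k_close = 1.4, k_open = 5.3,
                            n_max = 0, t_add = Inf),
    binary_dideoxy = cfg("binary_dideoxy", k_close = 1.1, k_open = 29,
                         n_max = 0, t_add = Inf),
    extension_5nt = cfg("extension_5nt", n_max = 5, t_add = 72,
                        incorporation_rates = base_inc),
    extension_10nt = cfg("extension_10nt", n_max = 10, t_add = 72,
                         incorporation_rates = base_inc),
    extension_15nt = cfg("extension_15nt", n_max = 15, t_add = 72,
                         incorporation_rates = base_inc),
    single_dTTP = cfg("single_dTTP", n_max = 1, t_add = 72,
                      template_sequence = "ATAATCACTAGCGAG",
                      incorporation_rates = base_inc),
    no_dNTP = cfg("no_dNTP", n_max = 0, t_add = Inf,
                  k_close = 1.4, k_open = 5.3),
    mismatch = cfg("mismatch", n_max = 0, t_add = Inf,
                   k_close = 0.14, k_open = 5.3)
  )
}
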