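RUN_CONFIG_KEYS <- c("synth", "input", "sessions", "subject", "preprocess",
                     "regions", "coupling", "seed", "out_dir")
PREPROCESS_KEYS <- c("seg_len_s", "seg_factor", "bandpass_hz", "notch_hz",
                     "ica", "epoch_ms", "reject_uv")

#' Validate a pipeline run configuration
#'
#' Checks the configuration schema before any computation: unknown keys are
#' rejected, synthetic runs must carry a seed, and preprocessing keys must
#' be from the known set. A configuration is either a list or a path to a
#' JSON file with the same structure.
#'
#' @param config List or JSON path.
#' @return The validated configuration list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$synth) && is.null(config$input)) {
    stop("config must request synthesis (synth) or name input recordings (input)")
  }
  if (!is.null(config$synth) && is.null(config$seed) &&
      is.null(config$synth$seed)) {
    stop("a seed is mandatory for synthetic runs")
  }
  if (!is.null(config$preprocess)) {
    bad <- setdiff(names(config$preprocess), PREPROCESS_KEYS)
    if (length(bad)) {
      stop("unknown preprocess key(s): ", paste(bad, collapse = ", "))
    }
  }
  if (!is.null(config$regions) && !length(names(config$regions))) {
    stop("regions must be a named list of electrode vectors")
  }
  config
}

#' Analyse one preprocessed subject-session
#'
#' Convenience wrapper: preprocessing, band power and region-pair coupling
#' for a single continuous recording.
#'
#' @param recording An [eeg_recording].
#' @param subject,session Labels for the output tables.
#' @param regions Region map.
#' @param pairs Coupling region pairs.
#' @param preprocess_args List of arguments for [preprocess()].
#' @param nm n:m ratio for the PPC.
#' @return List: `power`, `coupling`, `provenance`, `rejection_log`.
#' @export
analyze_recording <- function(recording, subject = "S01", session = "pre",
                              regions = region_map(),
                              pairs = list(c("left_frontal",
                                             "left_occipital")),
                              preprocess_args = list(), nm = c(1, 6)) {
  pp <- do.call(preprocess, c(list(recording), preprocess_args))
  list(
    power = band_power_table(pp$epochs, regions = regions,
                             subject = subject, session = session),
    coupling = couple_regions(pp$epochs, regions = regions, pairs = pairs,
                              subject = subject, session = session, nm = nm),
    provenance = pp$provenance,
    rejection_log = pp$rejection_log
  )
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates synthesis (or loading), preprocessing, band power, coupling
#' and behaviour summaries for every session, writes tidy CSV tables and a
#' provenance JSON (configuration, its hash, stage parameters, row counts)
#' into `out_dir`, and returns the tables. Outputs are deterministic given
#' the seed.
#'
#' @param config List or JSON path; see [validate_run_config()].
#' @param seed Overrides `config$seed`.
#' @param out_dir Overrides `config$out_dir`; created if missing.
#' @return List: `power`, `coupling`, `behavior`, `provenance`.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  config <- validate_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir)) stop("an output directory is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  regions <- if (is.null(config$regions)) region_map() else config$regions
  pairs <- if (is.null(config$coupling$pairs)) {
    list(c("left_frontal", "left_occipital"))
  } else if (is.list(config$coupling$pairs)) {
    config$coupling$pairs
  } else {
    apply(config$coupling$pairs, 1, identity, simplify = FALSE)
  }
  nm <- if (is.null(config$coupling$nm)) c(1, 6) else config$coupling$nm
  pp_args <- if (is.null(config$preprocess)) list() else config$preprocess
  subject <- if (is.null(config$subject)) "S01" else config$subject
  sessions <- if (is.null(config$sessions)) c("pre", "post") else config$sessions

  power <- list(); coupling <- list(); behavior <- list(); stage_prov <- list()
  if (!is.null(config$synth)) {
    for (i in seq_along(sessions)) {
      args <- config$synth
      args$seed <- (if (is.null(config$seed)) args$seed else config$seed) + i - 1L
      cfg <- do.call(synth_config, args)
      rec <- generate_recording(cfg)
      res <- analyze_recording(rec$recording, subject, sessions[i],
                               regions, pairs, pp_args, nm)
      power[[i]] <- res$power
      coupling[[i]] <- res$coupling
      behavior[[i]] <- summarize_behavior(
        generate_behavior(cfg, subject = subject, session = sessions[i]))
      stage_prov[[sessions[i]]] <- res$provenance
    }
  } else {
    inputs <- config$input$recordings
    for (i in seq_along(inputs$path)) {
      path <- inputs$path[i]
      rec <- if (grepl("\\.vhdr$", path)) read_brainvision(path)
             else read_edf(path)
      res <- analyze_recording(rec, inputs$subject[i], inputs$session[i],
                               regions, pairs, pp_args, nm)
      power[[i]] <- res$power
      coupling[[i]] <- res$coupling
      stage_prov[[paste(inputs$subject[i], inputs$session[i])]] <-
        res$provenance
    }
    if (!is.null(config$input$behavior)) {
      behavior[[1]] <- summarize_behavior(
        read_behavior_csv(config$input$behavior))
    }
  }

  power <- do.call(rbind, power)
  coupling <- do.call(rbind, coupling)
  behavior <- if (length(behavior)) do.call(rbind, behavior) else NULL

  utils::write.csv(power, file.path(config$out_dir, "band_power.csv"),
                   row.names = FALSE)
  utils::write.csv(coupling, file.path(config$out_dir, "coupling.csv"),
                   row.names = FALSE)
  if (!is.null(behavior)) {
    utils::write.csv(behavior, file.path(config$out_dir, "behavior.csv"),
                     row.names = FALSE)
  }
  provenance <- list(
    package_version = as.character(utils::packageVersion("tgcwm")),
    config = config,
    config_hash = fnv1a_hash(jsonlite::toJSON(config, auto_unbox = TRUE)),
    stages = stage_prov,
    rows = list(power = nrow(power), coupling = nrow(coupling),
                behavior = if (is.null(behavior)) 0L else nrow(behavior))
  )
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  list(power = power, coupling = coupling, behavior = behavior,
       provenance = provenance)
}

## 32-bit FNV-1a hash of a string, as 8 hex digits.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # xor only touches the low byte
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply in exact double arithmetic (split at 2^16)
    hi <- floor(h / 65536); lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
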