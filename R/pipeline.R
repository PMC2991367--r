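# 32-bit polynomial rolling hash of a string; stamps outputs with a config
# fingerprint (collision resistance beyond accidental mixups is not needed)
hash32 <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  hash32(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
}

#' Detect events across a set of traces
#'
#' @param traces list of [psc_trace()] objects.
#' @param bank a [build_bank()] result.
#' @param config a [detection_config()].
#' @param ipsc invert polarity before detection (IPSC data).
#' @param verbose log per-trace candidate counts to the console.
#' @return Data frame of events across traces, with `trace_index` and, when
#'   traces carry sites, `row`/`col` columns prepended.
#' @export
detect_events_multi <- function(traces, bank, config = detection_config(),
                                ipsc = FALSE, verbose = FALSE) {
  rows <- list()
  for (i in seq_along(traces)) {
    ev <- detect_events(traces[[i]], bank, config, ipsc = ipsc)
    if (verbose) {
      message(sprintf("trace %d: %d events", i, nrow(ev)))
    }
    if (!nrow(ev)) next
    ev <- cbind(data.frame(trace_index = i), ev)
    site <- traces[[i]]$site
    if (!is.null(site)) {
      ev <- cbind(data.frame(row = site[1], col = site[2]), ev)
    }
    rows[[length(rows) + 1L]] <- ev
  }
  if (!length(rows)) {
    return(data.frame(trace_index = integer(0), t_p_ms = numeric(0),
                      onset_ms = numeric(0), offset_ms = numeric(0),
                      peak_amplitude_pA = numeric(0), rise_time_ms = numeric(0),
                      summed_input_pAms = numeric(0), latency_ms = numeric(0),
                      flags = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an events table as CSV with provenance headers
#'
#' @param events data frame from [detect_events()] or
#'   [detect_events_multi()].
#' @param path destination.
#' @param seed,config recorded as `# seed=` / `# config_hash=` comment
#'   headers.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s", seed), con)
  if (!is.null(config)) {
    writeLines(sprintf("# config_hash=%s", config_hash(config)), con)
  }
  utils::write.csv(events, con, row.names = FALSE)
  invisible(path)
}

#' Read an events CSV written by [write_events()]
#'
#' @param path file path.
#' @return Data frame of events.
#' @export
read_events <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run the pipeline end to end
#'
#' Executes the requested stages in order -- `train` (traces + marks to a
#' filter bank), `detect` (traces + bank to an events table), `evaluate`
#' (simulated ROC curves against ground truth) and `map` (events to the
#' three per-site map layers) -- and writes each artifact under `out_dir`
#' stamped with the seed and a hash of the configuration. Identical
#' configuration and seed reproduce identical outputs.
#'
#' @param stages character subset of `c("train", "detect", "evaluate",
#'   "map")`.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param traces list of [psc_trace()] objects (stages `train`/`detect`).
#' @param marks mark table for [train_bank()] (stage `train`).
#' @param bank a `psc_bank`; defaults to the stage-`train` result.
#' @param config a [detection_config()].
#' @param sim a [simulation_spec()] (stage `evaluate`).
#' @param library,noise simulation libraries (stage `evaluate`); generated
#'   from `sim`'s seed when `NULL`.
#' @param snrs,k_grid ROC grids (stage `evaluate`).
#' @param grid,window map layout and analysis window (stage `map`).
#' @param seed root seed; recorded in every output.
#' @return List with whichever of `bank`, `events`, `roc`, `maps` were
#'   produced.
#' @export
run_pipeline <- function(stages = c("train", "detect"), out_dir = NULL,
                         traces = NULL, marks = NULL, bank = NULL,
                         config = detection_config(),
                         sim = simulation_spec(), library = NULL,
                         noise = NULL, snrs = c(3, 6, 9), k_grid = -2:3,
                         grid = c(16, 16), window = c(10, 150),
                         seed = 1L) {
  stages <- match.arg(stages, c("train", "detect", "evaluate", "map"),
                      several.ok = TRUE)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  prov <- list(seed = seed, config = unclass(config))
  out <- list()
  if ("train" %in% stages) {
    if (is.null(traces) || is.null(marks)) {
      stop("stage 'train' needs 'traces' and 'marks'")
    }
    bank <- train_bank(traces, marks)
    out$bank <- bank
    if (!is.null(out_dir)) write_bank(bank, file.path(out_dir, "bank.json"))
  }
  if ("detect" %in% stages) {
    if (is.null(traces) || is.null(bank)) {
      stop("stage 'detect' needs 'traces' and a trained 'bank'")
    }
    out$events <- detect_events_multi(traces, bank, config)
    if (!is.null(out_dir)) {
      write_events(out$events, file.path(out_dir, "events.csv"),
                   seed = seed, config = prov$config)
    }
  }
  if ("evaluate" %in% stages) {
    if (is.null(bank) && is.null(library)) {
      stop("stage 'evaluate' needs a 'bank' or a template 'library'")
    }
    set.seed(seed)
    if (is.null(library)) library <- synth_template_library()
    if (is.null(noise)) noise <- synth_noise_library()
    if (is.null(bank)) bank <- train_bank_from_library(library)
    sim$seed <- seed
    out$roc <- roc_curve(sim, bank, library, noise, snrs = snrs,
                         k_grid = k_grid, config = config)
    if (!is.null(out_dir)) {
      con <- file(file.path(out_dir, "roc.csv"), "w")
      writeLines(sprintf("# seed=%s", seed), con)
      writeLines(sprintf("# config_hash=%s", config_hash(prov$config)), con)
      utils::write.csv(out$roc, con, row.names = FALSE)
      close(con)
    }
  }
  if ("map" %in% stages) {
    if (is.null(out$events)) stop("stage 'map' needs stage 'detect' output")
    if (!all(c("row", "col") %in% names(out$events))) {
      stop("stage 'map' needs traces with grid sites")
    }
    out$maps <- build_maps(out$events, grid = grid, window = window)
    if (!is.null(out_dir)) {
      jsonlite::write_json(
        c(list(seed = seed, config_hash = config_hash(prov$config)),
          out$maps),
        file.path(out_dir, "maps.json"), digits = NA, na = "null")
    }
  }
  out
}
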