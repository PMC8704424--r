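# Tabular readers/writers and the configurable pipeline driver.
#
# CSV dialects encode units in column names (charge_nC, spike_time_s, ...):
# the study mixes nC/uA/ms in its reporting, and silent unit errors are the
# main integration risk, so files are validated by range-checked schemas.

.spike_cols <- c("cell_id", "diameter_um", "protocol_id", "trial",
                 "charge_nC", "spike_time_s")
.trial_cols <- c("cell_id", "diameter_um", "protocol_id", "trial", "charge_nC")
.protocol_cols <- c("protocol_id", "phase_width_ms", "n_pulses", "freq_hz",
                    "n_repeats", "inter_trial_s")

.check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_stim(sprintf("%s file missing columns: %s", what,
                      paste(miss, collapse = ", ")), "schema")
  }
}

#' Write spike, trial and protocol tables
#'
#' One row per spike in `spikes.csv`; every trial (including zero-spike
#' trials) appears in `trials.csv`; protocols in `protocols.csv`.
#'
#' @param trials_by_cell Named list (by cell id) of lists of
#'   [trial_response()] objects.
#' @param meta data.frame with per-cell `cell_id`, `diameter_um`,
#'   `protocol_id`.
#' @param protocols data.frame with the protocol table columns.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_spike_tables <- function(trials_by_cell, meta, protocols, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spikes <- list(); trials <- list()
  for (cid in names(trials_by_cell)) {
    m <- meta[meta$cell_id == cid, , drop = FALSE]
    for (tr in trials_by_cell[[cid]]) {
      trials[[length(trials) + 1L]] <- data.frame(
        cell_id = cid, diameter_um = m$diameter_um[1],
        protocol_id = m$protocol_id[1], trial = tr$trial,
        charge_nC = tr$charge_nC)
      if (length(tr$spike_times_s)) {
        spikes[[length(spikes) + 1L]] <- data.frame(
          cell_id = cid, diameter_um = m$diameter_um[1],
          protocol_id = m$protocol_id[1], trial = tr$trial,
          charge_nC = tr$charge_nC, spike_time_s = tr$spike_times_s)
      }
    }
  }
  paths <- file.path(dir, c("spikes.csv", "trials.csv", "protocols.csv"))
  utils::write.csv(do.call(rbind, spikes), paths[1], row.names = FALSE)
  utils::write.csv(do.call(rbind, trials), paths[2], row.names = FALSE)
  utils::write.csv(protocols, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read and join spike, trial and protocol tables
#'
#' Validates referential integrity (every spike row must reference a trial
#' row; every trial a protocol) and value ranges, then regroups into
#' [trial_response()] objects per cell.
#'
#' @param spikes_csv,trials_csv,protocols_csv File paths.
#' @return List with `trials_by_cell` (named list of trial lists), `meta`
#'   (per-cell data.frame) and `protocols`.
#' @export
read_spike_tables <- function(spikes_csv, trials_csv, protocols_csv) {
  trials <- utils::read.csv(trials_csv)
  protocols <- utils::read.csv(protocols_csv)
  .check_cols(trials, .trial_cols, "trials")
  .check_cols(protocols, .protocol_cols, "protocols")
  spikes <- utils::read.csv(spikes_csv)
  if (nrow(trials) == 0L) {
    warn_stim("empty trials file", "empty_input")
    return(list(trials_by_cell = list(),
                meta = trials[0, c("cell_id", "diameter_um", "protocol_id")],
                protocols = protocols))
  }
  .check_cols(spikes, .spike_cols, "spikes")
  if (any(trials$charge_nC < 0 | trials$charge_nC > 1e3, na.rm = TRUE)) {
    stop_stim("charge_nC out of plausible nC range; check units", "schema")
  }

  tkey <- with(trials, paste(cell_id, protocol_id, trial, sep = "|"))
  skey <- with(spikes, paste(cell_id, protocol_id, trial, sep = "|"))
  orphan <- !(skey %in% tkey)
  if (any(orphan)) {
    stop_stim(sprintf("spike rows reference unknown trials: %s",
                      paste(utils::head(unique(skey[orphan]), 5), collapse = "; ")),
              "integrity")
  }
  if (!all(trials$protocol_id %in% protocols$protocol_id)) {
    stop_stim("trial rows reference unknown protocols", "integrity")
  }

  trials_by_cell <- lapply(split(trials, trials$cell_id), function(tt) {
    lapply(seq_len(nrow(tt)), function(r) {
      key <- paste(tt$cell_id[r], tt$protocol_id[r], tt$trial[r], sep = "|")
      st <- spikes$spike_time_s[skey == key]
      p <- protocols[protocols$protocol_id == tt$protocol_id[r], ]
      proto <- stimulus_pulse(1e-6, p$phase_width_ms * 1e-3,
                              n_pulses = p$n_pulses,
                              freq_hz = if (p$n_pulses > 1) p$freq_hz else NA_real_)
      trial_response(sort(st), trial = tt$trial[r], charge_nC = tt$charge_nC[r],
                     protocol = proto)
    })
  })
  meta <- unique(trials[, c("cell_id", "diameter_um", "protocol_id")])
  list(trials_by_cell = trials_by_cell, meta = meta, protocols = protocols)
}

# --- pipeline configuration ------------------------------------------------

.config_schema <- list(
  seed = "numeric", out_dir = "character", verbose = "logical",
  electrochem = list(diameters_um = "numeric", n_currents = "numeric",
                     noise_sd_V = "numeric"),
  field = list(sigma_S_per_m = "numeric", diameters_um = "numeric",
               e_threshold_V_per_m = "numeric", pulse_width_ms = "numeric",
               domain = "character"),
  ephys = list(diameters_um = "numeric", n_cells = "numeric",
               protocols = "character"))

.validate_block <- function(cfg, schema, path = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop_stim(sprintf("unknown config key%s: %s",
                      if (length(unknown) > 1) "s" else "",
                      paste0(path, unknown, collapse = ", ")), "schema")
  }
  for (k in names(cfg)) {
    if (is.list(schema[[k]])) {
      if (!is.list(cfg[[k]])) stop_stim(sprintf("config key %s%s must be a block", path, k), "schema")
      .validate_block(cfg[[k]], schema[[k]], paste0(path, k, "."))
    } else if (!is.null(cfg[[k]]) && !inherits(cfg[[k]], schema[[k]]) &&
               !(schema[[k]] == "numeric" && is.numeric(cfg[[k]]))) {
      stop_stim(sprintf("config key %s%s must be %s", path, k, schema[[k]]), "schema")
    }
  }
  invisible(TRUE)
}

#' Pipeline run configuration
#'
#' Validates a configuration list (or YAML file) against the pipeline
#' schema before any stage runs; unknown keys are rejected.
#'
#' @param config A named list, or path to a YAML file.
#' @return Validated config list of class `run_config` (defaults filled in).
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validate_block(config, .config_schema)
  defaults <- list(
    seed = 1, out_dir = "results", verbose = FALSE,
    electrochem = list(diameters_um = c(10, 20, 30), n_currents = 12,
                       noise_sd_V = 0),
    field = list(sigma_S_per_m = 0.2, diameters_um = c(10, 20, 30),
                 e_threshold_V_per_m = 1000, pulse_width_ms = 1,
                 domain = "fullspace"),
    ephys = list(diameters_um = c(10, 20, 30), n_cells = 30,
                 protocols = c("single", "train")))
  merged <- utils::modifyList(defaults, config)
  structure(merged, class = c("run_config", "list"))
}

#' Run the full pipeline: electrochemistry, field model, evoked responses
#'
#' Executes the three analysis stages on synthetic presets as configured
#' and writes a JSON report plus CSV tables to `out_dir`. Deterministic for
#' a fixed seed (all randomness flows from the top-level seed through named
#' per-stage substreams); only the log line carries a timestamp.
#'
#' @param config A [run_config()], plain list or YAML path.
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  report <- list(seed = config$seed)

  # --- electrochemistry stage
  say("stage electrochem")
  circuit <- sirof_circuit_preset(noise_sd_V = config$electrochem$noise_sd_V)
  geom10 <- electrode_geometry(config$electrochem$diameters_um[1])
  csc <- compute_csc(gen_cv_trace(circuit, geom10,
                                  seed = substream_seed(config$seed, "cv")),
                     geom10)
  q_lim <- max_injectable_charge(geom10, 3.3)
  fam <- gen_transient_family(circuit, geom10,
                              currents_A = seq(0.3, 1.6, length.out =
                                                 config$electrochem$n_currents) *
                                q_lim * 1e-9 / 1e-3,
                              seed = substream_seed(config$seed, "vt"))
  cic <- compute_cic(fam, geom10)
  per_electrode <- lapply(config$electrochem$diameters_um, function(d) {
    list(diameter_um = d,
         qmax_nC = max_injectable_charge(electrode_geometry(d), cic$cic_mC_cm2))
  })
  report$electrochem <- list(
    csc_anodic_mC_cm2 = csc$csc_anodic_mC_cm2,
    csc_cathodic_mC_cm2 = csc$csc_cathodic_mC_cm2,
    cic_mC_cm2 = cic$cic_mC_cm2, per_electrode = per_electrode)

  # --- field stage
  say("stage field")
  crit <- activation_criterion(config$field$e_threshold_V_per_m,
                               config$field$pulse_width_ms * 1e-3)
  report$field <- lapply(config$field$diameters_um, function(d) {
    model <- volume_conductor(electrode_geometry(d),
                              sigma_S_per_m = config$field$sigma_S_per_m,
                              domain = config$field$domain)
    q_nC <- max_injectable_charge(electrode_geometry(d), report$electrochem$cic_mC_cm2)
    I_cic <- q_nC * 1e-9 / crit$pulse_width_s
    ad <- activation_depth(model, I_cic, crit)
    list(diameter_um = d, I_cic_uA = I_cic * 1e6,
         activation_depth_um = ad$depth_um, status = ad$status)
  })

  # --- ephys stage
  say("stage ephys")
  arms <- list()
  for (d in config$ephys$diameters_um) {
    for (pr in config$ephys$protocols) {
      arm <- simulate_population_study(
        rgc_population_preset(d), config$ephys$n_cells, protocol = pr,
        seed = substream_seed(config$seed, paste0("ephys", d, pr)))
      arms[[paste0(d, "_", pr)]] <- arm$cells
    }
  }
  cells <- do.call(rbind, arms)
  pop <- population_summary(cells)
  utils::write.csv(cells, file.path(config$out_dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(pop, file.path(config$out_dir, "population_summary.csv"),
                   row.names = FALSE)
  report$ephys <- list(
    n_cells = nrow(cells),
    threshold_median_nC = stats::setNames(
      as.list(pop$threshold_median_nC),
      paste0("d", pop$diameter_um, "_", pop$protocol_id)))

  cfg_hash <- sum(utf8ToInt(paste(deparse(unclass(config)), collapse = "")))
  report$config_hash <- cfg_hash
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat(sprintf("%s stimlimit %s seed=%s hash=%s\n", format(Sys.time()),
              as.character(utils::packageVersion("stimlimit")),
              config$seed, cfg_hash),
      file = file.path(config$out_dir, "run.log"), append = TRUE)
  invisible(report)
}
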