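# Plain-text readers/writers and the end-to-end pipeline runner. Sessions
# are stored as a CSV of channel samples plus a YAML metadata sidecar;
# floats are written with 17 significant digits so read(write(x)) is
# bit-identical. Tables are CSV with checked header contracts.

SCHEMA_VERSION <- "1"

fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a photometry session
#'
#' `write_session()` stores the channel samples as a two-column CSV
#' (`signal`, `isosbestic`) and the metadata (sampling rate, LED epochs,
#' schema version, package version) as a YAML sidecar `<path>.yml`.
#' `read_session()` reverses it losslessly.
#'
#' @param session a [photometry_session()].
#' @param path CSV file path.
#' @return `write_session()`: the path, invisibly. `read_session()`: a
#'   `photometry_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "photometry_session"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("signal,isosbestic", con)
  writeLines(paste(fmt17(session$signal), fmt17(session$isosbestic),
                   sep = ","), con)
  meta <- list(schema_version = SCHEMA_VERSION,
               package_version = as.character(utils::packageVersion("neawake")),
               fs = session$fs,
               led_epochs = lapply(seq_len(nrow(session$led_epochs)),
                 function(i) list(start_s = session$led_epochs$start_s[i],
                                  end_s = session$led_epochs$end_s[i])))
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  d <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("signal", "isosbestic") %in% names(d)))
    stop("session file lacks signal/isosbestic columns", call. = FALSE)
  led <- do.call(rbind, lapply(meta$led_epochs, as.data.frame))
  photometry_session(d$signal, d$isosbestic, meta$fs, led)
}

#' Write / read a checked CSV table
#'
#' CSV round-trip with a header contract: required columns must be present
#' with parseable values; unknown columns are preserved with a warning on
#' read; malformed rows are rejected with their row number.
#'
#' @param table data.frame to write.
#' @param path CSV path.
#' @param required named character of required columns and their types
#'   (`"numeric"` or `"character"`).
#' @return the table (read) or the path, invisibly (write).
#' @export
write_table_checked <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(table[num], fmt17)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_checked
#' @export
read_table_checked <- function(path, required) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(required), names(d))
  if (length(missing_cols))
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(d), names(required))
  if (length(extra))
    warning(sprintf("unknown column(s) preserved: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  for (nm in names(required)) {
    if (required[[nm]] == "numeric") {
      v <- suppressWarnings(as.numeric(d[[nm]]))
      bad <- which(is.na(v) & !is.na(d[[nm]]) & d[[nm]] != "NA")
      if (length(bad))
        stop(sprintf("column '%s' malformed at row %d", nm, bad[1]),
             call. = FALSE)
      d[[nm]] <- v
    }
  }
  d
}

# canonical MD5 hash of a resolved configuration list
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(config[order(names(config))], tf)
  unname(tools::md5sum(tf))
}

#' Run the simulation-to-statistics pipeline
#'
#' Executes the stages in dependency order on a synthetic cohort: simulate
#' (per-mouse sessions, schedules, ground truth), preprocess (reference fit
#' and dF/F), epoch, detect response windows, score elements and trial
#' outcomes, and compute the awakening probability. All stage outputs are
#' written under `out_dir` and listed, with MD5 checksums, in the returned
#' manifest together with the seed chain and the resolved-config hash.
#' Rerunning with an identical config yields identical checksums.
#'
#' @param config list with optional entries `seed`, `n_mice`,
#'   `duration_s`, plus any [sim_config()] override; or a YAML file path.
#' @param out_dir output directory (created if needed).
#' @return the manifest (list), invisibly written as
#'   `out_dir/manifest.yml`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("neawake_run_")) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(seed = 1L, n_mice = 4L, duration_s = 600,
                   noise_sd = 0.3, surge_amp = 2, rise_amp = 1)
  config <- utils::modifyList(defaults, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seeds <- split_seed(config$seed, config$n_mice)
  files <- character(0)
  epochs <- list(); all_scores <- list(); all_trials <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  for (m in seq_len(config$n_mice)) {
    cfg <- sim_config(seed = seeds[m], duration_s = config$duration_s,
                      noise_sd = config$noise_sd,
                      surge_amp = config$surge_amp,
                      rise_amp = config$rise_amp,
                      led_cycle_s = c(on = config$duration_s, off = 0))
    trials <- stage("simulate", sim_trial_schedule(cfg))
    truth <- stage("simulate", sim_ground_truth(cfg, trials))
    ses <- stage("simulate", sim_photometry(cfg, trials, truth, "PRN"))
    spath <- file.path(out_dir, sprintf("session_m%02d.csv", m))
    write_session(ses, spath)
    files <- c(files, spath, paste0(spath, ".yml"))
    dff <- stage("preprocess", compute_dff(ses, fit_isosbestic(ses)))
    ep <- stage("epoch", epoch_trials(dff, trials$onset_s))
    epochs[[m]] <- ep
    trials$outcome <- truth$trial_outcomes
    trials$mouse <- sprintf("m%02d", m)
    trials$baseline_state <- "NREM"
    all_trials[[m]] <- trials
    tpath <- file.path(out_dir, sprintf("trials_m%02d.csv", m))
    write_table_checked(trials, tpath)
    files <- c(files, tpath)
  }
  win <- stage("detect-windows", detect_response_windows(epochs))
  wpath <- file.path(out_dir, "windows.json")
  jsonlite::write_json(
    lapply(win$windows, function(w) w[c("start_s", "end_s", "p")]),
    wpath, auto_unbox = TRUE, digits = NA)
  files <- c(files, wpath)
  trials_all <- do.call(rbind, all_trials)
  if (length(win$windows)) {
    sc <- do.call(rbind, lapply(seq_along(epochs), function(m) {
      s <- score_elements(epochs[[m]], win$windows[[1]],
                          outcomes = all_trials[[m]]$outcome)
      s$mouse <- sprintf("m%02d", m)
      s
    }))
    spath2 <- file.path(out_dir, "element_scores.csv")
    write_table_checked(sc, spath2)
    files <- c(files, spath2)
  }
  ap <- stage("score-trials", awakening_probability(trials_all))
  manifest <- list(schema_version = SCHEMA_VERSION,
                   package_version = as.character(utils::packageVersion("neawake")),
                   config = config, config_hash = hash,
                   seed_chain = as.list(seeds),
                   awakening_probability = ap$p,
                   n_windows = length(win$windows),
                   artifacts = lapply(files, function(f)
                     list(file = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  invisible(manifest)
}
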