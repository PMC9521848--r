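# Disk layout: one CSV per subject/timepoint/condition named
# SUBJ_{baseline|post}_{rest|task}.csv (header row = channel labels),
# subjects.csv, couplings.csv (ground truth), manifest.json, config.yaml.

#' Write / read a recording as delimited text
#'
#' Canonical on-disk form of a recording: comma-separated, one column per
#' channel, header row of electrode labels. The sampling rate travels in
#' the dataset manifest, so `read_recording()` takes it as an argument.
#'
#' @param rec Recording (list with `data`, `rate`, `channels`).
#' @param path Output CSV file.
#' @return `read_recording()` returns the recording list.
#' @export
write_recording <- function(rec, path) {
  utils::write.table(round(rec$data, 6), path, sep = ",", row.names = FALSE,
                     col.names = rec$channels, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param rate Sampling rate in samples/second.
#' @export
read_recording <- function(path, rate) {
  X <- as.matrix(utils::read.csv(path, check.names = FALSE))
  storage.mode(X) <- "double"
  list(data = X, rate = rate, channels = colnames(X))
}

#' Write a simulated trial dataset to a directory
#'
#' Writes every recording (`<id>_<timepoint>_<condition>.csv`), the subject
#' table, the ground-truth couplings, and a manifest (seed, rate, design,
#' file list with a content hash per file) so the directory is
#' self-describing.
#'
#' @param trial A `"capen_trial"`.
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_trial <- function(trial, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("output directory not writable: ", dir)
  files <- character(0)
  for (id in names(trial$recordings))
    for (tp in names(trial$recordings[[id]]))
      for (cond in names(trial$recordings[[id]][[tp]])) {
        f <- sprintf("%s_%s_%s.csv", id, tp, cond)
        write_recording(trial$recordings[[id]][[tp]][[cond]],
                        file.path(dir, f))
        files <- c(files, f)
      }
  utils::write.csv(trial$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$couplings, file.path(dir, "couplings.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = trial$seed, rate = trial$design$rate,
    design = unclass(trial$design),
    effects = unclass(trial$effects),
    n_subjects = nrow(trial$subjects),
    files = as.list(stats::setNames(tools::md5sum(file.path(dir, files)),
                                    files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a trial dataset from a directory
#'
#' Expects the layout written by [write_trial()] /
#' `SUBJ_{baseline|post}_{rest|task}.csv`. A subject's missing condition
#' files are tolerated: the corresponding cells are left absent (the
#' pipeline marks them missing) and the run continues.
#'
#' @param dir Dataset directory.
#' @return A `"capen_trial"` (without generator internals; `design` is
#'   restored from the manifest).
#' @export
read_trial <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  rate <- manifest$rate
  recordings <- list()
  problems <- character(0)
  for (id in subjects$id) {
    recordings[[id]] <- list()
    for (tp in c("baseline", "post")) {
      recordings[[id]][[tp]] <- list()
      for (cond in c("rest", "task")) {
        f <- file.path(dir, sprintf("%s_%s_%s.csv", id, tp, cond))
        if (file.exists(f)) {
          rec <- tryCatch(read_recording(f, rate), error = function(e) {
            problems <<- c(problems, paste0(basename(f), ": ", conditionMessage(e)))
            NULL
          })
          if (!is.null(rec)) recordings[[id]][[tp]][[cond]] <- rec
        } else {
          problems <- c(problems, paste0(basename(f), ": not found"))
        }
      }
    }
  }
  design <- tryCatch(do.call(trial_design, manifest$design[
    intersect(names(manifest$design), names(formals(trial_design)))]),
    error = function(e) trial_design())
  structure(list(subjects = subjects, recordings = recordings,
                 couplings = tryCatch(
                   utils::read.csv(file.path(dir, "couplings.csv"),
                                   stringsAsFactors = FALSE),
                   error = function(e) NULL, warning = function(w) NULL),
                 design = design, effects = NULL, seed = manifest$seed,
                 problems = problems),
            class = "capen_trial")
}

#' Pipeline entry points: simulate, connectivity, stats
#'
#' Thin orchestration over the package's functions, mirroring the
#' command-line subcommands (`inst/scripts/capen-cli.R`). Every output
#' directory receives a verbatim copy of the run configuration and a
#' manifest, so reruns with identical config and inputs are byte-identical.
#'
#' @param design A [trial_design()].
#' @param effects An [effect_spec()].
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param config A [capen_config()].
#' @return `run_simulate()`: the dataset directory; `run_connectivity()`:
#'   the `"connectivity_table"` (also written as TSV);
#'   `run_stats()`: list of report data.frames (also written as TSVs).
#' @export
run_simulate <- function(design, effects, seed, out_dir,
                         config = capen_config()) {
  trial <- simulate_trial(design, effects, seed, montage = config$montage)
  write_trial(trial, out_dir)
  write_config(config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' @rdname run_simulate
#' @param data_dir Dataset directory (layout of [write_trial()]), or a
#'   `"capen_trial"` object.
#' @export
run_connectivity <- function(data_dir, config = capen_config(),
                             out_dir = NULL) {
  trial <- if (inherits(data_dir, "capen_trial")) data_dir
           else read_trial(data_dir)
  conn <- connectivity_table(trial, config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(conn, file.path(out_dir, "connectivity.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    if (length(trial$problems))
      writeLines(trial$problems, file.path(out_dir, "input_problems.log"))
  }
  conn
}

#' @rdname run_simulate
#' @param conn A `"connectivity_table"`.
#' @param subjects Subject table.
#' @export
run_stats <- function(conn, subjects, config = capen_config(),
                      out_dir = NULL) {
  if (min(table(subjects$arm)) < 3L)
    stop("need at least 3 subjects per arm for the statistics layer")
  adjust <- config$adjust
  reports <- list(
    speech_prepost = speech_prepost_report(subjects),
    speech_change = speech_change_report(subjects),
    connectivity_prepost_tDCS = compare_prepost(conn, "tDCS", adjust),
    connectivity_prepost_control = compare_prepost(conn, "control", adjust),
    connectivity_change = compare_changes(conn, adjust),
    regression = word_repetition_regression(subjects, config$screen_p))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(reports)) {
      x <- reports[[nm]]
      if (inherits(x, "capen_regression"))
        x <- rbind(cbind(model = "univariate", x$univariate),
                   cbind(model = "multivariate", x$multivariate))
      utils::write.table(x, file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  reports
}
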