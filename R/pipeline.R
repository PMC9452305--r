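config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Read/write pipeline tables
#'
#' CSV round-trips for the pipeline's tabular artifacts. Writers emit plain
#' CSV; readers validate the schema and restore classes. Protocol rows with
#' `onset_frame >= offset_frame` are rejected on read.
#'
#' @param x the table to write.
#' @param path file path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_neurons <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_neurons <- function(path) {
  x <- utils::read.csv(path)
  req <- c("neuron_id", "x_um", "y_um", "z_um", "plane")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("neurons file missing column(s): ",
                         paste(miss, collapse = ", "))
  class(x) <- c("viscmap_neurons", "data.frame")
  x
}

#' @rdname table_io
#' @export
write_responses <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_responses <- function(path) {
  x <- utils::read.csv(path)
  req <- c("neuron_id", "stim_id", "organ", "modality", "responsive",
           "magnitude", "theta")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("responses file missing column(s): ",
                         paste(miss, collapse = ", "))
  x$responsive <- as.logical(x$responsive)
  class(x) <- c("viscmap_responses", "data.frame")
  x
}

#' @rdname table_io
#' @export
write_points <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_points <- function(path) {
  x <- utils::read.csv(path)
  req <- c("x_um", "y_um", "label")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("points file missing column(s): ",
                         paste(miss, collapse = ", "))
  x
}

#' @rdname table_io
#' @param si a `viscmap_si` or pooled result.
#' @export
write_si_json <- function(si, path) {
  jsonlite::write_json(unclass(si), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the end-to-end synthetic pipeline
#'
#' Generates a synthetic experiment, converts raw fluorescence to detrended
#' dF/F, calls responses, builds tuning profiles, computes the spatial
#' segregation of the first two organs' selectively tuned neurons, and (when
#' the protocol contains simultaneous-stimulation trials flagged via
#' `suppression_trials`) classifies cross-inhibition. Artifacts are written
#' under `out_dir` together with a manifest recording the seed and a config
#' hash. Stages run in dependency order; `mode` selects how far to go.
#'
#' @param sim_cfg a [sim_config()].
#' @param protocol a [stimulus_protocol()]; default [default_protocol()].
#' @param out_dir output directory (created).
#' @param mode one of `"simulate"`, `"call"`, `"map"`, `"suppress"`,
#'   `"all"`; each mode runs every stage up to and including itself
#'   (`"suppress"` and `"all"` are equivalent when suppression trials
#'   exist).
#' @param suppression_trials optional named vector for
#'   [suppression_calls()] (`d_S1` ... `d_M2` to stim ids).
#' @param si_permutations permutations for [segregation_index()].
#' @return list with the in-memory artifacts (`experiment`, `dff`,
#'   `responses`, `profiles`, `si`, `suppression`, `manifest`), invisibly
#'   written to `out_dir`.
#' @export
run_pipeline <- function(sim_cfg = sim_config(), protocol = default_protocol(),
                         out_dir = tempfile("viscmap_run_"),
                         mode = c("all", "simulate", "call", "map",
                                  "suppress"),
                         suppression_trials = NULL,
                         si_permutations = 1000) {
  mode <- match.arg(mode)
  stages <- c(simulate = 1, call = 2, map = 3, suppress = 4, all = 4)
  depth <- stages[[mode]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = sim_cfg$seed, config_hash = config_hash(sim_cfg),
                   mode = mode, outputs = character(0))
  emit <- function(name) manifest$outputs <<- c(manifest$outputs, name)

  exp <- generate_experiment(sim_cfg, protocol)
  write_neurons(exp$neurons, file.path(out_dir, "neurons.csv")); emit("neurons.csv")
  utils::write.csv(cbind(exp$truth$neurons,
                         as.data.frame(exp$truth$amplitude)),
                   file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  emit("ground_truth.csv")
  write_protocol(protocol, file.path(out_dir, "protocol.csv")); emit("protocol.csv")

  out <- list(experiment = exp, manifest = manifest)
  if (depth >= 2) {
    base_win <- seq_len(min(protocol$onset_frame))
    dff <- detrend_dff(compute_dff(exp$fluor, base_win), protocol)
    responses <- call_responses(dff, protocol)
    profiles <- build_tuning_profiles(responses)
    write_responses(responses, file.path(out_dir, "responses.csv"))
    emit("responses.csv")
    utils::write.csv(profiles, file.path(out_dir, "tuning_profiles.csv"),
                     row.names = FALSE)
    emit("tuning_profiles.csv")
    out$dff <- dff; out$responses <- responses; out$profiles <- profiles
  }
  if (depth >= 3) {
    orgs <- names(sim_cfg$organs)[1:2]
    sel <- out$profiles[out$profiles$selectivity == "selective", ]
    grp <- lapply(orgs, function(o) {
      ids <- sel$neuron_id[sel$dominant_organ == o]
      as.matrix(exp$neurons[exp$neurons$neuron_id %in% ids,
                            c("x_um", "y_um")])
    })
    if (all(vapply(grp, nrow, integer(1)) >= 2)) {
      si <- segregation_index(grp[[1]], grp[[2]],
                              n_permutations = si_permutations,
                              seed = sim_cfg$seed)
      write_si_json(si, file.path(out_dir, "segregation_index.json"))
      emit("segregation_index.json")
      out$si <- si
    } else warning("fewer than 2 tuned neurons per organ; SI skipped")
  }
  if (depth >= 4 && !is.null(suppression_trials)) {
    calls <- suppression_calls(out$responses, suppression_trials)
    summ <- suppression_summary(calls)
    jsonlite::write_json(summ[c("fraction", "n_suppressed", "n_eligible")],
                         file.path(out_dir, "suppression.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("suppression.json")
    out$suppression <- list(calls = calls, summary = summ)
  }
  manifest$outputs <- unique(manifest$outputs)
  out$manifest <- manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$out_dir <- out_dir
  invisible(out)
}
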