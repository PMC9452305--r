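#' Classify paired-stimulus suppression for one neuron
#'
#' Responses are measured in the fixed order stomach (d_S1), duodenum
#' (d_D1), simultaneous mix (d_M1), then a second round (d_S2, d_D2, d_M2).
#' A duodenum response is suppressed by the mixture only when all of
#' `d_M1 < d_D1`, `d_M2 < d_D2`, and `(d_M1 + d_M2)/2 < d_D2` hold; for
#' stomach responses the same three criteria with d_S substituted. All
#' inequalities are strict, so ties (including the boundary case
#' `(d_M1 + d_M2)/2 == d_D2`) are not suppressed. Criterion (3) compares the
#' mix average against the second single trial only, implemented literally.
#'
#' @param series named list or vector with `d_S1`, `d_D1`, `d_M1`, `d_S2`,
#'   `d_D2`, `d_M2` (response magnitudes, max smoothed dF/F minus theta).
#' @param target `"duodenum"` or `"stomach"`: which single-stimulus response
#'   is tested for suppression.
#' @return list: `target`, `suppressed` (logical), `criteria` (the three
#'   individual comparisons).
#' @export
classify_suppression <- function(series, target = c("duodenum", "stomach")) {
  target <- match.arg(target)
  need <- c("d_S1", "d_D1", "d_M1", "d_S2", "d_D2", "d_M2")
  s <- unlist(series)[need]
  if (anyNA(s))
    stop("missing trial(s): ", paste(need[is.na(s)], collapse = ", "))
  d1 <- if (target == "duodenum") s[["d_D1"]] else s[["d_S1"]]
  d2 <- if (target == "duodenum") s[["d_D2"]] else s[["d_S2"]]
  crit <- c(c1 = s[["d_M1"]] < d1,
            c2 = s[["d_M2"]] < d2,
            c3 = (s[["d_M1"]] + s[["d_M2"]]) / 2 < d2)
  list(target = target, suppressed = all(crit), criteria = crit)
}

#' Summarize suppression calls
#'
#' Pooled and per-mouse fractions of eligible neurons classified as
#' suppressed. Per-mouse summaries include only animals in which both
#' suppressed and non-suppressed neurons were observed.
#'
#' @param calls data frame with columns `neuron_id`, `suppressed` (logical),
#'   and optionally `mouse_id`.
#' @return list: `fraction` (pooled), `n_suppressed`, `n_eligible`, and
#'   `per_mouse` (data frame, mice with both response types only).
#' @export
suppression_summary <- function(calls) {
  if (!nrow(calls)) return(list(fraction = NA_real_, n_suppressed = 0L,
                                n_eligible = 0L,
                                per_mouse = data.frame()))
  pooled <- mean(calls$suppressed)
  per_mouse <- data.frame()
  if ("mouse_id" %in% names(calls)) {
    by_m <- split(calls, calls$mouse_id)
    keep <- vapply(by_m, function(d)
      any(d$suppressed) && any(!d$suppressed), logical(1))
    per_mouse <- do.call(rbind, lapply(by_m[keep], function(d)
      data.frame(mouse_id = d$mouse_id[1], fraction = mean(d$suppressed),
                 n = nrow(d))))
    rownames(per_mouse) <- NULL
  }
  list(fraction = pooled, n_suppressed = sum(calls$suppressed),
       n_eligible = nrow(calls), per_mouse = per_mouse)
}

#' Build suppression series from a response table
#'
#' Collects the six ordered magnitudes per neuron from a protocol in which
#' each of the six trials carries a distinct stimulus id, classifies every
#' neuron responsive to the target's single stimulus in both trials, and
#' returns the calls.
#'
#' @param responses a `viscmap_responses` table.
#' @param trial_ids named character vector mapping `d_S1`, `d_D1`, `d_M1`,
#'   `d_S2`, `d_D2`, `d_M2` to stimulus ids in the table.
#' @param target passed to [classify_suppression()].
#' @param mouse_id optional per-neuron mouse labels (named by neuron id).
#' @return data frame of calls: `neuron_id`, `suppressed`, the six
#'   magnitudes, and `mouse_id` when given.
#' @export
suppression_calls <- function(responses, trial_ids,
                              target = c("duodenum", "stomach"),
                              mouse_id = NULL) {
  target <- match.arg(target)
  need <- c("d_S1", "d_D1", "d_M1", "d_S2", "d_D2", "d_M2")
  if (!all(need %in% names(trial_ids)))
    stop("trial_ids must name all six trials: ",
         paste(need, collapse = ", "))
  single <- if (target == "duodenum") c("d_D1", "d_D2") else c("d_S1", "d_S2")
  wide <- lapply(need, function(tr) {
    sub <- responses[responses$stim_id == trial_ids[[tr]], ]
    stats::setNames(sub$magnitude, sub$neuron_id)
  })
  names(wide) <- need
  resp_flag <- lapply(single, function(tr) {
    sub <- responses[responses$stim_id == trial_ids[[tr]], ]
    stats::setNames(sub$responsive, sub$neuron_id)
  })
  ids <- Reduce(intersect, lapply(wide, names))
  eligible <- ids[vapply(ids, function(i)
    all(vapply(resp_flag, function(f) isTRUE(f[[i]]), logical(1))),
    logical(1))]
  rows <- lapply(eligible, function(i) {
    series <- lapply(wide, `[[`, i)
    cl <- classify_suppression(series, target)
    cbind(data.frame(neuron_id = as.integer(i), suppressed = cl$suppressed),
          as.data.frame(series))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(neuron_id = integer(0), suppressed = logical(0))
  if (!is.null(mouse_id) && nrow(out))
    out$mouse_id <- mouse_id[as.character(out$neuron_id)]
  rownames(out) <- NULL
  out
}

#' Dose-series table for cross-inhibition experiments
#'
#' Generic "target magnitude vs co-stimulus intensity" summary: for each
#' co-stimulus intensity level, the mean and SEM of the target-stimulus
#' magnitudes across neurons.
#'
#' @param responses a `viscmap_responses` table.
#' @param target_stim_ids stimulus ids of the target presentations, one per
#'   co-stimulus level.
#' @param co_intensity numeric co-stimulus intensities, same order.
#' @return data frame: `co_intensity`, `mean_magnitude`, `sem`, `n`.
#' @export
dose_series_table <- function(responses, target_stim_ids, co_intensity) {
  stopifnot(length(target_stim_ids) == length(co_intensity))
  rows <- lapply(seq_along(target_stim_ids), function(k) {
    m <- responses$magnitude[responses$stim_id == target_stim_ids[k]]
    data.frame(co_intensity = co_intensity[k], mean_magnitude = mean(m),
               sem = stats::sd(m) / sqrt(length(m)), n = length(m))
  })
  do.call(rbind, rows)
}
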