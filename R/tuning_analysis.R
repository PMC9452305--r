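#' Build per-neuron tuning profiles
#'
#' Maps each stimulus to its organ and summarizes every neuron's responsive
#' set: the organs with at least one responsive stimulus, the selectivity
#' class (`selective` = exactly one organ, `multi_organ` = two or more,
#' `none` = no responses), and the dominant organ (organ of the maximal
#' response magnitude over responsive stimuli; ties broken by `organ_order`).
#'
#' @param responses a `viscmap_responses` table ([call_responses()]).
#' @param stim_organ optional named character vector mapping `stim_id` to
#'   organ; defaults to the `organ` column of `responses`.
#' @param organ_order organ labels in tie-break priority order.
#' @return data frame (class `viscmap_profiles`): `neuron_id`,
#'   `responsive_set` and `organ_set` (comma-joined), `selectivity`,
#'   `dominant_organ` (`NA` when `none`), `max_magnitude`.
#' @export
build_tuning_profiles <- function(responses, stim_organ = NULL,
                                  organ_order = NULL) {
  if (is.null(stim_organ)) {
    stim_organ <- responses$organ
    names(stim_organ) <- responses$stim_id
    stim_organ <- stim_organ[!duplicated(names(stim_organ))]
  }
  unmapped <- setdiff(unique(responses$stim_id), names(stim_organ))
  if (length(unmapped))
    stop("stimulus id(s) not mapped to an organ: ",
         paste(unmapped, collapse = ", "))
  organ_order <- organ_order %||% unique(unname(stim_organ))
  by_neuron <- split(responses, responses$neuron_id)
  rows <- lapply(by_neuron, function(tb) {
    resp <- tb[tb$responsive, , drop = FALSE]
    orgs <- unique(stim_organ[resp$stim_id])
    sel <- if (length(orgs) == 0) "none"
           else if (length(orgs) == 1) "selective" else "multi_organ"
    dom <- NA_character_; mx <- NA_real_
    if (nrow(resp)) {
      org_max <- tapply(resp$magnitude, stim_organ[resp$stim_id], max)
      mx <- max(org_max)
      top <- names(org_max)[org_max == mx]
      dom <- top[order(match(top, organ_order))][1]
    }
    data.frame(neuron_id = tb$neuron_id[1],
               responsive_set = paste(resp$stim_id, collapse = ","),
               organ_set = paste(sort(orgs), collapse = ","),
               selectivity = sel, dominant_organ = dom,
               max_magnitude = mx, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$neuron_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("viscmap_profiles", "data.frame")
  out
}

#' Pearson correlation matrix across stimulus pairs
#'
#' Correlates per-neuron response-magnitude vectors between every pair of
#' stimuli, over the neurons responsive to at least one stimulus in the set.
#' Non-responsive magnitudes enter as their computed (possibly negative)
#' values, not as zeros. A zero-variance column yields `NA` entries with a
#' warning.
#'
#' @param responses a `viscmap_responses` table.
#' @param stimuli stimulus ids to include (default: all).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
stimulus_correlation_matrix <- function(responses, stimuli = NULL) {
  stimuli <- stimuli %||% unique(responses$stim_id)
  sub <- responses[responses$stim_id %in% stimuli, , drop = FALSE]
  mag <- tapply(sub$magnitude, list(sub$neuron_id, sub$stim_id), mean)
  mag <- mag[, stimuli, drop = FALSE]
  resp <- tapply(sub$responsive, list(sub$neuron_id, sub$stim_id), any)
  include <- rowSums(resp[, stimuli, drop = FALSE], na.rm = TRUE) > 0
  if (sum(include) < 3)
    stop("need at least 3 neurons responsive to a stimulus in the set")
  m <- mag[include, , drop = FALSE]
  zv <- apply(m, 2, stats::sd, na.rm = TRUE) == 0
  if (any(zv))
    warning("zero-variance magnitude column(s): ",
            paste(stimuli[zv], collapse = ", "), "; entries set to NA")
  R <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(R) <- 1
  R
}

#' Responder-set overlap between two stimuli
#'
#' Reports `|A∩B|/|A|`, `|A∩B|/|B|`, and the fold increase in the
#' probability of responding to B given a response to A relative to the
#' population base rate `P(B)` (computed over all neurons in the table).
#'
#' @param responses a `viscmap_responses` table.
#' @param stim_a,stim_b stimulus ids.
#' @return list: `frac_a_in_b` (= |A∩B|/|A|), `frac_b_in_a` (= |A∩B|/|B|),
#'   `fold_enrichment` (= P(B|A)/P(B)), `n_a`, `n_b`, `n_both`. Fractions are
#'   `NA` when the conditioning set is empty.
#' @export
convergence_summary <- function(responses, stim_a, stim_b) {
  for (s in c(stim_a, stim_b))
    if (!s %in% responses$stim_id) stop("stimulus '", s, "' not in table")
  ids <- function(s) unique(responses$neuron_id[
    responses$stim_id == s & responses$responsive])
  A <- ids(stim_a); B <- ids(stim_b)
  n_all <- length(unique(responses$neuron_id))
  n_both <- length(intersect(A, B))
  fa <- if (length(A)) n_both / length(A) else NA_real_
  fb <- if (length(B)) n_both / length(B) else NA_real_
  p_b <- length(B) / n_all
  fold <- if (length(A) && p_b > 0) (n_both / length(A)) / p_b else NA_real_
  if (!length(A) || !length(B))
    warning("empty responder set; overlap fractions undefined")
  list(frac_a_in_b = fa, frac_b_in_a = fb, fold_enrichment = fold,
       n_a = length(A), n_b = length(B), n_both = n_both)
}
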