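# Comparison of pipeline output against the simulator's ground-truth
# ledger: matching, recall/precision and per-call accuracies.

#' Match reported elements to ground-truth ledger records
#'
#' Greedy one-to-one matching by interval overlap on the same contig: each
#' ledger record is paired with the reported element of largest overlap
#' (requiring overlap of at least half the truth span).
#'
#' @param elements element tibble from [annotate_elements()].
#' @param ledger truth ledger from [tcme_simulate()].
#' @return the ledger with columns `matched` and, for matched records, the
#'   corresponding element fields prefixed `det_`.
#' @export
match_elements <- function(elements, ledger) {
  out <- ledger
  out$matched <- FALSE
  out$det_start <- NA_integer_
  out$det_end <- NA_integer_
  out$det_subgroup <- NA_character_
  out$det_completeness <- NA_character_
  out$det_group <- NA_character_
  out$det_le_present <- NA
  out$det_re_present <- NA
  used <- rep(FALSE, nrow(elements))
  for (i in seq_len(nrow(ledger))) {
    tr <- ledger[i, ]
    cand <- which(!used &
                    elements$genome_id == tr$genome_id &
                    elements$contig_id == tr$contig_id &
                    elements$start < tr$end & elements$end > tr$start)
    if (length(cand) == 0) next
    ov <- pmin(elements$end[cand], tr$end) - pmax(elements$start[cand], tr$start)
    best <- cand[order(-ov)][1]
    if (ov[order(-ov)][1] < (tr$end - tr$start) / 2) next
    used[best] <- TRUE
    out$matched[i] <- TRUE
    out$det_start[i] <- elements$start[best]
    out$det_end[i] <- elements$end[best]
    out$det_subgroup[i] <- elements$subgroup[best]
    out$det_completeness[i] <- elements$completeness[best]
    out$det_group[i] <- elements$group[best]
    out$det_le_present[i] <- elements$le_present[best]
    out$det_re_present[i] <- elements$re_present[best]
  }
  attr(out, "n_unmatched_elements") <- sum(!used)
  out
}

#' Recovery metrics of a simulate-and-mine experiment
#'
#' Compares pipeline output with the truth ledger and reports detection
#' recall and precision, subgroup-classification accuracy (non-decay
#' records), completeness-call accuracy (decay records count as correct
#' when flagged `decay`), and boundary-coordinate agreement on truth-full
#' records (fraction of boundary coordinates within `boundary_tol` nt and
#' the fraction exactly recovered).
#'
#' @param elements element tibble.
#' @param ledger truth ledger.
#' @param boundary_tol coordinate tolerance in nt.
#' @return one-row tibble of metrics (percentages in `[0, 100]`).
#' @export
recovery_metrics <- function(elements, ledger, boundary_tol = 5L) {
  m <- match_elements(elements, ledger)
  n_truth <- nrow(m)
  matched <- m[m$matched, ]
  recall <- 100 * nrow(matched) / max(1, n_truth)
  precision <- 100 * nrow(matched) /
    max(1, nrow(matched) + attr(m, "n_unmatched_elements"))
  nondecay <- matched[matched$completeness != "decay", ]
  sub_acc <- if (nrow(nondecay) > 0) {
    100 * mean(nondecay$det_subgroup == nondecay$subgroup)
  } else NA_real_
  comp_ok <- ifelse(matched$completeness == "decay",
                    matched$det_group == "decay",
                    matched$det_completeness == matched$completeness &
                      matched$det_group != "decay")
  comp_acc <- if (nrow(matched) > 0) 100 * mean(comp_ok) else NA_real_
  full <- matched[matched$completeness == "full" &
                    matched$det_completeness == "full", ]
  if (nrow(full) > 0) {
    dev <- c(abs(full$det_start - full$start), abs(full$det_end - full$end))
    b_within <- 100 * mean(dev <= boundary_tol)
    b_exact <- 100 * mean(dev == 0)
    b_max <- max(dev)
  } else {
    b_within <- NA_real_
    b_exact <- NA_real_
    b_max <- NA_real_
  }
  tibble::tibble(
    n_truth = n_truth, n_detected = nrow(elements),
    recall = recall, precision = precision,
    subgroup_accuracy = sub_acc,
    completeness_accuracy = comp_acc,
    boundary_within_tol = b_within,
    boundary_exact = b_exact,
    boundary_max_dev = b_max
  )
}
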