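#' Expand homoeologous-exchange truth events to both subgenome sides
#'
#' A simulated exchange is stored once, on the gaining subgenome; in the
#' dosage data it also manifests as the reciprocal loss of the homoeologous
#' interval on the other subgenome. For evaluating a caller against truth,
#' this adds one pseudo-event per affected partner chromosome block
#' (`event_class = "exchange_partner_loss"`).
#'
#' @param events Truth event tibble ([simulate_lesions()]).
#' @param pair_map The homoeologue pair map.
#' @return Events with partner-side rows appended.
#' @export
expand_exchange_truth <- function(events, pair_map) {
  he <- events[events$event_class == "homoeologous_exchange", , drop = FALSE]
  if (nrow(he) == 0) return(events)
  extra <- lapply(seq_len(nrow(he)), function(i) {
    stopifnot(he$subgenome[i] == "A") # exchanges are drawn A-replaces-C
    pr <- pair_map[pair_map$chrom_A == he$chrom[i] &
                     pair_map$idx_A >= he$start_idx[i] &
                     pair_map$idx_A < he$end_idx[i], , drop = FALSE]
    if (nrow(pr) == 0) return(NULL)
    blocks <- split(pr, pr$chrom_C)
    dplyr::bind_rows(lapply(blocks, function(b) tibble::tibble(
      sample_id = he$sample_id[i], subgenome = "C", chrom = b$chrom_C[1],
      start_idx = min(b$idx_C), end_idx = max(b$idx_C) + 1L,
      event_class = "exchange_partner_loss",
      copies = 4L - he$copies[i], zygosity = he$zygosity[i],
      m1_family = he$m1_family[i], lesion_id = he$lesion_id[i])))
  })
  dplyr::bind_rows(events, dplyr::bind_rows(extra))
}

#' Match called events against simulated truth
#'
#' Greedy per-event matching on (sample, subgenome, chromosome) with an
#' interval Jaccard threshold; reports per-truth-event recovery and
#' per-call support, from which sensitivity and precision follow.
#'
#' @param truth Truth event tibble (use [expand_exchange_truth()] first if
#'   exchanges were simulated).
#' @param calls Called event tibble ([call_segments()]).
#' @param min_jaccard Interval Jaccard for a match (default 0.5).
#' @return List with `truth_matched` (logical per truth row), `call_matched`
#'   (logical per call row), `sensitivity`, `precision`.
#' @export
match_events <- function(truth, calls, min_jaccard = 0.5) {
  truth_matched <- vapply(seq_len(nrow(truth)), function(i) {
    cand <- calls[calls$sample_id == truth$sample_id[i] &
                    calls$subgenome == truth$subgenome[i] &
                    calls$chrom == truth$chrom[i], , drop = FALSE]
    nrow(cand) > 0 &&
      any(interval_jaccard(truth$start_idx[i], truth$end_idx[i],
                           cand$start_idx, cand$end_idx) >= min_jaccard)
  }, logical(1))
  call_matched <- vapply(seq_len(nrow(calls)), function(i) {
    cand <- truth[truth$sample_id == calls$sample_id[i] &
                    truth$subgenome == calls$subgenome[i] &
                    truth$chrom == calls$chrom[i], , drop = FALSE]
    nrow(cand) > 0 &&
      any(pmin(cand$end_idx, calls$end_idx[i]) -
            pmax(cand$start_idx, calls$start_idx[i]) > 0)
  }, logical(1))
  list(truth_matched = truth_matched, call_matched = call_matched,
       sensitivity = if (nrow(truth)) mean(truth_matched) else NA_real_,
       precision = if (nrow(calls)) mean(call_matched) else NA_real_)
}
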