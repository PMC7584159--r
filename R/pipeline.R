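# End-to-end orchestration: simulate -> infer -> compare-to-truth.

#' Infer an inversion and its junction architecture from four assemblies
#'
#' Chains the full inference: anchor-based synteny scan of the inverted
#' against the reference uninverted assembly, inversion-candidate calling,
#' segment demarcation, second-pass homology, architecture reconstruction,
#' and mechanism classification.
#'
#' @param seqs Labeled-sequence tibble with ids `inverted`,
#'   `uninverted_1`, `uninverted_2` (optional), `outgroup` (optional).
#' @param k,max_gap,min_anchors Synteny-scan parameters.
#' @param expected_span Optional expected inversion span (bp) used to
#'   filter candidates.
#' @param pad Demarcation padding (bp); enlarged automatically when the
#'   breakpoint gap is wide (insertion-bearing junctions).
#' @param min_len,min_identity Duplication-call thresholds.
#' @param inv_id,uninv_id Ids of the inverted and reference uninverted
#'   assemblies.
#' @return A list of class `"inversion_inference"`: `anchors` counts,
#'   `blocks`, `candidates`, `candidate` (the analyzed one), `segment_map`,
#'   `architecture`, `call`; or, when no orientation flip exists, a list
#'   with `status = "no_inversion_candidate"`.
#' @export
infer_inversion <- function(seqs, k = 15L, max_gap = 2000L, min_anchors = 3L,
                            expected_span = NULL, pad = 1200L,
                            min_len = 20L, min_identity = 0.85,
                            inv_id = "inverted", uninv_id = "uninverted_1") {
  anchors <- find_anchors(seqs[seqs$id == inv_id, ],
                          seqs[seqs$id == uninv_id, ], k = k)
  blocks <- chain_blocks(anchors, max_gap = max_gap,
                         min_anchors = min_anchors)
  candidates <- call_inversion_candidates(blocks, expected_span)
  if (nrow(candidates) == 0L) {
    return(structure(list(status = "no_inversion_candidate",
                          blocks = blocks, candidates = candidates),
                     class = "inversion_inference"))
  }
  cand <- candidates[which.max(candidates$flipped_span), ]
  # widen padding when the junction gap itself is wide (e.g. an insertion)
  gapw <- max(cand$q_prox_end - cand$q_prox_start,
              cand$q_dist_end - cand$q_dist_start)
  pad_used <- max(pad, as.integer(ceiling(0.25 * gapw)))
  map <- demarcate_segments(seqs, cand, inv_id = inv_id, uninv_id = uninv_id,
                            pad = pad_used)
  map <- second_pass_homology(map, seqs, min_len = min_len,
                              min_identity = min_identity)
  uninv_ids <- intersect(c("uninverted_1", "uninverted_2"), seqs$id)
  arch <- reconstruct_architecture(seqs, map, uninv_ids = uninv_ids,
                                   min_len = min_len,
                                   min_identity = min_identity)
  call <- classify_mechanism(arch)
  structure(list(
    status = "inversion_candidate",
    blocks = blocks, candidates = candidates, candidate = cand,
    segment_map = map, architecture = arch, call = call,
    params = list(k = k, max_gap = max_gap, min_anchors = min_anchors,
                  pad = pad_used, min_len = min_len,
                  min_identity = min_identity)
  ), class = "inversion_inference")
}

#' @export
print.inversion_inference <- function(x, ...) {
  cat(sprintf("<inversion_inference> %s\n", x$status))
  if (x$status == "inversion_candidate") {
    cat(sprintf("  flipped span: %d bp\n", x$candidate$flipped_span))
    print(x$call)
  }
  invisible(x)
}

truth_label_map <- c(
  NAHR = "NAHR", CUT_AND_PASTE = "NHEJ_CUT_AND_PASTE",
  STAGGERED_ISO = "NHEJ_STAGGERED", STAGGERED_CHROMATID = "NHEJ_STAGGERED",
  CHROMOSOME = "CHROMOSOME_MODEL", BIR_MMBIR = "NHEJ_STAGGERED"
)

#' Compare an inference against simulation ground truth
#'
#' Joins an [infer_inversion()] result with the `truth` of
#' [simulate_dataset()] and emits recovery metrics: breakpoint offsets in
#' bp, duplication recovery (pair-by-pair extent agreement), microinversion
#' span error, central-deletion length error, mechanism-label match and
#' BIR/MMBIR flag agreement.
#'
#' @param inference An `"inversion_inference"`.
#' @param truth A `"sim_truth"`.
#' @param match_tol Coordinate slack (bp) when matching duplication pairs.
#' @return A one-row tibble of recovery metrics.
#' @export
evaluate_inference <- function(inference, truth, match_tol = 5L) {
  stopifnot(inherits(truth, "sim_truth"))
  expected_label <- truth_label_map[[truth$mechanism]]
  if (truth$complex_proximal && truth$distal_chromosome) {
    expected_label <- "NHEJ_STAGGERED+CHROMOSOME_MODEL"
  } else if (truth$distal_chromosome && truth$mechanism != "CHROMOSOME") {
    expected_label <- paste0(truth_label_map[[truth$mechanism]],
                             "+CHROMOSOME_MODEL")
  }
  if (inference$status != "inversion_candidate") {
    return(tibble(
      label_expected = expected_label, label_called = "none",
      label_match = FALSE, prox_offset = NA_integer_,
      dist_offset = NA_integer_, n_dups_true = nrow(truth$duplications),
      n_dups_exact = 0L, dups_exact = FALSE,
      micro_span_error = NA_integer_, dd7_error = NA_integer_,
      bir_flag_true = isTRUE(truth$filler_planted), bir_flag_called = FALSE
    ))
  }
  jt <- inference$segment_map$junctions
  tb <- truth$breakpoints
  off <- function(junction) {
    tpos <- tb$pos[tb$assembly == "inverted" & tb$junction == junction]
    row <- jt[jt$junction == paste0("inv_", junction), ]
    if (!row$resolved) return(NA_integer_)
    as.integer(max(0L, max(row$lo - tpos, tpos - row$hi)))
  }
  d <- inference$architecture$duplications
  td <- truth$duplications
  n_exact <- 0L
  if (nrow(td)) {
    for (i in seq_len(nrow(td))) {
      if (nrow(d) == 0L) break
      hit <- abs(d$a_start - td$a_start[[i]]) <= match_tol &
        abs(d$a_end - td$a_end[[i]]) <= match_tol &
        abs(d$b_start - td$b_start[[i]]) <= match_tol &
        abs(d$b_end - td$b_end[[i]]) <= match_tol &
        d$orientation == td$orientation[[i]]
      exact <- d$a_start == td$a_start[[i]] & d$a_end == td$a_end[[i]] &
        d$b_start == td$b_start[[i]] & d$b_end == td$b_end[[i]] &
        d$orientation == td$orientation[[i]]
      if (any(exact)) n_exact <- n_exact + 1L
    }
  }
  micro_err <- if (!is.null(truth$microinversion)) {
    called <- inference$architecture$microinversion
    if (is.null(called)) NA_integer_ else {
      span_t <- truth$microinversion$end - truth$microinversion$start
      as.integer(min(abs(called$span - span_t)))
    }
  } else NA_integer_
  dd7_err <- if (!is.null(truth$central_deletion)) {
    cd <- inference$architecture$central_deletion
    len_t <- truth$central_deletion$end - truth$central_deletion$start
    if (is.null(cd)) NA_integer_ else
      as.integer(abs((cd$end - cd$start) - len_t))
  } else NA_integer_
  tibble(
    label_expected = expected_label,
    label_called = inference$call$label,
    label_match = identical(inference$call$label, expected_label),
    prox_offset = off("prox"), dist_offset = off("dist"),
    n_dups_true = nrow(td), n_dups_exact = n_exact,
    dups_exact = n_exact == nrow(td),
    micro_span_error = micro_err, dd7_error = dd7_err,
    bir_flag_true = isTRUE(truth$filler_planted),
    bir_flag_called = isTRUE(inference$call$bir_mmbir_flag)
  )
}
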