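# Mechanism classification from junction-architecture evidence.
#
# Decision table, applied per breakpoint and then combined:
#   duplications present in both states            -> NAHR
#   no duplications + clean junctions              -> NHEJ cut-and-paste
#   inverted duplications in the inverted state
#   only                                           -> NHEJ staggered
#     (isochromatid and chromatid variants are indistinguishable by the
#      duplication pattern and are never reported as distinct labels)
#   mosaic spacer + central deletion               -> chromosome model
#   microhomology filler                           -> BIR/MMBIR-compatible
#                                                     flag (never the sole
#                                                     label)
# Conflicting per-breakpoint calls yield a composite label.

#' Classify the inversion-formation mechanism
#'
#' @param architecture A [reconstruct_architecture()] result.
#' @param nonb_hits Optional tibble of non-B motif hits on the inverted
#'   assembly ([find_inverted_repeats()] and friends); used only to set the
#'   `nonb_at_breaks` evidence feature.
#' @param junction_window Distance (bp) within which a duplication copy
#'   counts as junction-associated.
#' @return An object of class `"mechanism_call"`: `label`, per-breakpoint
#'   calls, `bir_mmbir_flag`, a named `evidence` vector, and notes.
#' @export
classify_mechanism <- function(architecture, nonb_hits = NULL,
                               junction_window = 4000L) {
  a <- architecture
  jt <- a$junctions
  if (is.null(jt) || !any(jt$resolved)) {
    return(new_mechanism_call("UNRESOLVED", "UNRESOLVED", "UNRESOLVED",
                              FALSE, evidence = NULL,
                              note = "no resolved junctions"))
  }
  inv_j <- jt[jt$junction %in% c("inv_prox", "inv_dist"), ]
  zones <- stats::setNames(
    lapply(seq_len(nrow(inv_j)), function(i) c(inv_j$lo[[i]], inv_j$hi[[i]])),
    inv_j$junction
  )
  d <- a$duplications
  within_w <- function(zone, s, e) {
    pmin(e, zone[2] + junction_window) - pmax(s, zone[1] - junction_window) > 0
  }
  touches <- function(s, e, lo, hi) pmin(e, hi + 2L) - pmax(s, lo - 2L) > 0
  if (is.null(d)) d <- tibble(a_start = integer(0))
  if (nrow(d)) {
    a_p <- within_w(zones$inv_prox, d$a_start, d$a_end)
    a_d <- within_w(zones$inv_dist, d$a_start, d$a_end)
    b_p <- within_w(zones$inv_prox, d$b_start, d$b_end)
    b_d <- within_w(zones$inv_dist, d$b_start, d$b_end)
    spanning <- (a_p & b_d) | (a_d & b_p)
    # a direct pair whose upstream copy begins at the proximal junction
    # (the -C start) and whose downstream copy sits at the distal junction
    # is the two-haplotype spacer/inverted-repeat structure of an in-trans
    # junction, already explained by the mosaic - not a breakage footprint
    if (isTRUE(a$mosaic$called)) {
      zp <- zones$inv_prox; zd <- zones$inv_dist
      mosaic_explained <- d$orientation == "direct" &
        d$a_start >= zp[1] - 50L & d$a_start <= zp[2] + 200L &
        pmin(d$b_end, zd[2] + 2000L) - pmax(d$b_start, zd[1] - 2000L) > 0
      spanning <- spanning & !mosaic_explained
      a_p <- a_p & !mosaic_explained
      b_p <- b_p & !mosaic_explained
      a_d <- a_d & !mosaic_explained
      b_d <- b_d & !mosaic_explained
    }
    # junction-associated local pairs: a copy touches the junction zone or
    # an unassigned interval; pairs wholly interior to a segment are
    # pre-existing repeats, not breakage footprints
    assoc <- rep(FALSE, nrow(d))
    for (z in zones) {
      assoc <- assoc | touches(d$a_start, d$a_end, z[1], z[2]) |
        touches(d$b_start, d$b_end, z[1], z[2])
    }
    if (nrow(a$unassigned)) {
      for (i in seq_len(nrow(a$unassigned))) {
        u <- a$unassigned[i, ]
        assoc <- assoc | touches(d$a_start, d$a_end, u$start, u$end) |
          touches(d$b_start, d$b_end, u$start, u$end)
      }
    }
  } else {
    spanning <- assoc <- logical(0)
  }

  per_break <- function(which_j) {
    zone <- zones[[which_j]]
    resolved <- jt$resolved[jt$junction == which_j][[1]]
    if (!resolved) return("UNRESOLVED")
    mosaic_here <- which_j == "inv_dist" && isTRUE(a$mosaic$called) &&
      !is.null(a$central_deletion)
    if (mosaic_here) return("CHROMOSOME_MODEL")
    here <- if (nrow(d)) {
      (if (which_j == "inv_prox") a_p | b_p else a_d | b_d)
    } else logical(0)
    sp <- nrow(d) && any(spanning & here)
    if (sp && any(d$present_in[spanning & here] == "both_states")) {
      return("NAHR")
    }
    footprint <- nrow(d) && any(here & (spanning | assoc) &
                                  d$present_in == "inverted_only")
    inv_foot <- nrow(d) && any(here & (spanning | assoc) &
                                 d$orientation == "inverted" &
                                 d$present_in == "inverted_only")
    if (inv_foot) return("NHEJ_STAGGERED")
    una_here <- nrow(a$unassigned) &&
      any(touches(a$unassigned$start, a$unassigned$end,
                  zone[1] - junction_window, zone[2] + junction_window))
    clean <- jt$is_point[jt$junction == which_j][[1]] && !una_here
    if (!footprint && clean) return("NHEJ_CUT_AND_PASTE")
    if (footprint) return("NHEJ_STAGGERED")
    "UNRESOLVED"
  }

  prox <- per_break("inv_prox")
  dist <- per_break("inv_dist")
  bir_flag <- !is.null(a$microhomology) && a$microhomology$length >= 4L

  label <- if (prox == dist) prox else if (
    all(c(prox, dist) %in% c("NHEJ_STAGGERED", "NHEJ_CUT_AND_PASTE"))) {
    "NHEJ_STAGGERED"
  } else if ("UNRESOLVED" %in% c(prox, dist)) {
    setdiff(c(prox, dist), "UNRESOLVED")[[1]]
  } else if ("CHROMOSOME_MODEL" %in% c(prox, dist) &&
             "NHEJ_CUT_AND_PASTE" %in% c(prox, dist)) {
    # a clean break on one side does not contradict in-trans repair
    "CHROMOSOME_MODEL"
  } else {
    paste(prox, dist, sep = "+")
  }

  nonb_at_breaks <- FALSE
  if (!is.null(nonb_hits) && nrow(nonb_hits)) {
    for (zone in zones) {
      nonb_at_breaks <- nonb_at_breaks ||
        any(nonb_hits$end > zone[1] - 500L & nonb_hits$start < zone[2] + 500L)
    }
  }

  evidence <- c(
    dups_both_states = nrow(d) > 0L &&
      any(spanning & d$present_in == "both_states"),
    inverted_dups_inverted_only = nrow(d) > 0L &&
      any((spanning | assoc) & d$orientation == "inverted" &
            d$present_in == "inverted_only"),
    clean_junctions = all(jt$is_point) && nrow(a$unassigned) == 0L,
    mosaic_spacer = isTRUE(a$mosaic$called),
    central_deletion = !is.null(a$central_deletion),
    microhomology_filler = bir_flag,
    multibreak = !is.null(a$microinversion),
    nonb_at_breaks = nonb_at_breaks
  )

  note <- character(0)
  if (grepl("NHEJ_STAGGERED", label)) {
    note <- c(note, "isochromatid and chromatid staggered models are indistinguishable by the duplication pattern")
  }
  if (bir_flag) {
    note <- c(note, "junction filler with microhomology: BIR/MMBIR-compatible")
  }
  new_mechanism_call(label, prox, dist, bir_flag, evidence,
                     paste(note, collapse = "; "))
}

new_mechanism_call <- function(label, prox, dist, bir_flag, evidence, note) {
  structure(list(
    label = label, proximal = prox, distal = dist,
    bir_mmbir_flag = bir_flag, evidence = evidence, note = note
  ), class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s%s\n", x$label,
              if (x$bir_mmbir_flag) " [BIR/MMBIR-compatible]" else ""))
  cat(sprintf("  proximal: %s | distal: %s\n", x$proximal, x$distal))
  if (length(x$evidence)) {
    on <- names(x$evidence)[x$evidence]
    cat(sprintf("  evidence: %s\n",
                if (length(on)) paste(on, collapse = ", ") else "none"))
  }
  if (nzchar(x$note)) cat(sprintf("  note: %s\n", x$note))
  invisible(x)
}

#' Tidy a mechanism call into its evidence-feature table
#'
#' @param x A `"mechanism_call"`.
#' @param ... Unused.
#' @return Tibble of `feature`, `value` rows (one per evidence feature).
#' @method tidy mechanism_call
#' @export
tidy.mechanism_call <- function(x, ...) {
  if (is.null(x$evidence)) {
    return(tibble(feature = character(), value = logical()))
  }
  tibble(feature = names(x$evidence), value = unname(x$evidence))
}

#' One-row summary of a mechanism call
#'
#' @param x A `"mechanism_call"`.
#' @param ... Unused.
#' @return One-row tibble with `label`, per-breakpoint calls and the
#'   BIR/MMBIR flag.
#' @method glance mechanism_call
#' @export
glance.mechanism_call <- function(x, ...) {
  tibble(label = x$label, proximal = x$proximal, distal = x$distal,
         bir_mmbir_flag = x$bir_mmbir_flag)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
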