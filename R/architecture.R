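# Reconstruction of junction architecture: duplication pairs, the nested
# microinversion, spacer-haplotype mosaicism with its central deletion, and
# filler DNA with microhomology.

#' Call duplication pairs around the breakpoint junctions
#'
#' Scans windows around the two inverted-assembly junctions against each
#' other and against themselves for ungapped homology matches in both
#' orientations; every pair of non-overlapping copies matching at
#' `min_identity` over at least `min_len` bp is reported. `present_in` is
#' decided by counting occurrences of the copy (both orientations, allowing
#' for line divergence) in the uninverted assemblies: two or more copies
#' there means the duplication predates the inversion (`both_states`),
#' otherwise it exists in the inverted state only.
#'
#' @param seqs Labeled-sequence tibble with the assemblies.
#' @param map A [second_pass_homology()]-annotated (or plain)
#'   [demarcate_segments()] result.
#' @param min_len,min_identity Reporting thresholds; identity is computed
#'   excluding gap columns (matches the excluding-indels convention).
#' @param window Half-width (bp) of the junction neighborhoods scanned.
#' @param uninv_ids Uninverted assemblies used for the `present_in` search.
#' @return Tibble of duplication pairs: `a_start`, `a_end`, `b_start`,
#'   `b_end` (inverted-assembly coordinates, copy A leftmost),
#'   `orientation` (`direct`/`inverted`), `length`, `identity`,
#'   `present_in`.
#' @export
call_duplications <- function(seqs, map, min_len = 20L, min_identity = 0.85,
                              window = 4000L,
                              uninv_ids = c("uninverted_1", "uninverted_2")) {
  inv <- seqs$seq[seqs$id == map$inv_id][[1]]
  n <- nchar(inv)
  j <- map$junctions
  zones <- j[j$assembly == map$inv_id, ]
  wins <- unique(lapply(seq_len(nrow(zones)), function(i) {
    clip0(c(zones$lo[[i]] - window, zones$hi[[i]] + window), 0L, n)
  }))
  # merge overlapping windows
  wins <- wins[order(vapply(wins, `[`, integer(1), 1L))]
  merged <- list()
  for (w in wins) {
    if (length(merged) && w[1] <= merged[[length(merged)]][2]) {
      merged[[length(merged)]][2] <- max(merged[[length(merged)]][2], w[2])
    } else merged[[length(merged) + 1L]] <- w
  }
  pairs <- list()
  for (i in seq_along(merged)) {
    for (jj in seq(i, length(merged))) {
      wi <- merged[[i]]; wj <- merged[[jj]]
      hits <- find_local_matches(sub0s(inv, wi[1], wi[2]),
                                 sub0s(inv, wj[1], wj[2]),
                                 min_len = min_len,
                                 min_identity = min_identity,
                                 self = i == jj)
      if (nrow(hits) == 0L) next
      hits$q_start <- hits$q_start + wi[1]; hits$q_end <- hits$q_end + wi[1]
      hits$t_start <- hits$t_start + wj[1]; hits$t_end <- hits$t_end + wj[1]
      pairs[[length(pairs) + 1L]] <- hits
    }
  }
  empty <- tibble(a_start = integer(), a_end = integer(),
                  b_start = integer(), b_end = integer(),
                  orientation = character(), length = integer(),
                  identity = double(), present_in = character())
  if (!length(pairs)) return(empty)
  hits <- dplyr::bind_rows(pairs)
  # canonical order: copy A leftmost; drop self-identical and overlapping
  a_first <- hits$q_start <= hits$t_start
  res <- tibble(
    a_start = ifelse(a_first, hits$q_start, hits$t_start),
    a_end = ifelse(a_first, hits$q_end, hits$t_end),
    b_start = ifelse(a_first, hits$t_start, hits$q_start),
    b_end = ifelse(a_first, hits$t_end, hits$q_end),
    orientation = ifelse(hits$orientation == "+", "direct", "inverted"),
    length = hits$length, identity = hits$identity
  ) |>
    dplyr::filter(.data$b_start >= .data$a_end) |> # copies must not overlap
    dplyr::distinct(.data$a_start, .data$a_end, .data$b_start, .data$b_end,
                    .data$orientation, .keep_all = TRUE) |>
    dplyr::arrange(.data$a_start, .data$b_start)
  if (nrow(res) == 0L) return(empty)
  # prune pairs dominated by a longer pair covering (almost) the same
  # copies - shifted re-detections inside tandem or low-complexity runs
  tol <- 10L
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    dom <- res$a_start <= res$a_start[[i]] + tol &
      res$a_end >= res$a_end[[i]] - tol &
      res$b_start <= res$b_start[[i]] + tol &
      res$b_end >= res$b_end[[i]] - tol &
      res$length > res$length[[i]]
    if (any(dom & keep)) keep[i] <- FALSE
  }
  res <- res[keep, ]
  probe_len <- 80L
  res$present_in <- vapply(seq_len(nrow(res)), function(i) {
    len <- min(res$a_end[[i]] - res$a_start[[i]], probe_len)
    probe <- Biostrings::DNAString(sub0s(inv, res$a_start[[i]],
                                         res$a_start[[i]] + len))
    mm <- ceiling(0.05 * len) + 1L
    total <- 0L
    for (uid in intersect(uninv_ids, seqs$id)) {
      subj <- Biostrings::DNAString(seqs$seq[seqs$id == uid][[1]])
      cnt <- Biostrings::countPattern(probe, subj, max.mismatch = mm) +
        Biostrings::countPattern(Biostrings::reverseComplement(probe), subj,
                                 max.mismatch = mm)
      total <- max(total, cnt)
    }
    if (total >= 2L) "both_states" else "inverted_only"
  }, character(1))
  res
}

#' Call a nested microinversion from the duplication layout
#'
#' The staggered-break layout nests a short inversion at the proximal
#' junction: an inverted duplication pair (d1-like) whose copies bracket
#' one copy of a second pair (d2-like) whose partner lies outside. When
#' that layout is present the microinversion spans from the first base of
#' the upstream d1 copy to the last base of the downstream d1 copy
#' (fill-in copies inclusive). Conflicting layouts are all returned with a
#' warning flag; none is auto-selected.
#'
#' @param duplications Tibble from [call_duplications()].
#' @param map The segment map (used only for context checks).
#' @param max_span Maximum credible microinversion span in bp.
#' @param partner_min_len Minimum length (bp) of the partner (d2-like)
#'   duplication whose single inside copy certifies the layout; fill-in
#'   copies of a staggered overhang run to hundreds of bp, which separates
#'   them from low-complexity repeat noise.
#' @return `NULL` when no layout is found; otherwise a tibble with
#'   `start`, `end`, `span` and `ambiguous` (TRUE on conflicting layouts).
#' @export
call_microinversion <- function(duplications, map = NULL, max_span = 5000L,
                                partner_min_len = 100L) {
  d <- duplications
  if (is.null(d) || nrow(d) == 0L) return(NULL)
  inv_pairs <- d[d$orientation == "inverted" &
                   (d$b_end - d$a_start) <= max_span, ]
  if (nrow(inv_pairs) == 0L) return(NULL)
  rows <- list()
  for (i in seq_len(nrow(inv_pairs))) {
    p <- inv_pairs[i, ]
    big <- d$length >= partner_min_len
    inside_a <- d$a_start >= p$a_end & d$a_end <= p$b_start & big
    inside_b <- d$b_start >= p$a_end & d$b_end <= p$b_start & big
    # exactly one copy of some other (large) pair inside the bracket
    partner <- which(xor(inside_a, inside_b))
    partner <- setdiff(partner, i)
    if (length(partner)) {
      rows[[length(rows) + 1L]] <- tibble(
        start = p$a_start, end = p$b_end, span = p$b_end - p$a_start
      )
    }
  }
  if (!length(rows)) return(NULL)
  res <- dplyr::distinct(dplyr::bind_rows(rows))
  res$ambiguous <- nrow(res) > 1L
  if (res$ambiguous[[1]]) {
    warn("conflicting microinversion layouts; all candidates returned")
  }
  res
}

#' Phase a mosaic spacer against the uninverted haplotypes
#'
#' Each half of the inverted-state spacer is assigned to the uninverted
#' line it matches best (identity excluding indels). A mosaic is called
#' when the two halves assign to different lines with an identity gap of at
#' least `min_gap` (fraction) in both halves; the unmatched central residue
#' of the lines is reported as the central deletion.
#'
#' @param inv_spacer Reconstructed spacer region of the inverted assembly
#'   (junction-centered, in +C|+D orientation).
#' @param uninv_spacers Named character vector/list of the corresponding
#'   regions from two or more uninverted lines, in the same frame.
#' @param min_gap Identity-gap threshold (default 0.20, i.e. 20 points).
#' @param half_window Width (bp) adjacent to the switch point over which
#'   half identities are computed (the spacer-half scale).
#' @return A list: `called`, `halves` (tibble of half, line, identity,
#'   other identity), `split` (0-based switch zone in `inv_spacer`),
#'   `filler` (central sequence matching neither line, possibly empty),
#'   `deletion_len` (estimated central deletion, bp), `note`.
#' @export
phase_spacer_mosaic <- function(inv_spacer, uninv_spacers, min_gap = 0.20,
                                half_window = 150L) {
  if (length(uninv_spacers) < 2L) {
    return(list(called = FALSE, halves = NULL, split = NULL, filler = NULL,
                deletion_len = NA_integer_,
                note = "insufficient haplotypes"))
  }
  u <- as.list(uninv_spacers)[1:2]
  nms <- names(u) %||% c("line1", "line2")
  if (is.null(names(u))) names(u) <- nms
  lj <- locate_junction(inv_spacer, u[[1]], u[[2]])
  n <- nchar(inv_spacer)
  prof <- list(match_profile(inv_spacer, u[[1]], n)$profile,
               match_profile(inv_spacer, u[[2]], n)$profile)
  id_over <- function(p, a, b) {
    v <- p[(a + 1L):b]
    if (!sum(!is.na(v))) return(0)
    sum(v, na.rm = TRUE) / max(1L, b - a)
  }
  j1 <- lj$zone[1]; j2 <- lj$zone[2]
  up <- c(max(0L, j1 - half_window), j1)
  dn <- c(j2, min(n, j2 + half_window))
  if (up[2] - up[1] < 20L || dn[2] - dn[1] < 20L) {
    return(list(called = FALSE, halves = NULL, split = lj$zone, filler = NULL,
                deletion_len = NA_integer_, note = "switch at region edge"))
  }
  up_id <- vapply(prof, id_over, numeric(1), up[1], up[2])
  dn_id <- vapply(prof, id_over, numeric(1), dn[1], dn[2])
  up_line <- which.max(up_id); dn_line <- which.max(dn_id)
  halves <- tibble(
    half = c("upstream", "downstream"),
    line = c(names(u)[up_line], names(u)[dn_line]),
    identity = c(up_id[up_line], dn_id[dn_line]),
    other_identity = c(min(up_id), min(dn_id))
  )
  called <- lj$resolved && up_line != dn_line &&
    (up_id[up_line] - up_id[-up_line] >= min_gap) &&
    (dn_id[dn_line] - dn_id[-dn_line] >= min_gap)
  deletion_len <- if (!is.na(lj$f1_end) && !is.na(lj$f2_start)) {
    as.integer(lj$f2_start - lj$f1_end)
  } else NA_integer_
  filler <- if (j2 > j1) sub0s(inv_spacer, j1, j2) else ""
  list(called = called, halves = halves, split = c(j1, j2), filler = filler,
       deletion_len = deletion_len, deletion_at = lj$f1_end,
       flank_d = sub0s(inv_spacer, j2, min(n, j2 + 50L)),
       note = if (called) "mosaic" else "no mosaic")
}

#' Detect filler microhomology against the +D flank
#'
#' Finds the longest substring of the junction gap that aligns, without
#' gaps and with at most `max_mismatch` mismatches, to a window anchored at
#' the start of the downstream (+D) flank; this is the footprint expected
#' of microhomology-templated repair.
#'
#' @param junction_gap Junction gap sequence (assigned to neither flank).
#' @param flank_d Downstream flank, at least 8 bp.
#' @param max_mismatch Maximum mismatches tolerated.
#' @param min_len Minimum reportable match length (bp).
#' @return `NULL` when the gap is empty or the best match is shorter than
#'   `min_len`; otherwise a list with `length`, `mismatches`, `gap_offset`
#'   (0-based offset of the match in the gap), `gap_substring` and
#'   `flank_window`.
#' @export
find_filler_microhomology <- function(junction_gap, flank_d,
                                      max_mismatch = 1L, min_len = 4L) {
  gap <- toupper(junction_gap)
  fl <- toupper(flank_d)
  if (!nzchar(gap)) return(NULL)
  if (nchar(fl) < 8L) abort("flank_d must be at least 8 bp")
  gv <- strsplit(gap, "")[[1]]
  fv <- strsplit(fl, "")[[1]]
  for (L in seq(min(length(gv), length(fv)), min_len)) {
    win <- fv[seq_len(L)]
    best_mm <- Inf; best_i <- NA_integer_
    for (i in 0:(length(gv) - L)) {
      mm <- sum(gv[(i + 1):(i + L)] != win | win == "N")
      if (mm < best_mm) { best_mm <- mm; best_i <- i }
    }
    if (best_mm <= max_mismatch) {
      return(list(length = L, mismatches = as.integer(best_mm),
                  gap_offset = best_i,
                  gap_substring = substr(gap, best_i + 1L, best_i + L),
                  flank_window = substr(fl, 1L, L)))
    }
  }
  NULL
}

#' Reconstruct the full junction architecture
#'
#' Orchestrates the architecture calls on a demarcated candidate:
#' duplication pairs, microinversion, spacer mosaic with central deletion
#' (phased against both uninverted lines when available), and junction
#' filler with microhomology against the +D flank.
#'
#' @param seqs Labeled-sequence tibble with the four assemblies.
#' @param map A [demarcate_segments()] result (the second homology pass is
#'   run here if absent).
#' @param uninv_ids Uninverted assembly ids, in phasing order.
#' @param min_len,min_identity Duplication-call thresholds.
#' @param spacer_window Half-width (bp) of the reconstructed spacer region
#'   used for mosaic phasing.
#' @return An object of class `"junction_architecture"`.
#' @export
reconstruct_architecture <- function(seqs, map,
                                     uninv_ids = c("uninverted_1",
                                                   "uninverted_2"),
                                     min_len = 20L, min_identity = 0.85,
                                     spacer_window = 600L) {
  if (is.null(map$homologies)) map <- second_pass_homology(map, seqs)
  inv <- seqs$seq[seqs$id == map$inv_id][[1]]
  n <- nchar(inv)
  dups <- call_duplications(seqs, map, min_len = min_len,
                            min_identity = min_identity,
                            uninv_ids = uninv_ids)
  micro <- call_microinversion(dups, map)

  jt <- map$junctions
  zp_hi <- jt$hi[jt$junction == "inv_prox"][[1]]
  zd <- c(jt$lo[jt$junction == "inv_dist"][[1]],
          jt$hi[jt$junction == "inv_dist"][[1]])
  cd <- jt$pos[jt$junction == "uninv_dist"][[1]]

  mosaic <- list(called = FALSE, note = "not attempted",
                 deletion_len = NA_integer_, filler = NULL, halves = NULL)
  central_deletion <- NULL
  have_lines <- intersect(uninv_ids, seqs$id)
  if (!is.na(cd) && !is.na(zp_hi) && length(have_lines) >= 1L) {
    w <- spacer_window
    s_rec <- paste0(
      revcomp(sub0s(inv, zp_hi, min(n, zp_hi + w))),
      sub0s(inv, zd[1], min(n, zd[2] + w))
    )
    slack <- 200L
    uwin_lo <- max(0L, cd - w - slack)
    uwin_hi <- cd + w + slack
    uspacers <- lapply(have_lines, function(uid) {
      us <- seqs$seq[seqs$id == uid][[1]]
      sub0s(us, uwin_lo, min(nchar(us), uwin_hi))
    })
    names(uspacers) <- have_lines
    mosaic <- phase_spacer_mosaic(s_rec, uspacers)
    if (isTRUE(mosaic$called) && !is.na(mosaic$deletion_len) &&
        mosaic$deletion_len > 0L) {
      del_at <- uwin_lo + mosaic$deletion_at
      central_deletion <- interval(have_lines[[1]], del_at,
                                   del_at + mosaic$deletion_len, "+", "dd7")
    }
  }

  # filler: central unassigned of the mosaic when phased, else a short
  # distal unassigned interval from demarcation
  filler <- NULL
  filler_from <- NULL
  if (isTRUE(mosaic$called) && !is.null(mosaic$filler) &&
      nzchar(mosaic$filler %||% "") && nchar(mosaic$filler) <= 100L) {
    filler <- mosaic$filler
    filler_from <- "mosaic"
  } else {
    ud <- map$unassigned[map$unassigned$name == "unassigned_dist", ]
    if (nrow(ud) == 1L && nchar(ud$seq[[1]]) <= 60L) {
      filler <- ud$seq[[1]]
      filler_from <- "demarcation"
    }
  }
  microhomology <- NULL
  if (!is.null(filler) && nzchar(filler)) {
    # +D begins immediately downstream of the filler: inside the
    # reconstructed spacer frame when the mosaic was phased, otherwise
    # right after the distal junction zone on the inverted assembly.
    # The filler/flank split is scanned over a few bp because a chance
    # match at the boundary can shift it by a base or two.
    context <- if (identical(filler_from, "mosaic")) {
      paste0(filler, mosaic$flank_d)
    } else {
      paste0(filler, sub0s(inv, zd[2], min(n, zd[2] + 50L)))
    }
    nf <- nchar(filler)
    best <- NULL; best_o <- 0L
    for (o in -3:3) {
      cut <- nf + o
      if (cut < 4L || cut > nchar(context) - 8L) next
      mh_o <- find_filler_microhomology(substr(context, 1L, cut),
                                        substr(context, cut + 1L,
                                               nchar(context)))
      if (!is.null(mh_o) &&
          (is.null(best) || mh_o$length > best$length ||
             (mh_o$length == best$length && abs(o) < abs(best_o)))) {
        best <- mh_o; best_o <- o
      }
    }
    microhomology <- best
    if (!is.null(best) && best_o != 0L) {
      filler <- substr(context, 1L, nf + best_o)
    }
  }

  structure(list(
    duplications = dups,
    microinversion = micro,
    mosaic = mosaic,
    central_deletion = central_deletion,
    filler = filler,
    filler_from = filler_from,
    microhomology = microhomology,
    unassigned = map$unassigned,
    junctions = map$junctions
  ), class = "junction_architecture")
}

#' @export
print.junction_architecture <- function(x, ...) {
  cat("<junction_architecture>\n")
  cat(sprintf("  duplication pairs: %d\n", nrow(x$duplications)))
  if (!is.null(x$microinversion)) {
    cat(sprintf("  microinversion span: %d bp\n", x$microinversion$span[[1]]))
  }
  cat(sprintf("  mosaic spacer: %s\n",
              if (isTRUE(x$mosaic$called)) "called" else "absent"))
  if (!is.null(x$central_deletion)) {
    cat(sprintf("  central deletion: %d bp\n",
                x$central_deletion$end - x$central_deletion$start))
  }
  if (!is.null(x$filler)) {
    cat(sprintf("  filler: %d nt inserted at the distal junction\n",
                nchar(x$filler)))
  }
  if (!is.null(x$microhomology)) {
    cat(sprintf("  microhomology: %d bp, %d mismatch(es)\n",
                x$microhomology$length, x$microhomology$mismatches))
  }
  invisible(x)
}
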