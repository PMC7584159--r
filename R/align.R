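# Pairwise alignment surface. The dynamic programming itself is delegated
# to Biostrings::pairwiseAlignment; this module fixes the scoring
# conventions (N scores as a mismatch), converts alignments into per-column
# tracks in 0-based coordinates, and provides the change-point machinery
# used to localize breakpoint junctions at base-pair resolution.

dna_submat <- function(match = 1, mismatch = -1) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", "N"] <- mismatch # N never matches, even itself
  m
}

#' Globally or locally align two DNA sequences
#'
#' Affine-gap alignment with explicit scoring; deterministic for fixed
#' scoring. `N` scores as a mismatch against every base including itself.
#'
#' @param x,y DNA strings (or single-row labeled-sequence tibbles).
#' @param match,mismatch Per-column scores.
#' @param gap_open,gap_extend Gap penalties (negative values); the first
#'   base of a gap costs `gap_open + gap_extend`.
#' @param type `"global"`, `"local"`, or `"overlap"`.
#' @return An object of class `"alignment_track"`: a list with `columns`
#'   (tibble of `col`, `x_pos`, `y_pos` 0-based or `NA` in gaps, and
#'   `state` among match/mismatch/gap_x/gap_y), `score`, `type`, and the
#'   0-based half-open aligned ranges `x_range`, `y_range`.
#' @export
align_pair <- function(x, y, match = 1, mismatch = -1,
                       gap_open = -4, gap_extend = -0.5, type = "global") {
  x <- as_seq_string(x); y <- as_seq_string(y)
  if (nchar(x) > 200000L || nchar(y) > 200000L) {
    abort("sequences exceed 200 kb; narrow the candidate region first")
  }
  if (!nzchar(x) || !nzchar(y)) abort("cannot align empty sequences")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(x), Biostrings::DNAString(y),
    substitutionMatrix = dna_submat(match, mismatch),
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend),
    type = type
  )
  ax <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ay <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gx <- ax == "-"
  gy <- ay == "-"
  x0 <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  y0 <- Biostrings::start(Biostrings::subject(aln)) - 1L
  x_pos <- ifelse(gx, NA_integer_, x0 + cumsum(!gx) - 1L)
  y_pos <- ifelse(gy, NA_integer_, y0 + cumsum(!gy) - 1L)
  state <- dplyr::case_when(
    gx ~ "gap_x",
    gy ~ "gap_y",
    ax == ay & ax != "N" ~ "match",
    TRUE ~ "mismatch"
  )
  structure(list(
    columns = tibble(col = seq_along(ax), x_pos = as.integer(x_pos),
                     y_pos = as.integer(y_pos), state = state),
    score = Biostrings::score(aln), type = type,
    x_range = c(x0, x0 + sum(!gx)), y_range = c(y0, y0 + sum(!gy))
  ), class = "alignment_track")
}

#' @export
print.alignment_track <- function(x, ...) {
  tab <- table(x$columns$state)
  cat(sprintf(
    "<alignment_track> %s, score %.1f, %d columns (%s)\n",
    x$type, x$score, nrow(x$columns),
    paste(sprintf("%s %d", names(tab), tab), collapse = ", ")
  ))
  invisible(x)
}

#' Sliding-window identity along an alignment track
#'
#' @param track An [align_pair()] result.
#' @param window Window width in alignment columns.
#' @return Tibble of `col` (window center) and `identity` (matches over
#'   window columns; gap columns count as non-identity).
#' @export
window_identity <- function(track, window = 11L) {
  m <- as.numeric(track$columns$state == "match")
  w <- stats::filter(m, rep(1 / window, window), sides = 2)
  tibble(col = track$columns$col, identity = as.numeric(w))
}

# Per-position match profile of `s` (length n) against flank `f`: 1 match,
# 0 mismatch, NA outside homology. `ymap` carries the aligned flank
# coordinate per s position.
#
# Profiles are built from ungapped homology hits, accepted greedily
# (longest first) under a target-disjointness rule: a hit whose flank
# interval is already substantially explained by a longer hit is dropped.
# This enforces a one-to-one positional homology mapping, so a duplicate
# copy of a flank region inside s (a junction duplication) does not extend
# the flank's apparent homology past the junction; and because no gapped
# optimization is run over non-homologous stretches, junk never aligns at
# inflated identity. When the hits cover almost nothing (high divergence
# or dense indels), the best gapped local alignment is used as a fallback.
match_profile <- function(s, f, n = nchar(s)) {
  prof <- rep(NA_real_, n)
  ymap <- rep(NA_integer_, n)
  hits <- tryCatch(
    find_local_matches(s, f, k = 12L, min_len = 30L, min_identity = 0.85,
                       tolerate = 1L),
    error = function(e) NULL
  )
  covered <- 0L
  if (!is.null(hits) && nrow(hits)) {
    hits <- hits[hits$orientation == "+", ]
    hits <- hits[order(-hits$length), ]
    t_taken <- rep(FALSE, nchar(f))
    for (i in seq_len(nrow(hits))) {
      ts <- (hits$t_start[[i]] + 1L):hits$t_end[[i]]
      if (mean(t_taken[ts]) > 0.5) next
      t_taken[ts] <- TRUE
      # colinear overhang: raw per-position evidence a little beyond the
      # confirmed hit, so the change-point model can weigh the final bases
      # next to a junction even when a substitution sits among them
      over <- 25L
      # a chain merged across a small diagonal shift can have unequal
      # q/t spans; anchor at the start and walk the common length
      L <- min(hits$q_end[[i]] - hits$q_start[[i]],
               hits$t_end[[i]] - hits$t_start[[i]])
      xs <- (hits$q_start[[i]] - over):(hits$q_start[[i]] + L - 1L + over)
      ys <- (hits$t_start[[i]] - over):(hits$t_start[[i]] + L - 1L + over)
      ok <- xs >= 0L & ys >= 0L & xs < n & ys < nchar(f)
      xs <- xs[ok]; ys <- ys[ok]
      keep <- is.na(prof[xs + 1L])
      eq <- substring(s, xs + 1L, xs + 1L) == substring(f, ys + 1L, ys + 1L)
      prof[xs[keep] + 1L] <- as.numeric(eq[keep])
      ymap[xs[keep] + 1L] <- ys[keep]
      covered <- covered + sum(keep)
    }
  }
  tr <- NULL
  if (covered < 50L) {
    tr <- align_pair(s, f, type = "local")
    cols <- tr$columns[!is.na(tr$columns$x_pos), ]
    fill <- is.na(prof[cols$x_pos + 1L])
    prof[cols$x_pos[fill] + 1L] <- as.numeric(cols$state[fill] == "match")
    ok <- fill & !is.na(cols$y_pos)
    ymap[cols$x_pos[ok] + 1L] <- cols$y_pos[ok]
  }
  list(profile = prof, ymap = ymap, track = tr)
}

# flank coordinate corresponding to an x-position boundary of s, obtained
# by colinear extrapolation with the modal alignment offset of the covered
# positions adjacent to the boundary (robust to stray secondary hits)
flank_coord <- function(ymap, x_boundary, side, probe = 80L) {
  n <- length(ymap)
  if (side == "end") {
    xs <- which(!is.na(ymap) & seq_len(n) - 1L < x_boundary)
    if (!length(xs)) return(NA_integer_)
    xs <- utils::tail(sort(xs), probe) - 1L
  } else {
    xs <- which(!is.na(ymap) & seq_len(n) - 1L >= x_boundary)
    if (!length(xs)) return(NA_integer_)
    xs <- utils::head(sort(xs), probe) - 1L
  }
  offs <- ymap[xs + 1L] - xs
  off <- as.integer(names(sort(table(offs), decreasing = TRUE))[[1]])
  x_boundary + off
}

# log-likelihood ratio (homology vs background) per position
llr <- function(prof, p_hom = 0.95, p_bg = 0.25) {
  r <- rep(log((1 - p_hom) / (1 - p_bg)), length(prof)) # mismatch / NA
  r[!is.na(prof) & prof == 1] <- log(p_hom / p_bg)
  r
}

# Competitive change-point localization of a junction in `s` between
# homology to flank f1 (upstream) and flank f2 (downstream).
#
# Two-state model: one switch point; ties between equally likely switch
# points are broken leftmost, so a chance match to f1 just past the true
# junction does not displace it when f2 also matches there.  Three-state
# model: an interior segment homologous to neither flank (insertion or
# filler).  The three-state call is preferred only when it improves the
# log-likelihood by `delta`.
# Colinear boundary polish for an unassigned middle segment: anchored at a
# confident aligned pair well inside the flank homology, step base by base
# toward the junction, crossing an isolated substitution only when backed
# by a clean run. Being ungapped, the walk cannot absorb a
# microhomology-templated copy of the downstream flank into the flank
# itself (the copy is non-colinear with it).
polish_boundary <- function(mp, s, f, x_from, direction, look = 5L) {
  cand_x <- which(!is.na(mp$profile) & mp$profile == 1 &
                    !is.na(mp$ymap)) - 1L
  if (!length(cand_x)) return(NA_integer_)
  ns <- nchar(s); nf <- nchar(f)
  ok <- function(x, y) {
    x >= 0L && y >= 0L && x < ns && y < nf &&
      char_at(s, x) == char_at(f, y) && char_at(s, x) != "N"
  }
  # a substitution is crossed when most of the following run is clean;
  # 4-of-5 tolerates the occasional pair of nearby substitutions
  run_ok <- function(get_ok) sum(vapply(seq_len(look), get_ok, logical(1))) >= look - 1L
  if (direction == "left") {
    cand <- cand_x[cand_x >= x_from]
    if (!length(cand)) return(NA_integer_)
    xa <- min(cand); ya <- mp$ymap[[xa + 1L]]
    e <- 0L
    repeat {
      if (ok(xa - 1L - e, ya - 1L - e)) { e <- e + 1L; next }
      run <- run_ok(function(j) ok(xa - 1L - e - j, ya - 1L - e - j))
      if (run && xa - 1L - e >= 0L && ya - 1L - e >= 0L) e <- e + 1L else break
    }
    xa - e
  } else {
    cand <- cand_x[cand_x <= x_from]
    if (!length(cand)) return(NA_integer_)
    xa <- max(cand); ya <- mp$ymap[[xa + 1L]]
    e <- 0L
    repeat {
      if (ok(xa + 1L + e, ya + 1L + e)) { e <- e + 1L; next }
      run <- run_ok(function(j) ok(xa + 1L + e + j, ya + 1L + e + j))
      if (run && xa + 1L + e < ns && ya + 1L + e < nf) e <- e + 1L else break
    }
    xa + e + 1L
  }
}

locate_junction <- function(s, f1, f2, delta = 6, max_point_zone = 10L) {
  n <- nchar(s)
  mp1 <- match_profile(s, f1, n)
  mp2 <- match_profile(s, f2, n)
  r1 <- llr(mp1$profile)
  r2 <- llr(mp2$profile)
  P <- c(0, cumsum(r1))          # P[j+1] = sum of r1 over positions < j
  S <- rev(c(0, cumsum(rev(r2)))) # S[j+1] = sum of r2 over positions >= j
  # two-state: maximize P[j] + S[j], leftmost tie-break
  tot2 <- P + S
  j_point <- which.max(tot2) - 1L
  best2 <- tot2[[j_point + 1L]]
  # three-state: maximize P[j1] + S[j2], j1 <= j2
  prefmax <- cummax(P)
  tot3 <- prefmax + S
  j2 <- which.max(tot3) - 1L
  j1 <- which.max(P[seq_len(j2 + 1L)]) - 1L
  best3 <- tot3[[j2 + 1L]]
  # both flanks must show real homology support for a switch to be called
  resolved <- sum(mp1$profile == 1, na.rm = TRUE) >= 20 &&
    sum(mp2$profile == 1, na.rm = TRUE) >= 20
  if (resolved && best3 > best2 + delta && j2 > j1) {
    zone <- c(j1, j2)
    unassigned <- c(j1, j2)
  } else {
    zone <- c(j_point, j_point)
    unassigned <- NULL
  }
  list(
    zone = zone,
    width = zone[2] - zone[1],
    point = if (is.null(unassigned)) zone[1] else as.integer(floor(mean(zone))),
    is_point = is.null(unassigned) || (zone[2] - zone[1]) <= max_point_zone,
    unassigned = unassigned,
    resolved = resolved,
    f1_end = flank_coord(mp1$ymap, zone[1], "end"),
    f2_start = flank_coord(mp2$ymap, zone[2], "start"),
    track1 = mp1$track, track2 = mp2$track
  )
}
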