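# Scanners for non-B DNA-forming motifs: inverted repeats (hairpin and
# cruciform), mirror repeats (triplex), tandem/direct repeats (slipped
# structures), alternating purine-pyrimidine tracts (Z-DNA), G-quadruplex
# motifs, and A-phased repeats (static bending).
#
# All scanners return tibbles with 0-based half-open `start`/`end` and a
# `kind` column; columns not applicable to a kind are NA. Bases `N` never
# match anything.

seq_ints <- function(s) {
  chartr("ACGTN", "12345", toupper(s)) |>
    strsplit("") |> (\(x) as.integer(x[[1]]))()
}

# complement in integer coding (A1 C2 G3 T4 N5); N complements to N but
# never pairs
COMP_INT <- c(4L, 3L, 2L, 1L, 5L)

empty_motifs <- function() {
  tibble(kind = character(), start = integer(), end = integer(),
         arm_len = integer(), spacer_len = integer(), mismatches = integer(),
         period = integer(), copy_number = double(), consensus = character(),
         score = double())
}

motif_rows <- function(kind, start, end, arm_len = NA_integer_,
                       spacer_len = NA_integer_, mismatches = NA_integer_,
                       period = NA_integer_, copy_number = NA_real_,
                       consensus = NA_character_, score = NA_real_) {
  tibble(kind = kind, start = as.integer(start), end = as.integer(end),
         arm_len = as.integer(arm_len), spacer_len = as.integer(spacer_len),
         mismatches = as.integer(mismatches), period = as.integer(period),
         copy_number = copy_number, consensus = consensus, score = score)
}

# Shared enumeration engine for inverted (complemented) and mirror
# (reversed) repeats. Reports all maximal repeats: a repeat is non-maximal
# when the arms can be extended outward by one base (same spacer) or
# inward by one base (spacer shrinks by two - the same structure with a
# longer stem) without violating the mismatch bound, the arm cap, or the
# sequence bounds. Nested and overlapping repeats with distinct centers
# are all retained.
scan_paired_arms <- function(seq, arm_min, arm_max, max_spacer, max_mismatch,
                             complemented, kind) {
  x <- seq_ints(as_seq_string(seq))
  n <- length(x)
  if (n < 2L * arm_min) return(empty_motifs()) # nothing can satisfy arm_min
  partner <- if (complemented) COMP_INT[x] else x

  # mm vectors per (spacer, arm); only the arrays for sp and sp-2 are
  # needed at a time, so storage rotates over three spacer slots
  mm_arrays <- function(sp) {
    res <- vector("list", arm_max)
    mm_prev <- NULL
    for (a in 1:min(arm_max, (n - sp) %/% 2L)) {
      len <- n - 2L * a - sp + 1L
      if (len < 1L) break
      i <- seq_len(len)
      outer_mis <- as.integer(x[i] != partner[i + 2L * a + sp - 1L] |
                                x[i] == 5L | partner[i + 2L * a + sp - 1L] == 5L)
      mm <- if (is.null(mm_prev)) outer_mis else mm_prev[i + 1L] + outer_mis
      res[[a]] <- mm
      mm_prev <- mm
    }
    res
  }

  out <- list()
  cache <- list()
  for (sp in 0:max_spacer) {
    slot <- (sp %% 3L) + 1L
    cache[[slot]] <- mm_arrays(sp)
    M <- cache[[slot]]
    M_in <- if (sp >= 2L) cache[[((sp - 2L) %% 3L) + 1L]] else NULL
    for (a in arm_min:arm_max) {
      if (a > length(M) || is.null(M[[a]])) break
      mm <- M[[a]]
      hit <- which(mm <= max_mismatch)
      if (!length(hit)) next
      ext_ok <- rep(FALSE, length(hit))
      if (a < arm_max && !is.null(M[a + 1L][[1]])) {
        mo <- M[[a + 1L]]
        hi <- hit - 1L
        valid <- hi >= 1L & hi <= length(mo)
        ext_ok[valid] <- mo[hi[valid]] <= max_mismatch
      }
      if (a < arm_max && !is.null(M_in) && length(M_in) >= a + 1L &&
            !is.null(M_in[a + 1L][[1]])) {
        mi <- M_in[[a + 1L]]
        valid <- hit <= length(mi)
        ext_ok[valid] <- ext_ok[valid] | mi[hit[valid]] <= max_mismatch
      }
      keep <- hit[!ext_ok]
      if (length(keep)) {
        out[[length(out) + 1L]] <- motif_rows(
          kind, keep - 1L, keep - 1L + 2L * a + sp,
          arm_len = a, spacer_len = sp, mismatches = mm[keep]
        )
      }
    }
  }
  if (!length(out)) return(empty_motifs())
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$end)
}

#' Find inverted repeats (hairpin/cruciform-forming)
#'
#' Reports all maximal inverted repeats with arm length in `arm_range`,
#' spacer at most `max_spacer` and at most `max_mismatch` mismatched arm
#' pairs (defaults follow the standard palindrome-scan settings: arms
#' 6-20 nt, spacer <= 10 nt, <= 1 mismatch). Nested and overlapping
#' repeats are retained; a repeat is non-maximal only when its arms can be
#' extended outward without violating the bounds.
#'
#' @param seq DNA string or single-row labeled-sequence tibble.
#' @param arm_range Length-2 integer vector, minimum and maximum arm.
#' @param max_spacer Maximum spacer length (bp).
#' @param max_mismatch Maximum mismatched arm pairs.
#' @return Motif tibble (`kind = "IR"`) with 0-based `start`/`end`,
#'   `arm_len`, `spacer_len`, `mismatches`.
#' @export
#' @examples
#' find_inverted_repeats("ATGAACTAGTTCAT") # one perfect 14-bp palindrome
find_inverted_repeats <- function(seq, arm_range = c(6L, 20L),
                                  max_spacer = 10L, max_mismatch = 1L) {
  if (arm_range[1] < 4L) abort("minimum arm must be at least 4")
  scan_paired_arms(seq, arm_range[1], arm_range[2], max_spacer,
                   max_mismatch, complemented = TRUE, kind = "IR")
}

#' Find mirror repeats (triplex-forming)
#'
#' As [find_inverted_repeats()] but the downstream arm is the reverse (not
#' the reverse complement) of the upstream arm. The default spacer bound
#' is wider (50 nt), matching the scale of reported triplex-forming mirror
#' repeats.
#'
#' @inheritParams find_inverted_repeats
#' @return Motif tibble (`kind = "MIRROR"`).
#' @export
find_mirror_repeats <- function(seq, arm_range = c(6L, 20L),
                                max_spacer = 50L, max_mismatch = 1L) {
  if (arm_range[1] < 4L) abort("minimum arm must be at least 4")
  scan_paired_arms(seq, arm_range[1], arm_range[2], max_spacer,
                   max_mismatch, complemented = FALSE, kind = "MIRROR")
}

#' Cruciform-formation propensity of an inverted repeat
#'
#' Scores the propensity of an inverted repeat to extrude into a hairpin
#' or cruciform as the stability of the intrastrand arm duplex minus a
#' loop penalty for the spacer:
#' `score = sum over arm dinucleotide steps of -dG(step) -
#' (loop_init + loop_per_base * spacer_len)`, with nearest-neighbor
#' duplex free energies (37 C, kcal/mol) read from a packaged, documented
#' table. Higher scores mean higher propensity; mismatched arm pairs
#' contribute no stacking term. Only the rank order of scores is
#' comparable across tools, since published cruciform scorers use
#' unpublished parameter sets.
#'
#' @param ir One row of a motif tibble with `kind == "IR"`.
#' @param seq The sequence the motif was found on.
#' @param table Data frame of `step`, `dg` (kcal/mol); default the
#'   packaged nearest-neighbor table.
#' @param loop_init,loop_per_base Loop penalty parameters (kcal/mol).
#' @return Numeric propensity score.
#' @export
cruciform_dG <- function(ir, seq, table = nn_stacking_table(),
                         loop_init = 2.5, loop_per_base = 0.3) {
  stopifnot(nrow(ir) == 1L)
  if (!identical(ir$kind, "IR")) abort("cruciform_dG requires an IR motif")
  if (ir$arm_len < 1L) abort("zero-length arm")
  s <- as_seq_string(seq)
  arm <- substr(s, ir$start + 1L, ir$start + ir$arm_len)
  partner <- substr(s, ir$end - ir$arm_len + 1L, ir$end)
  # pairing state of each arm position (mismatches stack nothing)
  a1 <- strsplit(arm, "")[[1]]
  a2 <- rev(strsplit(chartr("ACGTN", "TGCAN", partner), "")[[1]])
  paired <- a1 == a2 & a1 != "N"
  dg <- stats::setNames(table$dg, table$step)
  total <- 0
  for (j in seq_len(ir$arm_len - 1L)) {
    if (paired[j] && paired[j + 1L]) {
      step <- paste0(a1[j], a1[j + 1L])
      total <- total + -unname(dg[step])
    }
  }
  total - (loop_init + loop_per_base * ir$spacer_len)
}

#' Packaged nearest-neighbor stacking table
#'
#' Unified nearest-neighbor free energies (kcal/mol at 37 C) for DNA
#' duplex dinucleotide steps, shipped as plain text under `extdata`.
#'
#' @return Data frame with columns `step`, `dg`.
#' @export
nn_stacking_table <- function() {
  path <- system.file("extdata", "nn_stacking_dg37.tsv", package = "invarch")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Find tandem repeats
#'
#' Period-by-period scan: positions where the sequence equals itself
#' shifted by `p` delimit maximal runs; a run of length `L` is a tandem
#' array of span `L + p` with fractional copy number `(L + p) / p`. The
#' consensus is the per-column majority over the array. Overlapping calls
#' are resolved to the highest span (copies x period), then to the
#' smallest period.
#'
#' @param seq DNA string or labeled-sequence tibble row.
#' @param min_copies Minimum (fractional) copy number to report.
#' @param max_period Maximum period (bp), at most 50.
#' @return Motif tibble (`kind = "TANDEM"`) with `period`, `copy_number`,
#'   `consensus`.
#' @export
find_tandem_repeats <- function(seq, min_copies = 1.9, max_period = 50L) {
  if (max_period > 50L) abort("max_period must be <= 50")
  s <- as_seq_string(seq)
  x <- seq_ints(s)
  n <- length(x)
  cand <- list()
  for (p in 1:min(max_period, n - 1L)) {
    i <- seq_len(n - p)
    eq <- x[i] == x[i + p] & x[i] != 5L
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run <- which(r$values & (r$lengths + p) / p >= min_copies)
    for (k in run) {
      span <- r$lengths[k] + p
      st <- starts[k] - 1L # 0-based
      cand[[length(cand) + 1L]] <- motif_rows(
        "TANDEM", st, st + span, period = p,
        copy_number = span / p,
        consensus = tandem_consensus(s, st, span, p)
      )
    }
  }
  if (!length(cand)) return(empty_motifs())
  cand <- dplyr::bind_rows(cand) |>
    dplyr::arrange(dplyr::desc(.data$end - .data$start), .data$period,
                   .data$start)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(cand)) > i &
                     pmin(cand$end, cand$end[i]) -
                       pmax(cand$start, cand$start[i]) > 0)
    keep[setdiff(later, i)] <- FALSE
  }
  dplyr::arrange(cand[keep, ], .data$start)
}

tandem_consensus <- function(s, start, span, p) {
  chars <- strsplit(substr(s, start + 1L, start + span), "")[[1]]
  cons <- vapply(0:(p - 1L), function(j) {
    col <- chars[seq(j + 1L, span, by = p)]
    names(sort(table(col), decreasing = TRUE))[[1]]
  }, character(1))
  paste(cons, collapse = "")
}

#' Find Z-DNA-prone tracts
#'
#' Maximal alternating purine-pyrimidine runs of at least `min_len` bp.
#' The score weights dinucleotide steps by their Z-propensity (GC/CG
#' steps 1.0, mixed GT/AC-type steps 0.5, AT/TA steps 0.25).
#'
#' @param seq DNA string or labeled-sequence tibble row.
#' @param min_len Minimum tract length (bp), default 12.
#' @return Motif tibble (`kind = "ZDNA"`) with a `score` column.
#' @export
find_zdna <- function(seq, min_len = 12L) {
  s <- as_seq_string(seq)
  x <- seq_ints(s)
  n <- length(x)
  if (n < 2L) return(empty_motifs())
  pur <- x == 1L | x == 3L # A or G
  okb <- x != 5L
  alt <- pur[-n] != pur[-1L] & okb[-n] & okb[-1L]
  r <- rle(alt)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values & r$lengths + 1L >= min_len)) {
    st <- starts[k] - 1L
    len <- r$lengths[k] + 1L
    steps <- substring(s, (st + 1L):(st + len - 1L), (st + 2L):(st + len))
    w <- ifelse(steps %in% c("GC", "CG"), 1,
                ifelse(steps %in% c("AT", "TA"), 0.25, 0.5))
    out[[length(out) + 1L]] <- motif_rows("ZDNA", st, st + len,
                                          score = sum(w))
  }
  if (!length(out)) return(empty_motifs())
  dplyr::bind_rows(out)
}

#' Find G-quadruplex motifs
#'
#' Canonical G4 pattern `G3+ N1-7 G3+ N1-7 G3+ N1-7 G3+` on both strands
#' (leftmost non-overlapping matches per strand). Coordinates are always
#' on the forward sequence; minus-strand hits are C-tract motifs.
#'
#' @param seq DNA string or labeled-sequence tibble row.
#' @return Motif tibble (`kind = "G4"`) with a `score` column holding the
#'   motif length and the strand encoded in `consensus` (`"+"`/`"-"`).
#' @export
find_g4 <- function(seq) {
  s <- as_seq_string(seq)
  pat <- "G{3,}([ACGT]{1,7}G{3,}){3}"
  hits_for <- function(str) {
    m <- gregexpr(pat, str, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    tibble(start = as.integer(m) - 1L,
           len = attr(m, "match.length"))
  }
  n <- nchar(s)
  out <- list()
  h <- hits_for(s)
  if (!is.null(h)) {
    out[[1]] <- motif_rows("G4", h$start, h$start + h$len,
                           consensus = "+", score = h$len)
  }
  h <- hits_for(revcomp(s))
  if (!is.null(h)) {
    out[[2]] <- motif_rows("G4", n - h$start - h$len, n - h$start,
                           consensus = "-", score = h$len)
  }
  if (!length(out)) return(empty_motifs())
  dplyr::arrange(dplyr::bind_rows(out), .data$start)
}

#' Find A-phased repeats (static bending)
#'
#' Three or more A-tracts (or T-tracts) of 3-9 bp whose centers are
#' spaced one helical turn apart (10 +/- 1 bp).
#'
#' @param seq DNA string or labeled-sequence tibble row.
#' @return Motif tibble (`kind = "APHASED"`); `copy_number` holds the
#'   number of phased tracts.
#' @export
find_aphased <- function(seq) {
  s <- as_seq_string(seq)
  out <- list()
  for (base in c("A", "T")) {
    m <- gregexpr(sprintf("%s{3,9}", base), s, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m) - 1L
    lens <- attr(m, "match.length")
    centers <- starts + lens / 2
    if (length(centers) < 3L) next
    i <- 1L
    while (i <= length(centers) - 2L) {
      j <- i
      while (j < length(centers) &&
               abs(centers[j + 1L] - centers[j] - 10) <= 1) {
        j <- j + 1L
      }
      if (j - i + 1L >= 3L) {
        out[[length(out) + 1L]] <- motif_rows(
          "APHASED", starts[i], starts[j] + lens[j],
          copy_number = j - i + 1L, consensus = base
        )
      }
      i <- max(j, i + 1L)
    }
  }
  if (!length(out)) return(empty_motifs())
  dplyr::arrange(dplyr::bind_rows(out), .data$start)
}

#' Per-window census of inverted-repeat density
#'
#' Counts motif midpoints per sliding window; used to reproduce the
#' breakpoint-proximal density profile of hairpin/cruciform-forming IRs.
#'
#' @param motifs Motif tibble (any scanner).
#' @param seq_len Sequence length (bp).
#' @param window,step Window size and step (bp).
#' @return Tibble of `start`, `end`, `n`.
#' @export
nonb_window_census <- function(motifs, seq_len, window = 150L, step = 10L) {
  starts <- seq(0L, max(0L, seq_len - window), by = step)
  mid <- (motifs$start + motifs$end) / 2
  tibble(
    start = as.integer(starts), end = as.integer(starts + window),
    n = vapply(starts, function(s0)
      sum(mid >= s0 & mid < s0 + window), integer(1))
  )
}

#' Plot a non-B motif density profile
#'
#' @param census Tibble from [nonb_window_census()].
#' @return A ggplot object.
#' @export
plot_nonb_density <- function(census) {
  ggplot2::ggplot(census, ggplot2::aes((.data$start + .data$end) / 2, .data$n)) +
    ggplot2::geom_line(colour = "#2c5f8a") +
    ggplot2::labs(x = "position (bp)", y = "motifs per window") +
    ggplot2::theme_minimal()
}
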