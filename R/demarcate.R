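# Base-pair demarcation of breakpoint segments A, B, C, D via the four
# comparative alignments of the inverted junction regions against the
# uninverted flanks, plus the second homology pass over unassigned
# sequence.

clip0 <- function(x, lo, hi) as.integer(pmin(pmax(x, lo), hi))

sub0s <- function(s, a, b) substr(s, a + 1L, b) # 0-based half-open

#' Demarcate breakpoint segments from an inversion candidate
#'
#' For each junction region of the inverted assembly, homology to the two
#' uninverted flanks is profiled by local alignment and the switch point is
#' localized by a competitive change-point model: a single switch for clean
#' junctions, or a three-segment model whose middle segment (homologous to
#' neither flank) is cataloged as unassigned sequence (candidate insertion
#' or filler). Junction positions wider than `max_point_zone` are reported
#' as intervals, not points.
#'
#' @param seqs Labeled-sequence tibble holding the inverted and uninverted
#'   assemblies.
#' @param candidate One row of [call_inversion_candidates()] output, called
#'   with the inverted assembly as query and an uninverted assembly as
#'   target.
#' @param inv_id,uninv_id Sequence ids of query and target assemblies.
#' @param pad Flanking sequence (bp) added around each breakpoint region
#'   before alignment.
#' @param max_point_zone Maximum width (bp) of a transition zone still
#'   reported as a point junction.
#' @param delta Log-likelihood margin by which the three-segment model must
#'   beat the single-switch model before an unassigned segment is called.
#' @return An object of class `"segment_map"`: tibbles `junctions`
#'   (+A|+B, +C|+D, +A|-C, -B|+D positions and transition-zone widths),
#'   `segments` (per-assembly A, B, C, D intervals), `unassigned`
#'   (cataloged insertions with sequence), plus the analyzed regions.
#' @export
demarcate_segments <- function(seqs, candidate, inv_id = "inverted",
                               uninv_id = "uninverted_1", pad = 1200L,
                               max_point_zone = 10L, delta = 6) {
  stopifnot(nrow(candidate) == 1L)
  inv <- seqs$seq[seqs$id == inv_id][[1]]
  uni <- seqs$seq[seqs$id == uninv_id][[1]]
  nq <- nchar(inv); nt <- nchar(uni)

  rip <- clip0(c(candidate$q_prox_start - pad, candidate$q_prox_end + pad), 0L, nq)
  rid <- clip0(c(candidate$q_dist_start - pad, candidate$q_dist_end + pad), 0L, nq)
  if (rip[2] > rid[1]) { # keep the two query regions disjoint
    m <- (rip[2] + rid[1]) %/% 2L
    rip[2] <- m; rid[1] <- m
  }
  rup <- clip0(c(candidate$t_prox_start - pad, candidate$t_prox_end + pad), 0L, nt)
  rud <- clip0(c(candidate$t_dist_start - pad, candidate$t_dist_end + pad), 0L, nt)
  if (rup[2] > rud[1]) {
    m <- (rup[2] + rud[1]) %/% 2L
    rup[2] <- m; rud[1] <- m
  }

  f_up <- sub0s(uni, rup[1], rup[2])   # +A|+B region
  f_ud <- sub0s(uni, rud[1], rud[2])   # +C|+D region
  s_ip <- sub0s(inv, rip[1], rip[2])   # +A|-C region
  s_id <- sub0s(inv, rid[1], rid[2])   # -B|+D region

  jp <- locate_junction(s_ip, f_up, revcomp(f_ud), delta, max_point_zone)
  jd <- locate_junction(s_id, revcomp(f_up), f_ud, delta, max_point_zone)

  # uninverted-coordinate endpoints recovered from the four alignments
  a_end <- if (is.na(jp$f1_end)) NA_integer_ else rup[1] + jp$f1_end
  c_end <- if (is.na(jp$f2_start)) NA_integer_ else rud[2] - jp$f2_start
  b_start <- if (is.na(jd$f1_end)) NA_integer_ else rup[2] - jd$f1_end
  d_start <- if (is.na(jd$f2_start)) NA_integer_ else rud[1] + jd$f2_start

  zone_p <- rip[1] + jp$zone
  zone_d <- rid[1] + jd$zone
  jtab <- tibble(
    junction = c("uninv_prox", "uninv_dist", "inv_prox", "inv_dist"),
    label = c("+A|+B", "+C|+D", "+A|-C", "-B|+D"),
    assembly = c(uninv_id, uninv_id, inv_id, inv_id),
    lo = c(min(a_end, b_start), min(c_end, d_start), zone_p[1], zone_d[1]),
    hi = c(max(a_end, b_start), max(c_end, d_start), zone_p[2], zone_d[2]),
    resolved = c(!is.na(a_end) && !is.na(b_start),
                 !is.na(c_end) && !is.na(d_start),
                 jp$resolved, jd$resolved)
  ) |>
    dplyr::mutate(
      pos = as.integer(floor((.data$lo + .data$hi) / 2)),
      width = .data$hi - .data$lo,
      is_point = .data$width <= max_point_zone
    )

  segs <- dplyr::bind_rows(
    tibble(assembly = uninv_id,
           segment = c("A", "B", "C", "D"),
           start = c(rup[1], b_start, rud[1], d_start),
           end = c(a_end, rup[2], c_end, rud[2]),
           strand = "+"),
    tibble(assembly = inv_id,
           segment = c("A", "C", "B", "D"),
           start = c(rip[1], zone_p[2], rid[1], zone_d[2]),
           end = c(zone_p[1], rip[2], zone_d[1], rid[2]),
           strand = c("+", "-", "-", "+"))
  )

  una <- list()
  if (!is.null(jp$unassigned)) {
    una[[length(una) + 1L]] <- tibble(
      seq_id = inv_id, start = rip[1] + jp$unassigned[1],
      end = rip[1] + jp$unassigned[2], strand = "+", name = "unassigned_prox",
      seq = sub0s(inv, rip[1] + jp$unassigned[1], rip[1] + jp$unassigned[2])
    )
  }
  if (!is.null(jd$unassigned)) {
    una[[length(una) + 1L]] <- tibble(
      seq_id = inv_id, start = rid[1] + jd$unassigned[1],
      end = rid[1] + jd$unassigned[2], strand = "+", name = "unassigned_dist",
      seq = sub0s(inv, rid[1] + jd$unassigned[1], rid[1] + jd$unassigned[2])
    )
  }
  una <- if (length(una)) dplyr::bind_rows(una) else
    tibble(seq_id = character(), start = integer(), end = integer(),
           strand = character(), name = character(), seq = character())

  structure(list(
    junctions = jtab, segments = segs, unassigned = una,
    regions = list(inv_prox = rip, inv_dist = rid,
                   uninv_prox = rup, uninv_dist = rud),
    inv_id = inv_id, uninv_id = uninv_id,
    params = list(pad = pad, max_point_zone = max_point_zone, delta = delta)
  ), class = "segment_map")
}

#' @export
print.segment_map <- function(x, ...) {
  cat("<segment_map>\n")
  print(x$junctions, n = Inf)
  if (nrow(x$unassigned)) {
    cat(sprintf("%d unassigned interval(s), total %d bp\n",
                nrow(x$unassigned), sum(x$unassigned$end - x$unassigned$start)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Ungapped homology matches between two sequences (both orientations),
# seeded by shared k-mers and extended across isolated substitutions.

extend_match <- function(s1, s2, qa, qb, ta, tb, orientation, look = 5L,
                         tolerate = 0L) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  # a substitution is crossed when the run behind it is clean; with
  # tolerate = 1 a second nearby substitution is forgiven, which carries
  # extension across divergence clusters but must not be used where
  # low-complexity sequence could sustain a chance-match random walk
  ok_run <- function(get_pair, steps) {
    sum(vapply(steps, function(j) {
      p <- get_pair(j)
      !is.na(p[1]) && p[1] == p[2] && p[1] != "N"
    }, logical(1))) >= length(steps) - tolerate
  }
  if (orientation == "+") {
    pair_right <- function(j) {
      if (qb + j >= n1 || tb + j >= n2) return(c(NA, NA))
      c(char_at(s1, qb + j), char_at(s2, tb + j))
    }
    pair_left <- function(j) {
      if (qa - 1L - j < 0L || ta - 1L - j < 0L) return(c(NA, NA))
      c(char_at(s1, qa - 1L - j), char_at(s2, ta - 1L - j))
    }
  } else {
    # q [qa,qb) matches revcomp of t [ta,tb): extending q right consumes t left
    pair_right <- function(j) {
      if (qb + j >= n1 || ta - 1L - j < 0L) return(c(NA, NA))
      c(char_at(s1, qb + j), comp_base(char_at(s2, ta - 1L - j)))
    }
    pair_left <- function(j) {
      if (qa - 1L - j < 0L || tb + j >= n2) return(c(NA, NA))
      c(char_at(s1, qa - 1L - j), comp_base(char_at(s2, tb + j)))
    }
  }
  grow <- function(pair_fun) {
    ext <- 0L
    repeat {
      p <- pair_fun(ext)
      if (!is.na(p[1]) && p[1] == p[2] && p[1] != "N") {
        ext <- ext + 1L
      } else if (!is.na(p[1]) && ok_run(pair_fun, ext + seq_len(look))) {
        ext <- ext + 1L # cross an isolated substitution backed by a clean run
      } else break
    }
    ext
  }
  er <- grow(pair_right)
  el <- grow(pair_left)
  if (orientation == "+") {
    c(qa - el, qb + er, ta - el, tb + er)
  } else {
    c(qa - el, qb + er, ta - er, tb + el)
  }
}

match_identity <- function(s1, s2, qa, qb, ta, tb, orientation) {
  q <- sub0s(s1, qa, qb)
  t <- sub0s(s2, ta, tb)
  if (orientation == "-") t <- revcomp(t)
  cq <- strsplit(q, "")[[1]]
  ct <- strsplit(t, "")[[1]]
  L <- min(length(cq), length(ct))
  mean(cq[seq_len(L)] == ct[seq_len(L)] & cq[seq_len(L)] != "N")
}

# All ungapped homology matches between s1 and s2 (or within s1 when
# self = TRUE); returns extended extents with identity.
find_local_matches <- function(s1, s2, k = 12L, min_len = 20L,
                               min_identity = 0.85, self = FALSE,
                               tolerate = 0L) {
  if (nchar(s1) < k || nchar(s2) < k) {
    return(tibble(q_start = integer(), q_end = integer(),
                  t_start = integer(), t_end = integer(),
                  orientation = character(), length = integer(),
                  identity = double()))
  }
  anchors <- find_anchors(s1, s2, k = k, unique_target = FALSE)
  if (self) {
    anchors <- anchors[!(anchors$orientation == "+" &
                           anchors$q_pos == anchors$t_pos), ]
    keep <- (anchors$orientation == "+" & anchors$q_pos < anchors$t_pos) |
      (anchors$orientation == "-" & anchors$q_pos <= anchors$t_pos)
    anchors <- anchors[keep, ]
  }
  blocks <- chain_blocks(anchors, max_gap = 3L * k, min_anchors = 1L)
  if (nrow(blocks) == 0L) return(blocks_to_matches(NULL))
  rows <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    e <- extend_match(s1, s2, b$q_start, b$q_end, b$t_start, b$t_end,
                      b$orientation, tolerate = tolerate)
    len <- e[2] - e[1]
    if (len < min_len) next
    id <- match_identity(s1, s2, e[1], e[2], e[3], e[4], b$orientation)
    if (id < min_identity) next
    rows[[length(rows) + 1L]] <- tibble(
      q_start = e[1], q_end = e[2], t_start = e[3], t_end = e[4],
      orientation = b$orientation, length = len, identity = id
    )
  }
  blocks_to_matches(rows)
}

blocks_to_matches <- function(rows) {
  if (is.null(rows) || !length(rows)) {
    return(tibble(q_start = integer(), q_end = integer(),
                  t_start = integer(), t_end = integer(),
                  orientation = character(), length = integer(),
                  identity = double()))
  }
  res <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$q_start, .data$t_start, dplyr::desc(.data$length))
  # collapse duplicates produced by different seeds of the same extent
  dplyr::distinct(res, .data$q_start, .data$q_end, .data$t_start,
                  .data$t_end, .data$orientation, .keep_all = TRUE)
}

#' Second homology pass over unassigned sequence
#'
#' Aligns every unassigned interval against the demarcated segments and
#' against the other unassigned intervals (and itself), in both
#' orientations; ungapped matches of at least `min_len` bp at
#' `min_identity` are recorded as homology hits with parent and
#' orientation, turning anonymous insertions into duplication copies.
#'
#' @param map A [demarcate_segments()] result.
#' @param seqs The labeled-sequence tibble the map was built from.
#' @param k Seed k-mer length.
#' @param min_len,min_identity Reporting thresholds.
#' @return The map with a `homologies` tibble added (absolute coordinates
#'   on the inverted assembly and parent labels).
#' @export
second_pass_homology <- function(map, seqs, k = 12L, min_len = 20L,
                                 min_identity = 0.85) {
  inv <- seqs$seq[seqs$id == map$inv_id][[1]]
  uni <- seqs$seq[seqs$id == map$uninv_id][[1]]
  segs <- map$segments
  targets <- list()
  for (i in seq_len(nrow(segs))) {
    r <- segs[i, ]
    if (is.na(r$start) || is.na(r$end) || r$end <= r$start) next
    src <- if (r$assembly == map$inv_id) inv else uni
    nm <- sprintf("%s:%s", r$assembly, r$segment)
    targets[[nm]] <- list(seq = sub0s(src, r$start, r$end), start = r$start,
                          assembly = r$assembly)
  }
  una <- map$unassigned
  for (i in seq_len(nrow(una))) {
    targets[[una$name[[i]]]] <- list(seq = una$seq[[i]], start = una$start[[i]],
                                     assembly = una$seq_id[[i]])
  }
  rows <- list()
  for (i in seq_len(nrow(una))) {
    q <- una[i, ]
    for (nm in names(targets)) {
      tg <- targets[[nm]]
      self <- identical(nm, q$name)
      hits <- find_local_matches(q$seq, tg$seq, k = k, min_len = min_len,
                                 min_identity = min_identity, self = self)
      if (nrow(hits) == 0L) next
      hits$query <- q$name
      hits$q_start <- hits$q_start + q$start
      hits$q_end <- hits$q_end + q$start
      hits$parent <- nm
      hits$parent_assembly <- tg$assembly
      hits$t_start <- hits$t_start + tg$start
      hits$t_end <- hits$t_end + tg$start
      rows[[length(rows) + 1L]] <- hits
    }
  }
  map$homologies <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(q_start = integer(), q_end = integer(), t_start = integer(),
           t_end = integer(), orientation = character(), length = integer(),
           identity = double(), query = character(), parent = character(),
           parent_assembly = character())
  map
}
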