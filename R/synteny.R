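# Anchor-based conserved-synteny comparison: exact k-mer anchors unique in
# the target, greedy colinear chaining, and inversion candidates called as
# orientation flips between adjacent blocks.

as_seq_string <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x$seq[[1]]
  } else {
    toupper(as.character(x)[[1]])
  }
}

kmer_starts <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# Exact integer encoding of all k-mers (k <= 15 fits in 31 bits; base-4
# digits, no hashing so no collisions). Windows containing N get NA.
kmer_keys <- function(x, k) {
  n <- length(x)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  key <- integer(m)
  pow <- 1L
  for (j in 0:(k - 1L)) {
    key <- key + (pmin(x[(1L + j):(m + j)], 4L) - 1L) * pow
    if (j < k - 1L) pow <- pow * 4L
  }
  cn <- c(0L, cumsum(x == 5L))
  key[(cn[(k + 1L):(n + 1L)] - cn[1:m]) > 0L] <- NA_integer_
  key
}

#' Find exact k-mer anchors between two sequences
#'
#' Reports every exact match of a query k-mer to a target k-mer, in both
#' orientations. With `unique_target = TRUE` (the default) only k-mers that
#' occur exactly once in the target are used, which suppresses repeat noise
#' and turns repeat-rich breakpoint regions into anchor deserts bounded by
#' unique flanks. K-mers containing `N` never match.
#'
#' @param query,target DNA strings or single-row labeled-sequence tibbles.
#' @param k Anchor length in bp; at least 11 (spurious-match floor).
#' @param unique_target Restrict to k-mers unique in the target.
#' @return Tibble with 0-based `q_pos`, `t_pos`, `k`, `orientation`
#'   (`"+"`/`"-"`), sorted by `q_pos` then `t_pos`. For a `-` anchor the
#'   query k-mer equals the reverse complement of the target k-mer.
#' @export
find_anchors <- function(query, target, k = 15L, unique_target = TRUE) {
  if (k < 11L) abort("k must be >= 11 (spurious-match floor)")
  q <- as_seq_string(query)
  t <- as_seq_string(target)
  if (nchar(q) < k || nchar(t) < k) abort("sequences must be at least k long")
  if (k > 15L) abort("k must be <= 15")
  xt <- seq_ints(t)
  tk <- kmer_keys(xt, k)
  keep <- !is.na(tk)
  if (unique_target) {
    dup <- duplicated(tk, incomparables = NA_integer_) |
      duplicated(tk, incomparables = NA_integer_, fromLast = TRUE)
    keep <- keep & !dup
  }
  tpos0 <- which(keep) - 1L
  o_t <- order(tk[keep])
  st_keys <- tk[keep][o_t]
  st_pos <- tpos0[o_t]

  hit_rows <- function(qk, qpos0, orientation) {
    ok <- !is.na(qk)
    qk <- qk[ok]; qpos0 <- qpos0[ok]
    if (!length(qk)) {
      return(list(q_pos = integer(), t_pos = integer(),
                  orientation = character()))
    }
    hi <- findInterval(qk, st_keys)
    lo <- findInterval(qk - 1L, st_keys) + 1L
    found <- hi >= lo & hi >= 1L
    found[found] <- st_keys[hi[found]] == qk[found]
    lens <- ifelse(found, hi - lo + 1L, 0L)
    idx <- sequence(lens[found], from = lo[found])
    list(
      q_pos = rep(qpos0[found], lens[found]),
      t_pos = st_pos[idx],
      orientation = rep(orientation, sum(lens))
    )
  }

  nq <- nchar(q)
  fwd <- hit_rows(kmer_keys(seq_ints(q), k), 0:(nq - k), "+")
  rq <- revcomp(q)
  # k-mer starting at i (0-based) of revcomp(q) covers query [nq-k-i, nq-i)
  rev <- hit_rows(kmer_keys(seq_ints(rq), k), (nq - k):0, "-")
  q_pos <- c(fwd$q_pos, rev$q_pos)
  t_pos <- c(fwd$t_pos, rev$t_pos)
  orientation <- c(fwd$orientation, rev$orientation)
  o <- order(q_pos, t_pos, orientation)
  tibble::new_tibble(list(
    q_pos = q_pos[o], t_pos = t_pos[o],
    k = rep(as.integer(k), length(o)), orientation = orientation[o]
  ), nrow = length(o))
}

# Collapse anchors into per-diagonal runs with q-gap <= max_gap, fully
# vectorized: along one diagonal, the t interval follows directly from the
# q interval, so only run boundaries in q order are needed.
diagonal_runs_all <- function(a, ori, max_gap) {
  k <- a$k[[1]]
  diag <- if (ori == "+") a$t_pos - a$q_pos else a$t_pos + a$q_pos
  o <- order(diag, a$q_pos)
  dg <- diag[o]; qp <- a$q_pos[o]
  newrun <- c(TRUE, dg[-1] != dg[-length(dg)] |
                qp[-1] - qp[-length(qp)] > max_gap)
  first <- which(newrun)
  last <- c(first[-1] - 1L, length(qp))
  q_min <- qp[first]; q_max <- qp[last]
  d <- dg[first]
  if (ori == "+") {
    t_start <- q_min + d
    t_end <- q_max + d + k
  } else {
    t_start <- d - q_max
    t_end <- d - q_min + k
  }
  tibble(q_start = q_min, q_end = q_max + k,
         t_start = t_start, t_end = t_end,
         n_anchors = last - first + 1L,
         score = (last - first + 1L) * k)
}

#' Chain anchors into colinear synteny blocks
#'
#' Greedy chaining: anchors are first collapsed along exact diagonals, and
#' runs are then merged left to right whenever both the query gap and the
#' target gap to the chain tail are at most `max_gap` and the target
#' coordinate moves in the orientation-consistent direction (increasing for
#' `+`, decreasing for `-`). Ties are broken leftmost. No anchor is
#' assigned to more than one block.
#'
#' @param anchors Anchor tibble from [find_anchors()].
#' @param max_gap Maximum inter-anchor gap in bp on both sequences.
#' @param min_anchors Minimum anchors per reported block.
#' @return Tibble of blocks (`q_start`, `q_end`, `t_start`, `t_end`,
#'   `orientation`, `n_anchors`, `score`), sorted by `q_start`.
#' @export
chain_blocks <- function(anchors, max_gap = 2000L, min_anchors = 3L) {
  empty <- tibble(q_start = integer(), q_end = integer(),
                  t_start = integer(), t_end = integer(),
                  orientation = character(), n_anchors = integer(),
                  score = integer())
  if (is.null(anchors) || nrow(anchors) == 0L) return(empty)
  out <- list()
  for (ori in c("+", "-")) {
    a <- anchors[anchors$orientation == ori, ]
    if (nrow(a) == 0L) next
    runs <- diagonal_runs_all(a, ori, max_gap) |>
      dplyr::arrange(.data$q_start, .data$t_start)
    # merge runs left to right into chains
    chains <- list()
    for (i in seq_len(nrow(runs))) {
      r <- runs[i, ]
      merged <- FALSE
      if (length(chains)) {
        # candidate chains whose tail precedes this run within max_gap
        best <- NA_integer_; best_d <- Inf
        ovl <- 25L # small overlap tolerated for diagonal shifts
        for (j in seq_along(chains)) {
          ch <- chains[[j]]
          qg <- r$q_start - ch$q_end
          tg <- if (ori == "+") r$t_start - ch$t_end else ch$t_start - r$t_end
          if (qg >= -ovl && qg <= max_gap && tg >= -ovl && tg <= max_gap) {
            d <- abs(qg - tg)
            if (d < best_d) { best_d <- d; best <- j }
          }
        }
        if (!is.na(best)) {
          ch <- chains[[best]]
          chains[[best]] <- tibble(
            q_start = min(ch$q_start, r$q_start),
            q_end = max(ch$q_end, r$q_end),
            t_start = min(ch$t_start, r$t_start),
            t_end = max(ch$t_end, r$t_end),
            n_anchors = ch$n_anchors + r$n_anchors,
            score = ch$score + r$score
          )
          merged <- TRUE
        }
      }
      if (!merged) chains[[length(chains) + 1L]] <- r
    }
    blocks <- dplyr::bind_rows(chains)
    blocks$orientation <- ori
    out[[ori]] <- blocks
  }
  res <- dplyr::bind_rows(out)
  res <- res[res$n_anchors >= min_anchors, ]
  dplyr::arrange(
    dplyr::select(res, "q_start", "q_end", "t_start", "t_end",
                  "orientation", "n_anchors", "score"),
    .data$q_start
  )
}

#' Call inversion candidates from synteny blocks
#'
#' One candidate per `-` block that is flanked by `+` blocks on both sides
#' in query order. Breakpoint regions are the unanchored inter-block gaps;
#' on the target, the proximal gap abuts the low-coordinate end of the
#' flipped block and the distal gap its high-coordinate end.
#'
#' @param blocks Block tibble from [chain_blocks()].
#' @param expected_span Optional expected inversion span in bp; candidates
#'   are kept when their flipped span is within `span_tol` of it.
#' @param span_tol Relative tolerance for `expected_span` (default 0.2).
#' @return Tibble with one row per candidate: query and target breakpoint
#'   regions (`q_prox_start` ... `t_dist_end`, 0-based half-open) and
#'   `flipped_span` (bp).
#' @export
call_inversion_candidates <- function(blocks, expected_span = NULL,
                                      span_tol = 0.2) {
  empty <- tibble(
    q_prox_start = integer(), q_prox_end = integer(),
    q_dist_start = integer(), q_dist_end = integer(),
    t_prox_start = integer(), t_prox_end = integer(),
    t_dist_start = integer(), t_dist_end = integer(),
    flipped_span = integer()
  )
  if (is.null(blocks) || nrow(blocks) == 0L) return(empty)
  blocks <- dplyr::arrange(blocks, .data$q_start)
  minus <- which(blocks$orientation == "-")
  rows <- list()
  for (i in minus) {
    # flanking + blocks must precede/follow the - block on BOTH sequences
    # (colinear outside the inversion); they may still overlap it by a
    # shared repeat (NAHR), and the overlap then becomes the breakpoint
    # ambiguity region
    before <- which(blocks$orientation == "+" &
                      blocks$q_start < blocks$q_start[i] &
                      blocks$q_end < blocks$q_end[i] &
                      blocks$t_start < blocks$t_start[i] &
                      blocks$t_end < blocks$t_end[i])
    after <- which(blocks$orientation == "+" &
                     blocks$q_start > blocks$q_start[i] &
                     blocks$q_end > blocks$q_end[i] &
                     blocks$t_start > blocks$t_start[i] &
                     blocks$t_end > blocks$t_end[i])
    if (!length(before) || !length(after)) next
    p <- before[which.max(blocks$q_end[before])]
    d <- after[which.min(blocks$q_start[after])]
    gap <- function(a, b) c(min(a, b), max(a, b, a + 1L))
    qp <- gap(blocks$q_end[p], blocks$q_start[i])
    qd <- gap(blocks$q_end[i], blocks$q_start[d])
    tp <- gap(blocks$t_end[p], blocks$t_start[i])
    td <- gap(blocks$t_end[i], blocks$t_start[d])
    rows[[length(rows) + 1L]] <- tibble(
      q_prox_start = qp[1], q_prox_end = qp[2],
      q_dist_start = qd[1], q_dist_end = qd[2],
      t_prox_start = tp[1], t_prox_end = tp[2],
      t_dist_start = td[1], t_dist_end = td[2],
      flipped_span = blocks$q_end[i] - blocks$q_start[i]
    )
  }
  res <- if (length(rows)) dplyr::bind_rows(rows) else empty
  if (!is.null(expected_span) && nrow(res)) {
    keep <- abs(res$flipped_span - expected_span) <= span_tol * expected_span
    res <- res[keep, ]
  }
  res
}

#' Dot-plot of anchors between two sequences
#'
#' @param anchors Anchor tibble from [find_anchors()].
#' @return A ggplot object (query position vs target position, colored by
#'   orientation).
#' @export
plot_dotplot <- function(anchors) {
  ggplot2::ggplot(anchors, ggplot2::aes(.data$q_pos, .data$t_pos,
                                        colour = .data$orientation)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = c("+" = "#d66a84", "-" = "#4a9d5f")) +
    ggplot2::labs(x = "query position (bp)", y = "target position (bp)",
                  colour = "orientation") +
    ggplot2::theme_minimal()
}
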