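# Position-weight-matrix scanning of transcription-factor binding sites
# with exact p-values from the score distribution under a 0-order
# background.

#' Read position weight matrices from a text file
#'
#' Format: one or more motifs, each a `>name` header followed by four
#' whitespace-separated rows labelled `A`, `C`, `G`, `T` holding counts
#' (or frequencies) per motif position, e.g.
#' ```
#' >dFOXO
#' A 12  0  3 ...
#' C  1  0 14 ...
#' G  2 18  0 ...
#' T  5  2  3 ...
#' ```
#'
#' @param path Path to the matrix file.
#' @return A named list of `"pwm"` objects (name + 4 x width count
#'   matrix).
#' @export
read_pwm <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) abort("no '>' motif headers found")
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4L) {
      abort(sprintf("motif '%s': expected 4 base rows, got %d",
                    name, length(body)))
    }
    rows <- lapply(body, function(l) strsplit(l, "\\s+")[[1]])
    bases <- toupper(vapply(rows, `[`, character(1), 1L))
    if (!setequal(bases, c("A", "C", "G", "T"))) {
      abort(sprintf("motif '%s': rows must be labelled A, C, G, T", name))
    }
    vals <- lapply(rows, function(r) as.numeric(r[-1L]))
    if (length(unique(lengths(vals))) != 1L) {
      abort(sprintf("motif '%s': ragged rows", name))
    }
    m <- do.call(rbind, vals)
    rownames(m) <- bases
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    if (ncol(m) < 4L) abort(sprintf("motif '%s': width must be >= 4", name))
    out[[name]] <- new_pwm(name, m)
  }
  out
}

#' Construct a PWM object
#'
#' @param name Motif name.
#' @param counts 4 x width numeric matrix with rows A, C, G, T (counts or
#'   frequencies).
#' @return Object of class `"pwm"`.
#' @export
new_pwm <- function(name, counts) {
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  structure(list(name = name, counts = counts), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d\n", x$name, ncol(x$counts)))
  invisible(x)
}

# log2-odds score matrix with pseudocounts against a background
pwm_logodds <- function(pwm, background, pseudocount = 0.25) {
  cnt <- pwm$counts
  tot <- colSums(cnt)
  freq <- sweep(cnt + pseudocount * background * 4 / 4, 2,
                tot + pseudocount, "/")
  # guard: background probabilities strictly positive
  bg <- pmax(background, 1e-6)
  log2(freq / bg)
}

# Exact distribution of the per-window score under the 0-order background,
# by convolution over positions with score discretization. Returns a
# function mapping a score to P(Score >= s).
pwm_score_tail <- function(S, background, bin = 0.01) {
  q <- round(S / bin)
  probs <- c(1)
  offset <- 0L
  for (j in seq_len(ncol(q))) {
    vals <- q[, j]
    lo <- min(vals)
    width <- max(vals) - lo
    new <- numeric(length(probs) + width)
    for (b in 1:4) {
      k <- vals[b] - lo
      idx <- seq_along(probs) + k
      new[idx] <- new[idx] + probs * background[b]
    }
    probs <- new
    offset <- offset + lo
  }
  tail_p <- rev(cumsum(rev(probs)))
  function(score) {
    k <- round(score / bin) - offset + 1L
    k <- pmin(pmax(k, 1L), length(tail_p))
    # scores above the maximum have probability 0; clamp into (0, 1]
    p <- tail_p[k]
    pmin(pmax(p, .Machine$double.xmin), 1)
  }
}

#' Scan a sequence with a position weight matrix
#'
#' Log-odds scanning of both strands with pseudocounts; p-values are exact
#' tail probabilities of the per-window score under the 0-order background
#' model, computed by convolution over motif positions with score
#' discretization (`bin` log-odds units). No multiple-testing correction
#' is applied; hit counts are reported so downstream corrections can be.
#'
#' @param seq DNA string or labeled-sequence tibble row.
#' @param pwm A `"pwm"` object.
#' @param p_cutoff Report hits with `p_value <= p_cutoff`.
#' @param background Length-4 nucleotide frequency vector (A, C, G, T);
#'   default estimated from `seq`.
#' @param pseudocount Pseudocount added per matrix cell.
#' @param bin Score discretization (log2-odds units).
#' @return Tibble of hits: `pwm`, `start`, `end` (0-based half-open, on
#'   the forward sequence), `strand`, `score`, `p_value`, sorted by
#'   position.
#' @export
scan_pwm <- function(seq, pwm, p_cutoff = 1e-3, background = NULL,
                     pseudocount = 0.25, bin = 0.01) {
  s <- as_seq_string(seq)
  n <- nchar(s)
  w <- ncol(pwm$counts)
  empty <- tibble(pwm = character(), start = integer(), end = integer(),
                  strand = character(), score = double(), p_value = double())
  if (w > n) return(empty)
  if (is.null(background)) {
    x <- seq_ints(s)
    cnt <- tabulate(x[x <= 4L], 4L)
    if (sum(cnt) == 0L) abort("sequence contains no unambiguous bases")
    background <- cnt / sum(cnt)
  }
  background <- pmax(background / sum(background), 1e-6)
  S <- pwm_logodds(pwm, background, pseudocount)
  tail_fun <- pwm_score_tail(S, background, bin)

  score_strand <- function(str) {
    x <- seq_ints(str)
    np <- length(x) - w + 1L
    sc <- numeric(np)
    bad <- rep(FALSE, np)
    for (j in seq_len(w)) {
      xi <- x[j:(j + np - 1L)]
      nn <- xi == 5L
      bad <- bad | nn
      xi[nn] <- 1L
      sc <- sc + S[cbind(xi, j)]
    }
    sc[bad] <- -Inf
    sc
  }
  fwd <- score_strand(s)
  rev_ <- score_strand(revcomp(s))
  rows <- list()
  add <- function(sc, strand) {
    keep <- which(is.finite(sc))
    if (!length(keep)) return()
    p <- tail_fun(sc[keep])
    ok <- p <= p_cutoff
    if (!any(ok)) return()
    i0 <- keep[ok] - 1L
    start <- if (strand == "+") i0 else n - i0 - w
    rows[[length(rows) + 1L]] <<- tibble(
      pwm = pwm$name, start = as.integer(start),
      end = as.integer(start + w), strand = strand,
      score = sc[keep][ok], p_value = p[ok]
    )
  }
  add(fwd, "+")
  add(rev_, "-")
  if (!length(rows)) return(empty)
  dplyr::arrange(dplyr::bind_rows(rows), .data$start, .data$strand)
}

#' Extract strand-aware upstream windows of annotated genes
#'
#' Returns the `length`-bp window upstream of each gene's transcription
#' start site; windows truncated at a sequence end are flagged. Gene
#' coordinates follow GFF3 conventions (1-based inclusive); a GFF3 file
#' path may be given instead of a data frame (requires rtracklayer).
#'
#' @param genes Data frame with columns `seqid`, `start`, `end`, `strand`
#'   and a name column (`ID` or `name`), or a GFF3 file path.
#' @param seqs Labeled-sequence tibble holding the genome.
#' @param length Window length in bp.
#' @return Labeled-sequence tibble with one row per gene (ids are gene
#'   names) plus columns `seq_id`, `start`, `end`, `strand`, `truncated`.
#' @export
extract_upstream <- function(genes, seqs, length = 1000L) {
  if (is.character(genes) && length(genes) == 1L) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GFF3 requires the rtracklayer package")
    }
    g <- as.data.frame(rtracklayer::readGFF(genes))
    genes <- g
  }
  nm <- genes[["ID"]] %||% genes[["name"]] %||%
    sprintf("gene_%d", seq_len(nrow(genes)))
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    sid <- as.character(genes$seqid[[i]])
    row <- seqs[seqs$id == sid, ]
    if (nrow(row) != 1L) {
      abort(sprintf("gene '%s': no sequence with id '%s'", nm[[i]], sid))
    }
    n <- nchar(row$seq[[1]])
    g_start <- as.integer(genes$start[[i]]) - 1L # to 0-based
    g_end <- as.integer(genes$end[[i]])
    if (g_start < 0L || g_end > n || g_start >= g_end) {
      abort(sprintf("gene '%s' lies off sequence '%s'", nm[[i]], sid))
    }
    if (genes$strand[[i]] == "+") {
      lo <- max(0L, g_start - length)
      hi <- g_start
      sseq <- substr(row$seq[[1]], lo + 1L, hi)
    } else {
      lo <- g_end
      hi <- min(n, g_end + length)
      sseq <- revcomp(substr(row$seq[[1]], lo + 1L, hi))
    }
    if (hi <= lo) abort(sprintf("gene '%s': empty upstream window", nm[[i]]))
    rows[[i]] <- tibble(
      id = nm[[i]], seq = sseq, offset = as.integer(lo),
      seq_id = sid, start = as.integer(lo), end = as.integer(hi),
      strand = as.character(genes$strand[[i]]),
      truncated = (hi - lo) < length
    )
  }
  dplyr::bind_rows(rows)
}

#' Cross-state presence table of motif hits
#'
#' Builds the per-factor presence/absence matrix across chromosome states
#' and genes, retaining all-absent rows, and flags factors whose hits in
#' the inverted state fall entirely within sequence newly attached by the
#' rearrangement.
#'
#' @param hits Tibble with columns `gene`, `state`, `pwm`, `start`, `end`
#'   (concatenated [scan_pwm()] results, annotated with gene and state).
#' @param genes,states,pwms Optional vectors fixing the full grid (default
#'   the values observed in `hits`).
#' @param new_regions Optional interval tibble (columns `gene`, `start`,
#'   `end`, upstream-window coordinates) marking sequence attached to the
#'   gene by the rearrangement; used for the `gained` flag.
#' @param inverted_state Name of the inverted state (default
#'   `"inverted"`).
#' @return Tibble with one row per gene x pwm: presence per state
#'   (logical columns) and `gained`.
#' @export
compare_states <- function(hits, genes = NULL, states = NULL, pwms = NULL,
                           new_regions = NULL, inverted_state = "inverted") {
  genes <- genes %||% unique(hits$gene)
  states <- states %||% unique(hits$state)
  pwms <- pwms %||% unique(hits$pwm)
  grid <- tidyr::expand_grid(gene = genes, pwm = pwms)
  for (st in states) {
    grid[[st]] <- purrr::map2_lgl(grid$gene, grid$pwm, function(g, m) {
      any(hits$gene == g & hits$pwm == m & hits$state == st)
    })
  }
  grid$gained <- purrr::map2_lgl(grid$gene, grid$pwm, function(g, m) {
    h <- hits[hits$gene == g & hits$pwm == m &
                hits$state == inverted_state, ]
    if (nrow(h) == 0L || is.null(new_regions)) return(FALSE)
    nr <- new_regions[new_regions$gene == g, ]
    if (nrow(nr) == 0L) return(FALSE)
    inside <- vapply(seq_len(nrow(h)), function(i) {
      any(h$start[[i]] >= nr$start & h$end[[i]] <= nr$end)
    }, logical(1))
    others <- grid[[setdiff(states, inverted_state)[1]]][
      grid$gene == g & grid$pwm == m]
    all(inside) && !any(others)
  })
  grid
}
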