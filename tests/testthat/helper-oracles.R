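# Independent brute-force oracles and fixture builders. These deliberately
# use naive algorithms (double loops, full dynamic programming, full
# enumeration) so that they share no code path with the implementations
# they check.

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

# all exact k-mer anchors, double loop over query k-mers
oracle_anchors <- function(q, t, k, unique_target = TRUE) {
  tk <- substring(t, 1:(nchar(t) - k + 1L), k:nchar(t))
  usable <- !grepl("N", tk, fixed = TRUE)
  if (unique_target) {
    counts <- table(tk)
    usable <- usable & tk %in% names(counts)[counts == 1L]
  }
  rows <- list()
  scan_one <- function(qs, ori) {
    qk <- substring(qs, 1:(nchar(qs) - k + 1L), k:nchar(qs))
    for (i in seq_along(qk)) {
      if (grepl("N", qk[i], fixed = TRUE)) next
      hits <- which(tk == qk[i] & usable)
      q0 <- if (ori == "+") i - 1L else nchar(q) - k - (i - 1L)
      for (h in hits) {
        rows[[length(rows) + 1L]] <<- data.frame(
          q_pos = q0, t_pos = h - 1L, orientation = ori,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  scan_one(q, "+")
  scan_one(oracle_revcomp(q), "-")
  if (!length(rows)) {
    return(data.frame(q_pos = integer(), t_pos = integer(),
                      orientation = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$q_pos, out$t_pos, out$orientation), , drop = FALSE]
}

# global alignment score, full Needleman-Wunsch with linear gap penalty
oracle_nw_score <- function(x, y, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(x, "")[[1]]
  b <- strsplit(y, "")[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1] <- gap * (0:n)
  D[1, ] <- gap * (0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (a[i] == b[j] && a[i] != "N") match else mismatch
      D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + gap,
                             D[i + 1, j] + gap)
    }
  }
  D[n + 1, m + 1]
}

# all maximal inverted/mirror repeats, full enumeration over
# (start, arm, spacer)
oracle_paired_arms <- function(s, arm_min, arm_max, max_spacer,
                               max_mismatch, complemented) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  mism <- function(i, a, sp) { # 1-based start
    mm <- 0L
    for (j in 0:(a - 1L)) {
      u <- chars[i + j]
      v <- chars[i + 2L * a + sp - 1L - j]
      pv <- if (complemented) unname(comp[v]) else v
      if (u != pv || u == "N") mm <- mm + 1L
    }
    mm
  }
  valid <- function(i, a, sp) {
    a >= 1L && a <= arm_max && sp >= 0L && i >= 1L &&
      i + 2L * a + sp - 1L <= n && mism(i, a, sp) <= max_mismatch
  }
  rows <- list()
  for (i in 1:n) {
    for (a in arm_min:arm_max) {
      for (sp in 0:max_spacer) {
        if (i + 2L * a + sp - 1L > n) next
        if (mism(i, a, sp) > max_mismatch) next
        if (valid(i - 1L, a + 1L, sp)) next      # outward extension
        if (sp >= 2L && valid(i, a + 1L, sp - 2L)) next # inward extension
        rows[[length(rows) + 1L]] <- data.frame(
          start = i - 1L, end = i - 1L + 2L * a + sp,
          arm_len = a, spacer_len = sp, mismatches = mism(i, a, sp)
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      arm_len = integer(), spacer_len = integer(),
                      mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

# exact PWM p-values by full enumeration over all 4^w windows
oracle_pwm <- function(pwm, seq, background, p_cutoff, pseudocount = 0.25) {
  cnt <- pwm$counts
  w <- ncol(cnt)
  tot <- colSums(cnt)
  freq <- sweep(cnt + pseudocount * background * 4 / 4, 2,
                tot + pseudocount, "/")
  S <- log2(freq / pmax(background, 1e-6))
  words <- expand.grid(rep(list(1:4), w))
  word_scores <- apply(words, 1, function(ix) sum(S[cbind(ix, 1:w)]))
  word_probs <- apply(words, 1, function(ix) prod(background[ix]))
  exact_tail <- function(sc) sum(word_probs[word_scores >= sc - 1e-9])
  score_at <- function(chars, i) {
    ix <- match(chars[i:(i + w - 1L)], c("A", "C", "G", "T"))
    if (anyNA(ix)) return(NA_real_)
    sum(S[cbind(ix, 1:w)])
  }
  hits <- list()
  for (strand in c("+", "-")) {
    str <- if (strand == "+") seq else oracle_revcomp(seq)
    chars <- strsplit(str, "")[[1]]
    n <- length(chars)
    for (i in 1:(n - w + 1L)) {
      sc <- score_at(chars, i)
      if (is.na(sc)) next
      p <- exact_tail(sc)
      start <- if (strand == "+") i - 1L else n - (i - 1L) - w
      hits[[length(hits) + 1L]] <- data.frame(
        start = start, strand = strand, score = sc, p_value = p
      )
    }
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# effective number of codons, computed family by family with an explicit
# family table (independent of the genetic-code machinery in the package)
oracle_nc_wright <- function(codons) {
  fams <- list(
    F = c("TTT", "TTC"), Y = c("TAT", "TAC"), C = c("TGT", "TGC"),
    H = c("CAT", "CAC"), Q = c("CAA", "CAG"), N = c("AAT", "AAC"),
    K = c("AAA", "AAG"), D = c("GAT", "GAC"), E = c("GAA", "GAG"),
    I = c("ATT", "ATC", "ATA"),
    V = c("GTT", "GTC", "GTA", "GTG"), P = c("CCT", "CCC", "CCA", "CCG"),
    Tt = c("ACT", "ACC", "ACA", "ACG"), A = c("GCT", "GCC", "GCA", "GCG"),
    G = c("GGT", "GGC", "GGA", "GGG"),
    L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
    S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
    R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG")
  )
  fs <- list()
  for (nm in names(fams)) {
    cods <- fams[[nm]]
    ni <- sapply(cods, function(cd) sum(codons == cd))
    n <- sum(ni)
    f <- if (n >= 2L) {
      p <- ni / n
      max((n * sum(p^2) - 1) / (n - 1), 0)
    } else NA
    fs[[nm]] <- c(k = length(cods), n = n, f = f)
  }
  tab <- do.call(rbind, fs)
  classmean <- function(k) mean(tab[tab[, "k"] == k, "f"], na.rm = TRUE)
  nc <- 2 + 9 / classmean(2) + 1 / classmean(3) + 5 / classmean(4) +
    3 / classmean(6)
  min(max(nc, 20), 61)
}

# small simulated dataset at desk scale (shared by several test files)
quick_sim <- function(mechanism, seed, ...) {
  cfg <- sim_config(mechanism = mechanism, genome_length = 30000L,
                    inversion_span = 8000L, seed = seed, ...)
  simulate_dataset(cfg)
}
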