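write_demo_pwm <- function(path, name, counts) {
  lines <- c(paste0(">", name))
  for (b in c("A", "C", "G", "T")) {
    lines <- c(lines, paste(b, paste(counts[b, ], collapse = " ")))
  }
  writeLines(lines, path)
}

one_hot_pwm <- function(word, weight = 100) {
  w <- nchar(word)
  m <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:w) m[substr(word, j, j), j] <- weight
  new_pwm(word, m)
}

test_that("the matrix text format round-trips and validates", {
  p <- withr::local_tempfile()
  m <- matrix(sample(0:20, 24, TRUE), 4, 6,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  write_demo_pwm(p, "demo", m)
  got <- read_pwm(p)
  expect_equal(names(got), "demo")
  expect_equal(unname(got$demo$counts), unname(m))
  writeLines(c(">bad", "A 1 2 3 4", "C 1 2 3 4", "G 1 2 3 4"), p)
  expect_error(read_pwm(p), "4 base rows")
  writeLines(c(">bad", "A 1 2 3", "C 1 2 3", "G 1 2 3", "T 1 2 3"), p)
  expect_error(read_pwm(p), "width")
})

test_that("a one-hot PWM hits exactly its planted word", {
  set.seed(81)
  word <- "TGTTTAC"
  s <- paste0(rand_dna(200), word, rand_dna(200))
  # make sure no chance second occurrence on either strand
  stopifnot(length(gregexpr(word, s, fixed = TRUE)[[1]]) == 1L,
            !grepl(revcomp(word), s, fixed = TRUE))
  hits <- scan_pwm(s, one_hot_pwm(word), p_cutoff = 1e-3,
                   background = rep(0.25, 4))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 200L)
  expect_equal(hits$strand, "+")
})

test_that("a uniform PWM yields no hits at p <= 1e-3", {
  set.seed(82)
  m <- matrix(10, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  hits <- scan_pwm(rand_dna(2000), new_pwm("flat", m), p_cutoff = 1e-3,
                   background = rep(0.25, 4))
  expect_equal(nrow(hits), 0L)
  # wider than the sequence: empty, not an error
  expect_equal(nrow(scan_pwm("ACGTAC", one_hot_pwm("TGTTTACA"))), 0L)
})

test_that("hit sets match full-enumeration exact p-values", {
  set.seed(83)
  for (rep in 1:6) {
    w <- sample(5:6, 1)
    m <- matrix(sample(0:15, 4 * w, TRUE), 4, w,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    pwm <- new_pwm("r", m)
    s <- rand_dna(300)
    bg <- rep(0.25, 4)
    cutoff <- 5e-3
    got <- scan_pwm(s, pwm, p_cutoff = cutoff, background = bg, bin = 0.002)
    oracle <- oracle_pwm(pwm, s, bg, cutoff)
    # near the cutoff the exact tail moves in whole word-class masses, so
    # the set comparison uses an epsilon band around the cutoff
    must_have <- oracle[oracle$p_value <= cutoff / 1.5, ]
    may_have <- oracle[oracle$p_value <= cutoff * 1.5, ]
    key <- function(d) paste(d$start, d$strand)
    expect_true(all(key(must_have) %in% key(got)))
    expect_true(all(key(got) %in% key(may_have)))
    # scores agree exactly where both report
    j <- match(key(got), key(oracle))
    expect_equal(got$score, oracle$score[j], tolerance = 1e-9)
  }
})

test_that("scanning the reverse complement swaps strands and coordinates", {
  set.seed(84)
  s <- rand_dna(500)
  pwm <- one_hot_pwm("TGTTTAC", weight = 50)
  a <- scan_pwm(paste0(s, "TGTTTAC", s), pwm, background = rep(0.25, 4))
  b <- scan_pwm(revcomp(paste0(s, "TGTTTAC", s)), pwm,
                background = rep(0.25, 4))
  expect_equal(nrow(a), nrow(b))
  n <- 2L * nchar(s) + 7L
  flip <- c("+" = "-", "-" = "+")
  expect_setequal(paste(n - b$end, unname(flip[b$strand])),
                  paste(a$start, a$strand))
})

test_that("p-values are calibrated on i.i.d. background", {
  set.seed(85)
  m <- matrix(sample(1:20, 36, TRUE), 4, 9,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- new_pwm("cal", m)
  s <- rand_dna(20000)
  bg <- rep(0.25, 4)
  for (alpha in c(1e-2, 1e-3)) {
    hits <- scan_pwm(s, pwm, p_cutoff = alpha, background = bg)
    n_pos <- 2L * (nchar(s) - 8L) # both strands
    expected <- n_pos * alpha
    sdv <- sqrt(n_pos * alpha * (1 - alpha))
    expect_lt(abs(nrow(hits) - expected), 3 * sdv + 3)
  }
})

test_that("upstream windows are strand-aware and truncation-flagged", {
  seqs <- labeled_seq("chr", strrep("ACGT", 2500))
  genes <- data.frame(seqid = "chr", start = c(5001, 4001, 201),
                      end = c(5600, 5000, 900),
                      strand = c("+", "-", "+"),
                      ID = c("gA", "gB", "gC"))
  up <- extract_upstream(genes, seqs, length = 1000L)
  expect_equal(up$start[1], 4000L)
  expect_equal(up$end[1], 5000L)
  expect_false(up$truncated[1])
  # minus strand: window downstream of gene end, reverse-complemented
  expect_equal(up$start[2], 5000L)
  expect_equal(up$end[2], 6000L)
  expect_equal(up$seq[2],
               revcomp(substr(seqs$seq[[1]], 5001, 6000)))
  # near the sequence start: truncated and flagged
  expect_equal(up$start[3], 0L)
  expect_equal(up$end[3], 200L)
  expect_true(up$truncated[3])
  genes_bad <- data.frame(seqid = "chr", start = 10001, end = 10100,
                          strand = "+", ID = "gX")
  expect_error(extract_upstream(genes_bad, seqs), "gX")
})

test_that("the presence table keeps all-absent rows and flags gains", {
  hits <- tibble::tibble(
    gene = c("AttA2a", "AttA2a", "AttA2b"),
    state = c("inverted", "inverted", "uninverted_B"),
    pwm = c("dFOXO", "dFOXO", "Relish"),
    start = c(120L, 300L, 40L), end = c(128L, 308L, 48L)
  )
  tab <- compare_states(
    hits, genes = c("AttA2a", "AttA2b"),
    states = c("inverted", "uninverted_B", "uninverted_chcu"),
    pwms = c("dFOXO", "Relish", "Dorsal"),
    new_regions = tibble::tibble(gene = "AttA2a", start = 0L, end = 400L)
  )
  expect_equal(nrow(tab), 6L)
  dfoxo <- tab[tab$gene == "AttA2a" & tab$pwm == "dFOXO", ]
  expect_true(dfoxo$inverted)
  expect_false(dfoxo$uninverted_B)
  expect_true(dfoxo$gained)
  dorsal <- tab[tab$pwm == "Dorsal", ]
  expect_true(all(!dorsal$inverted & !dorsal$uninverted_B))
  # identical hit sets across states give identical rows
  hits2 <- tibble::tibble(
    gene = "g", state = rep(c("inverted", "uninverted_B"), each = 1L),
    pwm = "TF", start = 10L, end = 18L
  )
  tab2 <- compare_states(hits2)
  expect_true(tab2$inverted == tab2$uninverted_B)
  expect_false(tab2$gained)
})
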