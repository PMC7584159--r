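test_that("the distal-junction palindrome is found as one perfect IR", {
  ir <- find_inverted_repeats("ATGAACTAGTTCAT", max_mismatch = 0)
  expect_equal(nrow(ir), 1L)
  expect_equal(ir$arm_len, 7L)
  expect_equal(ir$spacer_len, 0L)
  expect_equal(ir$mismatches, 0L)
  expect_equal(ir$end - ir$start, 14L)

  at <- find_inverted_repeats("AATTTTAAAATT", max_mismatch = 0)
  expect_true(any(at$arm_len == 6L & at$spacer_len == 0L))
  expect_error(find_inverted_repeats("ACGTACGTAC", arm_range = c(3L, 20L)),
               "at least 4")
})

test_that("IR and mirror scans equal full enumeration on random inputs", {
  set.seed(71)
  for (rep in 1:8) {
    s <- rand_dna(200, gc = 0.35)
    got <- as.data.frame(find_inverted_repeats(
      s, arm_range = c(5L, 12L), max_spacer = 6L, max_mismatch = 1L
    ))[, c("start", "end", "arm_len", "spacer_len", "mismatches")]
    want <- oracle_paired_arms(s, 5L, 12L, 6L, 1L, complemented = TRUE)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)

    gotm <- as.data.frame(find_mirror_repeats(
      s, arm_range = c(5L, 10L), max_spacer = 8L, max_mismatch = 1L
    ))[, c("start", "end", "arm_len", "spacer_len", "mismatches")]
    wantm <- oracle_paired_arms(s, 5L, 10L, 8L, 1L, complemented = FALSE)
    rownames(gotm) <- rownames(wantm) <- NULL
    expect_identical(gotm, wantm)
  }
})

test_that("an 11-nt mirror repeat with a 30-nt spacer is detected", {
  set.seed(72)
  arm <- "ACCTGATTACA"
  s <- paste0(rand_dna(20), arm, rand_dna(30),
              paste(rev(strsplit(arm, "")[[1]]), collapse = ""), rand_dna(20))
  mr <- find_mirror_repeats(s, max_mismatch = 0)
  expect_true(any(mr$arm_len >= 11L & mr$spacer_len == 30L))
  # trivially mirror-symmetric homopolymers below arm_min are not reported
  expect_equal(nrow(find_mirror_repeats("AAAA", arm_range = c(6L, 20L),
                                        max_spacer = 2L)), 0L)
})

test_that("IR scanning is strand-symmetric", {
  set.seed(73)
  s <- rand_dna(300, gc = 0.4)
  a <- find_inverted_repeats(s)
  b <- find_inverted_repeats(revcomp(s))
  n <- nchar(s)
  mirrored <- tibble::tibble(start = n - b$end, end = n - b$start,
                             arm_len = b$arm_len, spacer_len = b$spacer_len)
  mirrored <- mirrored[order(mirrored$start, mirrored$end), ]
  a2 <- a[order(a$start, a$end), c("start", "end", "arm_len", "spacer_len")]
  expect_equal(as.data.frame(a2), as.data.frame(mirrored),
               ignore_attr = TRUE)
})

test_that("tandem repeats recover the printed heptamer array", {
  # G/C flanks cannot extend an A/T-only array
  s <- paste0(strrep("GC", 25), strrep("AATAAAT", 8), "AATAA",
              strrep("CG", 25))
  tr <- find_tandem_repeats(s)
  hit <- tr[tr$period == 7L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$consensus, "AATAAAT")
  expect_equal(hit$copy_number, 61 / 7, tolerance = 0.001)

  di <- find_tandem_repeats("ATATATATATATATATATAT")
  expect_equal(di$period, 2L)
  expect_equal(di$copy_number, 10)
})

test_that("perfect repeats of periods 3-10 give exact fractional copies", {
  set.seed(75)
  for (p in 3:10) {
    # A/T-only unit between G/C flanks so the array cannot extend
    unit <- paste(sample(c("A", "T"), p, TRUE), collapse = "")
    copies <- 4L
    extra <- max(1L, p %/% 2L)
    s <- paste0(strrep("G", 30), strrep(unit, copies),
                substr(unit, 1, extra), strrep("C", 30))
    tr <- find_tandem_repeats(s, min_copies = 1.9, max_period = 15L)
    hit <- tr[tr$period == p, ]
    if (nrow(hit) == 1L) {
      expect_equal(hit$copy_number, copies + extra / p, tolerance = 1e-9)
      expect_equal(hit$consensus, unit)
    } else {
      # a rotation of the unit may itself be periodic; accept the
      # equivalent shorter-period call covering the same span
      expect_gte(nrow(tr), 1L)
    }
  }
})

test_that("Z-DNA, G4 and A-phased scanners match their definitions", {
  z <- find_zdna("GCGCGCGCGCGC")
  expect_equal(nrow(z), 1L)
  expect_equal(z$end - z$start, 12L)
  expect_equal(nrow(find_zdna("GCGCGCGCGC")), 0L) # below min_len

  g <- find_g4("GGGTTAGGGTTAGGGTTAGGG")
  expect_equal(nrow(g), 1L)
  expect_equal(g$start, 0L)
  expect_equal(g$end, 21L)
  # strand symmetry: the complement strand carries the same motif
  g2 <- find_g4(revcomp("GGGTTAGGGTTAGGGTTAGGG"))
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$consensus, "-")
  expect_equal(g2$start, 0L)

  set.seed(76)
  ap <- find_aphased(paste0("G", strrep("AAAAGCGCGC", 3), "AAAA", "GG"))
  expect_equal(nrow(ap), 1L)
  expect_gte(ap$copy_number, 3)
  expect_equal(nrow(find_aphased(rand_dna(60, gc = 0.9))), 0L)
})

test_that("cruciform propensity is monotone in arm length and hand-summable", {
  tab <- nn_stacking_table()
  s_long <- "CCCCGGGGGGCCCCGGGG" # not used; construct matched IRs below
  arm10 <- "ACGTACGTAC"
  ir10 <- paste0(arm10, revcomp(arm10))
  arm6 <- substr(arm10, 1, 6)
  ir6 <- paste0(arm6, revcomp(arm6))
  m10 <- find_inverted_repeats(ir10, max_mismatch = 0)
  m6 <- find_inverted_repeats(ir6, max_mismatch = 0)
  m10 <- m10[which.max(m10$arm_len), ]
  m6 <- m6[which.max(m6$arm_len), ]
  expect_gte(cruciform_dG(m10, ir10), cruciform_dG(m6, ir6))

  # hand-summed oracle on a fixture IR: arm ACGT, spacer 2
  ir <- find_inverted_repeats("ACGTAAACGT", arm_range = c(4L, 4L),
                              max_spacer = 4L, max_mismatch = 0L)
  ir <- ir[ir$spacer_len == 2L, ][1, ]
  dg <- stats::setNames(tab$dg, tab$step)
  hand <- -(dg[["AC"]] + dg[["CG"]] + dg[["GT"]]) - (2.5 + 0.3 * 2)
  expect_equal(cruciform_dG(ir, "ACGTAAACGT"), unname(hand))

  bad <- find_tandem_repeats("ATATATAT")
  expect_error(cruciform_dG(bad[1, ], "ATATATAT"), "IR")
})

test_that("IR density peaks at the planted breakpoint cluster", {
  cfg <- sim_config(genome_length = 30000L, inversion_span = 8000L,
                    seed = 77L)
  anc <- simulate_ancestor(cfg)
  p <- cfg$inversion_pos
  region <- substr(anc$seq[[1]], p - 5000L, p + 5000L)
  irs <- find_inverted_repeats(region)
  census <- nonb_window_census(irs, nchar(region), window = 200L,
                               step = 50L)
  peak <- census[which.max(census$n), ]
  cluster_at <- 5000L - 150L # cluster sits just upstream of the break
  expect_lt(abs((peak$start + peak$end) / 2 - cluster_at), 400L)
})
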