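test_that("anchors on identical and reverse-complemented sequences", {
  set.seed(21)
  s <- rand_dna(1000)
  a <- find_anchors(s, s, k = 15)
  expect_true(all(a$orientation == "+"))
  expect_true(all(a$q_pos == a$t_pos))
  b <- find_anchors(revcomp(s), s, k = 15)
  expect_true(all(b$orientation == "-"))
  expect_true(all(b$q_pos + b$t_pos == 1000 - 15))
  expect_error(find_anchors(s, s, k = 9), "11")
})

test_that("anchor sets equal the brute-force double loop", {
  set.seed(22)
  for (rep in 1:6) {
    q <- rand_dna(300)
    # embed shared and inverted material plus an N patch
    t <- paste0(substr(q, 40, 160), rand_dna(60), revcomp(substr(q, 180, 260)),
                "NNNN", rand_dna(40))
    for (uniq in c(TRUE, FALSE)) {
      got <- as.data.frame(find_anchors(q, t, k = 12,
                                        unique_target = uniq))[
        , c("q_pos", "t_pos", "orientation")]
      want <- oracle_anchors(q, t, 12L, unique_target = uniq)
      rownames(got) <- rownames(want) <- NULL
      expect_identical(got, want)
    }
  }
})

test_that("chaining produces single blocks from clean diagonals", {
  set.seed(23)
  s <- rand_dna(3000)
  a <- find_anchors(s, s, k = 15)
  b <- chain_blocks(a)
  expect_equal(nrow(b), 1L)
  expect_equal(b$orientation, "+")
  expect_equal(b$q_start, 0L)
  expect_equal(b$q_end, 3000L)
})

test_that("interleaved diagonals within max_gap stay separate blocks", {
  # constructed anchor list: two + diagonals overlapping in query range
  anchors <- tibble::tibble(
    q_pos = rep(seq(0L, 900L, by = 100L), 2L),
    t_pos = c(seq(0L, 900L, by = 100L), seq(5000L, 5900L, by = 100L)),
    k = 15L, orientation = "+"
  )
  b <- chain_blocks(anchors, max_gap = 2000L, min_anchors = 3L)
  expect_equal(nrow(b), 2L)
  expect_equal(sum(b$n_anchors), nrow(anchors)) # no anchor used twice
})

test_that("a planted inversion yields the +,-,+ block pattern", {
  ds <- quick_sim("CUT_AND_PASTE", 31)
  a <- find_anchors(ds$seqs[ds$seqs$id == "inverted", ],
                    ds$seqs[ds$seqs$id == "uninverted_1", ])
  b <- chain_blocks(a)
  big <- b[b$q_end - b$q_start > 1000L, ]
  expect_equal(big$orientation[order(big$q_start)], c("+", "-", "+"))
  cand <- call_inversion_candidates(b)
  cand <- cand[which.max(cand$flipped_span), ]
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$flipped_span, 8000L, tolerance = 0.02)
})

test_that("candidate calling returns empty without an orientation flip", {
  set.seed(24)
  s <- rand_dna(5000)
  b <- chain_blocks(find_anchors(s, s))
  expect_equal(nrow(call_inversion_candidates(b)), 0L)
  expect_equal(nrow(call_inversion_candidates(b[0, ])), 0L)
})

test_that("swapping query and target mirrors the candidate intervals", {
  ds <- quick_sim("CUT_AND_PASTE", 33)
  inv <- ds$seqs[ds$seqs$id == "inverted", ]
  un <- ds$seqs[ds$seqs$id == "uninverted_1", ]
  c1 <- call_inversion_candidates(chain_blocks(find_anchors(inv, un)))
  c2 <- call_inversion_candidates(chain_blocks(find_anchors(un, inv)))
  c1 <- c1[which.max(c1$flipped_span), ]
  c2 <- c2[which.max(c2$flipped_span), ]
  expect_equal(c1$q_prox_start, c2$t_prox_start, tolerance = 1e-9)
  expect_equal(c1$t_dist_start, c2$q_dist_start, tolerance = 1e-9)
  expect_equal(c1$flipped_span, c2$flipped_span, tolerance = 0.01)
})

test_that("true breakpoints fall inside reported regions across mechanisms", {
  # reduced-replicate form of the recovery property at default k and
  # max_gap; the full-replicate rate is asserted in the acceptance suite
  mechs <- c("CUT_AND_PASTE", "NAHR", "STAGGERED_ISO", "CHROMOSOME",
             "BIR_MMBIR")
  hits <- 0L; total <- 0L
  for (i in seq_along(mechs)) {
    for (s in 1:4) {
      ds <- quick_sim(mechs[i], 100 + s)
      cand <- call_inversion_candidates(chain_blocks(find_anchors(
        ds$seqs[ds$seqs$id == "inverted", ],
        ds$seqs[ds$seqs$id == "uninverted_1", ]
      )))
      cand <- cand[which.max(cand$flipped_span), ]
      bp <- ds$truth$breakpoints
      p <- bp$pos[bp$assembly == "inverted" & bp$junction == "prox"]
      d <- bp$pos[bp$assembly == "inverted" & bp$junction == "dist"]
      total <- total + 1L
      slack <- 30L
      if (nrow(cand) == 1L &&
            p >= cand$q_prox_start - slack && p <= cand$q_prox_end + slack &&
            d >= cand$q_dist_start - slack && d <= cand$q_dist_end + slack) {
        hits <- hits + 1L
      }
    }
  }
  expect_gte(hits / total, 0.95)
})
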