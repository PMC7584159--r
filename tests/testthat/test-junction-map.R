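infer_map <- function(ds, pad = 1200L) {
  cand <- call_inversion_candidates(chain_blocks(find_anchors(
    ds$seqs[ds$seqs$id == "inverted", ],
    ds$seqs[ds$seqs$id == "uninverted_1", ]
  )))
  cand <- cand[which.max(cand$flipped_span), ]
  demarcate_segments(ds$seqs, cand, pad = pad)
}

test_that("clean-cut junctions are localized to within one base pair", {
  for (s in c(3, 14, 27)) {
    ds <- quick_sim("CUT_AND_PASTE", s)
    map <- infer_map(ds)
    bp <- ds$truth$breakpoints
    jt <- map$junctions
    expect_true(all(jt$resolved))
    expect_equal(nrow(map$unassigned), 0L)
    for (j in c("prox", "dist")) {
      tpos <- bp$pos[bp$assembly == "inverted" & bp$junction == j]
      row <- jt[jt$junction == paste0("inv_", j), ]
      expect_lte(max(abs(c(row$lo, row$hi) - tpos)), 1L)
    }
    # uninverted junctions recovered as well
    expect_lte(abs(jt$pos[jt$junction == "uninv_prox"] -
                     bp$pos[bp$assembly == "uninverted_1" &
                              bp$junction == "prox"]), 1L)
  }
})

test_that("staggered junctions land within the fill-in length and the
           complex insertion is cataloged as unassigned", {
  ds <- quick_sim("STAGGERED_ISO", 8)
  map <- infer_map(ds)
  bp <- ds$truth$breakpoints
  jt <- map$junctions
  for (j in c("prox", "dist")) {
    tpos <- bp$pos[bp$assembly == "inverted" & bp$junction == j]
    row <- jt[jt$junction == paste0("inv_", j), ]
    expect_lte(min(abs(c(row$lo, row$hi) - tpos)), 534L + 59L)
  }

  cfg <- o7_sim_config(genome_length = 40000L, seed = 8L)
  dso <- simulate_dataset(cfg)
  mo <- infer_map(dso, pad = 1500L)
  una <- mo$unassigned[mo$unassigned$name == "unassigned_prox", ]
  ins <- dso$truth$insertion
  expect_equal(nrow(una), 1L)
  # the R1-2 direct repeat of the upstream flank makes the insertion start
  # ambiguous by up to its own length; the remainder must be covered
  expect_lte(una$start, ins$start + 153L + 2L)
  expect_gte(una$end, ins$end - 2L)
})

test_that("junction positions are invariant to padding the regions", {
  ds <- quick_sim("CUT_AND_PASTE", 19)
  m1 <- infer_map(ds, pad = 1200L)
  m2 <- infer_map(ds, pad = 2200L)
  j1 <- m1$junctions[m1$junctions$assembly == "inverted", c("junction", "pos")]
  j2 <- m2$junctions[m2$junctions$assembly == "inverted", c("junction", "pos")]
  expect_equal(j1, j2)
})

test_that("segments plus unassigned tile each analyzed junction region", {
  for (mech in c("CUT_AND_PASTE", "STAGGERED_ISO", "BIR_MMBIR")) {
    ds <- quick_sim(mech, 12)
    map <- infer_map(ds)
    segs <- map$segments[map$segments$assembly == "inverted", ]
    for (reg in list(map$regions$inv_prox, map$regions$inv_dist)) {
      parts <- dplyr::bind_rows(
        segs[segs$start >= reg[1] & segs$end <= reg[2], c("start", "end")],
        map$unassigned[map$unassigned$start >= reg[1] &
                         map$unassigned$end <= reg[2], c("start", "end")]
      )
      parts <- parts[order(parts$start), ]
      expect_equal(parts$start[1], reg[1])
      expect_equal(parts$end[nrow(parts)], reg[2])
      expect_true(all(parts$start[-1] == parts$end[-nrow(parts)]))
    }
  }
})

test_that("the second homology pass relabels planted duplication copies", {
  cfg <- o7_sim_config(genome_length = 40000L, seed = 10L)
  ds <- simulate_dataset(cfg)
  map <- second_pass_homology(infer_map(ds, pad = 1500L), ds$seqs)
  hom <- map$homologies
  expect_gt(nrow(hom), 0L)
  tr <- ds$truth$duplications
  d2 <- tr[tr$name == "d2", ]
  # the d2A copy inside the unassigned insertion hits its parent material:
  # the part beyond the insertion as a long match into the resumed flank,
  # the part inside it as a self-match to the insertion tail
  over <- hom[hom$q_end > d2$a_start & hom$q_start < d2$a_end, ]
  expect_true(any(over$length >= 390L & over$orientation == "+"))
  covered <- sum(pmin(over$q_end, d2$a_end) - pmax(over$q_start, d2$a_start))
  expect_gte(covered, d2$a_end - d2$a_start - 20L)
})

test_that("two unassigned copies of each other are cross-linked", {
  set.seed(17)
  shared <- rand_dna(40)
  u1 <- paste0(rand_dna(10), shared, rand_dna(10))
  u2 <- paste0(rand_dna(12), shared, rand_dna(8))
  inv <- paste0(rand_dna(200), u1, rand_dna(200), u2, rand_dna(100))
  seqs <- labeled_seq(c("inverted", "uninverted_1"),
                      c(inv, rand_dna(nchar(inv))))
  map <- structure(list(
    segments = tibble::tibble(assembly = character(), segment = character(),
                              start = integer(), end = integer(),
                              strand = character()),
    unassigned = tibble::tibble(
      seq_id = "inverted", start = c(200L, 460L), end = c(260L, 520L),
      strand = "+", name = c("unassigned_prox", "unassigned_dist"),
      seq = c(u1, u2)
    ),
    junctions = NULL, regions = NULL,
    inv_id = "inverted", uninv_id = "uninverted_1"
  ), class = "segment_map")
  map <- second_pass_homology(map, seqs)
  hom <- map$homologies
  link <- hom[hom$query == "unassigned_prox" &
                hom$parent == "unassigned_dist", ]
  expect_gte(nrow(link), 1L)
  expect_equal(link$orientation[1], "+")
  expect_gte(link$length[1], 40L)
})

test_that("random unassigned sequence stays unassigned in the second pass", {
  ds <- quick_sim("BIR_MMBIR", 15)
  map <- second_pass_homology(infer_map(ds), ds$seqs)
  una <- map$unassigned[map$unassigned$name == "unassigned_dist", ]
  # the filler is homologous to nothing at duplication scale
  if (nrow(una) == 1L) {
    hits <- map$homologies[map$homologies$query == "unassigned_dist", ]
    expect_equal(nrow(hits), 0L)
  }
})
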