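test_that("the ancestor simulator is seed-deterministic and hits target GC", {
  cfg <- sim_config(genome_length = 100000L, seed = 1L,
                    plant_nonb_cluster = FALSE)
  a1 <- simulate_ancestor(cfg)
  a2 <- simulate_ancestor(cfg)
  expect_identical(a1$seq, a2$seq)
  expect_lt(abs(gc_content(a1$seq) - 0.438), 0.01)

  cfg0 <- sim_config(genome_length = 5000L, gc_content = 0,
                     inversion_span = 1000L, seed = 2L,
                     plant_nonb_cluster = FALSE)
  expect_false(grepl("[GC]", simulate_ancestor(cfg0)$seq[[1]]))
})

test_that("configuration validation rejects inconsistent setups", {
  expect_error(sim_config(genome_length = 1000L, inversion_span = 2000L),
               "inside the genome")
  expect_error(sim_config(line_divergence = 0.5), "divergences")
  expect_error(sim_config(mechanism = "CUT_AND_PASTE",
                          complex_proximal = TRUE), "staggered")
  expect_error(sim_config(mechanism = "CHROMOSOME",
                          spacer_haplotypes = "+"), "haplotypes")
})

test_that("sequence length bookkeeping matches each mechanism", {
  n <- 30000L
  ds <- quick_sim("CUT_AND_PASTE", 3)
  expect_equal(nchar(ds$seqs$seq[ds$seqs$id == "inverted"]), n)
  expect_equal(nrow(ds$truth$duplications), 0L)

  cfg <- sim_config(mechanism = "STAGGERED_ISO", genome_length = n,
                    inversion_span = 8000L, seed = 3L)
  dst <- simulate_dataset(cfg)
  expect_equal(nchar(dst$seqs$seq[dst$seqs$id == "inverted"]),
               n + cfg$d1_len + cfg$d2a_len)

  dsc <- quick_sim("CHROMOSOME", 3)
  expect_equal(nchar(dsc$seqs$seq[dsc$seqs$id == "inverted"]),
               n - 100L) # central deletion, no filler

  dsb <- quick_sim("BIR_MMBIR", 3)
  expect_equal(nchar(dsb$seqs$seq[dsb$seqs$id == "inverted"]),
               n + 59L + 534L + 21L) # fill-ins plus filler
})

test_that("the inverted line matches line 1 outside the rearranged region", {
  ds <- quick_sim("CUT_AND_PASTE", 5)
  inv <- ds$seqs$seq[ds$seqs$id == "inverted"]
  un1 <- ds$seqs$seq[ds$seqs$id == "uninverted_1"]
  bp <- ds$truth$breakpoints
  p <- bp$pos[bp$assembly == "inverted" & bp$junction == "prox"]
  a_inv <- substr(inv, 1, p)
  a_un <- substr(un1, 1, p)
  mism <- mapply(function(x, y) x != y,
                 strsplit(a_inv, "")[[1]], strsplit(a_un, "")[[1]])
  # two independent draws of 0.5% divergence
  expect_lt(mean(mism), 0.03)
  expect_gt(mean(mism), 0.0005)
})

test_that("planted duplication copies are reverse complements before divergence", {
  cfg <- sim_config(mechanism = "STAGGERED_ISO", genome_length = 30000L,
                    inversion_span = 8000L, seed = 9L,
                    line_divergence = 0, outgroup_divergence = 0)
  ds <- simulate_dataset(cfg)
  inv <- ds$seqs$seq[ds$seqs$id == "inverted"]
  d <- ds$truth$duplications
  for (i in seq_len(nrow(d))) {
    a <- substr(inv, d$a_start[i] + 1L, d$a_end[i])
    b <- substr(inv, d$b_start[i] + 1L, d$b_end[i])
    if (d$orientation[i] == "inverted") b <- revcomp(b)
    expect_identical(a, b)
  }
})

test_that("the complex proximal layout reproduces the printed arithmetic", {
  cfg <- o7_sim_config(genome_length = 40000L, seed = 4L)
  ds <- simulate_dataset(cfg)
  tr <- ds$truth
  mi <- tr$microinversion
  expect_equal(mi$end - mi$start, 2026L) # 59 + 534 + 1374 + 59
  ins <- tr$insertion
  expect_equal(ins$end - ins$start, 2445L)
  expect_equal(tr$microhomology$length, 8L)
  expect_equal(tr$microhomology$mismatches, 1L)
  expect_equal(nchar(tr$filler), 21L)
})

test_that("the BIR/MMBIR filler carries the configured microhomology", {
  cfg <- sim_config(mechanism = "BIR_MMBIR", genome_length = 30000L,
                    inversion_span = 8000L, seed = 6L,
                    line_divergence = 0, outgroup_divergence = 0)
  ds <- simulate_dataset(cfg)
  inv <- ds$seqs$seq[ds$seqs$id == "inverted"]
  bp <- ds$truth$breakpoints
  jd <- bp$pos[bp$assembly == "inverted" & bp$junction == "dist"]
  filler <- substr(inv, jd + 1L, jd + 21L)
  expect_identical(filler, ds$truth$filler)
  flank <- substr(inv, jd + 22L, jd + 29L)
  mh <- substr(filler, 14L, 21L)
  mism <- sum(strsplit(mh, "")[[1]] != strsplit(flank, "")[[1]])
  expect_equal(mism, 1L)
})

test_that("emitted datasets are complete and byte-reproducible", {
  cfg <- sim_config(genome_length = 20000L, inversion_span = 5000L,
                    seed = 8L, distal_chromosome = FALSE)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_dataset(cfg, d1, force = TRUE)
  emit_dataset(cfg, d2, force = TRUE)
  expect_length(dir(d1), 6L)
  expect_identical(readLines(file.path(d1, "truth.txt")),
                   readLines(file.path(d2, "truth.txt")))
  expect_identical(readLines(file.path(d1, "inverted.fasta")),
                   readLines(file.path(d2, "inverted.fasta")))
  expect_error(emit_dataset(cfg, d1), "force")
  cfg2 <- sim_config(genome_length = 20000L, inversion_span = 5000L,
                     seed = 9L, distal_chromosome = FALSE)
  emit_dataset(cfg2, d2, force = TRUE)
  expect_false(identical(readLines(file.path(d1, "inverted.fasta")),
                         readLines(file.path(d2, "inverted.fasta"))))
})
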