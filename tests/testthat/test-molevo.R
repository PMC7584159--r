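test_that("identity excluding indels counts only non-gap columns", {
  expect_equal(identity_excluding_indels(c("ACGTACGTAC", "ACGTACGTAC")), 1)
  # 9 matches, 1 mismatch, 5 gap columns
  x <- paste0("ACGTACGTAC", "-----")
  y <- paste0("ACGTACGTAA", "GGGGG")
  expect_equal(identity_excluding_indels(c(x, y)), 0.9)
  expect_warning(v <- identity_excluding_indels(c("---", "---")), "undefined")
  expect_true(is.na(v))

  set.seed(91)
  for (i in 1:5) {
    a <- strsplit(rand_dna(120), "")[[1]]
    b <- strsplit(rand_dna(120), "")[[1]]
    gap <- sample(120, 12)
    a[gap[1:6]] <- "-"; b[gap[7:12]] <- "-"
    keep <- a != "-" & b != "-"
    direct <- mean(a[keep] == b[keep])
    expect_equal(identity_excluding_indels(c(paste(a, collapse = ""),
                                             paste(b, collapse = ""))),
                 direct)
  }
})

test_that("the relative-rate test matches its closed form", {
  anc <- strrep("ACGT", 50)
  expect_equal(tajima_rrt(anc, anc, anc)$p, 1)

  # m1 = 10, m2 = 2 by construction
  a <- strsplit(anc, "")[[1]]; b <- a; o <- a
  flip <- function(ch) chartr("ACGT", "CGTA", ch)
  a[1:10] <- vapply(a[1:10], flip, "")
  b[51:52] <- vapply(b[51:52], flip, "")
  r <- tajima_rrt(paste(a, collapse = ""), paste(b, collapse = ""),
                  paste(o, collapse = ""))
  expect_equal(r$m1, 10L)
  expect_equal(r$m2, 2L)
  expect_equal(r$chi2, 64 / 12)
  expect_equal(r$p, stats::pchisq(64 / 12, 1, lower.tail = FALSE))

  # permuting the ingroup sequences swaps counts, p unchanged
  r2 <- tajima_rrt(paste(b, collapse = ""), paste(a, collapse = ""),
                   paste(o, collapse = ""))
  expect_equal(r2$m1, r$m2)
  expect_equal(r2$p, r$p)
  expect_error(tajima_rrt("----", "----", "----"), "unambiguous")

  td <- tidy(r)
  expect_equal(td$statistic, r$chi2)
  expect_equal(td$p.value, r$p)
})

test_that("null relative-rate p-values are uniform", {
  set.seed(92)
  ps <- replicate(400, {
    anc <- strsplit(rand_dna(400), "")[[1]]
    mut <- function(v, d) {
      hit <- which(stats::runif(length(v)) < d)
      v[hit] <- vapply(v[hit], function(ch)
        sample(setdiff(c("A", "C", "G", "T"), ch), 1), "")
      paste(v, collapse = "")
    }
    tajima_rrt(mut(anc, 0.03), mut(anc, 0.03), mut(anc, 0.1))$p
  })
  # chi-square p-values are discrete at small counts; compare the CDF at
  # fixed points with a generous binomial band rather than exact KS
  for (q in c(0.2, 0.5, 0.8)) {
    expect_lt(abs(mean(ps <= q) - q), 4 * sqrt(q * (1 - q) / 400) + 0.05)
  }
})

test_that("Nc spans its bounds and matches the family-by-family oracle", {
  # maximal bias: every amino acid used through a single codon
  one_each <- c("TTT", "TAT", "TGT", "CAT", "CAA", "AAT", "AAA", "GAT",
                "GAA", "ATT", "GTT", "CCT", "ACT", "GCT", "GGT", "TTA",
                "TCT", "CGT")
  biased <- paste(rep(one_each, 20), collapse = "")
  expect_equal(effective_number_of_codons(biased, "wright")$nc, 20)

  # uniform synonymous usage at large n approaches 61
  fams <- list(
    c("TTT", "TTC"), c("TAT", "TAC"), c("TGT", "TGC"), c("CAT", "CAC"),
    c("CAA", "CAG"), c("AAT", "AAC"), c("AAA", "AAG"), c("GAT", "GAC"),
    c("GAA", "GAG"), c("ATT", "ATC", "ATA"),
    c("GTT", "GTC", "GTA", "GTG"), c("CCT", "CCC", "CCA", "CCG"),
    c("ACT", "ACC", "ACA", "ACG"), c("GCT", "GCC", "GCA", "GCG"),
    c("GGT", "GGC", "GGA", "GGG"),
    c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
    c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
    c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG")
  )
  uniform <- paste(unlist(lapply(fams, function(f) rep(f, 40))),
                   collapse = "")
  expect_gt(effective_number_of_codons(uniform, "wright")$nc, 60)

  set.seed(93)
  cods <- unlist(lapply(fams, function(f)
    sample(f, 17, TRUE, prob = seq_along(f))))
  cds <- paste(sample(cods), collapse = "")
  got <- effective_number_of_codons(cds, "wright")$nc
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  expect_equal(got, oracle_nc_wright(codons), tolerance = 1e-9)

  expect_error(effective_number_of_codons("GCTTAAGCT"), "stop")
  expect_error(effective_number_of_codons("GCTA"), "divisible")
})

test_that("Nc is invariant to synonymous-preserving codon order shuffles", {
  set.seed(94)
  cods <- c(rep("GCT", 10), rep("GCC", 3), rep("AAA", 8), rep("AAG", 8),
            rep("TTT", 4), rep("CTG", 9), rep("CTA", 2))
  nc1 <- effective_number_of_codons(paste(cods, collapse = ""))$nc
  nc2 <- effective_number_of_codons(paste(sample(cods), collapse = ""))$nc
  expect_equal(nc1, nc2)
})

test_that("concerted and escaped paralog patterns are classified", {
  labs <- c("sp1_a", "sp1_b", "sp2_a", "sp2_b")
  species <- c("sp1", "sp1", "sp2", "sp2")
  m <- matrix(0.05, 4, 4, dimnames = list(labs, labs))
  diag(m) <- 0
  m["sp1_a", "sp1_b"] <- m["sp1_b", "sp1_a"] <- 0.01
  m["sp2_a", "sp2_b"] <- m["sp2_b", "sp2_a"] <- 0.01
  expect_equal(concerted_pattern(m, species)$pattern, "concerted")

  all_eq <- matrix(0.05, 4, 4, dimnames = list(labs, labs)); diag(all_eq) <- 0
  expect_equal(concerted_pattern(all_eq, species)$pattern, "undetermined")

  # a relocated, accelerated copy: larger distance to every other sequence
  esc <- m
  esc["sp1_b", ] <- esc[, "sp1_b"] <- 0.2
  esc["sp1_b", "sp1_b"] <- 0
  r <- concerted_pattern(esc, species)
  expect_equal(r$pattern, "escaped")
  expect_equal(r$escaped, "sp1_b")
})
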