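# Mechanism-aware simulator of inversion formation.
#
# The uninverted arrangement is +A +B +C +D (junctions +A|+B proximal,
# +C|+D distal); the inverted arrangement is +A -C -B +D.  Inverting the
# middle block B+C therefore sends material from just downstream of the
# proximal break to the distal junction (-B end) and material from just
# upstream of the distal break to the proximal junction (-C start).  All
# truth coordinates are emitted in the coordinates of the assembly that
# carries the feature, 0-based half-open.

MECHANISMS <- c("NAHR", "CUT_AND_PASTE", "STAGGERED_ISO",
                "STAGGERED_CHROMATID", "CHROMOSOME", "BIR_MMBIR")

#' Simulation configuration
#'
#' Assembles and validates the parameter set for one simulated inversion
#' dataset. Component-length defaults follow the dissected junction of the
#' *D. subobscura* O7 inversion: a 2,445-bp proximal insertion opening with
#' a 153-bp direct repeat of the upstream flank (R1-2), inverted
#' duplications d1 (59 bp) and d2 (534/540 bp) separated by a 1,374-bp
#' intervening sequence (microinversion span 2,026 bp), a distal spacer
#' flanked by long inverted repeats with a central deletion (dd7), and a
#' 21-nt junction filler with 8 bp of microhomology to the +D end.
#'
#' @param genome_length Chromosome length in bp.
#' @param gc_content Target GC fraction of the background sequence.
#' @param inversion_span Length of the inverted segment in bp.
#' @param inversion_pos 0-based proximal breakpoint; default 35% of the
#'   genome.
#' @param mechanism One of `"NAHR"`, `"CUT_AND_PASTE"`, `"STAGGERED_ISO"`,
#'   `"STAGGERED_CHROMATID"`, `"CHROMOSOME"`, `"BIR_MMBIR"`.
#' @param complex_proximal Plant the full R1-2/d1/d2/microinversion layout
#'   at the proximal junction (staggered and BIR mechanisms only).
#' @param distal_chromosome Use the in-trans (chromosome-model) distal
#'   junction even when `mechanism` is a staggered variant; this is how the
#'   mixed proximal-staggered / distal-chromosome configuration is requested.
#' @param r12_len,d1_len,d2a_len,d2b_len Component lengths in bp.
#' @param d2b_split Two integers: how much of the d2B copy lies inside the
#'   proximal insertion versus in the resumed-homology flank. Exposed as a
#'   parameter because the printed flank extension (409 bp) plus the printed
#'   insertion remainder do not uniquely partition d2B.
#' @param intervening_len Length of the sequence between the d1A/d2A and
#'   d1B/d2B copies.
#' @param ins_gaps Four spacer lengths between insertion elements
#'   (R1-2 | g1 | d1A | g2 | d2A | g3 | intervening | g4 | d1B); the default
#'   `c(135, 0, 0, 0)` reproduces both the 2,445-bp insertion total and the
#'   2,026-bp microinversion span.
#' @param nahr_repeat_len Arm length of the breakpoint-flanking inverted
#'   repeat recombined under NAHR.
#' @param spacer_len,dd7_len Distal spacer length and central-deletion
#'   length (chromosome model); `spacer_len - dd7_len` is the inverted
#'   line's residual spacer.
#' @param ir1_len,ir2_len Lengths of the long inverted repeats flanking the
#'   distal spacer.
#' @param spacer_haplotypes Orientation of the spacer in the two uninverted
#'   lines (`"-"` = reversed, ch-cu-like; `"+"` = ancestral, B-like).
#' @param filler `NULL`, a DNA string, or an integer length. `NA` (default)
#'   means mechanism-dependent: a filler is planted for `BIR_MMBIR` only.
#' @param microhomology_len,microhomology_mismatch Length of the filler
#'   substring templated from the +D end, and the number of mismatches
#'   introduced into it.
#' @param line_divergence,outgroup_divergence Per-site substitution
#'   probabilities applied independently to each conspecific line and to the
#'   outgroup.
#' @param plant_nonb_cluster Overwrite the 150 bp upstream of the proximal
#'   break with an AT-rich cluster of non-B motifs (inverted repeat, tandem
#'   heptamer, mirror repeat), emulating the repeat-rich breakpoint
#'   neighborhood.
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(genome_length = 100000L,
                       gc_content = 0.438,
                       inversion_span = 10000L,
                       inversion_pos = NULL,
                       mechanism = "STAGGERED_ISO",
                       complex_proximal = FALSE,
                       distal_chromosome = NULL,
                       r12_len = 153L,
                       d1_len = 59L,
                       d2a_len = 534L,
                       d2b_len = 540L,
                       d2b_split = c(131L, 409L),
                       intervening_len = 1374L,
                       ins_gaps = c(135L, 0L, 0L, 0L),
                       nahr_repeat_len = 300L,
                       spacer_len = 350L,
                       dd7_len = 100L,
                       ir1_len = 1117L,
                       ir2_len = 1112L,
                       spacer_haplotypes = c("-", "+"),
                       filler = NA,
                       filler_template = NA,
                       microhomology_len = 8L,
                       microhomology_mismatch = 1L,
                       line_divergence = 0.005,
                       outgroup_divergence = 0.05,
                       plant_nonb_cluster = TRUE,
                       seed = 1L) {
  mechanism <- match.arg(mechanism, MECHANISMS)
  if (is.null(inversion_pos)) inversion_pos <- as.integer(floor(0.35 * genome_length))
  if (is.null(distal_chromosome)) distal_chromosome <- mechanism == "CHROMOSOME"
  if (mechanism == "CHROMOSOME" && !distal_chromosome) {
    abort("the CHROMOSOME mechanism requires its distal junction model")
  }
  if (complex_proximal && mechanism %in% c("NAHR", "CUT_AND_PASTE")) {
    abort("complex_proximal requires a staggered or BIR/MMBIR mechanism")
  }
  if (distal_chromosome && length(spacer_haplotypes) != 2L) {
    abort("the chromosome model needs two spacer haplotypes")
  }
  if (inversion_span <= 0 || inversion_pos <= 0 ||
      inversion_pos + inversion_span >= genome_length) {
    abort("inversion must lie strictly inside the genome")
  }
  if (line_divergence < 0 || line_divergence > 0.2 ||
      outgroup_divergence < 0 || outgroup_divergence > 0.2) {
    abort("divergences must lie in [0, 0.2]")
  }
  if (sum(d2b_split) != d2b_len) abort("d2b_split must sum to d2b_len")
  cfg <- list(
    genome_length = as.integer(genome_length), gc_content = gc_content,
    inversion_span = as.integer(inversion_span),
    inversion_pos = as.integer(inversion_pos),
    mechanism = mechanism, complex_proximal = complex_proximal,
    distal_chromosome = distal_chromosome,
    r12_len = as.integer(r12_len), d1_len = as.integer(d1_len),
    d2a_len = as.integer(d2a_len), d2b_len = as.integer(d2b_len),
    d2b_split = as.integer(d2b_split),
    intervening_len = as.integer(intervening_len),
    ins_gaps = as.integer(ins_gaps),
    nahr_repeat_len = as.integer(nahr_repeat_len),
    spacer_len = as.integer(spacer_len), dd7_len = as.integer(dd7_len),
    ir1_len = as.integer(ir1_len), ir2_len = as.integer(ir2_len),
    spacer_haplotypes = spacer_haplotypes,
    filler = filler, filler_template = filler_template,
    microhomology_len = as.integer(microhomology_len),
    microhomology_mismatch = as.integer(microhomology_mismatch),
    line_divergence = line_divergence,
    outgroup_divergence = outgroup_divergence,
    plant_nonb_cluster = plant_nonb_cluster,
    seed = as.integer(seed)
  )
  # features planted around the breaks must fit inside the genome
  need <- inversion_pos + inversion_span +
    (if (distal_chromosome) spacer_len / 2 + ir2_len else d2a_len) + 10L
  if (need >= genome_length) abort("genome_length too small for the planted features")
  structure(cfg, class = "sim_config")
}

#' O7-parameter simulation configuration
#'
#' The demonstration configuration that reproduces the published junction
#' layout: staggered proximal breakpoint carrying the full complex insertion,
#' in-trans (chromosome-model) distal junction with mosaic spacer and
#' central deletion, and the printed 21-nt filler whose final 8 bp match the
#' +D start (`CATCAAAG`) with one mismatch.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `"sim_config"` object.
#' @export
o7_sim_config <- function(...) {
  sim_config(
    mechanism = "STAGGERED_ISO", complex_proximal = TRUE,
    distal_chromosome = TRUE, filler = "GAGCACTCTCCACAGCAAAGT",
    filler_template = "CATCAAAG", ...
  )
}

random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# substitute each site independently with probability d (always to a
# different base); returns the mutated string
mutate_seq <- function(s, d) {
  if (d <= 0) return(s)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(x)) < d)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      alt <- bases[bases != x[i]]
      x[i] <- alt[sample.int(3L, 1L)]
    }
  }
  paste(x, collapse = "")
}

substr_put <- function(s, at, piece) {
  # overwrite s starting at 0-based position `at`
  paste0(substr(s, 1L, at), piece, substr(s, at + nchar(piece) + 1L, nchar(s)))
}

# 150-bp AT-rich cluster: tandem heptamer (9 copies), the perfect 12-bp
# hairpin arm, an 11-nt mirror repeat with a 30-nt spacer, (ATTT)n padding
nonb_cluster <- function() {
  arm <- "ATTACTTTATA"
  mirror <- paste0(arm, strrep("AT", 15L), paste(rev(strsplit(arm, "")[[1]]), collapse = ""))
  s <- paste0(strrep("AATAAAT", 9L), "AATTTTAAAATT", mirror, strrep("ATTT", 6L))
  substr(s, 1L, 150L)
}

#' Simulate the ancestral chromosome
#'
#' Draws an i.i.d. background sequence at the requested GC content and
#' plants the mechanism-specific features the breakage models operate on:
#' an inverted-repeat pair at the future breakpoints (NAHR), the long
#' inverted repeats flanking the future distal spacer (chromosome model),
#' and optionally an AT-rich non-B motif cluster abutting the proximal
#' break. Deterministic for a fixed `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A one-row labeled-sequence tibble (id `"ancestor"`).
#' @export
simulate_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$genome_length
  s <- random_dna(n, config$gc_content)
  P <- config$inversion_pos
  D <- P + config$inversion_span
  if (config$plant_nonb_cluster && P >= 160L) {
    s <- substr_put(s, P - 150L, nonb_cluster())
  }
  if (config$mechanism == "NAHR") {
    arm <- random_dna(config$nahr_repeat_len, config$gc_content)
    s <- substr_put(s, P, arm)
    s <- substr_put(s, D - nchar(arm), revcomp(arm))
  }
  if (config$distal_chromosome) {
    ir1 <- random_dna(config$ir1_len, config$gc_content)
    spacer <- random_dna(config$spacer_len, 0.35) # AT-leaning, like the region
    sp_s <- D - config$spacer_len %/% 2L
    s <- substr_put(s, sp_s - config$ir1_len, ir1)
    s <- substr_put(s, sp_s, spacer)
    s <- substr_put(s, sp_s + config$spacer_len,
                    substr(revcomp(ir1), 1L, config$ir2_len))
  }
  labeled_seq("ancestor", s)
}

# introduce exactly k mismatches into a string at random positions
mismatch_seq <- function(s, k) {
  if (k <= 0L) return(s)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(x), k)
  bases <- c("A", "C", "G", "T")
  for (i in pos) x[i] <- bases[bases != x[i]][sample.int(3L, 1L)]
  paste(x, collapse = "")
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

char_at <- function(s, i) substr(s, i + 1L, i + 1L) # 0-based

# Break chance homology extensions at the flanks of planted duplication
# copies (see apply_mechanism). For each pair end, the flank base that lies
# outside every planted copy is substituted when it would extend the match.
enforce_dup_maximality <- function(s, dups) {
  if (nrow(dups) == 0L) return(s)
  n <- nchar(s)
  inside <- function(p) {
    any(p >= dups$a_start & p < dups$a_end) ||
      any(p >= dups$b_start & p < dups$b_end)
  }
  break_match <- function(s, pa, pb, complement_b) {
    # comparison: s[pa] vs (comp?) s[pb]; mutate whichever is free
    if (pa < 0L || pb < 0L || pa >= n || pb >= n) return(s)
    va <- char_at(s, pa)
    vb <- char_at(s, pb)
    if (complement_b) vb <- comp_base(vb)
    if (va != vb || va == "N") return(s)
    if (!inside(pa)) {
      repl <- setdiff(c("A", "C", "G", "T"), vb)[[1]]
      s <- substr_put(s, pa, repl)
    } else if (!inside(pb)) {
      target <- if (complement_b) comp_base(va) else va
      repl <- setdiff(c("A", "C", "G", "T"), target)[[1]]
      s <- substr_put(s, pb, repl)
    }
    s
  }
  for (i in seq_len(nrow(dups))) {
    d <- dups[i, ]
    if (d$orientation == "direct") {
      s <- break_match(s, d$a_start - 1L, d$b_start - 1L, FALSE)
      s <- break_match(s, d$a_end, d$b_end, FALSE)
    } else {
      s <- break_match(s, d$a_start - 1L, d$b_end, TRUE)
      s <- break_match(s, d$a_end, d$b_start - 1L, TRUE)
    }
  }
  s
}

# piece-wise assembly keeps truth coordinates honest: `pieces` is a named
# character vector; returns list(seq, offsets tibble)
assemble_pieces <- function(pieces) {
  lens <- nchar(pieces)
  ends <- cumsum(lens)
  starts <- ends - lens
  list(
    seq = paste(pieces, collapse = ""),
    map = tibble(piece = names(pieces), start = as.integer(starts),
                 end = as.integer(ends))
  )
}

piece_iv <- function(map, name) {
  r <- map[map$piece == name, ]
  c(start = r$start[[1]], end = r$end[[1]])
}

#' Apply an inversion-formation mechanism
#'
#' Rearranges the ancestor into the inverted chromosome under the requested
#' mechanism, builds the two uninverted lines and the outgroup, applies
#' per-line divergence, and records the machine-readable ground truth
#' (breakpoints, duplication pairs, microinversion, central deletion,
#' spacer mosaic, filler and microhomology) in the coordinates of the
#' assemblies that carry each feature.
#'
#' @param ancestor Labeled-sequence tibble from [simulate_ancestor()].
#' @param config The same [sim_config()] object.
#' @return A list with elements `seqs` (labeled-sequence tibble with ids
#'   `inverted`, `uninverted_1`, `uninverted_2`, `outgroup`) and `truth`
#'   (class `"sim_truth"`).
#' @export
apply_mechanism <- function(ancestor, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  anc <- ancestor$seq[[1]]
  n <- nchar(anc)
  P <- config$inversion_pos
  D <- P + config$inversion_span
  mech <- config$mechanism
  sub0 <- function(s, a, b) substr(s, a + 1L, b) # 0-based half-open helper

  dups <- tibble(name = character(), a_start = integer(), a_end = integer(),
                 b_start = integer(), b_end = integer(),
                 orientation = character(), present_in = character())
  add_dup <- function(name, a, b, orientation, present_in) {
    dups <<- dplyr::bind_rows(dups, tibble(
      name = name, a_start = as.integer(a[1]), a_end = as.integer(a[2]),
      b_start = as.integer(b[1]), b_end = as.integer(b[2]),
      orientation = orientation, present_in = present_in
    ))
  }

  want_filler <- if (identical(config$filler, NA)) mech == "BIR_MMBIR" else
    !is.null(config$filler) && !identical(config$filler, 0L)
  tpl <- if (is.character(config$filler_template) &&
               !is.na(config$filler_template)) {
    toupper(config$filler_template)
  } else NULL
  # an explicit +D-start template (e.g. the printed CATCAAAG) must be
  # carried by every line, so it is planted before the lines are derived
  if (want_filler && !is.null(tpl) && !config$distal_chromosome) {
    anc <- substr_put(anc, D, tpl)
  }

  line1_seq <- anc
  line2_seq <- anc
  spacer_truth <- NULL
  dd7_iv <- NULL
  filler_seq <- NULL
  micro_truth <- NULL
  microinv <- NULL
  insertion_iv <- NULL

  make_filler <- function(flank_d) {
    mh_len <- config$microhomology_len
    if (is.character(config$filler) && !is.na(config$filler)) {
      return(list(seq = toupper(config$filler), mh_len = mh_len,
                  mm = config$microhomology_mismatch))
    }
    total <- if (is.numeric(config$filler) && !is.na(config$filler)) {
      as.integer(config$filler)
    } else 21L
    mh <- mismatch_seq(substr(flank_d, 1L, mh_len), config$microhomology_mismatch)
    list(seq = paste0(random_dna(total - mh_len, config$gc_content), mh),
         mh_len = mh_len, mm = config$microhomology_mismatch)
  }
  filler_obj <- NULL

  # --- standing distal-spacer polymorphism (chromosome-model junction) ----
  if (config$distal_chromosome) {
    sp_len <- config$spacer_len
    sp_s <- D - sp_len %/% 2L
    sp_e <- sp_s + sp_len
    spacer_anc <- sub0(anc, sp_s, sp_e)
    hap <- list()
    for (i in 1:2) {
      ori <- config$spacer_haplotypes[[i]]
      base <- if (ori == "-") revcomp(spacer_anc) else spacer_anc
      hap[[i]] <- mutate_seq(base, config$line_divergence)
    }
    half0 <- (sp_len - config$dd7_len) %/% 2L
    if (want_filler && !is.null(tpl)) {
      # the +D end begins at the downstream spacer half of line 2
      hap[[2]] <- substr_put(hap[[2]], sp_len - half0, tpl)
    }
    # Identifiability of the junction coordinates: every base adjacent to
    # a planted junction that would let a flank homology chance-extend
    # across it is redrawn. Without this the break coordinates (and hence
    # the central-deletion length) are ambiguous by a base or two in
    # principle, not just in inference.
    pick_not <- function(exclude) setdiff(c("A", "C", "G", "T"), exclude)[[1]]
    guard <- function(s, i, exclude) {
      if (char_at(s, i) %in% exclude) substr_put(s, i, pick_not(exclude)) else s
    }
    aP <- char_at(anc, P)
    aPm1 <- char_at(anc, P - 1L)
    # +A|-C junction: A may not extend onto -C's first base and -C may not
    # extend onto A's last base
    hap[[1]] <- guard(hap[[1]], half0 - 1L, comp_base(aP))
    hap[[1]] <- guard(hap[[1]], half0, comp_base(aPm1))
    # D-side: the +D homology (IR2 onward) may not extend onto X2's tail
    hap[[2]] <- guard(hap[[2]], sp_len - 1L, char_at(hap[[1]], sp_len - 1L))
    if (want_filler) {
      flank_preview <- substr(hap[[2]], sp_len - half0 + 1L, sp_len)
      filler_obj <- make_filler(flank_preview)
      fs <- filler_obj$seq
      first_b <- substr(fs, 1L, 1L)
      last_b <- substr(fs, nchar(fs), nchar(fs))
      # filler boundaries: the deleted bases adjoining the junction may
      # not chance-match the filler ends, and -B may not extend onto the
      # filler's first base
      hap[[1]] <- guard(hap[[1]], half0,
                        c(comp_base(aPm1), first_b))
      hap[[2]] <- guard(hap[[2]], sp_len - half0 - 1L,
                        c(char_at(hap[[1]], half0 - 1L), last_b))
      if (aPm1 == comp_base(first_b)) {
        repl <- pick_not(comp_base(first_b))
        anc <- substr_put(anc, P - 1L, repl)
        line1_seq <- substr_put(line1_seq, P - 1L, repl)
        line2_seq <- substr_put(line2_seq, P - 1L, repl)
      }
    } else {
      # blunt X1|X2 junction: neither retained half may be extendable by
      # the base the other haplotype carries at the junction, and -B may
      # not extend onto X2's first base
      hap[[2]] <- guard(hap[[2]], sp_len - half0, comp_base(aPm1))
      hap[[1]] <- guard(hap[[1]], half0,
                        c(comp_base(aPm1), char_at(hap[[2]], sp_len - half0)))
      hap[[2]] <- guard(hap[[2]], sp_len - half0 - 1L,
                        char_at(hap[[1]], half0 - 1L))
    }
    line1_seq <- substr_put(line1_seq, sp_s, hap[[1]])
    line2_seq <- substr_put(line2_seq, sp_s, hap[[2]])
    half <- (sp_len - config$dd7_len) %/% 2L
    dd7_iv <- interval("uninverted_1", sp_s + half, sp_e - half, "+", "dd7")
    spacer_truth <- list(
      spacer_start = sp_s, spacer_end = sp_e, half_len = half,
      haplotypes = config$spacer_haplotypes
    )
  }

  # --- complex proximal insertion (R1-2 + d1 + d2 + microinversion) ------
  build_insertion <- function(after_ins_409) {
    g <- config$ins_gaps
    r12 <- sub0(anc, P - config$r12_len, P)
    d1a <- random_dna(config$d1_len, config$gc_content)
    tail_in <- random_dna(config$d2b_split[[1]], config$gc_content)
    d2_parent <- paste0(tail_in, substr(after_ins_409, 1L, config$d2b_split[[2]]))
    d2a <- substr(d2_parent, 1L, config$d2a_len)
    pieces <- c(
      R12 = r12, g1 = random_dna(g[1], config$gc_content),
      d1A = d1a, g2 = random_dna(g[2], config$gc_content),
      d2A = d2a, g3 = random_dna(g[3], config$gc_content),
      intervening = random_dna(config$intervening_len, config$gc_content),
      g4 = random_dna(g[4], config$gc_content),
      d1B = revcomp(d1a), tail = tail_in
    )
    pieces
  }

  # --- assemble the inverted chromosome, piece by piece -------------------
  o1 <- config$d1_len
  o2 <- config$d2a_len
  pieces <- c(A = sub0(anc, 0L, P))
  if (mech %in% c("STAGGERED_ISO", "STAGGERED_CHROMATID", "BIR_MMBIR") &&
      !config$complex_proximal) {
    pieces <- c(pieces, prox_ov = sub0(anc, P, P + o1))
  }
  if (mech == "NAHR") {
    Lf <- config$nahr_repeat_len
    pieces <- c(pieces, prox_rep = sub0(anc, P, P + Lf))
  }

  # middle block (reverse-complemented); its ancestor extent depends on the
  # distal junction model
  if (config$distal_chromosome) {
    sp_s <- spacer_truth$spacer_start
    half <- spacer_truth$half_len
    hap1_half <- substr(line1_seq, sp_s + 1L, sp_s + half)
    mid <- paste0(sub0(anc, P, sp_s), hap1_half)
    tail_start <- spacer_truth$spacer_end
    tail_lead <- substr(line2_seq, tail_start - half + 1L, tail_start)
    tail_rest <- sub0(anc, tail_start, n)
  } else if (mech == "NAHR") {
    Lf <- config$nahr_repeat_len
    mid <- sub0(anc, P + Lf, D - Lf)
    tail_lead <- ""
    tail_rest <- sub0(anc, D - Lf, n)
  } else if (mech %in% c("STAGGERED_ISO", "STAGGERED_CHROMATID", "BIR_MMBIR")) {
    mid <- sub0(anc, P, D + o2)
    tail_lead <- ""
    tail_rest <- sub0(anc, D, n)
  } else { # CUT_AND_PASTE
    mid <- sub0(anc, P, D)
    tail_lead <- ""
    tail_rest <- sub0(anc, D, n)
  }

  if (config$complex_proximal) {
    rc_mid <- revcomp(mid)
    ins <- build_insertion(rc_mid)
    pieces <- c(pieces, ins)
    pieces <- c(pieces, mid_rc = rc_mid)
  } else {
    pieces <- c(pieces, mid_rc = revcomp(mid))
  }

  if (want_filler) {
    flank_d <- paste0(tail_lead, substr(tail_rest, 1L, 50L))
    f <- filler_obj %||% make_filler(flank_d)
    filler_seq <- f$seq
    micro_truth <- list(length = f$mh_len, mismatches = f$mm)
    pieces <- c(pieces, filler = f$seq)
  }
  if (nzchar(tail_lead)) pieces <- c(pieces, hap2_half = tail_lead)
  pieces <- c(pieces, D = tail_rest)

  asm <- assemble_pieces(pieces)
  inv_seq <- asm$seq
  map <- asm$map

  # --- truth bookkeeping --------------------------------------------------
  at <- function(nm) piece_iv(map, nm)
  # the proximal junction sits where ancestral continuation of A ends
  j_prox_inv <- if (mech == "NAHR") at("prox_rep")[["end"]] else
    if (!config$complex_proximal &&
        mech %in% c("STAGGERED_ISO", "STAGGERED_CHROMATID", "BIR_MMBIR")) {
      at("prox_ov")[["end"]]
    } else at("A")[["end"]]
  j_dist_inv <- at("mid_rc")[["end"]]

  if (mech == "NAHR") {
    Lf <- config$nahr_repeat_len
    add_dup("nahr_repeat", at("prox_rep"), c(j_dist_inv, j_dist_inv + Lf),
            "inverted", "both_states")
  }
  if (mech %in% c("STAGGERED_ISO", "STAGGERED_CHROMATID", "BIR_MMBIR")) {
    mrc <- at("mid_rc")
    if (!config$complex_proximal) {
      add_dup("prox_overhang", at("prox_ov"),
              c(mrc[["end"]] - o1, mrc[["end"]]), "inverted", "inverted_only")
    }
    if (!config$distal_chromosome) {
      dst <- at("D")
      add_dup("dist_overhang", c(mrc[["start"]], mrc[["start"]] + o2),
              c(dst[["start"]], dst[["start"]] + o2), "inverted", "inverted_only")
    }
  }
  if (config$complex_proximal) {
    ivd1a <- at("d1A"); ivd1b <- at("d1B"); ivd2a <- at("d2A")
    ivtail <- at("tail"); ivr12 <- at("R12")
    add_dup("R1-2", c(ivr12[["start"]] - config$r12_len, ivr12[["start"]]),
            ivr12, "direct", "inverted_only")
    add_dup("d1", ivd1a, ivd1b, "inverted", "inverted_only")
    # homologous extent of the d2 pair is min(d2a, d2b); the parent region
    # itself is d2b_len long, extending past the insertion boundary
    add_dup("d2", ivd2a,
            c(ivtail[["start"]], ivtail[["start"]] + config$d2a_len),
            "direct", "inverted_only")
    microinv <- interval("inverted", ivd1a[["start"]], ivd1b[["end"]], "+",
                         "microinversion")
    insertion_iv <- interval("inverted", ivr12[["start"]], ivtail[["end"]],
                             "+", "insertion")
  }

  truth <- structure(list(
    mechanism = mech,
    complex_proximal = config$complex_proximal,
    distal_chromosome = config$distal_chromosome,
    filler_planted = want_filler,
    breakpoints = tibble(
      assembly = c("inverted", "inverted", "uninverted_1", "uninverted_1"),
      junction = c("prox", "dist", "prox", "dist"),
      pos = as.integer(c(j_prox_inv, j_dist_inv, P, D))
    ),
    duplications = dups,
    microinversion = microinv,
    insertion = insertion_iv,
    central_deletion = dd7_iv,
    spacer = spacer_truth,
    filler = filler_seq,
    microhomology = micro_truth,
    piece_map = map
  ), class = "sim_truth")

  # planted duplication copies are maximal by construction: if a base just
  # outside a planted copy would extend the homology by chance, it is
  # replaced, so that planted extents are identifiable ground truth
  inv_seq <- enforce_dup_maximality(inv_seq, dups)

  # --- divergence, drawn in fixed order -----------------------------------
  seqs <- labeled_seq(
    c("inverted", "uninverted_1", "uninverted_2", "outgroup"),
    c(mutate_seq(inv_seq, config$line_divergence),
      mutate_seq(line1_seq, config$line_divergence),
      mutate_seq(line2_seq, config$line_divergence),
      mutate_seq(anc, config$outgroup_divergence))
  )

  # Truth duplication extents are restated as the maximal observable
  # ungapped homologous extents in the emitted (post-divergence) inverted
  # assembly: a substitution in the terminal bases of a copy shortens the
  # homology every downstream analysis can see, so the observable extent -
  # not the planted one - is the recoverable ground truth. The planted
  # component lengths remain in the configuration.
  if (nrow(truth$duplications)) {
    inv_mut <- seqs$seq[[1]]
    for (i in seq_len(nrow(truth$duplications))) {
      r <- truth$duplications[i, ]
      core <- 6L
      if (r$a_end - r$a_start <= 2L * core + 3L) next
      e <- extend_match(inv_mut, inv_mut,
                        r$a_start + core, r$a_end - core,
                        if (r$orientation == "direct") r$b_start + core else r$b_start + core,
                        r$b_end - core,
                        if (r$orientation == "direct") "+" else "-")
      truth$duplications$a_start[[i]] <- e[1]
      truth$duplications$a_end[[i]] <- e[2]
      truth$duplications$b_start[[i]] <- e[3]
      truth$duplications$b_end[[i]] <- e[4]
    }
  }
  list(seqs = seqs, truth = truth)
}

#' Simulate a complete four-assembly dataset
#'
#' Convenience wrapper: [simulate_ancestor()] then [apply_mechanism()].
#'
#' @param config A [sim_config()] object.
#' @return List with `seqs` (four labeled sequences) and `truth`.
#' @export
simulate_dataset <- function(config) {
  apply_mechanism(simulate_ancestor(config), config)
}

#' Write a simulated dataset to disk
#'
#' Emits four FASTA files (inverted line, two uninverted lines, outgroup),
#' the ground truth as a structured text report, and the resolved
#' configuration. Re-running with the same seed reproduces the bytes.
#'
#' @param config A [sim_config()] object.
#' @param outdir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Character vector of the six paths written, invisibly.
#' @export
emit_dataset <- function(config, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0L && !force) {
    abort(sprintf("output directory '%s' is non-empty (use force = TRUE)", outdir))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(config)
  paths <- character(0)
  for (i in seq_len(nrow(ds$seqs))) {
    p <- file.path(outdir, paste0(ds$seqs$id[[i]], ".fasta"))
    write_fasta(ds$seqs[i, ], p)
    paths <- c(paths, p)
  }
  pt <- file.path(outdir, "truth.txt")
  write_report(ds$truth, pt)
  pc <- file.path(outdir, "config.txt")
  write_report(config, pc)
  invisible(c(paths, pt, pc))
}
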