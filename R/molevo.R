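# Small molecular-evolution statistics: identity excluding indels,
# Tajima's relative-rate test, effective number of codons, and the
# concerted-evolution pattern test.

#' Pairwise identity excluding indels
#'
#' Fraction of matching columns among aligned non-gap columns (gap
#' columns are excluded entirely, matching the excluding-indels
#' convention used for reporting junction identities).
#'
#' @param aln An [align_pair()] result, or a character vector of two
#'   aligned (equal-length, gapped) sequences.
#' @return Fraction in `[0, 1]`; `NA` (with a warning) when no non-gap
#'   columns exist.
#' @export
identity_excluding_indels <- function(aln) {
  if (inherits(aln, "alignment_track")) {
    st <- aln$columns$state
  } else {
    stopifnot(length(aln) == 2L, nchar(aln[[1]]) == nchar(aln[[2]]))
    a <- strsplit(toupper(aln[[1]]), "")[[1]]
    b <- strsplit(toupper(aln[[2]]), "")[[1]]
    st <- ifelse(a == "-" | b == "-", "gap",
                 ifelse(a == b & a != "N", "match", "mismatch"))
  }
  m <- sum(st == "match")
  mm <- sum(st == "mismatch")
  if (m + mm == 0L) {
    warn("no non-gap columns; identity undefined")
    return(NA_real_)
  }
  m / (m + mm)
}

#' Tajima's relative-rate test
#'
#' Given three aligned sequences (two ingroup lineages and an outgroup),
#' counts the sites at which each ingroup sequence alone differs from the
#' other two (`m1`, `m2`) and tests rate equality with a chi-square
#' statistic `(m1 - m2)^2 / (m1 + m2)` on 1 degree of freedom. Only
#' columns in which all three sequences carry unambiguous bases are used.
#'
#' @param seq1,seq2 Aligned ingroup sequences (gapped strings of equal
#'   length).
#' @param outgroup Aligned outgroup sequence of the same length.
#' @return Object of class `"tajima_rrt"` with fields `m1`, `m2`,
#'   `chi2`, `p`, `n_sites`.
#' @export
#' @examples
#' tajima_rrt("ACGTACGTAC", "ACGTACGTAC", "ACGTACGAAC")
tajima_rrt <- function(seq1, seq2, outgroup) {
  s <- lapply(list(seq1, seq2, outgroup),
              function(x) strsplit(toupper(as_seq_string(x)), "")[[1]])
  if (length(unique(lengths(s))) != 1L) {
    abort("sequences must be aligned to equal length")
  }
  ok <- Reduce(`&`, lapply(s, function(v) v %in% c("A", "C", "G", "T")))
  if (!any(ok)) abort("no columns with all three sequences unambiguous")
  a <- s[[1]][ok]; b <- s[[2]][ok]; o <- s[[3]][ok]
  m1 <- sum(a != b & a != o & b == o)
  m2 <- sum(a != b & b != o & a == o)
  chi2 <- if (m1 + m2 > 0L) (m1 - m2)^2 / (m1 + m2) else 0
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  structure(list(m1 = m1, m2 = m2, chi2 = chi2, p = p, n_sites = sum(ok)),
            class = "tajima_rrt")
}

#' @export
print.tajima_rrt <- function(x, ...) {
  cat(sprintf(
    "Tajima relative-rate test: m1 = %d, m2 = %d, chi2 = %.3f, p = %.4g (%d sites)\n",
    x$m1, x$m2, x$chi2, x$p, x$n_sites
  ))
  invisible(x)
}

#' @rdname tajima_rrt
#' @param x A `"tajima_rrt"` object.
#' @param ... Unused.
#' @method tidy tajima_rrt
#' @export
tidy.tajima_rrt <- function(x, ...) {
  tibble(m1 = x$m1, m2 = x$m2, statistic = x$chi2, p.value = x$p,
         n_sites = x$n_sites)
}

#' @rdname tajima_rrt
#' @method glance tajima_rrt
#' @export
glance.tajima_rrt <- function(x, ...) tidy(x)

# synonymous families of the standard genetic code, excluding stops and
# the single-codon amino acids (Met, Trp)
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  fam <- split(names(gc), gc)
  fam[lengths(fam) > 1L]
}

#' Effective number of codons (Nc)
#'
#' Codon-usage bias summary ranging from 20 (one codon per amino acid) to
#' 61 (uniform synonymous usage). Per synonymous family, a codon
#' homozygosity `F` is computed from observed codon frequencies; families
#' are averaged within degeneracy classes and combined as
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`. Two `F` estimators are
#' provided: `"wright"`, the classic small-sample estimator
#' `F = (n * sum(p^2) - 1) / (n - 1)`; and `"sun2013"`, a
#' pseudocount-regularized estimator `F = sum(((n_i + 1) / (n + k))^2)`
#' that is defined for every observed family (the package's reading of
#' the improved index). Families with no observations are imputed from
#' their degeneracy-class mean; the result is clamped to `[20, 61]`.
#'
#' @param cds Coding sequence (length divisible by 3, no internal stop;
#'   a terminal stop codon is tolerated and dropped).
#' @param variant `"sun2013"` (default) or `"wright"`.
#' @return Object of class `"codon_usage"`: `nc`, `variant`, per-family
#'   tibble `families`.
#' @export
effective_number_of_codons <- function(cds, variant = c("sun2013", "wright")) {
  variant <- match.arg(variant)
  s <- as_seq_string(cds)
  if (nchar(s) %% 3L != 0L) abort("CDS length must be divisible by 3")
  codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  if (!is.na(aa[length(aa)]) && aa[length(aa)] == "*") {
    codons <- codons[-length(codons)]
    aa <- aa[-length(aa)]
  }
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    abort(sprintf("internal stop codon %s at codon position %d",
                  codons[stop_at[1]], stop_at[1]))
  }
  codons <- codons[!is.na(aa)]
  fams <- codon_families()
  rows <- list()
  for (aa1 in names(fams)) {
    cods <- fams[[aa1]]
    k <- length(cods)
    ni <- vapply(cods, function(cd) sum(codons == cd), numeric(1))
    n <- sum(ni)
    f <- if (n == 0L) {
      NA_real_
    } else if (variant == "wright") {
      if (n < 2L) NA_real_ else {
        p <- ni / n
        max((n * sum(p^2) - 1) / (n - 1), 0)
      }
    } else {
      sum(((ni + 1) / (n + k))^2)
    }
    rows[[aa1]] <- tibble(aa = aa1, degeneracy = k, n = n, f = f)
  }
  fam_tab <- dplyr::bind_rows(rows)
  class_f <- fam_tab |>
    dplyr::group_by(.data$degeneracy) |>
    dplyr::summarise(
      mean_f = mean(.data$f, na.rm = TRUE),
      n_fam = dplyr::n(), .groups = "drop"
    )
  # impute unobserved/undefined families from their degeneracy-class mean;
  # a class with no defined family at all falls back to uniform usage
  fbar <- stats::setNames(class_f$mean_f, class_f$degeneracy)
  for (d in names(fbar)) {
    if (!is.finite(fbar[[d]]) || fbar[[d]] <= 0) {
      fbar[[d]] <- 1 / as.numeric(d)
    }
  }
  nc <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] +
    3 / fbar[["6"]]
  nc <- min(max(nc, 20), 61)
  structure(list(nc = unname(nc), variant = variant, families = fam_tab),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("Effective number of codons (%s): Nc = %.1f\n",
              x$variant, x$nc))
  invisible(x)
}

#' @rdname effective_number_of_codons
#' @param x A `"codon_usage"` object.
#' @param ... Unused.
#' @method glance codon_usage
#' @export
glance.codon_usage <- function(x, ...) {
  tibble(nc = x$nc, variant = x$variant)
}

#' Concerted-evolution pattern test
#'
#' Classifies a set of paralogs across species from their pairwise
#' distances: `"concerted"` when every within-species paralog distance is
#' smaller than every cross-species ortholog/paralog distance (paralogs
#' resemble each other more than their orthologs); `"escaped"` when one
#' paralog's distances to all non-partner sequences exceed its
#' within-species partner's corresponding distances (the pattern of a
#' copy relocated by a rearrangement and evolving faster);
#' `"undetermined"` on ties or mixtures.
#'
#' @param dist A `dist` object or symmetric matrix with labelled
#'   rows/columns.
#' @param species Character vector of species assignments, one per label
#'   (in label order).
#' @return List with `pattern` (one of concerted/escaped/undetermined)
#'   and, for `"escaped"`, the `escaped` label.
#' @export
concerted_pattern <- function(dist, species) {
  m <- as.matrix(dist)
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("seq", seq_len(nrow(m)))
  stopifnot(length(species) == nrow(m))
  if (length(unique(species)) < 2L || nrow(m) < 4L) {
    abort("need at least 2 species x 2 paralogs")
  }
  within <- c(); cross <- c()
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in (i + 1L):nrow(m)) {
      if (species[i] == species[j]) {
        within <- c(within, m[i, j])
      } else {
        cross <- c(cross, m[i, j])
      }
    }
  }
  if (length(within) && length(cross) && max(within) < min(cross)) {
    return(list(pattern = "concerted", escaped = NULL))
  }
  for (i in seq_len(nrow(m))) {
    partners <- which(species == species[i] & seq_len(nrow(m)) != i)
    for (p in partners) {
      others <- setdiff(seq_len(nrow(m)), c(i, p))
      if (length(others) && all(m[i, others] > m[p, others])) {
        return(list(pattern = "escaped", escaped = labs[i]))
      }
    }
  }
  list(pattern = "undetermined", escaped = NULL)
}
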