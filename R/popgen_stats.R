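#  Per-population diversity statistics and pairwise F_ST.

#' Within-population allele frequencies
#'
#' Frequency of `allele_b` among non-missing calls at each SNP. SNPs with no
#' non-missing call in the population are returned as `NA` (undefined).
#'
#' @param ds a [snp_dataset()]
#' @param population population label
#' @return named numeric vector, one frequency per SNP
#' @export
allele_frequencies <- function(ds, population) {
  rows <- .pop_rows(ds, population)
  g <- ds$geno[rows, , drop = FALSE]
  colMeans(g, na.rm = TRUE) / 2
}

#' Observed and expected heterozygosity
#'
#' Per SNP, observed heterozygosity is the fraction of non-missing genotypes
#' that are heterozygous and expected heterozygosity is `2 p (1 - p)` from
#' the within-population allele frequency (no small-sample correction, the
#' usual array-panel convention). Reported values are means over all panel
#' SNPs with at least one non-missing call in the population, including SNPs
#' monomorphic within it.
#'
#' @inheritParams allele_frequencies
#' @return list with `h_observed` and `h_expected` (panel means) and the
#'   per-SNP vectors `h_obs_snp`, `h_exp_snp`
#' @export
heterozygosity <- function(ds, population) {
  rows <- .pop_rows(ds, population)
  .assert(length(rows) >= 2, "population '%s' has < 2 samples", population,
          class = "wolfdogpop_insufficient_data_error")
  g <- ds$geno[rows, , drop = FALSE]
  called <- colSums(!is.na(g))
  h_obs <- colSums(g == 1L, na.rm = TRUE) / called
  p <- colMeans(g, na.rm = TRUE) / 2
  h_exp <- 2 * p * (1 - p)
  ok <- called > 0
  list(h_observed = mean(h_obs[ok]), h_expected = mean(h_exp[ok]),
       h_obs_snp = h_obs, h_exp_snp = h_exp)
}

#' Count SNPs polymorphic within a population
#'
#' @inheritParams allele_frequencies
#' @return number of SNPs with within-population allele frequency strictly
#'   between 0 and 1 (computed over non-missing calls)
#' @export
count_polymorphic <- function(ds, population) {
  p <- allele_frequencies(ds, population)
  sum(p > 0 & p < 1, na.rm = TRUE)
}

#' @noRd
.fst_components_wc <- function(n1, n2, p1, p2, h1, h2) {
  # Weir & Cockerham (1984) two-population variance components per locus.
  # n*: sample sizes (individuals), p*: allele_b frequency, h*: observed
  # heterozygote frequency. Returns a (between), b (within-pop between-
  # individual) and c (within-individual) per SNP.
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Pairwise fixation index between two populations
#'
#' Weir-Cockerham (1984) two-population estimator, combined across SNPs as a
#' ratio of averages (sum of per-locus numerators over sum of per-locus
#' denominators). SNPs monomorphic across both populations, or without a
#' genotyped individual in each, are excluded. The raw estimate is returned
#' unclamped; [stats_report()] clamps negatives to 0 for the matrix. A
#' Hudson-type estimator is available for sensitivity checks.
#'
#' @param ds a [snp_dataset()]
#' @param pop_a,pop_b distinct population labels (each with >= 2 samples)
#' @param estimator `"wc"` (default) or `"hudson"`
#' @return the ratio-of-averages F_ST estimate (may be slightly negative)
#' @export
pairwise_fst <- function(ds, pop_a, pop_b, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  ra <- .pop_rows(ds, pop_a); rb <- .pop_rows(ds, pop_b)
  .assert(pop_a != pop_b && length(intersect(ra, rb)) == 0,
          "populations overlap", class = "wolfdogpop_input_error")
  .assert(length(ra) >= 2 && length(rb) >= 2,
          "both populations need >= 2 samples",
          class = "wolfdogpop_insufficient_data_error")
  ga <- ds$geno[ra, , drop = FALSE]; gb <- ds$geno[rb, , drop = FALSE]
  n1 <- colSums(!is.na(ga)); n2 <- colSums(!is.na(gb))
  p1 <- colMeans(ga, na.rm = TRUE) / 2; p2 <- colMeans(gb, na.rm = TRUE) / 2
  pbar <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * (n1 + n2))
  keep <- n1 > 0 & n2 > 0 & pbar > 0 & pbar < 1 & (n1 + n2) > 2
  if (estimator == "wc") {
    h1 <- colSums(ga == 1L, na.rm = TRUE) / n1
    h2 <- colSums(gb == 1L, na.rm = TRUE) / n2
    comp <- .fst_components_wc(n1[keep], n2[keep], p1[keep], p2[keep],
                               h1[keep], h2[keep])
    sum(comp$a) / sum(comp$a + comp$b + comp$c)
  } else {
    q1 <- p1[keep]; q2 <- p2[keep]; m1 <- n1[keep]; m2 <- n2[keep]
    num <- (q1 - q2)^2 - q1 * (1 - q1) / (2 * m1 - 1) -
      q2 * (1 - q2) / (2 * m2 - 1)
    den <- q1 * (1 - q2) + q2 * (1 - q1)
    sum(num) / sum(den)
  }
}

#' Per-population summaries and the pairwise F_ST matrix
#'
#' @param ds a [snp_dataset()] with at least two populations
#' @param estimator passed to [pairwise_fst()]
#' @return list with `population_summary` (one row per population:
#'   `h_expected`, `h_observed`, `n_polymorphic`, `missing_pct`) and `fst`, a
#'   list holding `populations`, the symmetric `values` matrix (negatives
#'   clamped to 0, diagonal 0) and `raw` (unclamped estimates)
#' @export
stats_report <- function(ds, estimator = "wc") {
  pops <- populations(ds)
  .assert(length(pops) >= 2, "need >= 2 populations",
          class = "wolfdogpop_insufficient_data_error")
  summ <- do.call(rbind, lapply(pops, function(p) {
    rows <- .pop_rows(ds, p)
    h <- heterozygosity(ds, p)
    data.frame(population = p,
               h_expected = h$h_expected,
               h_observed = h$h_observed,
               n_polymorphic = count_polymorphic(ds, p),
               missing_pct = 100 * mean(is.na(ds$geno[rows, , drop = FALSE])),
               stringsAsFactors = FALSE)
  }))
  k <- length(pops)
  raw <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    raw[i, j] <- raw[j, i] <- pairwise_fst(ds, pops[i], pops[j],
                                           estimator = estimator)
  }
  vals <- pmin(pmax(raw, 0), 1)
  diag(vals) <- 0
  list(population_summary = summ,
       fst = list(populations = pops, values = vals, raw = raw))
}

#' Write the diversity report as TSV files
#'
#' `population_summary.tsv` mirrors the per-population table (H_E, H_O,
#' polymorphic sites, % missing); `fst_matrix.tsv` holds the lower triangle
#' of the pairwise F_ST matrix.
#'
#' @param report output of [stats_report()]
#' @param dir output directory (created if needed)
#' @return invisibly, the written paths
#' @export
write_stats_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "population_summary.tsv")
  data.table::fwrite(report$population_summary, f1, sep = "\t")
  m <- report$fst$values
  m[upper.tri(m, diag = TRUE)] <- NA
  out <- data.frame(population = rownames(m), m, check.names = FALSE)
  f2 <- file.path(dir, "fst_matrix.tsv")
  data.table::fwrite(out, f2, sep = "\t", na = "")
  invisible(c(f1, f2))
}
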