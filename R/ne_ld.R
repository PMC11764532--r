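#  Historical effective population size from the decay of linkage
#  disequilibrium with genetic distance (Sved equation), one estimate per
#  generation bin.

#' Parameters for the LD-based N_E trajectory
#'
#' Genetic distances come from physical positions at a constant rate
#' (default 1e-8 Morgans/bp, i.e. 100 Mb = 1 Morgan). Each generation `t` in
#' `1..max_generations` is probed by SNP pairs around distance
#' `c = 1/(2t)` Morgans; the estimate for bin `t` is dated
#' `sampling_year - t * generation_interval_years`.
#'
#' @param max_generations deepest generation bin (default 30)
#' @param generation_interval_years years per generation (default 3, the
#'   conventional dog value)
#' @param morgans_per_bp map rate (default 1e-8)
#' @param maf_min minor-allele-frequency floor for SNPs entering r2 pairs
#'   (default 0.05; an assumption, not a reconstruction)
#' @param sample_correction_n number of genotyped individuals for the `1/n`
#'   sampling correction; `NULL` (default) uses the population's sample
#'   count, `Inf` drops the correction
#' @param chromosome_count_correction use `1/(2n)` instead of `1/n`
#'   (off by default; sensitivity flag)
#' @param sampling_year calendar year the samples represent (default 2021)
#' @return a list of class `ne_params`
#' @export
ne_params <- function(max_generations = 30L, generation_interval_years = 3,
                      morgans_per_bp = 1e-8, maf_min = 0.05,
                      sample_correction_n = NULL,
                      chromosome_count_correction = FALSE,
                      sampling_year = 2021L) {
  .assert(max_generations >= 1, "max_generations must be >= 1")
  .assert(morgans_per_bp > 0, "morgans_per_bp must be > 0")
  structure(list(max_generations = as.integer(max_generations),
                 generation_interval_years = generation_interval_years,
                 morgans_per_bp = morgans_per_bp,
                 maf_min = maf_min,
                 sample_correction_n = sample_correction_n,
                 chromosome_count_correction = chromosome_count_correction,
                 sampling_year = as.integer(sampling_year)),
            class = "ne_params")
}

#' Expected r-squared under drift-recombination equilibrium
#'
#' `E(r2) = 1 / (1 + 4 Ne c) + 1/n`: the Sved relation between linkage
#' disequilibrium and effective population size, plus the finite-sample
#' inflation `1/n`. `n = Inf` drops the correction.
#'
#' @param ne effective population size (>= 0)
#' @param c genetic distance in Morgans (>= 0)
#' @param n number of genotyped individuals (>= 1, may be `Inf`)
#' @return expected squared genotypic correlation
#' @export
expected_r2 <- function(ne, c, n = Inf) {
  .assert(all(ne >= 0) && all(c >= 0) && all(n >= 1),
          "ne, c must be >= 0 and n >= 1",
          class = "wolfdogpop_domain_error")
  1 / (1 + 4 * ne * c) + 1 / n
}

#' Invert the Sved equation for N_E
#'
#' Solves `mean_r2 = 1/(1 + 4 Ne c) + 1/n` for `Ne`. Estimates are flagged
#' invalid (not clamped) when the observed r2 does not exceed the sampling
#' floor `1/n` or the solution is not positive.
#'
#' @param mean_r2 observed mean squared correlation for the distance bin
#' @param c bin genetic distance in Morgans (> 0)
#' @param n individuals behind the `1/n` correction (may be `Inf`)
#' @return list with `ne` (NA when invalid) and `valid`
#' @export
invert_to_ne <- function(mean_r2, c, n = Inf) {
  .assert(all(c > 0), "c must be > 0", class = "wolfdogpop_domain_error")
  adj <- mean_r2 - 1 / n
  ne <- ifelse(adj > 0 & adj < 1, (1 / adj - 1) / (4 * c), NA_real_)
  valid <- !is.na(ne) & ne > 0
  ne[!valid] <- NA_real_
  list(ne = ne, valid = valid)
}

#' Generation-to-distance bins for the trajectory
#'
#' Uses the standard Sved/Hayes correspondence `t = 1/(2c)`: generation `t`
#' is probed at center distance `c = 1/(2t)` Morgans, with bin edges at the
#' midpoints of adjacent centers in `1/c` space, `[1/(2(t+0.5)),
#' 1/(2(t-0.5)))`; the `t = 1` upper edge is capped at 0.5 Morgans. Bins are
#' disjoint and contiguous.
#'
#' @param params an [ne_params()]
#' @return data.frame with `t_generations`, `c_low`, `c_center`, `c_high`
#' @export
build_generation_bins <- function(params = ne_params()) {
  t <- seq_len(params$max_generations)
  data.frame(t_generations = t,
             c_low = 1 / (2 * (t + 0.5)),
             c_center = 1 / (2 * t),
             c_high = pmin(1 / (2 * (t - 0.5)), 0.5))
}

#' @noRd
.ld_bin_stats <- function(ds, population, edges, params, top_closed = TRUE) {
  rows <- .pop_rows(ds, population)
  .assert(length(rows) >= 2, "population '%s' has < 2 samples", population,
          class = "wolfdogpop_insufficient_data_error")
  nb <- length(edges) - 1L
  sum_r2 <- numeric(nb); n_pairs <- numeric(nb)
  for (ch in unique(ds$map$chrom)) {
    ci <- which(ds$map$chrom == ch)
    g <- ds$geno[rows, ci, drop = FALSE]
    p <- colMeans(g, na.rm = TRUE) / 2
    called <- colSums(!is.na(g))
    keep <- !is.na(p) & pmin(p, 1 - p) >= params$maf_min & called >= 2 &
      apply(g, 2, function(x) length(unique(x[!is.na(x)]))) > 1
    if (sum(keep) < 2) next
    g <- g[, keep, drop = FALSE]
    pos <- ds$map$pos[ci][keep]
    cm <- if (anyNA(g)) suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
          else suppressWarnings(stats::cor(g))
    d <- abs(outer(pos, pos, "-")) * params$morgans_per_bp
    ut <- upper.tri(cm)
    r2 <- cm[ut]^2
    dd <- d[ut]
    ok <- !is.na(r2)
    bin <- findInterval(dd[ok], edges, rightmost.closed = top_closed)
    bin[bin < 1 | bin > nb] <- NA
    use <- !is.na(bin)
    if (!any(use)) next
    sum_r2 <- sum_r2 + vapply(seq_len(nb), function(b)
      sum(r2[ok][use][bin[use] == b]), 0)
    n_pairs <- n_pairs + tabulate(bin[use], nbins = nb)
  }
  data.frame(bin = seq_len(nb),
             n_pairs = n_pairs,
             mean_r2 = ifelse(n_pairs > 0, sum_r2 / n_pairs, NA_real_))
}

#' Mean pairwise r-squared within one genetic-distance bin
#'
#' Squared Pearson correlation of genotype dosages (composite, unphased LD)
#' over all intra-chromosomal SNP pairs whose distance lies in
#' `[c_low, c_high)`, both SNPs passing the MAF floor within the population;
#' individuals missing at either SNP are dropped pairwise. Monomorphic SNPs
#' are excluded (undefined correlation).
#'
#' @param ds a [snp_dataset()]
#' @param population population label (>= 2 samples)
#' @param c_low,c_high bin edges in Morgans (`c_high > c_low`)
#' @param params an [ne_params()]
#' @return list (`SnpPairBin`): `c_low`, `c_center`, `c_high`, `n_pairs`,
#'   `mean_r2` (NA when no pair qualifies)
#' @export
pairwise_r2 <- function(ds, population, c_low, c_high,
                        params = ne_params()) {
  .assert(c_high > c_low, "c_high must exceed c_low",
          class = "wolfdogpop_input_error")
  st <- .ld_bin_stats(ds, population, c(c_low, c_high), params,
                      top_closed = FALSE)
  list(c_low = c_low, c_center = (c_low + c_high) / 2, c_high = c_high,
       n_pairs = st$n_pairs[1], mean_r2 = st$mean_r2[1])
}

#' Historical N_E trajectory from LD decay
#'
#' For every generation bin, computes the mean pairwise r2 and inverts the
#' Sved equation at the bin's center distance with the `1/n` correction.
#' Bins whose mean r2 sits at or below the sampling floor are reported with
#' `valid = FALSE` rather than dropped; no smoothing or interpolation is
#' applied.
#'
#' @param ds a [snp_dataset()]
#' @param population population label (>= 2 samples)
#' @param params an [ne_params()]
#' @return data.frame ordered `t = 1..max_generations` with columns
#'   `t_generations`, `calendar_year`, `c_center`, `n_pairs`, `mean_r2`,
#'   `ne`, `valid`
#' @export
ne_trajectory <- function(ds, population, params = ne_params()) {
  rows <- which(ds$samples$population == population)
  if (length(rows) < 2)
    .stopf("population '%s' has %d sample(s); need >= 2 for LD",
           population, length(rows),
           class = "wolfdogpop_insufficient_data_error")
  bins <- build_generation_bins(params)
  n <- params$sample_correction_n %||% length(rows)
  if (isTRUE(params$chromosome_count_correction)) n <- 2 * n
  # edges ascending in c = descending in t; bin k maps to t = max_gen - k + 1
  edges <- c(bins$c_low[params$max_generations], rev(bins$c_high))
  st <- .ld_bin_stats(ds, population, edges, params, top_closed = TRUE)
  st <- st[rev(seq_len(nrow(st))), ]  # back to t ascending
  inv <- invert_to_ne(ifelse(is.na(st$mean_r2), Inf, st$mean_r2),
                      bins$c_center, n)
  inv$valid[is.na(st$mean_r2)] <- FALSE
  inv$ne[is.na(st$mean_r2)] <- NA_real_
  data.frame(t_generations = bins$t_generations,
             calendar_year = params$sampling_year -
               bins$t_generations * params$generation_interval_years,
             c_center = bins$c_center,
             n_pairs = st$n_pairs,
             mean_r2 = st$mean_r2,
             ne = inv$ne,
             valid = inv$valid)
}

#' Expected accumulation of new variation
#'
#' The back-of-the-envelope product `mu * n_generations * Ne`: the expected
#' per-site probability that a new mutation arose and is segregating after
#' the stated number of generations, used to argue that breed histories are
#' far too short for new variants to matter.
#'
#' @param mu mutation rate per site per generation
#' @param n_generations elapsed generations
#' @param ne effective population size
#' @return the product (dimensionless fraction)
#' @export
expected_new_variation <- function(mu, n_generations, ne) {
  .assert(all(mu >= 0) && all(n_generations >= 0) && all(ne >= 0),
          "inputs must be >= 0", class = "wolfdogpop_domain_error")
  mu * n_generations * ne
}

#' Write an N_E trajectory as TSV
#'
#' @param trajectory output of [ne_trajectory()]
#' @param path output TSV
#' @export
write_ne_trajectory <- function(trajectory, path) {
  data.table::fwrite(trajectory, path, sep = "\t")
  invisible(path)
}
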