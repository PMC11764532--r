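#  Sliding-window detection of runs of homozygosity, length-class summaries
#  and the genomic inbreeding coefficient F_ROH.

#' Parameters for sliding-window ROH detection
#'
#' The window size (50 SNPs) and minimum SNPs per run (20) follow the
#' standard canine SNP-array setting; the remaining knobs default to the
#' documented defaults of the common sliding-window implementation and are
#' explicit assumptions, not reconstructions.
#'
#' @param window_snps SNPs per sliding window (default 50)
#' @param min_snps_in_run minimum SNPs for an emitted run (default 20)
#' @param max_het_per_window heterozygous calls tolerated per homozygous
#'   window (default 1)
#' @param max_missing_per_window missing calls tolerated per window
#'   (default 1)
#' @param snp_inclusion_threshold minimum fraction of overlapping windows
#'   that must be homozygous for a SNP to be in-run (default 0.05)
#' @param min_length_bp minimum run length in bp (default 1000)
#' @param max_gap_bp adjacent in-run SNPs farther apart than this split the
#'   run (default 1e6)
#' @return a list of class `roh_params`
#' @export
roh_params <- function(window_snps = 50L, min_snps_in_run = 20L,
                       max_het_per_window = 1L, max_missing_per_window = 1L,
                       snp_inclusion_threshold = 0.05, min_length_bp = 1000,
                       max_gap_bp = 1e6) {
  .assert(window_snps >= 1, "window_snps must be >= 1")
  .assert(min_snps_in_run >= 1, "min_snps_in_run must be >= 1")
  .assert(max_het_per_window >= 0 && max_missing_per_window >= 0,
          "window allowances must be >= 0")
  .assert(snp_inclusion_threshold > 0 && snp_inclusion_threshold <= 1,
          "snp_inclusion_threshold must be in (0, 1]")
  structure(list(window_snps = as.integer(window_snps),
                 min_snps_in_run = as.integer(min_snps_in_run),
                 max_het_per_window = as.integer(max_het_per_window),
                 max_missing_per_window = as.integer(max_missing_per_window),
                 snp_inclusion_threshold = snp_inclusion_threshold,
                 min_length_bp = min_length_bp,
                 max_gap_bp = max_gap_bp),
            class = "roh_params")
}

#' @noRd
.empty_segments <- function() {
  data.frame(sample_id = character(), chrom = integer(), start_bp = numeric(),
             end_bp = numeric(), n_snps = integer(), length_bp = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect runs of homozygosity for one individual
#'
#' Per chromosome, every window of `window_snps` consecutive SNPs is scored
#' homozygous if it holds at most `max_het_per_window` heterozygous and
#' `max_missing_per_window` missing calls. Each SNP's support is the fraction
#' of the windows overlapping it (the actual overlapping-window count at
#' chromosome edges) that are homozygous; SNPs with support at or above
#' `snp_inclusion_threshold` are in-run. Maximal stretches of in-run SNPs are
#' split wherever adjacent SNPs are more than `max_gap_bp` apart, and emitted
#' when they hold at least `min_snps_in_run` SNPs and span at least
#' `min_length_bp`. Run coordinates are SNP-bounded (first to last in-run
#' SNP, inclusive). Chromosomes with fewer SNPs than one window yield no
#' runs.
#'
#' @param genotypes dosage vector (0/1/2/NA) for one sample, aligned with
#'   `snps`
#' @param snps map data.frame (`snp_id`, `chrom`, `pos`) sorted by
#'   chromosome then position
#' @param params a [roh_params()]
#' @param sample_id label recorded in the output
#' @return data.frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`
#' @export
detect_roh_individual <- function(genotypes, snps, params = roh_params(),
                                  sample_id = "sample") {
  .assert(length(genotypes) == nrow(snps), "genotype / map length mismatch",
          class = "wolfdogpop_input_error")
  ord_ok <- !is.unsorted(order(snps$chrom, snps$pos), strictly = FALSE) &&
    identical(order(snps$chrom, snps$pos), seq_len(nrow(snps)))
  .assert(ord_ok, "map must be sorted by chromosome then position",
          class = "wolfdogpop_input_error")
  out <- list()
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    g <- genotypes[idx]
    pos <- snps$pos[idx]
    m <- length(idx)
    w <- params$window_snps
    if (m < w) next
    het <- as.integer(!is.na(g) & g == 1L)
    mis <- as.integer(is.na(g))
    ok <- .window_sum(het, w) <= params$max_het_per_window &
      .window_sum(mis, w) <= params$max_missing_per_window
    nW <- m - w + 1L
    cs <- cumsum(c(0, ok))
    i <- seq_len(m)
    lo <- pmax(1L, i - w + 1L)
    hi <- pmin(i, nW)
    support <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    in_run <- support >= params$snp_inclusion_threshold
    if (!any(in_run)) next
    r <- rle(in_run)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run_idx <- starts[k]:ends[k]
      # split at physical gaps
      gaps <- which(diff(pos[run_idx]) > params$max_gap_bp)
      piece_start <- c(run_idx[1], run_idx[gaps + 1L])
      piece_end <- c(run_idx[gaps], run_idx[length(run_idx)])
      for (p in seq_along(piece_start)) {
        ii <- piece_start[p]:piece_end[p]
        len <- pos[ii[length(ii)]] - pos[ii[1]] + 1
        if (length(ii) >= params$min_snps_in_run &&
            len >= params$min_length_bp) {
          out[[length(out) + 1L]] <- data.frame(
            sample_id = sample_id, chrom = ch,
            start_bp = pos[ii[1]], end_bp = pos[ii[length(ii)]],
            n_snps = length(ii), length_bp = len,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(.empty_segments())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' ROH length classes (Mbp)
#'
#' The five canonical classes 0-2, 2-4, 4-8, 8-16 and >16 Mbp. Intervals are
#' half-open `[lo, hi)`; a run of exactly 2.0 Mbp falls in the 2-4 class.
#' @export
roh_class_bounds <- function() {
  data.frame(class = c("0-2", "2-4", "4-8", "8-16", ">16"),
             lo_mbp = c(0, 2, 4, 8, 16),
             hi_mbp = c(2, 4, 8, 16, Inf),
             stringsAsFactors = FALSE)
}

#' Summarize ROH segments by length class
#'
#' @param segments data.frame as returned by [detect_roh_individual()]
#' @return data.frame with one row per length class: `class`, `n_segments`,
#'   `total_length_bp`, `mean_length_bp` (NA when the class is empty)
#' @export
classify_segments <- function(segments) {
  bounds <- roh_class_bounds()
  mbp <- segments$length_bp / 1e6
  cls <- findInterval(mbp, bounds$lo_mbp)  # [lo, hi) with last class open
  data.frame(class = bounds$class,
             n_segments = vapply(seq_len(5), function(k) sum(cls == k), 0L),
             total_length_bp = vapply(seq_len(5), function(k)
               sum(segments$length_bp[cls == k]), 0),
             mean_length_bp = vapply(seq_len(5), function(k) {
               v <- segments$length_bp[cls == k]
               if (length(v)) mean(v) else NA_real_
             }, 0),
             stringsAsFactors = FALSE)
}

#' Genomic inbreeding coefficient from ROH segments
#'
#' `froh` is the summed ROH length over the genome length covered by the
#' analyzed SNPs, where the covered length is the sum over chromosomes of
#' last-minus-first SNP position plus one.
#'
#' @param segments segments of one sample ([detect_roh_individual()])
#' @param snps the SNP map the segments were detected on
#' @return list with `sample_id`, `froh` and `covered_length_bp`
#' @export
froh <- function(segments, snps) {
  .assert(nrow(snps) > 0, "empty map", class = "wolfdogpop_input_error")
  spans <- tapply(snps$pos, snps$chrom, function(p) max(p) - min(p) + 1)
  covered <- sum(spans)
  f <- if (nrow(segments)) sum(segments$length_bp) / covered else 0
  list(sample_id = if (nrow(segments)) segments$sample_id[1] else NA_character_,
       froh = f, covered_length_bp = covered)
}

#' Population-level ROH summary
#'
#' Detects runs for every individual, then reports, per population, the mean
#' percentage of an individual's total ROH coverage falling in each length
#' class (individual-wise mean over individuals carrying at least one run),
#' the mean run length per class, and per-sample / mean F_ROH.
#'
#' @param ds a [snp_dataset()]
#' @param params a [roh_params()]
#' @return list with `class_summary` (population x class table:
#'   `pct_of_coverage`, `mean_length_bp`, `n_segments`), `froh_by_sample`,
#'   `froh_by_population` and the raw `segments` table
#' @export
population_roh_summary <- function(ds, params = roh_params()) {
  segs <- lapply(seq_len(n_samples(ds)), function(i)
    detect_roh_individual(ds$geno[i, ], ds$map, params,
                          sample_id = ds$samples$sample_id[i]))
  segments <- do.call(rbind, segs)
  if (is.null(segments)) segments <- .empty_segments()

  spans <- tapply(ds$map$pos, ds$map$chrom, function(p) max(p) - min(p) + 1)
  covered <- sum(spans)
  froh_by_sample <- data.frame(
    sample_id = ds$samples$sample_id,
    population = ds$samples$population,
    froh = vapply(segs, function(s)
      if (nrow(s)) sum(s$length_bp) / covered else 0, 0),
    covered_length_bp = covered,
    stringsAsFactors = FALSE)

  bounds <- roh_class_bounds()
  pops <- populations(ds)
  class_rows <- list()
  for (p in pops) {
    sidx <- which(ds$samples$population == p)
    per_ind <- lapply(segs[sidx], function(s) {
      if (!nrow(s)) return(NULL)
      cl <- classify_segments(s)
      100 * cl$total_length_bp / sum(s$length_bp)
    })
    per_ind <- per_ind[!vapply(per_ind, is.null, TRUE)]
    pct <- if (length(per_ind)) rowMeans(do.call(cbind, per_ind))
           else rep(NA_real_, 5)
    pop_segs <- segments[segments$sample_id %in%
                           ds$samples$sample_id[sidx], , drop = FALSE]
    cl_all <- classify_segments(pop_segs)
    class_rows[[p]] <- data.frame(population = p, class = bounds$class,
                                  pct_of_coverage = pct,
                                  mean_length_bp = cl_all$mean_length_bp,
                                  n_segments = cl_all$n_segments,
                                  stringsAsFactors = FALSE)
  }
  froh_by_population <- aggregate(froh ~ population, froh_by_sample, mean)
  list(class_summary = do.call(rbind, c(class_rows, make.row.names = FALSE)),
       froh_by_sample = froh_by_sample,
       froh_by_population = froh_by_population,
       segments = segments)
}

#' Write ROH results as TSV files
#'
#' @param summary output of [population_roh_summary()]
#' @param dir output directory
#' @return invisibly, the written paths
#' @export
write_roh_summary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("roh_segments.tsv", "roh_class_summary.tsv",
                            "froh_per_sample.tsv"))
  data.table::fwrite(summary$segments, paths[1], sep = "\t")
  data.table::fwrite(summary$class_summary, paths[2], sep = "\t")
  data.table::fwrite(summary$froh_by_sample, paths[3], sep = "\t")
  invisible(paths)
}
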