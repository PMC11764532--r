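#' SNP genotype dataset
#'
#' The container every stage of the pipeline exchanges: a dosage matrix over
#' samples and autosomal SNPs, a physical map, and a sample/population table.
#' Dosages count copies of `allele_b` (0, 1, 2; `NA` = missing call). SNPs
#' are kept sorted by chromosome then base-pair position, with unique ids.
#'
#' @param geno integer matrix, samples in rows, SNPs in columns. Values in
#'   `{0, 1, 2, NA}`, counting copies of `allele_b`.
#' @param map data.frame with columns `snp_id`, `chrom` (integer autosome
#'   label), `pos` (1-based bp), `allele_a`, `allele_b`. One row per column
#'   of `geno`, in the same order.
#' @param samples data.frame with columns `sample_id` (unique) and
#'   `population`. One row per row of `geno`, in the same order.
#' @param haplotypes optional phased haplotype matrix, SNPs in rows and one
#'   column per haplotype (columns `2i - 1` and `2i` belong to sample `i`;
#'   entries 0/1 counting `allele_b`). Carried by the simulator so breeding
#'   can continue from a dataset; ignored by the analysis modules.
#'
#' @return An object of class `snp_dataset`.
#' @export
snp_dataset <- function(geno, map, samples, haplotypes = NULL) {
  .assert(is.matrix(geno), "geno must be a matrix")
  map <- as.data.frame(map)
  samples <- as.data.frame(samples)
  need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  .assert(all(need %in% names(map)), "map lacks columns: %s",
          paste(setdiff(need, names(map)), collapse = ", "))
  .assert(all(c("sample_id", "population") %in% names(samples)),
          "samples needs sample_id and population columns")
  .assert(nrow(map) == ncol(geno),
          "map rows (%d) != geno columns (%d)", nrow(map), ncol(geno))
  .assert(nrow(samples) == nrow(geno),
          "sample rows (%d) != geno rows (%d)", nrow(samples), nrow(geno))
  .assert(!anyDuplicated(samples$sample_id),
          "duplicate sample_id in samples table")
  .assert(all(map$pos > 0, na.rm = TRUE), "positions must be positive")
  map$chrom <- as.integer(map$chrom)
  map$pos <- as.numeric(map$pos)
  map$snp_id <- as.character(map$snp_id)

  if (anyDuplicated(map$snp_id)) .stopf("duplicate snp_id in map")

  # sort by chromosome, position; ties on position keep the lexicographically
  # first snp_id and drop the rest (logged via attribute)
  ord <- order(map$chrom, map$pos, map$snp_id)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  dup <- duplicated(map[c("chrom", "pos")])
  n_dup_pos <- sum(dup)
  if (n_dup_pos > 0) {
    message(sprintf("dropping %d SNP(s) at duplicated positions", n_dup_pos))
    map <- map[!dup, , drop = FALSE]
    geno <- geno[, !dup, drop = FALSE]
  }
  rownames(map) <- NULL
  rownames(samples) <- NULL
  storage.mode(geno) <- "integer"
  .assert(all(geno %in% c(0L, 1L, 2L) | is.na(geno)),
          "genotype dosages must be 0, 1, 2 or NA")
  dimnames(geno) <- list(samples$sample_id, map$snp_id)

  ds <- structure(
    list(geno = geno, map = map, samples = samples, haplotypes = haplotypes),
    n_duplicate_pos_dropped = n_dup_pos,
    class = "snp_dataset"
  )
  ds
}

#' @export
print.snp_dataset <- function(x, ...) {
  cat(sprintf("<snp_dataset> %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  tab <- table(x$samples$population)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat(sprintf("  genotyping rate: %.4f\n", mean(!is.na(x$geno))))
  invisible(x)
}

#' Number of samples / SNPs in a dataset
#' @param ds a [snp_dataset()]
#' @return integer count
#' @export
n_samples <- function(ds) nrow(ds$geno)

#' @rdname n_samples
#' @export
n_snps <- function(ds) ncol(ds$geno)

#' Population labels present in a dataset
#' @param ds a [snp_dataset()]
#' @return character vector of unique population labels
#' @export
populations <- function(ds) unique(ds$samples$population)

#' @noRd
.pop_rows <- function(ds, population) {
  .assert(population %in% ds$samples$population,
          "unknown population label '%s'", population,
          class = "wolfdogpop_lookup_error")
  which(ds$samples$population == population)
}

#' Subset a dataset by samples or SNPs
#'
#' @param ds a [snp_dataset()]
#' @param samples sample ids, row indices or logical mask
#' @param snps snp ids, column indices or logical mask
#' @return a new `snp_dataset`
#' @export
subset_dataset <- function(ds, samples = NULL, snps = NULL) {
  ri <- seq_len(nrow(ds$geno))
  ci <- seq_len(ncol(ds$geno))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, ds$samples$sample_id)
          else ri[samples]
    .assert(!anyNA(ri), "unknown sample id(s)")
  }
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, ds$map$snp_id) else ci[snps]
    .assert(!anyNA(ci), "unknown snp id(s)")
  }
  hap <- ds$haplotypes
  if (!is.null(hap)) {
    hc <- as.vector(rbind(2L * ri - 1L, 2L * ri))
    hap <- hap[ci, hc, drop = FALSE]
  }
  snp_dataset(ds$geno[ri, ci, drop = FALSE],
              ds$map[ci, , drop = FALSE],
              ds$samples[ri, , drop = FALSE],
              haplotypes = hap)
}

#' Test two datasets for equal genotype content
#' @param a,b [snp_dataset()] objects
#' @return TRUE if map, samples and dosage matrices are identical
#' @export
dataset_equal <- function(a, b) {
  isTRUE(all.equal(a$map[c("snp_id", "chrom", "pos", "allele_a", "allele_b")],
                   b$map[c("snp_id", "chrom", "pos", "allele_a", "allele_b")])) &&
    identical(a$samples$sample_id, b$samples$sample_id) &&
    identical(a$samples$population, b$samples$population) &&
    identical(unname(a$geno), unname(b$geno))
}
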