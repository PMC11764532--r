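#  Cross-panel allele harmonization, merging and missingness filtering.

#' @noRd
.merge_report <- function(n_flipped = 0L, n_ambiguous_dropped = 0L,
                          n_name_conflicts = 0L, n_removed_missingness = 0L,
                          genotyping_rate = NA_real_) {
  structure(list(n_flipped = as.integer(n_flipped),
                 n_ambiguous_dropped = as.integer(n_ambiguous_dropped),
                 n_name_conflicts = as.integer(n_name_conflicts),
                 n_removed_missingness = as.integer(n_removed_missingness),
                 genotyping_rate = genotyping_rate),
            class = "merge_report")
}

#' @export
print.merge_report <- function(x, ...) {
  cat("<merge_report>\n")
  cat(sprintf("  strand-flipped SNPs:        %d\n", x$n_flipped))
  cat(sprintf("  ambiguous A/T, C/G dropped: %d\n", x$n_ambiguous_dropped))
  cat(sprintf("  irreconcilable dropped:     %d\n", x$n_name_conflicts))
  cat(sprintf("  removed by missingness:     %d\n", x$n_removed_missingness))
  if (!is.na(x$genotyping_rate))
    cat(sprintf("  genotyping rate:            %.4f\n", x$genotyping_rate))
  invisible(x)
}

#' Harmonize allele strand and orientation between two panels
#'
#' For SNPs shared by id, `other` is brought onto `reference`'s strand and
#' dosage orientation: alleles that are the reverse complement of the
#' reference pair are strand-flipped; pairs listed in the opposite order are
#' swapped (dosage recoded `2 - x`). Strand-ambiguous SNPs (A/T or C/G in
#' either panel) cannot be checked and are removed from both datasets, as are
#' shared SNPs whose alleles cannot be reconciled at all.
#'
#' @param reference,other [snp_dataset()] objects sharing at least one snp_id
#' @return list with elements `reference`, `other` (both possibly reduced),
#'   and `report` (a `merge_report` with `n_flipped`, `n_ambiguous_dropped`,
#'   `n_name_conflicts`)
#' @export
harmonize_alleles <- function(reference, other) {
  shared <- intersect(reference$map$snp_id, other$map$snp_id)
  .assert(length(shared) > 0, "datasets share no SNP ids",
          class = "wolfdogpop_empty_intersection_error")
  ri <- match(shared, reference$map$snp_id)
  oi <- match(shared, other$map$snp_id)
  ra <- reference$map$allele_a[ri]; rb <- reference$map$allele_b[ri]
  oa <- other$map$allele_a[oi];     ob <- other$map$allele_b[oi]

  amb <- .is_ambiguous_pair(ra, rb) | .is_ambiguous_pair(oa, ob)

  # classify each remaining shared SNP: keep / swap / flip / flip+swap / conflict
  same_pair  <- !amb & !is.na(ob) & ((oa == ra & ob == rb) | (oa == rb & ob == ra))
  swap_only  <- same_pair & oa == rb
  ca <- .complement(oa); cb <- .complement(ob)
  comp_pair  <- !amb & !same_pair & !is.na(ob) &
    ((ca == ra & cb == rb) | (ca == rb & cb == ra))
  flip_swap  <- comp_pair & ca == rb
  # monomorphic in `other` (allele_b unknown): orient by the one known allele
  mono       <- !amb & is.na(ob) & !is.na(oa)
  mono_keep  <- mono & oa == ra
  mono_swap  <- mono & oa == rb
  mono_flip  <- mono & !mono_keep & !mono_swap & ca == ra
  mono_fswap <- mono & !mono_keep & !mono_swap & ca == rb
  resolved <- same_pair | comp_pair | mono_keep | mono_swap | mono_flip |
    mono_fswap
  conflict <- !amb & !resolved

  geno <- other$geno
  map <- other$map
  apply_swap <- oi[swap_only | flip_swap | mono_swap | mono_fswap]
  if (length(apply_swap))
    geno[, apply_swap] <- 2L - geno[, apply_swap, drop = FALSE]
  n_flipped <- sum(comp_pair | mono_flip | mono_fswap)
  # after flip/swap the shared SNPs adopt the reference orientation outright
  fix <- oi[resolved]
  map$allele_a[fix] <- ra[resolved]
  map$allele_b[fix] <- rb[resolved]

  drop_ids <- shared[amb | conflict]
  keep_other <- !(map$snp_id %in% drop_ids)
  keep_ref <- !(reference$map$snp_id %in% drop_ids)

  out_other <- snp_dataset(geno[, keep_other, drop = FALSE],
                           map[keep_other, , drop = FALSE],
                           other$samples)
  out_ref <- subset_dataset(reference, snps = keep_ref)
  list(reference = out_ref,
       other = out_other,
       report = .merge_report(n_flipped = n_flipped,
                              n_ambiguous_dropped = sum(amb),
                              n_name_conflicts = sum(conflict)))
}

#' Merge harmonized datasets
#'
#' SNP set is the intersection across inputs (compared by id, with allele
#' orientation required to agree — run [harmonize_alleles()] first); sample
#' set is the union. Result is sorted by chromosome and position.
#'
#' @param datasets list of pairwise-harmonized [snp_dataset()] objects
#' @return a merged [snp_dataset()]
#' @export
merge_datasets <- function(datasets) {
  .assert(length(datasets) >= 1, "need at least one dataset")
  if (length(datasets) == 1L) return(datasets[[1]])
  ids <- unlist(lapply(datasets, function(d) d$samples$sample_id))
  if (anyDuplicated(ids))
    .stopf("duplicate sample_id across inputs: %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           class = "wolfdogpop_conflict_error")
  common <- Reduce(intersect, lapply(datasets, function(d) d$map$snp_id))
  .assert(length(common) > 0, "no SNPs shared by all inputs",
          class = "wolfdogpop_empty_intersection_error")
  ref_map <- datasets[[1]]$map
  ref_map <- ref_map[match(common, ref_map$snp_id), , drop = FALSE]
  pieces <- lapply(datasets, function(d) {
    i <- match(common, d$map$snp_id)
    a <- d$map$allele_a[i]; b <- d$map$allele_b[i]
    ok <- (is.na(a) | is.na(ref_map$allele_a) | a == ref_map$allele_a) &
      (is.na(b) | is.na(ref_map$allele_b) | b == ref_map$allele_b)
    if (!all(ok))
      .stopf("allele orientation disagrees for %d SNP(s); harmonize first",
             sum(!ok), class = "wolfdogpop_conflict_error")
    d$geno[, i, drop = FALSE]
  })
  # adopt allele labels from the first dataset that knows them
  for (d in datasets) {
    i <- match(common, d$map$snp_id)
    upd <- is.na(ref_map$allele_b) & !is.na(d$map$allele_b[i])
    ref_map$allele_b[upd] <- d$map$allele_b[i][upd]
    upd <- is.na(ref_map$allele_a) & !is.na(d$map$allele_a[i])
    ref_map$allele_a[upd] <- d$map$allele_a[i][upd]
  }
  snp_dataset(do.call(rbind, pieces), ref_map,
              do.call(rbind, lapply(datasets, `[[`, "samples")))
}

#' Drop SNPs missing in too many samples
#'
#' Removes SNPs where strictly more than `max_missing_samples` samples have a
#' missing call (the merged-panel filter: "more than 6 samples missing").
#'
#' @param ds a [snp_dataset()]
#' @param max_missing_samples maximum tolerated number of missing calls per
#'   SNP (default 6)
#' @return list with `dataset` (filtered) and `report` (a `merge_report`
#'   carrying `n_removed_missingness` and the post-filter `genotyping_rate`)
#' @export
filter_by_missing_count <- function(ds, max_missing_samples = 6L) {
  .assert(max_missing_samples >= 0, "max_missing_samples must be >= 0")
  nmiss <- colSums(is.na(ds$geno))
  keep <- nmiss <= max_missing_samples
  out <- subset_dataset(ds, snps = keep)
  list(dataset = out,
       report = .merge_report(n_removed_missingness = sum(!keep),
                              genotyping_rate = genotyping_rate(out)))
}

#' Overall genotyping rate
#'
#' @param ds a [snp_dataset()]
#' @return fraction of non-missing calls over all (sample, SNP) cells
#' @export
genotyping_rate <- function(ds) {
  .assert(length(ds$geno) > 0, "empty dataset",
          class = "wolfdogpop_undefined_input_error")
  mean(!is.na(ds$geno))
}
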