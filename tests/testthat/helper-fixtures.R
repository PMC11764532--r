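# In-code fixture builders shared by the unit tests.

# dataset from a dosage matrix with evenly spaced SNPs
make_dataset <- function(geno, pops, chrom = NULL, pos = NULL,
                         ids = NULL, allele_a = "A", allele_b = "G") {
  geno <- as.matrix(geno)
  S <- ncol(geno)
  chrom <- chrom %||% rep(1L, S)
  pos <- pos %||% as.numeric(ave(seq_len(S), chrom, FUN = seq_along) * 1e5)
  ids <- ids %||% sprintf("ind%d", seq_len(nrow(geno)))
  snp_dataset(geno,
              data.frame(snp_id = sprintf("s%d", seq_len(S)), chrom = chrom,
                         pos = pos,
                         allele_a = rep_len(allele_a, S),
                         allele_b = rep_len(allele_b, S),
                         stringsAsFactors = FALSE),
              data.frame(sample_id = ids,
                         population = rep_len(pops, nrow(geno)),
                         stringsAsFactors = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random dataset for property sweeps
random_dataset <- function(n, S, pops = "pop", miss = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- runif(S, 0.05, 0.95)
  g <- sapply(p, function(pp) rbinom(n, 2, pp))
  if (miss > 0) g[matrix(runif(n * S) < miss, n, S)] <- NA
  make_dataset(g, pops)
}

# write a PED/MAP pair from inline text, returns the prefix
write_ped_fixture <- function(ped_lines, map_lines, dir = tempfile("plink")) {
  dir.create(dir)
  prefix <- file.path(dir, "panel")
  writeLines(map_lines, paste0(prefix, ".map"))
  writeLines(ped_lines, paste0(prefix, ".ped"))
  prefix
}

tiny_scenario_args <- function() {
  list(n_chromosomes = 2L, n_snps_per_chromosome = 250L,
       parental_split_generations = 8L, dog_lineage_generations = 3L,
       parental_sizes = c(dog = 20L, wolf = 24L), ancestral_size = 24L,
       breed_a = list(breed_size_per_generation = rep(15L, 6L),
                      infusion_schedule = data.frame(generation = c(2L, 4L),
                                                     n_wild = 1L)),
       breed_b = list(breed_size_per_generation = rep(12L, 7L),
                      infusion_schedule = data.frame(generation = 3L,
                                                     n_wild = 1L)),
       n_sample = c(CSW_like = 14L, SAW_like = 10L, GSH_like = 8L,
                    WLF_like = 10L))
}
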