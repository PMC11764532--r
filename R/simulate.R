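#  Forward-in-time diploid Wright-Fisher simulator of wolf x dog breed
#  formation: diverged parental pools, founder crosses, scheduled wild
#  infusions, popular-sire mating bias, and pedigree-based ground truth.

#' Simulator configuration
#'
#' Defaults describe the study conditions the analysis modules are verified
#' under: a 10-chromosome array-like panel (2,000 common SNPs per 100 Mb
#' chromosome at 1 cM/Mb), dog and wolf pools split 50 generations from a
#' shared ancestral pool, and a hybrid breed founded by a dog x wolf cross
#' with scheduled wolf infusions. No new mutations arise during the breed
#' history (decades are mutation-negligible).
#'
#' @param n_chromosomes autosome count (default 10)
#' @param chromosome_length_bp chromosome length (default 1e8 = 100 Mb)
#' @param n_snps_per_chromosome array SNPs per chromosome (default 2000)
#' @param recombination_morgans_per_bp constant map rate (default 1e-8,
#'   i.e. 1 cM/Mb, matching the N_E module's distance convention)
#' @param ancestral_size diploid size of the shared ancestral pool
#'   (default 200)
#' @param parental_split_generations generations the two parental pools
#'   drift after the split (default 50)
#' @param parental_sizes named vector `c(dog = , wolf = )` of diploid pool
#'   sizes (default 100 and 200)
#' @param dog_lineages number of closed stud-book lineages the dog pool
#'   splits into for its final generations (default 3; produces the Wahlund
#'   heterozygote deficit typical of pooled breed samples — the closure must
#'   be deep enough that the deficit is not masked by the small-sample
#'   inflation of observed relative to expected heterozygosity)
#' @param dog_lineage_generations generations the dog lineages stay closed
#'   (default 15, roughly 45 years of separate show/working lines)
#' @param founder_cross named vector `c(n_dog_founders = , n_wolf_founders
#'   = )` (default 4 dogs, 1 wolf)
#' @param infusion_schedule data.frame (`generation`, `n_wild`): wolves
#'   added to the breeding pool at those breed generations (default
#'   generations 2, 4, 6, 9, one wolf each — the recorded cadence of
#'   Carpathian wolf pairings)
#' @param breed_size_per_generation offspring per breed generation (default
#'   60 for 22 generations, a ~66-year history at 3 years/generation)
#' @param popular_sire_weight Dirichlet concentration for per-sire usage
#'   weights; small values concentrate matings on few sires, large values
#'   approach uniform usage (default 2)
#' @param missing_rate genotype missingness planted in sampled datasets
#'   (default 0.01)
#' @param ascertainment_maf minimum ancestral-pool frequency for a SNP to be
#'   on the simulated array (default 0.05; common-variant ascertainment)
#' @param seed integer RNG seed; every simulator entry point is
#'   deterministic given the config
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_chromosomes = 10L, chromosome_length_bp = 1e8,
                       n_snps_per_chromosome = 2000L,
                       recombination_morgans_per_bp = 1e-8,
                       ancestral_size = 200L,
                       parental_split_generations = 50L,
                       parental_sizes = c(dog = 100L, wolf = 200L),
                       dog_lineages = 3L, dog_lineage_generations = 15L,
                       founder_cross = c(n_dog_founders = 4L,
                                         n_wolf_founders = 1L),
                       infusion_schedule = data.frame(
                         generation = c(2L, 4L, 6L, 9L), n_wild = 1L),
                       breed_size_per_generation = rep(60L, 22L),
                       popular_sire_weight = 2,
                       missing_rate = 0.01,
                       ascertainment_maf = 0.05,
                       seed = 1L) {
  # tolerate JSON-parsed configs where vectors arrive as named lists
  parental_sizes <- unlist(parental_sizes)
  founder_cross <- unlist(founder_cross)
  infusion_schedule <- as.data.frame(infusion_schedule)
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_bp = chromosome_length_bp,
              n_snps_per_chromosome = as.integer(n_snps_per_chromosome),
              recombination_morgans_per_bp = recombination_morgans_per_bp,
              ancestral_size = as.integer(ancestral_size),
              parental_split_generations = as.integer(parental_split_generations),
              parental_sizes = parental_sizes,
              dog_lineages = as.integer(dog_lineages),
              dog_lineage_generations = as.integer(dog_lineage_generations),
              founder_cross = founder_cross,
              infusion_schedule = infusion_schedule,
              breed_size_per_generation = as.integer(breed_size_per_generation),
              popular_sire_weight = popular_sire_weight,
              missing_rate = missing_rate,
              ascertainment_maf = ascertainment_maf,
              seed = as.integer(seed))
  bad <- character()
  if (cfg$n_chromosomes < 1) bad <- c(bad, "n_chromosomes")
  if (cfg$chromosome_length_bp < 1) bad <- c(bad, "chromosome_length_bp")
  if (cfg$n_snps_per_chromosome < 1) bad <- c(bad, "n_snps_per_chromosome")
  if (cfg$recombination_morgans_per_bp <= 0)
    bad <- c(bad, "recombination_morgans_per_bp")
  if (cfg$ancestral_size < 1) bad <- c(bad, "ancestral_size")
  if (cfg$parental_split_generations < 0)
    bad <- c(bad, "parental_split_generations")
  if (length(cfg$parental_sizes) != 2 || any(cfg$parental_sizes < 2))
    bad <- c(bad, "parental_sizes")
  if (cfg$dog_lineages < 1) bad <- c(bad, "dog_lineages")
  if (length(cfg$founder_cross) != 2 || any(cfg$founder_cross < 0) ||
      sum(cfg$founder_cross) < 2) bad <- c(bad, "founder_cross")
  if (any(cfg$breed_size_per_generation < 1))
    bad <- c(bad, "breed_size_per_generation")
  if (cfg$popular_sire_weight <= 0) bad <- c(bad, "popular_sire_weight")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1) bad <- c(bad, "missing_rate")
  if (cfg$ascertainment_maf < 0 || cfg$ascertainment_maf >= 0.5)
    bad <- c(bad, "ascertainment_maf")
  if (nrow(cfg$infusion_schedule) &&
      (any(cfg$infusion_schedule$generation < 1) ||
       any(cfg$infusion_schedule$generation >
           length(cfg$breed_size_per_generation))))
    bad <- c(bad, "infusion_schedule")
  if (length(bad))
    .stopf("invalid sim_config field(s): %s", paste(bad, collapse = ", "),
           class = "wolfdogpop_validation_error")
  structure(cfg, class = "sim_config")
}

# ---- genome geometry ------------------------------------------------------

#' @noRd
.sim_geometry <- function(config) {
  S <- config$n_chromosomes * config$n_snps_per_chromosome
  chrom <- rep(seq_len(config$n_chromosomes),
               each = config$n_snps_per_chromosome)
  pos <- unlist(lapply(seq_len(config$n_chromosomes), function(ch)
    sort(sample.int(config$chromosome_length_bp,
                    config$n_snps_per_chromosome))))
  # allele pairs drawn from the four strand-unambiguous combinations
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  pick <- pairs[sample.int(4, S, replace = TRUE), , drop = FALSE]
  map <- data.frame(snp_id = sprintf("snp_%d_%d", chrom, pos),
                    chrom = chrom, pos = as.numeric(pos),
                    allele_a = pick[, 1], allele_b = pick[, 2],
                    stringsAsFactors = FALSE)
  idx <- split(seq_len(S), chrom)
  list(map = map,
       chr_idx = idx,
       chr_pos = lapply(idx, function(i) map$pos[i]),
       chr_len = rep(config$chromosome_length_bp, config$n_chromosomes),
       chr_morgans = rep(config$chromosome_length_bp *
                           config$recombination_morgans_per_bp,
                         config$n_chromosomes))
}

#' @noRd
.ancestral_frequencies <- function(config) {
  # Beta(0.8, 0.8) truncated to [maf, 1 - maf]: array-like common-variant SFS
  S <- config$n_chromosomes * config$n_snps_per_chromosome
  a <- config$ascertainment_maf
  lo <- stats::pbeta(a, 0.8, 0.8); hi <- stats::pbeta(1 - a, 0.8, 0.8)
  stats::qbeta(stats::runif(S, lo, hi), 0.8, 0.8)
}

#' @noRd
.founder_haplotypes <- function(p, n_diploid) {
  # linkage-equilibrium founders: independent Bernoulli(p) per haplotype;
  # haplotypes are columns (SNP-major) so gamete formation is contiguous
  S <- length(p)
  matrix(stats::rbinom(2L * n_diploid * S, 1L, p),
         nrow = S, ncol = 2L * n_diploid)
}

# one recombinant gamete from diploid parent `pr` (columns 2pr-1, 2pr of H)
#' @noRd
.gamete <- function(H, pr, geom) {
  h1 <- H[, 2L * pr - 1L]
  h2 <- H[, 2L * pr]
  out <- h1
  nch <- length(geom$chr_idx)
  ks <- stats::rpois(nch, geom$chr_morgans)
  starts <- stats::runif(nch) < 0.5
  for (ch in seq_len(nch)) {
    k <- ks[ch]
    idx <- geom$chr_idx[[ch]]
    if (k == 0L) {
      if (starts[ch]) out[idx] <- h2[idx]
      next
    }
    pos <- geom$chr_pos[[ch]]
    phase <- if (k == 1L) {
      (starts[ch] + (pos > stats::runif(1, 0, geom$chr_len[ch]))) %% 2L
    } else {
      xo <- sort.int(stats::runif(k, 0, geom$chr_len[ch]), method = "quick")
      (starts[ch] + findInterval(pos, xo)) %% 2L
    }
    sw <- idx[phase == 1L]
    out[sw] <- h2[sw]
  }
  out
}

# one Wright-Fisher generation: N_next offspring from random distinct parents
#' @noRd
.wf_step <- function(H, N_next, geom) {
  N <- ncol(H) %/% 2L
  p1 <- sample.int(N, N_next, replace = TRUE)
  p2 <- sample.int(N, N_next, replace = TRUE)
  clash <- which(p1 == p2)
  while (length(clash)) {
    p2[clash] <- sample.int(N, length(clash), replace = TRUE)
    clash <- clash[p1[clash] == p2[clash]]
  }
  Hn <- matrix(0L, nrow(H), 2L * N_next)
  for (i in seq_len(N_next)) {
    Hn[, 2L * i - 1L] <- .gamete(H, p1[i], geom)
    Hn[, 2L * i] <- .gamete(H, p2[i], geom)
  }
  Hn
}

#' @noRd
.hap_to_dataset <- function(H, geom, ids, population, missing_rate = 0) {
  g <- t(H[, seq(1L, ncol(H), by = 2L), drop = FALSE] +
           H[, seq(2L, ncol(H), by = 2L), drop = FALSE])
  if (missing_rate > 0) {
    mask <- stats::runif(length(g)) < missing_rate
    g[mask] <- NA_integer_
  }
  snp_dataset(g, geom$map,
              data.frame(sample_id = ids, population = population,
                         stringsAsFactors = FALSE),
              haplotypes = H)
}

# ---- parental pools -------------------------------------------------------

#' Simulate diverged dog and wolf parental pools
#'
#' Draws ancestral allele frequencies from a truncated Beta spectrum, builds
#' a shared ancestral haplotype pool, then lets a dog pool and a wolf pool
#' drift independently for `parental_split_generations` under Wright-Fisher
#' reproduction with recombination. With `parental_split_generations = 0`
#' both pools are literal copies of the ancestral pool. The dog pool can
#' spend its final generations split into closed lineages (see
#' [sim_config()]), mimicking stud-book substructure.
#'
#' @param config a [sim_config()]
#' @return list with `dog` and `wolf` ([snp_dataset()] objects carrying
#'   haplotypes; the dog samples table gains a `lineage` column when
#'   substructured) and `truth` (`divergence_fst_expected`, the closed-form
#'   drift expectation `mean(1 - (1 - 1/(2 N_i))^t)` over the two pools)
#' @export
simulate_parental_pools <- function(config = sim_config()) {
  set.seed(config$seed)
  geom <- .sim_geometry(config)
  p <- .ancestral_frequencies(config)
  H_anc <- .founder_haplotypes(p, config$ancestral_size)

  t_split <- config$parental_split_generations
  n_dog <- config$parental_sizes[[1]]
  n_wolf <- config$parental_sizes[[2]]

  drift <- function(H, N, gens) {
    for (g in seq_len(gens)) H <- .wf_step(H, N, geom)
    H
  }

  lineage <- NULL
  if (t_split == 0) {
    H_dog <- H_anc
    H_wolf <- H_anc
  } else {
    t_lin <- if (config$dog_lineages > 1)
      min(config$dog_lineage_generations, t_split) else 0L
    H_dog <- drift(H_anc, n_dog, t_split - t_lin)
    if (t_lin > 0) {
      L <- config$dog_lineages
      sizes <- rep(n_dog %/% L, L)
      sizes[L] <- n_dog - sum(sizes[-L])
      grp <- rep(seq_len(L), sizes)
      parts <- lapply(seq_len(L), function(l) {
        cols <- which(grp == l)
        drift(H_dog[, as.vector(rbind(2L * cols - 1L, 2L * cols)),
                    drop = FALSE], sizes[l], t_lin)
      })
      H_dog <- do.call(cbind, parts)
      lineage <- rep(seq_len(L), sizes)
    }
    H_wolf <- drift(H_anc, n_wolf, t_split)
  }

  dog_ids <- sprintf("dog_%d", seq_len(ncol(H_dog) %/% 2L))
  wolf_ids <- sprintf("wolf_%d", seq_len(ncol(H_wolf) %/% 2L))
  dog <- .hap_to_dataset(H_dog, geom, dog_ids, "dog_pool")
  if (!is.null(lineage)) dog$samples$lineage <- lineage
  wolf <- .hap_to_dataset(H_wolf, geom, wolf_ids, "wolf_pool")
  f_drift <- function(N, t) 1 - (1 - 1 / (2 * N))^t
  list(dog = dog, wolf = wolf,
       truth = list(divergence_fst_expected =
                      mean(c(f_drift(n_dog, t_split), f_drift(n_wolf, t_split)))),
       geometry = geom, config = config)
}

# ---- breed history --------------------------------------------------------

#' @noRd
.draw_sires <- function(n_offspring, n_sires, weight) {
  # popularity weights ~ Dirichlet(weight); weight -> Inf gives uniform usage
  w <- stats::rgamma(n_sires, shape = weight, rate = 1)
  if (all(w == 0)) w <- rep(1, n_sires)
  sample.int(n_sires, n_offspring, replace = TRUE, prob = w / sum(w))
}

#' Simulate a hybrid breed from two parental pools
#'
#' Founds the breed with `founder_cross` dogs and wolves drawn from the
#' pools (wolf founders enter as dams, matching the recorded histories),
#' then breeds discrete generations of `breed_size_per_generation` offspring.
#' Dams are used uniformly; sires are reused with Dirichlet-distributed
#' popularity weights (`popular_sire_weight`). Wolves listed in
#' `infusion_schedule` join the breeding pool at the stated generation. The
#' full pedigree is recorded; the final generation is genotyped with
#' `missing_rate` missingness.
#'
#' @param dog,wolf parental-pool datasets from [simulate_parental_pools()]
#'   (must carry haplotypes)
#' @param config a [sim_config()]
#' @param label population label and id prefix for the breed
#' @param seed RNG seed for the breed history (default `config$seed + 1`)
#' @return list with `dataset` (final generation, class [snp_dataset()]) and
#'   `truth`: `pedigree` (id, sire, dam, generation, sex, origin, f_ped),
#'   `f_ped` for the sampled individuals, `realized_ne` per generation
#'   (distinct breeders, sex-ratio formula and offspring-variance adjusted),
#'   `mean_het_per_generation`
#' @export
simulate_breed <- function(dog, wolf, config = sim_config(), label = "breed",
                           seed = config$seed + 1L) {
  .assert(!is.null(dog$haplotypes) && !is.null(wolf$haplotypes),
          "parental datasets must carry haplotypes (see simulate_parental_pools)")
  set.seed(seed)
  n_chr <- length(unique(dog$map$chrom))
  geom <- list(map = dog$map,
               chr_idx = split(seq_len(nrow(dog$map)), dog$map$chrom),
               chr_pos = split(dog$map$pos, dog$map$chrom),
               chr_len = rep(config$chromosome_length_bp, n_chr),
               chr_morgans = rep(config$chromosome_length_bp *
                                   config$recombination_morgans_per_bp, n_chr))
  n_fd <- config$founder_cross[[1]]
  n_fw <- config$founder_cross[[2]]
  .assert(n_fd <= n_samples(dog) && n_fw <= n_samples(wolf),
          "founder_cross exceeds pool sizes",
          class = "wolfdogpop_validation_error")

  pick_dog <- sample.int(n_samples(dog), n_fd)
  wolf_order <- sample.int(n_samples(wolf))  # founders then infusions
  n_inf_total <- if (nrow(config$infusion_schedule))
    sum(config$infusion_schedule$n_wild) else 0L
  .assert(n_fw + n_inf_total <= n_samples(wolf),
          "wolf pool too small for founders plus infusions",
          class = "wolfdogpop_validation_error")
  wolf_ptr <- 0L
  take_wolves <- function(k) {
    out <- wolf_order[wolf_ptr + seq_len(k)]
    wolf_ptr <<- wolf_ptr + k
    out
  }

  hap_cols <- function(i) as.vector(rbind(2L * i - 1L, 2L * i))
  H_breeders <- cbind(dog$haplotypes[, hap_cols(pick_dog), drop = FALSE],
                      if (n_fw > 0)
                        wolf$haplotypes[, hap_cols(take_wolves(n_fw)),
                                        drop = FALSE])
  # dogs alternate male/female starting male; wolf founders are dams
  sex_d <- rep(c("M", "F"), length.out = n_fd)
  sexes <- c(sex_d, rep("F", n_fw))
  ids <- c(sprintf("%s_fd%d", label, seq_len(n_fd)),
           if (n_fw > 0) sprintf("%s_fw%d", label, seq_len(n_fw)))
  ped <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                    generation = 0L, sex = sexes,
                    origin = c(rep("dog_founder", n_fd),
                               rep("wolf_founder", n_fw)),
                    stringsAsFactors = FALSE)

  sizes <- config$breed_size_per_generation
  G <- length(sizes)
  mean_het <- numeric(G)
  ne_rows <- list()
  inf <- config$infusion_schedule

  for (g in seq_len(G)) {
    if (nrow(inf)) {
      row <- which(inf$generation == g)
      for (r in row) {
        k <- inf$n_wild[r]
        widx <- take_wolves(k)
        H_breeders <- cbind(H_breeders,
                            wolf$haplotypes[, hap_cols(widx), drop = FALSE])
        ped <- rbind(ped, data.frame(
          id = sprintf("%s_inf%d_%d", label, g, seq_len(k)),
          sire = NA_character_, dam = NA_character_,
          generation = g - 1L, sex = "F", origin = "wolf_infusion",
          stringsAsFactors = FALSE))
      }
    }
    breeders <- which(ped$generation == g - 1L)
    b_ids <- ped$id[breeders]
    b_sex <- ped$sex[breeders]
    males <- which(b_sex == "M"); females <- which(b_sex == "F")
    if (!length(males) || !length(females))
      .stopf("breed '%s' collapsed at generation %d (no %s breeders)",
             label, g, if (length(males)) "female" else "male",
             class = "wolfdogpop_collapse_error")
    N_off <- sizes[g]
    sire_pick <- males[.draw_sires(N_off, length(males),
                                   config$popular_sire_weight)]
    dam_pick <- females[sample.int(length(females), N_off, replace = TRUE)]
    H_next <- matrix(0L, nrow(H_breeders), 2L * N_off)
    for (i in seq_len(N_off)) {
      H_next[, 2L * i - 1L] <- .gamete(H_breeders, sire_pick[i], geom)
      H_next[, 2L * i] <- .gamete(H_breeders, dam_pick[i], geom)
    }
    off <- data.frame(id = sprintf("%s_g%d_%d", label, g, seq_len(N_off)),
                      sire = b_ids[sire_pick], dam = b_ids[dam_pick],
                      generation = g,
                      sex = sample(c("M", "F"), N_off, replace = TRUE),
                      origin = "breed", stringsAsFactors = FALSE)
    ped <- rbind(ped, off)
    H_breeders <- H_next
    mean_het[g] <- mean(H_next[, seq(1L, 2L * N_off, 2L)] !=
                          H_next[, seq(2L, 2L * N_off, 2L)])

    ks <- table(off$sire); kd <- table(off$dam)
    ne_rows[[g]] <- data.frame(
      breed = label, generation = g,
      n_sires = length(ks), n_dams = length(kd),
      ne_sex_ratio = 4 * length(ks) * length(kd) /
        (length(ks) + length(kd)),
      ne_adjusted = .ne_crow_denniston(as.integer(ks), as.integer(kd)))
  }

  f <- pedigree_inbreeding(ped)
  ped$f_ped <- f
  final <- ped[ped$generation == G, , drop = FALSE]
  ds <- .hap_to_dataset(H_breeders, geom, final$id, label,
                        missing_rate = config$missing_rate)
  list(dataset = ds,
       truth = list(pedigree = ped,
                    f_ped = data.frame(sample_id = final$id,
                                       f_ped = final$f_ped,
                                       stringsAsFactors = FALSE),
                    realized_ne = do.call(rbind, ne_rows),
                    mean_het_per_generation = mean_het))
}

#' @noRd
.ne_crow_denniston <- function(k_sires, k_dams) {
  per_sex <- function(k) {
    N <- length(k); kb <- mean(k); V <- stats::var(k)
    if (is.na(V)) V <- 0
    den <- kb - 1 + V / kb
    if (den <= 0) return(Inf)
    (N * kb - 1) / den
  }
  nm <- per_sex(k_sires); nf <- per_sex(k_dams)
  if (!is.finite(nm) || !is.finite(nf)) return(NA_real_)
  4 * nm * nf / (nm + nf)
}

# ---- pedigree ground truth ------------------------------------------------

#' Kinship matrix from a recorded pedigree (tabular method)
#'
#' Founders (missing parents) are assumed unrelated and non-inbred. The
#' pedigree must list parents before offspring.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam` (NA for
#'   founders)
#' @return symmetric kinship matrix (self-kinship on the diagonal)
#' @export
kinship_from_pedigree <- function(pedigree) {
  n <- nrow(pedigree)
  id <- pedigree$id
  si <- match(pedigree$sire, id)
  di <- match(pedigree$dam, id)
  .assert(all(is.na(si) | si < seq_len(n)) && all(is.na(di) | di < seq_len(n)),
          "pedigree must list parents before offspring",
          class = "wolfdogpop_input_error")
  phi <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s) && is.na(d)) {
      phi[i, i] <- 0.5
    } else {
      prev <- seq_len(i - 1L)
      ks <- if (is.na(s)) 0 else phi[s, prev]
      kd <- if (is.na(d)) 0 else phi[d, prev]
      v <- 0.5 * (ks + kd)
      phi[i, prev] <- v
      phi[prev, i] <- v
      phi[i, i] <- 0.5 * (1 + if (is.na(s) || is.na(d)) 0 else phi[s, d])
    }
  }
  phi
}

#' Pedigree inbreeding coefficients
#'
#' `F` of an individual equals the kinship of its parents; founders get 0.
#'
#' @inheritParams kinship_from_pedigree
#' @return numeric vector of inbreeding coefficients, one per pedigree row
#' @export
pedigree_inbreeding <- function(pedigree) {
  phi <- kinship_from_pedigree(pedigree)
  unname(2 * diag(phi) - 1)
}

# ---- convenience scenarios ------------------------------------------------

#' Constant-size Wright-Fisher population for parameter-recovery checks
#'
#' Founds a population at linkage equilibrium with the array-like frequency
#' spectrum and drifts it at constant diploid size `n`, letting LD build to
#' the drift-recombination equilibrium that the Sved inversion assumes.
#'
#' @param n constant diploid population size
#' @param n_generations generations of drift (default 100, comfortably past
#'   equilibration for the 1-30 generation lookback window)
#' @param n_sample diploid individuals sampled at the end
#' @param config a [sim_config()] (geometry, ascertainment, seed)
#' @param label population label
#' @return a [snp_dataset()] of the sampled individuals
#' @export
simulate_constant_size <- function(n = 100L, n_generations = 100L,
                                   n_sample = 50L, config = sim_config(),
                                   label = "simpop") {
  set.seed(config$seed)
  geom <- .sim_geometry(config)
  p <- .ancestral_frequencies(config)
  H <- .founder_haplotypes(p, n)
  for (g in seq_len(n_generations)) H <- .wf_step(H, n, geom)
  pick <- sort(sample.int(n, min(n_sample, n)))
  cols <- as.vector(rbind(2L * pick - 1L, 2L * pick))
  .hap_to_dataset(H[, cols, drop = FALSE], geom,
                  sprintf("%s_%d", label, seq_along(pick)), label,
                  missing_rate = config$missing_rate)
}

#' The shipped two-breed wolfdog scenario
#'
#' Builds the default study system: a dog pool (with stud-book lineages) and
#' a wolf pool split 50 generations ago, a CSW-like breed (four dog founders
#' plus one wolf, four scheduled wolf infusions, moderate sire reuse, 22
#' generations of 60) and a SAW-like breed (a single dog x wolf pair, early
#' infusions only, heavy sire reuse, 29 generations of 40). Samples the
#' paper-scale population sizes (46/20/12/20) into one merged dataset.
#'
#' @param seed integer seed; the whole scenario is deterministic given it
#' @param n_sample named sample sizes for `CSW_like`, `SAW_like`,
#'   `GSH_like`, `WLF_like`
#' @param breed_a,breed_b named lists overriding [sim_config()] fields for
#'   the CSW-like / SAW-like breed histories
#' @param ... overrides passed to the base [sim_config()] (genome geometry,
#'   pool sizes, split depth) — handy for scaled-down test runs
#' @return list with `dataset` (merged, 4 populations), `truth` (per-breed
#'   pedigrees, `f_ped`, `realized_ne`, pool drift expectation) and
#'   `configs`
#' @export
simulate_wolfdog_scenario <- function(seed = 1L,
                                      n_sample = c(CSW_like = 46L,
                                                   SAW_like = 20L,
                                                   GSH_like = 12L,
                                                   WLF_like = 20L),
                                      breed_a = list(), breed_b = list(),
                                      ...) {
  n_sample <- unlist(n_sample)
  base <- sim_config(seed = seed, ...)
  # wholesale field replacement: data.frame-valued fields (e.g. the infusion
  # schedule) must never be merged column-wise
  override <- function(args, ...) {
    for (ov in list(...)) for (nm in names(ov)) args[[nm]] <- ov[[nm]]
    args
  }
  cfg_a <- do.call(sim_config, override(
    c(unclass(base)),
    list(founder_cross = c(n_dog_founders = 4L, n_wolf_founders = 1L),
         infusion_schedule = data.frame(generation = c(2L, 4L, 6L, 9L),
                                        n_wild = 1L),
         breed_size_per_generation = rep(60L, 22L),
         popular_sire_weight = 2),
    breed_a))
  cfg_b <- do.call(sim_config, override(
    c(unclass(base)),
    list(founder_cross = c(n_dog_founders = 1L, n_wolf_founders = 1L),
         infusion_schedule = data.frame(generation = c(3L, 5L, 7L, 9L),
                                        n_wild = 1L),
         breed_size_per_generation = rep(40L, 29L),
         popular_sire_weight = 0.25),
    breed_b))

  pools <- simulate_parental_pools(base)
  a <- simulate_breed(pools$dog, pools$wolf, cfg_a, "CSW_like",
                      seed = base$seed + 1L)
  b <- simulate_breed(pools$dog, pools$wolf, cfg_b, "SAW_like",
                      seed = base$seed + 2L)

  set.seed(base$seed + 3L)
  ds_a <- if (n_sample[["CSW_like"]] < n_samples(a$dataset))
    subset_dataset(a$dataset, samples = sort(sample.int(
      n_samples(a$dataset), n_sample[["CSW_like"]]))) else a$dataset
  ds_b <- if (n_sample[["SAW_like"]] < n_samples(b$dataset))
    subset_dataset(b$dataset, samples = sort(sample.int(
      n_samples(b$dataset), n_sample[["SAW_like"]]))) else b$dataset

  # balanced draw across dog lineages for the GSH-like sample
  n_gsh <- min(n_sample[["GSH_like"]], n_samples(pools$dog))
  lin <- pools$dog$samples$lineage %||% rep(1L, n_samples(pools$dog))
  by_lin <- split(seq_len(n_samples(pools$dog)), lin)
  quota <- rep(seq_along(by_lin), length.out = n_gsh)
  gsh_rows <- sort(unlist(Map(function(rows, k) sample(rows, k),
                              by_lin, tabulate(quota, length(by_lin)))))
  ds_g <- subset_dataset(pools$dog, samples = gsh_rows)
  ds_g$samples$population <- "GSH_like"
  ds_w <- subset_dataset(pools$wolf, samples = sort(
    sample.int(n_samples(pools$wolf), min(n_sample[["WLF_like"]],
                                          n_samples(pools$wolf)))))
  ds_w$samples$population <- "WLF_like"
  # pool samples get the same planted missingness as the breed datasets
  for (nm in c("ds_g", "ds_w")) {
    d <- get(nm)
    mask <- stats::runif(length(d$geno)) < base$missing_rate
    d$geno[mask] <- NA_integer_
    assign(nm, d)
  }
  ds_g$samples$lineage <- NULL
  merged <- merge_datasets(list(ds_a, ds_b, ds_g, ds_w))
  ped <- rbind(a$truth$pedigree, b$truth$pedigree)
  ped$breed <- rep(c("CSW_like", "SAW_like"),
                   c(nrow(a$truth$pedigree), nrow(b$truth$pedigree)))
  list(dataset = merged,
       truth = list(pedigree = ped,
                    f_ped = rbind(a$truth$f_ped, b$truth$f_ped),
                    realized_ne = rbind(a$truth$realized_ne,
                                        b$truth$realized_ne),
                    mean_het_per_generation = list(
                      CSW_like = a$truth$mean_het_per_generation,
                      SAW_like = b$truth$mean_het_per_generation),
                    divergence_fst_expected =
                      pools$truth$divergence_fst_expected),
       configs = list(base = base, breed_a = cfg_a, breed_b = cfg_b))
}

# ---- output ---------------------------------------------------------------

#' Write a simulated dataset plus its ground truth to disk
#'
#' Produces a PLINK text fileset (`simulated.ped` / `.map`), the population
#' table, the full SNP map with allele orientation (usable as `allele_ref`
#' for an exact round trip), and whichever truth tables are present
#' (`pedigree.tsv`, `f_ped.tsv`, `realized_ne.tsv`), with the configuration
#' serialized as JSON.
#'
#' @param ds a [snp_dataset()]
#' @param truth truth list as returned by the simulators (may be `NULL`)
#' @param out_dir output directory, created if needed
#' @param config optional [sim_config()] to serialize
#' @return invisibly, the output directory
#' @export
write_simulation <- function(ds, truth = NULL, out_dir, config = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .assert(dir.exists(out_dir), "cannot create output directory %s", out_dir,
          class = "wolfdogpop_io_error")
  prefix <- file.path(out_dir, "simulated")
  write_plink_text(ds, prefix)
  write_population_table(ds, file.path(out_dir, "populations.tsv"))
  write_map_table(ds, file.path(out_dir, "snp_map.tsv"))
  if (!is.null(truth)) {
    if (!is.null(truth$pedigree))
      data.table::fwrite(truth$pedigree, file.path(out_dir, "pedigree.tsv"),
                         sep = "\t")
    if (!is.null(truth$f_ped))
      data.table::fwrite(truth$f_ped, file.path(out_dir, "f_ped.tsv"),
                         sep = "\t")
    if (!is.null(truth$realized_ne))
      data.table::fwrite(truth$realized_ne,
                         file.path(out_dir, "realized_ne.tsv"), sep = "\t")
  }
  if (!is.null(config))
    jsonlite::write_json(unclass(config), file.path(out_dir, "sim_config.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(out_dir)
}
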