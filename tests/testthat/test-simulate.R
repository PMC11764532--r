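small_cfg <- function(seed = 1L, ...) {
  defaults <- list(n_chromosomes = 2L, n_snps_per_chromosome = 200L,
                   ancestral_size = 24L,
                   parental_sizes = c(dog = 20L, wolf = 24L),
                   parental_split_generations = 8L,
                   dog_lineage_generations = 3L,
                   founder_cross = c(n_dog_founders = 2L, n_wolf_founders = 1L),
                   infusion_schedule = data.frame(generation = 3L, n_wild = 1L),
                   breed_size_per_generation = rep(12L, 6L),
                   seed = seed)
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  do.call(sim_config, defaults)
}

test_that("invalid configurations are rejected with the offending fields", {
  err <- tryCatch(sim_config(n_chromosomes = 0, missing_rate = 2),
                  error = identity)
  expect_s3_class(err, "wolfdogpop_validation_error")
  expect_match(conditionMessage(err), "n_chromosomes")
  expect_match(conditionMessage(err), "missing_rate")
  expect_error(sim_config(infusion_schedule = data.frame(generation = 99L,
                                                         n_wild = 1L)),
               class = "wolfdogpop_validation_error")
})

test_that("identical configs give bit-identical simulations", {
  a <- simulate_parental_pools(small_cfg(5))
  b <- simulate_parental_pools(small_cfg(5))
  expect_identical(a$dog$geno, b$dog$geno)
  expect_identical(a$wolf$haplotypes, b$wolf$haplotypes)
  ba <- simulate_breed(a$dog, a$wolf, small_cfg(5), "x")
  bb <- simulate_breed(b$dog, b$wolf, small_cfg(5), "x")
  expect_identical(ba$dataset$geno, bb$dataset$geno)
  expect_identical(ba$truth$pedigree, bb$truth$pedigree)
})

test_that("a zero-generation split leaves both pools identical", {
  cfg <- small_cfg(9, parental_split_generations = 0L)
  pools <- simulate_parental_pools(cfg)
  expect_identical(unname(pools$dog$geno), unname(pools$wolf$geno))
  fa <- allele_frequencies(pools$dog, "dog_pool")
  fb <- allele_frequencies(pools$wolf, "wolf_pool")
  expect_equal(fa, fb, ignore_attr = TRUE)
})

test_that("ascertainment truncates founder frequencies at the MAF floor", {
  cfg <- small_cfg(13, parental_split_generations = 0L,
                   ascertainment_maf = 0.2)
  pools <- simulate_parental_pools(cfg)
  f <- allele_frequencies(pools$dog, "dog_pool")
  # binomial sampling scatters realized frequencies around the truncated law
  expect_gt(mean(pmin(f, 1 - f) >= 0.1), 0.95)
})

test_that("pool divergence tracks the closed-form drift expectation", {
  fsts <- vapply(1:3, function(s) {
    cfg <- sim_config(n_chromosomes = 2L, n_snps_per_chromosome = 400L,
                      ancestral_size = 50L,
                      parental_sizes = c(dog = 50L, wolf = 50L),
                      dog_lineages = 1L, parental_split_generations = 60L,
                      seed = 600 + s)
    pools <- simulate_parental_pools(cfg)
    expect_equal(pools$truth$divergence_fst_expected,
                 1 - (1 - 1 / 100)^60)
    m <- merge_datasets(list(pools$dog, pools$wolf))
    pairwise_fst(m, "dog_pool", "wolf_pool")
  }, 0)
  expected <- 1 - (1 - 1 / 100)^60
  expect_gt(mean(fsts), 0.5 * expected)
  expect_lt(mean(fsts), 1.5 * expected)
})

test_that("allele-frequency change under neutral drift is centered on zero", {
  cfg <- small_cfg(21)
  set.seed(cfg$seed)
  geom <- wolfdogpop:::.sim_geometry(cfg)
  p <- wolfdogpop:::.ancestral_frequencies(cfg)
  H0 <- wolfdogpop:::.founder_haplotypes(p, 30L)
  p0 <- rowMeans(H0)
  reps <- 40
  snp_pick <- seq_len(50)
  deltas <- matrix(0, reps, length(snp_pick))
  for (r in seq_len(reps)) {
    H1 <- wolfdogpop:::.wf_step(H0, 30L, geom)
    deltas[r, ] <- rowMeans(H1)[snp_pick] - p0[snp_pick]
  }
  # per-SNP t-tests across replicates, Holm-controlled at alpha = 0.01
  pvals <- apply(deltas, 2, function(d) t.test(d)$p.value)
  expect_equal(sum(p.adjust(pvals, "holm") < 0.01), 0L)
  expect_lt(abs(mean(deltas)), 0.02)
})

test_that("a single full-sib mating gives offspring F = 0.25", {
  ped <- data.frame(id = c("a", "b", "c", "d", "e"),
                    sire = c(NA, NA, "a", "a", "c"),
                    dam = c(NA, NA, "b", "b", "d"),
                    stringsAsFactors = FALSE)
  f <- pedigree_inbreeding(ped)
  expect_equal(f, c(0, 0, 0, 0, 0.25))
  phi <- kinship_from_pedigree(ped)
  expect_equal(phi["c", "d"], 0.25)
})

test_that("tabular inbreeding equals Wright's path-counting oracle", {
  # half sibs, parent-offspring backcross, and random small pedigrees
  half <- data.frame(id = c("s", "d1", "d2", "x", "y", "z"),
                     sire = c(NA, NA, NA, "s", "s", "x"),
                     dam = c(NA, NA, NA, "d1", "d2", "y"),
                     stringsAsFactors = FALSE)
  expect_equal(pedigree_inbreeding(half)[6], 0.125)
  expect_equal(oracle_inbreeding(half, "z"), 0.125)
  back <- data.frame(id = c("s", "d", "o", "q"),
                     sire = c(NA, NA, "s", "s"),
                     dam = c(NA, NA, "d", "o"),
                     stringsAsFactors = FALSE)
  expect_equal(pedigree_inbreeding(back)[4], 0.25)
  expect_equal(oracle_inbreeding(back, "q"), 0.25)

  set.seed(52)
  for (case in 1:8) {
    n_founders <- sample(2:4, 1)
    ids <- sprintf("p%d", seq_len(n_founders + 12))
    ped <- data.frame(id = ids[seq_len(n_founders)], sire = NA_character_,
                      dam = NA_character_, stringsAsFactors = FALSE)
    for (i in (n_founders + 1):(n_founders + 12)) {
      pair <- sample(ped$id, 2)
      ped <- rbind(ped, data.frame(id = ids[i], sire = pair[1],
                                   dam = pair[2], stringsAsFactors = FALSE))
    }
    f_tab <- pedigree_inbreeding(ped)
    for (i in sample(seq_len(nrow(ped)), 4))
      expect_equal(f_tab[i], oracle_inbreeding(ped, ped$id[i]),
                   info = sprintf("case %d id %s", case, ped$id[i]))
  }
})

test_that("breed simulation records a consistent pedigree and truth tables", {
  pools <- simulate_parental_pools(small_cfg(33))
  br <- simulate_breed(pools$dog, pools$wolf, small_cfg(33), "breedx")
  ped <- br$truth$pedigree
  G <- length(small_cfg(33)$breed_size_per_generation)
  expect_equal(sum(ped$generation == G), 12L)
  expect_equal(n_samples(br$dataset), 12L)
  expect_equal(br$truth$f_ped$sample_id, ped$id[ped$generation == G])
  expect_true(all(br$truth$f_ped$f_ped >= 0 & br$truth$f_ped$f_ped < 1))
  expect_equal(nrow(br$truth$realized_ne), G)
  expect_true(all(br$truth$realized_ne$ne_sex_ratio <=
                    2 * (br$truth$realized_ne$n_sires +
                           br$truth$realized_ne$n_dams)))
  # infusion wolves appear as founders in the pedigree
  expect_equal(sum(ped$origin == "wolf_infusion"), 1L)
  # offspring sires are all male, dams female
  sex_of <- setNames(ped$sex, ped$id)
  kids <- ped[!is.na(ped$sire), ]
  expect_true(all(sex_of[kids$sire] == "M"))
  expect_true(all(sex_of[kids$dam] == "F"))
})

test_that("popular-sire weights reach the uniform multinomial limit", {
  set.seed(61)
  n_off <- 400L; n_sires <- 8L
  theory <- n_off * (1 / n_sires) * (1 - 1 / n_sires)
  v_unif <- replicate(60, {
    counts <- tabulate(wolfdogpop:::.draw_sires(n_off, n_sires, 1e9), n_sires)
    var(counts)
  })
  expect_equal(mean(v_unif), theory, tolerance = 0.25)
  v_conc <- replicate(60, {
    counts <- tabulate(wolfdogpop:::.draw_sires(n_off, n_sires, 0.2), n_sires)
    var(counts)
  })
  expect_gt(mean(v_conc), 2 * theory)
})

test_that("wild infusion lifts heterozygosity above the pre-infusion level", {
  diffs <- vapply(1:20, function(s) {
    cfg <- small_cfg(700 + s,
                     infusion_schedule = data.frame(generation = 4L,
                                                    n_wild = 3L),
                     breed_size_per_generation = rep(14L, 6L),
                     popular_sire_weight = 5)
    pools <- simulate_parental_pools(cfg)
    br <- simulate_breed(pools$dog, pools$wolf, cfg, "b")
    het <- br$truth$mean_het_per_generation
    het[5] - het[3]
  }, 0)
  expect_gt(mean(diffs), 0)
})

test_that("a single-sex breeding pool collapses with an informative error", {
  cfg <- small_cfg(71, founder_cross = c(n_dog_founders = 2L,
                                         n_wolf_founders = 0L),
                   infusion_schedule = data.frame(generation = integer(),
                                                  n_wild = integer()),
                   breed_size_per_generation = rep(1L, 8L))
  pools <- simulate_parental_pools(cfg)
  # a single offspring per generation leaves a single-sex breeding pool at
  # generation 2 regardless of seed
  err <- tryCatch(simulate_breed(pools$dog, pools$wolf, cfg, "c"),
                  error = identity)
  expect_s3_class(err, "wolfdogpop_collapse_error")
  expect_match(conditionMessage(err), "collapsed at generation")
})

test_that("written simulations round trip through the PLINK reader", {
  sc <- do.call(simulate_wolfdog_scenario,
                c(list(seed = 19), tiny_scenario_args()))
  out <- tempfile("simout")
  write_simulation(sc$dataset, sc$truth, out, config = sc$configs$base)
  ref <- data.table::fread(file.path(out, "snp_map.tsv"), data.table = FALSE)
  ds <- read_plink_text(file.path(out, "simulated.ped"),
                        file.path(out, "simulated.map"),
                        populations = file.path(out, "populations.tsv"),
                        allele_ref = ref)
  expect_true(dataset_equal(ds, sc$dataset))
  # truth tables align with the pedigree and missing calls are "0 0"
  ped <- data.table::fread(file.path(out, "pedigree.tsv"), data.table = FALSE)
  expect_equal(nrow(data.table::fread(file.path(out, "f_ped.tsv"))),
               sum(ped$generation == max(ped$generation[ped$breed == "CSW_like"]) &
                     ped$breed == "CSW_like") +
                 sum(ped$generation == max(ped$generation[ped$breed == "SAW_like"]) &
                       ped$breed == "SAW_like"))
  toks <- strsplit(readLines(file.path(out, "simulated.ped"))[1], " ")[[1]]
  expect_true(any(toks[-(1:6)] == "0"))  # missing calls encoded as "0 0"
  cfg <- jsonlite::read_json(file.path(out, "sim_config.json"))
  expect_equal(cfg$seed, 19L)
})

test_that("the two-breed scenario is deterministic end to end", {
  args <- c(list(seed = 23), tiny_scenario_args())
  s1 <- do.call(simulate_wolfdog_scenario, args)
  s2 <- do.call(simulate_wolfdog_scenario, args)
  expect_identical(s1$dataset$geno, s2$dataset$geno)
  expect_identical(s1$truth$f_ped, s2$truth$f_ped)
  expect_equal(n_samples(s1$dataset), 14L + 10L + 8L + 10L)
  expect_setequal(populations(s1$dataset),
                  c("CSW_like", "SAW_like", "GSH_like", "WLF_like"))
})
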