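plant_chromosome <- function(m = 1000, tract = 300:599, spacing = 1e5) {
  # homozygous tract flanked by alternating-heterozygous background,
  # with het calls immediately adjacent to both tract ends
  g <- rep(c(1L, 0L), length.out = m)
  first <- tract[1]; last <- tract[length(tract)]
  if (g[first - 1] != 1L) g[seq_len(first - 1)] <- rev(rep(c(1L, 0L),
      length.out = first - 1))
  g[tract] <- rep(c(0L, 2L), length.out = length(tract))
  if (last < m) g[(last + 1):m] <- rep(c(1L, 0L), length.out = m - last)
  list(g = g, pos = seq_len(m) * spacing,
       map = data.frame(snp_id = sprintf("s%d", seq_len(m)), chrom = 1L,
                        pos = seq_len(m) * spacing))
}

test_that("a planted homozygous tract yields exactly the oracle's segment", {
  pc <- plant_chromosome()
  params <- roh_params()
  segs <- detect_roh_individual(pc$g, pc$map, params)
  orc <- oracle_roh_chromosome(pc$g, pc$pos, params)
  expect_equal(nrow(segs), 1L)
  expect_equal(nrow(orc), 1L)
  expect_equal(segs$start_bp, pc$pos[orc$start_idx])
  expect_equal(segs$end_bp, pc$pos[orc$end_idx])
  # the detected run covers the planted tract to within a couple of SNPs
  expect_lte(abs(segs$start_bp - pc$pos[300]), 2e5)
  expect_lte(abs(segs$end_bp - pc$pos[599]), 2e5)
})

test_that("degenerate inputs produce no runs", {
  map <- data.frame(snp_id = sprintf("s%d", 1:200), chrom = 1L,
                    pos = (1:200) * 1e5)
  expect_equal(nrow(detect_roh_individual(rep(1L, 200), map)), 0L)
  # a 19-SNP tract cannot satisfy the 20-SNP minimum
  g <- rep(c(1L, 0L), 100)
  g[91:109] <- 0L
  expect_equal(nrow(detect_roh_individual(g, map)), 0L)
  # fewer SNPs than one window: no windows at all
  short <- data.frame(snp_id = sprintf("s%d", 1:30), chrom = 1L,
                      pos = (1:30) * 1e5)
  expect_equal(nrow(detect_roh_individual(rep(0L, 30), short)), 0L)
  expect_error(detect_roh_individual(rep(0L, 10), short),
               class = "wolfdogpop_input_error")
})

test_that("an unsorted map is rejected", {
  map <- data.frame(snp_id = c("a", "b"), chrom = 1L, pos = c(2e5, 1e5))
  expect_error(detect_roh_individual(c(0L, 0L), map),
               class = "wolfdogpop_input_error")
})

test_that("detection equals the brute-force oracle on random chromosomes", {
  set.seed(1234)
  n_cases <- 80
  for (case in seq_len(n_cases)) {
    m <- sample(100:500, 1)
    p_het <- runif(1, 0.02, 0.25)
    g <- sample(c(0L, 1L, 2L, NA), m, replace = TRUE,
                prob = c((1 - p_het) / 2, p_het, (1 - p_het) / 2, 0.02))
    pos <- sort(sample.int(5e7, m))
    params <- roh_params(
      window_snps = sample(c(10L, 20L, 50L), 1),
      min_snps_in_run = sample(c(5L, 10L, 20L), 1),
      max_het_per_window = sample(0:2, 1),
      max_missing_per_window = sample(0:2, 1),
      snp_inclusion_threshold = sample(c(0.05, 0.5), 1),
      min_length_bp = 1000, max_gap_bp = sample(c(1e6, 1e7), 1))
    map <- data.frame(snp_id = sprintf("s%d", seq_len(m)), chrom = 1L,
                      pos = pos)
    segs <- detect_roh_individual(g, map, params)
    orc <- oracle_roh_chromosome(g, pos, params)
    expect_equal(nrow(segs), nrow(orc),
                 info = sprintf("case %d: segment count", case))
    if (nrow(orc)) {
      expect_equal(segs$start_bp, pos[orc$start_idx],
                   info = sprintf("case %d: starts", case))
      expect_equal(segs$end_bp, pos[orc$end_idx],
                   info = sprintf("case %d: ends", case))
      expect_equal(segs$n_snps, orc$end_idx - orc$start_idx + 1L,
                   info = sprintf("case %d: n_snps", case))
    }
  }
})

test_that("tightening the heterozygote allowance never grows the in-run set", {
  set.seed(99)
  relaxed_params <- function(h) roh_params(window_snps = 20L,
                                           min_snps_in_run = 1L,
                                           max_het_per_window = h,
                                           min_length_bp = 0)
  for (case in 1:10) {
    m <- 400
    g <- sample(c(0L, 1L, 2L), m, replace = TRUE, prob = c(0.45, 0.1, 0.45))
    map <- data.frame(snp_id = sprintf("s%d", seq_len(m)), chrom = 1L,
                      pos = seq_len(m) * 1e5)
    # with min_snps_in_run = 1 total n_snps equals the in-run SNP count
    tot <- vapply(c(3L, 2L, 1L, 0L), function(h)
      sum(detect_roh_individual(g, map, relaxed_params(h))$n_snps), 0L)
    expect_true(all(diff(tot) <= 0L))
  }
})

test_that("length classes use half-open bounds", {
  segs <- data.frame(sample_id = "s", chrom = 1L,
                     start_bp = 1, end_bp = 1,
                     n_snps = 20L,
                     length_bp = c(1.5e6, 2.0e6, 5e6, 9.5e6, 16e6, 26.9e6))
  cl <- classify_segments(segs)
  expect_equal(cl$n_segments, c(1L, 1L, 1L, 1L, 2L))
  expect_equal(cl$class, c("0-2", "2-4", "4-8", "8-16", ">16"))
  # 2.0 Mbp sits in 2-4; 16 Mbp sits in >16; 26.9 Mbp lands in the open class
  expect_equal(cl$mean_length_bp[2], 2.0e6)
  expect_equal(cl$mean_length_bp[5], mean(c(16e6, 26.9e6)))
})

test_that("froh is segment coverage over the SNP-covered genome", {
  map <- data.frame(snp_id = c("a", "b", "c", "d"), chrom = c(1L, 1L, 2L, 2L),
                    pos = c(1, 1000e6, 1, 1500e6))
  none <- froh(data.frame(sample_id = character(), length_bp = numeric()), map)
  expect_equal(none$froh, 0)
  expect_equal(none$covered_length_bp, 2500e6)
  segs <- data.frame(sample_id = "s", length_bp = c(600e6, 340e6))
  expect_equal(froh(segs, map)$froh, 0.376)
  expect_error(froh(segs, map[0, ]), class = "wolfdogpop_input_error")
})

test_that("froh reaches 1 when a single run spans the whole chromosome", {
  m <- 120
  map <- data.frame(snp_id = sprintf("s%d", 1:m), chrom = 1L, pos = (1:m) * 1e4)
  segs <- detect_roh_individual(rep(0L, m), map)
  expect_equal(nrow(segs), 1L)
  expect_equal(froh(segs, map)$froh, 1)
})

test_that("planted-tract froh is recovered within one inter-SNP spacing", {
  pc <- plant_chromosome()
  segs <- detect_roh_individual(pc$g, pc$map)
  f <- froh(segs, pc$map)
  truth <- (pc$pos[599] - pc$pos[300] + 1) / (pc$pos[1000] - pc$pos[1] + 1)
  spacing_frac <- 1e5 / (pc$pos[1000] - pc$pos[1] + 1)
  expect_lt(abs(f$froh - truth), spacing_frac)
})

test_that("population summaries aggregate per individual correctly", {
  # one individual, one ~3 Mbp run: the 2-4 class holds 100%
  m <- 60
  g <- rep(0L, m)
  ds <- make_dataset(matrix(g, 1, m), pops = "p", pos = (1:m) * 5e4)
  rs <- population_roh_summary(ds)
  expect_equal(rs$class_summary$pct_of_coverage[2], 100)
  expect_equal(sum(rs$class_summary$n_segments), 1L)

  # two identical individuals: identical breakdowns, mean equals either
  ds2 <- make_dataset(rbind(g, g), pops = "p", pos = (1:m) * 5e4)
  rs2 <- population_roh_summary(ds2)
  expect_equal(rs2$froh_by_population$froh, rs$froh_by_sample$froh[1])
  expect_equal(rs2$class_summary$pct_of_coverage,
               rs$class_summary$pct_of_coverage)
})

test_that("a tight inbred line shows higher froh than its source pool", {
  cfg <- sim_config(n_chromosomes = 2L, n_snps_per_chromosome = 400L,
                    ancestral_size = 30L,
                    parental_sizes = c(dog = 30L, wolf = 30L),
                    dog_lineages = 1L, parental_split_generations = 6L,
                    founder_cross = c(n_dog_founders = 2L, n_wolf_founders = 0L),
                    infusion_schedule = data.frame(generation = integer(),
                                                   n_wild = integer()),
                    breed_size_per_generation = rep(3L, 7L),
                    popular_sire_weight = 5, missing_rate = 0,
                    seed = 424)
  pools <- simulate_parental_pools(cfg)
  line <- NULL
  for (s in 0:20) {  # sib lines can collapse; take the first surviving seed
    line <- tryCatch(simulate_breed(pools$dog, pools$wolf, cfg, "line",
                                    seed = cfg$seed + s), error = function(e) NULL)
    if (!is.null(line)) break
  }
  expect_false(is.null(line))
  outbred <- subset_dataset(pools$dog, samples = 1:10)
  both <- merge_datasets(list(line$dataset, outbred))
  rs <- population_roh_summary(both)
  fr <- rs$froh_by_population
  expect_gt(fr$froh[fr$population == "line"],
            fr$froh[fr$population == "dog_pool"])
})

test_that("froh ranks individuals like their pedigree inbreeding", {
  cfg <- sim_config(n_chromosomes = 4L, n_snps_per_chromosome = 700L,
                    ancestral_size = 40L,
                    parental_sizes = c(dog = 40L, wolf = 40L),
                    dog_lineages = 1L, parental_split_generations = 10L,
                    seed = 77)
  pools <- simulate_parental_pools(cfg)
  mk <- function(sizes, alpha, label, seed) {
    c2 <- sim_config(n_chromosomes = 4L, n_snps_per_chromosome = 700L,
                     ancestral_size = 40L,
                     parental_sizes = c(dog = 40L, wolf = 40L),
                     dog_lineages = 1L, parental_split_generations = 10L,
                     founder_cross = c(n_dog_founders = 2L,
                                       n_wolf_founders = 1L),
                     infusion_schedule = data.frame(generation = integer(),
                                                    n_wild = integer()),
                     breed_size_per_generation = sizes,
                     popular_sire_weight = alpha, missing_rate = 0,
                     seed = seed)
    simulate_breed(pools$dog, pools$wolf, c2, label, seed = seed)
  }
  tight <- mk(rep(10L, 9L), 0.3, "tight", 501)
  loose <- mk(rep(30L, 5L), 10, "loose", 502)
  ds <- merge_datasets(list(tight$dataset, loose$dataset,
                            subset_dataset(pools$dog, samples = 1:15)))
  rs <- population_roh_summary(ds)
  fped <- rbind(tight$truth$f_ped, loose$truth$f_ped,
                data.frame(sample_id = pools$dog$samples$sample_id[1:15],
                           f_ped = 0))
  m <- merge(rs$froh_by_sample, fped, by = "sample_id")
  expect_gte(nrow(m), 50)
  rho <- suppressWarnings(cor(m$froh, m$f_ped, method = "spearman"))
  expect_gt(rho, 0.7)
})
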