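#  PLINK text (PED/MAP) and binary (BED/BIM/FAM) readers and writers.
#  Dosages count allele_b: by default the minor allele observed in the file,
#  or the allele named in an explicit reference table.

.NONAUTOSOMAL <- c("X", "Y", "XY", "MT", "M", "0")

#' @noRd
.read_map <- function(map_path) {
  .assert(file.exists(map_path), "map file not found: %s", map_path,
          class = "wolfdogpop_io_error")
  m <- data.table::fread(map_path, header = FALSE, colClasses = "character",
                         data.table = FALSE)
  .assert(ncol(m) %in% c(3L, 4L),
          "MAP must have 3 or 4 columns, found %d", ncol(m),
          class = "wolfdogpop_parse_error")
  pos_col <- ncol(m)
  data.frame(chrom_label = toupper(m[[1]]), snp_id = m[[2]],
             pos = suppressWarnings(as.numeric(m[[pos_col]])),
             stringsAsFactors = FALSE)
}

#' @noRd
.autosome_mask <- function(chrom_label) {
  suppressWarnings(num <- as.integer(chrom_label))
  ok <- !is.na(num) & num >= 1 & !(chrom_label %in% .NONAUTOSOMAL)
  ok
}

#' @noRd
.orient_alleles <- function(a1, a2, allele_ref, snp_id) {
  # a1/a2: n x S character matrices of observed alleles ("0" = missing side)
  S <- ncol(a1)
  allele_a <- character(S); allele_b <- character(S)
  if (!is.null(allele_ref)) {
    idx <- match(snp_id, allele_ref$snp_id)
    .assert(!anyNA(idx), "allele reference table lacks %d panel SNP(s)",
            sum(is.na(idx)), class = "wolfdogpop_parse_error")
    allele_a <- as.character(allele_ref$allele_a[idx])
    allele_b <- as.character(allele_ref$allele_b[idx])
  }
  n <- nrow(a1)
  dosage <- matrix(NA_integer_, n, S)
  for (j in seq_len(S)) {
    obs <- c(a1[, j], a2[, j])
    miss <- a1[, j] == "0" | a2[, j] == "0"
    alleles <- setdiff(unique(obs), "0")
    if (length(alleles) > 2L)
      .stopf("SNP %s has >2 alleles (%s)", snp_id[j],
             paste(alleles, collapse = "/"),
             class = "wolfdogpop_parse_error")
    if (is.null(allele_ref)) {
      if (length(alleles) == 0L) {
        allele_a[j] <- NA_character_; allele_b[j] <- NA_character_
      } else if (length(alleles) == 1L) {
        # monomorphic in file: minor allele unobserved
        allele_a[j] <- alleles; allele_b[j] <- NA_character_
      } else {
        cnt <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
        # allele_b = minor; tie broken to the alphabetically later allele
        o <- order(cnt, rank(alleles))
        allele_b[j] <- alleles[o[1]]
        allele_a[j] <- alleles[o[2]]
      }
    } else if (length(alleles) > 0L) {
      .assert(all(alleles %in% c(allele_a[j], allele_b[j])),
              "SNP %s: observed alleles disagree with reference table",
              snp_id[j], class = "wolfdogpop_parse_error")
    }
    d <- (a1[, j] == allele_b[j]) + (a2[, j] == allele_b[j])
    if (is.na(allele_b[j])) d <- rep(0L, n)
    d[miss] <- NA_integer_
    dosage[, j] <- as.integer(d)
  }
  list(dosage = dosage, allele_a = allele_a, allele_b = allele_b)
}

#' Read a PLINK text fileset (PED/MAP)
#'
#' Non-autosomal SNPs (X/Y/MT or chromosome 0) are excluded on load with a
#' message. Either allele coded `0` makes the whole call missing, following
#' the PED convention. Without a reference table the counted allele
#' (`allele_b`) is the minor allele observed in the file.
#'
#' @param ped_path,map_path paths to the `.ped` and `.map` files
#' @param populations optional data.frame (`sample_id`, `population`) or path
#'   to a two-column TSV assigning samples to populations; unlisted samples
#'   keep the PED family id as their population
#' @param allele_ref optional data.frame (`snp_id`, `allele_a`, `allele_b`)
#'   fixing dosage orientation, e.g. the map TSV written by
#'   [write_simulation()]
#' @return a [snp_dataset()]
#' @export
read_plink_text <- function(ped_path, map_path, populations = NULL,
                            allele_ref = NULL) {
  map <- .read_map(map_path)
  .assert(file.exists(ped_path), "ped file not found: %s", ped_path,
          class = "wolfdogpop_io_error")
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  .assert(length(lines) > 0, "empty PED file", class = "wolfdogpop_parse_error")
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * nrow(map)
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != want)
      .stopf("PED line %d has %d fields, expected %d (6 + 2 x %d map SNPs)",
             i, length(toks[[i]]), want, nrow(map),
             class = "wolfdogpop_structure_error")
  }
  tm <- do.call(rbind, toks)
  n <- nrow(tm)
  fam <- tm[, 1]; iid <- tm[, 2]
  gcols <- tm[, -(1:6), drop = FALSE]
  a1 <- gcols[, seq(1L, ncol(gcols), by = 2L), drop = FALSE]
  a2 <- gcols[, seq(2L, ncol(gcols), by = 2L), drop = FALSE]

  keep <- .autosome_mask(map$chrom_label)
  if (any(!keep))
    message(sprintf("excluding %d non-autosomal SNP(s)", sum(!keep)))
  map <- map[keep, , drop = FALSE]
  a1 <- a1[, keep, drop = FALSE]; a2 <- a2[, keep, drop = FALSE]

  orient <- .orient_alleles(a1, a2, allele_ref, map$snp_id)

  pop <- fam
  if (!is.null(populations)) {
    ptab <- if (is.character(populations))
      read_population_table(populations) else as.data.frame(populations)
    hit <- match(iid, ptab$sample_id)
    pop[!is.na(hit)] <- ptab$population[hit[!is.na(hit)]]
  }
  snp_dataset(orient$dosage,
              data.frame(snp_id = map$snp_id,
                         chrom = as.integer(map$chrom_label),
                         pos = map$pos,
                         allele_a = orient$allele_a,
                         allele_b = orient$allele_b,
                         stringsAsFactors = FALSE),
              data.frame(sample_id = iid, population = pop,
                         stringsAsFactors = FALSE))
}

#' Write a PLINK text fileset (PED/MAP)
#'
#' @param ds a [snp_dataset()]
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`
#' @return invisibly, the two file paths
#' @export
write_plink_text <- function(ds, prefix) {
  map <- ds$map
  data.table::fwrite(
    data.frame(map$chrom, map$snp_id, 0, format(map$pos, scientific = FALSE, trim = TRUE)),
    paste0(prefix, ".map"), sep = "\t", col.names = FALSE)
  a <- ifelse(is.na(map$allele_a), "0", map$allele_a)
  b <- ifelse(is.na(map$allele_b), "0", map$allele_b)
  # genotype word per (dosage state, SNP): 0 -> "a a", 1 -> "a b", 2 -> "b b"
  words <- rbind(paste(a, a), paste(a, b), paste(b, b), "0 0")
  g <- ds$geno
  state <- g + 1L; state[is.na(state)] <- 4L
  n <- nrow(g)
  lines <- character(n)
  for (i in seq_len(n)) {
    lines[i] <- paste(ds$samples$population[i], ds$samples$sample_id[i],
                      0, 0, 0, -9,
                      paste(words[cbind(state[i, ], seq_len(ncol(g)))],
                            collapse = " "))
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read a PLINK binary fileset (BED/BIM/FAM, SNP-major)
#'
#' @param bed_path,bim_path,fam_path paths to the three files
#' @inheritParams read_plink_text
#' @return a [snp_dataset()]; BIM column 5 (A1) becomes `allele_b`, column 6
#'   (A2) becomes `allele_a`, so dosage counts A1 as in PLINK `--recode A`
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path,
                              populations = NULL) {
  for (p in c(bed_path, bim_path, fam_path))
    .assert(file.exists(p), "file not found: %s", p,
            class = "wolfdogpop_io_error")
  bim <- data.table::fread(bim_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  .assert(ncol(bim) == 6L, "BIM must have 6 columns",
          class = "wolfdogpop_parse_error")
  fam <- data.table::fread(fam_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  n <- nrow(fam); S <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  .assert(length(raw) >= 3 && raw[1] == as.raw(0x6c) && raw[2] == as.raw(0x1b),
          "not a PLINK BED file (bad magic bytes)",
          class = "wolfdogpop_format_error")
  .assert(raw[3] == as.raw(0x01), "BED must be SNP-major",
          class = "wolfdogpop_format_error")
  bps <- ceiling(n / 4)
  .assert(length(raw) == 3 + bps * S,
          "truncated BED: %d bytes, expected %d", length(raw), 3 + bps * S,
          class = "wolfdogpop_format_error")
  body <- as.integer(raw[-(1:3)])
  # 2-bit codes, sample-fastest within byte: 0=hom A1, 1=missing, 2=het, 3=hom A2
  crumbs <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                  (body %/% 16L) %% 4L, body %/% 64L)
  codes <- matrix(as.integer(crumbs), nrow = bps * 4L, ncol = S)[seq_len(n), ,
                                                                 drop = FALSE]
  lookup <- c(2L, NA_integer_, 1L, 0L)  # code -> dosage of A1 (= allele_b)
  dosage <- matrix(lookup[codes + 1L], n, S)

  keep <- .autosome_mask(toupper(bim[[1]]))
  if (any(!keep))
    message(sprintf("excluding %d non-autosomal SNP(s)", sum(!keep)))
  pop <- fam[[1]]
  iid <- fam[[2]]
  if (!is.null(populations)) {
    ptab <- if (is.character(populations))
      read_population_table(populations) else as.data.frame(populations)
    hit <- match(iid, ptab$sample_id)
    pop[!is.na(hit)] <- ptab$population[hit[!is.na(hit)]]
  }
  snp_dataset(dosage[, keep, drop = FALSE],
              data.frame(snp_id = bim[[2]][keep],
                         chrom = as.integer(bim[[1]][keep]),
                         pos = as.numeric(bim[[4]][keep]),
                         allele_a = ifelse(bim[[6]][keep] == "0",
                                           NA_character_, bim[[6]][keep]),
                         allele_b = ifelse(bim[[5]][keep] == "0",
                                           NA_character_, bim[[5]][keep]),
                         stringsAsFactors = FALSE),
              data.frame(sample_id = iid, population = pop,
                         stringsAsFactors = FALSE))
}

#' Write a PLINK binary fileset (BED/BIM/FAM, SNP-major)
#'
#' @param ds a [snp_dataset()]
#' @param prefix output path prefix
#' @return invisibly, the three file paths
#' @export
write_plink_binary <- function(ds, prefix) {
  map <- ds$map
  data.table::fwrite(
    data.frame(map$chrom, map$snp_id, 0,
               format(map$pos, scientific = FALSE, trim = TRUE),
               ifelse(is.na(map$allele_b), "0", map$allele_b),
               ifelse(is.na(map$allele_a), "0", map$allele_a)),
    paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)
  data.table::fwrite(
    data.frame(ds$samples$population, ds$samples$sample_id, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)

  g <- ds$geno
  n <- nrow(g); S <- ncol(g)
  enc <- c(3L, 2L, 0L)  # dosage 0/1/2 -> code
  codes <- matrix(enc[g + 1L], n, S)
  codes[is.na(g)] <- 1L
  n_pad <- ceiling(n / 4) * 4L
  if (n_pad > n) codes <- rbind(codes, matrix(3L, n_pad - n, S))  # pad hom A2
  i1 <- seq(1L, n_pad, by = 4L)
  bytes <- codes[i1, , drop = FALSE] + 4L * codes[i1 + 1L, , drop = FALSE] +
    16L * codes[i1 + 2L, , drop = FALSE] + 64L * codes[i1 + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read / write a two-column sample-to-population table
#'
#' @param path TSV with columns `sample_id` and `population` (header optional)
#' @return data.frame with columns `sample_id`, `population`
#' @export
read_population_table <- function(path) {
  .assert(file.exists(path), "population table not found: %s", path,
          class = "wolfdogpop_io_error")
  tab <- data.table::fread(path, header = "auto", colClasses = "character",
                           data.table = FALSE)
  .assert(ncol(tab) >= 2, "population table needs two columns",
          class = "wolfdogpop_parse_error")
  if (!all(c("sample_id", "population") %in% names(tab)))
    names(tab)[1:2] <- c("sample_id", "population")
  tab[c("sample_id", "population")]
}

#' @rdname read_population_table
#' @param ds a [snp_dataset()]
#' @export
write_population_table <- function(ds, path) {
  data.table::fwrite(ds$samples[c("sample_id", "population")], path,
                     sep = "\t")
  invisible(path)
}

#' Export the SNP map (with allele orientation) as TSV
#'
#' The written table doubles as an `allele_ref` for [read_plink_text()],
#' guaranteeing exact dosage round trips.
#'
#' @param ds a [snp_dataset()]
#' @param path output TSV path
#' @export
write_map_table <- function(ds, path) {
  data.table::fwrite(ds$map, path, sep = "\t")
  invisible(path)
}
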