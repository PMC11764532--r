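# Independent brute-force oracles. These deliberately re-derive each
# quantity with plain loops from the definitions, sharing no code with the
# package implementations they check.

# -- sliding-window ROH, one chromosome -------------------------------------
oracle_roh_chromosome <- function(g, pos, params) {
  m <- length(g)
  w <- params$window_snps
  empty <- data.frame(start_idx = integer(), end_idx = integer())
  if (m < w) return(empty)
  nW <- m - w + 1L
  ok <- logical(nW)
  for (j in seq_len(nW)) {
    win <- g[j:(j + w - 1L)]
    ok[j] <- sum(win == 1L, na.rm = TRUE) <= params$max_het_per_window &&
      sum(is.na(win)) <= params$max_missing_per_window
  }
  in_run <- logical(m)
  for (i in seq_len(m)) {
    js <- max(1L, i - w + 1L):min(i, nW)
    in_run[i] <- (sum(ok[js]) / length(js)) >= params$snp_inclusion_threshold
  }
  segs <- empty
  i <- 1L
  while (i <= m) {
    if (!in_run[i]) { i <- i + 1L; next }
    j <- i
    while (j < m && in_run[j + 1L] && (pos[j + 1L] - pos[j]) <= params$max_gap_bp)
      j <- j + 1L
    n <- j - i + 1L
    len <- pos[j] - pos[i] + 1
    if (n >= params$min_snps_in_run && len >= params$min_length_bp)
      segs <- rbind(segs, data.frame(start_idx = i, end_idx = j))
    i <- j + 1L
  }
  segs
}

# -- Weir-Cockerham two-population F_ST, scalar per-locus loop ---------------
oracle_wc_fst <- function(ga, gb) {
  num <- 0; den <- 0
  for (j in seq_len(ncol(ga))) {
    xa <- ga[, j]; xa <- xa[!is.na(xa)]
    xb <- gb[, j]; xb <- xb[!is.na(xb)]
    n1 <- length(xa); n2 <- length(xb)
    if (n1 < 1 || n2 < 1 || (n1 + n2) <= 2) next
    p1 <- sum(xa) / (2 * n1); p2 <- sum(xb) / (2 * n2)
    p_pool <- (sum(xa) + sum(xb)) / (2 * (n1 + n2))
    if (p_pool <= 0 || p_pool >= 1) next
    h1 <- sum(xa == 1) / n1; h2 <- sum(xb == 1) / n2
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# -- Wright's path-counting inbreeding coefficient ---------------------------
oracle_inbreeding <- function(ped, id) {
  sire <- ped$sire[match(id, ped$id)]
  dam <- ped$dam[match(id, ped$id)]
  if (is.na(sire) || is.na(dam)) return(0)
  paths_up <- function(i) {
    out <- list(i)
    for (par in c(ped$sire[match(i, ped$id)], ped$dam[match(i, ped$id)])) {
      if (!is.na(par))
        out <- c(out, lapply(paths_up(par), function(p) c(i, p)))
    }
    out
  }
  ps <- paths_up(sire)
  pd <- paths_up(dam)
  f <- 0
  for (a in ps) for (b in pd) {
    anc <- a[length(a)]
    if (anc != b[length(b)]) next
    # the two paths may share only the common ancestor itself
    if (length(intersect(a[-length(a)], b[-length(b)])) > 0) next
    f <- f + 0.5^((length(a) - 1) + (length(b) - 1) + 1) *
      (1 + oracle_inbreeding(ped, anc))
  }
  f
}

# -- mean pairwise dosage r2 in a distance bin, explicit loops ---------------
oracle_mean_r2 <- function(X, pos, c_low, c_high, morgans_per_bp = 1e-8,
                           maf_min = 0.05) {
  keep <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j][!is.na(X[, j])]
    p <- mean(x) / 2
    keep[j] <- length(x) >= 2 && min(p, 1 - p) >= maf_min &&
      length(unique(x)) > 1
  }
  r2s <- c()
  for (j in seq_len(ncol(X) - 1)) for (k in (j + 1):ncol(X)) {
    if (!keep[j] || !keep[k]) next
    d <- abs(pos[k] - pos[j]) * morgans_per_bp
    if (d < c_low || d >= c_high) next
    use <- !is.na(X[, j]) & !is.na(X[, k])
    x <- X[use, j]; y <- X[use, k]
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    r2s <- c(r2s, r^2)
  }
  if (!length(r2s)) return(list(n_pairs = 0, mean_r2 = NA_real_))
  list(n_pairs = length(r2s), mean_r2 = mean(r2s))
}
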