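# Independent oracles and small dataset builders shared across the suite.

# ---- brute-force consecutive-runs enumerator -------------------------------
# Validity of every window is established by naive counting over the window;
# greedy selection (leftmost valid start, furthest end; accepted runs consume
# their span, rejected candidates advance one marker) mirrors the documented
# scan semantics while sharing no arithmetic with the implementation.
brute_force_runs <- function(typ, pos, params) {
  m <- length(typ)
  valid <- function(i, j) {
    if (typ[i] != 1L || typ[j] != 1L) return(FALSE)
    w <- typ[i:j]
    if (sum(w == 0L) > params$max_missing) return(FALSE)
    if (sum(w == -1L) > params$max_opposite) return(FALSE)
    if (j > i && any(diff(pos[i:j]) > params$max_gap_bp)) return(FALSE)
    TRUE
  }
  res <- NULL
  cursor <- 1L
  while (cursor <= m) {
    cand <- NULL
    for (i in cursor:m) {
      js <- which(vapply(i:m, function(j) valid(i, j), logical(1)))
      if (length(js)) { cand <- c(i, i - 1L + max(js)); break }
    }
    if (is.null(cand)) break
    s <- cand[1]; e <- cand[2]
    n_snps <- sum(typ[s:e] == 1L)
    if (n_snps >= params$min_snps && (pos[e] - pos[s]) >= params$min_length_bp) {
      res <- rbind(res, c(s, e, n_snps))
      cursor <- e + 1L
    } else {
      cursor <- s + 1L
    }
  }
  if (is.null(res)) {
    data.frame(start_idx = integer(0), end_idx = integer(0), n_snps = integer(0))
  } else {
    data.frame(start_idx = res[, 1], end_idx = res[, 2], n_snps = res[, 3])
  }
}

random_run_instance <- function(m = 30) {
  list(
    typ = sample(c(1L, 0L, -1L), m, replace = TRUE, prob = c(0.6, 0.15, 0.25)),
    pos = cumsum(sample(c(1e4, 5e4, 2e5, 1.2e6), m, replace = TRUE,
                        prob = c(0.4, 0.4, 0.15, 0.05))),
    params = run_params("het",
                        min_snps = sample(2:5, 1),
                        max_opposite = sample(0:1, 1),
                        max_missing = sample(0:2, 1),
                        min_length_bp = sample(c(3e4, 1e5), 1),
                        max_gap_bp = 1e6))
}

# ---- brute-force Mann-Whitney ----------------------------------------------
# U computed directly from value comparisons (ties count 1/2); the two-sided
# p enumerates every assignment of the pooled values to the two samples.
mwu_brute <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  u_of <- function(xi) {
    xs <- pooled[xi]; ys <- pooled[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# ---- independent Tajima's D ------------------------------------------------
# Expands genotypes into 2N pseudo-sequences and counts pairwise differences
# explicitly; constants evaluated by direct summation of the published
# formulas (no code shared with tajima_d beyond arithmetic).
tajima_oracle <- function(geno) {
  n_ind <- nrow(geno); n <- 2 * n_ind
  seqs <- matrix(0L, n, ncol(geno))
  for (j in seq_len(ncol(geno))) {
    k <- sum(geno[, j])
    if (k > 0) seqs[seq_len(k), j] <- 1L
  }
  S <- sum(apply(seqs, 2, function(col) length(unique(col)) > 1))
  if (S == 0) return(list(S = 0L, pi = 0, D = NA_real_))
  tot <- 0; np <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    tot <- tot + sum(seqs[a, ] != seqs[b, ])
    np <- np + 1
  }
  pi <- tot / np
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(S = S, pi = pi, D = D)
}

# ---- dataset builders ------------------------------------------------------
# A one-chromosome dataset from a calls matrix (rows = individuals).
make_dataset <- function(calls, pos = NULL, chrom = 1L, herd = "herd_1",
                         herds = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls); n <- nrow(calls)
  pos <- pos %||% seq(10000L, by = 50000L, length.out = m)
  map <- data.frame(chrom = rep(as.integer(chrom), length.out = m),
                    snp_id = sprintf("t_snp_%03d", seq_len(m)),
                    cm = 0, pos_bp = as.integer(pos),
                    allele_a = "A", allele_b = "G",
                    stringsAsFactors = FALSE)
  individuals <- data.frame(
    individual_id = sprintf("t_ind_%03d", seq_len(n)),
    herd_id = herds %||% rep(herd, n),
    pheno = as.character(seq_len(n)),
    stringsAsFactors = FALSE)
  genotype_dataset(map, calls, individuals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# An incidence track without running detection.
make_track <- function(incidence, pos = NULL, chrom = 1L, group = "g",
                       run_type = "HRR") {
  m <- length(incidence)
  pos <- pos %||% seq(10000L, by = 50000L, length.out = m)
  tr <- data.frame(chrom = rep(as.integer(chrom), length.out = m),
                   pos_bp = as.integer(pos),
                   snp_id = sprintf("t_snp_%03d", seq_len(m)),
                   incidence = incidence, stringsAsFactors = FALSE)
  attr(tr, "group_id") <- group
  attr(tr, "group_size") <- 10L
  attr(tr, "run_type") <- run_type
  tr
}
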