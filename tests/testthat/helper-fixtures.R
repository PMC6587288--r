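# fixture builders shared across test files

make_cs <- function(seqs, ind = "ind1", pop = "pop1", strategy = "sexual",
                    marker = "locus", ploidy = 2, code_table = 1,
                    coding_ranges = "") {
  if (is.null(names(seqs))) {
    names(seqs) <- sprintf("%s_c%02d", ind, seq_along(seqs))
  }
  clone_set(seqs, specimen_meta(ind, pop, strategy, ploidy, marker,
                                code_table, 0L, coding_ranges))
}

# random clone set drawn from a small haplotype pool so that repeats occur;
# optionally salts in gap/N columns
random_clone_set <- function(n, L, n_hap = 3, gap_frac = 0.05,
                             ind = "ind1", pop = "pop1") {
  pool <- replicate(n_hap, paste(sample(c("A", "C", "G", "T"), L, TRUE),
                                 collapse = ""))
  seqs <- sample(pool, n, replace = TRUE)
  if (gap_frac > 0) {
    for (i in seq_len(n)) {
      ch <- strsplit(seqs[i], "")[[1]]
      hit <- which(stats::runif(L) < gap_frac)
      ch[hit] <- sample(c("-", "N"), length(hit), TRUE)
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  make_cs(seqs, ind = ind, pop = pop)
}

# independent Hd oracle: probability that two clones drawn without
# replacement carry different sequences, by direct pair enumeration
hd_oracle <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(NA_real_)
  diff <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (seqs[i] != seqs[j]) diff <- diff + 1
  }
  diff / choose(n, 2)
}

# independent pi oracle via haplotype frequencies:
# (n/(n-1)) * sum_{i<j} 2 p_i p_j d_ij per gap-free site
pi_oracle <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(NA_real_)
  m <- do.call(rbind, strsplit(seqs, ""))
  m <- m[, colSums(m == "-" | m == "N") == 0, drop = FALSE]
  if (ncol(m) == 0) return(NA_real_)
  hap <- apply(m, 1, paste, collapse = "")
  u <- unique(hap)
  p <- as.vector(table(factor(hap, levels = u))) / n
  tot <- 0
  if (length(u) > 1) {
    for (i in seq_len(length(u) - 1)) for (j in (i + 1):length(u)) {
      d <- sum(strsplit(u[i], "")[[1]] != strsplit(u[j], "")[[1]])
      tot <- tot + 2 * p[i] * p[j] * d / ncol(m)
    }
  }
  n / (n - 1) * tot
}

# independent three-level AMOVA oracle: sums of squares and variance
# components written out directly from the expected-mean-square equations,
# evaluated by exhaustive summation over clone pairs
amova_oracle <- function(d, ind, pop) {
  n <- length(ind)
  d2 <- d^2
  sum_pairs <- function(sel) {
    idx <- which(sel)
    tot <- 0
    if (length(idx) >= 2) {
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
        tot <- tot + d2[idx[a], idx[b]]
      }
    }
    tot / length(idx)
  }
  sst <- sum_pairs(rep(TRUE, n))
  ssw <- 0
  for (i in unique(ind)) ssw <- ssw + sum_pairs(ind == i)
  ssp <- 0
  for (p in unique(pop)) ssp <- ssp + sum_pairs(pop == p)
  ss_ai <- ssp - ssw
  ss_ap <- sst - ssp

  G <- length(unique(pop))
  I <- length(unique(ind))
  ni <- sapply(unique(ind), function(i) sum(ind == i))
  pop_of <- pop[match(unique(ind), ind)]
  np <- sapply(unique(pop), function(p) sum(pop == p))
  A <- sum(sapply(unique(pop), function(p) {
    sum(ni[pop_of == p]^2) / np[unique(pop) == p]
  }))
  n1 <- (n - A) / (I - G)
  n2 <- (A - sum(ni^2) / n) / (G - 1)
  n3 <- (n - sum(np^2) / n) / (G - 1)

  sc <- ssw / (n - I)
  sb <- (ss_ai / (I - G) - sc) / n1
  sa <- (ss_ap / (G - 1) - sc - n2 * sb) / n3
  c(a = sa, b = sb, c = sc)
}

# exhaustive Steiner-minimal network cost for small binary instances:
# minimum, over all ways of adding up to n-2 unobserved sequences, of the
# minimum-spanning-tree cost of the augmented node set
hamming_str <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

mst_cost_oracle <- function(seqs) {
  n <- length(seqs)
  if (n <= 1) return(0)
  d <- outer(seqs, seqs, Vectorize(hamming_str))
  used <- 1
  cost <- 0
  while (length(used) < n) {
    rest <- setdiff(seq_len(n), used)
    sub <- d[used, rest, drop = FALSE]
    cost <- cost + min(sub)
    used <- c(used, rest[which(sub == min(sub), arr.ind = TRUE)[1, 2]])
  }
  cost
}

steiner_min_cost <- function(obs) {
  stopifnot(length(unique(nchar(obs))) == 1)
  chars <- do.call(rbind, strsplit(obs, ""))
  varying <- which(apply(chars, 2, function(x) length(unique(x)) > 1))
  proj <- apply(chars[, varying, drop = FALSE], 1, paste, collapse = "")
  alpha <- sort(unique(as.vector(chars[, varying])))
  stopifnot(length(alpha) <= 2)
  v <- length(varying)
  cand <- apply(expand.grid(rep(list(alpha), v)), 1, paste, collapse = "")
  cand <- setdiff(cand, proj)
  best <- mst_cost_oracle(proj)
  kmax <- max(0, length(obs) - 2)
  for (k in seq_len(min(kmax, length(cand)))) {
    for (cc in utils::combn(cand, k, simplify = FALSE)) {
      best <- min(best, mst_cost_oracle(c(proj, cc)))
    }
  }
  best
}
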