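#' Haplotype diversity (Nei's unbiased estimator)
#'
#' `Hd = n (1 - sum p_i^2) / (n - 1)`: the probability that two clones drawn
#' without replacement carry different haplotypes.
#'
#' @param counts Per-haplotype counts (integer vector).
#' @param n Total number of clones; defaults to `sum(counts)`.
#' @return Hd in `[0, 1]`, or `NA` when `n < 2` (undefined, not zero).
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  if (n < 2L) return(NA_real_)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity per site
#'
#' Mean proportion of differing sites over all unordered clone pairs, which
#' equals the unbiased estimator `(n/(n-1)) * sum_{i<j} 2 p_i p_j d_ij` on
#' haplotype frequencies. Columns containing a gap or `N` anywhere in the
#' clone set are excluded (complete deletion within the individual, the
#' convention of standard polymorphism software).
#'
#' @param cs A [clone_set()], or a character vector of aligned sequences.
#' @return pi per site; `NA` when `n < 2` or no ungapped column remains.
#' @export
nucleotide_diversity <- function(cs) {
  seqs <- if (inherits(cs, "clone_set")) cs$seqs else as.character(cs)
  n <- length(seqs)
  if (n < 2L) return(NA_real_)
  m <- seq_matrix(seqs)
  keep <- colSums(m == "-" | m == "N") == 0L
  if (!any(keep)) return(NA_real_)
  m <- m[, keep, drop = FALSE]
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      total <- total + sum(m[i, ] != m[j, ])
    }
  }
  total / choose(n, 2) / ncol(m)
}

# ---- Nei-Gojobori (1986) proportions with Jukes-Cantor correction --------

# synonymous site count of one codon: per position, the fraction of the three
# single-base changes that preserve the amino acid (changes to stop codons
# count as nonsynonymous; stop codons contribute no sites)
ng_codon_sites <- function(codon, code) {
  aa <- code[[codon]]
  if (is.na(aa) || aa == "*") return(c(syn = 0, total = 0))
  chars <- strsplit(codon, "", fixed = TRUE)[[1]]
  syn <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, chars[pos])) {
      alt <- chars
      alt[pos] <- b
      alt_aa <- code[[paste(alt, collapse = "")]]
      if (!is.na(alt_aa) && alt_aa != "*" && alt_aa == aa) syn <- syn + 1 / 3
    }
  }
  c(syn = syn, total = 3)
}

# classify the differences between two codons, averaging over all orderings
# of the substitutions (pathways through stop codons are excluded unless all
# pathways are blocked)
ng_codon_diffs <- function(c1, c2, code) {
  a <- strsplit(c1, "", fixed = TRUE)[[1]]
  b <- strsplit(c2, "", fixed = TRUE)[[1]]
  diff_pos <- which(a != b)
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(diff_pos) else {
    if (k == 2L) {
      list(diff_pos, rev(diff_pos))
    } else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) diff_pos[i])
    }
  }
  score_path <- function(order) {
    cur <- a
    sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa1 <- code[[paste(cur, collapse = "")]]
      aa2 <- code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" || aa1 == "*") return(NULL)  # pathway through a stop
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  scores <- Filter(Negate(is.null), lapply(perms, score_path))
  if (length(scores) == 0L) {
    # all pathways blocked by stops: fall back to counting through them
    scores <- lapply(perms, function(order) {
      cur <- a; sd <- 0; nd <- 0
      for (pos in order) {
        nxt <- cur; nxt[pos] <- b[pos]
        if (identical(code[[paste(cur, collapse = "")]],
                      code[[paste(nxt, collapse = "")]])) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
  }
  colMeans(do.call(rbind, scores))
}

jukes_cantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori Ka, Ks and their ratio
#'
#' Counts synonymous and nonsynonymous sites per codon (each position
#' weighted by the fraction of its three single-base changes that are
#' synonymous under the given code), classifies observed codon differences
#' with pathway averaging for multi-hit codons, averages the proportions
#' `pN = Nd/N` and `pS = Sd/S` over all unordered clone pairs, and applies
#' the Jukes-Cantor correction `d = -(3/4) log(1 - 4p/3)`. Codons containing
#' a gap or `N` in either member of a pair are excluded for that pair.
#'
#' @param cs A [clone_set()] restricted to coding columns, or a character
#'   vector of in-frame coding sequences.
#' @param code Genetic code table or ID (see [genetic_code()]).
#' @param frame_offset 0-based reading-frame offset.
#' @return List with `Ka`, `Ks` and `omega`. `omega` is `NA` when both are
#'   zero (undefined) and `Inf` when `Ks = 0 < Ka`. A pairwise proportion
#'   `>= 3/4` makes the correction undefined and propagates `NA`.
#' @export
nei_gojobori <- function(cs, code = 1L, frame_offset = 0L) {
  if (!is.character(code) || length(code) != 64L) code <- genetic_code(code)
  seqs <- if (inherits(cs, "clone_set")) cs$seqs else as.character(cs)
  n <- length(seqs)
  if (n < 2L) stop("Ka/Ks needs at least two sequences")
  strip <- substring(seqs, frame_offset + 1L)
  n_codon <- min(nchar(strip)) %/% 3L
  if (n_codon < 1L) stop("coding region shorter than one codon after offset")
  starts <- (seq_len(n_codon) - 1L) * 3L + 1L
  codons <- lapply(strip, function(s) substring(s, starts, starts + 2L))
  clean <- lapply(codons, function(cd) !grepl("[^ACGT]", cd))

  site_cache <- new.env(parent = emptyenv())
  sites_of <- function(cd) {
    got <- site_cache[[cd]]
    if (is.null(got)) {
      got <- ng_codon_sites(cd, code)
      site_cache[[cd]] <- got
    }
    got
  }

  pn <- 0; ps <- 0; npairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- clean[[i]] & clean[[j]]
      if (!any(use)) next
      S <- 0; N <- 0; Sd <- 0; Nd <- 0
      for (k in which(use)) {
        s1 <- sites_of(codons[[i]][k]); s2 <- sites_of(codons[[j]][k])
        S <- S + (s1[["syn"]] + s2[["syn"]]) / 2
        N <- N + (s1[["total"]] - s1[["syn"]] + s2[["total"]] - s2[["syn"]]) / 2
        if (codons[[i]][k] != codons[[j]][k]) {
          d <- ng_codon_diffs(codons[[i]][k], codons[[j]][k], code)
          Sd <- Sd + d[["sd"]]
          Nd <- Nd + d[["nd"]]
        }
      }
      npairs <- npairs + 1L
      pn <- pn + if (N > 0) Nd / N else 0
      ps <- ps + if (S > 0) Sd / S else 0
    }
  }
  if (npairs == 0L) return(list(Ka = NA_real_, Ks = NA_real_, omega = NA_real_))
  Ka <- jukes_cantor(pn / npairs)
  Ks <- jukes_cantor(ps / npairs)
  omega <- if (is.na(Ka) || is.na(Ks)) NA_real_
           else if (Ks > 0) Ka / Ks
           else if (Ka > 0) Inf
           else NA_real_
  list(Ka = Ka, Ks = Ks, omega = omega)
}

#' Per-individual diversity and selection statistics
#'
#' @param cs A [clone_set()]. Ka/Ks is computed on the coding columns
#'   declared in the metadata (skipped when none are declared).
#' @return One-row data frame: individual, strategy, marker, n, h, Hd, pi,
#'   Ka, Ks, omega.
#' @export
diversity_stats <- function(cs) {
  validate_clone_set(cs)
  ht <- collapse_haplotypes(list(cs))
  n <- length(cs$ids)
  cnt <- ht$counts[, 1]
  cols <- range_columns(cs$meta$coding_ranges)
  if (length(cols) >= 3L && n >= 2L) {
    coding <- vapply(strsplit(cs$seqs, "", fixed = TRUE),
                     function(ch) paste(ch[cols], collapse = ""), character(1))
    ng <- nei_gojobori(coding, code = cs$meta$code_table,
                       frame_offset = cs$meta$frame_offset)
  } else {
    ng <- list(Ka = NA_real_, Ks = NA_real_, omega = NA_real_)
  }
  data.frame(
    individual = cs$meta$individual_id,
    population = cs$meta$population,
    strategy   = cs$meta$strategy,
    marker     = cs$meta$marker,
    n          = n,
    h          = length(ht$seq),
    Hd         = haplotype_diversity(cnt, n),
    pi         = nucleotide_diversity(cs),
    Ka         = ng$Ka,
    Ks         = ng$Ks,
    omega      = ng$omega,
    stringsAsFactors = FALSE
  )
}

# ---- group comparisons ---------------------------------------------------

dunn_pairwise <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_corr
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    i <- groups == pr[1]; j <- groups == pr[2]
    z <- (mean(r[i]) - mean(r[j])) /
      sqrt(v * (1 / sum(i) + 1 / sum(j)))
    data.frame(group1 = pr[1], group2 = pr[2],
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
}

games_howell_pairwise <- function(values, groups) {
  lev <- levels(groups)
  k <- length(lev)
  stats_by <- lapply(lev, function(g) {
    x <- values[groups == g]
    list(m = mean(x), v = stats::var(x), n = length(x))
  })
  names(stats_by) <- lev
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    a <- stats_by[[pr[1]]]; b <- stats_by[[pr[2]]]
    se2 <- a$v / a$n + b$v / b$n
    t <- abs(a$m - b$m) / sqrt(se2)
    df <- se2^2 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
    p <- stats::ptukey(t * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2], p = p, stringsAsFactors = FALSE)
  }))
}

#' Compare a per-individual statistic across reproductive strategies
#'
#' Test selection follows the usual decision tree: Shapiro-Wilk normality
#' per group at alpha = 0.05, then Levene's test for homogeneity of
#' variances. Normal + homoscedastic data get one-way ANOVA with Tukey HSD;
#' normal but heteroscedastic data get Welch's F with Games-Howell; anything
#' non-normal gets Kruskal-Wallis with Dunn's post hoc. Pairwise p-values
#' from Dunn and Games-Howell are multiplicity-adjusted (Holm by default;
#' Tukey-based p-values are already family-wise).
#'
#' @param values Named list: strategy -> numeric vector of per-individual
#'   values (NAs dropped).
#' @param adjust Adjustment method for [stats::p.adjust()].
#' @param alpha Significance level used by the selection diagnostics.
#' @return A `group_comparison` list: `test`, `statistic`, `p` (omnibus) and
#'   `pairwise` (data frame with adjusted p for every strategy pair).
#' @export
compare_groups <- function(values, adjust = "holm", alpha = 0.05) {
  values <- lapply(values, function(x) x[!is.na(x) & is.finite(x)])
  if (length(values) < 2L || any(lengths(values) < 2L)) {
    stop("need at least two groups with at least two values each")
  }
  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), lengths(values)), levels = names(values))

  pairs <- utils::combn(names(values), 2, simplify = FALSE)
  if (stats::var(x) == 0) {
    warning("all values identical; omnibus test degenerate")
    pairwise <- do.call(rbind, lapply(pairs, function(pr) {
      data.frame(group1 = pr[1], group2 = pr[2], p_adj = 1)
    }))
    return(structure(list(test = "degenerate", statistic = NA_real_, p = 1,
                          pairwise = pairwise), class = "group_comparison"))
  }

  normal <- all(vapply(values, function(v) {
    if (length(v) < 3L || stats::var(v) == 0) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha
  }, logical(1)))

  if (normal) {
    lev_p <- car::leveneTest(x ~ g)[1, "Pr(>F)"]
    if (lev_p >= alpha) {
      fit <- stats::aov(x ~ g)
      an <- summary(fit)[[1]]
      tuk <- stats::TukeyHSD(fit)$g
      pairwise <- data.frame(
        group1 = sub("-.*$", "", rownames(tuk)),
        group2 = sub("^.*-", "", rownames(tuk)),
        p_adj = tuk[, "p adj"], row.names = NULL, stringsAsFactors = FALSE)
      res <- list(test = "anova_tukey", statistic = an[1, "F value"],
                  p = an[1, "Pr(>F)"], pairwise = pairwise)
    } else {
      w <- stats::oneway.test(x ~ g, var.equal = FALSE)
      pw <- games_howell_pairwise(x, g)
      pw$p_adj <- stats::p.adjust(pw$p, method = adjust)
      res <- list(test = "welch_games_howell",
                  statistic = unname(w$statistic), p = w$p.value,
                  pairwise = pw[, c("group1", "group2", "p_adj")])
    }
  } else {
    kw <- stats::kruskal.test(x, g)
    pw <- dunn_pairwise(x, g)
    pw$p_adj <- stats::p.adjust(pw$p, method = adjust)
    res <- list(test = "kruskal_dunn", statistic = unname(kw$statistic),
                p = kw$p.value, pairwise = pw[, c("group1", "group2", "p_adj")])
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$test, ": statistic = ",
      format(x$statistic, digits = 4), ", p = ",
      format.pval(x$p, digits = 3), "\n", sep = "")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
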