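test_that("haplotype diversity matches hand-computed values", {
  expect_equal(haplotype_diversity(c(15)), 0)
  expect_equal(haplotype_diversity(c(3, 1)), 0.5)  # (4/3) * (1 - 10/16)
  expect_equal(haplotype_diversity(rep(1, 8)), 1)
  expect_true(is.na(haplotype_diversity(c(1))))
})

test_that("nucleotide diversity equals the average pairwise proportion", {
  # 2 clones differing at 1 of 10 gap-free sites (11th column gapped)
  cs <- make_cs(c("AAAAAAAAAA-", "AAAAAAAAATG"))
  expect_equal(nucleotide_diversity(cs), 0.1)
  expect_equal(nucleotide_diversity(make_cs(rep("ACGT", 5))), 0)
  expect_true(is.na(nucleotide_diversity(make_cs(c("----", "----")))))
})

test_that("Hd and pi agree with independent oracles on random clone sets", {
  set.seed(101)
  for (rep in 1:40) {
    cs <- random_clone_set(sample(2:20, 1), sample(5:50, 1),
                           n_hap = sample(2:6, 1), gap_frac = 0.03)
    ht <- collapse_haplotypes(list(cs))
    expect_equal(haplotype_diversity(ht$counts[, 1]),
                 hd_oracle(cs$seqs), tolerance = 1e-12)
    expect_equal(nucleotide_diversity(cs), pi_oracle(cs$seqs),
                 tolerance = 1e-12)
  }
})

test_that("Nei-Gojobori classifies changes correctly under both codes", {
  # glycine padding supplies synonymous sites so the distance is defined
  pad <- paste(rep("GGA", 6), collapse = "")
  s1 <- paste0(pad, "AAA")
  s2 <- paste0(pad, "AAG")
  # AAA -> AAG: Lys -> Lys under code 1 (synonymous)
  ng1 <- nei_gojobori(c(s1, s2), code = 1)
  expect_gt(ng1$Ks, 0)
  expect_equal(ng1$Ka, 0)
  # AAA (Asn) -> AAG (Lys) under code 9 (nonsynonymous)
  ng9 <- nei_gojobori(c(s1, s2), code = 9)
  expect_gt(ng9$Ka, 0)
  expect_equal(ng9$Ks, 0)

  # identical sequences: Ka = Ks = 0, omega undefined
  ng0 <- nei_gojobori(c("ATGAAA", "ATGAAA"), code = 1)
  expect_equal(ng0$Ka, 0)
  expect_equal(ng0$Ks, 0)
  expect_true(is.na(ng0$omega))
})

test_that("Nei-Gojobori site counting matches enumeration", {
  # TTT (Phe): only the third-position change to TTC is synonymous -> 1/3
  s <- planmosaic:::ng_codon_sites("TTT", genetic_code(1))
  expect_equal(unname(s["syn"]), 1 / 3)
  expect_equal(unname(s["total"]), 3)
  # single-difference pairs: classification must equal direct translation
  set.seed(5)
  gc1 <- genetic_code(1)
  for (rep in 1:30) {
    c1 <- paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
    pos <- sample(3, 1)
    ch <- strsplit(c1, "")[[1]]
    ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
    c2 <- paste(ch, collapse = "")
    if (gc1[[c1]] == "*" || gc1[[c2]] == "*") next
    d <- planmosaic:::ng_codon_diffs(c1, c2, gc1)
    if (gc1[[c1]] == gc1[[c2]]) {
      expect_equal(unname(d), c(1, 0))
    } else {
      expect_equal(unname(d), c(0, 1))
    }
  }
})

test_that("omega handles the Ks = 0 sentinel", {
  # one nonsynonymous difference, no synonymous: omega = +Inf
  ng <- nei_gojobori(c("ATGAAA", "ATGACA"), code = 1)  # Lys -> Thr
  expect_gt(ng$Ka, 0)
  expect_equal(ng$Ks, 0)
  expect_identical(ng$omega, Inf)
})

test_that("group comparison picks sensible tests and p-values", {
  # clear separation, non-normal (constant group): Kruskal-Wallis + Dunn
  vals <- list(sexual = c(0, 0, 0), fissiparous = c(1, 1, 1),
               facultative = c(1, 1, 1))
  cmp <- compare_groups(vals)
  expect_identical(cmp$test, "kruskal_dunn")
  expect_lt(cmp$p, 0.05)
  pw <- cmp$pairwise
  sex_rows <- pw$group1 == "sexual" | pw$group2 == "sexual"
  expect_true(all(pw$p_adj[sex_rows] < 0.05))
  expect_equal(pw$p_adj[!sex_rows], 1)

  # two identical groups: adjusted p = 1 for that pair
  vals2 <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(9, 10, 11, 12))
  cmp2 <- suppressWarnings(compare_groups(vals2))
  in_pair <- function(pw, x, y) {
    (pw$group1 == x & pw$group2 == y) | (pw$group1 == y & pw$group2 == x)
  }
  ab <- cmp2$pairwise$p_adj[in_pair(cmp2$pairwise, "a", "b")]
  expect_equal(unname(ab), 1, tolerance = 1e-6)

  # degenerate input: omnibus p = 1 with a warning
  expect_warning(cmp3 <- compare_groups(list(a = c(1, 1), b = c(1, 1))),
                 "identical")
  expect_equal(cmp3$p, 1)
})

test_that("type-I error of the omnibus decision tree is near nominal", {
  set.seed(202)
  rejections <- 0
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    vals <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
    cmp <- compare_groups(vals)
    if (cmp$p < 0.05) rejections <- rejections + 1
  }
  # nominal 0.05 plus three Monte-Carlo standard errors
  expect_lte(rejections / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
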