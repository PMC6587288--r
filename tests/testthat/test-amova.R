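amova_fixture <- function(seqs_by_ind, pops) {
  css <- mapply(function(seqs, ind, pop) {
    make_cs(seqs, ind = ind, pop = pop)
  }, seqs_by_ind, names(seqs_by_ind), pops, SIMPLIFY = FALSE)
  unname(css)
}

test_that("pairwise differences count columns with gaps as a fifth state", {
  css <- amova_fixture(list(i1 = c("AAAA", "AAAA"), i2 = c("AATA", "AA-A")),
                       c("p1", "p1"))
  dm <- pairwise_differences(css)
  expect_equal(unname(dm$d[1, 2]), 0)
  expect_equal(unname(dm$d[1, 3]), 1)  # AAAA vs AATA
  expect_equal(unname(dm$d[1, 4]), 1)  # AAAA vs AA-A (gap counts)
  expect_equal(unname(dm$d[3, 4]), 1)  # AATA vs AA-A
  expect_true(isSymmetric(dm$d))
  expect_true(all(diag(dm$d) == 0))
})

test_that("monomorphic data give zero components; a clean split gives 100%", {
  css0 <- amova_fixture(list(i1 = rep("AAAA", 2), i2 = rep("AAAA", 2),
                             i3 = rep("AAAA", 2), i4 = rep("AAAA", 2)),
                        c("p1", "p1", "p2", "p2"))
  r0 <- amova_three_level(pairwise_differences(css0))
  expect_equal(unname(r0$sigma), c(0, 0, 0))

  A <- "AAAAAAAA"; B <- "TTTTTAAA"  # 5 differences
  css <- amova_fixture(list(i1 = rep(A, 3), i2 = rep(A, 3),
                            i3 = rep(B, 3), i4 = rep(B, 3)),
                       c("p1", "p1", "p2", "p2"))
  r <- amova_three_level(pairwise_differences(css))
  expect_equal(unname(r$percent),
               c(100, 0, 0), tolerance = 1e-9)
  expect_equal(unname(r$phi[["phi_CT"]]), 1, tolerance = 1e-9)
})

test_that("sums of squares decompose and respect label permutations", {
  set.seed(77)
  for (rep in 1:10) {
    n_ind <- sample(4:6, 1)
    pops <- sample(paste0("p", 1:2), n_ind, replace = TRUE)
    pops[1:2] <- c("p1", "p2")  # ensure both populations occur
    seqs_by_ind <- lapply(seq_len(n_ind), function(i) {
      random_clone_set(sample(2:3, 1), 12, n_hap = 3, gap_frac = 0)$seqs
    })
    names(seqs_by_ind) <- paste0("i", seq_len(n_ind))
    css <- amova_fixture(seqs_by_ind, pops)
    dm <- pairwise_differences(css)
    r <- amova_three_level(dm)
    ss <- r$ss
    expect_equal(unname(ss["total"]),
                 unname(ss["among_populations"] + ss["among_individuals"] +
                          ss["within_individuals"]), tolerance = 1e-9)
    expect_equal(unname(sum(r$df[c("among_populations", "among_individuals",
                                   "within_individuals")])),
                 nrow(dm$d) - 1L)
    # total SS is invariant under uniform relabeling of clones
    perm <- sample(nrow(dm$d))
    cmp <- planmosaic:::amova_components(dm$d[perm, perm]^2,
                                         dm$design$individual,
                                         dm$design$population)
    expect_equal(unname(cmp$ss["total"]), unname(ss["total"]),
                 tolerance = 1e-9)
  }
})

test_that("variance components match the exhaustive-summation oracle", {
  set.seed(123)
  for (rep in 1:15) {
    n_ind <- sample(4:6, 1)
    pops <- sample(paste0("p", 1:3), n_ind, replace = TRUE)
    pops[1:2] <- c("p1", "p2")
    seqs_by_ind <- lapply(seq_len(n_ind), function(i) {
      random_clone_set(sample(2:3, 1), 15, n_hap = 4, gap_frac = 0.02)$seqs
    })
    names(seqs_by_ind) <- paste0("i", seq_len(n_ind))
    dm <- pairwise_differences(amova_fixture(seqs_by_ind, pops))
    if (length(unique(dm$design$population)) < 2) next
    r <- amova_three_level(dm)
    oracle <- amova_oracle(dm$d, dm$design$individual, dm$design$population)
    expect_equal(unname(r$sigma), unname(oracle), tolerance = 1e-9)
  }
})

test_that("permutation p-values are calibrated and deterministic", {
  # no structure at all: p = 1 everywhere
  css0 <- amova_fixture(list(i1 = rep("AAAA", 2), i2 = rep("AAAA", 2),
                             i3 = rep("AAAA", 2), i4 = rep("AAAA", 2)),
                        c("p1", "p1", "p2", "p2"))
  set.seed(1)
  r0 <- amova_permutation(pairwise_differences(css0), n_perm = 99)
  expect_equal(unname(r0$p), rep(1, 3))

  # clean two-population split with 4 individuals per population
  A <- "AAAAAAAA"; B <- "TTTTTAAA"
  seqs <- c(rep(list(rep(A, 2)), 4), rep(list(rep(B, 2)), 4))
  names(seqs) <- paste0("i", 1:8)
  dm <- pairwise_differences(amova_fixture(seqs, rep(c("p1", "p2"), each = 4)))
  set.seed(2)
  r <- amova_permutation(dm, n_perm = 999)
  expect_lte(r$p[["phi_CT"]], 0.05)  # 35 distinct splits exist
  expect_lte(r$p[["phi_ST"]], 0.05)
  set.seed(2)
  r2 <- amova_permutation(dm, n_perm = 999)
  expect_identical(r$p, r2$p)
})

test_that("single population is rejected", {
  css <- amova_fixture(list(i1 = c("AAAA", "AATA"), i2 = c("AAAA", "AAAA")),
                       c("p1", "p1"))
  expect_error(amova_three_level(pairwise_differences(css)), "two populations")
})
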