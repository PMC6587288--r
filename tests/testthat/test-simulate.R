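# small configs keep these tests quick; the acceptance suite exercises the
# shipped defaults at full scale

small_cfg <- function(...) {
  args <- list(n_neoblasts = 4L, L_n = 60L, L_m = 40L, coding_n = "1-60",
               coding_m = "1-39", n_pop = 6L, generations = 10L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("invariants: allele and mitochondrion counts are conserved", {
  cfg <- small_cfg(mu_n = 1e-3, mu_m = 1e-3, seed = 1)
  set.seed(1)
  p <- founder_planarian(cfg)
  for (i in 1:20) p <- step_homeostasis(p, cfg)
  off <- fission_and_regenerate(p, cfg)
  for (q in c(list(p), off)) {
    expect_length(q$neoblasts, cfg$n_neoblasts)
    for (nb in q$neoblasts) {
      expect_length(nb$nuc, cfg$ploidy)
      expect_length(nb$mito, cfg$m_mito)
      expect_true(all(lengths(nb$nuc) == cfg$L_n))
    }
  }
})

test_that("mu = 0 changes identity but never sequence content", {
  cfg <- small_cfg(mu_n = 0, mu_m = 0, seed = 2)
  set.seed(2)
  p <- founder_planarian(cfg)
  founder_alleles <- unique(unlist(lapply(p$neoblasts, function(nb) {
    sapply(nb$nuc, paste, collapse = "")
  })))
  q <- p
  for (i in 1:10) q <- step_homeostasis(q, cfg)
  off <- fission_and_regenerate(q, cfg)
  seen <- unique(unlist(lapply(c(off[[1]]$neoblasts, off[[2]]$neoblasts),
                               function(nb) sapply(nb$nuc, paste, collapse = ""))))
  expect_true(all(seen %in% founder_alleles))
})

test_that("fission partitions the neoblast pool between the offspring", {
  cfg <- small_cfg(mu_n = 0, mu_m = 0)
  set.seed(3)
  p <- founder_planarian(cfg)
  # mark each neoblast with a distinct first allele
  for (i in seq_along(p$neoblasts)) {
    marked <- p$neoblasts[[i]]
    marked$nuc[[1]][1:4] <- rep(i %% 4 + 1L, 4)
    marked$nuc[[1]][5] <- i %/% 4 + 1L
    p$neoblasts[[i]] <- marked
  }
  marks <- function(q) unique(sapply(q$neoblasts, function(nb) {
    paste(nb$nuc[[1]][1:5], collapse = "")
  }))
  off <- fission_and_regenerate(p, cfg)
  m1 <- marks(off[[1]]); m2 <- marks(off[[2]])
  expect_length(intersect(m1, m2), 0)      # halves are disjoint
  expect_true(all(c(m1, m2) %in% marks(p)))  # no innovation at mu = 0
  expect_error(fission_and_regenerate(
    structure(list(id = "x", ploidy = 3L, age = 0L,
                   neoblasts = p$neoblasts[1]), class = "planarian"), cfg),
    "at least two")
})

test_that("hard purifying selection blocks all nonsynonymous change", {
  cfg <- small_cfg(mu_n = 2e-3, mu_m = 0, selection = 1, seed = 4)
  set.seed(4)
  p <- founder_planarian(cfg)
  ref_aa <- as.character(translate_seq(
    planmosaic:::int_to_seq(p$neoblasts[[1]]$nuc[[1]]), 0, cfg$code_n))
  for (i in 1:200) p <- step_homeostasis(p, cfg)
  for (nb in p$neoblasts) for (al in nb$nuc) {
    expect_identical(as.character(translate_seq(planmosaic:::int_to_seq(al),
                                                0, cfg$code_n)),
                     ref_aa)
  }
})

test_that("sexual crosses follow the gamete arithmetic", {
  cfg <- small_cfg(mu_n = 0, mu_m = 0)
  set.seed(5)
  mother <- founder_planarian(cfg)
  father <- founder_planarian(cfg)  # different random genome: private alleles
  off <- sexual_cross(mother, father, cfg)
  expect_equal(off$ploidy, 3L)
  off_alleles <- unique(sapply(off$neoblasts[[1]]$nuc, paste, collapse = ""))
  mom_alleles <- unique(unlist(lapply(mother$neoblasts, function(nb) {
    sapply(nb$nuc, paste, collapse = "")
  })))
  dad_alleles <- unique(unlist(lapply(father$neoblasts, function(nb) {
    sapply(nb$nuc, paste, collapse = "")
  })))
  expect_length(intersect(off_alleles, mom_alleles), 1)  # founders homozygous
  expect_length(intersect(off_alleles, dad_alleles), 1)
  # offspring is non-mosaic
  sigs <- unique(sapply(off$neoblasts, function(nb) {
    paste(sapply(nb$nuc, paste, collapse = ""), collapse = "|")
  }))
  expect_length(sigs, 1)
  # a haploid mother cannot form a diploid oocyte
  hap <- mother; hap$ploidy <- 1L
  expect_error(sexual_cross(hap, father, cfg), "ploidy")
})

test_that("mitochondrial inheritance matches the exact bottleneck probability", {
  cfg <- small_cfg(mu_n = 0, mu_m = 0)
  set.seed(6)
  mother <- founder_planarian(cfg)
  father <- founder_planarian(cfg)
  # make every maternal neoblast heteroplasmic: 2 copies of A, 3 of B
  mitoA <- mother$neoblasts[[1]]$mito[[1]]
  mitoB <- mitoA; mitoB[1] <- mitoB[1] %% 4L + 1L
  for (i in seq_along(mother$neoblasts)) {
    nb <- mother$neoblasts[[i]]
    nb$mito <- c(rep(list(mitoA), 2), rep(list(mitoB), 3))
    mother$neoblasts[[i]] <- nb
  }
  # P(homoplasmic offspring pool) = P(oocyte AA) + P(oocyte BB)
  #   + P(mixed oocyte) * P(resampling m copies from one type)
  p_aa <- choose(2, 2) / choose(5, 2)
  p_bb <- choose(3, 2) / choose(5, 2)
  p_resample <- 2 * 0.5^cfg$m_mito
  p_expected <- p_aa + p_bb + (1 - p_aa - p_bb) * p_resample
  homo <- replicate(4000, {
    off <- sexual_cross(mother, father, cfg)
    length(unique(sapply(off$neoblasts[[1]]$mito, paste, collapse = ""))) == 1
  })
  se <- sqrt(p_expected * (1 - p_expected) / length(homo))
  expect_lt(abs(mean(homo) - p_expected), 4 * se)
})

test_that("scenarios are reproducible and respect their event regime", {
  cfg <- small_cfg(mu_n = 1e-4, mu_m = 1e-4, sex_prob = 0, seed = 11,
                   generations = 6L)
  s1 <- run_scenario(cfg)
  s2 <- run_scenario(cfg)
  sig <- function(s) sapply(s$populations[[1]], function(p) {
    paste(sapply(p$neoblasts[[1]]$nuc, paste, collapse = ""), collapse = "|")
  })
  expect_identical(sig(s1), sig(s2))
  expect_true(all(s1$log$event == "fission"))
  expect_equal(nrow(s1$log), 6)

  cfg_sex <- small_cfg(mu_n = 0, mu_m = 0, sex_prob = 1, seed = 12,
                       generations = 5L)
  s3 <- run_scenario(cfg_sex)
  expect_true(all(s3$log$event == "sex"))
  # mu = 0 and sexual reproduction: every individual stays non-mosaic
  for (p in s3$populations[[1]]) {
    sigs <- unique(sapply(p$neoblasts, function(nb) {
      paste(sapply(nb$nuc, paste, collapse = ""), collapse = "|")
    }))
    expect_length(sigs, 1)
  }
})

test_that("repeated fission does not erode intraindividual diversity", {
  # mean pi over replicates is non-decreasing between early and late samples
  set.seed(13)
  cfg <- small_cfg(mu_n = 5e-4, mu_m = 0, generations = 0L)
  pi_at <- function(p, cfg) {
    cs <- sample_clone_dataset(p, cfg, 10, "nuclear")
    nucleotide_diversity(cs)
  }
  early <- late <- numeric(30)
  for (r in 1:30) {
    p <- founder_planarian(cfg)
    for (g in 1:5) {
      p <- step_homeostasis(p, cfg)
      p <- fission_and_regenerate(p, cfg)[[1]]
    }
    early[r] <- pi_at(p, cfg)
    for (g in 1:25) {
      p <- step_homeostasis(p, cfg)
      p <- fission_and_regenerate(p, cfg)[[1]]
    }
    late[r] <- pi_at(p, cfg)
  }
  expect_gte(mean(late), mean(early))
})

test_that("clone sampling reflects the tissue and records the truth", {
  cfg <- small_cfg(mu_n = 0, mu_m = 0, sex_prob = 1)
  set.seed(14)
  p <- founder_planarian(cfg)
  cs <- sample_clone_dataset(p, cfg, 12, "nuclear")
  expect_length(unique(cs$seqs), 1)  # non-mosaic, noise-free: one haplotype
  expect_identical(attr(cs, "truth")$true_seq, cs$seqs)
  expect_identical(cs$meta$strategy, "sexual")

  # with PCR noise the truth diverges from the observation
  pcr <- pcr_error_model(5e-4, cfg$L_n, 35)
  cs2 <- sample_clone_dataset(p, cfg, 12, "nuclear", pcr = pcr)
  expect_true(any(cs2$seqs != attr(cs2, "truth")$true_seq))

  # zero clones: documented empty-set contract
  cs0 <- sample_clone_dataset(p, cfg, 0, "nuclear")
  expect_length(cs0$ids, 0)

  # mitochondrial sampling uses the mito locus metadata
  csm <- sample_clone_dataset(p, cfg, 5, "mito")
  expect_identical(csm$meta$marker, "Cox1")
  expect_equal(csm$aln_len, cfg$L_m)
})

test_that("under neutrality omega is near 1; under selection it is below", {
  set.seed(15)
  run_omega <- function(selection, seed) {
    cfg <- sim_config(n_neoblasts = 6L, L_n = 300L, L_m = 30L,
                      coding_n = "1-300", coding_m = "1-30",
                      mu_n = 1.5e-3, mu_m = 0, turnover = 0.5,
                      selection = selection, generations = 0L, seed = seed)
    set.seed(seed)
    p <- founder_planarian(cfg)
    for (i in 1:120) p <- step_homeostasis(p, cfg)
    cs <- sample_clone_dataset(p, cfg, 10, "nuclear")
    nei_gojobori(cs$seqs, code = cfg$code_n)
  }
  sel <- sapply(1:15, function(s) run_omega(0.98, 1500 + s)$omega)
  sel <- sel[is.finite(sel)]
  expect_gte(mean(sel < 1), 0.95)
  neu <- sapply(1:15, function(s) run_omega(0, 2500 + s)$omega)
  neu <- neu[is.finite(neu)]
  expect_gt(mean(neu), 0.4)   # wide tolerance: few events per replicate
  expect_lt(mean(neu), 2.5)
})
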