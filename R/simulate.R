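# ---- forward-time mosaic Meselson simulator ------------------------------
#
# Individuals are bags of neoblasts (the planarian stem cells); each
# neoblast carries `ploidy` nuclear allele copies of the nuclear locus and
# `m_mito` mitochondrial sequences. Somatic mutations arise at cell
# divisions (homeostatic turnover and regeneration after fission). Under
# pure fission the homologous allele copies within a cell never pass through
# a zygote, so they diverge without bound (the Meselson effect) while
# different cells accumulate different mutations (mosaicism). A sexual event
# funnels the genome through single-allele sperm and two-allele oocytes with
# a mitochondrial bottleneck, producing non-mosaic offspring.
#
# Sequences are integer vectors over 1..4 (A, C, G, T); unchanged molecules
# are shared by reference, so a division without mutation costs nothing.

#' Simulator configuration
#'
#' Defaults mirror the study system: a homozygous triploid founder, a 948 bp
#' nuclear amplicon whose first 197 columns are exonic, and a 649 bp fully
#' coding mitochondrial fragment translated with the echinoderm/flatworm
#' mitochondrial code. Mutation rate, pool size and turnover are calibration
#' choices discussed in the package vignette.
#'
#' @param n_neoblasts Neoblasts per individual.
#' @param ploidy Nuclear allele copies per neoblast.
#' @param m_mito Mitochondrial sequences per neoblast.
#' @param L_n,L_m Nuclear and mitochondrial sequence lengths (bp).
#' @param mu_n,mu_m Per-site per-division substitution rates.
#' @param turnover Fraction of neoblasts replaced per homeostasis step.
#' @param generations Number of generations in [run_scenario()].
#' @param sex_prob Per-generation probability that reproduction is sexual
#'   (0 = strictly fissiparous, 1 = strictly sexual).
#' @param selection Probability that a nonsynonymous coding substitution is
#'   rejected (redrawn as no mutation); 0 = neutral.
#' @param n_pop Population carrying capacity.
#' @param n_populations Number of isolated populations sharing the founder.
#' @param coding_n,coding_m Coding column ranges (`"start-end"` strings).
#' @param code_n,code_m NCBI genetic code IDs for the two loci.
#' @param haploid_oocytes If `TRUE`, oocytes carry one allele instead of two
#'   (producing diploid offspring from triploid parents).
#' @param seed RNG seed recorded in the config; [run_scenario()] applies it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_neoblasts = 8L, ploidy = 3L, m_mito = 5L,
                       L_n = 948L, L_m = 649L,
                       mu_n = 3e-5, mu_m = 3e-5,
                       turnover = 0.25, generations = 200L,
                       sex_prob = 0, selection = 0,
                       n_pop = 20L, n_populations = 1L,
                       coding_n = "1-197", coding_m = "1-649",
                       code_n = 1L, code_m = 9L,
                       haploid_oocytes = FALSE, seed = NULL) {
  cfg <- list(n_neoblasts = as.integer(n_neoblasts), ploidy = as.integer(ploidy),
              m_mito = as.integer(m_mito), L_n = as.integer(L_n),
              L_m = as.integer(L_m), mu_n = mu_n, mu_m = mu_m,
              turnover = turnover, generations = as.integer(generations),
              sex_prob = sex_prob, selection = selection,
              n_pop = as.integer(n_pop),
              n_populations = as.integer(n_populations),
              coding_n = coding_n, coding_m = coding_m,
              code_n = as.integer(code_n), code_m = as.integer(code_m),
              haploid_oocytes = isTRUE(haploid_oocytes), seed = seed)
  with(cfg, {
    stopifnot(n_neoblasts >= 2L, ploidy >= 2L, m_mito >= 1L,
              mu_n >= 0, mu_m >= 0,
              turnover >= 0, turnover < 1,
              sex_prob >= 0, sex_prob <= 1,
              selection >= 0, selection <= 1)
  })
  class(cfg) <- "sim_config"
  cfg
}

# codon bookkeeping for the selection filter: codon_of[pos] = codon index or
# NA; cod_pos = 3 x n_codon matrix of genome positions; aa = amino acid per
# packed codon index (b1-1)*16 + (b2-1)*4 + b3
locus_context <- function(L, mu, coding, frame_offset, code_id, selection) {
  cols <- range_columns(parse_ranges(coding))
  cols <- cols[cols > frame_offset]
  n_codon <- length(cols) %/% 3L
  codon_of <- rep(NA_integer_, L)
  cod_pos <- matrix(integer(0), nrow = 3L)
  if (n_codon > 0L) {
    used <- cols[seq_len(3L * n_codon)]
    cod_pos <- matrix(used, nrow = 3L)
    codon_of[used] <- rep(seq_len(n_codon), each = 3L)
  }
  code <- genetic_code(code_id)
  idx <- integer(64)
  aa <- character(64)
  for (b1 in 1:4) for (b2 in 1:4) for (b3 in 1:4) {
    k <- (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3
    aa[k] <- code[[paste0(BASES[b1], BASES[b2], BASES[b3])]]
  }
  list(L = L, lambda = mu * L, sel = selection,
       codon_of = codon_of, cod_pos = cod_pos, aa = aa)
}

sim_env <- function(cfg) {
  nuc <- locus_context(cfg$L_n, cfg$mu_n, cfg$coding_n, 0L, cfg$code_n,
                       cfg$selection)
  mito <- locus_context(cfg$L_m, cfg$mu_m, cfg$coding_m, 0L, cfg$code_m,
                        cfg$selection)
  list(cfg = cfg, nuc = nuc, mito = mito,
       lambda_total = cfg$ploidy * nuc$lambda + cfg$m_mito * mito$lambda,
       mol_w = c(rep(nuc$lambda, cfg$ploidy), rep(mito$lambda, cfg$m_mito)))
}

# one substitution attempt on an integer sequence; nonsynonymous coding
# changes are rejected with probability ctx$sel
mutate_one <- function(vec, ctx) {
  pos <- sample.int(ctx$L, 1L)
  cur <- vec[pos]
  alt <- sample.int(3L, 1L)
  if (alt >= cur) alt <- alt + 1L
  if (ctx$sel > 0) {
    cid <- ctx$codon_of[pos]
    if (!is.na(cid)) {
      tri <- ctx$cod_pos[, cid]
      old <- vec[tri]
      new <- old
      new[match(pos, tri)] <- alt
      k_old <- (old[1] - 1L) * 16L + (old[2] - 1L) * 4L + old[3]
      k_new <- (new[1] - 1L) * 16L + (new[2] - 1L) * 4L + new[3]
      if (ctx$aa[k_old] != ctx$aa[k_new] && stats::runif(1) < ctx$sel) {
        return(vec)  # purifying selection: mutation rejected
      }
    }
  }
  vec[pos] <- alt
  vec
}

# mutated copy of a neoblast; the m mitochondria are resampled with
# replacement (intracellular drift at division)
copy_neoblast <- function(nb, env) {
  cfg <- env$cfg
  nb$mito <- nb$mito[sample.int(cfg$m_mito, cfg$m_mito, replace = TRUE)]
  k <- stats::rpois(1L, env$lambda_total)
  if (k > 0L) {
    hit <- sample.int(cfg$ploidy + cfg$m_mito, k, replace = TRUE,
                      prob = env$mol_w)
    for (mol in hit) {
      if (mol <= cfg$ploidy) {
        nb$nuc[[mol]] <- mutate_one(nb$nuc[[mol]], env$nuc)
      } else {
        i <- mol - cfg$ploidy
        nb$mito[[i]] <- mutate_one(nb$mito[[i]], env$mito)
      }
    }
  }
  nb
}

#' Create a founder planarian
#'
#' The founder is homozygous (all allele copies identical) and homoplasmic,
#' with every neoblast identical; its genome is drawn uniformly at random
#' from the current RNG state.
#'
#' @param cfg A [sim_config()].
#' @return A `planarian` object.
#' @export
founder_planarian <- function(cfg) {
  nuc_seq <- sample.int(4L, cfg$L_n, replace = TRUE)
  mito_seq <- sample.int(4L, cfg$L_m, replace = TRUE)
  nb <- list(nuc = rep(list(nuc_seq), cfg$ploidy),
             mito = rep(list(mito_seq), cfg$m_mito))
  structure(list(id = "founder", ploidy = cfg$ploidy, age = 0L,
                 neoblasts = rep(list(nb), cfg$n_neoblasts)),
            class = "planarian")
}

#' @export
print.planarian <- function(x, ...) {
  cat("<planarian> ", x$id, ": ", length(x$neoblasts), " neoblasts, ploidy ",
      x$ploidy, ", age ", x$age, "\n", sep = "")
  invisible(x)
}

#' Homeostatic turnover step
#'
#' Replaces `round(turnover * N)` uniformly chosen neoblasts by mutated
#' copies of uniformly chosen surviving neoblasts.
#'
#' @param p A `planarian`.
#' @param cfg A [sim_config()] (or a prebuilt internal environment).
#' @return The updated planarian.
#' @export
step_homeostasis <- function(p, cfg) {
  env <- if (inherits(cfg, "sim_config")) sim_env(cfg) else cfg
  N <- length(p$neoblasts)
  k <- round(env$cfg$turnover * N)
  if (k == 0L) return(p)
  die <- sample.int(N, k)
  survive <- setdiff(seq_len(N), die)
  parents <- survive[sample.int(length(survive), k, replace = TRUE)]
  p$neoblasts[die] <- lapply(p$neoblasts[parents], copy_neoblast, env = env)
  p
}

# regrow a partial neoblast pool back to N by copying uniformly chosen
# members with replacement
regrow <- function(nbs, N, env) {
  while (length(nbs) < N) {
    need <- N - length(nbs)
    parents <- sample.int(length(nbs), need, replace = TRUE)
    nbs <- c(nbs, lapply(nbs[parents], copy_neoblast, env = env))
  }
  nbs
}

#' Binary fission followed by regeneration
#'
#' The neoblast pool is partitioned uniformly at random into two halves;
#' each half regenerates back to the configured pool size by copying its own
#' members (with replacement, mutating as in homeostasis).
#'
#' @param p A `planarian` with at least two neoblasts.
#' @param cfg A [sim_config()].
#' @return List of the two offspring planarians.
#' @export
fission_and_regenerate <- function(p, cfg) {
  env <- if (inherits(cfg, "sim_config")) sim_env(cfg) else cfg
  N <- length(p$neoblasts)
  if (N < 2L) stop("fission requires at least two neoblasts")
  idx <- sample.int(N)
  halves <- list(idx[seq_len(N %/% 2L)], idx[(N %/% 2L + 1L):N])
  lapply(seq_along(halves), function(i) {
    off <- p
    off$id <- paste0(p$id, ".", i)
    off$age <- p$age + 1L
    off$neoblasts <- regrow(p$neoblasts[halves[[i]]], env$cfg$n_neoblasts, env)
    off
  })
}

#' Sexual cross between two planarians
#'
#' The sperm carries a single nuclear allele drawn from one uniformly chosen
#' paternal neoblast. The oocyte carries two distinct allele copies from one
#' uniformly chosen maternal neoblast plus two mitochondria sampled without
#' replacement from that neoblast (the oogenesis bottleneck). Gametes
#' segregate existing alleles without new mutation. The offspring is
#' non-mosaic: every neoblast is an identical copy of the zygote, with the
#' two zygotic mitochondria resampled up to the configured count.
#'
#' @param mother,father `planarian` objects; the mother must have ploidy
#'   >= 2 to form a diploid oocyte.
#' @param cfg A [sim_config()].
#' @param id Offspring ID.
#' @return The offspring `planarian`.
#' @export
sexual_cross <- function(mother, father, cfg, id = "offspring") {
  env <- if (inherits(cfg, "sim_config")) sim_env(cfg) else cfg
  cfg <- env$cfg
  if (mother$ploidy < 2L) stop("mother ploidy < 2: cannot form a diploid oocyte")
  mnb <- mother$neoblasts[[sample.int(length(mother$neoblasts), 1L)]]
  fnb <- father$neoblasts[[sample.int(length(father$neoblasts), 1L)]]
  n_oo <- if (cfg$haploid_oocytes) 1L else 2L
  oo_alleles <- mnb$nuc[sample.int(mother$ploidy, n_oo)]
  oo_mito <- mnb$mito[sample.int(cfg$m_mito, 2L)]
  sperm <- fnb$nuc[sample.int(father$ploidy, 1L)]
  # gametes segregate existing alleles faithfully: new mutations arise at
  # neoblast divisions (homeostasis/regeneration), not at gametogenesis
  zyg_nuc <- c(oo_alleles, sperm)
  pool <- oo_mito[sample.int(2L, cfg$m_mito, replace = TRUE)]
  nb <- list(nuc = zyg_nuc, mito = pool)
  structure(list(id = id, ploidy = length(zyg_nuc), age = 0L,
                 neoblasts = rep(list(nb), cfg$n_neoblasts)),
            class = "planarian")
}

#' Run a reproduction scenario forward in time
#'
#' Starts each of `n_populations` isolated populations from `n_pop` copies
#' of a single founder. Every generation, all individuals undergo
#' homeostasis; then, with probability `sex_prob`, the population reproduces
#' by a round of random-pair crosses (each pair contributing two offspring,
#' an unpaired individual fissioning), otherwise every individual fissions.
#' Offspring are culled uniformly at random to the carrying capacity. The
#' trajectory is deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `scenario` object: `config`, `populations` (list of lists of
#'   planarians) and an event `log` data frame.
#' @export
run_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  env <- sim_env(cfg)
  founder <- founder_planarian(cfg)
  pops <- lapply(seq_len(cfg$n_populations), function(i) {
    lapply(seq_len(cfg$n_pop), function(j) {
      p <- founder
      p$id <- paste0("P", i, "I", j)
      p
    })
  })
  log <- vector("list", cfg$generations * cfg$n_populations)
  li <- 0L
  for (gen in seq_len(cfg$generations)) {
    for (pi in seq_along(pops)) {
      pop <- lapply(pops[[pi]], step_homeostasis, cfg = env)
      sexual <- stats::runif(1) < cfg$sex_prob
      if (sexual && length(pop) >= 2L) {
        ord <- sample(length(pop))
        offspring <- list()
        i <- 1L
        while (i + 1L <= length(ord)) {
          a <- pop[[ord[i]]]; b <- pop[[ord[i + 1L]]]
          offspring <- c(offspring,
                         list(sexual_cross(a, b, env,
                                           id = paste0("G", gen, "S", i)),
                              sexual_cross(b, a, env,
                                           id = paste0("G", gen, "S", i + 1L))))
          i <- i + 2L
        }
        if (i <= length(ord)) {
          offspring <- c(offspring, fission_and_regenerate(pop[[ord[i]]], env))
        }
        event <- "sex"
      } else {
        # fission: partition every parent, then regrow only the culled-in
        # survivors (equivalent in distribution to regrowing all offspring
        # and culling afterwards, but avoids wasted regeneration work)
        halves <- list()
        for (p in pop) {
          N <- length(p$neoblasts)
          idx <- sample.int(N)
          halves <- c(halves, list(
            list(p = p, keep = idx[seq_len(N %/% 2L)], tag = 1L),
            list(p = p, keep = idx[(N %/% 2L + 1L):N], tag = 2L)))
        }
        surv <- sample.int(length(halves), min(cfg$n_pop, length(halves)))
        offspring <- lapply(seq_along(surv), function(k) {
          h <- halves[[surv[k]]]
          off <- h$p
          off$id <- sprintf("P%dG%dI%d", pi, gen, k)
          off$age <- h$p$age + 1L
          off$neoblasts <- regrow(h$p$neoblasts[h$keep], cfg$n_neoblasts, env)
          off
        })
        event <- "fission"
      }
      if (length(offspring) > cfg$n_pop) {
        offspring <- offspring[sample.int(length(offspring), cfg$n_pop)]
      }
      pops[[pi]] <- offspring
      li <- li + 1L
      log[[li]] <- data.frame(generation = gen, population = pi,
                              event = event, n = length(offspring))
    }
  }
  structure(list(config = cfg, populations = pops,
                 founder = founder, log = do.call(rbind, log[seq_len(li)])),
            class = "scenario")
}

int_to_seq <- function(vec) intToUtf8(c(65L, 67L, 71L, 84L)[vec])

#' Sample a cloned-sequence dataset from a simulated individual
#'
#' Each clone picks a uniform neoblast, then a uniform allele (nuclear) or
#' mitochondrion, mimicking PCR amplification from a tissue lysate followed
#' by cloning. Optional polymerase noise is added per clone via
#' [inject_pcr_errors()]; the pre-noise sequences are kept in the `truth`
#' attribute for benchmarking error correction.
#'
#' @param p A `planarian`.
#' @param cfg The [sim_config()] it was simulated under.
#' @param n_clones Number of clones to draw (0 returns an empty clone set).
#' @param locus `"nuclear"` or `"mito"`.
#' @param pcr Optional [pcr_error_model()]; `NULL` for noise-free sampling.
#' @param individual_id,population Labels for the attached metadata.
#' @return A [clone_set()] with attribute `truth` (data frame `record_id`,
#'   `true_seq`).
#' @export
sample_clone_dataset <- function(p, cfg, n_clones = 15L,
                                 locus = c("nuclear", "mito"), pcr = NULL,
                                 individual_id = p$id, population = "simpop") {
  locus <- match.arg(locus)
  strategy <- if (cfg$sex_prob == 0) "fissiparous"
              else if (cfg$sex_prob == 1) "sexual" else "facultative"
  meta <- specimen_meta(
    individual_id = individual_id, population = population,
    strategy = strategy, ploidy = p$ploidy,
    marker = if (locus == "nuclear") "TMED9" else "Cox1",
    code_table = if (locus == "nuclear") cfg$code_n else cfg$code_m,
    frame_offset = 0L,
    coding_ranges = if (locus == "nuclear") cfg$coding_n else cfg$coding_m)
  n_clones <- as.integer(n_clones)
  ids <- sprintf("%s_c%02d", individual_id, seq_len(n_clones))
  true_seq <- character(n_clones)
  obs_seq <- character(n_clones)
  for (i in seq_len(n_clones)) {
    nb <- p$neoblasts[[sample.int(length(p$neoblasts), 1L)]]
    vec <- if (locus == "nuclear") {
      nb$nuc[[sample.int(p$ploidy, 1L)]]
    } else {
      nb$mito[[sample.int(length(nb$mito), 1L)]]
    }
    true_seq[i] <- int_to_seq(vec)
    obs_seq[i] <- if (is.null(pcr)) true_seq[i] else
      inject_pcr_errors(true_seq[i], pcr)
  }
  if (n_clones == 0L) {
    cs <- structure(list(meta = meta, ids = character(0),
                         seqs = character(0),
                         aln_len = if (locus == "nuclear") cfg$L_n else cfg$L_m),
                    class = "clone_set")
  } else {
    cs <- clone_set(stats::setNames(obs_seq, ids), meta)
  }
  attr(cs, "truth") <- data.frame(record_id = ids, true_seq = true_seq,
                                  stringsAsFactors = FALSE)
  cs
}
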