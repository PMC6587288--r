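#' Pairwise difference matrix over clone sets
#'
#' `d(i, j)` counts the alignment columns at which two clones differ, with
#' gaps as a fifth character state (raw difference counts, no distance
#' model, matching the classical AMOVA input).
#'
#' @param clone_sets List of [clone_set()] objects with a shared alignment
#'   length.
#' @return A `distance_matrix`: list with `d` (symmetric integer matrix) and
#'   `design` (data frame clone / individual / population).
#' @export
pairwise_differences <- function(clone_sets) {
  if (inherits(clone_sets, "clone_set")) clone_sets <- list(clone_sets)
  lens <- unique(vapply(clone_sets, `[[`, integer(1), "aln_len"))
  if (length(lens) > 1L) stop("clone sets have different alignment lengths")
  ids <- unlist(lapply(clone_sets, function(cs) {
    paste(cs$meta$individual_id, cs$ids, sep = "::")
  }))
  seqs <- unlist(lapply(clone_sets, `[[`, "seqs"))
  design <- do.call(rbind, lapply(clone_sets, function(cs) {
    data.frame(clone = paste(cs$meta$individual_id, cs$ids, sep = "::"),
               individual = cs$meta$individual_id,
               population = cs$meta$population, stringsAsFactors = FALSE)
  }))
  n <- length(seqs)
  raw <- lapply(seqs, charToRaw)
  d <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- sum(raw[[i]] != raw[[j]])
      }
    }
  }
  structure(list(d = d, design = design), class = "distance_matrix")
}

# sums of squared deviations for one group of clone indices:
# SS = sum_{i<j in group} d_ij^2 / group size
ss_group <- function(d2, idx) {
  if (length(idx) < 2L) return(0)
  sum(d2[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]) / length(idx)
}

amova_components <- function(d2, individual, population) {
  N <- nrow(d2)
  pops <- unique(population)
  inds <- unique(individual)
  G <- length(pops)
  I <- length(inds)

  ss_total <- ss_group(d2, seq_len(N))
  ss_wi <- sum(vapply(inds, function(ind) ss_group(d2, which(individual == ind)),
                      numeric(1)))
  ss_wp <- sum(vapply(pops, function(p) ss_group(d2, which(population == p)),
                      numeric(1)))
  ss_ai <- ss_wp - ss_wi     # among individuals within populations
  ss_ap <- ss_total - ss_wp  # among populations

  df_ap <- G - 1L
  df_ai <- I - G
  df_wi <- N - I

  n_ind <- vapply(inds, function(ind) sum(individual == ind), numeric(1))
  pop_of_ind <- population[match(inds, individual)]
  n_pop <- vapply(pops, function(p) sum(population == p), numeric(1))
  sum_ni2_by_pop <- vapply(pops, function(p) {
    sum(n_ind[pop_of_ind == p]^2) / n_pop[pops == p]
  }, numeric(1))

  # unequal-size coefficients of the expected mean squares
  n1 <- (N - sum(sum_ni2_by_pop)) / df_ai
  n2 <- (sum(sum_ni2_by_pop) - sum(n_ind^2) / N) / df_ap
  n3 <- (N - sum(n_pop^2) / N) / df_ap

  ms_wi <- ss_wi / df_wi
  ms_ai <- if (df_ai > 0) ss_ai / df_ai else NA_real_
  ms_ap <- if (df_ap > 0) ss_ap / df_ap else NA_real_

  sigma_c <- ms_wi
  sigma_b <- if (df_ai > 0) (ms_ai - sigma_c) / n1 else NA_real_
  sigma_a <- if (df_ap > 0) (ms_ap - sigma_c - n2 * sigma_b) / n3 else NA_real_

  list(ss = c(among_populations = ss_ap, among_individuals = ss_ai,
              within_individuals = ss_wi, total = ss_total),
       df = c(among_populations = df_ap, among_individuals = df_ai,
              within_individuals = df_wi, total = N - 1L),
       sigma = c(a = sigma_a, b = sigma_b, c = sigma_c))
}

phi_stats <- function(sigma) {
  tot <- sum(sigma)
  c(phi_CT = sigma[["a"]] / tot,
    phi_SC = sigma[["b"]] / (sigma[["b"]] + sigma[["c"]]),
    phi_ST = (sigma[["a"]] + sigma[["b"]]) / tot)
}

#' Three-level analysis of molecular variance
#'
#' Excoffier-style nested decomposition of squared pairwise differences into
#' among-population, among-individual-within-population and
#' within-individual components, with unequal-size coefficients in the
#' expected mean squares. Raw difference counts are squared inside the sums
#' of squares (no metric correction). Negative variance components are
#' reported as-is; `percent_truncated` additionally gives the display
#' convention that truncates negatives at zero.
#'
#' @param dm A [pairwise_differences()] object.
#' @return An `amova_result` with `ss`, `df`, `sigma`, `percent`,
#'   `percent_truncated` and `phi`.
#' @export
amova_three_level <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  des <- dm$design
  if (length(unique(des$population)) < 2L) {
    stop("AMOVA needs at least two populations (sigma^2_a undefined otherwise)")
  }
  cmp <- amova_components(dm$d^2, des$individual, des$population)
  sigma <- cmp$sigma
  percent <- 100 * sigma / sum(sigma)
  trunc <- pmax(sigma, 0)
  structure(list(
    ss = cmp$ss, df = cmp$df, sigma = sigma,
    percent = stats::setNames(percent, names(sigma)),
    percent_truncated = stats::setNames(100 * trunc / sum(trunc), names(sigma)),
    phi = phi_stats(sigma)
  ), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  lev <- c("among_populations", "among_individuals", "within_individuals")
  df <- data.frame(
    level = lev, df = x$df[lev], SS = x$ss[lev],
    sigma2 = unname(x$sigma), percent = unname(x$percent))
  if (!is.null(x$p)) df$p <- unname(x$p)
  cat("<amova_result>\n")
  print(df, row.names = FALSE, digits = 4)
  cat("Phi_CT =", format(x$phi[["phi_CT"]], digits = 4),
      " Phi_SC =", format(x$phi[["phi_SC"]], digits = 4),
      " Phi_ST =", format(x$phi[["phi_ST"]], digits = 4), "\n")
  invisible(x)
}

#' Permutation p-values for the three AMOVA Phi statistics
#'
#' Null resampling schemes follow the hierarchical convention: Phi_ST
#' permutes clones across the whole design; Phi_SC permutes clones among
#' individuals within their population; Phi_CT permutes whole individuals
#' among populations. `p = (#(Phi_perm >= Phi_obs) + 1) / (n_perm + 1)`.
#'
#' @param dm A [pairwise_differences()] object.
#' @param n_perm Number of permutations (the field default is 10000).
#' @return The [amova_three_level()] result with an added `p` vector
#'   (`phi_CT`, `phi_SC`, `phi_ST`) and `n_perm`.
#' @export
amova_permutation <- function(dm, n_perm = 10000L) {
  res <- amova_three_level(dm)
  des <- dm$design
  d2 <- dm$d^2
  obs <- res$phi
  count <- c(phi_CT = 0L, phi_SC = 0L, phi_ST = 0L)

  inds <- unique(des$individual)
  pop_of_ind <- des$population[match(inds, des$individual)]

  for (b in seq_len(n_perm)) {
    # Phi_ST: clones exchangeable across everything
    perm <- sample(nrow(d2))
    phi <- phi_stats(amova_components(d2, des$individual[perm],
                                      des$population[perm])$sigma)
    if (!is.na(phi[["phi_ST"]]) && phi[["phi_ST"]] >= obs[["phi_ST"]] - 1e-12) {
      count["phi_ST"] <- count["phi_ST"] + 1L
    }

    # Phi_SC: clones exchangeable among individuals within populations
    ind_sc <- des$individual
    for (p in unique(des$population)) {
      idx <- which(des$population == p)
      ind_sc[idx] <- ind_sc[idx][sample(length(idx))]
    }
    phi <- phi_stats(amova_components(d2, ind_sc, des$population)$sigma)
    if (!is.na(phi[["phi_SC"]]) && phi[["phi_SC"]] >= obs[["phi_SC"]] - 1e-12) {
      count["phi_SC"] <- count["phi_SC"] + 1L
    }

    # Phi_CT: whole individuals exchangeable among populations
    new_pop_of_ind <- pop_of_ind[sample(length(inds))]
    pop_ct <- new_pop_of_ind[match(des$individual, inds)]
    phi <- phi_stats(amova_components(d2, des$individual, pop_ct)$sigma)
    if (!is.na(phi[["phi_CT"]]) && phi[["phi_CT"]] >= obs[["phi_CT"]] - 1e-12) {
      count["phi_CT"] <- count["phi_CT"] + 1L
    }
  }
  res$p <- (count + 1L) / (n_perm + 1L)
  # undefined observed Phi (no variation at that level) carries no evidence
  res$p[!is.finite(obs)] <- 1
  res$n_perm <- n_perm
  res
}

#' Write an AMOVA result as TSV
#'
#' @param res An `amova_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amova <- function(res, path) {
  lev <- c("among_populations", "among_individuals", "within_individuals")
  phi <- c("phi_CT", "phi_SC", "phi_ST")
  df <- data.frame(
    level = lev, df = res$df[lev], SS = res$ss[lev],
    variance = unname(res$sigma), percent = unname(res$percent),
    percent_truncated = unname(res$percent_truncated),
    phi = unname(res$phi[phi]),
    p = if (is.null(res$p)) NA_real_ else unname(res$p[phi]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
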