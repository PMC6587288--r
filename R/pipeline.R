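# ---- config-driven pipeline entry points ---------------------------------
#
# These functions are the orchestration layer: each takes a configuration
# (YAML path or list), runs one pipeline stage on files, and writes its
# outputs plus a JSON manifest sufficient to reproduce the run.

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

write_manifest <- function(out_dir, stage, config) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("planmosaic")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate a synthetic clone dataset bundle
#'
#' Config fields: the [sim_config()] fields, plus `out_dir`,
#' `n_individuals` (sampled per population, default 3), `n_clones`
#' (default 15), `loci` (subset of `nuclear`/`mito`), and `pcr_noise`
#' (logical; apply the default polymerase model when sampling). Writes one
#' FASTA per locus, a metadata TSV, a per-locus truth TSV mapping each clone
#' to its pre-noise sequence, the event log and a manifest.
#'
#' @param config YAML path or list. A seed is required.
#' @return Invisibly, the output directory.
#' @export
run_simulate <- function(config) {
  config <- read_config(config)
  if (is.null(config$seed)) stop("a seed is required for simulation")
  out_dir <- config$out_dir %||% stop("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_fields <- intersect(names(config), names(formals(sim_config)))
  cfg <- do.call(sim_config, config[sim_fields])
  scen <- run_scenario(cfg)

  n_ind <- config$n_individuals %||% 3L
  n_clones <- config$n_clones %||% 15L
  loci <- config$loci %||% c("nuclear", "mito")
  pcr <- NULL
  if (isTRUE(config$pcr_noise)) {
    pcr <- pcr_error_model(amplicon_len = cfg$L_n, cycles = 35L)
  }

  meta_list <- list()
  for (locus in loci) {
    seqs <- character(0)
    truth <- list()
    for (pi in seq_along(scen$populations)) {
      pop <- scen$populations[[pi]]
      pick <- sample.int(length(pop), min(n_ind, length(pop)))
      for (k in seq_along(pick)) {
        ind_id <- sprintf("pop%d_ind%d", pi, k)
        cs <- sample_clone_dataset(pop[[pick[k]]], cfg, n_clones = n_clones,
                                   locus = locus, pcr = pcr,
                                   individual_id = ind_id,
                                   population = paste0("pop", pi))
        seqs <- c(seqs, stats::setNames(cs$seqs, cs$ids))
        truth[[length(truth) + 1L]] <- attr(cs, "truth")
        if (locus == loci[[1]]) meta_list[[ind_id]] <- cs$meta
      }
    }
    write_fasta(seqs, file.path(out_dir, paste0(locus, ".fasta")))
    utils::write.table(do.call(rbind, truth),
                       file.path(out_dir, paste0(locus, "_truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_specimen_meta(meta_list, file.path(out_dir, "specimens.tsv"))
  utils::write.table(scen$log, file.path(out_dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "simulate", config)
  invisible(out_dir)
}

#' Recode putative PCR artifacts in a clone FASTA
#'
#' Config fields: `fasta`, `meta` (specimen TSV), `out_dir`, optional
#' `id_rule`. Applies [recode_singletons()] per individual and writes the
#' recoded FASTA, a recoding report TSV and JSON summary, and a manifest.
#'
#' @param config YAML path or list.
#' @return Invisibly, the output directory.
#' @export
run_recode <- function(config) {
  config <- read_config(config)
  out_dir <- config$out_dir %||% stop("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- read_fasta(config$fasta %||% stop("fasta is required"))
  meta <- read_specimen_meta(config$meta %||% stop("meta is required"))
  css <- build_clone_sets(seqs, meta, id_rule = config$id_rule %||% "^(.*)_")
  recoded <- lapply(css, recode_singletons)
  out_seqs <- unlist(lapply(recoded, function(r) {
    stats::setNames(r$clone_set$seqs, r$clone_set$ids)
  }))
  names(out_seqs) <- unlist(lapply(recoded, function(r) r$clone_set$ids))
  write_fasta(out_seqs, file.path(out_dir, "recoded.fasta"))
  write_recode_report(stats::setNames(lapply(recoded, `[[`, "report"),
                                      names(recoded)),
                      tsv_path = file.path(out_dir, "recode_report.tsv"),
                      json_path = file.path(out_dir, "recode_summary.json"))
  write_manifest(out_dir, "recode", config)
  invisible(out_dir)
}

#' Run the full intraindividual diversity analysis
#'
#' Config fields: `fasta`, `meta`, `out_dir`, optional `recode` (logical,
#' default TRUE), `n_perm` (AMOVA permutations, default 10000; 0 skips
#' p-values), `epsilon` (median-joining tolerance), `id_rule`, `seed`.
#' Writes per-individual statistics, group comparisons per statistic, one
#' AMOVA per reproductive strategy with >= 2 populations, per-individual
#' pattern classifications, a species-level network edge/node table, and a
#' manifest.
#'
#' @param config YAML path or list.
#' @return Invisibly, the output directory.
#' @export
run_analyze <- function(config) {
  config <- read_config(config)
  out_dir <- config$out_dir %||% stop("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  seqs <- read_fasta(config$fasta %||% stop("fasta is required"))
  meta <- read_specimen_meta(config$meta %||% stop("meta is required"))
  css <- build_clone_sets(seqs, meta, id_rule = config$id_rule %||% "^(.*)_")
  if (isTRUE(config$recode %||% TRUE)) {
    css <- lapply(css, function(cs) recode_singletons(cs)$clone_set)
  }

  stats_df <- do.call(rbind, lapply(css, diversity_stats))
  utils::write.table(stats_df, file.path(out_dir, "diversity_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # between-strategy comparisons for each statistic with enough groups
  comp_rows <- list()
  for (stat in c("h", "Hd", "pi", "Ka", "Ks", "omega")) {
    vals <- split(stats_df[[stat]], stats_df$strategy)
    vals <- lapply(vals, function(x) x[is.finite(x)])
    vals <- vals[lengths(vals) >= 2L]
    if (length(vals) < 2L) next
    cmp <- tryCatch(compare_groups(vals), error = function(e) NULL,
                    warning = function(w) suppressWarnings(compare_groups(vals)))
    if (is.null(cmp)) next
    comp_rows[[stat]] <- data.frame(statistic = stat, test = cmp$test,
                                    omnibus_p = cmp$p, cmp$pairwise)
  }
  if (length(comp_rows)) {
    utils::write.table(do.call(rbind, comp_rows),
                       file.path(out_dir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # one AMOVA per strategy (three-level: populations / individuals / clones)
  n_perm <- config$n_perm %||% 10000L
  strategies <- unique(vapply(css, function(cs) cs$meta$strategy, character(1)))
  for (st in strategies) {
    sub <- Filter(function(cs) cs$meta$strategy == st, css)
    pops <- unique(vapply(sub, function(cs) cs$meta$population, character(1)))
    if (length(pops) < 2L) next
    dm <- pairwise_differences(sub)
    res <- if (n_perm >= 1L) amova_permutation(dm, n_perm = n_perm) else {
      warning("n_perm = 0: AMOVA components reported without p-values")
      amova_three_level(dm)
    }
    write_amova(res, file.path(out_dir, paste0("amova_", st, ".tsv")))
  }

  # per-individual pattern classification
  cls <- do.call(rbind, lapply(css, function(cs) {
    ht <- collapse_haplotypes(list(cs))
    data.frame(individual = cs$meta$individual_id,
               strategy = cs$meta$strategy,
               pattern = classify_pattern(rowSums(ht$counts), seqs = ht$seq),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(cls, file.path(out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # species-level median-joining network
  ht_all <- collapse_haplotypes(css)
  net <- median_joining(ht_all, epsilon = config$epsilon %||% 0L)
  write_network(net,
                edges_path = file.path(out_dir, "network_edges.tsv"),
                nodes_path = file.path(out_dir, "network_nodes.tsv"))
  write_manifest(out_dir, "analyze", config)
  invisible(out_dir)
}
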