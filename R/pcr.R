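#' Polymerase fidelity model for a cloning PCR
#'
#' @param rate Polymerase error rate, errors per base per cycle. The default
#'   is the published Taq error rate used by common fidelity calculators.
#' @param amplicon_len Amplicon length in bp.
#' @param cycles Number of PCR cycles.
#' @return A `pcr_error_model` list.
#' @export
pcr_error_model <- function(rate = 2.28e-5, amplicon_len, cycles) {
  if (rate < 0 || amplicon_len < 0 || cycles < 0) {
    stop("rate, amplicon_len and cycles must all be >= 0")
  }
  structure(list(rate = rate, amplicon_len = as.integer(amplicon_len),
                 cycles = as.integer(cycles)),
            class = "pcr_error_model")
}

#' Expected polymerase errors per PCR product
#'
#' Returns the expectation `lambda = rate * amplicon_len * cycles`, the
#' quantity fidelity calculators print (as a percentage) when describing how
#' many products "contain an error". Strictly, `lambda` is the expected
#' number of errors per product; the probability that a product carries at
#' least one error is the Poisson tail `1 - exp(-lambda)`, reported
#' alongside. The two are close only for small `lambda`, so both are given.
#'
#' @param model A [pcr_error_model()].
#' @return List with `expected` (errors per product), `percent`
#'   (`100 * expected`) and `p_any_error` (`1 - exp(-expected)`).
#' @export
expected_errors_per_product <- function(model) {
  stopifnot(inherits(model, "pcr_error_model"))
  lambda <- model$rate * model$amplicon_len * model$cycles
  list(expected = lambda, percent = 100 * lambda,
       p_any_error = 1 - exp(-lambda))
}

#' Recode singleton clones that look like polymerase errors
#'
#' A sequence sampled exactly once in an individual and lying a single
#' mutation (one differing column, gaps as a fifth state) away from a
#' sequence sampled at least twice is most parsimoniously a PCR artifact of
#' that sequence. Each such singleton is replaced by its nonsingleton
#' neighbour. Singleton status is evaluated on the pre-recoding counts, in a
#' single simultaneous pass; the operation is therefore idempotent and never
#' cascades merges through chains of singletons. When a singleton is one
#' mutation from several nonsingletons it is recoded to the most frequent
#' one, ties broken by lexicographically smaller sequence.
#'
#' @param cs A [clone_set()].
#' @return List with `clone_set` (recoded, same N and record IDs) and
#'   `report` (fields `n_examined`, `n_recoded`, and `mapping`, a data frame
#'   with one row per recoded clone).
#' @export
recode_singletons <- function(cs) {
  validate_clone_set(cs)
  counts <- table(cs$seqs)
  singles <- names(counts)[counts == 1L]
  majors  <- names(counts)[counts >= 2L]
  mapping <- data.frame(record_id = character(0), source = character(0),
                        target = character(0), distance = integer(0),
                        stringsAsFactors = FALSE)
  seqs <- cs$seqs
  if (length(singles) && length(majors)) {
    major_n <- as.integer(counts[majors])
    for (s in singles) {
      d <- vapply(majors, function(m) seq_diff_count(s, m), integer(1))
      hit <- which(d == 1L)
      if (length(hit)) {
        # deterministic tie-break: highest count, then lexicographic order
        hit <- hit[order(-major_n[hit], majors[hit])]
        target <- majors[hit[1]]
        idx <- which(seqs == s)
        mapping <- rbind(mapping, data.frame(
          record_id = cs$ids[idx], source = s, target = target,
          distance = 1L, stringsAsFactors = FALSE))
        seqs[idx] <- target
      }
    }
  }
  out <- cs
  out$seqs <- seqs
  report <- list(n_examined = length(singles), n_recoded = nrow(mapping),
                 mapping = mapping)
  list(clone_set = out, report = report)
}

#' Inject random polymerase errors into a sequence
#'
#' The number of substitutions is Poisson with mean
#' `rate * n_bases * cycles`, where `n_bases` counts the A/C/G/T positions
#' (gap and `N` columns are alignment artifacts, not template bases, and are
#' never mutated). Positions are chosen uniformly without replacement and
#' each substituted base is uniform over the three alternatives. Uses R's
#' global RNG; seed with [set.seed()] for reproducibility.
#'
#' @param seq Nucleotide string.
#' @param model A [pcr_error_model()] (its `amplicon_len` is ignored in
#'   favour of the actual mutable length of `seq`).
#' @return The mutated sequence string.
#' @export
inject_pcr_errors <- function(seq, model) {
  stopifnot(inherits(model, "pcr_error_model"))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  mutable <- which(chars %in% BASES)
  lambda <- model$rate * length(mutable) * model$cycles
  if (lambda == 0) return(seq)
  k <- stats::rpois(1L, lambda)
  if (k == 0L) return(seq)
  k <- min(k, length(mutable))
  pos <- sample(mutable, k)
  for (p in pos) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Write a recoding report as TSV (+ JSON summary)
#'
#' @param report Report from [recode_singletons()] or a named list of them
#'   (one per individual).
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_recode_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(report$mapping)) report <- list(report)
  rows <- do.call(rbind, lapply(seq_along(report), function(i) {
    m <- report[[i]]$mapping
    if (nrow(m) == 0L) return(NULL)
    data.frame(individual = names(report)[i] %||% as.character(i), m,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(individual = character(0), record_id = character(0),
                       source = character(0), target = character(0),
                       distance = integer(0))
  }
  if (!is.null(tsv_path)) {
    utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    summ <- lapply(report, function(r) {
      list(n_examined = r$n_examined, n_recoded = r$n_recoded)
    })
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(tsv_path, json_path))
}
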