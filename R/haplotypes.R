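#' Genetic code table by NCBI ID
#'
#' Returns the 64-codon amino-acid mapping for NCBI translation table 1
#' (standard) or 9 (echinoderm and flatworm mitochondrial, the appropriate
#' code for planarian Cox1). Table 9 differs from the standard code at
#' AAA (Asn), AGA/AGG (Ser) and TGA (Trp).
#'
#' @param table_id 1 or 9.
#' @return Named character vector of length 64 mapping codons to one-letter
#'   amino acids, `"*"` for stops.
#' @export
genetic_code <- function(table_id = 1L) {
  table_id <- as.integer(table_id)
  if (!table_id %in% c(1L, 9L)) stop("supported genetic codes: 1, 9")
  Biostrings::getGeneticCode(as.character(table_id))
}

#' Translate an aligned nucleotide sequence
#'
#' Codons containing a gap or `N` translate to `X`. Translation is advisory:
#' internal stop codons are reported in the `stops` attribute (1-based codon
#' index) rather than raised as errors, since a premature stop in a cloned
#' somatic sequence is a finding, not a fault.
#'
#' @param seq Nucleotide string.
#' @param frame_offset 0-based offset at which the first codon starts.
#' @param code A code table from [genetic_code()], or a table ID.
#' @return Amino-acid string with attribute `stops` (integer codon positions
#'   of `*`).
#' @export
translate_seq <- function(seq, frame_offset = 0L, code = 1L) {
  if (!is.character(code) || length(code) != 64L) code <- genetic_code(code)
  s <- substring(seq, frame_offset + 1L)
  n_codon <- nchar(s) %/% 3L
  if (n_codon < 1L) stop("coding region shorter than one codon after offset")
  starts <- (seq_len(n_codon) - 1L) * 3L + 1L
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # gap or N in codon
  out <- paste(aa, collapse = "")
  attr(out, "stops") <- which(aa == "*")
  out
}

#' Collapse clone sets into a haplotype table
#'
#' Distinct sequences (exact string equality, gap columns included: a
#' one-column indel distinguishes haplotypes) are assigned stable IDs
#' `"<locus>-<k>"` ordered by descending total count, ties by lexicographic
#' sequence order (so IDs are invariant to record order).
#'
#' @param clone_sets List of [clone_set()] objects sharing one locus and
#'   alignment length.
#' @param locus Optional locus label; defaults to the shared marker.
#' @return A `haplotype_table`: list with `locus`, `haplotype_id`, `seq` and
#'   a counts matrix (rows = haplotypes, columns = individuals).
#' @export
collapse_haplotypes <- function(clone_sets, locus = NULL) {
  if (inherits(clone_sets, "clone_set")) clone_sets <- list(clone_sets)
  markers <- unique(vapply(clone_sets, function(cs) cs$meta$marker, character(1)))
  if (length(markers) > 1L) {
    stop("clone sets from mixed loci: ", paste(markers, collapse = ", "))
  }
  lens <- unique(vapply(clone_sets, `[[`, integer(1), "aln_len"))
  if (length(lens) > 1L) stop("clone sets have different alignment lengths")
  locus <- locus %||% markers
  inds <- vapply(clone_sets, function(cs) cs$meta$individual_id, character(1))

  all_seqs <- unlist(lapply(clone_sets, `[[`, "seqs"), use.names = FALSE)
  uniq <- unique(all_seqs)  # first-seen order
  counts <- vapply(clone_sets, function(cs) {
    tabulate(match(cs$seqs, uniq), nbins = length(uniq))
  }, integer(length(uniq)))
  counts <- matrix(counts, nrow = length(uniq),
                   dimnames = list(NULL, inds))
  # ties in total count break lexicographically so that IDs do not depend
  # on record order
  ord <- order(-rowSums(counts), uniq)
  counts <- counts[ord, , drop = FALSE]
  uniq <- uniq[ord]
  ids <- paste0(locus, "-", seq_along(uniq))
  rownames(counts) <- ids
  structure(list(locus = locus, haplotype_id = ids, seq = uniq,
                 counts = counts),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("<haplotype_table> ", x$locus, ": ", length(x$seq), " haplotypes, ",
      ncol(x$counts), " individuals, ", sum(x$counts), " clones\n", sep = "")
  invisible(x)
}

#' Check haplotype reading frames for premature stop codons
#'
#' Extracts the coding columns declared in `meta$coding_ranges`, applies the
#' frame offset and translates each haplotype under `meta$code_table`,
#' reporting every in-frame stop codon.
#'
#' @param ht A [collapse_haplotypes()] table.
#' @param meta A [specimen_meta()] carrying `coding_ranges`, `frame_offset`
#'   and `code_table`.
#' @return Data frame with columns `haplotype_id` and `stop_codon` (1-based
#'   codon index in the coding region); zero rows means all frames are clean.
#' @export
reading_frame_check <- function(ht, meta) {
  cols <- range_columns(meta$coding_ranges)
  if (length(cols) == 0L) stop("coding_ranges not set in metadata")
  code <- genetic_code(meta$code_table)
  hits <- lapply(seq_along(ht$seq), function(i) {
    coding <- paste(strsplit(ht$seq[i], "", fixed = TRUE)[[1]][cols],
                    collapse = "")
    aa <- translate_seq(coding, meta$frame_offset, code)
    stops <- attr(aa, "stops")
    if (length(stops)) {
      data.frame(haplotype_id = ht$haplotype_id[i], stop_codon = stops,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(haplotype_id = character(0), stop_codon = integer(0))
  }
  out
}

#' Expand a haplotype table back to per-clone sequences
#'
#' Repeats each haplotype by its count for one individual; the multiset of
#' sequences equals that individual's input clone sequences.
#'
#' @param ht Haplotype table.
#' @param individual_id Column of the counts matrix to expand.
#' @return Character vector of sequences.
#' @export
expand_haplotypes <- function(ht, individual_id) {
  cnt <- ht$counts[, individual_id]
  rep(ht$seq, cnt)
}

#' Write a haplotype table (FASTA of haplotypes + TSV count matrix)
#'
#' @param ht Haplotype table.
#' @param fasta_path,counts_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_haplotype_table <- function(ht, fasta_path, counts_path) {
  write_fasta(stats::setNames(ht$seq, ht$haplotype_id), fasta_path)
  df <- data.frame(haplotype_id = ht$haplotype_id, ht$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, counts_path))
}
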