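#' Read an aligned FASTA file of cloned sequences
#'
#' Sequences are uppercased and `U` is mapped to `T`. Only the characters
#' `A`, `C`, `G`, `T`, `-` and `N` are accepted: cloned amplicons are single
#' molecules, so IUPAC ambiguity codes signal an upstream editing problem and
#' are rejected rather than silently kept.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are record IDs, in
#'   file order).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(stats::setNames(character(0), character(0)))
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("FASTA parse error at line ", nonblank[1], ": expected '>' header")
  }
  hdr_lines <- which(startsWith(lines, ">"))
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr_lines]))
  if (any(!nzchar(ids))) {
    stop("FASTA parse error at line ", hdr_lines[which(!nzchar(ids))[1]],
         ": empty header ID")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("FASTA parse error at line ", hdr_lines[which(empty)[1]],
         ": record '", ids[which(empty)[1]], "' has an empty sequence")
  }
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(gsub("[ACGTN-]", "", seqs[bad]), "")))
    stop("disallowed sequence characters (", paste(chars, collapse = ", "),
         ") in record(s): ", paste(ids[bad], collapse = ", "))
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, path))` returns `x`.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta",
                              width = max(1L, as.integer(width)))
  invisible(path)
}

#' Specimen metadata for one individual at one locus
#'
#' @param individual_id,population Identifier strings.
#' @param strategy One of `"sexual"`, `"fissiparous"`, `"facultative"`.
#' @param ploidy Integer >= 2, or the string `"mixoploid"`.
#' @param marker Locus name (e.g. `"TMED9"`, `"Cox1"`).
#' @param code_table NCBI genetic code ID: 1 (standard) or 9
#'   (echinoderm/flatworm mitochondrial).
#' @param frame_offset 0-based offset of the reading frame within the coding
#'   region.
#' @param coding_ranges Coding alignment columns, either a 2-column matrix or
#'   a string `"start-end;start-end"` of 1-based inclusive intervals.
#' @return A `specimen_meta` list.
#' @export
specimen_meta <- function(individual_id, population, strategy, ploidy = 2L,
                          marker = "locus", code_table = 1L,
                          frame_offset = 0L, coding_ranges = "") {
  strategy <- match.arg(strategy, c("sexual", "fissiparous", "facultative"))
  if (!identical(ploidy, "mixoploid")) {
    ploidy <- as.integer(ploidy)
    if (is.na(ploidy) || ploidy < 2L) stop("ploidy must be >= 2 or 'mixoploid'")
  }
  code_table <- as.integer(code_table)
  if (!code_table %in% c(1L, 9L)) stop("code_table must be 1 or 9")
  frame_offset <- as.integer(frame_offset)
  if (is.na(frame_offset) || frame_offset < 0L) stop("frame_offset must be >= 0")
  structure(list(
    individual_id = as.character(individual_id),
    population    = as.character(population),
    strategy      = strategy,
    ploidy        = ploidy,
    marker        = as.character(marker),
    code_table    = code_table,
    frame_offset  = frame_offset,
    coding_ranges = parse_ranges(coding_ranges)
  ), class = "specimen_meta")
}

META_COLUMNS <- c("individual_id", "population", "strategy", "ploidy",
                  "marker", "code_table", "frame_offset", "coding_ranges")

#' Read a specimen metadata table (TSV)
#'
#' Expected columns: `individual_id`, `population`, `strategy`, `ploidy`,
#' `marker`, `code_table`, `frame_offset`, `coding_ranges` (intervals as
#' `"start-end;start-end"`, 1-based inclusive). Unknown columns are dropped
#' with a warning.
#'
#' @param path Path to the TSV file.
#' @return A list of [specimen_meta()] objects.
#' @export
read_specimen_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(META_COLUMNS, names(df))
  if (length(missing)) {
    stop("metadata file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), META_COLUMNS)
  if (length(extra)) {
    warning("ignoring unknown metadata column(s): ",
            paste(extra, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    specimen_meta(
      individual_id = df$individual_id[i],
      population    = df$population[i],
      strategy      = df$strategy[i],
      ploidy        = if (df$ploidy[i] == "mixoploid") "mixoploid" else df$ploidy[i],
      marker        = df$marker[i],
      code_table    = df$code_table[i],
      frame_offset  = df$frame_offset[i],
      coding_ranges = df$coding_ranges[i]
    )
  })
}

#' Write specimen metadata to TSV
#'
#' @param meta_list List of [specimen_meta()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_specimen_meta <- function(meta_list, path) {
  df <- do.call(rbind, lapply(meta_list, function(m) {
    data.frame(individual_id = m$individual_id, population = m$population,
               strategy = m$strategy, ploidy = as.character(m$ploidy),
               marker = m$marker, code_table = m$code_table,
               frame_offset = m$frame_offset,
               coding_ranges = format_ranges(m$coding_ranges),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a clone set (aligned clones of one individual at one locus)
#'
#' @param seqs Named character vector of aligned sequences.
#' @param meta A [specimen_meta()] object.
#' @return A `clone_set` object.
#' @export
clone_set <- function(seqs, meta) {
  cs <- structure(list(
    meta    = meta,
    ids     = names(seqs),
    seqs    = unname(as.character(seqs)),
    aln_len = if (length(seqs)) nchar(seqs[[1]]) else 0L
  ), class = "clone_set")
  validate_clone_set(cs)
  cs
}

#' @export
print.clone_set <- function(x, ...) {
  cat("<clone_set> ", x$meta$individual_id, " [", x$meta$marker, "]: ",
      length(x$ids), " clones x ", x$aln_len, " columns\n", sep = "")
  invisible(x)
}

validate_clone_set <- function(cs) {
  if (length(cs$ids) < 1L) stop("clone set must contain at least one record")
  if (anyDuplicated(cs$ids)) stop("duplicate record IDs in clone set")
  lens <- nchar(cs$seqs)
  if (any(lens != cs$aln_len)) {
    stop("alignment error in individual '", cs$meta$individual_id,
         "': records of length ", paste(unique(lens), collapse = ", "),
         " (expected ", cs$aln_len, ")")
  }
  rng <- cs$meta$coding_ranges
  if (nrow(rng) && max(rng[, 2]) > cs$aln_len) {
    stop("coding_ranges exceed alignment length for '",
         cs$meta$individual_id, "'")
  }
  invisible(cs)
}

#' Group sequence records into per-individual clone sets
#'
#' @param seqs Named character vector of aligned sequences (one locus).
#' @param meta_list List of [specimen_meta()] objects, one per individual.
#' @param id_rule How a record ID maps to an individual ID: either a regular
#'   expression whose first capture group is the individual ID, or a function
#'   of the record ID vector. The default strips the final
#'   underscore-delimited segment, so clone IDs like `"Calobra1S_03"` map to
#'   `"Calobra1S"`.
#' @return A list of `clone_set` objects, one per individual present.
#' @export
build_clone_sets <- function(seqs, meta_list, id_rule = "^(.*)_") {
  if (is.function(id_rule)) {
    ind <- id_rule(names(seqs))
  } else {
    m <- regmatches(names(seqs), regexec(id_rule, names(seqs)))
    ind <- vapply(m, function(g) if (length(g) >= 2) g[2] else NA_character_,
                  character(1))
  }
  known <- vapply(meta_list, `[[`, character(1), "individual_id")
  orphan <- is.na(ind) | !(ind %in% known)
  if (any(orphan)) {
    stop("records not mapped to any individual in the metadata: ",
         paste(names(seqs)[orphan], collapse = ", "))
  }
  present <- intersect(known, unique(ind))
  out <- lapply(present, function(id) {
    meta <- meta_list[[match(id, known)]]
    clone_set(seqs[ind == id], meta)
  })
  names(out) <- present
  out
}
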