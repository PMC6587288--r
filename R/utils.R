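BASES <- c("A", "C", "G", "T")

#' Count differing alignment columns between two aligned sequences
#'
#' Gaps (`-`) and `N` are treated as ordinary character states, so a
#' substitution against a gap column counts as one difference (the "fifth
#' state" convention used throughout the package).
#'
#' @param a,b Aligned sequence strings of identical length.
#' @return Integer count of columns at which `a` and `b` differ.
#' @export
seq_diff_count <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    stop("sequences have different lengths (", length(ra), " vs ", length(rb), ")")
  }
  sum(ra != rb)
}

# split aligned sequence strings into a character matrix (rows = sequences)
seq_matrix <- function(seqs) {
  if (length(seqs) == 0L) return(matrix(character(0), nrow = 0L, ncol = 0L))
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

# parse "start-end;start-end" into a 2-column integer matrix (1-based inclusive)
parse_ranges <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.null(x) || is.na(x) || !nzchar(x)) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  out <- t(vapply(parts, function(p) as.integer(p[1:2]), integer(2)))
  colnames(out) <- c("start", "end")
  if (any(is.na(out)) || any(out[, 1] > out[, 2])) {
    stop("malformed coding range specification: ", x)
  }
  o <- order(out[, 1])
  out <- out[o, , drop = FALSE]
  if (nrow(out) > 1 && any(out[-1, 1] <= out[-nrow(out), 2])) {
    stop("coding ranges overlap: ", x)
  }
  out
}

format_ranges <- function(rng) {
  if (nrow(rng) == 0L) return("")
  paste(paste0(rng[, 1], "-", rng[, 2]), collapse = ";")
}

# expand a range matrix into the vector of 1-based column indices it covers
range_columns <- function(rng) {
  if (nrow(rng) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(rng)), function(i) seq.int(rng[i, 1], rng[i, 2])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
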