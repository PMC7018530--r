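# Local pairwise protein alignment (exact Smith-Waterman, affine gaps),
# Karlin-Altschul bit-score conversion, and the bit score ratio (BSR).

#' Scoring scheme for pairwise alignment
#'
#' Defaults reproduce standard gapped-BLAST protein settings: BLOSUM62 with
#' gap open -11, gap extend -1 (a gap of length g costs 11 + g), and
#' Karlin-Altschul parameters lambda = 0.267, K = 0.041 for the bit-score
#' conversion.
#'
#' @param substitution symmetric integer substitution matrix with single-letter
#'   row/column names defining the alphabet; default BLOSUM62 (from Biostrings).
#' @param gap_open,gap_extend negative integers, `gap_open <= gap_extend < 0`.
#' @param lambda,k positive Karlin-Altschul parameters.
#' @param matrix_name label for the matrix.
#' @return An object of class `flg_scoring`.
#' @export
scoring_scheme <- function(substitution = NULL, gap_open = -11L,
                           gap_extend = -1L, lambda = 0.267, k = 0.041,
                           matrix_name = NULL) {
  if (is.null(substitution)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    substitution <- e$BLOSUM62
    if (is.null(matrix_name)) matrix_name <- "BLOSUM62"
  }
  if (is.null(matrix_name)) matrix_name <- "custom"
  substitution <- as.matrix(substitution)
  if (nrow(substitution) != ncol(substitution) ||
      is.null(rownames(substitution)) ||
      !identical(rownames(substitution), colnames(substitution)))
    stop("substitution matrix must be square with matching row/column names")
  if (!isTRUE(all.equal(substitution, t(substitution))))
    stop("substitution matrix must be symmetric")
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stop("need gap_open <= gap_extend < 0")
  if (lambda <= 0 || k <= 0) stop("lambda and k must be positive")
  storage.mode(substitution) <- "integer"
  out <- list(matrix_name = matrix_name, substitution = substitution,
              gap_open = as.integer(gap_open),
              gap_extend = as.integer(gap_extend),
              lambda = lambda, k = k,
              alphabet = rownames(substitution))
  class(out) <- "flg_scoring"
  out
}

#' Read a substitution matrix in NCBI text format
#'
#' @param path path to an NCBI-format matrix file (comment lines start `#`).
#' @param ... passed to [scoring_scheme()].
#' @return An `flg_scoring` object.
#' @export
read_scoring_matrix <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  rn <- vapply(body, `[`, character(1), 1L)
  m <- t(vapply(body, function(x) as.integer(x[-1]), integer(length(cols))))
  dimnames(m) <- list(rn, cols)
  scoring_scheme(substitution = m, matrix_name = basename(path), ...)
}

check_seq <- function(x, scheme, what = "sequence") {
  if (!is.character(x) || length(x) != 1 || !nzchar(x))
    stop(what, " must be a single non-empty string")
  chars <- unique(strsplit(x, "")[[1]])
  bad <- setdiff(chars, scheme$alphabet)
  if (length(bad))
    stop("illegal residue(s) ", paste(bad, collapse = ","), " in ", what)
  invisible(x)
}

#' Optimal local alignment of two sequences
#'
#' Exact Smith-Waterman with affine gaps. The traceback is deterministic
#' (diagonal preferred over a gap in the second sequence, over a gap in the
#' first); bit scores are path-independent, identity and coverage are pinned
#' by this tie-break. Identity is matches over all alignment columns
#' (including gap columns); each coverage is the aligned span over that
#' sequence's length.
#'
#' @param a,b sequences (single strings over the scheme's alphabet).
#' @param scheme an [scoring_scheme()] object.
#' @param traceback compute the alignment path (set `FALSE` for score only).
#' @return An object of class `flg_alignment`: `raw_score`, `bit_score`,
#'   `identity`, `query_cov`, `subject_cov`, `matches`, `columns`, 0-based
#'   half-open spans `a_start`/`a_end`/`b_start`/`b_end`, and the two gapped
#'   alignment strings. A raw score of 0 means no positive-scoring local
#'   alignment exists (empty path).
#' @export
align_local <- function(a, b, scheme = scoring_scheme(), traceback = TRUE) {
  check_seq(a, scheme, "a")
  check_seq(b, scheme, "b")
  r <- .sw_align_cpp(a, b, scheme$substitution, scheme$alphabet,
                     scheme$gap_open, scheme$gap_extend, traceback)
  cols <- r$columns
  out <- list(raw_score = r$raw_score,
              bit_score = bit_score(r$raw_score, scheme),
              identity = if (cols > 0) r$matches / cols else 0,
              query_cov = (r$a_end - r$a_start) / nchar(a),
              subject_cov = (r$b_end - r$b_start) / nchar(b),
              matches = r$matches, columns = cols,
              a_start = r$a_start, a_end = r$a_end,
              b_start = r$b_start, b_end = r$b_end,
              aligned_a = r$aligned_a, aligned_b = r$aligned_b)
  class(out) <- "flg_alignment"
  out
}

#' @export
print.flg_alignment <- function(x, ...) {
  cat(sprintf("local alignment: raw %d (%.1f bits), identity %.3f over %d columns\n",
              x$raw_score, x$bit_score, x$identity, x$columns))
  invisible(x)
}

#' Karlin-Altschul bit score
#'
#' `(lambda * raw - ln K) / ln 2`, strictly increasing in the raw score.
#'
#' @param raw non-negative raw alignment score(s).
#' @param scheme an [scoring_scheme()] object.
#' @return Bit score(s).
#' @export
bit_score <- function(raw, scheme = scoring_scheme()) {
  if (any(raw < 0)) stop("raw score must be >= 0")
  (scheme$lambda * raw - log(scheme$k)) / log(2)
}

#' Bit score ratio between two sequences
#'
#' BSR = bits(a, b) / min(bits(a, a), bits(b, b)), clipped to `[0, 1]`;
#' symmetric by construction. A local raw score of 0 gives BSR 0.
#'
#' @param a,b sequences.
#' @param scheme an [scoring_scheme()] object.
#' @return A ratio in `[0, 1]`.
#' @export
bsr <- function(a, b, scheme = scoring_scheme()) {
  raw_ab <- align_local(a, b, scheme, traceback = FALSE)$raw_score
  raw_aa <- align_local(a, a, scheme, traceback = FALSE)$raw_score
  raw_bb <- align_local(b, b, scheme, traceback = FALSE)$raw_score
  bsr_from_raw(raw_ab, raw_aa, raw_bb, scheme)
}

bsr_from_raw <- function(raw_ab, raw_aa, raw_bb, scheme) {
  denom <- min(bit_score(raw_aa, scheme), bit_score(raw_bb, scheme))
  if (denom <= 0) stop("degenerate sequence: self bit score <= 0")
  if (raw_ab <= 0) return(0)
  min(1, max(0, bit_score(raw_ab, scheme) / denom))
}

#' All-vs-all BSR matrix
#'
#' @param seqs named character vector of sequences.
#' @param scheme an [scoring_scheme()] object.
#' @return A symmetric matrix of BSR values with unit diagonal.
#' @export
bsr_matrix <- function(seqs, scheme = scoring_scheme()) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_len(n))
  for (s in seqs) check_seq(s, scheme)
  self <- .sw_score_pairs_cpp(seqs, seq_len(n), seq_len(n),
                              scheme$substitution, scheme$alphabet,
                              scheme$gap_open, scheme$gap_extend)
  out <- diag(1, n)
  dimnames(out) <- list(names(seqs), names(seqs))
  if (n < 2) return(out)
  pr <- combn(n, 2)
  raw <- .sw_score_pairs_cpp(seqs, pr[1, ], pr[2, ], scheme$substitution,
                             scheme$alphabet, scheme$gap_open,
                             scheme$gap_extend)
  for (k in seq_len(ncol(pr))) {
    i <- pr[1, k]; j <- pr[2, k]
    v <- bsr_from_raw(raw[k], self[i], self[j], scheme)
    out[i, j] <- v
    out[j, i] <- v
  }
  out
}

#' Write a BSR matrix as TSV
#'
#' @param m matrix from [bsr_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bsr_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared internal: batch raw scores for arbitrary index pairs
sw_scores <- function(seqs, ia, ib, scheme) {
  .sw_score_pairs_cpp(seqs, as.integer(ia), as.integer(ib),
                      scheme$substitution, scheme$alphabet,
                      scheme$gap_open, scheme$gap_extend)
}
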