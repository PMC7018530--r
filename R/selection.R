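# Codon-aware alignment (protein-guided, progressive) and cumulative
# synonymous / nonsynonymous / indel curves along the reference sequence,
# using Nei-Gojobori pathway counting between codon pairs.

#' Count synonymous and nonsynonymous differences between two codons
#'
#' Nei-Gojobori pathway counting: the mean over all minimal mutational
#' pathways between the codons of the number of synonymous and nonsynonymous
#' single-base steps. `syn + nonsyn` equals the nucleotide Hamming distance.
#' Pathways passing through a stop codon are excluded from the average; if
#' every pathway crosses a stop, all pathways are used instead (flagged via
#' the `stop_fallback` attribute). Codons containing `N` or a gap contribute
#' `(0, 0)` and are flagged via the `flagged` attribute.
#'
#' @param codon_a,codon_b length-3 codon strings.
#' @return Named numeric vector `c(syn = , nonsyn = )` with attributes
#'   `flagged` and `stop_fallback`.
#' @export
count_syn_nonsyn <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a)
  codon_b <- toupper(codon_b)
  if (nchar(codon_a) != 3 || nchar(codon_b) != 3)
    stop("codons must be length-3 strings")
  ok <- function(x) grepl("^[ACGT]{3}$", x)
  if (!ok(codon_a) || !ok(codon_b)) {
    out <- c(syn = 0, nonsyn = 0)
    attr(out, "flagged") <- TRUE
    attr(out, "stop_fallback") <- FALSE
    return(out)
  }
  code <- Biostrings::GENETIC_CODE
  if (code[[codon_a]] == "*" || code[[codon_b]] == "*")
    stop("sense codons required, got a stop codon")
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diff_pos <- which(a != b)
  d <- length(diff_pos)
  if (d == 0) {
    out <- c(syn = 0, nonsyn = 0)
    attr(out, "flagged") <- FALSE
    attr(out, "stop_fallback") <- FALSE
    return(out)
  }
  # enumerate all orderings of the differing positions (minimal pathways)
  perms <- permutations_of(diff_pos)
  path_counts <- lapply(perms, function(ord) {
    cur <- a
    syn <- 0
    nonsyn <- 0
    through_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- b[p]
      aa_cur <- code[[paste(cur, collapse = "")]]
      aa_nxt <- code[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*") through_stop <- TRUE
      if (aa_cur == aa_nxt) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, stop = as.numeric(through_stop))
  })
  mat <- do.call(rbind, path_counts)
  valid <- mat[, "stop"] == 0
  fallback <- !any(valid)
  if (fallback) valid <- rep(TRUE, nrow(mat))
  out <- c(syn = mean(mat[valid, "syn"]),
           nonsyn = mean(mat[valid, "nonsyn"]))
  attr(out, "flagged") <- FALSE
  attr(out, "stop_fallback") <- fallback
  out
}

# all permutations of a short vector (at most 3 elements here)
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Potential synonymous/nonsynonymous site counts of a codon
#'
#' The expected fraction of single-base changes that are synonymous, summed
#' over the three positions (changes to stop codons excluded from the
#' denominator), as used for site normalization.
#'
#' @param codon a sense codon string.
#' @return Named numeric vector `c(syn_sites = , nonsyn_sites = )`.
#' @export
syn_nonsyn_sites <- function(codon) {
  codon <- toupper(codon)
  code <- Biostrings::GENETIC_CODE
  a <- strsplit(codon, "")[[1]]
  syn_sites <- 0
  for (p in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), a[p])
    outcomes <- vapply(alts, function(nt) {
      nxt <- a
      nxt[p] <- nt
      code[[paste(nxt, collapse = "")]]
    }, character(1))
    sense <- outcomes != "*"
    if (any(sense))
      syn_sites <- syn_sites + sum(outcomes[sense] == code[[codon]]) / sum(sense)
  }
  c(syn_sites = syn_sites, nonsyn_sites = 3 - syn_sites)
}

#' Protein-guided progressive codon alignment
#'
#' Translates each coding sequence, aligns the proteins progressively (guide
#' order: descending protein length, ties by id; each new protein is aligned
#' globally with affine gaps against the profile of the growing alignment),
#' and back-threads the protein gaps onto the DNA as whole-codon gaps.
#' Pre-aligned input can bypass this via [codon_alignment_from_strings()].
#'
#' @param cds_records a [flg_records] data frame of kind `"dna"`, each
#'   translatable.
#' @param scheme an [scoring_scheme()] object for the protein alignment.
#' @return An object of class `flg_codon_alignment`: `ids`, and `codons`, a
#'   character matrix (rows = sequences, columns = alignment columns) whose
#'   cells are codon triplets or `"---"`.
#' @export
codon_align <- function(cds_records, scheme = scoring_scheme()) {
  prots <- translate_cds(cds_records)  # errors name the offending record
  ord <- order(-nchar(prots$residues), prots$id, method = "radix")
  ids <- cds_records$id[ord]
  aa <- strsplit(prots$residues[ord], "")
  cods <- lapply(cds_records$residues[ord], function(dna) {
    n <- nchar(dna)
    has_stop <- Biostrings::GENETIC_CODE[substr(dna, n - 2, n)] == "*"
    n_cod <- n / 3 - ifelse(isTRUE(has_stop), 1, 0)
    substring(dna, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod))
  })

  # protein alignment as a list of gapped character vectors
  aln <- list(aa[[1]])
  for (s in seq_along(aa)[-1]) {
    S <- profile_score_matrix(aln, scheme)
    ops <- .profile_align_cpp(S, paste(aa[[s]], collapse = ""),
                              scheme$alphabet,
                              scheme$gap_open, scheme$gap_extend)
    ops <- strsplit(ops, "")[[1]]
    new_rows <- rethread_alignment(aln, aa[[s]], ops)
    aln <- new_rows
  }

  # back-thread: protein gap -> codon gap
  n_col <- length(aln[[1]])
  codon_mat <- matrix("---", nrow = length(ids), ncol = n_col,
                      dimnames = list(ids, NULL))
  for (r in seq_along(ids)) {
    non_gap <- aln[[r]] != "-"
    codon_mat[r, non_gap] <- cods[[r]]
  }
  out <- list(ids = ids, codons = codon_mat)
  class(out) <- "flg_codon_alignment"
  out
}

# average substitution score of each profile column against each residue
profile_score_matrix <- function(aln, scheme) {
  n_col <- length(aln[[1]])
  sub <- scheme$substitution
  S <- matrix(0, nrow = n_col, ncol = length(scheme$alphabet))
  for (j in seq_len(n_col)) {
    col <- vapply(aln, `[`, character(1), j)
    col <- col[col != "-"]
    S[j, ] <- colMeans(sub[col, , drop = FALSE])
  }
  S
}

# apply a profile-vs-sequence op string, inserting gap columns as needed
rethread_alignment <- function(aln, new_aa, ops) {
  n_col <- length(aln[[1]])
  old_cols <- integer(0)  # source column per output column, 0 = all-gap
  new_res <- integer(0)   # residue index of the new row, 0 = gap
  i <- 0L
  j <- 0L
  for (op in ops) {
    if (op == "M") {
      i <- i + 1L; j <- j + 1L
      old_cols <- c(old_cols, i)
      new_res <- c(new_res, j)
    } else if (op == "D") {
      i <- i + 1L
      old_cols <- c(old_cols, i)
      new_res <- c(new_res, 0L)
    } else {
      j <- j + 1L
      old_cols <- c(old_cols, 0L)
      new_res <- c(new_res, j)
    }
  }
  stopifnot(i == n_col, j == length(new_aa))
  rows <- lapply(aln, function(row) {
    out <- rep("-", length(old_cols))
    out[old_cols > 0] <- row[old_cols[old_cols > 0]]
    out
  })
  new_row <- rep("-", length(new_res))
  new_row[new_res > 0] <- new_aa[new_res[new_res > 0]]
  c(rows, list(new_row))
}

#' Build a codon alignment from pre-aligned codon strings
#'
#' @param aligned named character vector of gapped DNA strings (gap `"-"`),
#'   equal lengths divisible by 3, gaps in whole-codon units.
#' @return An `flg_codon_alignment`.
#' @export
codon_alignment_from_strings <- function(aligned) {
  L <- unique(nchar(aligned))
  if (length(L) != 1 || L %% 3 != 0)
    stop("aligned strings must share one length divisible by 3")
  ids <- names(aligned)
  if (is.null(ids)) ids <- paste0("s", seq_along(aligned))
  n_cod <- L / 3
  codon_mat <- t(vapply(aligned, function(s)
    substring(s, 3 * seq_len(n_cod) - 2, 3 * seq_len(n_cod)),
    character(n_cod)))
  rownames(codon_mat) <- ids
  bad <- !grepl("^([ACGTN]{3}|---)$", codon_mat)
  if (any(bad)) stop("cells must be codon triplets or whole-codon gaps")
  out <- list(ids = ids, codons = codon_mat)
  class(out) <- "flg_codon_alignment"
  out
}

#' Recover the ungapped coding sequences from a codon alignment
#'
#' @param alignment an `flg_codon_alignment`.
#' @return Named character vector of ungapped DNA strings.
#' @export
ungap_alignment <- function(alignment) {
  vapply(seq_along(alignment$ids), function(r) {
    row <- alignment$codons[r, ]
    paste(row[row != "---"], collapse = "")
  }, character(1)) |> setNames(alignment$ids)
}

#' Cumulative synonymous/nonsynonymous/indel curves along a reference
#'
#' At each reference codon position, the mean Nei-Gojobori synonymous and
#' nonsynonymous counts of all non-reference rows against the reference codon
#' are added to the running totals; the indel series accumulates the number
#' of rows opening a gap run at that reference position (insertions relative
#' to the reference are attributed to the next reference position). All three
#' series are non-decreasing from N- to C-terminus.
#'
#' @param alignment an `flg_codon_alignment` with at least two rows.
#' @param reference_id id of the reference row; if `NULL`, one is chosen
#'   uniformly at random (seed-controlled, mirroring a randomly selected
#'   reference).
#' @param seed integer seed used only when `reference_id` is `NULL`.
#' @param per_pair_sums if `TRUE`, report sums over pairwise comparisons
#'   instead of per-position means.
#' @return A data frame of class `flg_cum_curves` with columns `position`
#'   (1-based reference codon index), `cum_syn`, `cum_nonsyn`, `cum_indel`,
#'   plus attributes `reference_id`, `n_rows` and `sites` (potential
#'   syn/nonsyn site totals of the reference).
#' @export
cumulative_curves <- function(alignment, reference_id = NULL, seed = 1L,
                              per_pair_sums = FALSE) {
  n <- length(alignment$ids)
  if (n < 2) stop("cumulative curves need at least 2 aligned sequences")
  if (is.null(reference_id)) {
    set.seed(seed)
    reference_id <- sample(alignment$ids, 1)
  }
  if (!reference_id %in% alignment$ids)
    stop("reference id '", reference_id, "' not in the alignment")
  ref_row <- which(alignment$ids == reference_id)
  ref <- alignment$codons[ref_row, ]
  others <- alignment$codons[-ref_row, , drop = FALSE]
  ref_pos_cols <- which(ref != "---")

  scale <- if (per_pair_sums) nrow(others) else 1
  inc <- vapply(ref_pos_cols, function(j) {
    counts <- vapply(seq_len(nrow(others)), function(r) {
      if (others[r, j] == "---") return(c(0, 0))
      unname(count_syn_nonsyn(ref[j], others[r, j])[c("syn", "nonsyn")])
    }, numeric(2))
    rowMeans(counts) * scale
  }, numeric(2))

  # gap-run openings per alignment column, then attributed to reference
  # positions (insertion columns roll forward onto the next reference codon)
  openings <- vapply(seq_len(ncol(alignment$codons)), function(j) {
    sum(vapply(seq_len(nrow(others)), function(r) {
      gap_here <- others[r, j] == "---"
      gap_prev <- j > 1 && others[r, j - 1] == "---"
      ins_here <- ref[j] == "---" && others[r, j] != "---"
      ins_prev <- j > 1 && ref[j - 1] == "---" && others[r, j - 1] != "---"
      (gap_here && !gap_prev) || (ins_here && !ins_prev)
    }, logical(1)))
  }, numeric(1))
  indel_inc <- numeric(length(ref_pos_cols))
  carry <- 0
  k <- 1
  for (j in seq_len(ncol(alignment$codons))) {
    carry <- carry + openings[j]
    if (ref[j] != "---") {
      indel_inc[k] <- carry
      carry <- 0
      k <- k + 1
    }
  }
  indel_inc[length(indel_inc)] <- indel_inc[length(indel_inc)] + carry

  sites <- rowSums(vapply(ref[ref_pos_cols], syn_nonsyn_sites, numeric(2)))
  out <- data.frame(position = seq_along(ref_pos_cols),
                    cum_syn = cumsum(inc[1, ]),
                    cum_nonsyn = cumsum(inc[2, ]),
                    cum_indel = cumsum(indel_inc))
  attr(out, "reference_id") <- reference_id
  attr(out, "n_rows") <- n
  attr(out, "sites") <- sites
  class(out) <- c("flg_cum_curves", "data.frame")
  out
}

#' Write cumulative curves as TSV
#'
#' @param curves an `flg_cum_curves` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  write.table(as.data.frame(curves), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
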