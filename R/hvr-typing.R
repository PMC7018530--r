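# Conserved/variable region partition of flagellin genes, classification of
# variable regions into hypervariable-region (HVR) forms (mutually
# non-alignable classes) and isoforms (distinct sequences within a form),
# plus neighbor-joining trees from pairwise alignment scores.

#' Partition a flagellin gene into conserved and variable regions
#'
#' DNA mode cuts the first 570 bp and the last 300 bp as the two conserved
#' regions (C1/C2) and keeps the remaining middle as the variable region;
#' protein mode uses the equivalent 190 aa / 100 aa boundaries. Coordinates
#' are 0-based half-open; the concatenation of the three regions restores the
#' input.
#'
#' @param record a single-row [flg_records] data frame, or a residue string
#'   (then `kind` must be given).
#' @param kind `"dna"` or `"protein"`; taken from the record if omitted.
#' @return An object of class `flg_partition`: `conserved5`, `variable`,
#'   `conserved3` (strings), `boundaries` (c5 end, c3 start), `kind`.
#' @export
partition_gene <- function(record, kind = NULL) {
  if (is.character(record)) {
    residues <- record
    if (is.null(kind)) stop("kind is required when passing a bare string")
  } else {
    residues <- record$residues[1]
    if (is.null(kind)) kind <- record$kind[1]
  }
  kind <- match.arg(kind, c("dna", "protein"))
  c5 <- if (kind == "dna") 570L else 190L
  c3 <- if (kind == "dna") 300L else 100L
  L <- nchar(residues)
  if (L <= c5 + c3)
    stop("sequence too short to partition: need length > ", c5 + c3,
         " (got ", L, ")")
  out <- list(conserved5 = substr(residues, 1L, c5),
              variable = substr(residues, c5 + 1L, L - c3),
              conserved3 = substr(residues, L - c3 + 1L, L),
              boundaries = c(conserved5_end = c5, conserved3_start = L - c3),
              kind = kind)
  class(out) <- "flg_partition"
  out
}

#' Alignability predicate between two variable regions
#'
#' Two hypervariable regions belong to the same form when their best local
#' alignment has identity at least `min_identity` and covers at least
#' `min_coverage` of the shorter region. "No alignment" between HVR forms is
#' the negation of this predicate; the defaults sit between observed
#' within-form identities (> 0.9) and cross-form, near-random identities.
#'
#' @param va,vb variable-region sequences (non-empty strings).
#' @param min_identity,min_coverage thresholds in `(0, 1]`.
#' @param scheme an [scoring_scheme()] object.
#' @return `TRUE` if the regions are alignable; symmetric in its arguments.
#' @export
alignable <- function(va, vb, min_identity = 0.35, min_coverage = 0.5,
                      scheme = scoring_scheme()) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  if (!nzchar(va) || !nzchar(vb)) stop("empty variable region")
  al <- align_local(va, vb, scheme)
  if (al$raw_score <= 0) return(FALSE)
  short_len <- min(nchar(va), nchar(vb))
  cov <- min(al$a_end - al$a_start, al$b_end - al$b_start) / short_len
  al$identity >= min_identity && cov >= min_coverage
}

#' Assign hypervariable regions to HVR forms and isoforms
#'
#' Forms are the connected components of the alignability relation
#' (single linkage, mirroring the definition of a form as having no
#' alignment with any other form). Within a form, isoforms are the distinct
#' region strings. Form ids are assigned by descending member count, then by
#' lexicographically smallest representative sequence; isoform ids likewise.
#'
#' @param regions named character vector: names are record ids, values are
#'   variable-region sequences.
#' @param min_identity,min_coverage passed to [alignable()].
#' @param scheme an [scoring_scheme()] object.
#' @return An object of class `flg_hvr_forms`: `forms` (list with `form_id`,
#'   `representative`, `isoforms` = list of `isoform_id`, `sequence`,
#'   `member_ids`) and `assignment` (data frame `id`, `form_id`,
#'   `isoform_id`).
#' @export
assign_hvr_forms <- function(regions, min_identity = 0.35,
                             min_coverage = 0.5,
                             scheme = scoring_scheme()) {
  if (!length(regions)) stop("no regions supplied")
  if (is.null(names(regions)) || anyDuplicated(names(regions)))
    stop("regions must be uniquely named by record id")
  # distinct strings first: exact duplicates are by definition alignable
  uniq <- sort(unique(unname(regions)), method = "radix")
  n <- length(uniq)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (find(i) == find(j)) next
        if (alignable(uniq[i], uniq[j], min_identity, min_coverage, scheme))
          parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comp <- match(comp, unique(comp))

  groups <- split(uniq, comp)
  # deterministic form ordering: descending total membership, then
  # lexicographic representative sequence
  form_info <- lapply(groups, function(strs) {
    members_per_iso <- lapply(strs, function(s)
      sort(names(regions)[unname(regions) == s], method = "radix"))
    counts <- lengths(members_per_iso)
    ord <- order(-counts, strs, method = "radix")
    list(strs = strs[ord], members = members_per_iso[ord],
         total = sum(counts), rep = strs[ord][1])
  })
  ord <- order(-vapply(form_info, `[[`, numeric(1), "total"),
               vapply(form_info, `[[`, character(1), "rep"),
               method = "radix")
  form_info <- form_info[ord]

  width <- max(2L, nchar(length(form_info)))
  forms <- lapply(seq_along(form_info), function(f) {
    fi <- form_info[[f]]
    form_id <- sprintf("F%0*d", width, f)
    isoforms <- lapply(seq_along(fi$strs), function(k) {
      list(isoform_id = sprintf("%s.i%d", form_id, k),
           sequence = fi$strs[k],
           member_ids = fi$members[[k]])
    })
    list(form_id = form_id, representative = fi$rep, isoforms = isoforms)
  })

  assignment <- do.call(rbind, lapply(forms, function(fm) {
    do.call(rbind, lapply(fm$isoforms, function(iso) {
      data.frame(id = iso$member_ids, form_id = fm$form_id,
                 isoform_id = iso$isoform_id, stringsAsFactors = FALSE)
    }))
  }))
  assignment <- assignment[order(assignment$id, method = "radix"), ,
                           drop = FALSE]
  rownames(assignment) <- NULL
  out <- list(forms = forms, assignment = assignment)
  class(out) <- "flg_hvr_forms"
  out
}

#' @export
print.flg_hvr_forms <- function(x, ...) {
  n_iso <- sum(vapply(x$forms, function(f) length(f$isoforms), integer(1)))
  cat("HVR typing:", length(x$forms), "forms,", n_iso, "isoforms,",
      nrow(x$assignment), "regions\n")
  invisible(x)
}

#' Write the HVR form table as TSV
#'
#' @param hvr an `flg_hvr_forms` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hvr_table <- function(hvr, path) {
  write.table(hvr$assignment, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape), with negative branch lengths
#' clamped to zero. Distances from pairwise alignment scores are typically
#' `d = 1 - raw(a, b) / min(raw(a, a), raw(b, b))`; see
#' [score_distance_matrix()].
#'
#' @param distances symmetric numeric matrix with zero diagonal; row names
#'   are the taxon labels.
#' @param labels optional labels overriding the matrix dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(distances, labels = NULL) {
  distances <- as.matrix(distances)
  n <- nrow(distances)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (ncol(distances) != n) stop("distance matrix must be square")
  if (!isTRUE(all.equal(distances, t(distances), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(distances)) > 1e-8))
    stop("distance matrix must have a zero diagonal")
  if (!is.null(labels)) dimnames(distances) <- list(labels, labels)
  if (is.null(rownames(distances)))
    dimnames(distances) <- list(paste0("t", seq_len(n)),
                                paste0("t", seq_len(n)))
  tree <- ape::nj(distances)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Score-based distance matrix for tree building
#'
#' `d(a, b) = 1 - raw(a, b) / min(raw(a, a), raw(b, b))`, clipped to
#' `[0, 1]`: the transform used to turn pairwise local alignment scores into
#' neighbor-joining distances.
#'
#' @param seqs named character vector of sequences.
#' @param scheme an [scoring_scheme()] object.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
score_distance_matrix <- function(seqs, scheme = scoring_scheme()) {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_len(n))
  self <- sw_scores(seqs, seq_len(n), seq_len(n), scheme)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    pr <- combn(n, 2)
    raw <- sw_scores(seqs, pr[1, ], pr[2, ], scheme)
    for (k in seq_len(ncol(pr))) {
      i <- pr[1, k]; j <- pr[2, k]
      v <- 1 - raw[k] / min(self[i], self[j])
      v <- min(1, max(0, v))
      d[i, j] <- v
      d[j, i] <- v
    }
  }
  d
}

#' Write a tree in newick format
#'
#' @param tree a `phylo` object (e.g. from [nj_tree()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
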