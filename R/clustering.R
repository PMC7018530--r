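# Greedy identity clustering of unique sequences, max-BSR inter-cluster
# similarities, and the minimum spanning forest over cluster distances
# (1 - similarity), with composition summaries and graph export.

#' Greedy set-cover clustering of unique sequences
#'
#' Sequences are processed by descending length (ties by representative id).
#' Each unassigned sequence founds a cluster; later sequences join the first
#' existing cluster whose representative they match at `min_identity`
#' (matches over alignment columns) with coverage of the shorter sequence at
#' least `min_coverage`. Every sequence is assigned exactly once.
#'
#' @param uniques an `flg_unique_set` from [deduplicate()], or a
#'   [flg_records] data frame of already-unique sequences.
#' @param min_identity,min_coverage thresholds in `(0, 1]`.
#' @param scheme an [scoring_scheme()] object.
#' @return List of `flg_cluster` objects, each with `cluster_id` (`"C1"`,
#'   `"C2"`, ... in creation order), `representative` (unique-sequence key =
#'   representative record id), `members` (keys), and `sequences` (named
#'   residue strings).
#' @export
greedy_cluster <- function(uniques, min_identity = 0.3, min_coverage = 0.8,
                           scheme = scoring_scheme()) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  if (inherits(uniques, "flg_unique_set")) {
    keys <- unname(uniques$rep_id)
    seqs <- setNames(names(uniques$members), keys)
  } else {
    keys <- uniques$id
    seqs <- setNames(uniques$residues, keys)
  }
  if (!length(keys)) return(list())
  ord <- order(-nchar(seqs), keys, method = "radix")
  keys <- keys[ord]
  seqs <- seqs[ord]

  reps <- integer(0)           # indices of representatives, creation order
  assignment <- integer(length(keys))
  for (i in seq_along(keys)) {
    placed <- FALSE
    for (r in seq_along(reps)) {
      ri <- reps[r]
      if (i == ri) next
      al <- align_local(seqs[[ri]], seqs[[i]], scheme)
      short_len <- min(nchar(seqs[[ri]]), nchar(seqs[[i]]))
      cov <- min(al$a_end - al$a_start, al$b_end - al$b_start) / short_len
      if (al$identity >= min_identity && cov >= min_coverage) {
        assignment[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assignment[i] <- length(reps)
    }
  }

  lapply(seq_along(reps), function(r) {
    members <- keys[assignment == r]
    cl <- list(cluster_id = paste0("C", r),
               representative = keys[reps[r]],
               members = sort(members, method = "radix"),
               sequences = seqs[members])
    class(cl) <- "flg_cluster"
    cl
  })
}

#' @export
print.flg_cluster <- function(x, ...) {
  cat(x$cluster_id, ": ", length(x$members), " members, representative ",
      x$representative, "\n", sep = "")
  invisible(x)
}

#' Maximum BSR between two clusters
#'
#' The similarity between clusters is the maximum bit score ratio over all
#' cross pairs of member sequences; the corresponding distance used by the
#' minimum spanning forest is `1 - similarity`.
#'
#' @param ci,cj `flg_cluster` objects.
#' @param scheme an [scoring_scheme()] object.
#' @return Similarity in `[0, 1]`.
#' @export
cluster_similarity <- function(ci, cj, scheme = scoring_scheme()) {
  seqs <- c(ci$sequences, cj$sequences)
  ni <- length(ci$sequences)
  nj <- length(cj$sequences)
  self <- sw_scores(seqs, seq_along(seqs), seq_along(seqs), scheme)
  ia <- rep(seq_len(ni), times = nj)
  ib <- rep(ni + seq_len(nj), each = ni)
  raw <- sw_scores(seqs, ia, ib, scheme)
  max(vapply(seq_along(raw), function(k) {
    bsr_from_raw(raw[k], self[ia[k]], self[ib[k]], scheme)
  }, numeric(1)))
}

#' Build the weighted cluster graph
#'
#' @param clusters list of `flg_cluster` objects.
#' @param scheme an [scoring_scheme()] object.
#' @return An object of class `flg_cluster_graph`: `clusters`, and `edges`
#'   data frame (`from`, `to`, `similarity`, `distance`) over all unordered
#'   cluster pairs. [minimum_spanning_forest()] adds `mst_edges` and
#'   `components`.
#' @export
build_cluster_graph <- function(clusters, scheme = scoring_scheme()) {
  ids <- vapply(clusters, `[[`, character(1), "cluster_id")
  if (length(clusters) > 1) {
    pr <- combn(length(clusters), 2)
    sim <- vapply(seq_len(ncol(pr)), function(k) {
      cluster_similarity(clusters[[pr[1, k]]], clusters[[pr[2, k]]], scheme)
    }, numeric(1))
    edges <- data.frame(from = ids[pr[1, ]], to = ids[pr[2, ]],
                        similarity = sim, distance = 1 - sim,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        similarity = numeric(), distance = numeric(),
                        stringsAsFactors = FALSE)
  }
  out <- list(clusters = clusters, node_ids = ids, edges = edges,
              mst_edges = NULL, components = NULL, link_threshold = NULL)
  class(out) <- "flg_cluster_graph"
  out
}

#' Minimum spanning forest over cluster distances
#'
#' Edges at or below the link threshold are discarded; within each remaining
#' connected component, Kruskal's algorithm minimizes total distance
#' (`1 - similarity`). Ties are broken by lexicographic (from, to) pair so the
#' forest is deterministic. Components are the superclusters.
#'
#' @param graph an `flg_cluster_graph` from [build_cluster_graph()].
#' @param link_threshold similarity at or below which clusters are not linked;
#'   the default 0.1 sits above the BSR noise floor of unrelated proteins.
#' @return The graph with `mst_edges` (subset of `edges`) and `components`
#'   (named integer membership vector) filled in.
#' @export
minimum_spanning_forest <- function(graph, link_threshold = 0.1) {
  stopifnot(link_threshold >= 0)
  edges <- graph$edges[graph$edges$similarity > link_threshold, , drop = FALSE]
  ids <- graph$node_ids
  parent <- seq_along(ids)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  ord <- order(edges$distance, edges$from, edges$to, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  keep <- logical(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    a <- find(match(edges$from[k], ids))
    b <- find(match(edges$to[k], ids))
    if (a != b) {
      parent[a] <- b
      keep[k] <- TRUE
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  graph$mst_edges <- edges[keep, , drop = FALSE]
  rownames(graph$mst_edges) <- NULL
  graph$components <- setNames(match(roots, unique(roots)), ids)
  graph$link_threshold <- link_threshold
  graph
}

#' @export
print.flg_cluster_graph <- function(x, ...) {
  cat("cluster graph:", length(x$node_ids), "clusters,",
      nrow(x$edges), "edges")
  if (!is.null(x$components))
    cat(";", max(x$components), "supercluster(s),",
        nrow(x$mst_edges), "MST edges")
  cat("\n")
  invisible(x)
}

cluster_phylum_counts <- function(cluster, taxonomy) {
  phyla <- taxonomy$phylum[match(cluster$members, taxonomy$id)]
  phyla[is.na(phyla)] <- "Unknown"
  table(phyla)
}

#' Per-cluster phylum composition and the multi-phylum fraction
#'
#' Phylum of a unique sequence is taken from its representative record id.
#' `"Unknown"` does not count toward the multi-phylum call.
#'
#' @param clusters list of `flg_cluster` objects.
#' @param taxonomy data frame with `id` and `phylum` columns covering the
#'   cluster member keys.
#' @return A list: `table` (long data frame `cluster_id`, `phylum`, `n`,
#'   `proportion`), `n_clusters`, `n_multi_phylum`, and
#'   `multi_phylum_percent` (nearest whole percent).
#' @export
summarize_composition <- function(clusters, taxonomy) {
  rows <- lapply(clusters, function(cl) {
    tab <- cluster_phylum_counts(cl, taxonomy)
    data.frame(cluster_id = cl$cluster_id,
               phylum = names(tab),
               n = as.integer(tab),
               proportion = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  multi <- vapply(clusters, function(cl) {
    tab <- cluster_phylum_counts(cl, taxonomy)
    sum(names(tab) != "Unknown" & tab > 0) >= 2
  }, logical(1))
  list(table = table,
       n_clusters = length(clusters),
       n_multi_phylum = sum(multi),
       multi_phylum_percent = round(100 * sum(multi) /
                                      max(1, length(clusters))))
}

#' Export the cluster table as TSV
#'
#' @param clusters list of `flg_cluster` objects.
#' @param taxonomy optional taxonomy data frame for phylum counts.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path, taxonomy = NULL) {
  df <- do.call(rbind, lapply(clusters, function(cl) {
    phyla <- if (is.null(taxonomy)) "" else {
      tab <- cluster_phylum_counts(cl, taxonomy)
      paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = ",")
    }
    data.frame(cluster_id = cl$cluster_id,
               representative = cl$representative,
               n_members = length(cl$members),
               members = paste(cl$members, collapse = ","),
               phylum_counts = phyla,
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the cluster graph
#'
#' Writes the full weighted edge list as TSV and, optionally, a GraphML file
#' (for Cytoscape-style rendering) in which MST edges are flagged.
#'
#' @param graph an `flg_cluster_graph`.
#' @param edge_tsv path for the edge-list TSV (or `NULL` to skip).
#' @param graphml path for the GraphML export (or `NULL` to skip).
#' @return Invisibly, the list of written paths.
#' @export
write_cluster_graph <- function(graph, edge_tsv = NULL, graphml = NULL) {
  written <- list()
  if (!is.null(edge_tsv)) {
    write.table(graph$edges, edge_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written$edge_tsv <- edge_tsv
  }
  if (!is.null(graphml)) {
    edges <- graph$edges
    edges$in_mst <- FALSE
    if (!is.null(graph$mst_edges) && nrow(graph$mst_edges)) {
      key <- paste(edges$from, edges$to)
      mkey <- paste(graph$mst_edges$from, graph$mst_edges$to)
      edges$in_mst <- key %in% mkey
    }
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(
                                         name = graph$node_ids,
                                         n_members = vapply(graph$clusters,
                                                            function(cl) length(cl$members),
                                                            integer(1))))
    igraph::write_graph(g, graphml, format = "graphml")
    written$graphml <- graphml
  }
  invisible(written)
}
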