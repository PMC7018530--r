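# Greedy clustering, max-BSR cluster similarity, minimum spanning forest
# optimality and composition summaries.

test_that("identical sequences form one cluster, unalignable ones split", {
  tsch <- toy_scheme()
  same <- flg_records(c("a", "b", "c"), rep("ACAACAACA", 3))
  cl <- greedy_cluster(deduplicate(same), scheme = tsch)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members, "a")  # one unique key

  apart <- flg_records(c("a", "b"), c("AAAAAA", "CCCCCC"))
  cl2 <- greedy_cluster(deduplicate(apart), scheme = tsch)
  expect_length(cl2, 2)
  expect_true(all(lengths(lapply(cl2, `[[`, "members")) == 1))

  expect_length(greedy_cluster(deduplicate(same[0, ]), scheme = tsch), 0)
})

test_that("well-separated families are recovered exactly", {
  set.seed(31)
  sch <- scoring_scheme()
  n_fam <- 4
  ancestors <- replicate(n_fam, random_aa_string(120))
  aa20 <- colnames(sch$substitution)[1:20]
  recs <- list()
  truth <- character()
  for (f in seq_len(n_fam)) {
    for (k in 1:5) {
      aa <- strsplit(ancestors[f], "")[[1]]
      hit <- which(runif(120) < 0.05)
      for (p in hit) aa[p] <- sample(setdiff(aa20, aa[p]), 1)
      id <- sprintf("f%d_m%d", f, k)
      recs[[id]] <- paste(aa, collapse = "")
      truth[id] <- paste0("fam", f)
    }
  }
  rec <- flg_records(names(recs), unlist(recs))
  cl <- greedy_cluster(deduplicate(rec), min_identity = 0.5,
                       min_coverage = 0.8, scheme = sch)
  expect_length(cl, n_fam)
  got <- unlist(lapply(cl, function(x)
    setNames(rep(x$cluster_id, length(x$members)), x$members)))
  expect_true(same_partition(got, truth))
})

test_that("clusters partition the unique set and respect threshold monotonicity", {
  p <- default_panel()
  rep <- default_curation()
  keep <- p$proteins[p$proteins$id %in% rep$accepted$id, ]
  u <- deduplicate(keep)
  cl <- default_clusters()
  members <- unlist(lapply(cl, `[[`, "members"))
  expect_setequal(members, unname(u$rep_id))
  expect_equal(length(members), length(unique(members)))
  # raising min_identity cannot merge clusters
  sub <- unique_records(u)[1:40, ]
  lo <- greedy_cluster(sub, min_identity = 0.3)
  hi <- greedy_cluster(sub, min_identity = 0.7)
  expect_gte(length(hi), length(lo))
})

test_that("cluster similarity equals the brute-force cross-pair maximum", {
  set.seed(41)
  sch <- scoring_scheme()
  mk <- function(tag) {
    seqs <- setNames(replicate(3, random_aa_string(60)),
                     paste0(tag, 1:3))
    cl <- list(cluster_id = tag, representative = names(seqs)[1],
               members = names(seqs), sequences = seqs)
    class(cl) <- "flg_cluster"
    cl
  }
  cls <- lapply(c("A", "B", "C"), mk)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    ci <- cls[[pair[1]]]
    cj <- cls[[pair[2]]]
    brute <- max(outer(seq_len(3), seq_len(3), Vectorize(function(i, j)
      bsr(ci$sequences[[i]], cj$sequences[[j]], sch))))
    expect_equal(cluster_similarity(ci, cj, sch), brute)
  }
})

test_that("clusters sharing an identical member pair have similarity 1", {
  shared <- random_aa_string(50)
  mk <- function(tag, seqs) {
    cl <- list(cluster_id = tag, representative = names(seqs)[1],
               members = names(seqs), sequences = seqs)
    class(cl) <- "flg_cluster"
    cl
  }
  ci <- mk("A", setNames(c(shared, random_aa_string(50)), c("a1", "a2")))
  cj <- mk("B", setNames(shared, "b1"))
  expect_equal(cluster_similarity(ci, cj), 1)
  tsch <- toy_scheme()
  di <- mk("D", setNames("AAAA", "d1"))
  dj <- mk("E", setNames("BBBB", "e1"))
  expect_equal(cluster_similarity(di, dj, tsch), 0)
})

make_graph <- function(ids, sims) {
  # sims: named vector "A|B" -> similarity
  clusters <- lapply(ids, function(i) {
    cl <- list(cluster_id = i, representative = i, members = i,
               sequences = setNames("M", i))
    class(cl) <- "flg_cluster"
    cl
  })
  pairs <- strsplit(names(sims), "|", fixed = TRUE)
  edges <- data.frame(from = vapply(pairs, `[`, "", 1),
                      to = vapply(pairs, `[`, "", 2),
                      similarity = unname(sims),
                      distance = 1 - unname(sims),
                      stringsAsFactors = FALSE)
  g <- list(clusters = clusters, node_ids = ids, edges = edges,
            mst_edges = NULL, components = NULL, link_threshold = NULL)
  class(g) <- "flg_cluster_graph"
  g
}

test_that("three-node MST picks the two strongest links", {
  g <- make_graph(c("A", "B", "C"),
                  c("A|B" = 0.9, "B|C" = 0.8, "A|C" = 0.1))
  g <- minimum_spanning_forest(g, link_threshold = 0)
  got <- paste(g$mst_edges$from, g$mst_edges$to, sep = "|")
  expect_setequal(got, c("A|B", "B|C"))
  expect_equal(max(g$components), 1)
})

test_that("zero-similarity graphs fall apart into singletons", {
  g <- make_graph(c("A", "B", "C"),
                  c("A|B" = 0, "B|C" = 0, "A|C" = 0))
  g <- minimum_spanning_forest(g, link_threshold = 0)
  expect_equal(nrow(g$mst_edges), 0)
  expect_equal(max(g$components), 3)
})

test_that("Kruskal matches exhaustive spanning-tree enumeration", {
  set.seed(51)
  for (trial in 1:25) {
    n <- sample(3:6, 1)
    ids <- LETTERS[1:n]
    pairs <- combn(ids, 2)
    sims <- setNames(round(runif(ncol(pairs), 0.05, 0.95), 3),
                     paste(pairs[1, ], pairs[2, ], sep = "|"))
    g <- make_graph(ids, sims)
    g <- minimum_spanning_forest(g, link_threshold = 0)
    expect_equal(max(g$components), 1)
    expect_equal(nrow(g$mst_edges), n - 1)
    expect_equal(sum(g$mst_edges$distance),
                 brute_mst_distance(ids, g$edges), tolerance = 1e-12,
                 info = paste("trial", trial))
    # cross-check against an independent MST implementation
    ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                        directed = FALSE)
    igraph::E(ig)$weight <- g$edges$distance
    expect_equal(sum(g$mst_edges$distance),
                 sum(igraph::E(igraph::mst(ig))$weight), tolerance = 1e-12)
  }
})

test_that("link threshold removes weak edges before the forest is built", {
  g <- make_graph(c("A", "B", "C", "D"),
                  c("A|B" = 0.9, "B|C" = 0.08, "C|D" = 0.7,
                    "A|C" = 0.05, "A|D" = 0.02, "B|D" = 0.0))
  g <- minimum_spanning_forest(g, link_threshold = 0.1)
  expect_equal(max(g$components), 2)
  got <- paste(g$mst_edges$from, g$mst_edges$to, sep = "|")
  expect_setequal(got, c("A|B", "C|D"))
  expect_true(all(g$mst_edges$similarity > 0.1))
})

test_that("superkingdoms never mix in the panel's spanning forest", {
  p <- default_panel()
  cl <- default_clusters()
  g <- default_graph()
  truth <- p$truth
  kingdom_of <- vapply(cl, function(x) {
    kd <- unique(truth$superkingdom[match(x$members, truth$id)])
    expect_length(kd, 1)  # no cluster mixes superkingdoms either
    kd
  }, character(1))
  for (comp in unique(g$components)) {
    expect_length(unique(kingdom_of[g$components == comp]), 1)
  }
  expect_gte(max(g$components), 2)
})

test_that("composition summary reports multi-phylum fractions", {
  mk <- function(tag, ids) {
    cl <- list(cluster_id = tag, representative = ids[1], members = ids,
               sequences = setNames(rep("M", length(ids)), ids))
    class(cl) <- "flg_cluster"
    cl
  }
  tax <- data.frame(id = c("a", "b", "c", "d", "e"),
                    phylum = c("P1", "P2", "P1", "Unknown", "P1"))
  cl <- list(mk("C1", c("a", "b")),    # two phyla
             mk("C2", c("c", "d")),    # one named phylum + Unknown
             mk("C3", "e"))            # single phylum
  s <- summarize_composition(cl, tax)
  expect_equal(s$n_clusters, 3)
  expect_equal(s$n_multi_phylum, 1)
  expect_equal(s$multi_phylum_percent, 33)
  expect_equal(sum(s$table$n[s$table$cluster_id == "C1"]), 2)
  # all single-phylum floors at zero
  s0 <- summarize_composition(list(mk("C1", "a"), mk("C2", "c")), tax)
  expect_equal(s0$multi_phylum_percent, 0)
})

test_that("shared-lineage phyla produce a known multi-phylum signal", {
  cfg <- panel_config(rng_seed = 5, n_phyla = 2, forms_per_species = 4,
                      isoforms_per_form = 2, species_divergence = 0.05,
                      n_decoys_flgl = 0, n_archaeal = 6, archaeal_forms = 2)
  p <- generate_panel(cfg)
  u <- deduplicate(p$proteins)
  cl <- greedy_cluster(u)
  s <- summarize_composition(cl, p$taxonomy)
  # with near-identical conserved lineages the two bacterial phyla merge
  # into one cluster; archaeal clusters stay single-phylum
  bact <- vapply(cl, function(x) {
    any(p$truth$superkingdom[match(x$members, p$truth$id)] == "Bacteria")
  }, logical(1))
  per_cluster_phyla <- vapply(cl, function(x)
    length(unique(p$truth$phylum[match(x$members, p$truth$id)])),
    integer(1))
  expect_equal(sum(bact), 1)
  expect_equal(per_cluster_phyla[bact], 2)
  expect_true(all(per_cluster_phyla[!bact] == 1))
  expect_equal(s$n_multi_phylum, 1)
})

test_that("cluster tables and graph exports are written", {
  cl <- default_clusters()
  p <- default_panel()
  g <- default_graph()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  edge_tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_cluster_table(cl, tsv, taxonomy = p$taxonomy)
  write_cluster_graph(g, edge_tsv = edge_tsv, graphml = gml)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), length(cl))
  expect_true(file.size(gml) > 0)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), length(cl))
})
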