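# Shared fixtures: the default synthetic panel is expensive enough to build
# once per test run and reuse across test files.

.panel_cache <- new.env(parent = emptyenv())

default_panel <- function() {
  if (is.null(.panel_cache$panel))
    .panel_cache$panel <- generate_panel(panel_config())
  .panel_cache$panel
}

default_curation <- function() {
  if (is.null(.panel_cache$curation)) {
    p <- default_panel()
    .panel_cache$curation <- curate(p$proteins, p$models)
  }
  .panel_cache$curation
}

default_clusters <- function() {
  if (is.null(.panel_cache$clusters)) {
    p <- default_panel()
    rep <- default_curation()
    keep <- p$proteins[p$proteins$id %in% rep$accepted$id, , drop = FALSE]
    .panel_cache$clusters <- greedy_cluster(deduplicate(keep))
  }
  .panel_cache$clusters
}

default_graph <- function() {
  if (is.null(.panel_cache$graph)) {
    g <- build_cluster_graph(default_clusters())
    .panel_cache$graph <- minimum_spanning_forest(g)
  }
  .panel_cache$graph
}

# partition equality: two labelings induce the same grouping of ids
same_partition <- function(labels_a, labels_b) {
  stopifnot(identical(sort(names(labels_a)), sort(names(labels_b))))
  labels_b <- labels_b[names(labels_a)]
  a_groups <- split(names(labels_a), unname(labels_a))
  b_groups <- split(names(labels_b), unname(labels_b))
  setequal(lapply(a_groups, sort), lapply(b_groups, sort))
}
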