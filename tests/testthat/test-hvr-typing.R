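# Region partition arithmetic, the alignability predicate, HVR form/isoform
# assignment and neighbor-joining trees.

test_that("gene partition uses the 570/300 bp and 190/100 aa boundaries", {
  set.seed(61)
  gene <- paste(sample(c("A", "C", "G", "T"), 1758, replace = TRUE),
                collapse = "")
  part <- partition_gene(gene, kind = "dna")
  expect_equal(nchar(part$conserved5), 570)
  expect_equal(nchar(part$variable), 888)
  expect_equal(nchar(part$conserved3), 300)
  expect_equal(paste0(part$conserved5, part$variable, part$conserved3), gene)
  expect_equal(unname(part$boundaries), c(570, 1458))

  edge <- paste(rep("A", 871), collapse = "")
  expect_equal(nchar(partition_gene(edge, kind = "dna")$variable), 1)
  too_short <- paste(rep("A", 870), collapse = "")
  expect_error(partition_gene(too_short, kind = "dna"), "870")

  prot <- random_aa_string(400)
  pp <- partition_gene(prot, kind = "protein")
  expect_equal(nchar(pp$conserved5), 190)
  expect_equal(nchar(pp$conserved3), 100)
  expect_equal(paste0(pp$conserved5, pp$variable, pp$conserved3), prot)
  expect_error(partition_gene(random_aa_string(290), kind = "protein"),
               "290")
})

test_that("alignability separates identical, mutated and random regions", {
  set.seed(62)
  v <- random_aa_string(150)
  expect_true(alignable(v, v))
  # SNP-level divergence stays alignable
  aa <- strsplit(v, "")[[1]]
  aa20 <- colnames(scoring_scheme()$substitution)[1:20]
  for (p in sample(150, 7)) aa[p] <- sample(setdiff(aa20, aa[p]), 1)
  expect_true(alignable(v, paste(aa, collapse = "")))
  # random pairs are not alignable
  for (k in 1:10) {
    expect_false(alignable(random_aa_string(150), random_aa_string(150)))
  }
  expect_false(alignable("AAAA", "CCCC", scheme = toy_scheme()))
  expect_error(alignable("", "MK"), "empty")
  # symmetry
  a <- random_aa_string(120)
  b <- random_aa_string(130)
  expect_equal(alignable(a, b), alignable(b, a))
})

test_that("forms are single-linkage components with deterministic ids", {
  set.seed(63)
  # n mutually non-alignable regions -> n singleton forms
  regions <- setNames(replicate(5, random_aa_string(140)),
                      paste0("r", 1:5))
  hv <- assign_hvr_forms(regions)
  expect_length(hv$forms, 5)
  expect_true(all(vapply(hv$forms, function(f)
    length(f$isoforms), integer(1)) == 1))

  # transitivity: a ~ b, b ~ c, a !~ c still one form
  base <- random_aa_string(160)
  mutate_at <- function(s, pos) {
    aa <- strsplit(s, "")[[1]]
    aa20 <- colnames(scoring_scheme()$substitution)[1:20]
    for (p in pos) aa[p] <- sample(setdiff(aa20, aa[p]), 1)
    paste(aa, collapse = "")
  }
  b <- mutate_at(base, 1:55)
  c_ <- mutate_at(b, 100:155)
  expect_true(alignable(base, b, min_identity = 0.6))
  expect_true(alignable(b, c_, min_identity = 0.6))
  stopifnot(!alignable(base, c_, min_identity = 0.6))
  hv2 <- assign_hvr_forms(setNames(c(base, b, c_), c("a", "b", "c")),
                          min_identity = 0.6)
  expect_length(hv2$forms, 1)
  expect_length(hv2$forms[[1]]$isoforms, 3)
})

test_that("form assignment is invariant to input order", {
  set.seed(64)
  anc <- replicate(3, random_aa_string(150))
  regions <- character()
  for (f in 1:3) {
    for (k in 1:3) {
      aa <- strsplit(anc[f], "")[[1]]
      aa20 <- colnames(scoring_scheme()$substitution)[1:20]
      for (p in sample(150, 3)) aa[p] <- sample(setdiff(aa20, aa[p]), 1)
      regions[sprintf("m%d_%d", f, k)] <- paste(aa, collapse = "")
    }
  }
  hv1 <- assign_hvr_forms(regions)
  hv2 <- assign_hvr_forms(rev(regions))
  expect_equal(hv1$assignment, hv2$assignment)
  expect_length(hv1$forms, 3)
})

test_that("the default panel yields its 26 forms with exact membership", {
  p <- default_panel()
  truth <- p$truth
  foc <- truth$species == "species_bact_01" & truth$category == "flagellin"
  ids <- truth$id[foc]
  recs <- p$proteins[match(ids, p$proteins$id), ]
  regions <- setNames(substr(recs$residues, truth$region_start[foc] + 1,
                             truth$region_end[foc]), ids)
  hv <- assign_hvr_forms(regions)
  expect_length(hv$forms, 26)
  got_form <- setNames(hv$assignment$form_id, hv$assignment$id)
  want_form <- setNames(truth$form_id[foc], ids)
  expect_true(same_partition(got_form, want_form))
  # isoforms = distinct strings within forms, matching truth labels
  got_iso <- setNames(hv$assignment$isoform_id, hv$assignment$id)
  want_iso <- setNames(truth$isoform_id[foc], ids)
  expect_true(same_partition(got_iso, want_iso))
  # dual-level separation: within-form conservative identity high,
  # cross-form low
  within <- c()
  cross <- c()
  forms_list <- split(names(regions), want_form[names(regions)])
  reps <- vapply(forms_list, function(m) regions[[m[1]]], character(1))
  for (f in seq_along(forms_list)) {
    m <- forms_list[[f]]
    if (length(unique(regions[m])) > 1) {
      al <- align_local(regions[[m[1]]], regions[[m[2]]])
      within <- c(within, al$matches / min(nchar(regions[[m[1]]]),
                                           nchar(regions[[m[2]]])))
    }
  }
  set.seed(65)
  for (k in 1:40) {
    ij <- sample(length(reps), 2)
    al <- align_local(reps[[ij[1]]], reps[[ij[2]]])
    cross <- c(cross, al$matches / min(nchar(reps[[ij[1]]]),
                                       nchar(reps[[ij[2]]])))
  }
  expect_gt(min(within), 0.9)
  expect_lt(max(cross), 0.35)
})

test_that("neighbor joining recovers additive trees exactly", {
  # hand-built additive 4-taxon matrix from tree ((A:2,B:3):1,(C:2,D:4):1)
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 5
  D["A", "C"] <- D["C", "A"] <- 6
  D["A", "D"] <- D["D", "A"] <- 8
  D["B", "C"] <- D["C", "B"] <- 7
  D["B", "D"] <- D["D", "B"] <- 9
  D["C", "D"] <- D["D", "C"] <- 6
  tree <- nj_tree(D)
  expect_s3_class(tree, "phylo")
  expect_equal(as.matrix(ape::cophenetic.phylo(tree))[rownames(D),
                                                      colnames(D)], D)
  # random additive trees up to 8 taxa: topology recovered exactly
  set.seed(66)
  for (k in 1:10) {
    n <- sample(4:8, 1)
    true_tree <- ape::rtree(n, rooted = FALSE)
    true_tree$edge.length <- true_tree$edge.length + 0.1
    Dk <- as.matrix(ape::cophenetic.phylo(true_tree))
    got <- nj_tree(Dk)
    expect_equal(as.numeric(ape::dist.topo(got, true_tree)), 0,
                 info = paste("replicate", k))
  }
})

test_that("three-taxon trees resolve with the closed-form star lengths", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- nj_tree(D)
  lens <- setNames(tree$edge.length,
                   tree$tip.label[tree$edge[, 2]])
  # d(x,v) = (d_xy + d_xz - d_yz)/2 = 1; same for y; z gets 3
  expect_equal(unname(lens[c("x", "y", "z")]), c(1, 1, 3))
  expect_error(nj_tree(D[1:2, 1:2]), "3 taxa")
  bad <- D
  bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
})

test_that("score-derived distances group isoforms within forms", {
  p <- default_panel()
  truth <- p$truth
  foc <- which(truth$species == "species_bact_01" &
                 truth$category == "flagellin")
  # three forms, two isoforms each, using unique region strings
  pick <- list()
  for (f in unique(truth$form_id[foc])[1:3]) {
    rows <- foc[truth$form_id[foc] == f]
    iso <- unique(truth$isoform_id[rows])
    if (length(iso) >= 2) {
      pick[[f]] <- vapply(iso[1:2], function(i) rows[truth$isoform_id[rows] == i][1],
                          integer(1))
    }
  }
  rows <- unlist(pick)
  regions <- setNames(
    substr(p$proteins$residues[match(truth$id[rows], p$proteins$id)],
           truth$region_start[rows] + 1, truth$region_end[rows]),
    truth$id[rows])
  d <- score_distance_matrix(regions)
  tree <- nj_tree(d)
  # each form's isoform pair must be monophyletic (sister tips)
  forms <- rep(names(pick), times = lengths(pick))
  for (f in unique(forms)) {
    tips <- truth$id[pick[[f]]]
    mrca <- ape::getMRCA(ape::root(tree,
                                   outgroup = setdiff(tree$tip.label,
                                                      tips)[1],
                                   resolve.root = TRUE), tips)
    desc <- ape::extract.clade(ape::root(tree,
                                         outgroup = setdiff(tree$tip.label,
                                                            tips)[1],
                                         resolve.root = TRUE),
                               mrca)$tip.label
    expect_setequal(desc, tips)
  }
})

test_that("negative branch lengths are clamped to zero", {
  D <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- nj_tree(D)
  expect_true(all(tree$edge.length >= 0))
})
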