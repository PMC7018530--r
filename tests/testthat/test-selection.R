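# Nei-Gojobori pathway counting, codon alignment and cumulative
# synonymous/nonsynonymous/indel curves.

test_that("single-step codon pairs classify directly", {
  expect_equal(unname(count_syn_nonsyn("TTT", "TTT")[1:2]), c(0, 0))
  expect_equal(unname(count_syn_nonsyn("TTT", "TTC")[1:2]), c(1, 0))
  expect_equal(unname(count_syn_nonsyn("TTT", "TTA")[1:2]), c(0, 1))
})

test_that("two-step pathways average over both orderings", {
  got <- count_syn_nonsyn("GTT", "AGT")
  expect_equal(unname(got[1:2]), unname(brute_syn_nonsyn("GTT", "AGT")))
  expect_equal(sum(got[1:2]), 2)
})

test_that("pathway counts match brute force over all sense-codon pairs", {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  for (a in sense) {
    for (b in sense) {
      got <- count_syn_nonsyn(a, b)
      want <- brute_syn_nonsyn(a, b)
      expect_equal(unname(got[1:2]), unname(want),
                   info = paste(a, b))
      # conservation: syn + nonsyn equals the Hamming distance
      hd <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      expect_equal(sum(got[1:2]), hd, info = paste(a, b))
    }
  }
})

test_that("ambiguous codons contribute nothing but are flagged", {
  got <- count_syn_nonsyn("TTN", "TTT")
  expect_equal(unname(got[1:2]), c(0, 0))
  expect_true(attr(got, "flagged"))
  expect_error(count_syn_nonsyn("TAA", "TTT"), "stop")
  expect_error(count_syn_nonsyn("TT", "TTT"), "length-3")
})

test_that("potential site counts sum to three per codon", {
  # TTT: only third-position T->C is synonymous among sense changes
  s <- syn_nonsyn_sites("TTT")
  expect_equal(unname(s["syn_sites"]), 1 / 3)
  expect_equal(sum(s), 3)
  # leucine CTG: third position fully synonymous, first position C->T too
  s2 <- syn_nonsyn_sites("CTG")
  expect_equal(unname(s2["syn_sites"]), 1 + 1 / 3)
})

test_that("identical coding sequences align without gaps and round-trip", {
  set.seed(81)
  prot <- random_aa_string(40)
  sets <- split(names(Biostrings::GENETIC_CODE),
                unname(Biostrings::GENETIC_CODE))
  cds <- vapply(1:3, function(i)
    paste(vapply(strsplit(prot, "")[[1]],
                 function(a) sample(sets[[a]], 1), character(1)),
          collapse = ""), character(1))
  rec <- flg_records(c("a", "b", "c"), cds, kind = "dna")
  aln <- codon_align(rec)
  expect_equal(ncol(aln$codons), 40)
  expect_false(any(aln$codons == "---"))
  back <- ungap_alignment(aln)
  expect_equal(unname(back[rec$id]), rec$residues)
})

test_that("a clean 3-bp deletion becomes a single one-codon gap column", {
  set.seed(82)
  prot <- random_aa_string(30)
  sets <- split(names(Biostrings::GENETIC_CODE),
                unname(Biostrings::GENETIC_CODE))
  cds_full <- paste(vapply(strsplit(prot, "")[[1]],
                           function(a) sample(sets[[a]], 1), character(1)),
                    collapse = "")
  # drop codon 12
  cds_del <- paste0(substr(cds_full, 1, 33), substr(cds_full, 37, 90))
  rec <- flg_records(c("full", "gap"), c(cds_full, cds_del), kind = "dna")
  aln <- codon_align(rec)
  expect_equal(ncol(aln$codons), 30)
  gaps <- which(aln$codons["gap", ] == "---")
  expect_length(gaps, 1)
  expect_equal(gaps, 12)
  expect_false(any(aln$codons["full", ] == "---"))
  back <- ungap_alignment(aln)
  expect_equal(unname(back[c("full", "gap")]), c(cds_full, cds_del))
})

test_that("untranslatable input names the offending record", {
  rec <- flg_records(c("ok", "bad"), c("ATGAAA", "ATGTAATTT"), kind = "dna")
  expect_error(codon_align(rec), "bad")
})

test_that("identical sequences give all-zero curves", {
  rec <- flg_records(c("a", "b"), rep("ATGAAATTTGGG", 2), kind = "dna")
  curves <- cumulative_curves(codon_align(rec), reference_id = "a")
  expect_equal(curves$cum_syn, rep(0, 4))
  expect_equal(curves$cum_nonsyn, rep(0, 4))
  expect_equal(curves$cum_indel, rep(0, 4))
})

test_that("one synonymous SNP at codon 10 steps the syn curve exactly there", {
  set.seed(83)
  prot <- random_aa_string(20)
  sets <- split(names(Biostrings::GENETIC_CODE),
                unname(Biostrings::GENETIC_CODE))
  codons <- vapply(strsplit(prot, "")[[1]],
                   function(a) sample(sets[[a]], 1), character(1))
  # force codon 10 to have a synonymous alternative
  codons[10] <- "TTT"
  alt <- codons
  alt[10] <- "TTC"
  rec <- flg_records(c("ref", "alt"),
                     c(paste(codons, collapse = ""),
                       paste(alt, collapse = "")), kind = "dna")
  curves <- cumulative_curves(codon_align(rec), reference_id = "ref")
  expect_equal(curves$cum_syn, c(rep(0, 9), rep(1, 11)))
  expect_equal(curves$cum_nonsyn, rep(0, 20))
  expect_equal(curves$cum_indel, rep(0, 20))
})

test_that("curves are monotone and invariant to row order", {
  p <- default_panel()
  truth <- p$truth
  # one HVR form's coding sequences
  top_form <- names(sort(table(truth$form_id), decreasing = TRUE))[1]
  ids <- unique(truth$id[!is.na(truth$form_id) & truth$form_id == top_form])
  cds <- p$cds[p$cds$id %in% ids, ]
  cds <- cds[!duplicated(cds$residues), ]
  aln <- codon_align(cds)
  curves <- cumulative_curves(aln, reference_id = aln$ids[1])
  expect_true(all(diff(curves$cum_syn) >= 0))
  expect_true(all(diff(curves$cum_nonsyn) >= 0))
  expect_true(all(diff(curves$cum_indel) >= 0))
  # permuting the non-reference rows changes nothing
  perm <- aln
  ord <- c(1, sample(2:length(aln$ids)))
  perm$ids <- aln$ids[ord]
  perm$codons <- aln$codons[ord, , drop = FALSE]
  curves2 <- cumulative_curves(perm, reference_id = aln$ids[1])
  expect_equal(curves2$cum_syn, curves$cum_syn)
  expect_equal(curves2$cum_nonsyn, curves$cum_nonsyn)
  # totals equal the sum of per-position increments
  expect_equal(curves$cum_syn[nrow(curves)], sum(diff(c(0, curves$cum_syn))))
})

test_that("random reference choice is reproducible from the seed", {
  p <- default_panel()
  truth <- p$truth
  top_form <- names(sort(table(truth$form_id), decreasing = TRUE))[1]
  ids <- unique(truth$id[!is.na(truth$form_id) & truth$form_id == top_form])
  cds <- p$cds[p$cds$id %in% ids, ][1:3, ]
  aln <- codon_align(cds)
  c1 <- cumulative_curves(aln, seed = 7)
  c2 <- cumulative_curves(aln, seed = 7)
  expect_equal(attr(c1, "reference_id"), attr(c2, "reference_id"))
  expect_equal(c1$cum_syn, c2$cum_syn)
})

test_that("synonymous changes concentrate in the conserved gene regions", {
  # a single-form, many-isoform panel: the within-form gene panel whose
  # conserved termini carry silent variation while the variable region
  # carries the replacement changes
  p <- generate_panel(panel_config(rng_seed = 9, forms_per_species = 1,
                                   isoforms_per_form = 20,
                                   n_decoys_flgl = 0, n_archaeal = 0,
                                   multiplicity_mean = 1))
  truth <- p$truth
  rows <- which(truth$category == "flagellin")
  cds <- p$cds[p$cds$id %in% truth$id[rows], ]
  cds <- cds[!duplicated(cds$residues), ]
  aln <- codon_align(cds)
  curves <- cumulative_curves(aln, reference_id = aln$ids[1])
  v_start <- truth$region_start[rows[1]]
  v_end <- truth$region_end[rows[1]]
  n <- nrow(curves)
  # per-region synonymous rates per codon
  syn_rate_cons <- (curves$cum_syn[v_start] +
                      curves$cum_syn[n] - curves$cum_syn[v_end]) /
    (v_start + n - v_end)
  syn_rate_var <- (curves$cum_syn[v_end] - curves$cum_syn[v_start]) /
    (v_end - v_start)
  nonsyn_rate_cons <- (curves$cum_nonsyn[v_start] +
                         curves$cum_nonsyn[n] - curves$cum_nonsyn[v_end]) /
    (v_start + n - v_end)
  nonsyn_rate_var <- (curves$cum_nonsyn[v_end] -
                        curves$cum_nonsyn[v_start]) / (v_end - v_start)
  expect_gt(syn_rate_cons, syn_rate_var)
  expect_gt(nonsyn_rate_var, nonsyn_rate_cons)
})
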