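# Seeded synthetic flagellin panels with ground truth. The generator emulates
# the dual-level structure the analysis assumes: conserved N/C-terminal
# domains with housekeeping-level divergence, a middle region partitioned
# into mutually non-alignable HVR forms each containing SNP-level isoforms,
# FlgL-like decoys, archaeal single-domain sequences, and duplicate
# observations of the same unique protein.

#' Panel generator configuration
#'
#' Defaults define the reference study conditions: one focal bacterial
#' species carrying 26 HVR forms with 3 isoforms each (the form count
#' mirrors the S. enterica H-antigen set structure), conserved domains of
#' 190 aa (N) and 100 aa (C), per-sequence conserved substitution rate 0.01,
#' within-form SNP rate 0.02, ten FlgL decoys (half single-domain, half
#' two-domain FlgL mimics), twelve archaeal sequences in four forms, and an
#' observation multiplicity of 1 + Geometric(mean 1) so roughly half the
#' observations are duplicates.
#'
#' @param rng_seed integer seed; the panel is fully determined by it.
#' @param n_phyla number of bacterial phyla (one species each).
#' @param forms_per_species HVR forms per bacterial species.
#' @param isoforms_per_form isoforms drawn per form.
#' @param conserved5_len,conserved3_len conserved domain lengths (aa).
#' @param morphotype_ranges named list of variable-region length ranges (aa)
#'   per morphotype class; forms cycle through the classes.
#' @param eps_c per-residue substitution rate of conserved domains per
#'   sequence; kept below `eps_v` because the terminal domains are under
#'   purifying selection while within-form variable-region changes are
#'   closer to neutral.
#' @param eps_v per-residue SNP rate within a form (isoform-level variation).
#' @param species_divergence per-residue divergence of each species'
#'   conserved-domain ancestors from the shared superkingdom root; the
#'   default 0.40 keeps species-level clusters distinct while leaving
#'   cross-cluster similarity well above the random-pair BSR floor.
#' @param n_decoys_flgl number of FlgL-like decoys.
#' @param n_archaeal number of archaeal sequences.
#' @param archaeal_forms number of archaeal variable-tail forms.
#' @param arch_domain_len archaeal conserved domain length (aa).
#' @param multiplicity_mean mean observation count per unique protein (>= 1).
#' @param syn_rate_conserved,syn_rate_variable per-codon synonymous
#'   resampling rates in the conserved and variable gene regions (the
#'   conserved regions carry more silent variation, emulating
#'   recombination-driven accumulation there).
#' @return A `flg_panel_config` list.
#' @export
panel_config <- function(rng_seed = 1L,
                         n_phyla = 1L,
                         forms_per_species = 26L,
                         isoforms_per_form = 3L,
                         conserved5_len = 190L,
                         conserved3_len = 100L,
                         morphotype_ranges = list(A = c(120L, 150L),
                                                  B = c(150L, 185L),
                                                  C = c(185L, 220L)),
                         eps_c = 0.01,
                         eps_v = 0.02,
                         species_divergence = 0.40,
                         n_decoys_flgl = 10L,
                         n_archaeal = 12L,
                         archaeal_forms = 4L,
                         arch_domain_len = 150L,
                         multiplicity_mean = 2,
                         syn_rate_conserved = 0.06,
                         syn_rate_variable = 0.01) {
  cfg <- list(rng_seed = as.integer(rng_seed), n_phyla = as.integer(n_phyla),
              forms_per_species = as.integer(forms_per_species),
              isoforms_per_form = as.integer(isoforms_per_form),
              conserved5_len = as.integer(conserved5_len),
              conserved3_len = as.integer(conserved3_len),
              morphotype_ranges = morphotype_ranges,
              eps_c = eps_c, eps_v = eps_v,
              species_divergence = species_divergence,
              n_decoys_flgl = as.integer(n_decoys_flgl),
              n_archaeal = as.integer(n_archaeal),
              archaeal_forms = as.integer(archaeal_forms),
              arch_domain_len = as.integer(arch_domain_len),
              multiplicity_mean = multiplicity_mean,
              syn_rate_conserved = syn_rate_conserved,
              syn_rate_variable = syn_rate_variable)
  stopifnot(cfg$forms_per_species >= 1, cfg$isoforms_per_form >= 1,
            cfg$conserved5_len > 0, cfg$conserved3_len > 0,
            cfg$eps_v >= 0, cfg$eps_c >= 0, cfg$eps_v < 0.35,
            cfg$multiplicity_mean >= 1)
  class(cfg) <- "flg_panel_config"
  cfg
}

# hierarchical sub-seeds: each generation stage reseeds from the master seed
# and a stage index, so stages stay reproducible independently
sub_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483647)
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  aa <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(aa)) < rate)
  for (i in hit) aa[i] <- sample(setdiff(AA20, aa[i]), 1)
  paste(aa, collapse = "")
}

# codons per amino acid under the standard code (sense codons only)
codons_for_aa <- function() {
  code <- Biostrings::GENETIC_CODE
  split(names(code), unname(code))
}

# fixed codon template for an amino-acid sequence
codon_template <- function(protein, codon_sets) {
  aa <- strsplit(protein, "")[[1]]
  vapply(aa, function(a) sample(codon_sets[[a]], 1), character(1),
         USE.NAMES = FALSE)
}

# CDS for a realized protein: reuse the ancestor's codon template where the
# residue is unchanged, pick a random codon for substituted residues, then
# resample synonymous codons at the region's silent rate
cds_from_template <- function(protein, ancestor, template, syn_rate,
                              codon_sets) {
  aa <- strsplit(protein, "")[[1]]
  anc <- strsplit(ancestor, "")[[1]]
  cods <- template
  changed <- which(aa != anc)
  for (i in changed) cods[i] <- sample(codon_sets[[aa[i]]], 1)
  silent <- which(runif(length(aa)) < syn_rate)
  for (i in silent) cods[i] <- sample(codon_sets[[aa[i]]], 1)
  paste(cods, collapse = "")
}

#' Generate a synthetic flagellin panel with ground truth
#'
#' See [panel_config()] for the structure generated. Variable-region form
#' ancestors are drawn independently at random and certified mutually
#' non-alignable at generation time (redrawn with an incremented sub-seed on
#' failure, with a message). Output is fully determined by the seed.
#'
#' @param config a [panel_config()] object.
#' @param scheme an [scoring_scheme()] used for the non-alignability
#'   certificate.
#' @return A list of class `flg_panel`: `proteins` and `cds`
#'   ([flg_records]), `taxonomy` (data frame), `truth` (data frame with one
#'   row per record: `id`, `phylum`, `species`, `category`, `form_id`,
#'   `isoform_id`, `cluster_family`, `region_start`, `region_end`),
#'   `models` (curation [domain_model()] list) and `config`.
#' @export
generate_panel <- function(config = panel_config(),
                           scheme = scoring_scheme()) {
  cfg <- config
  codon_sets <- codons_for_aa()

  # stage 1: conserved-domain roots and species ancestors
  set.seed(sub_seed(cfg$rng_seed, 1))
  bact_n_root <- random_protein(cfg$conserved5_len)
  bact_c_root <- random_protein(cfg$conserved3_len)
  arch_root <- random_protein(cfg$arch_domain_len)

  n_species <- cfg$n_phyla
  species <- sprintf("species_bact_%02d", seq_len(n_species))
  phyla <- sprintf("phylum_syn_%02d", seq_len(n_species))
  anc_n <- character(n_species)
  anc_c <- character(n_species)
  for (s in seq_len(n_species)) {
    anc_n[s] <- mutate_protein(bact_n_root, cfg$species_divergence)
    anc_c[s] <- mutate_protein(bact_c_root, cfg$species_divergence)
  }
  # FlgL paralog of the focal species: shares the N-domain fold but carries
  # a distinct discriminant segment at the domain's distal end
  disc_len <- min(30L, cfg$conserved5_len %/% 3)
  disc_start <- cfg$conserved5_len - disc_len + 1L
  flgl_n_root <- paste0(substr(anc_n[1], 1, disc_start - 1),
                        random_protein(disc_len))

  # stage 2: variable-region form ancestors, certified non-alignable
  set.seed(sub_seed(cfg$rng_seed, 2))
  classes <- names(cfg$morphotype_ranges)
  all_anc <- character(0)
  var_anc <- vector("list", n_species)
  for (s in seq_len(n_species)) {
    var_anc[[s]] <- character(cfg$forms_per_species)
    for (f in seq_len(cfg$forms_per_species)) {
      rng <- cfg$morphotype_ranges[[classes[(f - 1) %% length(classes) + 1]]]
      len <- sample(seq(rng[1], rng[2]), 1)
      tries <- 0
      repeat {
        cand <- random_protein(len)
        clash <- any(vapply(all_anc, function(prev)
          alignable(cand, prev, scheme = scheme), logical(1)))
        if (!clash) break
        tries <- tries + 1
        message("redrawing non-alignable form ancestor (attempt ",
                tries + 1, ")")
        set.seed(sub_seed(cfg$rng_seed, 200 + length(all_anc) * 50 + tries))
        if (tries > 25) stop("could not draw a non-alignable form ancestor")
      }
      var_anc[[s]][f] <- cand
      all_anc <- c(all_anc, cand)
    }
  }
  arch_var_anc <- character(cfg$archaeal_forms)
  for (f in seq_len(cfg$archaeal_forms)) {
    arch_var_anc[f] <- random_protein(80L)
  }

  # stage 3: isoform realizations (proteins)
  set.seed(sub_seed(cfg$rng_seed, 3))
  uniq <- list()  # per unique protein: residues, truth fields, cds
  add_unique <- function(entry) {
    key <- entry$residues
    if (is.null(uniq[[key]])) uniq[[key]] <<- entry
    invisible(NULL)
  }
  for (s in seq_len(n_species)) {
    n_tmpl <- codon_template(anc_n[s], codon_sets)
    c_tmpl <- codon_template(anc_c[s], codon_sets)
    for (f in seq_len(cfg$forms_per_species)) {
      v_tmpl <- codon_template(var_anc[[s]][f], codon_sets)
      for (k in seq_len(cfg$isoforms_per_form)) {
        n_dom <- mutate_protein(anc_n[s], cfg$eps_c)
        v_dom <- mutate_protein(var_anc[[s]][f], cfg$eps_v)
        c_dom <- mutate_protein(anc_c[s], cfg$eps_c)
        prot <- paste0(n_dom, v_dom, c_dom)
        cds <- paste0(
          cds_from_template(n_dom, anc_n[s], n_tmpl,
                            cfg$syn_rate_conserved, codon_sets),
          cds_from_template(v_dom, var_anc[[s]][f], v_tmpl,
                            cfg$syn_rate_variable, codon_sets),
          cds_from_template(c_dom, anc_c[s], c_tmpl,
                            cfg$syn_rate_conserved, codon_sets))
        add_unique(list(residues = prot, cds = cds,
                        phylum = phyla[s], species = species[s],
                        superkingdom = "Bacteria", category = "flagellin",
                        form_id = sprintf("%s_F%02d", species[s], f),
                        cluster_family = paste0("fam_", species[s]),
                        region_start = cfg$conserved5_len,
                        region_end = cfg$conserved5_len + nchar(v_dom)))
      }
    }
  }

  # stage 4: FlgL decoys (half single-domain, half two-domain mimics)
  set.seed(sub_seed(cfg$rng_seed, 4))
  if (cfg$n_decoys_flgl > 0) {
    for (d in seq_len(cfg$n_decoys_flgl)) {
      n_dom <- mutate_protein(flgl_n_root, cfg$eps_c)
      if (d %% 2 == 1) {
        body <- random_protein(150L)  # shuffled remainder, no C domain
        prot <- paste0(n_dom, body)
      } else {
        c_dom <- mutate_protein(anc_c[1], cfg$eps_c)
        prot <- paste0(n_dom, random_protein(140L), c_dom)
      }
      add_unique(list(residues = prot,
                      cds = paste(codon_template(prot, codon_sets),
                                  collapse = ""),
                      phylum = phyla[1], species = "species_flgl_01",
                      superkingdom = "Bacteria", category = "flgl_decoy",
                      form_id = NA_character_,
                      cluster_family = NA_character_,
                      region_start = NA_integer_, region_end = NA_integer_))
    }
  }

  # stage 5: archaeal single-domain sequences
  set.seed(sub_seed(cfg$rng_seed, 5))
  if (cfg$n_archaeal > 0) {
    for (a in seq_len(cfg$n_archaeal)) {
      f <- (a - 1) %% cfg$archaeal_forms + 1
      prot <- paste0(mutate_protein(arch_root, cfg$eps_c),
                     mutate_protein(arch_var_anc[f], cfg$eps_v))
      add_unique(list(residues = prot,
                      cds = paste(codon_template(prot, codon_sets),
                                  collapse = ""),
                      phylum = "phylum_arch_syn_01",
                      species = "species_arch_01",
                      superkingdom = "Archaea", category = "archaeal",
                      form_id = sprintf("species_arch_01_F%02d", f),
                      # the shared archaeal domain covers too little of the
                      # protein to merge different tail forms at default
                      # coverage, so each form is its own cluster family
                      cluster_family = sprintf("fam_species_arch_01_F%02d", f),
                      region_start = cfg$arch_domain_len,
                      region_end = cfg$arch_domain_len + 80L))
    }
  }

  # stage 6: observation multiplicity and record emission
  set.seed(sub_seed(cfg$rng_seed, 6))
  entries <- uniq[sort(names(uniq), method = "radix")]
  p_extra <- 1 / cfg$multiplicity_mean
  mult <- 1L + rgeom(length(entries), prob = p_extra)
  total <- sum(mult)
  width <- max(4L, nchar(total))
  rows <- vector("list", total)
  idx <- 0L
  for (e in seq_along(entries)) {
    for (m in seq_len(mult[e])) {
      idx <- idx + 1L
      rows[[idx]] <- c(entries[[e]],
                       list(id = sprintf("obs_%0*d", width, idx)))
    }
  }
  ids <- vapply(rows, `[[`, character(1), "id")
  proteins <- flg_records(ids,
                          vapply(rows, `[[`, character(1), "residues"),
                          kind = "protein",
                          description = vapply(rows, `[[`, character(1),
                                               "category"))
  cds <- flg_records(ids, vapply(rows, `[[`, character(1), "cds"),
                     kind = "dna",
                     description = vapply(rows, `[[`, character(1),
                                          "category"))
  truth <- data.frame(
    id = ids,
    superkingdom = vapply(rows, `[[`, character(1), "superkingdom"),
    phylum = vapply(rows, `[[`, character(1), "phylum"),
    species = vapply(rows, `[[`, character(1), "species"),
    category = vapply(rows, `[[`, character(1), "category"),
    form_id = vapply(rows, `[[`, character(1), "form_id"),
    cluster_family = vapply(rows, `[[`, character(1), "cluster_family"),
    region_start = vapply(rows, function(r)
      as.integer(r$region_start), integer(1)),
    region_end = vapply(rows, function(r)
      as.integer(r$region_end), integer(1)),
    stringsAsFactors = FALSE)
  # truth isoform ids: distinct realized region strings within each form
  truth$isoform_id <- NA_character_
  for (fid in unique(truth$form_id[!is.na(truth$form_id)])) {
    sel <- which(truth$form_id == fid)
    regions <- substr(proteins$residues[sel], truth$region_start[sel] + 1,
                      truth$region_end[sel])
    iso_strs <- sort(unique(regions), method = "radix")
    truth$isoform_id[sel] <- paste0(fid, ".u", match(regions, iso_strs))
  }

  taxonomy <- data.frame(
    id = ids,
    superkingdom = truth$superkingdom,
    phylum = truth$phylum,
    class = "Unknown", order = "Unknown", family = "Unknown",
    genus = "Unknown", species = truth$species,
    stringsAsFactors = FALSE)

  # stage 7: curation models built from the panel's own conserved domains
  set.seed(sub_seed(cfg$rng_seed, 7))
  flag_seqs <- truth$category == "flagellin"
  n_dom_seqs <- unique(substr(proteins$residues[flag_seqs], 1,
                              cfg$conserved5_len))
  c_dom_seqs <- unique(substring(proteins$residues[flag_seqs],
                                 nchar(proteins$residues[flag_seqs]) -
                                   cfg$conserved3_len + 1))
  arch_seqs <- truth$category == "archaeal"
  flgl_seqs <- truth$category == "flgl_decoy"
  models <- list(
    domain_model("FLAG_N", pssm_from_sequences(head(n_dom_seqs, 20)),
                 expected_terminus = "N"),
    domain_model("FLAG_C", pssm_from_sequences(head(c_dom_seqs, 20)),
                 expected_terminus = "C"))
  if (any(arch_seqs)) {
    a_dom <- unique(substr(proteins$residues[arch_seqs], 1,
                           cfg$arch_domain_len))
    models <- c(models, list(
      domain_model("ARCH_FLAG", pssm_from_sequences(head(a_dom, 20)),
                   expected_terminus = "N")))
  }
  if (any(flgl_seqs)) {
    f_dom <- unique(substr(proteins$residues[flgl_seqs], 1,
                           cfg$conserved5_len))
    models <- c(models, list(
      domain_model("FLGL_DISCRIM", pssm_from_sequences(head(f_dom, 20)),
                   expected_terminus = "N")))
  }

  out <- list(proteins = proteins, cds = cds, taxonomy = taxonomy,
              truth = truth, models = models, config = cfg)
  class(out) <- "flg_panel"
  out
}

#' @export
print.flg_panel <- function(x, ...) {
  cat("synthetic panel:", nrow(x$proteins), "observations,",
      length(unique(x$proteins$residues)), "unique proteins,",
      x$config$n_phyla, "bacterial phyla\n")
  invisible(x)
}

#' Generate a per-phylum counts table with a known log-log relationship
#'
#' Total counts are log-uniform over `10^log_total_range`; unique counts
#' follow `log10 n_unique = intercept + slope * log10 n_total + N(0, sd)`,
#' rounded and clipped to `[1, n_total]`.
#'
#' @param n_phyla number of rows.
#' @param slope,intercept generating line (slope in `(0, 1]`).
#' @param noise_sd standard deviation of the log10 noise.
#' @param rng_seed integer seed.
#' @param log_total_range range of `log10 n_total`.
#' @return An [taxon_diversity()] data frame with attribute `truth` holding
#'   the generating parameters.
#' @export
generate_counts_table <- function(n_phyla = 40L, slope = 0.93,
                                  intercept = -0.15, noise_sd = 0.05,
                                  rng_seed = 1L,
                                  log_total_range = c(1, 5)) {
  stopifnot(slope > 0, slope <= 1, noise_sd >= 0, n_phyla >= 3)
  set.seed(as.integer(rng_seed))
  log_total <- runif(n_phyla, log_total_range[1], log_total_range[2])
  n_total <- pmax(2, round(10^log_total))
  log_unique <- intercept + slope * log10(n_total) +
    rnorm(n_phyla, 0, noise_sd)
  n_unique <- pmin(n_total, pmax(1, round(10^log_unique)))
  out <- taxon_diversity(sprintf("phylum_syn_%02d", seq_len(n_phyla)),
                         n_total, n_unique)
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             noise_sd = noise_sd)
  out
}
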