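# End-to-end orchestration: curate -> deduplicate -> cluster -> minimum
# spanning forest -> HVR typing -> diversity -> selection, with stage
# toggles, per-stage outputs and a machine-readable run manifest that
# mirrors the multi-version database-construction funnel.

#' Pipeline configuration
#'
#' @param proteins_fasta path to the candidate protein FASTA (required).
#' @param cds_fasta optional path to the matching coding-sequence FASTA
#'   (enables the selection stage).
#' @param taxonomy_tsv optional taxonomy side table (see [read_taxonomy()]).
#' @param counts_tsv optional per-taxon counts table for the diversity stage;
#'   when absent, per-phylum counts are derived from the curated records'
#'   taxonomy (needs >= 3 phyla).
#' @param out_dir output directory (created if missing).
#' @param pool_fasta optional fishing pool FASTA.
#' @param exclusion_file optional file with one record id per line.
#' @param pssm_dir optional directory with `<DOMAIN_ID>.tsv` PSSM files plus
#'   `<DOMAIN_ID>.meta.tsv` (columns `min_score`, `expected_terminus`); when
#'   absent, `models` must be supplied to [run_pipeline()].
#' @param stages character vector of stages to run, in pipeline order.
#' @param min_bsr fishing threshold.
#' @param min_identity,min_coverage greedy clustering thresholds.
#' @param hvr_min_identity,hvr_min_coverage HVR alignability thresholds.
#' @param link_threshold minimum spanning forest link threshold.
#' @param hvr_species species whose records are HVR-typed; default the
#'   species with most curated records.
#' @param hvr_mode `"protein"` or `"dna"` region partition for HVR typing.
#' @param reference_id reference for the selection curves (`NULL` = random).
#' @param seed integer seed for seed-controlled choices.
#' @return A `flg_pipeline_config` list.
#' @export
pipeline_config <- function(proteins_fasta,
                            cds_fasta = NULL,
                            taxonomy_tsv = NULL,
                            counts_tsv = NULL,
                            out_dir = tempfile("flagdiv_run_"),
                            pool_fasta = NULL,
                            exclusion_file = NULL,
                            pssm_dir = NULL,
                            stages = c("curate", "dedup", "cluster",
                                       "mstree", "hvr", "diversity",
                                       "selection"),
                            min_bsr = 0.4,
                            min_identity = 0.3,
                            min_coverage = 0.8,
                            hvr_min_identity = 0.35,
                            hvr_min_coverage = 0.5,
                            link_threshold = 0.1,
                            hvr_species = NULL,
                            hvr_mode = c("protein", "dna"),
                            reference_id = NULL,
                            seed = 1L) {
  cfg <- list(proteins_fasta = proteins_fasta, cds_fasta = cds_fasta,
              taxonomy_tsv = taxonomy_tsv, counts_tsv = counts_tsv,
              out_dir = out_dir, pool_fasta = pool_fasta,
              exclusion_file = exclusion_file, pssm_dir = pssm_dir,
              stages = match.arg(stages, several.ok = TRUE),
              min_bsr = min_bsr, min_identity = min_identity,
              min_coverage = min_coverage,
              hvr_min_identity = hvr_min_identity,
              hvr_min_coverage = hvr_min_coverage,
              link_threshold = link_threshold,
              hvr_species = hvr_species,
              hvr_mode = match.arg(hvr_mode),
              reference_id = reference_id, seed = as.integer(seed))
  class(cfg) <- "flg_pipeline_config"
  cfg
}

read_domain_models <- function(pssm_dir) {
  files <- list.files(pssm_dir, pattern = "^[A-Z_]+\\.tsv$",
                      full.names = TRUE)
  files <- files[!grepl("meta\\.tsv$", files)]
  lapply(files, function(f) {
    did <- sub("\\.tsv$", "", basename(f))
    meta_path <- file.path(pssm_dir, paste0(did, ".meta.tsv"))
    pssm <- read_pssm(f)
    if (file.exists(meta_path)) {
      meta <- read.delim(meta_path, stringsAsFactors = FALSE)
      domain_model(did, pssm, min_score = meta$min_score[1],
                   expected_terminus = meta$expected_terminus[1])
    } else {
      domain_model(did, pssm)
    }
  })
}

pipeline_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in order, writes per-stage outputs under the
#' configured output directory, and returns (and writes) a run manifest with
#' the record counts entering and leaving every stage. A stage failure
#' aborts with the stage name; outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()] object.
#' @param models optional list of [domain_model()] objects, overriding
#'   `config$pssm_dir`.
#' @return Invisibly, a list with `manifest` (also written as JSON) and the
#'   per-stage result objects.
#' @export
run_pipeline <- function(config, models = NULL) {
  cfg <- config
  scheme <- scoring_scheme()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("flagdiv")),
                   seed = cfg$seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   parameters = cfg[c("min_bsr", "min_identity",
                                      "min_coverage", "hvr_min_identity",
                                      "hvr_min_coverage", "link_threshold",
                                      "hvr_mode")],
                   stages = list())
  results <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  records <- read_fasta(cfg$proteins_fasta, kind = "protein")
  if (!nrow(records)) stop("pipeline stage 'curate' failed: empty input",
                           call. = FALSE)
  taxonomy <- if (!is.null(cfg$taxonomy_tsv)) read_taxonomy(cfg$taxonomy_tsv)
  if (!is.null(taxonomy)) records <- attach_taxonomy(records, taxonomy)
  manifest$stages$input <- list(n_records = nrow(records))

  curated <- records
  if ("curate" %in% cfg$stages) {
    run_stage("curate", function() {
      if (is.null(models)) {
        if (is.null(cfg$pssm_dir))
          stop("curation needs domain models (pssm_dir or models argument)")
        models <<- read_domain_models(cfg$pssm_dir)
      }
      pool <- if (!is.null(cfg$pool_fasta))
        read_fasta(cfg$pool_fasta, kind = "protein")
      excl <- if (!is.null(cfg$exclusion_file))
        readLines(cfg$exclusion_file, warn = FALSE) else character()
      report <- curate(records, models, pool = pool, exclusion_ids = excl,
                       min_bsr = cfg$min_bsr, scheme = scheme)
      write.table(report$accepted,
                  file.path(cfg$out_dir, "curation_accepted.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(report$rejected,
                  file.path(cfg$out_dir, "curation_rejected.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      results$curation <<- report
      curated <<- records[records$id %in% report$accepted$id, , drop = FALSE]
      if (length(report$fished)) {
        fished_recs <- pool[pool$id %in% report$fished, , drop = FALSE]
        if (!is.null(taxonomy))
          fished_recs <- attach_taxonomy(fished_recs, taxonomy)
        curated <<- rbind(curated, fished_recs)
      }
      manifest$stages$curate <<- list(
        n_in = nrow(records),
        n_accepted = nrow(report$accepted),
        n_rejected = nrow(report$rejected),
        n_fished = length(report$fished),
        rejected_by_stage = as.list(table(report$rejected$stage)))
      pipeline_log("curate", nrow(report$accepted), " accepted of ",
                   nrow(records))
    })
  }

  uniques <- NULL
  if ("dedup" %in% cfg$stages) {
    run_stage("dedup", function() {
      uniques <<- deduplicate(curated)
      manifest$stages$dedup <<- list(n_total = uniques$n_total,
                                     n_unique = uniques$n_unique)
      pipeline_log("dedup", uniques$n_unique, " unique of ",
                   uniques$n_total)
    })
  }

  clusters <- NULL
  if ("cluster" %in% cfg$stages) {
    run_stage("cluster", function() {
      if (is.null(uniques)) uniques <<- deduplicate(curated)
      clusters <<- greedy_cluster(uniques, min_identity = cfg$min_identity,
                                  min_coverage = cfg$min_coverage,
                                  scheme = scheme)
      write_cluster_table(clusters,
                          file.path(cfg$out_dir, "clusters.tsv"),
                          taxonomy = taxonomy)
      comp <- if (!is.null(taxonomy))
        summarize_composition(clusters, taxonomy)
      results$composition <<- comp
      manifest$stages$cluster <<- list(
        n_unique = uniques$n_unique, n_clusters = length(clusters),
        multi_phylum_percent = if (!is.null(comp))
          comp$multi_phylum_percent)
      pipeline_log("cluster", length(clusters), " clusters")
    })
  }

  graph <- NULL
  if ("mstree" %in% cfg$stages && !is.null(clusters)) {
    run_stage("mstree", function() {
      graph <<- build_cluster_graph(clusters, scheme = scheme)
      graph <<- minimum_spanning_forest(graph,
                                        link_threshold = cfg$link_threshold)
      write_cluster_graph(graph,
                          edge_tsv = file.path(cfg$out_dir, "edges.tsv"),
                          graphml = file.path(cfg$out_dir, "mstree.graphml"))
      manifest$stages$mstree <<- list(
        n_components = max(graph$components),
        n_mst_edges = nrow(graph$mst_edges))
      pipeline_log("mstree", max(graph$components), " supercluster(s)")
    })
  }

  hvr <- NULL
  if ("hvr" %in% cfg$stages) {
    run_stage("hvr", function() {
      recs <- curated
      if (!is.null(taxonomy) && !is.null(recs$species)) {
        target <- cfg$hvr_species
        if (is.null(target)) {
          tab <- table(recs$species[recs$species != "Unknown"])
          if (!length(tab)) stop("no species labels for HVR typing")
          target <- names(tab)[which.max(tab)]
        }
        recs <- recs[recs$species == target, , drop = FALSE]
        manifest$stages$hvr_species <<- target
      }
      min_len <- if (cfg$hvr_mode == "protein") 290 else 870
      recs <- recs[nchar(recs$residues) > min_len, , drop = FALSE]
      if (!nrow(recs)) stop("no sequences long enough for HVR typing")
      regions <- vapply(seq_len(nrow(recs)), function(i)
        partition_gene(recs$residues[i], kind = cfg$hvr_mode)$variable,
        character(1))
      names(regions) <- recs$id
      hvr <<- assign_hvr_forms(regions,
                               min_identity = cfg$hvr_min_identity,
                               min_coverage = cfg$hvr_min_coverage,
                               scheme = scheme)
      write_hvr_table(hvr, file.path(cfg$out_dir, "hvr_forms.tsv"))
      # NJ tree over distinct regions when enough forms are present
      iso_seqs <- unlist(lapply(hvr$forms, function(f)
        setNames(vapply(f$isoforms, `[[`, character(1), "sequence"),
                 vapply(f$isoforms, `[[`, character(1), "isoform_id"))))
      if (length(iso_seqs) >= 3) {
        d <- score_distance_matrix(iso_seqs, scheme)
        write_newick(nj_tree(d), file.path(cfg$out_dir, "hvr_nj.nwk"))
      }
      manifest$stages$hvr <<- list(
        n_regions = length(regions),
        n_forms = length(hvr$forms),
        n_isoforms = sum(vapply(hvr$forms, function(f)
          length(f$isoforms), integer(1))))
      pipeline_log("hvr", length(hvr$forms), " forms")
    })
  }

  diversity <- NULL
  if ("diversity" %in% cfg$stages) {
    run_stage("diversity", function() {
      pts <- if (!is.null(cfg$counts_tsv)) {
        read_counts_table(cfg$counts_tsv)
      } else if (!is.null(curated$phylum)) {
        phylum_counts(curated)
      }
      if (is.null(pts) || nrow(pts) < 3) {
        manifest$stages$diversity <<- list(status = "skipped",
                                           reason = "fewer than 3 taxa")
        return()
      }
      fit <- fit_loglog(pts)
      annotated <- classify_diversity(pts, fit)
      write.table(annotated, file.path(cfg$out_dir, "diversity.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(slope = fit$slope, intercept = fit$intercept,
             r_squared = fit$r_squared, p_value = fit$p_value),
        file.path(cfg$out_dir, "diversity_fit.json"),
        auto_unbox = TRUE, digits = NA)
      results$diversity <<- list(fit = fit, table = annotated)
      manifest$stages$diversity <<- list(n_taxa = nrow(pts),
                                         r_squared = fit$r_squared,
                                         slope = fit$slope)
      pipeline_log("diversity", sprintf("R^2 = %.4f", fit$r_squared))
    })
  }

  if ("selection" %in% cfg$stages && !is.null(cfg$cds_fasta)) {
    run_stage("selection", function() {
      cds <- read_fasta(cfg$cds_fasta, kind = "dna")
      cds <- cds[cds$id %in% curated$id, , drop = FALSE]
      if (!is.null(hvr)) {
        # largest HVR form: the within-form panel whose silent/replacement
        # profile the curves describe
        top <- hvr$assignment$form_id[1]
        counts <- table(hvr$assignment$form_id)
        top <- names(counts)[which.max(counts)]
        ids <- hvr$assignment$id[hvr$assignment$form_id == top]
        cds <- cds[cds$id %in% ids, , drop = FALSE]
      }
      if (nrow(cds) < 2) {
        manifest$stages$selection <<- list(status = "skipped",
                                           reason = "fewer than 2 sequences")
        return()
      }
      aln <- codon_align(cds, scheme = scheme)
      curves <- cumulative_curves(aln, reference_id = cfg$reference_id,
                                  seed = cfg$seed)
      write_curves(curves, file.path(cfg$out_dir, "selection_curves.tsv"))
      results$selection <<- curves
      manifest$stages$selection <<- list(
        n_sequences = nrow(cds),
        reference_id = attr(curves, "reference_id"),
        final_cum_syn = curves$cum_syn[nrow(curves)],
        final_cum_nonsyn = curves$cum_nonsyn[nrow(curves)])
      pipeline_log("selection", "reference ", attr(curves, "reference_id"))
    })
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results,
                 clusters = clusters, graph = graph, hvr = hvr,
                 uniques = uniques))
}
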