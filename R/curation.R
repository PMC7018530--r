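# Database-construction funnel: conserved-domain PSSM filtering, homolog
# fishing by BSR, FlgL-like removal, and exclusion lists. The domain scanner
# is a pluggable sliding-window PSSM scorer; user-supplied profiles can stand
# in for Pfam/PANTHER models on real data.

DOMAIN_IDS <- c("FLAG_N", "FLAG_C", "ARCH_FLAG", "FLGL_DISCRIM")

#' Build a position-specific scoring matrix from example sequences
#'
#' Columns are per-position log2 odds of the observed residue frequency
#' (with a pseudocount) against a uniform background of 1/20.
#'
#' @param seqs character vector of equal-length protein segments.
#' @param pseudocount added to each residue count per position.
#' @return A numeric matrix, rows = positions, columns = the 20 amino acids,
#'   values in bits.
#' @export
pssm_from_sequences <- function(seqs, pseudocount = 1) {
  stopifnot(length(seqs) >= 1)
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("all example segments must have equal length")
  mat <- matrix(pseudocount / 20, nrow = L, ncol = 20,
                dimnames = list(NULL, AA20))
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  for (j in seq_len(L)) {
    tab <- table(factor(chars[, j], levels = AA20))
    mat[j, ] <- mat[j, ] + as.numeric(tab)
  }
  freq <- mat / (length(seqs) + pseudocount)
  log2(freq / (1 / 20))
}

#' Maximum achievable PSSM score (consensus score)
#'
#' @param pssm matrix from [pssm_from_sequences()] or [read_pssm()].
#' @return Sum of per-position column maxima, in bits.
#' @export
consensus_score <- function(pssm) sum(apply(pssm, 1, max))

#' Consensus sequence of a PSSM
#' @param pssm a PSSM matrix.
#' @return The residue string maximizing the PSSM score.
#' @export
consensus_sequence <- function(pssm) {
  paste(colnames(pssm)[apply(pssm, 1, which.max)], collapse = "")
}

#' Define a conserved-domain model
#'
#' @param domain_id one of `"FLAG_N"`, `"FLAG_C"`, `"ARCH_FLAG"`,
#'   `"FLGL_DISCRIM"`.
#' @param pssm PSSM matrix (>= 5 positions, 20 amino-acid columns, bits).
#' @param min_score acceptance threshold in bits; default half the consensus
#'   score.
#' @param expected_terminus `"N"`, `"C"` or `"any"`: the half of the protein
#'   in which the best window's midpoint must fall.
#' @return An object of class `flg_domain_model`.
#' @export
domain_model <- function(domain_id, pssm,
                         min_score = consensus_score(pssm) / 2,
                         expected_terminus = c("any", "N", "C")) {
  domain_id <- match.arg(domain_id, DOMAIN_IDS)
  expected_terminus <- match.arg(expected_terminus)
  pssm <- as.matrix(pssm)
  if (nrow(pssm) < 5) stop("pssm must have >= 5 positions")
  if (!identical(colnames(pssm), AA20))
    stop("pssm columns must be the 20 amino acids in standard order")
  if (!is.finite(min_score)) stop("min_score must be finite")
  out <- list(domain_id = domain_id, pssm = pssm, min_score = min_score,
              expected_terminus = expected_terminus)
  class(out) <- "flg_domain_model"
  out
}

#' Write / read a PSSM as TSV (rows = positions, columns = 20 amino acids)
#' @param pssm a PSSM matrix.
#' @param path file path.
#' @return `path` invisibly (write) or the matrix (read).
#' @export
write_pssm <- function(pssm, path) {
  write.table(pssm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  m <- as.matrix(read.delim(path, check.names = FALSE))
  if (!identical(colnames(m), AA20))
    stop("PSSM file must have the 20 amino-acid columns in standard order")
  rownames(m) <- NULL
  m
}

# all window scores of a PSSM along a protein; X scores 0 at any position
pssm_window_scores <- function(residues, pssm) {
  aa <- strsplit(residues, "")[[1]]
  W <- nrow(pssm)
  L <- length(aa)
  if (L < W) return(numeric(0))
  lookup <- cbind(pssm, X = 0)
  col_idx <- match(aa, colnames(lookup))
  n_win <- L - W + 1L
  scores <- numeric(n_win)
  per_pos <- lookup[cbind(rep(seq_len(W), n_win),
                          col_idx[outer(seq_len(W) - 1L, seq_len(n_win), "+")])]
  colSums(matrix(per_pos, nrow = W))
}

pssm_best_window <- function(residues, model) {
  scores <- pssm_window_scores(residues, model$pssm)
  if (!length(scores)) return(NULL)
  L <- nchar(residues)
  W <- nrow(model$pssm)
  mid <- seq_along(scores) - 1 + W / 2
  ok <- switch(model$expected_terminus,
               N = mid <= L / 2,
               C = mid >= L / 2,
               any = rep(TRUE, length(scores)))
  if (!any(ok)) return(NULL)
  idx <- which(ok)[which.max(scores[ok])]
  list(score = scores[idx], start = idx - 1L, end = idx - 1L + W)
}

#' Scan a protein for conserved-domain hits
#'
#' For each model the maximum-scoring window (midpoint restricted to the
#' model's expected terminus half) is reported iff its score reaches the
#' model's threshold. A protein shorter than a model's PSSM simply yields no
#' hit for that model.
#'
#' @param record a single-row [flg_records] protein record, or a residue
#'   string.
#' @param models list of [domain_model()] objects.
#' @return A data frame with columns `domain_id`, `score`, `start`, `end`
#'   (0-based half-open protein coordinates), one row per hit.
#' @export
scan_domains <- function(record, models) {
  residues <- if (is.character(record)) record else record$residues[1]
  hits <- lapply(models, function(m) {
    best <- pssm_best_window(residues, m)
    if (is.null(best) || best$score < m$min_score) return(NULL)
    data.frame(domain_id = m$domain_id, score = best$score,
               start = best$start, end = best$end,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(domain_id = character(), score = numeric(),
                       start = integer(), end = integer(),
                       stringsAsFactors = FALSE)
  hits
}

#' Classify a protein from its domain hits
#'
#' Bacterial flagellins carry both terminal domains and score at least as
#' well under the flagellin discriminant as under the FlgL discriminant
#' (ties go to flagellin); both domains with a higher FlgL score is
#' FlgL-like; the archaeal domain alone (without the bacterial pair) is an
#' archaeal flagellin; anything else is not a flagellin.
#'
#' @param hits data frame from [scan_domains()].
#' @param flgl_score bits under the FlgL discriminant profile.
#' @param flagellin_score bits under the flagellin discriminant profile.
#' @return One of `"bacterial_flagellin"`, `"archaeal_flagellin"`,
#'   `"flgl_like"`, `"non_flagellin"`.
#' @export
classify_flagellin <- function(hits, flgl_score = -Inf,
                               flagellin_score = -Inf) {
  has <- function(d) d %in% hits$domain_id
  if (has("FLAG_N") && has("FLAG_C")) {
    if (flgl_score > flagellin_score) return("flgl_like")
    return("bacterial_flagellin")
  }
  if (has("ARCH_FLAG")) return("archaeal_flagellin")
  "non_flagellin"
}

#' Fish flagellin-like homologs out of a candidate pool
#'
#' Returns the pool members whose best bit score ratio against any seed
#' reaches `min_bsr`. Fished sequences should be re-checked with
#' [scan_domains()] before acceptance, as [curate()] does.
#'
#' @param seeds,pool [flg_records] protein data frames.
#' @param min_bsr BSR threshold in `(0, 1]`.
#' @param scheme an [scoring_scheme()] object.
#' @return The fished subset of `pool` (rows preserved in pool order).
#' @export
fish_homologs <- function(seeds, pool, min_bsr = 0.4,
                          scheme = scoring_scheme()) {
  if (!nrow(seeds)) stop("fishing requires at least one seed sequence")
  if (!(min_bsr > 0 && min_bsr <= 1)) stop("min_bsr must be in (0, 1]")
  if (!nrow(pool)) return(pool)
  seqs <- c(seeds$residues, pool$residues)
  ns <- nrow(seeds)
  np <- nrow(pool)
  self <- sw_scores(seqs, seq_along(seqs), seq_along(seqs), scheme)
  ia <- rep(seq_len(ns), times = np)
  ib <- rep(ns + seq_len(np), each = ns)
  raw <- sw_scores(seqs, ia, ib, scheme)
  keep <- logical(np)
  for (p in seq_len(np)) {
    r <- raw[(p - 1) * ns + seq_len(ns)]
    best <- max(vapply(seq_len(ns), function(s) {
      bsr_from_raw(r[s], self[s], self[ns + p], scheme)
    }, numeric(1)))
    keep[p] <- best >= min_bsr
  }
  pool[keep, , drop = FALSE]
}

#' Run the full curation funnel
#'
#' Stages: conserved-domain filter, optional homolog fishing from a candidate
#' pool (fished sequences are re-scanned before acceptance), FlgL-like
#' removal, and an explicit exclusion list. Every input id is accounted for
#' in exactly one of `accepted`/`rejected`; fished additions are listed
#' separately.
#'
#' @param records [flg_records] protein data frame to curate.
#' @param models list of [domain_model()] objects; must contain `FLAG_N`,
#'   `FLAG_C` and may contain `ARCH_FLAG` and `FLGL_DISCRIM`.
#' @param pool optional [flg_records] pool for homolog fishing.
#' @param exclusion_ids ids to reject unconditionally (last stage).
#' @param min_bsr fishing threshold.
#' @param scheme an [scoring_scheme()] object.
#' @return An object of class `flg_curation_report`: `accepted` (data frame
#'   `id`, `category`), `rejected` (data frame `id`, `stage`, `reason`),
#'   `fished` (character ids added from the pool).
#' @export
curate <- function(records, models, pool = NULL,
                   exclusion_ids = character(), min_bsr = 0.4,
                   scheme = scoring_scheme()) {
  model_ids <- vapply(models, `[[`, character(1), "domain_id")
  names(models) <- model_ids
  flgl_model <- models[["FLGL_DISCRIM"]]
  flag_n <- models[["FLAG_N"]]
  if (is.null(flag_n)) stop("curation requires a FLAG_N model")

  classify_one <- function(residues) {
    hits <- scan_domains(residues, models[model_ids != "FLGL_DISCRIM"])
    flagellin_score <- -Inf
    flgl_score <- -Inf
    if (!is.null(flgl_model) && all(c("FLAG_N", "FLAG_C") %in% hits$domain_id)) {
      bw_flag <- pssm_best_window(residues, flag_n)
      bw_flgl <- pssm_best_window(residues, flgl_model)
      if (!is.null(bw_flag)) flagellin_score <- bw_flag$score
      if (!is.null(bw_flgl)) flgl_score <- bw_flgl$score
    }
    classify_flagellin(hits, flgl_score, flagellin_score)
  }

  categories <- vapply(records$residues, classify_one, character(1),
                       USE.NAMES = FALSE)

  fished_ids <- character()
  if (!is.null(pool) && nrow(pool)) {
    seeds <- records[categories %in%
                       c("bacterial_flagellin", "archaeal_flagellin"), ,
                     drop = FALSE]
    if (nrow(seeds)) {
      pool <- pool[!pool$id %in% records$id, , drop = FALSE]
      fished <- fish_homologs(seeds, pool, min_bsr = min_bsr, scheme = scheme)
      if (nrow(fished)) {
        # mirror the re-scan of fished candidates before acceptance
        fished_cat <- vapply(fished$residues, classify_one, character(1),
                             USE.NAMES = FALSE)
        ok <- fished_cat %in% c("bacterial_flagellin", "archaeal_flagellin")
        fished <- fished[ok, , drop = FALSE]
        fished_cat <- fished_cat[ok]
        if (nrow(fished)) {
          fished_ids <- fished$id
          records <- rbind(records, fished)
          categories <- c(categories, fished_cat)
        }
      }
    }
  }

  stage <- rep(NA_character_, nrow(records))
  reason <- rep(NA_character_, nrow(records))
  stage[categories == "non_flagellin"] <- "domain_filter"
  reason[categories == "non_flagellin"] <- "missing required conserved domains"
  stage[categories == "flgl_like"] <- "flgl_filter"
  reason[categories == "flgl_like"] <- "FlgL discriminant outscores flagellin"
  excl <- records$id %in% exclusion_ids & is.na(stage)
  stage[excl] <- "exclusion_list"
  reason[excl] <- "listed for manual exclusion"

  rejected <- data.frame(id = records$id[!is.na(stage)],
                         stage = stage[!is.na(stage)],
                         reason = reason[!is.na(stage)],
                         stringsAsFactors = FALSE)
  accepted <- data.frame(id = records$id[is.na(stage)],
                         category = categories[is.na(stage)],
                         stringsAsFactors = FALSE)
  out <- list(accepted = accepted, rejected = rejected, fished = fished_ids)
  class(out) <- "flg_curation_report"
  out
}

#' @export
print.flg_curation_report <- function(x, ...) {
  cat("curation report:", nrow(x$accepted), "accepted,",
      nrow(x$rejected), "rejected,", length(x$fished), "fished\n")
  invisible(x)
}
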