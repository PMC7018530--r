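# Core sequence data model: record collections, FASTA I/O, deduplication,
# taxonomy side-table join, and standard-code translation.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
PROTEIN_ALPHABET <- c(AA20, "X")
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Build a collection of sequence records
#'
#' A record collection is a plain `data.frame` (class `flg_records`) with one
#' row per sequence and columns `id`, `description`, `kind`, `residues` and
#' `accessions`. Taxonomy columns may be attached with [attach_taxonomy()].
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of sequences (uppercased on input).
#' @param kind `"protein"` or `"dna"` (recycled).
#' @param description free-text descriptions.
#' @param accessions provenance accession strings (defaults to `id`).
#' @return A `flg_records` data frame.
#' @export
flg_records <- function(id, residues, kind = "protein",
                        description = "", accessions = id) {
  stopifnot(length(id) == length(residues))
  kind <- rep_len(kind, length(id))
  df <- data.frame(id = as.character(id),
                   description = rep_len(as.character(description), length(id)),
                   kind = kind,
                   residues = toupper(as.character(residues)),
                   accessions = as.character(accessions),
                   stringsAsFactors = FALSE)
  validate_records(df)
  class(df) <- c("flg_records", "data.frame")
  df
}

validate_records <- function(df) {
  if (anyDuplicated(df$id))
    stop("record ids must be unique within a collection")
  if (any(nchar(df$residues) == 0))
    stop("residues must be non-empty")
  bad_kind <- setdiff(unique(df$kind), c("protein", "dna"))
  if (length(bad_kind))
    stop("unknown sequence kind: ", paste(bad_kind, collapse = ", "))
  for (k in unique(df$kind)) {
    pat <- if (k == "protein") {
      paste0("^[", paste(PROTEIN_ALPHABET, collapse = ""), "]+$")
    } else {
      "^[ACGTN]+$"
    }
    res <- df$residues[df$kind == k]
    ok <- grepl(pat, res)
    if (!all(ok)) {
      bad <- df$id[df$kind == k][!ok][1]
      stop("illegal residue in ", k, " record '", bad, "'")
    }
  }
  invisible(df)
}

#' Read sequences from a FASTA file
#'
#' @param path path to a FASTA file (protein or nucleotide).
#' @param kind `"protein"` or `"dna"`; controls alphabet validation.
#' @return A [flg_records] data frame, one row per FASTA entry in file order;
#'   residues are uppercased, `description` is the header text after the first
#'   whitespace.
#' @export
read_fasta <- function(path, kind = c("protein", "dna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) fasta_parse_error(path, conditionMessage(e))
  )
  if (length(set) == 0)
    return(flg_records(character(), character(), kind = kind))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  res <- toupper(as.character(set))
  rec <- tryCatch(
    flg_records(id, res, kind = kind, description = desc),
    error = function(e) fasta_residue_error(path, res, kind,
                                            conditionMessage(e))
  )
  rec
}

# Locate the offending line for error messages; FASTA parsing itself is done
# by Biostrings, this scan only serves diagnostics.
fasta_parse_error <- function(path, msg) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA in '", path, "': line ", nonblank[1],
         " precedes any '>' header")
  stop("malformed FASTA in '", path, "': ", msg)
}

fasta_residue_error <- function(path, residues, kind, msg) {
  lines <- readLines(path, warn = FALSE)
  pat <- if (kind == "protein") {
    paste0("^[", paste(PROTEIN_ALPHABET, collapse = ""), "]*$")
  } else {
    "^[ACGTN]*$"
  }
  body <- !startsWith(trimws(lines), ">") & nzchar(trimws(lines))
  bad <- which(body & !grepl(pat, toupper(trimws(lines))))
  if (length(bad))
    stop("illegal ", kind, " residue in '", path, "' at line ", bad[1])
  stop(msg)
}

#' Write records to a FASTA file
#'
#' @param records a [flg_records] data frame.
#' @param path output path.
#' @param width line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$description[i])) {
      paste(records$id[i], records$description[i])
    } else records$id[i]
    writeLines(paste0(">", hdr), con)
    seq <- records$residues[i]
    starts <- seq(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))),
               con)
  }
  invisible(path)
}

#' Read a taxonomy side table
#'
#' TSV with columns `id`, `superkingdom`, `phylum`, `class`, `order`,
#' `family`, `genus`, `species`. Missing cells become `"Unknown"`.
#'
#' @param path path to the TSV file.
#' @return A data frame with the eight columns above.
#' @export
read_taxonomy <- function(path) {
  tax <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("id", TAX_RANKS)
  missing <- setdiff(needed, names(tax))
  if (length(missing))
    stop("taxonomy table lacks columns: ", paste(missing, collapse = ", "))
  tax <- tax[, needed]
  for (r in TAX_RANKS) {
    v <- as.character(tax[[r]])
    v[is.na(v) | !nzchar(v)] <- "Unknown"
    tax[[r]] <- v
  }
  bad <- setdiff(unique(tax$superkingdom), c("Bacteria", "Archaea", "Unknown"))
  if (length(bad))
    stop("superkingdom must be Bacteria, Archaea or Unknown; found: ",
         paste(bad, collapse = ", "))
  tax
}

TAX_RANKS <- c("superkingdom", "phylum", "class", "order",
               "family", "genus", "species")

#' Attach taxonomy labels to records
#'
#' Records absent from the table get all-`"Unknown"` labels.
#'
#' @param records a [flg_records] data frame.
#' @param taxonomy a data frame as returned by [read_taxonomy()].
#' @return `records` with the seven rank columns appended.
#' @export
attach_taxonomy <- function(records, taxonomy) {
  idx <- match(records$id, taxonomy$id)
  for (r in TAX_RANKS) {
    v <- taxonomy[[r]][idx]
    v[is.na(v)] <- "Unknown"
    records[[r]] <- v
  }
  records
}

#' Deduplicate records into a unique-sequence set
#'
#' Exact string equality on the full-length sequence. The representative id of
#' each duplicate class is the lexicographically smallest member id.
#'
#' @param records a [flg_records] data frame (all rows the same kind).
#' @return An object of class `flg_unique_set`: list with `members` (named
#'   list, residue string -> sorted member ids), `rep_id` (named character,
#'   residue string -> representative id), `n_total`, `n_unique`, `kind`.
#' @export
deduplicate <- function(records) {
  if (nrow(records) && length(unique(records$kind)) > 1)
    stop("cannot deduplicate records of mixed kinds")
  members <- split(records$id, records$residues)
  members <- lapply(members, function(x) sort(x, method = "radix"))
  rep_id <- vapply(members, `[`, character(1), 1L)
  out <- list(members = members,
              rep_id = rep_id,
              n_total = nrow(records),
              n_unique = length(members),
              kind = if (nrow(records)) records$kind[1] else "protein")
  class(out) <- "flg_unique_set"
  out
}

#' @export
print.flg_unique_set <- function(x, ...) {
  cat("flg_unique_set:", x$n_unique, "unique sequences from",
      x$n_total, "observations\n")
  invisible(x)
}

#' Representative records of a unique-sequence set
#'
#' @param uniques an `flg_unique_set`.
#' @return A [flg_records] data frame with one row per unique sequence, id =
#'   representative member id, ordered by id.
#' @export
unique_records <- function(uniques) {
  rec <- flg_records(unname(uniques$rep_id), names(uniques$members),
                     kind = uniques$kind)
  rec[order(rec$id, method = "radix"), , drop = FALSE]
}

#' Translate coding sequences with the standard genetic code
#'
#' Trailing stop codons are dropped; codons containing `N` translate to `X`;
#' an internal stop codon is an error reporting the (1-based) codon index.
#'
#' @param records a [flg_records] data frame of kind `"dna"`.
#' @return A [flg_records] data frame of kind `"protein"` with the same ids.
#' @export
translate_cds <- function(records) {
  if (any(records$kind != "dna")) stop("translate_cds expects dna records")
  prot <- vapply(seq_len(nrow(records)), function(i) {
    translate_one(records$residues[i], records$id[i])
  }, character(1))
  flg_records(records$id, prot, kind = "protein",
              description = records$description,
              accessions = records$accessions)
}

translate_one <- function(dna, id = "<sequence>") {
  n <- nchar(dna)
  if (n %% 3 != 0)
    stop("length of '", id, "' (", n, " nt) is not divisible by 3")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # codons containing N (or other ambiguity)
  stops <- which(aa == "*")
  if (length(stops)) {
    internal <- stops[stops < length(aa)]
    if (length(internal))
      stop("internal stop codon in '", id, "' at codon ", internal[1])
    aa <- aa[-length(aa)]
  }
  if (!length(aa))
    stop("'", id, "' translates to an empty protein")
  paste(aa, collapse = "")
}
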