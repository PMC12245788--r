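#' Read per-structure docking records
#'
#' Parses a long-format docking-score table with one row per (ligand, PDB
#' entry, chain) docking result. Scores are in arbitrary docking units with
#' lower (more negative) values meaning stronger predicted binding; this
#' polarity is fixed throughout the package.
#'
#' Rows failing validation (non-numeric or non-finite score, empty ligand or
#' chain identifier, malformed PDB code) are rejected, counted and reported
#' with their line numbers; they never abort the read. A missing required
#' column is fatal.
#'
#' @param path Path to a CSV (or TSV, auto-detected from the `.tsv`/`.tab`
#'   extension) with a header row.
#' @param sep Field delimiter overriding the extension-based default.
#' @param columns Named character vector mapping the canonical names
#'   `ligand_id`, `pdb_id`, `chain`, `score` to the header names used in the
#'   file.
#' @return A `data.frame` of class `docking_records` with character columns
#'   `ligand_id`, `pdb_id`, `chain` and numeric `score`, in file order.
#'   Attributes `n_rejected` and `rejected_lines` report parse rejections.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("ligand_id,pdb_id,chain,score", "THC,1ABC,A,-55.0"), f)
#' read_docking_records(f)
#' @export
read_docking_records <- function(path, sep = NULL,
                                 columns = c(ligand_id = "ligand_id",
                                             pdb_id = "pdb_id",
                                             chain = "chain",
                                             score = "score")) {
  canonical <- c("ligand_id", "pdb_id", "chain", "score")
  stopifnot(all(canonical %in% names(columns)))
  df <- .read_table(path, sep)
  .require_columns(df, unname(columns[canonical]), "docking records")
  df <- df[, unname(columns[canonical]), drop = FALSE]
  names(df) <- canonical

  score <- suppressWarnings(as.numeric(df$score))
  ok <- is.finite(score) &
    nzchar(df$ligand_id) & nzchar(df$chain) &
    grepl(.re_pdb, df$pdb_id)
  rejected <- which(!ok)
  if (length(rejected) > 0L)
    dfp_log("rejected %d malformed row(s) at line(s) %s", length(rejected),
            paste(utils::head(rejected + 1L, 20L), collapse = ","),
            level = "WARN")

  out <- data.frame(ligand_id = df$ligand_id[ok], pdb_id = df$pdb_id[ok],
                    chain = df$chain[ok], score = score[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- length(rejected)
  attr(out, "rejected_lines") <- rejected + 1L  # header is line 1
  class(out) <- c("docking_records", "data.frame")
  out
}

#' Read a PDB-chain to UniProt mapping
#'
#' Reads the table mapping each (PDB entry, chain) to the UniProt accession
#' of the protein it represents, the key that collapses redundant structures
#' to unique targets. The mapping must be functional: two rows assigning
#' different accessions to the same (pdb_id, chain) are a fatal error naming
#' the offending key. Identical duplicate rows are collapsed. Rows whose
#' accession does not match the UniProt pattern (6 or 10 alphanumerics
#' starting with a letter) are dropped with a warning.
#'
#' @param path Path to a TSV (or CSV, by extension) with columns `pdb_id`,
#'   `chain`, `uniprot_id` and optional `target_name`, `target_class`.
#' @param sep Field delimiter override.
#' @return A `data.frame` of class `chain_map` with one row per (pdb_id,
#'   chain) key and columns `pdb_id`, `chain`, `uniprot_id`, `target_name`,
#'   `target_class` (the optional ones `NA` when absent).
#' @export
read_chain_map <- function(path, sep = NULL) {
  df <- .read_table(path, sep)
  .require_columns(df, c("pdb_id", "chain", "uniprot_id"), "chain map")
  for (optional in c("target_name", "target_class"))
    if (!optional %in% names(df)) df[[optional]] <- NA_character_
  df <- df[, c("pdb_id", "chain", "uniprot_id", "target_name", "target_class")]

  bad <- !grepl(.re_uniprot, df$uniprot_id)
  if (any(bad)) {
    dfp_log("dropping %d row(s) with malformed UniProt accession", sum(bad),
            level = "WARN")
    df <- df[!bad, , drop = FALSE]
  }
  df <- unique(df)
  key <- paste(df$pdb_id, df$chain, sep = "/")
  dup <- key[duplicated(key)]
  if (length(dup) > 0L)
    stop(sprintf("conflicting UniProt assignment for chain key(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("chain_map", "data.frame")
  df
}

#' Aggregate docking records to a best-score matrix over unique targets
#'
#' Maps every record's (pdb_id, chain) to its UniProt accession and keeps,
#' for each (ligand, target) pair, the minimum (best) docking score over all
#' contributing structures — the standard collapse of multi-structure
#' redundancy to one score per unique protein. Records whose chain key is
#' absent from the mapping are dropped with a warning and counted; duplicate
#' records for an identical (ligand, pdb_id, chain) keep the minimum score
#' and are counted. The provenance of every retained cell (which structure
#' supplied the minimum) is recorded.
#'
#' @param records A `docking_records` data frame from
#'   [read_docking_records()] (or any data frame with the same columns).
#' @param map A `chain_map` from [read_chain_map()].
#' @return An object of class `score_matrix`: a list with
#'   \describe{
#'     \item{scores}{numeric matrix, ligands (rows, sorted) by UniProt
#'       accessions (columns, sorted); `NA` where no record contributed.}
#'     \item{provenance}{data frame `ligand_id`, `uniprot_id`, `pdb_id`,
#'       `chain`, `score` — the structure supplying each cell's minimum.}
#'     \item{counts}{named integer vector: `used`, `unmapped`, `duplicate`.}
#'     \item{annotation}{per-target `target_name`/`target_class` carried
#'       over from the mapping (first non-missing value per accession).}
#'   }
#' @examples
#' rec <- data.frame(ligand_id = "THC", pdb_id = c("1ABC", "1ABC"),
#'                   chain = c("A", "B"), score = c(-55.2, -61.0))
#' map <- data.frame(pdb_id = "1ABC", chain = c("A", "B"),
#'                   uniprot_id = "P01116")
#' aggregate_best(rec, map)$scores
#' @export
aggregate_best <- function(records, map) {
  stopifnot(is.data.frame(records), is.data.frame(map))
  n_in <- nrow(records)
  key <- paste(records$pdb_id, records$chain, sep = "/")
  mkey <- paste(map$pdb_id, map$chain, sep = "/")
  idx <- match(key, mkey)
  unmapped <- is.na(idx)
  if (all(unmapped)) stop("no docking record maps to any target",
                          call. = FALSE)
  if (any(unmapped))
    dfp_log("dropped %d record(s) with unmapped (pdb_id, chain)",
            sum(unmapped), level = "WARN")
  rec <- records[!unmapped, , drop = FALSE]
  rec$uniprot_id <- map$uniprot_id[idx[!unmapped]]

  # duplicates of the same structure: the minimum wins below; count them
  n_dup <- sum(duplicated(rec[, c("ligand_id", "pdb_id", "chain")]))
  if (n_dup > 0L)
    dfp_log("found %d duplicate (ligand, pdb, chain) record(s); keeping minima",
            n_dup, level = "WARN")

  # argmin per (ligand, target): order by score, keep first in each group
  o <- order(rec$ligand_id, rec$uniprot_id, rec$score, rec$pdb_id, rec$chain)
  rec <- rec[o, , drop = FALSE]
  first <- !duplicated(rec[, c("ligand_id", "uniprot_id")])
  prov <- rec[first, c("ligand_id", "uniprot_id", "pdb_id", "chain", "score")]
  rownames(prov) <- NULL

  ligands <- sort(unique(rec$ligand_id))
  targets <- sort(unique(rec$uniprot_id))
  scores <- matrix(NA_real_, nrow = length(ligands), ncol = length(targets),
                   dimnames = list(ligands, targets))
  scores[cbind(match(prov$ligand_id, ligands),
               match(prov$uniprot_id, targets))] <- prov$score

  annotation <- NULL
  if (any(c("target_name", "target_class") %in% names(map))) {
    m <- map[match(targets, map$uniprot_id), , drop = FALSE]
    annotation <- data.frame(
      uniprot_id = targets,
      target_name = if ("target_name" %in% names(map)) m$target_name else NA,
      target_class = if ("target_class" %in% names(map)) m$target_class else NA,
      stringsAsFactors = FALSE)
  }

  structure(list(scores = scores, provenance = prov,
                 counts = c(used = nrow(rec), unmapped = sum(unmapped),
                            duplicate = n_dup, input = n_in),
                 annotation = annotation),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("Best-score matrix: %d ligand(s) x %d unique target(s)\n",
              nrow(x$scores), ncol(x$scores)))
  cat(sprintf("  filled cells: %d of %d; records used: %d, unmapped: %d\n",
              sum(!is.na(x$scores)), length(x$scores),
              x$counts[["used"]], x$counts[["unmapped"]]))
  invisible(x)
}

#' @export
as.matrix.score_matrix <- function(x, ...) x$scores

#' Write and read a best-score matrix as wide CSV
#'
#' The wide CSV has ligands as rows, UniProt accessions as columns and empty
#' cells for absent scores; `write_score_matrix()` also writes the
#' provenance long CSV alongside when `provenance_path` is given.
#'
#' @param x A `score_matrix`.
#' @param path Output CSV path.
#' @param provenance_path Optional path for the provenance long CSV.
#' @return `write_score_matrix()`: `path`, invisibly. `read_score_matrix()`:
#'   a `score_matrix` (with empty provenance and counts reconstructed from
#'   the cells).
#' @export
write_score_matrix <- function(x, path, provenance_path = NULL) {
  df <- data.frame(ligand_id = rownames(x$scores), x$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(provenance_path))
    utils::write.csv(x$provenance, provenance_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_matrix
#' @export
read_score_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "ligand_id")
    stop("score matrix CSV must have ligand_id as its first column",
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$ligand_id
  n_cells <- sum(!is.na(m))
  structure(list(scores = m,
                 provenance = data.frame(ligand_id = character(),
                                         uniprot_id = character(),
                                         pdb_id = character(),
                                         chain = character(),
                                         score = numeric()),
                 counts = c(used = n_cells, unmapped = 0L, duplicate = 0L,
                            input = n_cells),
                 annotation = NULL),
            class = "score_matrix")
}
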