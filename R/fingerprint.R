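#' Per-ligand Z-score fingerprints from a best-score matrix
#'
#' Standardizes each ligand's best-score profile across the common target
#' set: Z_l(i) = (s(l,i) - mu_l) / sigma_l, with mu_l and sigma_l the
#' ligand's mean and sample standard deviation (denominator N_t - 1) over
#' the targets scored for *every* ligand. Because docking units are
#' arbitrary and differ in location and spread between ligands, the Z scale
#' makes profiles comparable; a negative Z marks stronger-than-average
#' predicted binding for that ligand. The Z vector over all common targets
#' is the ligand's inverse docking fingerprint.
#'
#' Targets not scored for every ligand are dropped before computing the
#' statistics (so a single common N_t is well defined) and their count is
#' reported.
#'
#' @param matrix A `score_matrix` from [aggregate_best()].
#' @return An object of class `dock_fingerprints`: list with `Z` (numeric
#'   matrix, ligands x common targets), `mu` and `sigma` (named per-ligand
#'   vectors), `n_targets`, `n_dropped_targets`, and `annotation` carried
#'   over from the score matrix.
#' @examples
#' sm <- list(scores = matrix(c(-10, -8, -6), 1,
#'                            dimnames = list("L", c("T1", "T2", "T3"))))
#' class(sm) <- "score_matrix"
#' zscore_fingerprints(sm)$Z   # -1 0 1
#' @export
zscore_fingerprints <- function(matrix) {
  s <- matrix$scores
  complete <- colSums(is.na(s)) == 0L
  dropped <- sum(!complete)
  if (dropped > 0L)
    dfp_log("dropped %d target(s) not scored for every ligand", dropped)
  s <- s[, complete, drop = FALSE]
  nt <- ncol(s)
  if (nt < 3L)
    stop(sprintf("need at least 3 common targets, have %d", nt),
         call. = FALSE)
  mu <- rowMeans(s)
  sigma <- apply(s, 1L, stats::sd)  # sample SD, denominator N_t - 1
  if (any(sigma == 0))
    stop(sprintf("zero score variance for ligand(s): %s",
                 paste(rownames(s)[sigma == 0], collapse = ", ")),
         call. = FALSE)
  Z <- (s - mu) / sigma
  structure(list(Z = Z, mu = mu, sigma = sigma, n_targets = nt,
                 n_dropped_targets = dropped,
                 annotation = matrix$annotation),
            class = "dock_fingerprints")
}

#' @export
print.dock_fingerprints <- function(x, ...) {
  cat(sprintf("Inverse docking fingerprints: %d ligand(s) x %d common target(s)\n",
              nrow(x$Z), x$n_targets))
  if (x$n_dropped_targets > 0L)
    cat(sprintf("  (%d incompletely scored target(s) dropped)\n",
                x$n_dropped_targets))
  invisible(x)
}

#' @export
summary.dock_fingerprints <- function(object, z_cut = -2.58, ...) {
  strong <- rowSums(object$Z < z_cut)
  out <- data.frame(ligand_id = rownames(object$Z),
                    mean_score = unname(object$mu),
                    sd_score = unname(object$sigma),
                    min_Z = apply(object$Z, 1L, min),
                    n_below_cut = unname(strong),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Standard-normal percentile of a Z-score
#'
#' Returns 100 * P(X > z) for standard normal X: the percentage of the
#' reference score distribution that is weaker (less negative) than the
#' given Z. A strongly binding Z of -2.58 lies at the 99.5th percentile.
#'
#' @param z Finite numeric Z-score(s).
#' @param digits Decimal places for display rounding (default 1, the
#'   convention used when percentiles are reported).
#' @return Numeric percentile(s) in \[0, 100\], rounded to `digits`.
#' @examples
#' percentile_of_z(0)      # 50
#' percentile_of_z(-2.58)  # 99.5
#' @export
percentile_of_z <- function(z, digits = 1) {
  stopifnot(is.numeric(z), all(is.finite(z)))
  round(100 * stats::pnorm(z, lower.tail = FALSE), digits)
}

#' Union of each ligand's top-k targets
#'
#' For each ligand, takes the k targets with the lowest (strongest) Z and
#' forms the de-duplicated union across ligands — the shortlist of
#' candidate targets a target-fishing analysis inspects. A curation
#' `exclude` list is removed and an `include` list (e.g. established
#' reference targets) is appended at the end when not already present.
#'
#' Within the union, targets are ordered by their minimum Z across ligands
#' (ascending), ties broken by accession; ties within a ligand's top k are
#' broken by (Z ascending, accession ascending).
#'
#' @param fps A `dock_fingerprints` object.
#' @param k Targets taken per ligand (default 10).
#' @param exclude,include Character vectors of UniProt accessions. Included
#'   accessions absent from the fingerprint target list are skipped with a
#'   warning.
#' @return Character vector of accessions.
#' @export
select_top_targets <- function(fps, k = 10, exclude = character(),
                               include = character()) {
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  targets <- colnames(fps$Z)
  if (k > length(targets))
    stop(sprintf("k = %d exceeds the %d available targets", k,
                 length(targets)), call. = FALSE)
  if (length(intersect(exclude, include)) > 0L)
    stop("exclude and include lists overlap", call. = FALSE)
  picked <- unlist(lapply(seq_len(nrow(fps$Z)), function(l) {
    z <- fps$Z[l, ]
    targets[order(z, targets)[seq_len(k)]]
  }))
  union_set <- setdiff(unique(picked), exclude)
  min_z <- apply(fps$Z[, union_set, drop = FALSE], 2L, min)
  union_set <- union_set[order(min_z, union_set)]

  missing <- setdiff(include, targets)
  if (length(missing) > 0L) {
    warning(sprintf("include target(s) absent from fingerprints, skipped: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
    include <- setdiff(include, missing)
  }
  c(union_set, setdiff(include, union_set))
}

#' Hit table of targets bound strongly by several ligands
#'
#' Lists every target at which at least `min_ligands` ligands have a
#' fingerprint Z strictly below `z_cut`. The default cutoff -2.58 marks the
#' 99.5th percentile of the standard normal reference, i.e. scores in the
#' strongest half-percent of a ligand's distribution; requiring several
#' ligands guards against single-ligand artifacts.
#'
#' @param fps A `dock_fingerprints` object.
#' @param z_cut Strict upper bound on Z for a cell to count as a hit
#'   (default -2.58). The boundary value itself does not count.
#' @param min_ligands Minimum number of hit ligands for a target to be
#'   listed (default 3).
#' @return A data frame of class `hit_table` with columns `uniprot_id`,
#'   `hit_ligands` (comma-joined, alphabetical), `n_hits`, `min_Z`, sorted
#'   by (`n_hits` descending, `min_Z` ascending). May have zero rows.
#' @export
hit_table <- function(fps, z_cut = -2.58, min_ligands = 3) {
  stopifnot(min_ligands >= 1L)
  hits <- fps$Z < z_cut
  n_hits <- colSums(hits)
  keep <- which(n_hits >= min_ligands)
  out <- data.frame(
    uniprot_id = colnames(fps$Z)[keep],
    hit_ligands = vapply(keep, function(j)
      paste(sort(rownames(fps$Z)[hits[, j]]), collapse = ","), character(1)),
    n_hits = as.integer(n_hits[keep]),
    min_Z = vapply(keep, function(j) min(fps$Z[, j]), numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_hits, out$min_Z, out$uniprot_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Normality diagnostic for one ligand's score distribution
#'
#' The Z-score presentation assumes each ligand's best scores across
#' targets are roughly normal. This advisory diagnostic returns the sample
#' skewness, excess kurtosis and the Kolmogorov-Smirnov distance between
#' the empirical distribution and a normal with the ligand's sample
#' mean/SD. It never gates the pipeline.
#'
#' @param matrix A `score_matrix`.
#' @param ligand Ligand identifier present in the matrix with at least 20
#'   scored targets.
#' @return Named numeric vector `skewness`, `excess_kurtosis`, `ks_stat`.
#' @export
normality_diagnostic <- function(matrix, ligand) {
  if (!ligand %in% rownames(matrix$scores))
    stop(sprintf("unknown ligand: %s", ligand), call. = FALSE)
  x <- matrix$scores[ligand, ]
  x <- x[!is.na(x)]
  if (length(x) < 20L)
    stop(sprintf("ligand %s has only %d scores (need >= 20)", ligand,
                 length(x)), call. = FALSE)
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  z <- (x - m) / s
  skew <- sum(z^3) / n
  kurt <- sum(z^4) / n - 3
  ks <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean = m, sd = s)$statistic)
  c(skewness = skew, excess_kurtosis = kurt, ks_stat = unname(ks))
}

#' Export a fingerprint heatmap and its underlying values
#'
#' Renders the ligand-by-target Z-score block for a chosen (typically
#' curated top-target) list as a heatmap — ligands as rows, targets as
#' columns, more negative Z hotter — and writes the exact values as a long
#' CSV (`ligand,target,Z`). Z values are taken from the full-matrix
#' fingerprints, never recomputed on the subset, so the displayed scale
#' stays anchored to each ligand's whole-library distribution. When target
#' class annotations are available the columns are grouped by class.
#'
#' @param fps A `dock_fingerprints` object.
#' @param targets Ordered character vector of accessions to display; must
#'   all be fingerprint targets.
#' @param image_path Output image path (`.png`; omit with `NULL` to skip
#'   rendering and only write the CSV).
#' @param csv_path Output path for the long CSV (`NULL` to skip).
#' @return Invisibly, the long-format data frame that was (or would be)
#'   written.
#' @export
export_fingerprint_heatmap <- function(fps, targets, image_path = NULL,
                                       csv_path = NULL) {
  unknown <- setdiff(targets, colnames(fps$Z))
  if (length(unknown) > 0L)
    stop(sprintf("unknown target(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  # group columns by annotated class when available, preserving given order
  # within a class
  if (!is.null(fps$annotation)) {
    cls <- fps$annotation$target_class[match(targets,
                                             fps$annotation$uniprot_id)]
    if (any(!is.na(cls)))
      targets <- targets[order(is.na(cls), cls)]
  }
  block <- fps$Z[, targets, drop = FALSE]
  long <- data.frame(
    ligand = rep(rownames(block), times = ncol(block)),
    target = rep(colnames(block), each = nrow(block)),
    Z = as.vector(block), stringsAsFactors = FALSE)
  if (!is.null(csv_path))
    utils::write.csv(long, csv_path, row.names = FALSE)
  if (!is.null(image_path)) {
    # reversed RdBu-style ramp: strongly negative Z renders hot (red)
    pal <- grDevices::colorRampPalette(
      c("#b2182b", "#ef8a62", "#fddbc7", "#f7f7f7", "#d1e5f0",
        "#67a9cf", "#2166ac"))(101)
    pheatmap::pheatmap(block, cluster_rows = FALSE, cluster_cols = FALSE,
                       color = pal, filename = image_path, silent = TRUE,
                       fontsize_col = 6, main = "Inverse docking fingerprints (Z)")
  }
  invisible(long)
}

#' Write fingerprints or a hit table to CSV
#'
#' @param fps A `dock_fingerprints` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  df <- data.frame(ligand_id = rownames(fps$Z), fps$Z, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @param ht A `hit_table`.
#' @export
write_hit_table <- function(ht, path) {
  utils::write.csv(as.data.frame(ht), path, row.names = FALSE)
  invisible(path)
}
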