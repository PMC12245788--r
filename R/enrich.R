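#' Read known actives filtered by pChEMBL
#'
#' Reads a table of experimentally supported ligand-target pairs with their
#' pChEMBL value (-log10 molar activity, as curated in ChEMBL) and keeps
#' pairs with pChEMBL strictly greater than the threshold — the
#' experimentally-relevant positives used for retrospective validation.
#' Duplicated pairs collapse to their maximum pChEMBL; rows with a
#' non-numeric pChEMBL are rejected and logged.
#'
#' @param path CSV (or TSV by extension) with columns `ligand_id`,
#'   `uniprot_id`, `pchembl`.
#' @param pchembl_min Strict lower bound (default 4).
#' @param sep Delimiter override.
#' @return A data frame of class `actives_set` with columns `ligand_id`,
#'   `uniprot_id`, `pchembl`, one row per retained pair.
#' @export
read_actives <- function(path, pchembl_min = 4, sep = NULL) {
  df <- .read_table(path, sep)
  .require_columns(df, c("ligand_id", "uniprot_id", "pchembl"), "actives")
  pchembl <- suppressWarnings(as.numeric(df$pchembl))
  bad <- !is.finite(pchembl)
  if (any(bad))
    dfp_log("rejected %d actives row(s) with non-numeric pchembl at line(s) %s",
            sum(bad), paste(utils::head(which(bad) + 1L, 20L), collapse = ","),
            level = "WARN")
  df <- df[!bad, c("ligand_id", "uniprot_id"), drop = FALSE]
  df$pchembl <- pchembl[!bad]
  # collapse duplicates keeping the maximum pchembl, then strict filter
  o <- order(df$ligand_id, df$uniprot_id, -df$pchembl)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df[, c("ligand_id", "uniprot_id")]), , drop = FALSE]
  df <- df[df$pchembl > pchembl_min, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("actives_set", "data.frame")
  df
}

#' Construct a ranked screen
#'
#' A ranked screen is one ligand's ordered target list with active labels:
#' N ranked targets, N_a actives at distinct ranks r_i (1 = best score).
#' Usually built by [rank_targets()]; this constructor validates the
#' invariants and is convenient for simulation studies.
#'
#' @param ranks Integer ranks of the actives, distinct values in 1..N.
#' @param N Total number of ranked targets.
#' @param scores Optional raw scores in rank order (lower = better); when
#'   absent, tie-free scores equal to the ranks are assumed.
#' @param ligand_id Optional ligand identifier.
#' @param targets Optional target accessions in rank order.
#' @return An object of class `ranked_screen`.
#' @export
ranked_screen <- function(ranks, N, scores = NULL, ligand_id = NA_character_,
                          targets = NULL) {
  ranks <- sort(as.integer(ranks))
  if (length(ranks) == 0L || anyDuplicated(ranks) ||
      min(ranks) < 1L || max(ranks) > N)
    stop("active ranks must be distinct integers in 1..N", call. = FALSE)
  if (length(ranks) >= N)
    stop("need at least one inactive (N_a < N)", call. = FALSE)
  labels <- rep(FALSE, N)
  labels[ranks] <- TRUE
  if (is.null(scores)) scores <- as.numeric(seq_len(N))
  stopifnot(length(scores) == N, !is.unsorted(scores))
  structure(list(ligand_id = ligand_id, N = as.integer(N),
                 N_a = length(ranks), ranks = ranks, labels = labels,
                 scores = as.numeric(scores), targets = targets,
                 Ra = length(ranks) / N),
            class = "ranked_screen")
}

#' Rank one ligand's targets and label its actives
#'
#' Sorts the ligand's scored targets by raw docking score ascending (lower
#' = better), breaking exact ties by accession so repeated runs are
#' identical, and labels as active every target in the actives set for this
#' ligand. Actives absent from the scored targets are dropped with a logged
#' count.
#'
#' @param matrix A `score_matrix`.
#' @param ligand Ligand identifier present in the matrix.
#' @param actives An `actives_set` (or data frame with `ligand_id`,
#'   `uniprot_id`).
#' @return A `ranked_screen` carrying raw scores, so downstream AUC can be
#'   tie-aware.
#' @export
rank_targets <- function(matrix, ligand, actives) {
  if (!ligand %in% rownames(matrix$scores))
    stop(sprintf("unknown ligand: %s", ligand), call. = FALSE)
  s <- matrix$scores[ligand, ]
  s <- s[!is.na(s)]
  targets <- names(s)
  active_t <- unique(actives$uniprot_id[actives$ligand_id == ligand])
  missing <- setdiff(active_t, targets)
  if (length(missing) > 0L)
    dfp_log("ligand %s: %d active(s) absent from scored targets, dropped",
            ligand, length(missing))
  active_t <- setdiff(active_t, missing)
  if (length(active_t) == 0L)
    stop(sprintf("ligand %s has no usable actives", ligand), call. = FALSE)
  if (length(active_t) == length(targets))
    stop(sprintf("ligand %s has no inactives", ligand), call. = FALSE)
  o <- order(s, targets)
  ranked <- targets[o]
  ranked_screen(ranks = which(ranked %in% active_t), N = length(targets),
                scores = unname(s[o]), ligand_id = ligand, targets = ranked)
}

#' @export
print.ranked_screen <- function(x, ...) {
  cat(sprintf("Ranked screen%s: %d targets, %d actives (Ra = %.3f)\n",
              if (is.na(x$ligand_id)) "" else paste0(" for ", x$ligand_id),
              x$N, x$N_a, x$Ra))
  cat("  best active rank:", min(x$ranks), "\n")
  invisible(x)
}

#' ROC curve points of a ranked screen
#'
#' Stepwise-exact ROC: one (false positive fraction, true positive
#' fraction) point per rank threshold, prefixed with (0, 0). No
#' interpolation is stored.
#'
#' @param rs A `ranked_screen`.
#' @return Data frame with columns `FPF`, `TPF`, both non-decreasing from
#'   (0,0) to (1,1).
#' @export
roc_points <- function(rs) {
  tp <- cumsum(rs$labels)
  fp <- cumsum(!rs$labels)
  data.frame(FPF = c(0, fp / (rs$N - rs$N_a)), TPF = c(0, tp / rs$N_a))
}

#' ROC AUC of a ranked screen (tie-aware)
#'
#' The area under the ROC curve equals the Mann-Whitney probability that a
#' random active scores better (lower) than a random inactive, with ties in
#' the raw scores counted one half. It is computed from the raw scores, not
#' from the post-tie-break ranks, so ligands with many identical docking
#' scores are not credited for an arbitrary ordering.
#'
#' @param rs A `ranked_screen`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(rs) {
  r <- rank(rs$scores, ties.method = "average")
  na <- rs$N_a
  ni <- rs$N - na
  # sum of average ranks of actives counts pairs where the active loses
  1 - (sum(r[rs$labels]) - na * (na + 1) / 2) / (na * ni)
}

#' Enrichment factor at a screening fraction
#'
#' EF_f = (fraction of the top n = ceil(f N) targets that are active)
#' divided by the overall prevalence N_a / N. EF of 1 is random; the
#' maximum is min(1/f, N/N_a).
#'
#' @param rs A `ranked_screen`.
#' @param f Screening fraction in (0, 1\] (default 0.10).
#' @return Numeric EF value.
#' @export
enrichment_factor <- function(rs, f = 0.10) {
  stopifnot(f > 0, f <= 1)
  n <- ceiling(f * rs$N)
  hits <- sum(rs$ranks <= n)
  (hits / n) / rs$Ra
}

#' Robust initial enhancement (RIE)
#'
#' Exponentially rank-weighted early-recognition score: the mean of
#' exp(-alpha r_i / N) over the actives, normalized by its expectation
#' under a uniform random ranking,
#' \deqn{RIE = \frac{\frac{1}{N_a}\sum_i e^{-\alpha r_i/N}}
#'   {\frac{1}{N}\,\frac{1-e^{-\alpha}}{e^{\alpha/N}-1}}.}
#' RIE of 1 is random performance; larger alpha concentrates the weight on
#' the earliest ranks.
#'
#' @param rs A `ranked_screen`.
#' @param alpha Early-recognition exponent, > 0 (default 20).
#' @return Numeric RIE value.
#' @export
rie <- function(rs, alpha = 20) {
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  num <- mean(exp(-alpha * rs$ranks / rs$N))
  denom <- (1 / rs$N) * (1 - exp(-alpha)) / (exp(alpha / rs$N) - 1)
  num / denom
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' RIE rescaled to \[0, 1\] so that 0 is the worst possible and 1 the best
#' possible early recognition at the given prevalence Ra = N_a/N:
#' \deqn{BEDROC = RIE \cdot \frac{R_a \sinh(\alpha/2)}
#'   {\cosh(\alpha/2) - \cosh(\alpha/2 - \alpha R_a)}
#'   + \frac{1}{1 - e^{\alpha(1-R_a)}}.}
#' The result is clipped to \[0, 1\] against floating-point overshoot.
#'
#' @inheritParams rie
#' @return BEDROC in \[0, 1\].
#' @export
bedroc <- function(rs, alpha = 20) {
  r <- rie(rs, alpha)
  ra <- rs$Ra
  scale <- ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra))
  const <- 1 / (1 - exp(alpha * (1 - ra)))
  min(max(r * scale + const, 0), 1)
}

#' Total gain of the predictiveness curve
#'
#' Estimates the predictiveness curve R(p) — the probability of being
#' active as a function of score percentile p, best scores at the highest p
#' — by the active fraction within B equal-count bins of the score-ranked
#' list, and integrates its absolute deviation from the prevalence pi:
#' \deqn{TG = \frac{\sum_b w_b\,|R_b - \pi|}{2\pi(1-\pi)}, \qquad
#'   w_b = n_b / N.}
#' TG is 0 when scores carry no information about activity and 1 at
#' perfect separation (clipped to \[0, 1\]).
#'
#' @param scores Raw per-target scores (lower = better).
#' @param labels Logical active flags, same length, both classes present.
#' @param bins Number of equal-count bins B (default 10). Bin sizes differ
#'   by at most one when N is not divisible by B.
#' @return TG in \[0, 1\].
#' @export
total_gain <- function(scores, labels, bins = 10) {
  stopifnot(length(scores) == length(labels))
  n <- length(scores)
  if (n < 20L) stop("need at least 20 targets", call. = FALSE)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  labels <- labels[order(scores)]
  pi0 <- mean(labels)
  edges <- round(seq(0, n, length.out = bins + 1))
  sizes <- diff(edges)
  bin <- rep(seq_len(bins), times = sizes)
  rb <- tapply(labels, bin, mean)
  tg <- sum((sizes / n) * abs(rb - pi0)) / (2 * pi0 * (1 - pi0))
  min(max(tg, 0), 1)
}

#' Full retrospective enrichment report for one ligand
#'
#' Ranks the ligand's targets, labels its actives and aggregates all
#' retrospective metrics: ROC curve and AUC, enrichment factors at the
#' requested fractions, RIE and BEDROC at the given alpha, and total gain.
#'
#' @param matrix A `score_matrix`.
#' @param ligand Ligand identifier.
#' @param actives An `actives_set`.
#' @param alpha Early-recognition exponent for RIE/BEDROC (default 20).
#' @param fractions EF screening fractions (default 0.10).
#' @param bins Predictiveness-curve bin count (default 10).
#' @return An object of class `enrichment_report`: list with `ligand_id`,
#'   `n`, `n_actives`, `prevalence`, `auc`, `ef` (named by fraction),
#'   `rie`, `bedroc`, `tg`, `roc` (data frame of ROC points).
#' @export
evaluate_ligand <- function(matrix, ligand, actives, alpha = 20,
                            fractions = 0.10, bins = 10) {
  rs <- rank_targets(matrix, ligand, actives)
  ef <- vapply(fractions, function(f) enrichment_factor(rs, f), numeric(1))
  names(ef) <- .num_chr(fractions)
  structure(list(ligand_id = ligand, n = rs$N, n_actives = rs$N_a,
                 prevalence = rs$Ra, auc = roc_auc(rs), ef = ef,
                 rie = rie(rs, alpha), bedroc = bedroc(rs, alpha),
                 tg = total_gain(rs$scores, rs$labels, bins),
                 alpha = alpha, roc = roc_points(rs)),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("Retrospective enrichment for %s (N = %d, actives = %d)\n",
              x$ligand_id, x$n, x$n_actives))
  cat(sprintf("  AUC %.3f | EF@%s %.2f | RIE %.2f | BEDROC %.3f | TG %.3f\n",
              x$auc, names(x$ef)[1], x$ef[1], x$rie, x$bedroc, x$tg))
  invisible(x)
}

#' Enrichment summary across ligands
#'
#' Evaluates every ligand appearing in both the score matrix and the
#' actives set; ligands with no usable actives are skipped with a warning
#' and the rest proceed.
#'
#' @inheritParams evaluate_ligand
#' @return Data frame with one row per evaluated ligand and columns
#'   `ligand_id`, `auc`, `ef` (first fraction), `rie`, `bedroc`, `tg`,
#'   `n`, `n_actives`.
#' @export
enrichment_summary <- function(matrix, actives, alpha = 20,
                               fractions = 0.10, bins = 10) {
  ligands <- intersect(rownames(matrix$scores), unique(actives$ligand_id))
  rows <- lapply(ligands, function(l) {
    rep <- tryCatch(
      evaluate_ligand(matrix, l, actives, alpha, fractions, bins),
      error = function(e) {
        warning(sprintf("skipping %s: %s", l, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(rep)) return(NULL)
    data.frame(ligand_id = rep$ligand_id, auc = rep$auc,
               ef = unname(rep$ef[1]), rie = rep$rie, bedroc = rep$bedroc,
               tg = rep$tg, n = rep$n, n_actives = rep$n_actives,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(ligand_id = character(), auc = numeric(),
                      ef = numeric(), rie = numeric(), bedroc = numeric(),
                      tg = numeric(), n = integer(), n_actives = integer())
  rownames(out) <- NULL
  out
}
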