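# shared fixtures and independent oracles for the dockfp test suite

options(dockfp.quiet = TRUE)

# wrap a plain numeric matrix as a score_matrix
make_score_matrix <- function(m) {
  structure(list(scores = m,
                 provenance = data.frame(),
                 counts = c(used = sum(!is.na(m)), unmapped = 0L,
                            duplicate = 0L, input = sum(!is.na(m))),
                 annotation = NULL),
            class = "score_matrix")
}

# wrap a Z matrix (rows = ligands) as a dock_fingerprints object
make_fps <- function(Z, annotation = NULL) {
  structure(list(Z = Z, mu = rep(0, nrow(Z)), sigma = rep(1, nrow(Z)),
                 n_targets = ncol(Z), n_dropped_targets = 0L,
                 annotation = annotation),
            class = "dock_fingerprints")
}

# row-standardized random fingerprint matrix with ligand/target names
random_Z <- function(nl, nt) {
  Z <- matrix(rnorm(nl * nt), nl, nt,
              dimnames = list(sprintf("L%02d", seq_len(nl)),
                              sprintf("P%05d", seq_len(nt))))
  t(apply(Z, 1L, function(x) (x - mean(x)) / sd(x)))
}

# brute-force Eq.-style RMSD by explicit double loop
oracle_rmsd <- function(Z) {
  nl <- nrow(Z)
  R <- matrix(0, nl, nl, dimnames = list(rownames(Z), rownames(Z)))
  for (l in seq_len(nl)) for (k in seq_len(nl)) {
    acc <- 0
    for (i in seq_len(ncol(Z))) acc <- acc + (Z[l, i] - Z[k, i])^2
    R[l, k] <- sqrt(acc / ncol(Z))
  }
  R
}

# direct-sum RIE: numerator and uniform-ranking denominator both as
# explicit sums (the implementation uses the closed-form denominator)
oracle_rie <- function(ranks, N, alpha) {
  mean(exp(-alpha * ranks / N)) / mean(exp(-alpha * seq_len(N) / N))
}

# BEDROC recomputed independently from oracle_rie and the Ra-dependent
# rescaling constants
oracle_bedroc <- function(ranks, N, alpha) {
  ra <- length(ranks) / N
  oracle_rie(ranks, N, alpha) * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

# brute-force tie-aware AUC by pair counting
oracle_auc <- function(scores, labels) {
  a <- scores[labels]
  i <- scores[!labels]
  wins <- 0
  for (x in a) for (y in i)
    wins <- wins + if (x < y) 1 else if (x == y) 0.5 else 0
  wins / (length(a) * length(i))
}

# brute-force hit table by scanning every (ligand, target) cell
oracle_hit_table <- function(Z, z_cut, min_ligands) {
  rows <- list()
  for (j in seq_len(ncol(Z))) {
    ligs <- character()
    for (l in seq_len(nrow(Z)))
      if (Z[l, j] < z_cut) ligs <- c(ligs, rownames(Z)[l])
    if (length(ligs) >= min_ligands)
      rows[[length(rows) + 1L]] <- data.frame(
        uniprot_id = colnames(Z)[j],
        hit_ligands = paste(sort(ligs), collapse = ","),
        n_hits = length(ligs), min_Z = min(Z[, j]),
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(uniprot_id = character(), hit_ligands = character(),
                      n_hits = integer(), min_Z = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_hits, out$min_Z, out$uniprot_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# run generator output through aggregation, fingerprints, RMSD, Ward and a
# k-way cut, returning the flat labels
pipeline_cut <- function(sim, k = 2) {
  sm <- aggregate_best(sim$records, sim$map)
  fps <- zscore_fingerprints(sm)
  cut_tree(ward_linkage(fingerprint_rmsd(fps)), k = k)
}

write_lines_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
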