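#' Configuration for the synthetic docking-score generator
#'
#' Bundles and validates the parameters of the simulated inverse-docking
#' study. Defaults emulate the shape of a real desk-scale campaign: 14
#' ligands in two structural classes of 7 (mirroring a rigid/flexible
#' scaffold split), 500 unique protein targets, multi-structure redundancy
#' per target following 1 + Geometric(p) with p chosen so the median is 4
#' structures per target, per-ligand score location and spread drawn from
#' realistic arbitrary-unit ranges, a planted affinity block per class
#' (targets whose mean score is shifted down for that class's ligands), and
#' planted actives per ligand on block-free targets.
#'
#' @param n_ligands Number of ligands (default 14).
#' @param n_targets Number of unique protein targets (default 500, >= 20).
#' @param class_assignment Character vector of class labels per ligand;
#'   default splits the ligands into two equal classes `"A"` and `"B"`.
#' @param block_fraction Fraction of targets forming each class's affinity
#'   block, in (0, 1) (default 0.10); blocks are disjoint across classes.
#' @param block_shift Mean score decrease on block targets, in units of the
#'   ligand's SD (default 2.0, >= 0).
#' @param mu_range,sigma_range Ranges for per-ligand base mean and SD of
#'   docking scores, arbitrary units (defaults -60..-40 and 4..7).
#' @param struct_p Success probability of the geometric structures-per-
#'   target law, structures = 1 + Geom(p) (default 0.17, giving median 4).
#' @param struct_noise Structure-level noise as a fraction of the ligand SD
#'   (default 0.25); the remaining variance sits between targets, so a
#'   ligand's marginal per-structure score is Normal(mean, sigma_l) while
#'   structures of one protein stay correlated.
#' @param active_shift Mean score decrease on planted active pairs, in SD
#'   units (default 1.0, >= 0).
#' @param n_actives Planted actives per ligand (default 25).
#' @param seed RNG seed (default 1).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_ligands = 14, n_targets = 500,
                             class_assignment = NULL,
                             block_fraction = 0.10, block_shift = 2.0,
                             mu_range = c(-60, -40), sigma_range = c(4, 7),
                             struct_p = 0.17, struct_noise = 0.25,
                             active_shift = 1.0, n_actives = 25, seed = 1) {
  if (is.null(class_assignment)) {
    half <- ceiling(n_ligands / 2)
    class_assignment <- rep(c("A", "B"), c(half, n_ligands - half))
  }
  cfg <- list(n_ligands = as.integer(n_ligands),
              n_targets = as.integer(n_targets),
              class_assignment = as.character(class_assignment),
              block_fraction = block_fraction, block_shift = block_shift,
              mu_range = mu_range, sigma_range = sigma_range,
              struct_p = struct_p, struct_noise = struct_noise,
              active_shift = active_shift, n_actives = as.integer(n_actives),
              seed = as.integer(seed))
  checks <- c(
    n_targets = cfg$n_targets >= 20L,
    n_ligands = cfg$n_ligands >= 2L,
    class_assignment = length(cfg$class_assignment) == cfg$n_ligands &&
      all(table(cfg$class_assignment) > 0L),
    block_fraction = cfg$block_fraction > 0 && cfg$block_fraction < 1,
    block_shift = cfg$block_shift >= 0,
    active_shift = cfg$active_shift >= 0,
    struct_p = cfg$struct_p > 0 && cfg$struct_p < 1,
    struct_noise = cfg$struct_noise >= 0 && cfg$struct_noise < 1,
    n_actives = cfg$n_actives >= 1L,
    sigma_range = all(cfg$sigma_range > 0))
  if (any(!checks))
    stop(sprintf("invalid synthetic config field(s): %s",
                 paste(names(checks)[!checks], collapse = ", ")),
         call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

# deterministic fabricated PDB id for the i-th structure: digit + base-36
.fake_pdb <- function(i) {
  alphabet <- c(0:9, LETTERS)
  lead <- 1L + (i - 1L) %/% 36L^3 %% 9L
  rest <- (i - 1L) %% 36L^3
  paste0(lead,
         alphabet[rest %/% 36L^2 + 1L],
         alphabet[(rest %/% 36L) %% 36L + 1L],
         alphabet[rest %% 36L + 1L])
}

#' Generate a synthetic inverse-docking dataset with ground truth
#'
#' Simulates per-structure docking records with the statistical structure
#' the analysis assumes. Each target gets a synthetic UniProt-style
#' accession and 1 + Geometric(p) structure chains under fabricated PDB
#' identifiers (consecutive structure pairs of a target share a PDB id as
#' chains A/B, emulating homomeric entries). For ligand l and target t the
#' target-level mean is
#' Normal(mu_l - Delta sigma_l \[block\] - delta sigma_l \[active\],
#' sigma_l sqrt(1 - w^2)) and each structure adds Normal(0, sigma_l w)
#' noise, so the marginal per-structure score is Normal(mean, sigma_l) and
#' the best-of-structures aggregate preserves the planted shifts.
#' Identical seeds give identical output.
#'
#' @param config A [synthetic_config()].
#' @return List with `records` (a `docking_records` data frame), `map` (a
#'   `chain_map`), and `truth` (class labels, per-class block target sets,
#'   planted active pairs, and the generating parameters).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nl <- config$n_ligands
  nt <- config$n_targets
  ligands <- sprintf("L%02d", seq_len(nl))
  targets <- sprintf("P%05d", seq_len(nt))
  classes <- unique(config$class_assignment)

  mu <- runif(nl, config$mu_range[1], config$mu_range[2])
  sigma <- runif(nl, config$sigma_range[1], config$sigma_range[2])
  m_per_target <- 1L + stats::rgeom(nt, config$struct_p)

  block_size <- round(config$block_fraction * nt)
  block_pool <- sample(targets, block_size * length(classes))
  blocks <- split(block_pool, rep(classes, each = block_size))
  block_member <- matrix(0, nl, nt, dimnames = list(ligands, targets))
  for (cl in classes)
    block_member[config$class_assignment == cl, targets %in% blocks[[cl]]] <- 1

  free_targets <- setdiff(targets, block_pool)
  if (length(free_targets) < config$n_actives)
    stop("n_actives exceeds the number of block-free targets", call. = FALSE)
  actives <- do.call(rbind, lapply(ligands, function(l)
    data.frame(ligand_id = l,
               uniprot_id = sort(sample(free_targets, config$n_actives)),
               stringsAsFactors = FALSE)))
  active_member <- matrix(0, nl, nt, dimnames = list(ligands, targets))
  active_member[cbind(match(actives$ligand_id, ligands),
                      match(actives$uniprot_id, targets))] <- 1

  # target-level means, then structure-level noise around them
  mean_mat <- mu - config$block_shift * sigma * block_member -
    config$active_shift * sigma * active_member
  sd_between <- sigma * sqrt(1 - config$struct_noise^2)
  b <- mean_mat + matrix(stats::rnorm(nl * nt), nl, nt) * sd_between

  n_struct <- sum(m_per_target)
  target_of_struct <- rep(seq_len(nt), m_per_target)
  # consecutive structure pairs of one target share a PDB id as chains A/B
  within <- sequence(m_per_target)
  pdb_counter <- cumsum(within %% 2L == 1L)
  pdb <- .fake_pdb(pdb_counter)
  chain <- ifelse(within %% 2L == 1L, "A", "B")

  noise <- matrix(stats::rnorm(nl * n_struct), nl, n_struct) *
    (sigma * config$struct_noise)
  score <- b[, target_of_struct, drop = FALSE] + noise

  records <- data.frame(
    ligand_id = rep(ligands, each = n_struct),
    pdb_id = rep(pdb, times = nl),
    chain = rep(chain, times = nl),
    score = as.vector(t(score)),
    stringsAsFactors = FALSE)
  class(records) <- c("docking_records", "data.frame")

  map <- data.frame(pdb_id = pdb, chain = chain,
                    uniprot_id = targets[target_of_struct],
                    target_name = paste0("synthetic protein ",
                                         target_of_struct),
                    target_class = NA_character_,
                    stringsAsFactors = FALSE)
  map <- unique(map)
  rownames(map) <- NULL
  class(map) <- c("chain_map", "data.frame")

  truth <- list(ligands = ligands,
                class_assignment = stats::setNames(config$class_assignment,
                                                   ligands),
                blocks = blocks,
                actives = actives,
                params = unclass(config))
  list(records = records, map = map, truth = truth)
}

#' Write a synthetic fixture directory
#'
#' Writes `scores.csv`, `chain_map.tsv`, `actives.csv` (pChEMBL set to 6.0
#' for every planted pair) and `truth.json` so the fixture round-trips
#' through the package's own readers.
#'
#' @param sim Output of [generate_synthetic()].
#' @param out_dir Directory, created if needed.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(scores = file.path(out_dir, "scores.csv"),
             chain_map = file.path(out_dir, "chain_map.tsv"),
             actives = file.path(out_dir, "actives.csv"),
             truth = file.path(out_dir, "truth.json"))
  utils::write.csv(as.data.frame(sim$records), paths[["scores"]],
                   row.names = FALSE)
  utils::write.table(as.data.frame(sim$map), paths[["chain_map"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  act <- sim$truth$actives
  act$pchembl <- 6.0
  utils::write.csv(act, paths[["actives"]], row.names = FALSE)
  truth <- sim$truth
  truth$class_assignment <- as.list(truth$class_assignment)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
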