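test_that("actives are filtered by strict pChEMBL and deduplicated by max", {
  f <- write_lines_tmp(c("ligand_id,uniprot_id,pchembl",
                         "THC,P01116,3.9", "THC,P01116,4.1",
                         "CBD,P08631,4.0", "CBD,P23456,oops",
                         "CBD,P34567,5.2"))
  act <- read_actives(f)
  expect_equal(nrow(act), 2L)
  expect_equal(act$pchembl[act$ligand_id == "THC"], 4.1)
  expect_false("P08631" %in% act$uniprot_id)  # 4.0 is not > 4
  # boundary-only file yields an empty set
  g <- write_lines_tmp(c("ligand_id,uniprot_id,pchembl", "A,P01116,4.0"))
  expect_equal(nrow(read_actives(g)), 0L)
})

test_that("actives filtering equals a brute-force row filter", {
  set.seed(51)
  n <- 100
  df <- data.frame(ligand_id = sample(c("A", "B"), n, TRUE),
                   uniprot_id = sprintf("P%05d", sample(30, n, TRUE)),
                   pchembl = round(runif(n, 3, 7), 2))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  got <- read_actives(f)
  agg <- aggregate(pchembl ~ ligand_id + uniprot_id, df, max)
  agg <- agg[agg$pchembl > 4, ]
  expect_equal(nrow(got), nrow(agg))
  expect_setequal(paste(got$ligand_id, got$uniprot_id),
                  paste(agg$ligand_id, agg$uniprot_id))
})

test_that("target ranking is score-ascending with accession tie-breaks", {
  m <- matrix(c(-60, -50, -40), 1,
              dimnames = list("L", c("T1", "T2", "T3")))
  act <- data.frame(ligand_id = "L", uniprot_id = "T2")
  rs <- rank_targets(make_score_matrix(m), "L", act)
  expect_equal(rs$ranks, 2L)
  expect_equal(rs$ranks / rs$N, 2 / 3)
  # identical scores: accession order, reproducibly
  m2 <- matrix(c(-50, -50, -40), 1,
               dimnames = list("L", c("TB", "TA", "TC")))
  rs2 <- rank_targets(make_score_matrix(m2), "L", act = data.frame(
    ligand_id = "L", uniprot_id = "TC"))
  expect_equal(rs2$targets, c("TA", "TB", "TC"))
  expect_identical(rank_targets(make_score_matrix(m2), "L", data.frame(
    ligand_id = "L", uniprot_id = "TC"))$targets, rs2$targets)
  # actives absent from the matrix are dropped; none usable is fatal
  expect_error(rank_targets(make_score_matrix(m), "L",
                            data.frame(ligand_id = "L",
                                       uniprot_id = "NOPE")),
               "no usable actives")
})

test_that("ranks match an independent sort oracle on a large screen", {
  set.seed(52)
  s <- rnorm(500, -50, 6)
  names(s) <- sprintf("P%05d", sample(99999, 500))
  m <- matrix(s, 1, dimnames = list("L", names(s)))
  actives <- data.frame(ligand_id = "L",
                        uniprot_id = sample(names(s), 25))
  rs <- rank_targets(make_score_matrix(m), "L", actives)
  oracle_order <- names(sort(s))
  expect_equal(rs$ranks, sort(match(actives$uniprot_id, oracle_order)))
})

test_that("ROC points are stepwise-exact and bound the unit square", {
  first <- ranked_screen(1, 2)
  expect_equal(roc_points(first),
               data.frame(FPF = c(0, 0, 1), TPF = c(0, 1, 1)))
  last <- ranked_screen(2, 2)
  expect_equal(roc_points(last),
               data.frame(FPF = c(0, 1, 1), TPF = c(0, 0, 1)))
  set.seed(53)
  for (rep in 1:20) {
    rs <- ranked_screen(sample(50, 8), 50)
    pts <- roc_points(rs)
    expect_equal(pts[1, ], data.frame(FPF = 0, TPF = 0))
    expect_equal(unlist(pts[nrow(pts), ]), c(FPF = 1, TPF = 1))
    expect_false(is.unsorted(pts$FPF))
    expect_false(is.unsorted(pts$TPF))
    # trapezoid area over the step points equals the rank AUC
    area <- sum(diff(pts$FPF) * (utils::head(pts$TPF, -1) +
                                   utils::tail(pts$TPF, -1)) / 2)
    expect_equal(area, roc_auc(rs), tolerance = 1e-12)
  }
})

test_that("AUC is the tie-aware Mann-Whitney probability", {
  # labels A,I,A,I on ascending scores: 3 of 4 pairs won
  rs <- ranked_screen(c(1, 3), 4)
  expect_equal(roc_auc(rs), 0.75)
  expect_equal(roc_auc(ranked_screen(1:10, 100)), 1.0)
  # all raw scores identical: pure ties give 0.5
  tied <- ranked_screen(c(2, 5), 10, scores = rep(-50, 10))
  expect_equal(roc_auc(tied), 0.5)
  # invariant under strictly increasing transforms of the scores
  set.seed(54)
  for (rep in 1:10) {
    sc <- sort(rnorm(40))
    lab <- seq_len(40) %in% sample(40, 6)
    rs1 <- ranked_screen(which(lab), 40, scores = sc)
    rs2 <- ranked_screen(which(lab), 40, scores = exp(sc) + sc^3)
    expect_identical(roc_auc(rs1), roc_auc(rs2))
    expect_equal(roc_auc(rs1), oracle_auc(sc, lab), tolerance = 1e-12)
  }
  # ties against the brute-force pair count
  sc <- c(-5, -5, -5, -3, -3, 0)
  lab <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  rs3 <- ranked_screen(which(lab), 6, scores = sc)
  expect_equal(roc_auc(rs3), oracle_auc(sc, lab), tolerance = 1e-12)
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(62)
  for (rep in 1:10) {
    sc <- sort(round(rnorm(60), 1))  # rounding induces ties
    lab <- seq_len(60) %in% sample(60, 9)
    rs <- ranked_screen(which(lab), 60, scores = sc)
    ref <- suppressMessages(
      pROC::auc(pROC::roc(lab, sc, direction = ">", quiet = TRUE)))
    expect_equal(roc_auc(rs), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("enrichment factor handles analytic and oracle cases", {
  expect_equal(enrichment_factor(ranked_screen(1:10, 100), f = 0.10), 10.0)
  expect_equal(enrichment_factor(ranked_screen(seq(10, 100, 10), 100),
                                 f = 0.10), 1.0)
  set.seed(55)
  for (rep in 1:20) {
    rs <- ranked_screen(sample(200, 20), 200)
    f <- runif(1, 0.02, 0.5)
    n <- ceiling(f * 200)
    brute <- (sum(rs$ranks <= n) / n) / (20 / 200)
    expect_equal(enrichment_factor(rs, f), brute, tolerance = 1e-12)
    expect_lte(enrichment_factor(rs, f), min(1 / f, 200 / 20) + 1e-12)
  }
})

test_that("RIE and BEDROC match direct-sum oracles and frozen references", {
  set.seed(56)
  for (rep in 1:100) {
    rs <- ranked_screen(sample(200, 20), 200)
    expect_equal(rie(rs, 20), oracle_rie(rs$ranks, 200, 20),
                 tolerance = 1e-9)
    expect_equal(bedroc(rs, 20), oracle_bedroc(rs$ranks, 200, 20),
                 tolerance = 1e-6)
  }
  # vanishing exponent: every ranking is average
  expect_equal(rie(ranked_screen(sample(200, 20), 200), alpha = 1e-6), 1,
               tolerance = 1e-3)
  expect_error(rie(ranked_screen(1, 10), alpha = 0), "positive")
  # frozen cross-implementation reference values (RDKit CalcRIE/CalcBEDROC,
  # alpha = 20) for three fixed screens with N = 200, N_a = 20
  fixed <- list(
    list(r = c(20, 24, 47, 49, 65, 71, 74, 89, 100, 110, 111, 114, 122,
               128, 131, 146, 153, 154, 165, 200),
         rie = 0.258479077797, bedroc = 0.029893546539),
    list(r = c(3, 5, 24, 27, 36, 41, 42, 43, 58, 89, 92, 104, 109, 136,
               143, 150, 158, 162, 164, 190),
         rie = 1.662803990617, bedroc = 0.192306202461),
    list(r = c(2, 3, 4, 6, 68, 92, 99, 102, 109, 114, 116, 118, 130, 134,
               138, 146, 149, 154, 177, 178),
         rie = 2.923788306325, bedroc = 0.338141265216))
  for (case in fixed) {
    rs <- ranked_screen(case$r, 200)
    expect_equal(rie(rs, 20), case$rie, tolerance = 1e-9)
    expect_equal(bedroc(rs, 20), case$bedroc, tolerance = 1e-9)
  }
  # extremes of the BEDROC scale
  expect_equal(bedroc(ranked_screen(1:10, 100), 20), 1.0, tolerance = 0.01)
  expect_equal(bedroc(ranked_screen(91:100, 100), 20), 0.0,
               tolerance = 0.01)
})

test_that("mean RIE over random rankings is the uniform expectation", {
  set.seed(57)
  vals <- replicate(1000, rie(ranked_screen(sample(200, 20), 200), 20))
  expect_equal(mean(vals), 1.0, tolerance = 0.05)
})

test_that("total gain integrates the binned predictiveness curve", {
  # labels independent of scores, one bin: flat curve, zero gain
  expect_equal(total_gain(1:20, rep(c(TRUE, FALSE), 10), bins = 1), 0)
  # perfect separation at prevalence 0.5 with two bins
  expect_equal(total_gain(1:20, rep(c(TRUE, FALSE), each = 10), bins = 2),
               1.0)
  # toy 20-item screen, 4 bins, hand-computed bin sum
  lab <- seq_len(20) %in% c(1, 2, 3, 5, 9, 12, 17)
  pi0 <- 7 / 20
  hand <- 0.25 * (abs(4 / 5 - pi0) + 3 * abs(1 / 5 - pi0)) /
    (2 * pi0 * (1 - pi0))
  expect_equal(total_gain(1:20, lab, bins = 4), hand, tolerance = 1e-12)
  expect_error(total_gain(1:20, rep(TRUE, 20)), "both classes")
  expect_error(total_gain(1:10, rep(c(TRUE, FALSE), 5)), "at least 20")
})

test_that("per-ligand report aggregates consistent metrics", {
  set.seed(58)
  s <- rnorm(500, -50, 6)
  names(s) <- sprintf("P%05d", 1:500)
  act_idx <- sample(500, 50)
  actives <- data.frame(ligand_id = "L",
                        uniprot_id = names(s)[act_idx])
  # null: actives carry no signal
  m <- matrix(s, 1, dimnames = list("L", names(s)))
  rep0 <- evaluate_ligand(make_score_matrix(m), "L", actives)
  expect_equal(rep0$auc, 0.5, tolerance = 0.05)
  expect_equal(rep0$n_actives, 50L)
  area <- with(rep0$roc, sum(diff(FPF) * (utils::head(TPF, -1) +
                                            utils::tail(TPF, -1)) / 2))
  expect_equal(area, rep0$auc, tolerance = 1e-12)
  # forced perfect separation
  m2 <- m
  m2[1, act_idx] <- m2[1, act_idx] - 1000
  rep1 <- evaluate_ligand(make_score_matrix(m2), "L", actives)
  expect_equal(rep1$auc, 1.0)
  expect_equal(unname(rep1$ef["0.1"]), min(1 / 0.1, 500 / 50))
  expect_gt(rep1$bedroc, 0.99)
  expect_equal(rep1$tg, 1.0, tolerance = 1e-12)
})

test_that("metric ranges hold over a thousand random screens", {
  set.seed(59)
  ok <- vapply(1:1000, function(rep) {
    N <- sample(25:150, 1)
    na <- sample(2:(N %/% 3), 1)
    rs <- ranked_screen(sample(N, na), N)
    f <- runif(1, 0.05, 0.5)
    ef <- enrichment_factor(rs, f)
    b <- bedroc(rs, 20)
    tg <- total_gain(rs$scores, rs$labels, bins = 5)
    a <- roc_auc(rs)
    ef >= 0 && ef <= min(1 / f, N / na) + 1e-12 &&
      b >= 0 && b <= 1 && tg >= 0 && tg <= 1 && a >= 0 && a <= 1
  }, logical(1))
  expect_true(all(ok))
})

test_that("stronger planted active shifts never degrade mean AUC or BEDROC", {
  set.seed(60)
  deltas <- c(0, 0.5, 1, 2)
  n_seeds <- 50
  mean_auc <- mean_bed <- numeric(length(deltas))
  for (d in seq_along(deltas)) {
    auc_v <- bed_v <- numeric(n_seeds)
    for (s in seq_len(n_seeds)) {
      sc <- rnorm(200, -50, 6)
      lab <- seq_len(200) %in% sample(200, 20)
      sc[lab] <- sc[lab] - deltas[d] * 6
      o <- order(sc)
      rs <- ranked_screen(which(lab[o]), 200, scores = sc[o])
      auc_v[s] <- roc_auc(rs)
      bed_v[s] <- bedroc(rs, 20)
    }
    mean_auc[d] <- mean(auc_v)
    mean_bed[d] <- mean(bed_v)
  }
  expect_false(is.unsorted(mean_auc))
  expect_false(is.unsorted(mean_bed))
})

test_that("the cross-ligand summary skips unusable ligands and keeps going", {
  set.seed(61)
  m <- matrix(rnorm(2 * 100, -50, 5), 2, 100,
              dimnames = list(c("GOOD", "BARE"), sprintf("P%05d", 1:100)))
  actives <- data.frame(
    ligand_id = c(rep("GOOD", 10), "BARE"),
    uniprot_id = c(sprintf("P%05d", 1:10), "Q99999"))  # BARE: not scored
  out <- suppressWarnings(
    enrichment_summary(make_score_matrix(m), actives))
  expect_equal(out$ligand_id, "GOOD")
  expect_equal(out$n_actives, 10L)
  expect_warning(enrichment_summary(make_score_matrix(m), actives),
                 "BARE")
})
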