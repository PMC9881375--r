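trans_tbl <- function(n, peptide = "PEP") {
  tibble::tibble(run = "r1", condition = "c1", replicate = 1L,
                 peptide = peptide, charge = 2L, variant = "none",
                 fragment = paste0("y", seq_len(n)),
                 area = 10 * seq_len(n), detected = TRUE)
}

test_that("transition retention enforces the five-transition floor", {
  key <- c("peptide", "charge", "variant", "fragment")

  # 6 transitions, 1 flagged -> 5 remain
  rep6 <- trans_tbl(6)
  out <- retain_transitions(rep6, rep6[1, key])
  expect_equal(nrow(out), 5)
  expect_equal(nrow(attr(out, "refused")), 0)

  # 5 transitions, 1 flagged -> removal refused, all retained
  rep5 <- trans_tbl(5)
  out <- retain_transitions(rep5, rep5[1, key])
  expect_equal(nrow(out), 5)
  expect_equal(nrow(attr(out, "refused")), 1)

  # no flags -> identity
  expect_equal(nrow(retain_transitions(rep6)), 6)

  # fewer than five transitions in input -> warning, retained as-is
  expect_warning(retain_transitions(trans_tbl(3)), "fewer than 5")

  # flagging two of seven: one removed after the other hits the floor?
  # both still above floor here (7 -> 5), so both removed
  rep7 <- trans_tbl(7)
  out <- retain_transitions(rep7, rep7[1:2, key])
  expect_equal(nrow(out), 5)
  # a third flag would cross the floor and is refused
  out <- retain_transitions(rep7, rep7[1:3, key])
  expect_equal(nrow(out), 5)
  expect_equal(nrow(attr(out, "refused")), 1)
})

test_that("peptide areas sum over fragments, charges, and oxidation variants", {
  # one charge state: plain fragment sum
  r <- trans_tbl(5)
  r$area <- c(10, 20, 30, 15, 25)
  q <- aggregate_peptide_areas(r)
  expect_equal(q$area, 100)

  # 2+ variant totalling 100 plus Met-ox variant totalling 40 -> 140
  r2 <- dplyr::bind_rows(
    r,
    dplyr::mutate(r, variant = "metox", area = c(10, 10, 10, 5, 5)))
  q <- aggregate_peptide_areas(r2)
  expect_equal(q$area, 140)

  # aggregation is invariant to fragment row order
  perm <- r2[sample(nrow(r2)), ]
  expect_equal(aggregate_peptide_areas(perm)$area, 140)

  # a peptide absent from a run gets area 0 and detected FALSE
  r3 <- dplyr::bind_rows(
    r, dplyr::mutate(trans_tbl(5, "OTHER"), run = "r2", replicate = 2L))
  q <- aggregate_peptide_areas(r3)
  missing_cell <- q[q$peptide == "PEP" & q$run == "r2", ]
  expect_equal(missing_cell$area, 0)
  expect_false(missing_cell$detected)
})

test_that("median normalization equalizes MS1 medians and removes scaling", {
  base <- tibble::tibble(
    peptide = rep(c("A", "B", "C"), 2),
    run = rep(c("r1", "r2"), each = 3),
    condition = rep(c("c1", "c2"), each = 3),
    replicate = 1L,
    area = c(10, 20, 30, 10, 20, 30),
    detected = TRUE)
  ms1 <- tibble::tibble(run = rep(c("r1", "r2"), each = 5),
                        feature = rep(1:5, 2),
                        area = c(1:5, 3 * (1:5)))
  # run 2 scaled by 3: normalization makes the runs identical
  scaled <- base
  scaled$area[scaled$run == "r2"] <- scaled$area[scaled$run == "r2"] * 3
  qn <- median_normalize(scaled, ms1)
  expect_equal(qn$area[qn$run == "r1"] * 1, qn$area[qn$run == "r2"],
               tolerance = 1e-12)

  # already-equal medians: identity up to floating tolerance
  ms1_eq <- tibble::tibble(run = rep(c("r1", "r2"), each = 5),
                           feature = rep(1:5, 2), area = rep(1:5, 2))
  qn <- median_normalize(base, ms1_eq)
  expect_equal(qn$area, base$area, tolerance = 1e-12)

  # random matrices: post-normalization MS1 medians all equal
  set.seed(12)
  runs <- paste0("r", 1:6)
  ms1_r <- tibble::tibble(run = rep(runs, each = 20),
                          feature = rep(1:20, 6),
                          area = rlnorm(120, 4, 1))
  q <- tibble::tibble(peptide = rep("A", 6), run = runs,
                      condition = "c1", replicate = 1:6,
                      area = rlnorm(6), detected = TRUE)
  qn <- median_normalize(q, ms1_r)
  f <- attr(qn, "norm_factors")
  post_med <- vapply(runs, function(r) {
    median(ms1_r$area[ms1_r$run == r]) / f$factor[f$run == r]
  }, double(1))
  expect_lt(diff(range(post_med)), 1e-9)

  # a run without MS1 features is an error; absent table warns
  expect_error(median_normalize(q, ms1_r[ms1_r$run != "r3", ]), "r3")
  expect_warning(median_normalize(q), "no MS1 feature table")
})

test_that("detection policy keeps complete and on/off patterns only", {
  mk <- function(det1, det2) {
    tibble::tibble(
      peptide = "P",
      run = paste0("r", 1:8),
      condition = rep(c("L3", "dauer"), each = 4),
      replicate = rep(1:4, 2),
      area = ifelse(c(det1, det2), 100, 1),
      detected = c(det1, det2))
  }
  all4 <- rep(TRUE, 4); none <- rep(FALSE, 4)
  expect_equal(apply_detection_policy(mk(all4, all4))$classes$class,
               "quantifiable")
  expect_equal(apply_detection_policy(mk(none, all4))$classes$class, "on_off")
  expect_equal(apply_detection_policy(mk(all4, none))$classes$class, "on_off")
  expect_equal(apply_detection_policy(
    mk(c(TRUE, TRUE, TRUE, FALSE), all4))$classes$class, "dropped")
  # dropped peptides leave the matrix
  pol <- apply_detection_policy(mk(c(TRUE, TRUE, TRUE, FALSE), all4))
  expect_equal(nrow(pol$quant), 0)

  # zero areas are replaced by the dataset minimum
  q <- mk(all4, all4)
  q$area <- c(7.2, 10, 12, 9, 0, 11, 13, 8)
  pol <- apply_detection_policy(q)
  expect_equal(pol$imputation_floor, 7.2)
  expect_equal(sort(pol$quant$area)[1], 7.2)
  expect_true(all(pol$quant$area > 0))
})

test_that("differential t test matches the pooled-variance formula", {
  mk_quant <- function(x1, x2) {
    tibble::tibble(
      peptide = "P",
      run = paste0("r", seq_len(length(x1) + length(x2))),
      condition = rep(c("c1", "c2"), c(length(x1), length(x2))),
      replicate = c(seq_along(x1), seq_along(x2)),
      area = 10^c(x1, x2),
      detected = TRUE)
  }
  x1 <- c(2.0, 2.1, 1.9, 2.0); x2 <- c(2.8, 2.9, 2.7, 2.8)
  dt <- differential_test(mk_quant(x1, x2), conditions = c("c1", "c2"))
  # textbook pooled-variance two-sample t, computed from first principles
  n1 <- 4; n2 <- 4
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  t_hand <- (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_hand <- 2 * pt(-abs(t_hand), n1 + n2 - 2)
  expect_equal(dt$t, t_hand, tolerance = 1e-12)
  expect_equal(dt$p, p_hand, tolerance = 1e-12)
  expect_equal(dt$fold_change, 10^(mean(x2) - mean(x1)), tolerance = 1e-12)

  # identical symmetric groups: t = 0, p = 1
  dt0 <- differential_test(mk_quant(c(1, 2, 3), c(3, 2, 1)),
                           conditions = c("c1", "c2"))
  expect_equal(dt0$t, 0)
  expect_equal(dt0$p, 1)

  # swapping condition labels negates t, keeps p
  dt_sw <- differential_test(mk_quant(x1, x2), conditions = c("c2", "c1"))
  expect_equal(dt_sw$t, -dt$t, tolerance = 1e-12)
  expect_equal(dt_sw$p, dt$p, tolerance = 1e-12)

  # constant data: degenerate, flagged, p undefined
  dtc <- differential_test(mk_quant(c(2, 2, 2), c(2, 2, 2)),
                           conditions = c("c1", "c2"))
  expect_true(dtc$degenerate)
  expect_true(is.na(dtc$p))
})

test_that("the pipeline is invariant to rescaling one run's raw areas", {
  cfg <- sim_config(seed = 19, n_precursors = 6, n_decoys = 0)
  prot <- generate_proteome(cfg)
  rep <- generate_transition_report(cfg, prot$ground_truth)
  run_pipeline <- function(report, ms1) {
    q <- median_normalize(aggregate_peptide_areas(report), ms1)
    pol <- apply_detection_policy(q)
    differential_test(pol$quant, conditions = c("L3", "dauer"))
  }
  base <- run_pipeline(rep$report, rep$ms1)
  r2 <- rep$report
  pick <- r2$run == r2$run[1]
  r2$area[pick] <- r2$area[pick] * 37.5
  ms1_2 <- rep$ms1
  ms1_2$area[ms1_2$run == r2$run[1]] <- ms1_2$area[ms1_2$run == r2$run[1]] * 37.5
  rescaled <- run_pipeline(r2, ms1_2)
  expect_equal(rescaled$t, base$t, tolerance = 1e-9)
  expect_equal(rescaled$p, base$p, tolerance = 1e-9)
  expect_equal(rescaled$fold_change, base$fold_change, tolerance = 1e-9)
})

test_that("per-peptide CV follows the closed form and the configured level", {
  q2 <- tibble::tibble(peptide = "P", run = c("r1", "r2"),
                       condition = "c1", replicate = 1:2,
                       area = c(90, 110), detected = TRUE)
  cv <- compute_cv(q2)
  expect_equal(cv$per_peptide$cv_percent, 100 * sd(c(90, 110)) / 100,
               tolerance = 1e-12)
  expect_equal(cv$per_peptide$cv_percent, 14.14, tolerance = 1e-3)

  # identical replicates: zero CV
  q0 <- tibble::tibble(peptide = "P", run = c("r1", "r2", "r3"),
                       condition = "c1", replicate = 1:3,
                       area = 50, detected = TRUE)
  expect_equal(compute_cv(q0)$median_cv, 0)

  expect_error(compute_cv(q0[1, ]), ">=2 replicates")
})

test_that("fold-change estimates recover the simulated truth", {
  cfg <- sim_config(seed = 47, n_precursors = 20, n_decoys = 0,
                    n_replicates_per_condition = 8,
                    dropout_threshold = 0)
  prot <- generate_proteome(cfg)
  rep <- generate_transition_report(cfg, prot$ground_truth)
  q <- median_normalize(aggregate_peptide_areas(rep$report), rep$ms1)
  pol <- apply_detection_policy(q)
  dt <- differential_test(pol$quant, conditions = c("L3", "dauer"))
  truth <- rep$truth
  j <- match(dt$peptide, truth$peptide)
  # 95% CI for the log10 fold change from the pooled t
  n <- cfg$n_replicates_per_condition
  sigma10 <- nemapep:::cv_to_sigma10(cfg$technical_cv_percent)
  half <- qt(0.975, 2 * n - 2) * sigma10 * sqrt(2 / n)
  delta <- log10(dt$fold_change) - log10(truth$fold_change[j])
  expect_gt(mean(abs(delta) <= half), 0.9)
  expect_lt(abs(mean(delta)), 0.05)
})

test_that("the null pipeline has nominal type-I error", {
  cfg <- sim_config(seed = 53, n_precursors = 500, n_decoys = 0,
                    n_peptides_per_precursor = c(4, 4),
                    fold_changes = 1, dropout_threshold = 0)
  prot <- generate_proteome(cfg)
  rep <- generate_transition_report(cfg, prot$ground_truth)
  q <- median_normalize(aggregate_peptide_areas(rep$report), rep$ms1)
  pol <- apply_detection_policy(q)
  dt <- differential_test(pol$quant, conditions = c("L3", "dauer"))
  n_pep <- nrow(dt)
  expect_gte(n_pep, 2000)
  frac <- mean(dt$p < 0.05)
  # binomial 95% interval around 0.05
  half <- 1.96 * sqrt(0.05 * 0.95 / n_pep)
  expect_lt(abs(frac - 0.05), half + 0.005)
})
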