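test_that("enrichment calls interpret state paths correctly", {
  calls <- call_enrichment(c(a = "0MMMMM", b = "000000", c = "0MMFFF",
                             d = "0MM000", e = "FFFFFF", f = "00000M"))
  expect_equal(calls$class,
               c("male_enriched", "none", "switch", "none",
                 "female_enriched", "male_enriched"))
  expect_equal(calls$onset, c(2L, NA, 2L, NA, 1L, 6L))
  expect_true(calls$persists[calls$id == "a"])
  # relapsing paths are flagged, not called enriched
  expect_true(calls$relapsed[calls$id == "d"])
  expect_equal(calls$first_dimorphic[calls$id == "d"], 2L)
  # onset at stage 1 is left-censored
  expect_true(calls$left_censored[calls$id == "e"])
  expect_false(any(calls$left_censored[calls$id != "e"]))
  # class none implies null onset
  expect_true(all(is.na(calls$onset[calls$class == "none"])))
})

test_that("mechanism classification follows the activation/repression rules", {
  # gene "act": XY rises 1.2 from stage 1 to 6, XX flat
  # gene "rep": XX falls 1.2, XY flat (male enrichment via repression)
  # gene "none": both flat
  T_ <- 6
  means <- matrix(8, 3, 4 * T_)
  rownames(means) <- c("act", "rep", "none")
  xx_a <- seq_len(T_); xy_a <- T_ + seq_len(T_)
  ramp <- seq(0, 1.2, length.out = T_)
  means["act", xy_a] <- 8 + ramp
  means["rep", xx_a] <- 8 - ramp
  means["rep", xy_a] <- 8            # XY flat but dimorphic (XX falls)
  ds <- manual_dataset(means, n_reps = 3, noise_sd = 0.05, seed = 14)
  calls <- call_enrichment(c(act = "00MMMM", rep = "00MMMM",
                             none = "00MMMM"))
  out <- classify_mechanism(ds, calls, strain = "A")
  expect_equal(out$mechanism[out$id == "act"], "activated_in_XY")
  expect_equal(out$mechanism[out$id == "rep"], "repressed_in_XX")
  expect_equal(out$mechanism[out$id == "none"], "unclassified")
  expect_equal(out$ref_stage[out$id == "act"], 2L)
})

test_that("mechanism calls mirror exactly when the sexes are swapped", {
  s <- simulate_timecourse(sim_config(n_genes = 400, seed = 15))
  kept <- filter_detected(s$dataset)
  fds <- fold_differences(s$dataset, probes = kept)
  syms <- quantize_series(fds)
  fit <- dimorphism_hmm(syms, n_iter = 60)
  calls <- classify_mechanism(s$dataset,
                              call_enrichment(predict(fit, syms$A)), "A")
  # swap the sex labels: XX <-> XY
  ds_sw <- s$dataset
  ds_sw$design$sex <- ifelse(ds_sw$design$sex == "XX", "XY", "XX")
  calls_sw_in <- call_enrichment(
    data.frame(id = calls$id, path = chartr("MF", "FM", calls$path)))
  calls_sw <- classify_mechanism(ds_sw, calls_sw_in, "A")
  swap_mech <- c(activated_in_XY = "activated_in_XX",
                 activated_in_XX = "activated_in_XY",
                 repressed_in_XY = "repressed_in_XX",
                 repressed_in_XX = "repressed_in_XY",
                 combination = "combination",
                 unclassified = "unclassified")
  got <- calls$mechanism[!is.na(calls$mechanism)]
  got_sw <- calls_sw$mechanism[!is.na(calls_sw$mechanism)]
  expect_identical(unname(swap_mech[got]), got_sw)
})

test_that("onset matrices conserve cohort sizes and detect planted delays", {
  callsA <- call_enrichment(c(g1 = "0MMMMM", g2 = "0MMMMM", g3 = "00MMMM",
                              g4 = "000MMM", g5 = "000000"))
  # identical calls in both strains: all mass on the diagonal, offset 0
  om0 <- compare_strain_onsets(callsA, callsA, "male_enriched")
  expect_equal(om0$modal_offset, 0L)
  expect_true(all(om0$counts[upper.tri(om0$counts)] == 0))
  expect_true(all(om0$counts[lower.tri(om0$counts)] == 0))

  # one-stage delay in strain B
  callsB <- call_enrichment(c(g1 = "00MMMM", g2 = "00MMMM", g3 = "000MMM",
                              g4 = "0000MM", g5 = "000000"))
  om1 <- compare_strain_onsets(callsA, callsB, "male_enriched")
  expect_equal(om1$modal_offset, 1L)
  # marginals: row sums equal strain-A onset cohort sizes
  expect_equal(unname(rowSums(om1$counts)[c("2", "3", "4")]), c(2, 1, 1))
  expect_equal(sum(om1$counts), om1$universe_size)

  callsC <- call_enrichment(c(x1 = "0MMMMM"))
  expect_error(compare_strain_onsets(callsA, callsC), "disjoint")
})

test_that("onset-cell and gene-set hypergeometric p-values match enumeration", {
  # k = 5 overlap, cohorts of 10 and 10 in a universe of 100
  p_pkg <- stats::phyper(4, 10, 90, 10, lower.tail = FALSE)
  expect_equal(p_pkg, hyper_tail_oracle(5, 10, 10, 100), tolerance = 1e-12)

  # the generic overlap operation, k = 3, |a| = 5, |b| = 10, N = 50
  universe <- sprintf("u%02d", 1:50)
  a <- universe[1:5]; b <- universe[c(1:3, 11:17)]
  res <- test_gene_set_overlap(a, b, universe)
  expect_equal(res$overlap, 3L)
  expect_equal(res$fraction, 3 / 5)
  expect_equal(res$p_value, hyper_tail_oracle(3, 5, 10, 50),
               tolerance = 1e-12)

  expect_equal(test_gene_set_overlap(a, a, universe)$fraction, 1)
  disj <- test_gene_set_overlap(universe[1:5], universe[40:44], universe)
  expect_equal(disj$overlap, 0L)
  expect_gt(disj$p_value, 0.5)
  expect_error(test_gene_set_overlap(a, b, character(0)), "empty universe")
  expect_error(test_gene_set_overlap(c(a, "zz"), b, universe), "subsets")
})

test_that("scatter classification assigns the quadrant classes", {
  T_ <- 6
  means <- matrix(8, 5, 4 * T_)
  rownames(means) <- c("both_up", "male_act", "fem_rep", "male_rep", "flat")
  xx_a <- seq_len(T_); xy_a <- T_ + seq_len(T_)
  means["both_up", c(xx_a[T_], xy_a[T_])] <- 9
  means["male_act", xy_a[T_]] <- 9
  means["fem_rep", xy_a[T_]] <- 7     # XY falls, XX flat
  means["male_rep", xx_a[T_]] <- 7    # XX falls, XY flat
  ds <- manual_dataset(means, n_reps = 3, noise_sd = 0.05, seed = 16)
  sc <- scatter_classification(ds, "A")
  got <- stats::setNames(sc$class, sc$probe)
  expect_equal(unname(got[c("both_up", "male_act", "fem_rep", "male_rep",
                            "flat")]),
               c("similarly_up", "male_enriched", "female_enriched",
                 "male_enriched", "unchanged"))
  mech <- stats::setNames(sc$mechanism, sc$probe)
  expect_equal(unname(mech[c("male_act", "fem_rep", "male_rep")]),
               c("activation", "repression", "repression"))
})

test_that("scatter class counts track the planted mechanism mix", {
  cfg <- sim_config(n_genes = 1500, frac_dimorphic = 0.4, frac_male = 1,
                    mechanism_mix = c(activate = 0.6, repress = 0.3,
                                      both = 0.1),
                    onset_weights = c(1, 0, 0, 0, 0),  # all onsets at stage 2
                    seed = 18)
  s <- simulate_timecourse(cfg)
  tr <- s$truth
  dimg <- tr$gene[tr$dimorphic]
  sc <- scatter_classification(s$dataset, "A", probes = dimg)

  # analytic oracle: each planted class has per-sex true stage1->T changes
  # (XY, XX) of (1, 0) activation, (0, -1) repression, (0.5, -0.5) both;
  # empirical changes are the true change + N(0, s^2), s = sd * sqrt(2/n)
  s_ <- 0.25 * sqrt(2 / 3)
  thr <- 0.585
  p_up <- function(d) pnorm((d - thr) / s_)          # change > thr
  p_dn <- function(d) pnorm((-thr - d) / s_)         # change < -thr
  p_flat <- function(d) 1 - p_up(d) - p_dn(d)
  # P(labelled male_enriched with each mechanism | planted class)
  lab_probs <- function(dy, dx) c(
    activation = p_up(dy) * p_flat(dx),
    repression = p_flat(dy) * p_dn(dx),
    both = p_up(dy) * p_dn(dx)
  )
  mix <- c(activate = 0.6, repress = 0.3, both = 0.1)
  expected <- mix["activate"] * lab_probs(1, 0) +
    mix["repress"] * lab_probs(0, -1) +
    mix["both"] * lab_probs(0.5, -0.5)

  obs_tab <- table(factor(sc$mechanism[sc$class == "male_enriched"],
                          c("activation", "repression", "both")))
  obs <- as.numeric(obs_tab) / length(dimg)
  se <- sqrt(expected * (1 - expected) / length(dimg))
  expect_true(all(abs(obs - expected) < 4 * se + 0.01))
  expect_gt(mean(sc$class == "male_enriched"), sum(expected) - 0.05)
})

test_that("onset robustness binomial test detects stronger onsets in strain A", {
  callsA <- call_enrichment(stats::setNames(rep("0MMMMM", 20),
                                            sprintf("g%02d", 1:20)))
  callsB <- callsA
  fdA <- list(fd = matrix(2, 20, 6,
                          dimnames = list(sprintf("g%02d", 1:20), NULL)))
  fdB <- list(fd = matrix(1, 20, 6,
                          dimnames = list(sprintf("g%02d", 1:20), NULL)))
  res <- onset_robustness_test(callsA, callsB, fdA, fdB)
  expect_equal(res$n_same_onset, 20L)
  expect_equal(res$fraction, 1)
  expect_lt(res$p_value, 1e-5)
  expect_equal(res$p_value,
               stats::binom.test(20, 20, 0.5, "greater")$p.value)
})
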