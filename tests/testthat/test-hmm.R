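test_that("transition initialization reproduces the hand-counted example", {
  syms <- rbind(c("s", "s", "m1", "m2", "m3", "m3"),
                c("s", "s", "s", "s", "s", "s"))
  m <- hmm_initialize(syms, pseudocount = 1)
  # between stages 2 and 3: one S->M and one S->S observed; with a
  # pseudocount of 1 on each of the 3 admissible targets the S row of A[2]
  # is (2/5, 2/5, 1/5) over (M, S, F)
  expect_equal(unname(m$A[[2]]["S", ]), c(2, 2, 1) / 5)
  # stage-1 classes are both S: start distribution (1, 3, 1)/5
  expect_equal(unname(m$pi), c(1, 3, 1) / 5)
  expect_error(hmm_initialize(matrix(character(0), 0, 6)), "no sequences")
})

test_that("initialization and training keep the model row-stochastic and positive", {
  set.seed(5)
  syms <- t(replicate(40, random_symbols()))
  m0 <- hmm_initialize(syms)
  for (mod in list(m0, baum_welch(m0, syms, n_iter = 25))) {
    expect_equal(sum(mod$pi), 1)
    for (a in mod$A) expect_equal(unname(rowSums(a)), rep(1, 3))
    expect_equal(unname(rowSums(mod$B)), rep(1, 3))
  }
  expect_true(all(m0$pi > 0) && all(m0$B > 0))
  expect_true(all(vapply(m0$A, function(a) all(a > 0), TRUE)))
})

test_that("Baum-Welch log-likelihood trace is non-decreasing", {
  set.seed(6)
  gen <- random_hmm()
  syms <- simulate(gen, nsim = 120, seed = 61)
  fit <- dimorphism_hmm(syms, n_iter = 200)
  expect_length(fit$trace, 201)
  expect_true(all(diff(fit$trace) >= -1e-8))
  expect_equal(fit$logLik, fit$trace[length(fit$trace)])
  expect_equal(fit$logLik, sum(forward_loglik(fit, syms)))
})

test_that("training recovers the tied emission matrix of a known model", {
  pi0 <- c(0.05, 0.9, 0.05)
  A0 <- lapply(1:5, function(t)
    matrix(c(0.9, 0.05, 0.05, 0.1, 0.8, 0.1, 0.05, 0.05, 0.9),
           3, 3, byrow = TRUE))
  scaffold <- hmm_initialize(matrix("s", 2, 6))
  gen <- scaffold
  gen$pi <- stats::setNames(pi0, gen$states)
  gen$A <- lapply(A0, function(a) {
    dimnames(a) <- list(gen$states, gen$states); a
  })
  gen$B <- emission_init()
  syms <- simulate(gen, nsim = 500, seed = 71)
  fit <- dimorphism_hmm(syms, n_iter = 200)
  expect_lt(max(abs(fit$B - gen$B)), 0.05)
})

test_that("an all-s sequence keeps the S emission row concentrated on s", {
  syms <- matrix("s", 1, 6)
  fit <- dimorphism_hmm(syms, n_iter = 50)
  expect_gt(fit$B["S", "s"], 0.85)
  expect_equal(predict(fit, syms)$path, "000000")
})

test_that("Viterbi equals the exhaustive-enumeration argmax (oracle)", {
  set.seed(8)
  for (i in 1:50) {
    m <- random_hmm()
    seq_ <- random_symbols()
    v <- viterbi(m, matrix(seq_, 1))
    o <- enumerate_paths_decode(m, seq_)
    expect_identical(v$path, o$path)
    expect_equal(v$log_prob, o$log_prob)
    expect_identical(o$n_paths, 729L)
  }
})

test_that("enumerated path probabilities sum to the forward likelihood", {
  set.seed(9)
  for (i in 1:10) {
    m <- random_hmm()
    seq_ <- random_symbols()
    o <- enumerate_paths_decode(m, seq_)
    total <- max(o$log_probs) + log(sum(exp(o$log_probs - max(o$log_probs))))
    expect_equal(total, unname(forward_loglik(m, matrix(seq_, 1))),
                 tolerance = 1e-10)
  }
  expect_error(enumerate_paths_decode(random_hmm(T_ = 12),
                                      random_symbols(12)), "enumerate")
})

test_that("a Sox9-style sequence decodes to the 0MMMMM path", {
  set.seed(10)
  s <- simulate_timecourse(sim_config(n_genes = 600, seed = 101))
  kept <- filter_detected(s$dataset)
  fds <- fold_differences(s$dataset, probes = kept)
  syms <- quantize_series(fds)
  fit <- dimorphism_hmm(syms, n_iter = 100)
  sox9 <- matrix(c("s", "m2", "m3", "m3", "m3", "m3"), 1)
  expect_identical(predict(fit, sox9)$path, "0MMMMM")
  allS <- matrix("s", 1, 6)
  expect_identical(predict(fit, allS)$path, "000000")
})

test_that("swapping m and f symbols mirrors the trained model and paths", {
  set.seed(12)
  gen <- random_hmm()
  syms <- simulate(gen, nsim = 150, seed = 121)
  syms_sw <- chartr("mf", "fm", syms)
  fit <- dimorphism_hmm(syms, n_iter = 60)
  fit_sw <- dimorphism_hmm(syms_sw, n_iter = 60)
  # mirror: M<->F states, m<->f symbols
  sw_states <- c("F", "S", "M")
  sw_syms <- c("s", "f1", "f2", "f3", "m1", "m2", "m3")
  expect_equal(unname(fit_sw$pi[sw_states]), unname(fit$pi),
               tolerance = 1e-10)
  expect_equal(unname(fit_sw$B[sw_states, sw_syms]), unname(fit$B),
               tolerance = 1e-10)
  for (t in seq_along(fit$A))
    expect_equal(unname(fit_sw$A[[t]][sw_states, sw_states]),
                 unname(fit$A[[t]]), tolerance = 1e-10)
  p <- predict(fit, syms)$path
  p_sw <- predict(fit_sw, syms_sw)$path
  expect_identical(chartr("MF", "FM", p), p_sw)
})

test_that("probes sharing a state path cluster together", {
  paths <- data.frame(
    id = sprintf("g%02d", 1:10),
    path = c(rep("0MMMMM", 3), rep("00MMMM", 2), rep("000000", 5)),
    stringsAsFactors = FALSE
  )
  cl <- cluster_paths(paths)
  expect_equal(nrow(cl), 3)
  expect_equal(cl$size[cl$path == "0MMMMM"], 3L)
  expect_equal(cl$size[cl$path == "00MMMM"], 2L)
  expect_equal(cl$size[cl$path == "000000"], 5L)
  # sorted by onset; the all-0 cluster comes last
  expect_equal(cl$path, c("0MMMMM", "00MMMM", "000000"))
  one <- cluster_paths(data.frame(id = c("a", "b"), path = c("0MMMMM", "0MMMMM")))
  expect_equal(nrow(one), 1)
  expect_error(cluster_paths(data.frame(id = "a", path = c("0M", "0MM"))),
               "equal length")
})

test_that("models survive a JSON round-trip", {
  set.seed(13)
  syms <- t(replicate(30, random_symbols()))
  fit <- dimorphism_hmm(syms, n_iter = 20)
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm(fit, path)
  back <- read_hmm(path)
  expect_equal(back$pi, fit$pi)
  expect_equal(back$B, fit$B)
  for (t in seq_along(fit$A)) expect_equal(back$A[[t]], fit$A[[t]])
  expect_equal(back$logLik, fit$logLik)
})
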