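# Hidden state classes of the left-to-right model, in fixed tie-break order:
# M (XY-enriched), S (similar expression), F (XX-enriched). The full model
# has one copy of each per stage (3T states, e.g. 18 for T = 6), with
# transitions only between adjacent stages and one emission matrix tied
# across stages.
HMM_STATES <- c("M", "S", "F")

symbol_class <- function(sym) {
  cls <- ifelse(sym == "s", 2L, ifelse(substr(sym, 1, 1) == "m", 1L, 3L))
  if (is.matrix(sym)) cls <- matrix(cls, nrow(sym), ncol(sym))
  cls
}

symbols_to_int <- function(sym) {
  i <- match(sym, FD_SYMBOLS)
  if (anyNA(i)) stop("unknown symbol(s): ",
                     paste(unique(sym[is.na(i)]), collapse = ", "))
  if (is.matrix(sym)) i <- matrix(i, nrow(sym), ncol(sym),
                                  dimnames = dimnames(sym))
  i
}

#' Default tied emission initialization
#'
#' Each state concentrates `own_mass` of its probability on its own symbol
#' class — M on \{m1, m2, m3\} split (0.3, 0.3, 0.25) of the total mass, S
#' on \{s\}, F mirrored on \{f1, f2, f3\} — with the remainder spread
#' uniformly over the other symbols, so every entry is strictly positive.
#'
#' @param own_mass total probability a state gives its own symbol class.
#' @return 3 x 7 row-stochastic matrix (rows M, S, F; columns the symbol
#'   alphabet).
#' @export
emission_init <- function(own_mass = 0.85) {
  stopifnot(own_mass > 0, own_mass < 1)
  B <- matrix(0, 3, 7, dimnames = list(HMM_STATES, FD_SYMBOLS))
  split3 <- own_mass * c(0.3, 0.3, 0.25) / 0.85
  B["M", c("m1", "m2", "m3")] <- split3
  B["F", c("f1", "f2", "f3")] <- split3
  B["S", "s"] <- own_mass
  for (r in HMM_STATES) {
    zero <- B[r, ] == 0
    B[r, zero] <- (1 - sum(B[r, ])) / sum(zero)
  }
  B
}

new_hmm <- function(pi, A, B) {
  names(pi) <- HMM_STATES
  dimnames(B) <- list(HMM_STATES, FD_SYMBOLS)
  A <- lapply(A, function(a) {
    dimnames(a) <- list(HMM_STATES, HMM_STATES); a
  })
  structure(list(states = HMM_STATES, alphabet = FD_SYMBOLS,
                 n_stages = length(A) + 1L, pi = pi, A = A, B = B),
            class = "dimorph_hmm")
}

check_stochastic <- function(model, tol = 1e-8) {
  ok <- abs(sum(model$pi) - 1) < tol &&
    all(vapply(model$A, function(a) all(abs(rowSums(a) - 1) < tol), TRUE)) &&
    all(abs(rowSums(model$B) - 1) < tol) &&
    all(model$pi >= 0) && all(model$B >= 0) &&
    all(vapply(model$A, function(a) all(a >= 0), TRUE))
  if (!ok) stop("model is not row-stochastic")
  invisible(model)
}

#' Initialize the left-to-right HMM from symbol sequences
#'
#' Start and transition probabilities come from classifying each observed
#' symbol into its state class (m* -> M, s -> S, f* -> F), counting class
#' memberships at stage 1 and class transitions between adjacent stages,
#' adding `pseudocount` to every admissible transition and row-normalizing.
#' Emissions are set to the hand-chosen tied matrix from [emission_init()]
#' (or a user-supplied 3 x 7 matrix). All probabilities are strictly
#' positive.
#'
#' @param symbols character matrix (sequences x stages) over the 7-symbol
#'   alphabet, or a list of such matrices (pooled by row-binding).
#' @param pseudocount added to every admissible transition count
#'   (default 1).
#' @param emission 3 x 7 row-stochastic emission matrix.
#' @return an untrained `dimorph_hmm`.
#' @export
hmm_initialize <- function(symbols, pseudocount = 1,
                           emission = emission_init()) {
  symbols <- pool_symbols(symbols)
  T_ <- ncol(symbols)
  if (nrow(symbols) == 0) stop("no sequences supplied")
  if (T_ < 2) stop("sequences must have length >= 2")
  cls <- symbol_class(symbols)
  pi <- tabulate(cls[, 1], 3) + pseudocount
  pi <- pi / sum(pi)
  A <- vector("list", T_ - 1)
  for (t in seq_len(T_ - 1)) {
    cnt <- matrix(pseudocount, 3, 3)
    for (i in 1:3) for (j in 1:3)
      cnt[i, j] <- cnt[i, j] + sum(cls[, t] == i & cls[, t + 1] == j)
    A[[t]] <- cnt / rowSums(cnt)
  }
  stopifnot(is.matrix(emission), nrow(emission) == 3, ncol(emission) == 7,
            all(emission > 0), all(abs(rowSums(emission) - 1) < 1e-8))
  check_stochastic(new_hmm(pi, A, emission))
}

pool_symbols <- function(symbols) {
  if (is.list(symbols)) symbols <- do.call(rbind, symbols)
  if (!is.matrix(symbols)) symbols <- matrix(symbols, nrow = 1)
  symbols
}

#' Train the HMM by Baum-Welch expectation-maximization
#'
#' Runs `n_iter` EM iterations over the left-to-right lattice, with all
#' forward/backward recursions in log space (log-sum-exp). Transition
#' matrices are re-estimated per stage step; emissions are re-estimated
#' with expected counts pooled across stages (tied emissions). Identical
#' sequences are collapsed to weighted unique rows internally. The returned
#' log-likelihood trace has one entry per iteration plus the final fit and
#' is non-decreasing up to numerical tolerance.
#'
#' @param model an initialized `dimorph_hmm`.
#' @param symbols character matrix or list of matrices of training
#'   sequences.
#' @param n_iter number of EM iterations (default 200).
#' @param tol optional early-stopping tolerance on the log-likelihood
#'   increase; `NULL` (default) always runs all `n_iter` iterations.
#' @return the trained `dimorph_hmm` with elements `logLik`, `trace`
#'   (length iterations + 1) and `n_iter`.
#' @export
baum_welch <- function(model, symbols, n_iter = 200, tol = NULL) {
  symbols <- pool_symbols(symbols)
  T_ <- ncol(symbols)
  if (T_ != model$n_stages)
    stop("sequence length ", T_, " does not match model stages ",
         model$n_stages)
  obs_all <- symbols_to_int(symbols)
  key <- apply(obs_all, 1, paste, collapse = "")
  tab <- table(key)
  uk <- names(tab)
  obs <- obs_all[match(uk, key), , drop = FALSE]
  w <- as.numeric(tab)
  U <- nrow(obs)

  trace <- numeric(0)
  for (it in seq_len(n_iter)) {
    fb <- forward_backward(model, obs)
    ll <- sum(w * fb$ll_seq)
    if (!is.finite(ll)) stop("zero-probability sequence under the model")
    trace <- c(trace, ll)
    if (!is.null(tol) && it > 1 &&
        (ll - trace[it - 1]) < tol) break

    la <- fb$la; lb <- fb$lb
    gamma1 <- exp(la[[1]] + lb[[1]] - fb$ll_seq)
    pi_new <- colSums(w * gamma1)
    pi_new <- pi_new / sum(pi_new)

    logA <- lapply(model$A, log)
    logB <- log(model$B)
    A_new <- vector("list", T_ - 1)
    Bnum <- matrix(0, 3, 7)
    for (t in seq_len(T_)) {
      g <- exp(la[[t]] + lb[[t]] - fb$ll_seq)     # U x 3
      for (k in 1:7) {
        sel <- obs[, t] == k
        if (any(sel))
          Bnum[, k] <- Bnum[, k] + colSums(w[sel] * g[sel, , drop = FALSE])
      }
      if (t < T_) {
        xi <- matrix(0, 3, 3)
        for (i in 1:3) for (j in 1:3) {
          xi[i, j] <- sum(w * exp(la[[t]][, i] + logA[[t]][i, j] +
                                    logB[j, obs[, t + 1]] +
                                    lb[[t + 1]][, j] - fb$ll_seq))
        }
        rs <- rowSums(xi)
        a_old <- model$A[[t]]
        A_new[[t]] <- t(vapply(1:3, function(i) {
          if (rs[i] > 0) xi[i, ] / rs[i] else a_old[i, ]
        }, numeric(3)))
      }
    }
    rsB <- rowSums(Bnum)
    B_new <- t(vapply(1:3, function(i) {
      if (rsB[i] > 0) Bnum[i, ] / rsB[i] else model$B[i, ]
    }, numeric(7)))
    model <- new_hmm(pi_new, A_new, B_new)
  }
  fb <- forward_backward(model, obs, backward = FALSE)
  final_ll <- sum(w * fb$ll_seq)
  model$logLik <- final_ll
  model$trace <- c(trace, final_ll)
  model$n_iter <- length(trace)
  model$n_sequences <- nrow(symbols)
  model
}

# log-space forward (and optionally backward) over the T-stage lattice for
# an integer observation matrix (rows = sequences); returns lists of U x 3
# log alpha/beta matrices and per-sequence log-likelihoods
forward_backward <- function(model, obs, backward = TRUE) {
  T_ <- ncol(obs); U <- nrow(obs)
  logA <- lapply(model$A, log)
  logB <- log(model$B)
  la <- vector("list", T_)
  la[[1]] <- matrix(log(model$pi), U, 3, byrow = TRUE) +
    t(logB[, obs[, 1], drop = FALSE])
  for (t in seq_len(T_ - 1)) {
    prev <- la[[t]]
    nxt <- matrix(NA_real_, U, 3)
    for (j in 1:3)
      nxt[, j] <- lse3(prev + matrix(logA[[t]][, j], U, 3, byrow = TRUE)) +
        logB[j, obs[, t + 1]]
    la[[t + 1]] <- nxt
  }
  ll_seq <- lse3(la[[T_]])
  if (!backward) return(list(la = la, ll_seq = ll_seq))
  lb <- vector("list", T_)
  lb[[T_]] <- matrix(0, U, 3)
  for (t in rev(seq_len(T_ - 1))) {
    nxt <- lb[[t + 1]] + t(logB[, obs[, t + 1], drop = FALSE])
    cur <- matrix(NA_real_, U, 3)
    for (i in 1:3)
      cur[, i] <- lse3(nxt + matrix(logA[[t]][i, ], U, 3, byrow = TRUE))
    lb[[t]] <- cur
  }
  list(la = la, lb = lb, ll_seq = ll_seq)
}

# row-wise log-sum-exp of a U x 3 matrix, safe at -Inf
lse3 <- function(m) {
  mx <- pmax(m[, 1], m[, 2], m[, 3])
  mx0 <- ifelse(is.finite(mx), mx, 0)
  mx0 + log(exp(m[, 1] - mx0) + exp(m[, 2] - mx0) + exp(m[, 3] - mx0))
}

#' Fit the dimorphism-onset HMM
#'
#' One-call interface: initializes the left-to-right model from the symbol
#' sequences ([hmm_initialize()]) and trains it by Baum-Welch
#' ([baum_welch()]). Sequences from all strains should be pooled here (pass
#' the list returned by [quantize_series()]); decoding is then done per
#' strain with [predict.dimorph_hmm()].
#'
#' @param symbols character matrix of symbol sequences (rows = probe series,
#'   columns = stages) or a list of such matrices.
#' @param n_iter Baum-Welch iterations (default 200).
#' @param pseudocount transition pseudocount for initialization (default 1).
#' @param emission tied emission initialization (default [emission_init()]).
#' @param tol optional early-stopping tolerance (default `NULL`: fixed
#'   iteration count).
#' @return a trained `dimorph_hmm`; see [baum_welch()] for the fit fields.
#' @examples
#' syms <- rbind(c("s", "s", "m2", "m3", "m3", "m3"),
#'               c("s", "s", "s",  "s",  "s",  "s"))
#' fit <- dimorphism_hmm(syms, n_iter = 20)
#' predict(fit, syms)
#' @export
dimorphism_hmm <- function(symbols, n_iter = 200, pseudocount = 1,
                           emission = emission_init(), tol = NULL) {
  m0 <- hmm_initialize(symbols, pseudocount, emission)
  fit <- baum_welch(m0, symbols, n_iter = n_iter, tol = tol)
  fit$init <- list(pi = m0$pi, A = m0$A, B = m0$B)
  fit
}

#' @export
print.dimorph_hmm <- function(x, ...) {
  cat(sprintf("Left-to-right dimorphism HMM: %d stages, %d states (3/stage)\n",
              x$n_stages, 3 * x$n_stages))
  if (!is.null(x$logLik))
    cat(sprintf("  trained: %d Baum-Welch iterations, logLik %.3f on %d sequences\n",
                x$n_iter, x$logLik, x$n_sequences))
  else cat("  untrained (initialization only)\n")
  cat("  start distribution:\n")
  print(round(x$pi, 4))
  invisible(x)
}

#' @export
summary.dimorph_hmm <- function(object, ...) {
  print(object)
  cat("  tied emission matrix:\n")
  print(round(object$B, 4))
  cat("  transition matrices A[t] (stage t -> t+1):\n")
  for (t in seq_along(object$A)) {
    cat(sprintf("  t = %d:\n", t))
    print(round(object$A[[t]], 4))
  }
  invisible(object)
}

#' @export
coef.dimorph_hmm <- function(object, ...) {
  list(pi = object$pi, A = object$A, B = object$B)
}

#' @export
logLik.dimorph_hmm <- function(object, ...) {
  if (is.null(object$logLik)) stop("model not trained")
  structure(object$logLik, df = NA, class = "logLik")
}

#' @export
plot.dimorph_hmm <- function(x, ...) {
  if (is.null(x$trace)) stop("no training trace to plot")
  graphics::plot(seq_along(x$trace) - 1, x$trace, type = "l",
                 xlab = "Baum-Welch iteration", ylab = "total log-likelihood",
                 main = "EM log-likelihood trace", ...)
  invisible(x)
}

#' Decode state paths for symbol sequences
#'
#' Viterbi-decodes each row of `newdata` under the fitted model; see
#' [viterbi()]. This is the `predict` method of `dimorph_hmm`.
#'
#' @param object a `dimorph_hmm`.
#' @param newdata character matrix of symbol sequences.
#' @param ... unused.
#' @return data.frame with columns `id`, `path` (string over \{0, M, F\},
#'   0 = similar-expression state) and `log_prob`.
#' @export
predict.dimorph_hmm <- function(object, newdata, ...) {
  viterbi(object, newdata)
}

#' Sample symbol sequences from a model
#'
#' Draws `nsim` sequences: the stage-1 state from the start distribution,
#' subsequent states from the per-step transition matrices, and one symbol
#' per stage from the tied emission matrix.
#'
#' @param object a `dimorph_hmm`.
#' @param nsim number of sequences.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return character matrix `nsim` x T of symbols, with the hidden state
#'   paths in `attr(, "states")`.
#' @export
simulate.dimorph_hmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  T_ <- object$n_stages
  states <- matrix(NA_integer_, nsim, T_)
  states[, 1] <- sample.int(3, nsim, replace = TRUE, prob = object$pi)
  for (t in seq_len(T_ - 1)) {
    for (i in 1:3) {
      sel <- states[, t] == i
      if (any(sel))
        states[sel, t + 1] <- sample.int(3, sum(sel), replace = TRUE,
                                         prob = object$A[[t]][i, ])
    }
  }
  sym <- matrix(NA_character_, nsim, T_)
  for (i in 1:3) {
    sel <- states == i
    if (any(sel))
      sym[sel] <- sample(FD_SYMBOLS, sum(sel), replace = TRUE,
                         prob = object$B[i, ])
  }
  attr(sym, "states") <- matrix(HMM_STATES[states], nsim, T_)
  sym
}

#' Serialize / restore a model as JSON
#'
#' @param model a `dimorph_hmm`.
#' @param path file path.
#' @return `write_hmm` invisibly returns `path`; `read_hmm` a
#'   `dimorph_hmm`.
#' @export
write_hmm <- function(model, path) {
  obj <- list(states = model$states, alphabet = model$alphabet,
              n_stages = model$n_stages, pi = unname(model$pi),
              A = lapply(model$A, unname), B = unname(model$B),
              logLik = model$logLik, n_iter = model$n_iter)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- if (is.list(obj$A)) obj$A else apply(obj$A, 1, identity,
                                            simplify = FALSE)
  m <- new_hmm(obj$pi, lapply(A, function(a) matrix(unlist(a), 3, 3)),
               matrix(unlist(obj$B), 3, 7))
  m$logLik <- obj$logLik
  m$n_iter <- obj$n_iter
  check_stochastic(m)
}
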