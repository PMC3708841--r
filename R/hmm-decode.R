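#' Viterbi decoding
#'
#' Computes, for each symbol sequence, the maximum-joint-probability state
#' path through the left-to-right lattice, in log space. Ties are broken
#' deterministically by the fixed state order M < S < F at every backtrack
#' step. Paths are reported as strings over \{0, M, F\}, where 0 denotes
#' the similar-expression state.
#'
#' @param model a `dimorph_hmm`.
#' @param symbols character matrix of symbol sequences (rows decoded
#'   independently) or a single sequence as a character vector.
#' @return data.frame with columns `id`, `path`, `log_prob`.
#' @export
viterbi <- function(model, symbols) {
  symbols <- pool_symbols(symbols)
  obs <- symbols_to_int(symbols)
  T_ <- ncol(obs)
  if (T_ != model$n_stages)
    stop("sequence length does not match model stages")
  logA <- lapply(model$A, log)
  logB <- log(model$B)
  logpi <- log(model$pi)
  n <- nrow(obs)
  paths <- character(n)
  lp <- numeric(n)
  for (r in seq_len(n)) {
    delta <- matrix(NA_real_, 3, T_)
    psi <- matrix(NA_integer_, 3, T_)
    delta[, 1] <- logpi + logB[, obs[r, 1]]
    for (t in seq_len(T_ - 1)) {
      for (j in 1:3) {
        cand <- delta[, t] + logA[[t]][, j]
        psi[j, t + 1] <- which.max(cand)   # first max = lowest state index
        delta[j, t + 1] <- cand[psi[j, t + 1]] + logB[j, obs[r, t + 1]]
      }
    }
    sp <- integer(T_)
    sp[T_] <- which.max(delta[, T_])
    for (t in rev(seq_len(T_ - 1))) sp[t] <- psi[sp[t + 1], t + 1]
    paths[r] <- states_to_path(HMM_STATES[sp])
    lp[r] <- delta[sp[T_], T_]
  }
  ids <- rownames(symbols)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  data.frame(id = ids, path = paths, log_prob = lp,
             stringsAsFactors = FALSE)
}

#' Total (forward) log-likelihood of sequences
#'
#' @param model a `dimorph_hmm`.
#' @param symbols character matrix or vector of symbol sequences.
#' @return numeric vector: per-sequence log-likelihood, marginalized over
#'   all state paths.
#' @export
forward_loglik <- function(model, symbols) {
  symbols <- pool_symbols(symbols)
  obs <- symbols_to_int(symbols)
  forward_backward(model, obs, backward = FALSE)$ll_seq
}

#' Brute-force decoding by exhaustive path enumeration
#'
#' Evaluates the joint probability of every one of the 3^T admissible
#' state paths for one sequence and returns the argmax. Serves as an
#' independent oracle for [viterbi()]; the sum of all enumerated path
#' probabilities equals the forward likelihood.
#'
#' @param model a `dimorph_hmm`.
#' @param symbols one sequence (character vector of length T).
#' @return list with `path` (string), `log_prob`, `n_paths` (= 3^T) and
#'   `log_probs` (vector over all enumerated paths).
#' @export
enumerate_paths_decode <- function(model, symbols) {
  T_ <- model$n_stages
  if (T_ > 10) stop("T too large to enumerate (3^T paths)")
  obs <- as.vector(symbols_to_int(pool_symbols(symbols)))
  stopifnot(length(obs) == T_)
  grid <- as.matrix(expand.grid(rep(list(1:3), T_)))
  logA <- lapply(model$A, log)
  logB <- log(model$B)
  lp <- unname(log(model$pi))[grid[, 1]] + logB[cbind(grid[, 1], obs[1])]
  for (t in seq_len(T_ - 1)) {
    lp <- lp + logA[[t]][cbind(grid[, t], grid[, t + 1])] +
      logB[cbind(grid[, t + 1], obs[t + 1])]
  }
  best <- which.max(lp)
  list(path = states_to_path(HMM_STATES[grid[best, ]]),
       log_prob = lp[best], n_paths = nrow(grid), log_probs = lp)
}

#' Cluster probes by decoded state path
#'
#' Partitions decoded probes by their exact path string and reports cluster
#' sizes, sorted by onset stage (first non-0 position; all-0 last) and then
#' by decreasing size.
#'
#' @param paths data.frame from [viterbi()] / [predict.dimorph_hmm()].
#' @return data.frame of class `path_clusters` with columns `path`,
#'   `onset`, `size`; member ids in `attr(, "members")`.
#' @export
cluster_paths <- function(paths) {
  stopifnot(all(c("id", "path") %in% names(paths)))
  if (length(unique(nchar(paths$path))) > 1)
    stop("paths must all have equal length")
  members <- split(paths$id, paths$path)
  onset <- vapply(names(members), path_onset, 1L)
  size <- lengths(members)
  ord <- order(ifelse(is.na(onset), Inf, onset), -size, names(members))
  out <- data.frame(path = names(members)[ord], onset = onset[ord],
                    size = as.integer(size[ord]), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "members") <- members[ord]
  class(out) <- c("path_clusters", "data.frame")
  out
}

states_to_path <- function(states) {
  paste(ifelse(states == "S", "0", states), collapse = "")
}

path_to_states <- function(path) {
  ch <- strsplit(path, "")[[1]]
  ifelse(ch == "0", "S", ch)
}

# first stage in a dimorphic (M or F) state, NA for all-0 paths
path_onset <- function(path) {
  pos <- regexpr("[MF]", path)
  if (pos < 0) NA_integer_ else as.integer(pos)
}
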