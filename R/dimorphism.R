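# Symbol alphabet for quantized fold differences: similar, three grades of
# male (XY-higher) enrichment, three grades of female (XX-higher) enrichment.
FD_SYMBOLS <- c("s", "m1", "m2", "m3", "f1", "f2", "f3")

# log2 fold-difference bin edges: fold changes 1.25, 1.5 and 2
FD_THRESHOLDS <- c(0.3219, 0.585, 1)

#' Per-stage significance-gated fold differences
#'
#' For every probe, strain and stage computes FD = mean(log2 XY) -
#' mean(log2 XX) together with a two-sided pooled-variance two-sample
#' t-test p-value, then gates: the FD is set to 0 whenever p >= `p_gate` or
#' |FD| <= `fd_gate`. The gated series is what gets quantized and fed to
#' the HMM.
#'
#' @param dataset an [expression_dataset()].
#' @param probes probe subset (default all probes).
#' @param p_gate per-contrast significance gate (default 0.05).
#' @param fd_gate minimum |FD| to survive gating (default 0.3219, i.e. a
#'   1.25-fold change).
#' @return named list (one element per strain) of class `fd_series`; each
#'   element holds matrices `fd`, `p` and `gated` (probes x stages).
#' @export
fold_differences <- function(dataset, probes = NULL, p_gate = 0.05,
                             fd_gate = FD_THRESHOLDS[1]) {
  d <- dataset$design
  if (is.null(probes)) probes <- rownames(dataset$exprs)
  E <- dataset$exprs[probes, , drop = FALSE]
  T_ <- n_stages(dataset)
  out <- list()
  for (st in strains(dataset)) {
    fd <- p <- matrix(NA_real_, nrow(E), T_,
                      dimnames = list(probes, paste0("stage", seq_len(T_))))
    for (t in seq_len(T_)) {
      iy <- cell_index(d, "XY", st, t)
      ix <- cell_index(d, "XX", st, t)
      if (length(iy) < 2 || length(ix) < 2)
        stop(sprintf("cell %s/stage %d has <2 replicates in %s",
                     st, t, if (length(iy) < 2) "XY" else "XX"))
      tt <- row_t_test(E[, iy, drop = FALSE], E[, ix, drop = FALSE])
      fd[, t] <- tt$diff
      p[, t] <- tt$p
    }
    gated <- fd
    gated[p >= p_gate | abs(fd) <= fd_gate] <- 0
    out[[st]] <- structure(list(strain = st, fd = fd, p = p, gated = gated),
                           class = "fd_series")
  }
  out
}

# vectorized two-sided pooled-variance two-sample t-test over matrix rows;
# returns difference in row means (A - B) and p-values
row_t_test <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0] <- ifelse(ma[se == 0] == mb[se == 0], 1, 0)
  list(diff = ma - mb, p = p)
}

#' Quantize gated fold differences into the 7-symbol alphabet
#'
#' Maps each gated FD to one of \{s, m1, m2, m3, f1, f2, f3\}: `s` when
#' |FD| < 0.3219; m1/m2/m3 for FD in [0.3219, 0.585), [0.585, 1) and
#' [1, Inf); f1/f2/f3 mirrored for negative FD. Values exactly on a
#' threshold fall in the larger-magnitude bin. Total on the reals, and
#' mirror-symmetric: quantizing -FD swaps m and f at every position.
#'
#' @param fd numeric vector or matrix of (gated) fold differences.
#' @param thresholds increasing positive bin edges (default
#'   `c(0.3219, 0.585, 1)`).
#' @return character vector/matrix of symbols, same shape as `fd`.
#' @export
quantize_fd <- function(fd, thresholds = FD_THRESHOLDS) {
  stopifnot(length(thresholds) == 3, all(diff(thresholds) > 0),
            all(thresholds > 0))
  lev <- findInterval(abs(fd), thresholds)
  sym <- ifelse(lev == 0, "s",
                paste0(ifelse(fd > 0, "m", "f"), lev))
  if (is.matrix(fd)) {
    sym <- matrix(sym, nrow(fd), ncol(fd), dimnames = dimnames(fd))
  } else names(sym) <- names(fd)
  sym
}

#' Symbol matrices for all strains
#'
#' Convenience wrapper: quantizes the gated FD matrix of every strain in a
#' [fold_differences()] result.
#'
#' @param fds result of [fold_differences()].
#' @param thresholds passed to [quantize_fd()].
#' @return named list of character matrices (probes x stages).
#' @export
quantize_series <- function(fds, thresholds = FD_THRESHOLDS) {
  lapply(fds, function(s) quantize_fd(s$gated, thresholds))
}
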