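#' Quantile normalize an expression matrix
#'
#' Forces every column (sample) to share the same empirical distribution:
#' the per-rank mean across columns. Ties within a column receive the mean
#' of the normalized values at their ranks. Delegates to
#' `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param m numeric matrix, probes x samples, at least 2 columns, no NAs.
#' @return matrix of the same shape; applying twice equals applying once.
#' @export
quantile_normalize <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("`m` must be a numeric matrix")
  if (ncol(m) < 2) stop("need at least 2 columns to quantile normalize")
  if (anyNA(m)) stop("missing values present; impute or drop before normalizing")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Filter probes by detection p-values
#'
#' A probe is kept iff some sex x strain x stage cell has at least
#' `min_replicates` samples with detection p below `p_threshold` — i.e. the
#' probe is reliably detected in at least one sample type.
#'
#' @param dataset an [expression_dataset()] with a detection matrix.
#' @param p_threshold detection p-value cutoff (default 0.005).
#' @param min_replicates minimum detected replicates within one cell.
#' @return character vector of retained probe ids.
#' @export
filter_detected <- function(dataset, p_threshold = 0.005, min_replicates = 2) {
  if (is.null(dataset$detection))
    stop("no detection p-value matrix; to analyse all probes pass them explicitly")
  d <- dataset$design
  hit <- dataset$detection < p_threshold
  keep <- rep(FALSE, nrow(hit))
  for (sx in unique(d$sex)) for (st in unique(d$strain))
    for (tp in unique(d$stage)) {
      idx <- cell_index(d, sx, st, tp)
      keep <- keep | rowSums(hit[, idx, drop = FALSE]) >= min_replicates
    }
  rownames(dataset$exprs)[keep]
}

#' Screen probes with a sex x strain x stage factorial ANOVA
#'
#' Fits, per probe, an ordinary-least-squares factorial model with stage as
#' a categorical factor: sex + strain + stage + all two-way interactions +
#' the three-way interaction. Each term gets a partial F-test (full model vs
#' the model without that term's columns, under sum-to-zero contrasts);
#' Benjamini-Hochberg adjustment is applied per term across probes. A probe
#' passes the screen when it is detected and any adjusted term p-value is
#' below `alpha`. Probes with (numerically) zero total variance get p = 1
#' for every term.
#'
#' @param dataset an [expression_dataset()].
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param probes optional probe subset (default: [filter_detected()] result
#'   when a detection matrix is present, else all probes).
#' @return a data.frame of class `screen_result`: one row per probe with
#'   raw and BH-adjusted p-values per term (`p_<term>`, `padj_<term>`), a
#'   `detected` flag and a `passes_screen` flag.
#' @export
screen_probes <- function(dataset, alpha = 0.05, probes = NULL) {
  d <- dataset$design
  all_probes <- rownames(dataset$exprs)
  detected <- if (!is.null(dataset$detection)) {
    all_probes %in% filter_detected(dataset)
  } else rep(TRUE, length(all_probes))
  if (is.null(probes)) probes <- all_probes[detected]
  Y <- t(dataset$exprs[probes, , drop = FALSE])   # samples x probes

  fac <- data.frame(sex = factor(d$sex), strain = factor(d$strain),
                    stage = factor(d$stage))
  ctr <- list(sex = "contr.sum", strain = "contr.sum", stage = "contr.sum")
  X <- stats::model.matrix(~ sex * strain * stage, fac, contrasts.arg = ctr)
  asgn <- attr(X, "assign")
  terms_ <- attr(stats::terms(~ sex * strain * stage), "term.labels")
  df_res <- nrow(X) - ncol(X)
  if (df_res <= 0)
    stop("unreplicated design: no residual degrees of freedom for the screen")

  rss <- function(Xm) {
    Q <- qr.Q(qr(Xm))
    colSums(Y^2) - colSums(crossprod(Q, Y)^2)
  }
  rss_full <- rss(X)
  tot_ss <- colSums(scale(Y, scale = FALSE)^2)
  degenerate <- tot_ss < 1e-10 * nrow(Y)

  pvals <- matrix(NA_real_, length(probes), length(terms_),
                  dimnames = list(probes, terms_))
  for (k in seq_along(terms_)) {
    cols <- asgn != k
    df_term <- sum(asgn == k)
    rss_red <- rss(X[, cols, drop = FALSE])
    Fstat <- ((rss_red - rss_full) / df_term) / (rss_full / df_res)
    p <- stats::pf(Fstat, df_term, df_res, lower.tail = FALSE)
    p[degenerate | !is.finite(Fstat)] <- 1
    pvals[, k] <- p
  }
  padj <- apply(pvals, 2, stats::p.adjust, method = "BH")
  if (length(probes) == 1) padj <- matrix(padj, 1, dimnames = dimnames(pvals))

  res <- data.frame(probe = probes, stringsAsFactors = FALSE)
  for (k in seq_along(terms_)) {
    nm <- gsub(":", "_", terms_[k])
    res[[paste0("p_", nm)]] <- pvals[, k]
    res[[paste0("padj_", nm)]] <- padj[, k]
  }
  res$detected <- detected[match(probes, all_probes)]
  res$passes_screen <- res$detected &
    apply(padj, 1, min) < alpha
  class(res) <- c("screen_result", "data.frame")
  attr(res, "alpha") <- alpha
  res
}
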