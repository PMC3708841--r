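#' Enrichment calls from decoded state paths
#'
#' Interprets each Viterbi path: `male_enriched` / `female_enriched` when
#' the path enters the M / F state and stays there through the final stage
#' (strict persistence); `switch` when the path contains both M and F
#' states; `none` for all-0 paths. Paths that enter a dimorphic state but
#' relapse to 0 are classed `none` with `relapsed = TRUE` and their first
#' dimorphic stage recorded. Onset is the first stage in a dimorphic
#' state; onsets at stage 1 are flagged left-censored (dimorphism may
#' predate the sampled window).
#'
#' @param paths data.frame from [viterbi()] (columns `id`, `path`), or a
#'   character vector of path strings.
#' @return data.frame of class `enrichment_calls`: `id`, `path`, `class`,
#'   `onset` (NA unless male/female_enriched or switch), `persists`,
#'   `relapsed`, `first_dimorphic`, `left_censored`.
#' @export
call_enrichment <- function(paths) {
  if (is.character(paths))
    paths <- data.frame(id = if (is.null(names(paths)))
      as.character(seq_along(paths)) else names(paths),
      path = unname(paths), stringsAsFactors = FALSE)
  n <- nrow(paths)
  cls <- character(n); onset <- rep(NA_integer_, n)
  persists <- logical(n); relapsed <- logical(n)
  first_dim <- rep(NA_integer_, n)
  for (r in seq_len(n)) {
    p <- paths$path[r]
    T_ <- nchar(p)
    has_m <- grepl("M", p, fixed = TRUE)
    has_f <- grepl("F", p, fixed = TRUE)
    fd <- path_onset(p)
    first_dim[r] <- fd
    if (!has_m && !has_f) {
      cls[r] <- "none"
    } else if (has_m && has_f) {
      cls[r] <- "switch"
      onset[r] <- fd
      persists[r] <- substr(p, T_, T_) != "0"
    } else {
      state <- if (has_m) "M" else "F"
      tail_ok <- all(strsplit(substr(p, fd, T_), "")[[1]] == state)
      if (tail_ok) {
        cls[r] <- if (has_m) "male_enriched" else "female_enriched"
        onset[r] <- fd
        persists[r] <- TRUE
      } else {
        cls[r] <- "none"
        relapsed[r] <- TRUE
      }
    }
  }
  out <- data.frame(id = paths$id, path = paths$path, class = cls,
                    onset = onset, persists = persists, relapsed = relapsed,
                    first_dimorphic = first_dim,
                    left_censored = !is.na(onset) & onset == 1L,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_calls", "data.frame")
  out
}

#' Classify activation vs repression mechanism
#'
#' For each enriched gene, compares expression at the stage before onset
#' with the final stage, separately in each sex, using the pooled-variance
#' t-test. A male-enriched gene whose XY samples rise by more than
#' `threshold` (p < `alpha`) is `activated_in_XY`; one whose XX samples
#' fall below `-threshold` (p < `alpha`) is `repressed_in_XX`; both at once
#' is `combination`; neither is `unclassified`. Female-enriched genes are
#' mirrored (`activated_in_XX` / `repressed_in_XY`). Genes with onset at
#' stage 1 use stage 1 as the reference (flagged `ref_is_onset`).
#'
#' @param dataset an [expression_dataset()].
#' @param calls an `enrichment_calls` data.frame ([call_enrichment()]).
#' @param strain strain label the calls belong to.
#' @param threshold log2 change magnitude threshold (default 0.32).
#' @param alpha per-test significance level (default 0.05).
#' @return `calls` with added columns `change_XY`, `change_XX`, `p_XY`,
#'   `p_XX`, `mechanism`, `ref_stage`, `ref_is_onset`.
#' @export
classify_mechanism <- function(dataset, calls, strain, threshold = 0.32,
                               alpha = 0.05) {
  d <- dataset$design
  T_ <- n_stages(dataset)
  calls$change_XY <- NA_real_; calls$change_XX <- NA_real_
  calls$p_XY <- NA_real_; calls$p_XX <- NA_real_
  calls$mechanism <- NA_character_
  calls$ref_stage <- NA_integer_
  calls$ref_is_onset <- FALSE
  enriched <- which(calls$class %in% c("male_enriched", "female_enriched"))
  if (length(enriched) == 0) return(calls)

  for (ref in unique(pmax(calls$onset[enriched] - 1L, 1L))) {
    rows <- enriched[pmax(calls$onset[enriched] - 1L, 1L) == ref]
    ids <- calls$id[rows]
    for (sx in c("XY", "XX")) {
      i0 <- cell_index(d, sx, strain, ref)
      i1 <- cell_index(d, sx, strain, T_)
      tt <- row_t_test(dataset$exprs[ids, i1, drop = FALSE],
                       dataset$exprs[ids, i0, drop = FALSE])
      calls[rows, paste0("change_", sx)] <- tt$diff
      calls[rows, paste0("p_", sx)] <- tt$p
    }
    calls$ref_stage[rows] <- ref
    calls$ref_is_onset[rows] <- calls$onset[rows] == ref
  }

  for (r in enriched) {
    male <- calls$class[r] == "male_enriched"
    up_sx <- if (male) "XY" else "XX"   # enriched sex should rise
    dn_sx <- if (male) "XX" else "XY"   # other sex should fall
    act <- calls[[paste0("change_", up_sx)]][r] > threshold &&
      calls[[paste0("p_", up_sx)]][r] < alpha
    rep_ <- calls[[paste0("change_", dn_sx)]][r] < -threshold &&
      calls[[paste0("p_", dn_sx)]][r] < alpha
    calls$mechanism[r] <-
      if (act && rep_) "combination"
      else if (act) paste0("activated_in_", up_sx)
      else if (rep_) paste0("repressed_in_", dn_sx)
      else "unclassified"
  }
  calls
}

#' Cross-strain onset matrix with hypergeometric overlap tests
#'
#' Cross-tabulates the onset stage of one enrichment class (male or female)
#' between two strains, over the universe of probes carrying that class in
#' either strain; probes called in only one strain fall in the
#' `not_dimorphic` row/column. Each cell gets a one-sided hypergeometric
#' p-value for over-representation (drawing the row cohort from the
#' universe, successes = the column cohort), flagged at `p_flag`. Also
#' reports the modal onset offset of strain B relative to strain A among
#' probes called in both.
#'
#' @param calls_a,calls_b `enrichment_calls` for strains A and B, on the
#'   same probe universe.
#' @param sex_class `"male_enriched"` or `"female_enriched"`.
#' @param p_flag flagging threshold for cell overlap p-values (default
#'   0.001).
#' @return object of class `onset_matrix`: list with `counts`, `p_values`,
#'   `flagged`, `modal_offset`, `offsets` (table), `universe_size`.
#' @export
compare_strain_onsets <- function(calls_a, calls_b,
                                  sex_class = "male_enriched",
                                  p_flag = 0.001) {
  sex_class <- match.arg(sex_class, c("male_enriched", "female_enriched"))
  if (length(intersect(calls_a$id, calls_b$id)) == 0)
    stop("call sets have disjoint probe universes")
  oa <- stats::setNames(calls_a$onset, calls_a$id)[calls_a$class == sex_class]
  ob <- stats::setNames(calls_b$onset, calls_b$id)[calls_b$class == sex_class]
  universe <- union(names(oa), names(ob))
  N <- length(universe)
  if (N == 0) stop("no probes with class ", sex_class, " in either strain")
  stages <- sort(unique(c(oa, ob)))
  lev <- c(as.character(stages), "not_dimorphic")
  fa <- factor(ifelse(universe %in% names(oa),
                      as.character(oa[universe]), "not_dimorphic"), lev)
  fb <- factor(ifelse(universe %in% names(ob),
                      as.character(ob[universe]), "not_dimorphic"), lev)
  counts <- table(A = fa, B = fb)
  pv <- matrix(NA_real_, nrow(counts), ncol(counts),
               dimnames = dimnames(counts))
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    k <- counts[i, j]; K <- sum(counts[, j]); nr <- sum(counts[i, ])
    pv[i, j] <- stats::phyper(k - 1, K, N - K, nr, lower.tail = FALSE)
  }
  both <- intersect(names(oa), names(ob))
  offsets <- if (length(both)) table(ob[both] - oa[both]) else table(integer())
  modal <- if (length(both))
    as.integer(names(offsets)[which.max(offsets)]) else NA_integer_
  structure(list(counts = counts, p_values = pv, flagged = pv < p_flag,
                 modal_offset = modal, offsets = offsets,
                 universe_size = N, sex_class = sex_class),
            class = "onset_matrix")
}

#' @export
print.onset_matrix <- function(x, ...) {
  cat(sprintf("Onset matrix (%s), universe %d probes\n", x$sex_class,
              x$universe_size))
  m <- matrix(sprintf("%d%s", x$counts, ifelse(x$flagged, "*", "")),
              nrow(x$counts), dimnames = dimnames(x$counts))
  print(m, quote = FALSE)
  cat(sprintf("modal onset offset (B - A): %+d stage(s)\n", x$modal_offset))
  cat("* cell overlap p < 0.001 (hypergeometric)\n")
  invisible(x)
}

#' Two-sex fold-change scatter classification
#'
#' Computes, per probe, the log2 change from stage 1 to the final stage
#' separately in XX and XY samples of one strain, and assigns the
#' quadrant classes of the first-vs-last-stage scatter: similarly up/down
#' (both sexes beyond the threshold, same sign), enrichment of one sex via
#' activation (that sex up, the other flat), via repression (the other sex
#' down, this sex flat), via both, or unchanged.
#'
#' @param dataset an [expression_dataset()].
#' @param strain strain label.
#' @param threshold log2 change threshold (default 0.585, a 1.5-fold
#'   change).
#' @param probes optional probe subset.
#' @return data.frame: `probe`, `change_XY`, `change_XX`, `class`
#'   (similarly_up, similarly_down, male_enriched, female_enriched,
#'   unchanged), `mechanism` (activation, repression, both, or NA).
#' @export
scatter_classification <- function(dataset, strain, threshold = 0.585,
                                   probes = NULL) {
  d <- dataset$design
  T_ <- n_stages(dataset)
  if (is.null(probes)) probes <- rownames(dataset$exprs)
  ch <- list()
  for (sx in c("XY", "XX")) {
    i0 <- cell_index(d, sx, strain, 1)
    i1 <- cell_index(d, sx, strain, T_)
    ch[[sx]] <- rowMeans(dataset$exprs[probes, i1, drop = FALSE]) -
      rowMeans(dataset$exprs[probes, i0, drop = FALSE])
  }
  up_y <- ch$XY > threshold; dn_y <- ch$XY < -threshold
  up_x <- ch$XX > threshold; dn_x <- ch$XX < -threshold
  flat_y <- !up_y & !dn_y; flat_x <- !up_x & !dn_x
  cls <- rep("unchanged", length(probes))
  mech <- rep(NA_character_, length(probes))
  cls[up_y & up_x] <- "similarly_up"
  cls[dn_y & dn_x] <- "similarly_down"
  cls[up_y & flat_x] <- "male_enriched"; mech[up_y & flat_x] <- "activation"
  cls[flat_y & dn_x] <- "male_enriched"; mech[flat_y & dn_x] <- "repression"
  cls[up_y & dn_x] <- "male_enriched"; mech[up_y & dn_x] <- "both"
  cls[up_x & flat_y] <- "female_enriched"; mech[up_x & flat_y] <- "activation"
  cls[flat_x & dn_y] <- "female_enriched"; mech[flat_x & dn_y] <- "repression"
  cls[up_x & dn_y] <- "female_enriched"; mech[up_x & dn_y] <- "both"
  data.frame(probe = probes, change_XY = unname(ch$XY),
             change_XX = unname(ch$XX), class = cls, mechanism = mech,
             stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set overlap test
#'
#' One-sided over-representation test for the overlap of two probe sets
#' within a common universe.
#'
#' @param set_a,set_b character vectors of probe ids, subsets of
#'   `universe`.
#' @param universe character vector, the probe universe.
#' @return list: `overlap`, `fraction` (|a n b| / |a|), `p_value`.
#' @export
test_gene_set_overlap <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of the universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_b),
                     length(universe) - length(set_b), length(set_a),
                     lower.tail = FALSE)
  list(overlap = k,
       fraction = if (length(set_a)) k / length(set_a) else NA_real_,
       p_value = p)
}

#' Exact binomial test of onset robustness between strains
#'
#' Among probes of one enrichment class that become dimorphic at the same
#' stage in both strains, tests whether the fraction with a larger |FD| at
#' onset in strain A exceeds 1/2 (one-sided exact binomial test).
#'
#' @param calls_a,calls_b `enrichment_calls` for the two strains.
#' @param fds_a,fds_b matching `fd_series` objects ([fold_differences()]
#'   elements) for the two strains.
#' @param sex_class enrichment class to test.
#' @return list: `n_same_onset`, `n_larger_in_A`, `fraction`, `p_value`.
#' @export
onset_robustness_test <- function(calls_a, calls_b, fds_a, fds_b,
                                  sex_class = "male_enriched") {
  oa <- stats::setNames(calls_a$onset, calls_a$id)[calls_a$class == sex_class]
  ob <- stats::setNames(calls_b$onset, calls_b$id)[calls_b$class == sex_class]
  both <- intersect(names(oa), names(ob))
  same <- both[oa[both] == ob[both]]
  if (length(same) == 0)
    return(list(n_same_onset = 0L, n_larger_in_A = 0L, fraction = NA_real_,
                p_value = NA_real_))
  fa <- abs(fds_a$fd[cbind(match(same, rownames(fds_a$fd)), oa[same])])
  fb <- abs(fds_b$fd[cbind(match(same, rownames(fds_b$fd)), ob[same])])
  k <- sum(fa > fb)
  bt <- stats::binom.test(k, length(same), p = 0.5, alternative = "greater")
  list(n_same_onset = length(same), n_larger_in_A = k,
       fraction = k / length(same), p_value = bt$p.value)
}
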