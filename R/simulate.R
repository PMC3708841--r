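#' Simulation configuration for a planted dimorphism time course
#'
#' Describes a synthetic gonad-style expression study: two strains, two
#' sexes, T stages, replicated cells, with a fraction of genes planted to
#' become sexually dimorphic along an onset cascade. Defaults emulate the
#' design of a fine 24-hour time course: 6 stages, 3 replicates per
#' sex x strain x stage, a 1-stage onset delay in strain B, log2 effect 1.0
#' and replicate noise sd 0.25.
#'
#' @param n_genes total genes simulated (including background genes).
#' @param frac_dimorphic fraction of *expressed* genes planted dimorphic.
#' @param frac_male fraction of dimorphic genes enriched in XY.
#' @param onset_weights probability weights over onset stages 2..n_stages
#'   for strain A; normalized internally.
#' @param mechanism_mix named proportions over `activate`, `repress`, `both`
#'   (activation in the enriched sex, repression in the other sex, or half
#'   of each); normalized internally.
#' @param strain_delay integer >= 0, stages added to strain-B onsets; genes
#'   delayed past the last stage are not dimorphic in strain B.
#' @param effect asymptotic |log2 fold difference| of planted genes.
#' @param noise_sd per-cell Gaussian noise sd on the log2 scale.
#' @param n_replicates replicates per sex x strain x stage cell.
#' @param n_stages number of stages T (>= 2).
#' @param frac_background fraction of genes that are unexpressed background
#'   (flat low signal, detection p near 1).
#' @param ramp_intervals stages over which the planted difference ramps
#'   linearly to its full value; 1 means the full effect is present at the
#'   onset stage itself.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       frac_dimorphic = 0.3,
                       frac_male = 0.5,
                       onset_weights = c(0.05, 0.10, 0.20, 0.30, 0.35),
                       mechanism_mix = c(activate = 0.7, repress = 0.2,
                                         both = 0.1),
                       strain_delay = 1,
                       effect = 1.0,
                       noise_sd = 0.25,
                       n_replicates = 3,
                       n_stages = 6,
                       frac_background = 0.2,
                       ramp_intervals = 1,
                       seed = 1) {
  if (n_genes < 1 || n_replicates < 1)
    stop("configuration error: counts must be positive")
  if (noise_sd <= 0 || effect <= 0)
    stop("configuration error: effect and noise_sd must be positive")
  if (n_stages < 2) stop("configuration error: n_stages must be >= 2")
  for (p in c(frac_dimorphic, frac_male, frac_background))
    if (p < 0 || p > 1) stop("configuration error: proportions must be in [0,1]")
  if (length(onset_weights) != n_stages - 1 || any(onset_weights < 0) ||
      sum(onset_weights) <= 0)
    stop("configuration error: onset_weights must be ", n_stages - 1,
         " non-negative values")
  if (!all(c("activate", "repress", "both") %in% names(mechanism_mix)))
    stop("configuration error: mechanism_mix needs activate/repress/both")
  if (any(mechanism_mix < 0) || sum(mechanism_mix) <= 0)
    stop("configuration error: mechanism_mix must be non-negative")
  if (strain_delay < 0 || ramp_intervals < 1)
    stop("configuration error: strain_delay >= 0 and ramp_intervals >= 1")
  structure(list(
    n_genes = as.integer(n_genes), frac_dimorphic = frac_dimorphic,
    frac_male = frac_male,
    onset_weights = onset_weights / sum(onset_weights),
    mechanism_mix = mechanism_mix[c("activate", "repress", "both")] /
      sum(mechanism_mix),
    strain_delay = as.integer(strain_delay), effect = effect,
    noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
    n_stages = as.integer(n_stages), frac_background = frac_background,
    ramp_intervals = as.integer(ramp_intervals), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic dimorphism time course with ground truth
#'
#' Simulates a log2 expression matrix for 2 strains x 2 sexes x T stages x R
#' replicates. Dimorphic genes follow a linear log2 ramp from 0 to the full
#' planted fold difference starting at their onset stage, realized by the
#' assigned mechanism: activation raises the enriched sex, repression lowers
#' the other sex, `both` splits the difference. Strain B onsets are delayed
#' by `strain_delay` stages; genes delayed past stage T stay flat in B.
#' Background genes sit at a low flat baseline with detection p near 1;
#' expressed genes get detection p near 0.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (an [expression_dataset()]) and `truth`, a
#'   data.frame with one row per gene: `gene`, `background`, `dimorphic`,
#'   `sex` (enriched sex, "male"/"female"/NA), `onset_A`, `onset_B` (NA when
#'   not dimorphic in that strain), `mechanism`
#'   ("activate"/"repress"/"both"/NA) and `effect`.
#' @export
simulate_timecourse <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  T_ <- config$n_stages
  R <- config$n_replicates
  design <- expand.grid(replicate = seq_len(R), stage = seq_len(T_),
                        sex = c("XX", "XY"), strain = c("A", "B"),
                        stringsAsFactors = FALSE)
  design <- design[, c("strain", "sex", "stage", "replicate")]
  design$sample <- sprintf("%s_%s_s%d_r%d", design$strain, design$sex,
                           design$stage, design$replicate)
  design <- design[, c("sample", "sex", "strain", "stage", "replicate")]

  n <- config$n_genes
  genes <- sprintf("gene%05d", seq_len(n))
  background <- rep(FALSE, n)
  n_bg <- round(n * config$frac_background)
  if (n_bg > 0) background[sample.int(n, n_bg)] <- TRUE
  expressed <- which(!background)

  dimorphic <- rep(FALSE, n)
  n_dim <- round(length(expressed) * config$frac_dimorphic)
  if (n_dim > 0) dimorphic[sample(expressed, n_dim)] <- TRUE

  sex_enr <- rep(NA_character_, n)
  onset_A <- rep(NA_integer_, n)
  onset_B <- rep(NA_integer_, n)
  mechanism <- rep(NA_character_, n)
  idx <- which(dimorphic)
  if (length(idx) > 0) {
    sex_enr[idx] <- ifelse(stats::runif(length(idx)) < config$frac_male,
                           "male", "female")
    onset_A[idx] <- sample(2:T_, length(idx), replace = TRUE,
                           prob = config$onset_weights)
    ob <- onset_A[idx] + config$strain_delay
    onset_B[idx] <- ifelse(ob <= T_, ob, NA_integer_)
    mechanism[idx] <- sample(names(config$mechanism_mix), length(idx),
                             replace = TRUE, prob = config$mechanism_mix)
  }

  baseline <- numeric(n)
  baseline[expressed] <- stats::runif(length(expressed), 6, 12)
  baseline[background] <- stats::runif(sum(background), 3, 4)

  # planted |FD| at stage t for a gene with onset o (0 before onset)
  ramp <- function(t, o) {
    d <- pmax(0, pmin(1, (t - o + 1) / config$ramp_intervals))
    d * config$effect
  }

  mu <- matrix(baseline, n, nrow(design))
  for (j in seq_len(nrow(design))) {
    st <- design$strain[j]; t <- design$stage[j]; sx <- design$sex[j]
    o <- if (st == "A") onset_A else onset_B
    act <- which(dimorphic & !is.na(o) & t >= o)
    if (length(act) == 0) next
    d <- ramp(t, o[act])
    up_sex <- ifelse(sex_enr[act] == "male", "XY", "XX")
    mech <- mechanism[act]
    shift <- numeric(length(act))
    is_up <- sx == up_sex
    shift[mech == "activate" & is_up] <- d[mech == "activate" & is_up]
    shift[mech == "repress" & !is_up] <- -d[mech == "repress" & !is_up]
    shift[mech == "both"] <- ifelse(is_up[mech == "both"], 0.5, -0.5) *
      d[mech == "both"]
    mu[act, j] <- mu[act, j] + shift
  }

  exprs <- mu + matrix(stats::rnorm(n * nrow(design), 0, config$noise_sd),
                       n, nrow(design))
  rownames(exprs) <- genes
  colnames(exprs) <- design$sample

  detection <- matrix(0, n, nrow(design), dimnames = dimnames(exprs))
  detection[expressed, ] <- stats::runif(length(expressed) * nrow(design),
                                         0, 0.001)
  detection[background, ] <- stats::runif(sum(background) * nrow(design),
                                          0.5, 1)

  truth <- data.frame(
    gene = genes, background = background, dimorphic = dimorphic,
    sex = sex_enr, onset_A = onset_A, onset_B = onset_B,
    mechanism = mechanism,
    effect = ifelse(dimorphic, config$effect, NA_real_),
    stringsAsFactors = FALSE
  )
  list(dataset = expression_dataset(exprs, design, detection), truth = truth)
}

#' Write a simulated study to disk
#'
#' Writes expression, design, detection and truth tables as TSV.
#' @param sim result of [simulate_timecourse()].
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
write_simulation <- function(sim, dir) {
  paths <- write_dataset(sim$dataset, dir, prefix = "sim")
  tp <- file.path(dir, "sim_truth.tsv")
  utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, truth = tp))
}
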