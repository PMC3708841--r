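# Shared fixture builders. Everything is generated in code; no files.

# A small hand-controlled dataset: `means` is a probes x (2*2*T) matrix of
# cell means in column order strain(A,B) x sex(XX,XY) x stage(1..T);
# replicates get iid N(0, noise_sd) noise around their cell mean.
manual_dataset <- function(means, n_reps = 3, noise_sd = 0, T_ = NULL,
                           seed = 1) {
  set.seed(seed)
  if (is.null(T_)) T_ <- ncol(means) / 4
  design <- expand.grid(replicate = seq_len(n_reps), stage = seq_len(T_),
                        sex = c("XX", "XY"), strain = c("A", "B"),
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_%s_s%d_r%d", design$strain, design$sex,
                           design$stage, design$replicate)
  design <- design[, c("sample", "sex", "strain", "stage", "replicate")]
  col_of <- function(strain, sex, stage) {
    (match(strain, c("A", "B")) - 1) * 2 * T_ +
      (match(sex, c("XX", "XY")) - 1) * T_ + stage
  }
  exprs <- matrix(NA_real_, nrow(means), nrow(design))
  for (j in seq_len(nrow(design))) {
    mu <- means[, col_of(design$strain[j], design$sex[j], design$stage[j])]
    exprs[, j] <- mu + rnorm(nrow(means), 0, noise_sd)
  }
  rownames(exprs) <- rownames(means)
  if (is.null(rownames(exprs)))
    rownames(exprs) <- sprintf("p%03d", seq_len(nrow(exprs)))
  colnames(exprs) <- design$sample
  expression_dataset(exprs, design)
}

# cell-mean matrix for one flat probe, baseline b
flat_means <- function(b = 8, T_ = 6) matrix(b, 1, 4 * T_)

# a random valid left-to-right model (T stages)
random_hmm <- function(T_ = 6) {
  rrow <- function(n) { x <- runif(n) + 0.05; x / sum(x) }
  pi <- rrow(3)
  A <- lapply(seq_len(T_ - 1), function(t) t(replicate(3, rrow(3))))
  B <- t(replicate(3, rrow(7)))
  m <- hmm_initialize(matrix("s", 2, T_))   # scaffold with right shape
  m$pi <- stats::setNames(pi, m$states)
  m$A <- lapply(A, function(a) { dimnames(a) <- list(m$states, m$states); a })
  m$B <- matrix(B, 3, 7, dimnames = list(m$states, m$alphabet))
  m
}

# random symbol sequence of length T
random_symbols <- function(T_ = 6) sample(c("s", "m1", "m2", "m3",
                                            "f1", "f2", "f3"), T_,
                                          replace = TRUE)

# a 60-gene eQTL-interval annotation fixture with one planted tier-1
# profile (expressed, pathway-consistent dimorphism, expected-direction
# strain dimorphism, variation near the TSS) and 15 unexpressed genes
make_interval <- function(n = 60, seed = 20) {
  set.seed(seed)
  ann <- data.frame(
    gene = sprintf("Gene%02d", seq_len(n)),
    expressed_in_XY = c(rep(TRUE, n - 15), rep(FALSE, 15)),
    dimorphic = FALSE, dimorphic_direction = NA_character_,
    strain_dimorphic = FALSE, strain_direction = NA_character_,
    variant_near_tss = FALSE, abnormal_sd_phenotype = FALSE,
    target_pathway = "male",
    stringsAsFactors = FALSE
  )
  ann[1, c("dimorphic", "strain_dimorphic", "variant_near_tss")] <- TRUE
  ann$dimorphic_direction[1] <- "male"
  ann$strain_direction[1] <- "129S1"
  ann$dimorphic[2:6] <- TRUE; ann$dimorphic_direction[2:6] <- "male"
  ann$strain_dimorphic[4:8] <- TRUE; ann$strain_direction[4:8] <- "129S1"
  ann$variant_near_tss[10:20] <- TRUE
  ann
}

# independent hypergeometric upper-tail oracle via explicit enumeration of
# the probability mass with binomial coefficients
hyper_tail_oracle <- function(k, size_a, size_b, N) {
  j <- k:min(size_a, size_b)
  sum(choose(size_b, j) * choose(N - size_b, size_a - j)) / choose(N, size_a)
}
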