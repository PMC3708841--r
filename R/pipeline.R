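#' Pipeline configuration
#'
#' Bundles either a simulation block or input file paths with the analysis
#' thresholds. All thresholds default to the study values: detection
#' p < 0.005 in >= 2 replicates, screen FDR 0.05, FD gate p < 0.05 and
#' |FD| > 0.3219, quantization edges 0.3219/0.585/1, mechanism threshold
#' 0.32, transition pseudocount 1, 200 Baum-Welch iterations.
#'
#' @param simulation a [sim_config()], or `NULL` when reading from files.
#' @param input_dir directory holding `dataset_*.tsv` files written by
#'   [write_dataset()] (used when `simulation` is `NULL`).
#' @param detection_p,min_replicates detection filter parameters.
#' @param screen_alpha BH-adjusted ANOVA screen level.
#' @param p_gate,fd_gate fold-difference gating parameters.
#' @param thresholds quantization bin edges.
#' @param mechanism_threshold,mechanism_alpha mechanism-test parameters.
#' @param pseudocount,n_iter HMM initialization and training parameters.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(), input_dir = NULL,
                            detection_p = 0.005, min_replicates = 2,
                            screen_alpha = 0.05, p_gate = 0.05,
                            fd_gate = FD_THRESHOLDS[1],
                            thresholds = FD_THRESHOLDS,
                            mechanism_threshold = 0.32,
                            mechanism_alpha = 0.05,
                            pseudocount = 1, n_iter = 200) {
  if (is.null(simulation) && is.null(input_dir))
    stop("either a simulation block or an input directory is required")
  structure(list(simulation = simulation, input_dir = input_dir,
                 detection_p = detection_p, min_replicates = min_replicates,
                 screen_alpha = screen_alpha, p_gate = p_gate,
                 fd_gate = fd_gate, thresholds = thresholds,
                 mechanism_threshold = mechanism_threshold,
                 mechanism_alpha = mechanism_alpha,
                 pseudocount = pseudocount, n_iter = n_iter),
            class = "pipeline_config")
}

#' Run the full onset-of-dimorphism pipeline
#'
#' Executes the stages in order — simulate (or load), quantile normalize,
#' detection filter, factorial ANOVA screen, gated fold differences,
#' quantization, HMM initialization + Baum-Welch training (sequences of
#' both strains pooled), per-strain Viterbi decoding, path clustering,
#' enrichment calls, mechanism classification and cross-strain onset
#' matrices — writing every intermediate table as TSV plus the trained
#' model as JSON and a run manifest. Re-running with the same
#' configuration (and simulation seed) reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (`NULL` to skip writing files).
#' @param normalize quantile-normalize the expression matrix first
#'   (default TRUE; simulated data is already on a common scale but
#'   normalization is harmless).
#' @return invisibly, a list with all stage results (`dataset`, `truth`,
#'   `screen`, `fds`, `symbols`, `model`, `paths`, `calls`,
#'   `onset_matrices`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         normalize = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- simulate_timecourse(config$simulation)
    dataset <- sim$dataset
    truth <- sim$truth
  } else {
    dataset <- read_dataset(config$input_dir)
  }
  if (normalize)
    dataset$exprs <- quantile_normalize(dataset$exprs)

  detected <- if (!is.null(dataset$detection))
    filter_detected(dataset, config$detection_p, config$min_replicates)
  else rownames(dataset$exprs)
  screen <- screen_probes(dataset, alpha = config$screen_alpha,
                          probes = detected)
  kept <- screen$probe[screen$passes_screen]

  if (length(kept) == 0) {
    empty <- call_enrichment(character(0))
    res <- list(dataset = dataset, truth = truth, screen = screen,
                fds = NULL, symbols = NULL, model = NULL, paths = NULL,
                clusters = NULL,
                calls = stats::setNames(rep(list(empty), length(strains(dataset))),
                                        strains(dataset)),
                onset_matrices = list(),
                manifest = list(funnel = list(
                  n_probes = nrow(dataset$exprs),
                  n_detected = length(detected), n_screened = 0L)))
    return(invisible(res))
  }
  fds <- fold_differences(dataset, probes = kept, p_gate = config$p_gate,
                          fd_gate = config$fd_gate)
  symbols <- quantize_series(fds, thresholds = config$thresholds)
  model <- dimorphism_hmm(symbols, n_iter = config$n_iter,
                          pseudocount = config$pseudocount)

  paths <- lapply(symbols, function(s) predict(model, s))
  clusters <- lapply(paths, cluster_paths)
  calls <- list()
  for (st in names(paths)) {
    cl <- call_enrichment(paths[[st]])
    calls[[st]] <- classify_mechanism(dataset, cl, st,
                                      threshold = config$mechanism_threshold,
                                      alpha = config$mechanism_alpha)
  }
  onset_matrices <- list()
  if (length(calls) >= 2) {
    ab <- names(calls)[1:2]
    for (cls in c("male_enriched", "female_enriched")) {
      if (any(calls[[ab[1]]]$class == cls) &&
          any(calls[[ab[2]]]$class == cls))
        onset_matrices[[cls]] <-
          compare_strain_onsets(calls[[ab[1]]], calls[[ab[2]]], cls)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cascadeHMM")),
    seed = if (!is.null(config$simulation)) config$simulation$seed else NULL,
    thresholds = config[c("detection_p", "min_replicates", "screen_alpha",
                          "p_gate", "fd_gate", "thresholds",
                          "mechanism_threshold", "mechanism_alpha",
                          "pseudocount", "n_iter")],
    funnel = list(
      n_probes = nrow(dataset$exprs),
      n_detected = length(detected),
      n_screened = length(kept),
      n_dimorphic = lapply(calls, function(cl)
        sum(cl$class %in% c("male_enriched", "female_enriched"))),
      n_switch = lapply(calls, function(cl) sum(cl$class == "switch")),
      populated_paths = lapply(clusters, nrow),
      path_space = 3^model$n_stages
    )
  )

  res <- list(dataset = dataset, truth = truth, screen = screen, fds = fds,
              symbols = symbols, model = model, paths = paths,
              clusters = clusters, calls = calls,
              onset_matrices = onset_matrices, manifest = manifest)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  invisible(res)
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_dataset(res$dataset, outdir)
  if (!is.null(res$truth)) wtsv(res$truth, "truth.tsv")
  wtsv(as.data.frame(res$screen), "screen.tsv")
  for (st in names(res$fds)) {
    write_matrix_tsv(res$fds[[st]]$gated,
                     file.path(outdir, sprintf("fd_gated_%s.tsv", st)))
    write_matrix_tsv(res$symbols[[st]],
                     file.path(outdir, sprintf("symbols_%s.tsv", st)))
    wtsv(res$paths[[st]], sprintf("paths_%s.tsv", st))
    wtsv(as.data.frame(res$calls[[st]]), sprintf("calls_%s.tsv", st))
    wtsv(as.data.frame(res$clusters[[st]]), sprintf("clusters_%s.tsv", st))
  }
  for (cls in names(res$onset_matrices)) {
    om <- res$onset_matrices[[cls]]
    utils::write.table(as.data.frame.matrix(om$counts),
                       file.path(outdir, sprintf("onset_matrix_%s.tsv", cls)),
                       sep = "\t", quote = FALSE)
  }
  write_hmm(res$model, file.path(outdir, "model.json"))
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
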