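#' Rank candidate regulatory genes in an eQTL interval
#'
#' Implements the interval-candidate filter: genes not expressed in the XY
#' gonad by the mid-window stage are excluded outright; the remaining
#' genes are scored on three criteria — (1) sexually dimorphic expression
#' consistent with the target pathway of the eQTL, (2) strain-dimorphic
#' expression in the direction of the observed allelic effect, and (3)
#' characterized variation within 10 kb of the TSS — and placed in
#' lexicographic tiers: tier 1 = all three criteria (or a known abnormal
#' sex-determination knockout phenotype, which promotes a gene to tier 1
#' regardless), tier 2 = any two, tier 3 = one, tier 4 = none. Ties within
#' a tier are broken alphabetically by gene id, giving a deterministic
#' total order.
#'
#' @param annotations data.frame with one row per gene and columns:
#'   `gene`; `expressed_in_XY` (logical: expressed above background at or
#'   before the mid-window stage); `dimorphic` (logical) and
#'   `dimorphic_direction` (`"male"`/`"female"`/NA); `strain_dimorphic`
#'   (logical) and `strain_direction` (label of the higher-expressing
#'   strain, NA when not strain-dimorphic); `variant_near_tss` (logical);
#'   `abnormal_sd_phenotype` (logical); `target_pathway`
#'   (`"male"`, `"female"`, `"early_gonadogenesis"` or `"any"`).
#' @param expected_strain_direction strain whose allele raises target
#'   expression (e.g. `"129S1"`); a gene's strain criterion holds only
#'   when its `strain_direction` matches.
#' @return data.frame ranked best-first with the per-criterion booleans,
#'   `n_criteria`, `tier` and `rank`; unexpressed genes are absent.
#' @export
prioritize_candidates <- function(annotations, expected_strain_direction) {
  need <- c("gene", "expressed_in_XY", "dimorphic", "dimorphic_direction",
            "strain_dimorphic", "strain_direction", "variant_near_tss",
            "abnormal_sd_phenotype", "target_pathway")
  if (nrow(annotations) == 0) stop("empty annotation list")
  if (!all(need %in% names(annotations)))
    stop("annotations must have columns: ", paste(need, collapse = ", "))
  ann <- annotations[annotations$expressed_in_XY %in% TRUE, , drop = FALSE]
  if (nrow(ann) == 0)
    return(data.frame(gene = character(), tier = integer(),
                      rank = integer()))
  dim_ok <- ann$dimorphic %in% TRUE &
    (ann$target_pathway %in% c("any", "early_gonadogenesis") |
       (!is.na(ann$dimorphic_direction) &
          ann$dimorphic_direction == ann$target_pathway))
  strain_ok <- ann$strain_dimorphic %in% TRUE &
    !is.na(ann$strain_direction) &
    ann$strain_direction == expected_strain_direction
  var_ok <- ann$variant_near_tss %in% TRUE
  n_crit <- dim_ok + strain_ok + var_ok
  tier <- ifelse(ann$abnormal_sd_phenotype %in% TRUE | n_crit == 3, 1L,
                 ifelse(n_crit == 2, 2L, ifelse(n_crit == 1, 3L, 4L)))
  out <- data.frame(gene = ann$gene, dimorphic_consistent = dim_ok,
                    strain_consistent = strain_ok, variant_near_tss = var_ok,
                    abnormal_sd_phenotype = ann$abnormal_sd_phenotype %in% TRUE,
                    n_criteria = as.integer(n_crit), tier = tier,
                    stringsAsFactors = FALSE)
  out <- out[order(out$tier, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
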