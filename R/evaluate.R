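# Evaluation of a pipeline run against the generator's planted truth:
# ELE recall/precision, target-link recall and enrichment, homology
# category agreement, LTR age recovery.

#' Evaluate called ELEs against planted truth
#'
#' A called ELE cluster is a true positive iff it overlaps a planted ELE
#' interval; a planted ELE is recovered iff at least one called cluster
#' overlaps it.
#'
#' @param eles called ELE data.frame (`chrom`, `start`, `end`).
#' @param truth_eles planted ELE data.frame (`chrom`, `start`, `end`).
#' @return list with `recall`, `precision`, `n_called`, `n_truth`.
#' @export
evaluate_ele_calls <- function(eles, truth_eles) {
  if (nrow(truth_eles) == 0L) .stopf("no planted ELEs to evaluate")
  hits <- overlap_pairs(eles, truth_eles)
  list(recall = length(unique(hits$subject)) / nrow(truth_eles),
       precision = if (nrow(eles) == 0L) NA_real_
       else length(unique(hits$query)) / nrow(eles),
       n_called = nrow(eles), n_truth = nrow(truth_eles))
}

# Map called ELE cluster ids to planted truth ids by interval overlap.
.match_truth_ele <- function(eles, truth_eles) {
  hits <- overlap_pairs(eles, truth_eles)
  out <- rep(NA_character_, nrow(eles))
  out[hits$query] <- truth_eles$truth_id[hits$subject]
  out
}

#' Evaluate predicted ELE-gene links against planted links
#'
#' Recall is the fraction of planted (ELE, target) links recovered by a
#' predicted pair of a matching called ELE; the enrichment p-value is a
#' two-tailed Fisher test of predicted status against planted-link status
#' over all candidate pairs.
#'
#' @param links `target_links` from [predict_targets()].
#' @param eles called ELE data.frame with `ele_id`.
#' @param truth_eles planted ELEs with `truth_id` and `target_gene`.
#' @return list with `recall`, `fisher_p`, `n_true_links`.
#' @export
evaluate_targets <- function(links, eles, truth_eles) {
  truth_id <- .match_truth_ele(eles, truth_eles)
  link_truth <- truth_id[match(links$ele_id, eles$ele_id)]
  true_target <- truth_eles$target_gene[match(link_truth,
                                              truth_eles$truth_id)]
  is_true <- !is.na(true_target) & links$gene_id == true_target
  planted <- truth_eles[!is.na(truth_eles$target_gene), , drop = FALSE]
  recovered <- vapply(seq_len(nrow(planted)), function(i) {
    any(is_true & links$predicted &
          link_truth == planted$truth_id[i] &
          links$gene_id == planted$target_gene[i], na.rm = TRUE)
  }, TRUE)
  ft <- fisher_exact_2x2(sum(links$predicted & is_true, na.rm = TRUE),
                         sum(links$predicted & !is_true, na.rm = TRUE),
                         sum(!links$predicted & is_true, na.rm = TRUE),
                         sum(!links$predicted & !is_true, na.rm = TRUE))
  list(recall = mean(recovered), fisher_p = ft$p,
       n_true_links = nrow(planted))
}

#' Evaluate subgenome-homology categories for a hosted subfamily
#'
#' @param run `ele_run` object.
#' @param subfamily TE subfamily of interest.
#' @param home home subgenome label. Default "A".
#' @return fraction of called ELEs hosted by `subfamily` categorized as
#'   `<home>_specific`.
#' @export
evaluate_subfamily_specificity <- function(run, subfamily = "RLG_famc7.3",
                                           home = "A") {
  hosted <- run$te_assign$ele_id[!is.na(run$te_assign$subfamily) &
                                   run$te_assign$subfamily == subfamily]
  cat_ <- run$homology$categories
  cat_ <- cat_[cat_$ele_id %in% hosted & cat_$subgenome == home, ,
               drop = FALSE]
  if (nrow(cat_) == 0L) return(NA_real_)
  mean(cat_$category == paste0(home, "_specific"))
}

#' Evaluate LTR insertion-age recovery
#'
#' @param ltr_ages output of [ltr_age()].
#' @param truth_ltr planted divergences/ages (`te_id`,
#'   `age_generations`).
#' @return list with `mean_relative_error` of the mean estimated age and
#'   per-element data.frame.
#' @export
evaluate_ltr_ages <- function(ltr_ages, truth_ltr) {
  m <- merge(ltr_ages, truth_ltr, by = "te_id")
  m <- m[!m$saturated, , drop = FALSE]
  if (nrow(m) == 0L) .stopf("no dateable LTR elements")
  list(mean_relative_error =
         abs(mean(m$time_generations) - mean(m$age_generations)) /
         mean(m$age_generations),
       per_element = m)
}
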