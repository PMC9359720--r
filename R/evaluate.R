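#' @include em.R
NULL

#' Operating characteristics of the responder classifiers by simulation
#'
#' Repeatedly simulates cohorts with known ground-truth labels from a growth
#' configuration, runs the chosen classifier, and pools the confusion counts
#' over replicates: sensitivity is the fraction of true responders labelled
#' responder, specificity the fraction of true (treated) nonresponders
#' labelled nonresponder. With a `control_n_grid`, the misclassification rate
#' of the significance-based rule ([significanceClassify()]) is additionally
#' evaluated as a function of control-group size, the regime in which that
#' rule degrades as controls accumulate.
#'
#' @param config a `GrowthSimConfig` (e.g. [boundaryStressConfig()]) defining
#'   the true labels.
#' @param method "em" ([emAllocate()]) or "threshold" ([thresholdClassify()]).
#' @param level classification level, "mouse" or "tumor".
#' @param n_replicates number of simulated cohorts.
#' @param seed integer seed; per-replicate seeds are drawn from it.
#' @param threshold slope cut for the threshold rule / EM initialization.
#' @param control_n_grid optional integer vector of control-group sizes for
#'   the significance-rule misclassification curve.
#' @return list of class `ClassifierReport`: sensitivity, specificity (NA
#'   when a true class is empty), n_replicates, counts (pooled tp/fn/tn/fp),
#'   confusion (per-replicate data.frame), method, level, and
#'   control_size_curve (data.frame n_control, misclassification; NULL unless
#'   requested).
#' @examples
#' \donttest{
#' rep <- evaluateClassifier(boundaryStressConfig(), method = "threshold",
#'                           n_replicates = 20, seed = 1)
#' c(rep$sensitivity, rep$specificity)
#' }
#' @export
evaluateClassifier <- function(config, method = c("em", "threshold"),
                               level = c("mouse", "tumor"),
                               n_replicates = 100, seed = 1L,
                               threshold = 0.05, control_n_grid = NULL) {
  method <- match.arg(method)
  level <- match.arg(level)
  if (!inherits(config, "GrowthSimConfig"))
    stop("'config' must come from growthSimConfig()")
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(2^31 - 2, n_replicates)
  counts <- c(tp = 0L, fn = 0L, tn = 0L, fp = 0L)
  confusion <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cohort <- simulateGrowthCohort(config, seed = rep_seeds[i])
    truth <- cohortTruth(cohort, level)
    truth <- truth[truth$arm == "treated", , drop = FALSE]
    pred <- if (method == "em") {
      allocationLabels(emAllocate(cohort, level = level, threshold = threshold))
    } else {
      treated <- cohort[cohort$arm == "treated", , drop = FALSE]
      sl <- fitGrowthSlopes(treated, level)
      setNames(thresholdClassify(sl$slope, threshold), sl$unit_id)
    }
    pred <- pred[truth$unit_id]
    is_resp <- truth$true_group == "responder"
    ci <- c(tp = sum(is_resp & pred == "responder"),
            fn = sum(is_resp & pred == "nonresponder"),
            tn = sum(!is_resp & pred == "nonresponder"),
            fp = sum(!is_resp & pred == "responder"))
    counts <- counts + ci
    confusion[[i]] <- data.frame(replicate = i, t(ci))
  }
  curve <- NULL
  if (!is.null(control_n_grid)) {
    set.seed(as.integer(seed) + 1L)
    grid_seeds <- matrix(sample.int(2^31 - 2, n_replicates * length(control_n_grid)),
                         nrow = n_replicates)
    curve <- data.frame(n_control = as.integer(control_n_grid),
                        misclassification = NA_real_)
    for (k in seq_along(control_n_grid)) {
      cfg <- config
      cfg$n_control <- as.integer(control_n_grid[k])
      miss <- numeric(n_replicates)
      for (i in seq_len(n_replicates)) {
        cohort <- simulateGrowthCohort(cfg, seed = grid_seeds[i, k])
        truth <- cohortTruth(cohort, level)
        sl <- fitGrowthSlopes(cohort, level)
        sl <- merge(sl[c("unit_id", "slope")], truth, by = "unit_id")
        trt <- sl[sl$arm == "treated", , drop = FALSE]
        ctl <- sl[sl$arm == "control", , drop = FALSE]
        pred <- significanceClassify(trt$slope, ctl$slope)
        true_lab <- ifelse(trt$true_group == "responder",
                           "responder", "nonresponder")
        miss[i] <- mean(pred != true_lab)
      }
      curve$misclassification[k] <- mean(miss)
    }
  }
  structure(list(
    sensitivity = if (counts["tp"] + counts["fn"] > 0)
      unname(counts["tp"] / (counts["tp"] + counts["fn"])) else NA_real_,
    specificity = if (counts["tn"] + counts["fp"] > 0)
      unname(counts["tn"] / (counts["tn"] + counts["fp"])) else NA_real_,
    n_replicates = n_replicates,
    counts = counts,
    confusion = do.call(rbind, confusion),
    method = method, level = level,
    control_size_curve = curve), class = "ClassifierReport")
}
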