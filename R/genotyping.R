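## fit + OTV-detect + QC-classify one probeset at a given penalty
.process_probeset <- function(points, penalty, thresholds, otv_size_gap,
                              confidence_threshold) {
  ok <- stats::complete.cases(points[, c("contrast", "size")])
  if (sum(ok) < 5L) {
    calls <- rep("NN", nrow(points))
    metrics <- qc_metrics(calls, points)
    cls <- classify_probeset(metrics, NULL, thresholds)
    return(list(model = NULL, calls = calls, confidence = rep(NA_real_,
                nrow(points)), metrics = metrics, class = cls))
  }
  model <- fit_genotype_clusters(points, inbred_penalty = penalty)
  res <- detect_otv(model, points, otv_size_gap = otv_size_gap,
                    confidence_threshold = confidence_threshold)
  metrics <- qc_metrics(res$calls$call, points)
  cls <- classify_probeset(metrics, res$model, thresholds)
  list(model = res$model, calls = res$calls$call,
       confidence = res$calls$confidence, metrics = metrics, class = cls)
}

#' Two-step genotype calling over a signal table
#'
#' Step 1 fits, calls and classifies every probeset with a mild inbred
#' penalty (default 4). Probesets classified `Other` or `NMH` are then
#' reprocessed with a strong penalty (default 16) and re-classified; calls
#' for all other probesets are left exactly as in step 1. Off-target-variant
#' detection runs in both steps.
#'
#' @param signal_table Long-format data.frame with columns `probeset_id`,
#'   `sample_id`, `signal_a`, `signal_b` (see [read_signal_table()]).
#' @param penalty_step1,penalty_step2 Inbred penalties for the two passes.
#' @param thresholds A [qc_thresholds()] list.
#' @param otv_size_gap,confidence_threshold Passed to [detect_otv()] and
#'   [call_genotypes()].
#' @return list with elements
#'   \describe{
#'     \item{calls}{character matrix, samples x probesets, in
#'       `AA/AB/BB/OO/NN`.}
#'     \item{models}{named list of final `probeset_model`s (may contain
#'       `NULL` for unfittable probesets).}
#'     \item{qc}{per-probeset QC report (metrics + category + flags).}
#'     \item{step_log}{data.frame recording which probesets were
#'       reprocessed and the category at each step.}
#'   }
#' @export
two_step_genotyping <- function(signal_table, penalty_step1 = 4,
                                penalty_step2 = 16,
                                thresholds = qc_thresholds(),
                                otv_size_gap = 2,
                                confidence_threshold = 0.95) {
  req <- c("probeset_id", "sample_id", "signal_a", "signal_b")
  if (!is.data.frame(signal_table) || !all(req %in% names(signal_table))) {
    stop("signal_table must have columns ", paste(req, collapse = ", "))
  }
  probesets <- unique(signal_table$probeset_id)
  samples <- unique(signal_table$sample_id)
  if (length(probesets) == 0L) {
    return(list(calls = matrix(character(0), 0, 0), models = list(),
                qc = data.frame(), step_log = data.frame()))
  }
  cs <- to_contrast_size(signal_table$signal_a, signal_table$signal_b)
  pidx <- match(signal_table$probeset_id, probesets)
  sidx <- match(signal_table$sample_id, samples)
  contrast_m <- matrix(NA_real_, length(samples), length(probesets))
  size_m <- contrast_m
  contrast_m[cbind(sidx, pidx)] <- cs$contrast
  size_m[cbind(sidx, pidx)] <- cs$size

  calls <- matrix("NN", length(samples), length(probesets),
                  dimnames = list(samples, probesets))
  models <- stats::setNames(vector("list", length(probesets)), probesets)
  qc_rows <- vector("list", length(probesets))
  cat1 <- character(length(probesets))
  cat2 <- rep(NA_character_, length(probesets))

  for (i in seq_along(probesets)) {
    pts <- data.frame(contrast = contrast_m[, i], size = size_m[, i])
    res <- .process_probeset(pts, penalty_step1, thresholds, otv_size_gap,
                             confidence_threshold)
    cat1[i] <- res$class$category
    if (res$class$category %in% c("Other", "NMH")) {
      res <- .process_probeset(pts, penalty_step2, thresholds, otv_size_gap,
                               confidence_threshold)
      cat2[i] <- res$class$category
    }
    calls[, i] <- res$calls
    models[[i]] <- res$model
    qc_rows[[i]] <- cbind(data.frame(probeset_id = probesets[i]),
                          res$metrics, res$class)
  }
  qc <- do.call(rbind, qc_rows)
  rownames(qc) <- NULL
  step_log <- data.frame(probeset_id = probesets,
                         reprocessed = !is.na(cat2),
                         category_step1 = cat1,
                         category_step2 = cat2,
                         category_final = ifelse(is.na(cat2), cat1, cat2))
  list(calls = calls, models = models, qc = qc, step_log = step_log)
}
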