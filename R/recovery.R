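# Estimator-recovery report: compares purity/CCF/LOH3p estimates on a
# simulated cohort against the generator's retained ground truth.

#' Recovery report: estimates versus simulated truth
#'
#' Aligns clonality estimates and LOH3p calls with the truth table by
#' sample id and reports bias and mean absolute error for tumor purity and
#' for the CCF of each BSE gene, plus the 3-state confusion matrix for the
#' LOH3p caller.
#'
#' @param truth Truth data frame from [simulate_cohort()].
#' @param clonality Output of [estimate_clonality()] on the simulated reads.
#' @param loh_calls Optional output of [call_loh3p_cohort()].
#' @return List of class `recovery_report`: `purity` (bias, mae, n),
#'   `ccf` (per-gene data frame of bias, mae, n), `loh_confusion`
#'   (truth x call matrix or `NULL`), `loh_metrics` (sensitivity,
#'   specificity for LOH vs retention and loss-vs-isodisomy accuracy).
#' @export
recovery_report <- function(truth, clonality, loh_calls = NULL) {
  tp_est <- clonality[!duplicated(clonality$sample_id),
                      c("sample_id", "tp")]
  idx <- match(tp_est$sample_id, truth$sample_id)
  if (any(is.na(idx)))
    stop("sample ids in estimates not found in truth", call. = FALSE)
  d_tp <- tp_est$tp - truth$true_purity[idx]
  purity <- list(bias = mean(d_tp, na.rm = TRUE),
                 mae = mean(abs(d_tp), na.rm = TRUE),
                 n = sum(!is.na(d_tp)))

  ccf <- do.call(rbind, lapply(BSE_GENES, function(g) {
    est <- clonality[!is.na(clonality$gene) & clonality$gene == g, ]
    ti <- match(est$sample_id, truth$sample_id)
    tr <- truth[[paste0("true_ccf_", g)]][ti]
    d <- est$ccf - tr
    data.frame(gene = g, bias = mean(d, na.rm = TRUE),
               mae = mean(abs(d), na.rm = TRUE), n = sum(!is.na(d)),
               stringsAsFactors = FALSE)
  }))

  loh_confusion <- NULL
  loh_metrics <- NULL
  if (!is.null(loh_calls)) {
    li <- match(loh_calls$sample_id, truth$sample_id)
    if (any(is.na(li)))
      stop("sample ids in LOH calls not found in truth", call. = FALSE)
    lv <- c("retention", "loss", "isodisomy")
    loh_confusion <- table(truth = factor(truth$true_3p_state[li], lv),
                           call = factor(loh_calls$status, lv))
    true_loh <- truth$true_3p_state[li] != "retention"
    call_loh <- loh_calls$status != "retention"
    sens <- if (any(true_loh)) mean(call_loh[true_loh]) else NA_real_
    spec <- if (any(!true_loh)) mean(!call_loh[!true_loh]) else NA_real_
    sub <- true_loh & call_loh
    lva <- if (any(sub))
      mean(loh_calls$status[sub] == truth$true_3p_state[li][sub])
    else NA_real_
    loh_metrics <- list(sensitivity = sens, specificity = spec,
                        loss_vs_isodisomy_accuracy = lva)
  }
  structure(list(purity = purity, ccf = ccf,
                 loh_confusion = loh_confusion, loh_metrics = loh_metrics),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Purity: bias %+.4f, MAE %.4f (n = %d)\n", x$purity$bias,
              x$purity$mae, x$purity$n))
  cat("CCF recovery by gene:\n")
  print(transform(x$ccf, bias = round(bias, 4), mae = round(mae, 4)),
        row.names = FALSE)
  if (!is.null(x$loh_metrics)) {
    cat(sprintf(
      "LOH3p: sensitivity %.3f, specificity %.3f, loss-vs-isodisomy accuracy %.3f\n",
      x$loh_metrics$sensitivity, x$loh_metrics$specificity,
      x$loh_metrics$loss_vs_isodisomy_accuracy))
    print(x$loh_confusion)
  }
  invisible(x)
}
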