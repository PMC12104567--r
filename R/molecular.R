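# Scalar molecular quantifications: qPCR 2^-ddCt relative expression and
# western-blot densitometry normalization; plus behavioral table helpers.

#' Relative gene expression by the 2^-ddCt method
#'
#' For each sample, `dCt = ct_target - ct_reference` (normalization to the
#' internal reference gene, e.g. beta-actin); `ddCt = dCt - baseline`, where
#' the baseline is the arithmetic mean dCt of the control group (default) or
#' a position-paired control sample; relative expression is `2^(-ddCt)`.
#' With the group-mean baseline, the geometric mean expression of the
#' control group is exactly 1.
#'
#' @param samples data.frame with columns `subject_id`, `group_label`,
#'   `ct_target`, `ct_reference`.
#' @param control_group Label of the calibrator group (must be present).
#' @param baseline `"group_mean"` (default) or `"paired"` (i-th non-control
#'   sample calibrated against the i-th control sample; requires equal group
#'   sizes).
#' @return The input with added columns `dct`, `ddct`, `rel_expression`.
#' @export
ddct_relative_expression <- function(samples, control_group,
                                     baseline = c("group_mean", "paired")) {
  baseline <- match.arg(baseline)
  need <- c("subject_id", "group_label", "ct_target", "ct_reference")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    stop_validation("samples must have columns %s", paste(need, collapse = ", "))
  }
  ct <- c(samples$ct_target, samples$ct_reference)
  if (any(!is.finite(ct))) stop_validation("Ct values must be finite")
  if (any(ct < 5 | ct > 40)) {
    warning("Ct values outside the typical 5-40 cycle range", call. = FALSE)
  }
  is_ctrl <- samples$group_label == control_group
  if (!any(is_ctrl)) {
    stop_validation("control group '%s' not present", control_group)
  }
  out <- samples
  out$dct <- samples$ct_target - samples$ct_reference
  if (baseline == "group_mean") {
    base <- mean(out$dct[is_ctrl])
    out$ddct <- out$dct - base
  } else {
    ctrl_dct <- out$dct[is_ctrl]
    out$ddct <- NA_real_
    out$ddct[is_ctrl] <- ctrl_dct - ctrl_dct
    for (g in setdiff(unique(out$group_label), control_group)) {
      sel <- out$group_label == g
      if (sum(sel) != length(ctrl_dct)) {
        stop_validation("paired baseline needs equal group sizes ('%s' vs control)", g)
      }
      out$ddct[sel] <- out$dct[sel] - ctrl_dct
    }
  }
  out$rel_expression <- 2^(-out$ddct)
  out
}

#' Densitometry normalization to the internal loading control
#'
#' `ratio = intensity_target / intensity_control` per sample (lane); the
#' ratio is invariant to rescaling both intensities by a common factor.
#'
#' @param records data.frame with columns `subject_id`, `group_label`,
#'   `intensity_target`, `intensity_control` (all intensities > 0).
#' @return The input with an added `norm_ratio` column.
#' @export
normalize_densitometry <- function(records) {
  need <- c("subject_id", "group_label", "intensity_target", "intensity_control")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop_validation("records must have columns %s", paste(need, collapse = ", "))
  }
  if (any(!is.finite(records$intensity_target)) ||
      any(!is.finite(records$intensity_control)) ||
      any(records$intensity_target <= 0) ||
      any(records$intensity_control <= 0)) {
    stop_validation("intensities must be finite and > 0")
  }
  records$norm_ratio <- records$intensity_target / records$intensity_control
  records
}

#' Read a delimited measurement table
#'
#' Tab-separated, header row; checks the required columns are present.
#'
#' @param path TSV path.
#' @param required Character vector of required column names.
#' @return A data.frame.
#' @export
read_measure_table <- function(path, required = character(0)) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(required %in% names(df))) {
    stop_parse("table %s lacks columns: %s", path,
               paste(setdiff(required, names(df)), collapse = ", "))
  }
  df
}
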