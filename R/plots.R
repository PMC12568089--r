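#' Bland-Altman plot for a paired dataset
#'
#' Scatter of device-minus-reference differences against the pair means,
#' with horizontal lines at the mixed-model bias and 95% limits of
#' agreement.
#'
#' @param pd An `hr_paired` dataset.
#' @param ba Optional precomputed [lmm_bland_altman()] result; computed
#'   from `pd` when omitted.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pd, ba = NULL) {
  if (is.null(ba)) ba <- lmm_bland_altman(pd)
  df <- tibble::tibble(
    m = (pd$ref_bpm + pd$dev_bpm) / 2,
    d = pd$dev_bpm - pd$ref_bpm
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "steelblue") +
    ggplot2::geom_hline(
      yintercept = c(ba$loa_lower, ba$loa_upper),
      linetype = "dashed", colour = "steelblue"
    ) +
    ggplot2::labs(
      x = "Mean of reference and device (bpm)",
      y = "Device - reference (bpm)",
      title = sprintf(
        "%s @ %s: bias %.2f, LoA (%.2f, %.2f)",
        attr(pd, "device_id") %||% "device",
        attr(pd, "resolution") %||% "", ba$bias, ba$loa_lower, ba$loa_upper
      )
    ) +
    ggplot2::theme_minimal()
}

#' Notched boxplots of per-subject MAPE by condition
#'
#' One notched box per device and condition (steady vs. transition) from a
#' validation bundle, at the given resolution; the notch approximates the
#' 95% confidence interval of the median. A dashed line marks the 10%
#' acceptability threshold.
#'
#' @param bundle An `hr_validation` bundle from [run_validation()].
#' @param resolution `"trailing_10s"` (default) or `"per_second"`.
#' @return A ggplot object.
#' @export
plot_condition_mape <- function(bundle, resolution = "trailing_10s") {
  keys <- grep(paste0("^", resolution, " "), names(bundle$conditions),
    value = TRUE
  )
  df <- dplyr::bind_rows(lapply(keys, function(k) {
    dv <- sub(paste0("^", resolution, " "), "", k)
    dplyr::bind_rows(lapply(c("steady", "transition"), function(cond) {
      a <- bundle$conditions[[k]][[cond]]
      if (is.null(a)) return(NULL)
      tibble::tibble(
        device_id = dv, condition = cond,
        subject_id = a$per_subject$subject_id, mape = a$per_subject$mape
      )
    }))
  }))
  if (nrow(df) == 0) stop("no condition accuracy in this bundle", call. = FALSE)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$device_id, y = .data$mape, fill = .data$condition)
  ) +
    ggplot2::geom_boxplot(notch = TRUE, outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 10, linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "Per-subject MAPE (%)",
      title = sprintf("Steady vs. transition accuracy (%s)", resolution)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
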