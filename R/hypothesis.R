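align_by_subject <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    list(a = unname(a[common]), b = unname(b[common]), subjects = common)
  } else {
    if (length(a) != length(b)) {
      stop("unnamed inputs must have equal length", call. = FALSE)
    }
    list(a = a, b = b, subjects = seq_along(a))
  }
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on per-subject paired values. Inputs may be
#' named by subject, in which case pairing is by name and subjects missing
#' either value are dropped (pairwise-complete). Zero differences are
#' dropped (classic Wilcoxon convention; their count is messaged). The
#' exact null distribution is used for n <= `exact_max_n` nonzero
#' differences without ties among their absolute values; otherwise a normal
#' approximation with continuity and tie correction is used.
#'
#' @param a,b Numeric vectors of per-subject values (optionally named by
#'   subject id).
#' @param exact_max_n Largest n for the exact path (default 25).
#' @return The two-sided p-value.
#' @export
wilcoxon_paired <- function(a, b, exact_max_n = 25) {
  al <- align_by_subject(a, b)
  keep <- is.finite(al$a) & is.finite(al$b)
  d <- al$a[keep] - al$b[keep]
  if (length(d) < 5) {
    stop("need at least 5 complete pairs for the signed-rank test",
      call. = FALSE
    )
  }
  nz <- d[d != 0]
  if (length(d) - length(nz) > 0) {
    message(sprintf("dropped %d zero difference(s)", length(d) - length(nz)))
  }
  if (length(nz) == 0) {
    warning("all differences zero; p = 1", call. = FALSE)
    return(1)
  }
  ties <- any(duplicated(abs(nz)))
  use_exact <- length(nz) <= exact_max_n && !ties
  res <- suppressWarnings(
    wilcox.test(nz, mu = 0, exact = use_exact, correct = TRUE)
  )
  unname(res$p.value)
}

#' Pairwise device comparisons with Bonferroni control
#'
#' Runs a paired Wilcoxon signed-rank test for every unordered pair of
#' devices on per-subject accuracy values (typically MAPE), aligning
#' subjects by name per comparison, and applies a Bonferroni-adjusted
#' significance level `alpha / (k * (k - 1) / 2)`.
#'
#' @param values_by_device Named list mapping device id to a named numeric
#'   vector of per-subject values.
#' @param alpha Family-wise significance level (default 0.05).
#' @param exact_max_n Passed to [wilcoxon_paired()].
#' @return An `hr_comparison` list: `labels`, `p_values` (symmetric matrix,
#'   unit diagonal, `NA` where a pair had fewer than 5 usable subjects),
#'   `alpha`, `alpha_adjusted`, `n_comparisons`, `significant` (logical
#'   matrix).
#' @examples
#' x <- lapply(setNames(1:3, c("a", "b", "c")), function(i) {
#'   setNames(rnorm(8, i), paste0("S", 1:8))
#' })
#' pairwise_device_tests(x)
#' @export
pairwise_device_tests <- function(values_by_device, alpha = 0.05,
                                  exact_max_n = 25) {
  k <- length(values_by_device)
  if (k < 2) stop("need at least two devices", call. = FALSE)
  labels <- names(values_by_device)
  n_comparisons <- k * (k - 1) / 2
  alpha_adjusted <- alpha / n_comparisons
  p <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  diag(p) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pij <- tryCatch(
        suppressMessages(wilcoxon_paired(
          values_by_device[[i]], values_by_device[[j]],
          exact_max_n = exact_max_n
        )),
        error = function(e) NA_real_
      )
      p[i, j] <- pij
      p[j, i] <- pij
    }
  }
  structure(
    list(
      labels = labels, p_values = p, alpha = alpha,
      alpha_adjusted = alpha_adjusted, n_comparisons = n_comparisons,
      significant = !is.na(p) & p < alpha_adjusted & row(p) != col(p)
    ),
    class = "hr_comparison"
  )
}

#' @export
print.hr_comparison <- function(x, ...) {
  cat(sprintf(
    "<hr_comparison> %d devices, %d comparisons, adjusted alpha %.4f\n",
    length(x$labels), x$n_comparisons, x$alpha_adjusted
  ))
  print(round(x$p_values, 4))
  invisible(x)
}

#' Steady-state versus transition accuracy test
#'
#' Paired two-sided Wilcoxon signed-rank test on per-participant accuracy
#' (e.g. MAPE) between the steady-state and transition conditions, paired
#' by subject.
#'
#' @param steady,transition Named numeric vectors of per-subject values.
#' @inheritParams wilcoxon_paired
#' @return The two-sided p-value.
#' @export
condition_test <- function(steady, transition, exact_max_n = 25) {
  wilcoxon_paired(steady, transition, exact_max_n = exact_max_n)
}

#' Write a comparison matrix as CSV (upper-triangular layout)
#'
#' @param cm An `hr_comparison` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(cm, path) {
  stopifnot(inherits(cm, "hr_comparison"))
  m <- cm$p_values
  m[lower.tri(m, diag = TRUE)] <- NA
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, na = "")
  invisible(path)
}
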