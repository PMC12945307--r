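#' Clarke error grid region of prediction/reference glucose pairs
#'
#' Assigns each (reference, predicted) glucose pair to one of the canonical
#' Clarke error-grid regions:
#' * **A** — clinically accurate: within 20% of the reference, or both values
#'   in the hypoglycemic corner (<= 70 mg/dl);
#' * **B** — benign errors that would not lead to inappropriate treatment;
#' * **C** — errors leading to unnecessary corrective treatment;
#' * **D** — dangerous failure to detect hypo-/hyperglycemia;
#' * **E** — errors that would confuse treatment of hypoglycemia for
#'   hyperglycemia or vice versa.
#'
#' Boundaries follow the published Clarke (1987) inequalities.
#'
#' @param ref reference glucose (mg/dl), positive.
#' @param pred predicted glucose (mg/dl), positive, same length.
#' @return A factor with levels `A`-`E`.
#' @export
clarke_region <- function(ref, pred) {
  stopifnot(length(ref) == length(pred))
  if (any(!is.finite(ref)) || any(!is.finite(pred)) ||
      any(ref <= 0) || any(pred <= 0)) {
    stop("glucose values must be positive and finite", call. = FALSE)
  }
  x <- ref; y <- pred
  region <- character(length(x))
  A <- (y <= 70 & x <= 70) | (y <= 1.2 * x & y >= 0.8 * x)
  E <- !A & ((x >= 180 & y <= 70) | (x <= 70 & y >= 180))
  C <- !A & !E &
    (((x >= 70 & x <= 290) & y >= x + 110) |
       ((x >= 130 & x <= 180) & y <= (7 / 5) * x - 182))
  D <- !A & !E & !C &
    ((x >= 240 & (y >= 70 & y <= 180)) |
       (x <= 175 / 3 & (y <= 180 & y >= 70)) |
       ((x >= 175 / 3 & x <= 70) & y >= (6 / 5) * x))
  region[A] <- "A"; region[E] <- "E"; region[C] <- "C"; region[D] <- "D"
  region[region == ""] <- "B"
  factor(region, levels = c("A", "B", "C", "D", "E"))
}

#' Time in / above / below the target glucose range
#'
#' Fractions of samples within the closed interval `[lo, hi]`, above `hi`,
#' and below `lo`.  The default range 80-180 mg/dl is the reporting range of
#' the study (80 rather than the classical 70 compensates for CGM
#' overestimation of low glucose); boundary values count as in-range.
#'
#' @param G glucose series (mg/dl), non-empty.
#' @param lo,hi range bounds (mg/dl).
#' @return Named numeric vector `(tir, tar, tbr)`; sums to 1.
#' @export
range_fractions <- function(G, lo = 80, hi = 180) {
  if (length(G) == 0L) stop("empty glucose series", call. = FALSE)
  stopifnot(all(is.finite(G)))
  c(tir = mean(G >= lo & G <= hi),
    tar = mean(G > hi),
    tbr = mean(G < lo))
}

#' Compare episode-return distributions between two policies
#'
#' Two-sided nonparametric comparison of per-episode returns, defaulting to
#' the Wilcoxon rank-sum test (a paired signed-rank variant is available
#' when the returns are matched episode-by-episode).  Degenerate input
#' (all values equal across both groups) yields `p = 1` with a warning.
#'
#' @param returns_a,returns_b numeric vectors of episode returns (>= 2 each).
#' @param method `"wilcoxon"` (rank-sum / signed-rank) or `"t"`.
#' @param paired logical; requires equal lengths.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
compare_returns <- function(returns_a, returns_b,
                            method = c("wilcoxon", "t"), paired = FALSE) {
  method <- match.arg(method)
  if (length(returns_a) < 2L || length(returns_b) < 2L) {
    stop("need at least 2 returns per group", call. = FALSE)
  }
  if (paired && length(returns_a) != length(returns_b)) {
    stop("paired comparison needs equal lengths", call. = FALSE)
  }
  if (length(unique(c(returns_a, returns_b))) == 1L) {
    warning("degenerate (all-equal) returns; p = 1")
    return(list(statistic = NA_real_, p_value = 1, method = method))
  }
  res <- if (method == "wilcoxon") {
    suppressWarnings(wilcox.test(returns_a, returns_b, paired = paired,
                                 exact = FALSE))
  } else {
    stats::t.test(returns_a, returns_b, paired = paired)
  }
  list(statistic = unname(res$statistic), p_value = res$p.value,
       method = res$method)
}

#' Assemble a glycemic performance report
#'
#' Combines Clarke-grid region counts of predicted vs reference glucose,
#' time-in/above/below-range of the reference series, and return statistics
#' into one report object.
#'
#' @param ref reference glucose (mg/dl).
#' @param pred predicted glucose (mg/dl); defaults to `ref` (no prediction).
#' @param returns optional numeric vector of episode returns.
#' @param lo,hi target range bounds.
#' @return An object of class `glycemic_report`: a list with
#'   `clarke_counts`, `clarke_fractions`, `tir`, `tar`, `tbr`,
#'   `mean_return`, `return_sd`, `n_points`.
#' @export
glycemic_report <- function(ref, pred = ref, returns = NULL,
                            lo = 80, hi = 180) {
  regions <- clarke_region(ref, pred)
  counts <- table(regions)
  rf <- range_fractions(ref, lo, hi)
  structure(list(
    clarke_counts = counts,
    clarke_fractions = counts / length(regions),
    tir = rf[["tir"]], tar = rf[["tar"]], tbr = rf[["tbr"]],
    mean_return = if (is.null(returns)) NA_real_ else mean(returns),
    return_sd = if (is.null(returns) || length(returns) < 2L) NA_real_
                else sd(returns),
    n_points = length(regions)
  ), class = "glycemic_report")
}

#' @export
print.glycemic_report <- function(x, ...) {
  cat("<glycemic_report>", x$n_points, "points\n")
  cat("  Clarke regions:",
      paste(names(x$clarke_counts), as.integer(x$clarke_counts),
            sep = "=", collapse = " "), "\n")
  cat(sprintf("  A+B fraction: %.1f%%\n",
              100 * sum(x$clarke_fractions[c("A", "B")])))
  cat(sprintf("  TIR %.1f%% | TAR %.1f%% | TBR %.1f%%\n",
              100 * x$tir, 100 * x$tar, 100 * x$tbr))
  if (!is.na(x$mean_return)) {
    cat(sprintf("  mean return %.3f (sd %.3f)\n", x$mean_return,
                x$return_sd))
  }
  invisible(x)
}
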