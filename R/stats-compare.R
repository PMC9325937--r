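#' Median and quartiles
#'
#' Median, 1st and 3rd quartile by the linear-interpolation (type 7)
#' convention; permutation-invariant and affine-equivariant.
#'
#' @param values numeric vector, length >= 1.
#' @return Named numeric `c(median, q1, q3)`.
#' @export
median_iqr <- function(values) {
  if (length(values) < 1L || anyNA(values)) stop("need at least one non-NA value")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Over/underestimation factor between modalities
#'
#' How many times a modality's median over- or underestimates the reference:
#' `over` reports median(modality) / median(reference), `under` the
#' reciprocal. Full precision is returned; display rounding to one decimal is
#' left to table formatting. By construction
#' `estimation_factor(a, b, "over") * estimation_factor(a, b, "under") = 1`.
#'
#' @param modality_values numeric vector of the modality's per-specimen
#'   values (a single median is also accepted).
#' @param reference_values numeric vector for the reference modality.
#' @param direction `"over"` or `"under"`.
#' @return The factor (numeric scalar).
#' @export
estimation_factor <- function(modality_values, reference_values,
                              direction = c("over", "under")) {
  direction <- match.arg(direction)
  if (length(modality_values) == 0L || length(reference_values) == 0L)
    stop("both value sets must be non-empty")
  m_mod <- unname(median_iqr(modality_values)["median"])
  m_ref <- unname(median_iqr(reference_values)["median"])
  if (direction == "over") {
    if (m_ref == 0) stop("reference median is zero")
    m_mod / m_ref
  } else {
    if (m_mod == 0) stop("modality median is zero")
    m_ref / m_mod
  }
}

#' Spearman rank correlation with p-value and confidence interval
#'
#' The Pearson correlation of the mid-ranks (average ranks for ties). The
#' two-sided p-value uses the t approximation with n - 2 degrees of freedom
#' (standard at the cohort sizes involved); an exact permutation p-value is
#' available for n <= 8. The 95 percent confidence interval uses the Fisher
#' z transform (needs n > 3). Invariant under strictly monotone transforms of
#' either argument.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param exact compute the permutation p-value (only for n <= 8).
#' @return A list of class `correlation_result`: `rho`, `p_value`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
spearman <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("rank correlation is undefined for constant input")
  rx <- rank(x)
  ry <- rank(y)
  rho <- unname(stats::cor(rx, ry))
  rho <- max(-1, min(1, rho))

  if (exact) {
    if (n > 8L) stop("exact permutation p-value only supported for n <= 8")
    perms <- permutations_of(n)
    ref <- abs(rho)
    count <- 0L
    for (k in seq_len(nrow(perms))) {
      r <- abs(stats::cor(rx, ry[perms[k, ]]))
      if (r >= ref - 1e-12) count <- count + 1L
    }
    p <- count / nrow(perms)
  } else if (abs(rho) == 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }

  if (n > 3 && abs(rho) < 1) {
    z <- atanh(rho)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  } else {
    ci <- c(rho, rho)
  }
  structure(list(rho = rho, p_value = p, ci_low = ci[1], ci_high = ci[2],
                 n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (95%% CI %.3f to %.3f), p = %.4g, n = %d\n",
              x$rho, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[k, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Shapiro-Wilk normality test
#'
#' Two-sided p-value of the W statistic (Royston's algorithm as implemented
#' in base R). Advisory: in this workflow it only motivates the use of
#' nonparametric (median/quartile, rank-correlation) statistics.
#'
#' @param x numeric vector, 3 <= n <= 5000.
#' @return The p-value.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::var(x) == 0) stop("constant sample: normality test undefined")
  stats::shapiro.test(x)$p.value
}

#' Cross-modality comparison table
#'
#' Builds the descriptive-plus-agreement table used to compare modalities
#' against a reference: one row per (modality, parameter) with median and
#' quartiles, the median ratio and over/underestimation factor versus the
#' reference, and the Spearman correlation with p-value and 95 percent CI on
#' the paired per-specimen values.
#'
#' @param results data frame with columns `specimen`, `modality`, and one
#'   column per parameter (as returned by [cohort_morphometry()]).
#' @param reference reference modality name (must be present).
#' @param parameters parameter columns to summarize; defaults to all numeric
#'   columns except `specimen`.
#' @return A data frame of class `comparison_table`.
#' @export
build_comparison_table <- function(results, reference = "micro",
                                   parameters = NULL) {
  stopifnot(is.data.frame(results),
            all(c("specimen", "modality") %in% names(results)))
  mods <- unique(results$modality)
  if (!reference %in% mods) stop("reference modality not present: ", reference)
  if (is.null(parameters)) {
    parameters <- setdiff(names(results)[vapply(results, is.numeric, TRUE)],
                          "specimen")
  }
  ref <- results[results$modality == reference, , drop = FALSE]
  ref <- ref[order(ref$specimen), , drop = FALSE]
  rows <- list()
  for (mod in mods) {
    cur <- results[results$modality == mod, , drop = FALSE]
    cur <- cur[order(cur$specimen), , drop = FALSE]
    if (!identical(cur$specimen, ref$specimen))
      stop("modalities do not cover the same specimens")
    for (p in parameters) {
      mi <- median_iqr(cur[[p]])
      ratio <- unname(mi["median"]) / unname(median_iqr(ref[[p]])["median"])
      corr <- if (mod == reference) {
        list(rho = 1, p_value = 0, ci_low = 1, ci_high = 1, n = nrow(cur))
      } else {
        spearman(ref[[p]], cur[[p]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        modality = mod, parameter = p,
        median = unname(mi["median"]), q1 = unname(mi["q1"]),
        q3 = unname(mi["q3"]),
        ratio_vs_reference = ratio,
        factor = max(ratio, 1 / ratio),
        direction = if (ratio >= 1) "over" else "under",
        rho = corr$rho, p_value = corr$p_value,
        ci_low = corr$ci_low, ci_high = corr$ci_high, n = corr$n,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Reference structure-parameter medians for cadaveric radius specimens
#'
#' Published median values of the eight trabecular structure parameters and
#' CNR for 14 cadaveric human radius specimens, measured with a
#' photon-counting-detector CT (three reconstruction fields of view), an
#' energy-integrating-detector CT (two dose levels) and micro-CT as
#' reference. Units: BVTV is a fraction, Tb.Th/Tb.Sc/Tb.Sp and their
#' dispersions are mm, Tb.Nd is 1/mm^3, CNR is unitless. These serve as
#' inputs for over/underestimation-factor arithmetic.
#'
#' @return A data frame with columns `modality`, `parameter`, `median`.
#' @export
reference_medians <- function() {
  params <- c("bvtv", "tb_th", "tb_sc", "tb_sp", "tb_nd", "cnr",
              "s_tb_th", "s_tb_sc", "s_tb_sp")
  med <- rbind(
    pcd51   = c(0.32, 0.45, 1.16, 0.79, 1.36, 8.07, 0.15, 0.46, 0.37),
    pcd30   = c(0.32, 0.44, 1.16, 0.79, 1.39, 7.73, 0.15, 0.46, 0.37),
    pcd18   = c(0.33, 0.45, 1.15, 0.78, 1.39, 7.94, 0.15, 0.46, 0.36),
    eid1000 = c(0.34, 0.50, 1.20, 0.85, 0.86, 6.45, 0.13, 0.44, 0.35),
    eid600  = c(0.35, 0.53, 1.23, 0.85, 0.78, 5.93, 0.15, 0.45, 0.35),
    micro   = c(0.09, 0.14, 1.07, 0.91, 9.32, 24.94, 0.06, 0.30, 0.27)
  )
  data.frame(
    modality = rep(rownames(med), each = length(params)),
    parameter = rep(params, times = nrow(med)),
    median = as.vector(t(med)),
    stringsAsFactors = FALSE
  )
}
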