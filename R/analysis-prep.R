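#' Social-threshold transform for linear modelling
#'
#' The factor levels of the social threshold span two orders of magnitude
#' (0.5 to 10), so for linear mixed-model analysis they enter as
#' `L(m) = log(m + 1)` (natural log), a strictly increasing transform that
#' keeps `L(0) = 0`.
#'
#' @param m Threshold value(s), `m >= 0`.
#' @return `log(m + 1)`.
#' @examples
#' transform_threshold(c(0.5, 1.5, 2.5, 10))
#' @export
transform_threshold <- function(m) {
  if (any(m < 0)) stop("social thresholds must be non-negative")
  log1p(m)
}

#' Standardize a column to zero mean and unit variance
#'
#' @param x Numeric vector with at least two distinct values.
#' @param name Optional column name used in the error message.
#' @return `(x - mean(x)) / sd(x)`.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(x, name = deparse(substitute(x))) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("cannot standardize '%s': zero variance", name))
  }
  (x - mean(x)) / s
}

#' Replace a predictor by its residuals on a better one
#'
#' Sequential regression for collinear predictor pairs: the worse-fitting
#' member is replaced by the residuals from regressing it onto the better
#' one, retaining only the explanatory power it contributes beyond the
#' better predictor. The result is exactly (Pearson) uncorrelated with the
#' reference column.
#'
#' @param worse,better Equal-length numeric vectors; `better` must vary.
#' @return Residual vector, same length.
#' @examples
#' sequential_residualize(c(1, 2, 3, 5), c(1, 2, 3, 4))
#' @export
sequential_residualize <- function(worse, better) {
  stopifnot(length(worse) == length(better))
  if (sd(better) == 0) stop("reference predictor is constant")
  as.numeric(resid(lm(worse ~ better)))
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)`, with `R^2_k` from regressing predictor `k` on
#' all the others. Perfect collinearity is reported as `Inf`.
#'
#' @param predictors Data frame or matrix of numeric predictors (at least
#'   two columns, more rows than columns).
#' @return Named numeric vector of VIFs.
#' @examples
#' vif(data.frame(a = rnorm(20), b = rnorm(20)))
#' @export
vif <- function(predictors) {
  predictors <- as.data.frame(predictors)
  stopifnot(ncol(predictors) >= 2, nrow(predictors) > ncol(predictors))
  vapply(names(predictors), function(k) {
    fit <- lm(stats::reformulate(setdiff(names(predictors), k), response = k),
              data = predictors)
    # summary.lm warns on an essentially perfect fit; that case is exactly
    # the one we detect and report as Inf
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Screen kinetic predictors for collinearity
#'
#' The analysis-side correction pipeline for correlated kinetic metrics:
#' every metric pair with Spearman `|r|` above `threshold_r` is flagged; in
#' each flagged pair the worse-fitting member — ranked by AIC of the
#' single-predictor linear fit to the response — is replaced by its
#' residuals on the better member ([sequential_residualize()]); VIFs are
#' then re-checked against `threshold_vif`.
#'
#' @param data Data frame with the metric columns and the response.
#' @param metrics Character vector of metric column names to screen.
#' @param response Name of the response column used to rank fits.
#' @param threshold_r Spearman correlation magnitude above which a pair is
#'   flagged (default 0.5).
#' @param threshold_vif VIF level that the corrected table must satisfy
#'   (default 2.6).
#' @return An object of class `"collinearity_screen"`: list with `table`
#'   (the corrected tibble), `flagged` (tibble of flagged pairs with their
#'   r, the member residualized, and both AICs), `vif_before`, `vif_after`,
#'   and the thresholds.
#' @examples
#' d <- data.frame(v_T = rnorm(50))
#' d$v_G <- d$v_T + rnorm(50, sd = 0.1)
#' d$tor <- rnorm(50)
#' d$P_L <- d$v_G + rnorm(50)
#' screen_collinearity(d, metrics = c("v_T", "v_G", "tor"), response = "P_L")
#' @export
screen_collinearity <- function(data, metrics, response,
                                threshold_r = 0.5, threshold_vif = 2.6) {
  stopifnot(all(metrics %in% names(data)), response %in% names(data),
            length(metrics) >= 2)
  tbl <- tibble::as_tibble(data)
  rho <- cor(as.matrix(tbl[metrics]), method = "spearman")
  vif_before <- vif(tbl[metrics])

  pairs <- which(upper.tri(rho) & abs(rho) > threshold_r, arr.ind = TRUE)
  flagged <- tibble::tibble(
    metric_a = character(0), metric_b = character(0), spearman_r = numeric(0),
    aic_a = numeric(0), aic_b = numeric(0), residualized = character(0)
  )
  for (k in seq_len(nrow(pairs))) {
    a <- metrics[pairs[k, 1]]
    b <- metrics[pairs[k, 2]]
    aic_a <- AIC(lm(stats::reformulate(a, response = response), data = tbl))
    aic_b <- AIC(lm(stats::reformulate(b, response = response), data = tbl))
    worse <- if (aic_a <= aic_b) b else a
    better <- if (aic_a <= aic_b) a else b
    tbl[[worse]] <- sequential_residualize(tbl[[worse]], tbl[[better]])
    flagged <- dplyr::bind_rows(flagged, tibble::tibble(
      metric_a = a, metric_b = b,
      spearman_r = rho[pairs[k, 1], pairs[k, 2]],
      aic_a = aic_a, aic_b = aic_b, residualized = worse
    ))
  }
  vif_after <- vif(tbl[metrics])
  structure(
    list(table = tbl, flagged = flagged, vif_before = vif_before,
         vif_after = vif_after, threshold_r = threshold_r,
         threshold_vif = threshold_vif, metrics = metrics,
         response = response, spearman = rho),
    class = "collinearity_screen"
  )
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat("<collinearity_screen>\n")
  cat(sprintf("  %d metric(s), %d flagged pair(s) at |Spearman r| > %g\n",
              length(x$metrics), nrow(x$flagged), x$threshold_r))
  if (nrow(x$flagged) > 0) {
    for (k in seq_len(nrow(x$flagged))) {
      cat(sprintf("  %s ~ %s (r = %.3f): residualized %s\n",
                  x$flagged$metric_a[k], x$flagged$metric_b[k],
                  x$flagged$spearman_r[k], x$flagged$residualized[k]))
    }
  }
  cat(sprintf("  max VIF after screening: %.3f (threshold %g)\n",
              max(x$vif_after), x$threshold_vif))
  invisible(x)
}

#' @rdname screen_collinearity
#' @param x A `"collinearity_screen"` object.
#' @param ... Unused.
#' @export
tidy.collinearity_screen <- function(x, ...) {
  x$flagged
}

#' @rdname screen_collinearity
#' @export
glance.collinearity_screen <- function(x, ...) {
  tibble::tibble(
    n_metrics = length(x$metrics),
    n_flagged = nrow(x$flagged),
    max_abs_spearman = max(abs(x$spearman[upper.tri(x$spearman)])),
    max_vif_before = max(x$vif_before),
    max_vif_after = max(x$vif_after),
    passes = max(x$vif_after) <= x$threshold_vif
  )
}

#' Generic tidiers
#'
#' broom-style generics for the package's result objects.
#' @param x An object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Assemble the per-trial analysis table
#'
#' Joins design factors, capture scores, and kinetic metrics into the table
#' a mixed-model analysis consumes: threshold factors on the `L(m)` scale,
#' kinetic metrics standardized to zero mean and unit variance, responses
#' `P_L` and `P_A` untouched. Rows flagged as uncorrected misses keep `NA`
#' responses.
#'
#' @param trials Data frame with one row per trial carrying the design
#'   columns (`m_t`, `m_g`, `v_e`, `init_mode`, `veiled`), the kinetic
#'   metric columns, and the responses.
#' @param metrics Metric columns to standardize (those present are used).
#' @param responses Response columns to carry through.
#' @return A tibble with `L_m_t`, `L_m_g`, the factors, standardized
#'   metrics, and responses.
#' @export
prepare_analysis_table <- function(trials,
                                   metrics = c("v_T", "tor", "vpa", "v_G",
                                               "rho", "nnd"),
                                   responses = c("P_L", "P_A")) {
  stopifnot(all(c("m_t", "m_g") %in% names(trials)))
  metrics <- intersect(metrics, names(trials))
  responses <- intersect(responses, names(trials))
  out <- tibble::as_tibble(trials) |>
    dplyr::mutate(L_m_t = transform_threshold(.data$m_t),
                  L_m_g = transform_threshold(.data$m_g))
  for (m in metrics) out[[m]] <- standardize(out[[m]], name = m)
  keep <- c("L_m_t", "L_m_g",
            intersect(c("player", "trial_id", "session", "v_e", "init_mode",
                        "veiled", "replicate", "seed"), names(out)),
            metrics, responses)
  out[keep]
}
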