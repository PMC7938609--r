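#' Highly variable gene selection
#'
#' Two selection strategies over the coefficient of variation (CoV; sample
#' standard deviation / mean of the normalized, log-scale expression).
#' `"bins"`: genes are sorted by mean expression into `n_bins` equal-size
#' bins; within each bin CoV values are converted to z-scores, and genes with
#' z above `z_threshold` are flagged. `"loess"`: a locally weighted
#' regression of CoV on mean normalized expression (span 0.3) predicts the
#' expected CoV, and genes with observed CoV above the prediction are
#' flagged. Either way the flags are intersected with minimum mean-expression
#' and detection-fraction filters.
#'
#' @param state A `spat_state` with a normalized layer and statistics
#'   ([add_statistics()]).
#' @param method `"bins"` or `"loess"`.
#' @param n_bins Number of equal-size expression bins (default 20).
#' @param z_threshold Within-bin CoV z-score cutoff (default 1.5).
#' @param min_mean Minimum mean expression for a flagged gene (default 0).
#' @param min_detection Minimum detection fraction for a flagged gene
#'   (default 0).
#' @param span Smoother span for the loess method (default 0.3).
#' @return The state with a logical `hvg_flag` column in its gene metadata.
#' @export
find_hvg <- function(state, method = c("bins", "loess"), n_bins = 20,
                     z_threshold = 1.5, min_mean = 0, min_detection = 0,
                     span = 0.3) {
  method <- match.arg(method)
  norm <- get_expression(state, "normalized")
  if (is.null(state$genes$mean_expression))
    state <- add_statistics(state)
  G <- nrow(norm)
  if (method == "bins" && n_bins > G)
    stop("n_bins (", n_bins, ") exceeds the number of genes (", G,
         "); use a smaller n_bins")
  mu <- rowMeans(norm)
  sd <- apply(norm, 1, stats::sd)
  cov <- ifelse(mu > 0, sd / mu, 0)

  if (method == "bins") {
    # equal-size bins by mean-expression rank; ties split by original order
    bin <- ceiling(rank(mu, ties.method = "first") / (G / n_bins))
    bin <- pmin(pmax(bin, 1L), n_bins)
    z <- stats::ave(cov, bin, FUN = function(v) {
      s <- stats::sd(v)
      if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
    flag <- z > z_threshold
  } else {
    fit <- stats::loess(cov ~ mu, span = span, degree = 2)
    flag <- cov > stats::predict(fit)
  }
  flag <- flag & state$genes$mean_expression >= min_mean &
    state$genes$detection_fraction >= min_detection
  state$genes$hvg_flag <- unname(flag)
  .log_call(state, "find_hvg",
            list(method = method, n_bins = n_bins, z_threshold = z_threshold,
                 min_mean = min_mean, min_detection = min_detection,
                 n_hvg = sum(flag)))
}
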