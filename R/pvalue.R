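#' Exact null score distribution of a motif
#'
#' Computes the exact distribution of the motif's log-odds score for a
#' random sequence of motif width drawn i.i.d. from the motif's background.
#' Per-position scores are discretized to integer multiples of the
#' granularity `eps` and the distribution of their sum is obtained by
#' iterated convolution over positions, in O(width * range * 4) time. This
#' is the null distribution that defines match p-values: the p-value of a
#' raw score is the probability that a random background window scores at
#' least as high.
#'
#' @param m a `motif`.
#' @param granularity discretization step for scores, in bits. Default
#'   `(max_score - min_score) / 1e4`, which keeps the p-value discretization
#'   error far below reporting precision.
#' @param background optional override of the null base frequencies; default
#'   is the motif's own stored background.
#' @return An object of class `"score_distribution"`: list with `motif_id`,
#'   `granularity`, `support` (sorted integer score bins), `mass`
#'   (probability per bin), `cumulative_upper` (P(score >= bin)), and the
#'   motif's exact `min_score`/`max_score` on the unbinned scale.
#' @export
score_distribution <- function(m, granularity = NULL, background = NULL) {
  stopifnot(inherits(m, "motif"))
  bg <- if (is.null(background)) as.numeric(m$background) else {
    b <- as.numeric(background)
    if (length(b) != 4L || any(b <= 0)) stop("invalid background override")
    b / sum(b)
  }
  rng <- m$max_score - m$min_score
  if (rng <= 0) {
    # Degenerate motif: every sequence attains the same score.
    eps <- if (is.null(granularity)) 1 else granularity
    bin <- as.integer(round(m$max_score / eps))
    return(structure(list(
      motif_id = m$id, granularity = eps, support = bin, mass = 1,
      cumulative_upper = 1, min_score = m$min_score,
      max_score = m$max_score), class = "score_distribution"))
  }
  eps <- if (is.null(granularity)) rng / 1e4 else granularity
  if (!is.numeric(eps) || eps <= 0) stop("granularity must be > 0")
  kmat <- round(m$lods / eps)  # width x 4, integer-valued
  if (sum(apply(kmat, 1, max)) == sum(apply(kmat, 1, min)))
    stop("granularity ", eps, " is too coarse: score range collapses ",
         "to a single bin")

  cur <- 1    # mass vector; cur[j] = P(sum == cur_lo + j - 1)
  cur_lo <- 0
  for (i in seq_len(m$width)) {
    ks <- kmat[i, ]
    new_lo <- cur_lo + min(ks)
    new_hi <- cur_lo + length(cur) - 1L + max(ks)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- cur_lo + ks[b] - new_lo
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + bg[b] * cur
    }
    cur <- new
    cur_lo <- new_lo
  }
  support <- seq(cur_lo, length.out = length(cur))
  keep <- cur > 0
  structure(list(
    motif_id = m$id,
    granularity = eps,
    support = support[keep],
    mass = cur[keep],
    cumulative_upper = rev(cumsum(rev(cur)))[keep],
    min_score = m$min_score,
    max_score = m$max_score
  ), class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf(
    "<score_distribution> %s: eps=%.3g, %d bins, score range [%.3f, %.3f]\n",
    x$motif_id, x$granularity, length(x$support), x$min_score, x$max_score))
  invisible(x)
}

#' Exact match p-value for a raw motif score
#'
#' Returns P(null score >= raw_score) under the motif's discretized null
#' distribution. The p-value is per scanned window (a match p-value); it is
#' not corrected for the number of windows scanned. Monotone non-increasing
#' in `raw_score`; scores at or below the motif minimum return 1, scores
#' above the motif maximum return 0.
#'
#' @param sd a `score_distribution`.
#' @param raw_score numeric vector of raw log-odds scores.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
pwm_pvalue <- function(sd, raw_score) {
  stopifnot(inherits(sd, "score_distribution"))
  eps <- sd$granularity
  bins <- floor(raw_score / eps + 0.5)
  lo <- sd$support[1]
  hi <- sd$support[length(sd$support)]
  out <- numeric(length(bins))
  for (j in seq_along(bins)) {
    if (!is.finite(raw_score[j])) { out[j] <- NA_real_; next }
    if (raw_score[j] <= sd$min_score) { out[j] <- 1; next }
    # tiny relative tolerance: summation order can put an attainable
    # maximal score a few ulp above max_score
    if (raw_score[j] > sd$max_score +
        1e-9 * max(abs(sd$max_score), 1)) { out[j] <- 0; next }
    # attainable scores clamp into the discretized support: rounding the
    # query sum and rounding per-position scores can disagree by < w/2 bins
    b <- min(max(bins[j], lo), hi)
    k <- findInterval(b - 1, sd$support) + 1L
    out[j] <- if (k > length(sd$support)) 0 else sd$cumulative_upper[k]
  }
  out
}

#' Score threshold attaining a target p-value
#'
#' Inverts the null distribution: the smallest binned score `s` such that
#' P(score >= s) <= alpha. Used to pre-filter scans at a significance level
#' (for example the 1e-4 evidence filter used before peak annotation).
#'
#' @param sd a `score_distribution`.
#' @param alpha target p-value in (0, 1].
#' @return The threshold on the raw-score scale (bin * granularity). When
#'   `alpha` is below the smallest attainable nonzero tail mass, the maximum
#'   support bin is returned with attribute `attainable = FALSE`.
#' @export
score_for_pvalue <- function(sd, alpha) {
  stopifnot(inherits(sd, "score_distribution"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  viol <- which(sd$cumulative_upper > alpha)
  n <- length(sd$support)
  if (length(viol) == 0L) {
    # even the whole support satisfies the bound (alpha = 1)
    thr <- sd$support[1] * sd$granularity
    attr(thr, "attainable") <- TRUE
    return(thr)
  }
  if (max(viol) == n) {
    # alpha below the smallest attainable nonzero tail mass
    thr <- sd$support[n] * sd$granularity
    attr(thr, "attainable") <- FALSE
    return(thr)
  }
  # smallest bin above the last bin whose upper tail still exceeds alpha
  # (support may skip zero-mass bins, so this is support[max(viol)] + 1)
  thr <- (sd$support[max(viol)] + 1) * sd$granularity
  attr(thr, "attainable") <- TRUE
  thr
}
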