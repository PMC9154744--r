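#' Match pause calls across two replicates
#'
#' Pairs are formed by exact (chrom, position, strand) identity; pause scores
#' are log10 of the pause strength (read count) in each replicate.
#'
#' @param calls_rep1,calls_rep2 `pause_calls` data frames from
#'   [call_pauses()].
#' @return List with `pairs` (data frame: `chrom`, `pos`, `strand`,
#'   `gene_id`, `reads1`, `reads2`, `score1`, `score2`) and `unmatched1`,
#'   `unmatched2` (per-replicate calls without a partner).
#' @export
match_pauses <- function(calls_rep1, calls_rep2) {
  key <- function(d) paste(d$chrom, d$pos, d$strand)
  k1 <- key(calls_rep1); k2 <- key(calls_rep2)
  i1 <- which(k1 %in% k2)
  i2 <- match(k1[i1], k2)
  pairs <- data.frame(chrom = calls_rep1$chrom[i1], pos = calls_rep1$pos[i1],
                      strand = calls_rep1$strand[i1],
                      gene_id = calls_rep1$gene_id[i1],
                      reads1 = calls_rep1$reads[i1],
                      reads2 = calls_rep2$reads[i2],
                      stringsAsFactors = FALSE)
  pairs$score1 <- log10(pairs$reads1)
  pairs$score2 <- log10(pairs$reads2)
  list(pairs = pairs,
       unmatched1 = as.data.frame(calls_rep1)[!(k1 %in% k2), , drop = FALSE],
       unmatched2 = as.data.frame(calls_rep2)[!(k2 %in% k1), , drop = FALSE])
}

# mixture CDF G(z) = p N(z; mu, sigma) + (1-p) N(z; 0, 1)
.idr_G <- function(z, mu, sigma, p) {
  p * pnorm(z, mu, sigma) + (1 - p) * pnorm(z, 0, 1)
}

# invert G on a vector of probabilities by monotone interpolation on a grid
.idr_G_inv <- function(u, mu, sigma, p) {
  lo <- min(qnorm(min(u), 0, 1), qnorm(min(u), mu, sigma)) - 1
  hi <- max(qnorm(max(u), 0, 1), qnorm(max(u), mu, sigma)) + 1
  grid <- seq(lo, hi, length.out = 4000L)
  approx(.idr_G(grid, mu, sigma, p), grid, xout = u, ties = "ordered")$y
}

# bivariate normal log-density with common marginal (m, s) and correlation r
.log_dbvn <- function(zx, zy, m, s, r) {
  dx <- (zx - m) / s; dy <- (zy - m) / s
  -log(2 * pi) - 2 * log(s) - 0.5 * log(1 - r^2) -
    (dx^2 - 2 * r * dx * dy + dy^2) / (2 * (1 - r^2))
}

#' Estimate the irreproducible discovery rate for matched pause pairs
#'
#' Gaussian-copula two-component mixture (Li et al.): replicate scores are
#' converted to pseudo-values through the empirical CDF (average ranks for
#' ties, so any strictly monotone transform of the scores gives identical
#' results) and the inverse mixture CDF, and an EM alternation fits a
#' reproducible bivariate-normal component (mean `mu`, sd `sigma`,
#' correlation `rho`, weight `p`) against a standard-normal independent null.
#' The local idr of a pair is the posterior probability of the irreproducible
#' component; the global IDR is the running mean of local idr over pairs
#' ranked by local idr (the ENCODE convention).
#'
#' @param pairs data frame from [match_pauses()]`$pairs` (needs `score1`,
#'   `score2`), at least 20 rows.
#' @param mu,sigma,rho,p EM initialization (defaults 3, 1, 0.9, 0.5).
#' @param eps convergence tolerance on the pseudo-likelihood (default 1e-6).
#' @param max_iter iteration cap (default 200).
#' @return The pairs with `idr_local` and `idr` (global) columns, plus
#'   attributes `"params"` (fitted values), `"converged"`, `"iterations"`.
#' @export
estimate_idr <- function(pairs, mu = 3, sigma = 1, rho = 0.9, p = 0.5,
                         eps = 1e-6, max_iter = 200) {
  n <- nrow(pairs)
  if (n < 20) stop("need at least 20 matched pairs to estimate IDR")
  u <- rank(pairs$score1, ties.method = "average") / (n + 1)
  v <- rank(pairs$score2, ties.method = "average") / (n + 1)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    zx <- .idr_G_inv(u, mu, sigma, p)
    zy <- .idr_G_inv(v, mu, sigma, p)
    l1 <- .log_dbvn(zx, zy, mu, sigma, rho)
    l0 <- .log_dbvn(zx, zy, 0, 1, 0)
    m <- pmax(l1, l0)
    denom <- p * exp(l1 - m) + (1 - p) * exp(l0 - m)
    K <- p * exp(l1 - m) / denom
    ll <- sum(log(denom) + m)
    # M-step: weighted moments of the reproducible component
    sk <- sum(K)
    p <- min(max(sk / n, 1e-3), 1 - 1e-3)
    mu <- sum(K * (zx + zy)) / (2 * sk)
    sigma <- sqrt(sum(K * ((zx - mu)^2 + (zy - mu)^2)) / (2 * sk))
    sigma <- max(sigma, 1e-2)
    rho <- sum(K * (zx - mu) * (zy - mu)) / (sk * sigma^2)
    rho <- min(max(rho, -0.999), 0.999)
    if (is.finite(ll) && abs(ll - ll_old) < eps) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (!converged)
    warning("IDR EM did not converge within ", max_iter,
            " iterations; returning last iterate")
  # final posterior under the fitted parameters
  zx <- .idr_G_inv(u, mu, sigma, p)
  zy <- .idr_G_inv(v, mu, sigma, p)
  l1 <- .log_dbvn(zx, zy, mu, sigma, rho)
  l0 <- .log_dbvn(zx, zy, 0, 1, 0)
  m <- pmax(l1, l0)
  K <- p * exp(l1 - m) / (p * exp(l1 - m) + (1 - p) * exp(l0 - m))
  local <- 1 - K
  ord <- order(local)
  global <- numeric(n)
  global[ord] <- cumsum(local[ord]) / seq_len(n)
  global <- pmin(global, 1)
  out <- pairs
  out$idr_local <- local
  out$idr <- global
  attr(out, "params") <- list(mu = mu, sigma = sigma, rho = rho, p = p)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- it
  out
}

#' Retain reproducible pauses
#'
#' Pairs with IDR below the threshold (default 1%) are emitted as a single
#' merged pause set with strength equal to the summed replicate reads.
#'
#' @param pairs output of [estimate_idr()].
#' @param threshold IDR cutoff (default 0.01).
#' @param use_local threshold the local idr instead of the global IDR.
#' @return A `pause_calls`-style data frame (`chrom`, `pos`, `strand`,
#'   `gene_id`, `reads`, `idr`).
#' @export
reproducible_pauses <- function(pairs, threshold = 0.01, use_local = FALSE) {
  val <- if (use_local) pairs$idr_local else pairs$idr
  keep <- val < threshold
  out <- data.frame(chrom = pairs$chrom[keep], pos = pairs$pos[keep],
                    strand = pairs$strand[keep], gene_id = pairs$gene_id[keep],
                    reads = pairs$reads1[keep] + pairs$reads2[keep],
                    idr = val[keep], stringsAsFactors = FALSE)
  class(out) <- c("pause_calls", "data.frame")
  out
}
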