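# Independent brute-force oracles, coded separately from the package
# implementations they check.

# Naive O(N * W) pause caller on a single gene's count vector: explicit
# per-position loops, stats::mean/var, iterated to the same fixed point.
# Returns 1-based offsets (transcript orientation) of called positions.
naive_call_pauses <- function(x, z = 3, min_reads = 2, half = 100,
                              min_informative = 50, max_iter = 10) {
  n <- length(x)
  mask <- rep(FALSE, n)
  for (it in seq_len(max_iter)) {
    calls <- rep(FALSE, n)
    for (i in seq_len(n)) {
      w <- setdiff(max(1, i - half):min(n, i + half), i)
      w <- w[!mask[w]]
      if (length(w) < min_informative) next
      mu <- mean(x[w])
      vv <- if (length(w) > 1) stats::var(x[w]) else 0
      sdv <- if (vv > mu) sqrt(vv) else sqrt(mu)
      if (x[i] > mu + z * sdv && x[i] >= min_reads) calls[i] <- TRUE
    }
    if (identical(calls, mask)) break
    mask <- calls
  }
  which(mask)
}

# Independently coded IDR EM: same Gaussian-copula mixture model, but with
# per-point uniroot CDF inversion and scalar loops.
oracle_idr <- function(s1, s2, mu = 3, sigma = 1, rho = 0.9, p = 0.5,
                       eps = 1e-6, max_iter = 200) {
  n <- length(s1)
  u <- rank(s1, ties.method = "average") / (n + 1)
  v <- rank(s2, ties.method = "average") / (n + 1)
  Gfun <- function(zz, mu, sigma, p)
    p * pnorm(zz, mu, sigma) + (1 - p) * pnorm(zz)
  invert <- function(uu, mu, sigma, p) {
    vapply(uu, function(ui)
      uniroot(function(zz) Gfun(zz, mu, sigma, p) - ui,
              lower = -60, upper = 60, tol = 1e-12)$root, numeric(1))
  }
  dbv <- function(zx, zy, m, s, r) {
    q <- ((zx - m)^2 - 2 * r * (zx - m) * (zy - m) + (zy - m)^2) / (s^2 * (1 - r^2))
    exp(-q / 2) / (2 * pi * s^2 * sqrt(1 - r^2))
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    zx <- invert(u, mu, sigma, p)
    zy <- invert(v, mu, sigma, p)
    f1 <- p * dbv(zx, zy, mu, sigma, rho)
    f0 <- (1 - p) * dbv(zx, zy, 0, 1, 0)
    K <- f1 / (f1 + f0)
    ll <- sum(log(f1 + f0))
    sk <- sum(K)
    p <- min(max(sk / n, 1e-3), 1 - 1e-3)
    mu <- sum(K * (zx + zy)) / (2 * sk)
    sigma <- max(sqrt(sum(K * ((zx - mu)^2 + (zy - mu)^2)) / (2 * sk)), 1e-2)
    rho <- min(max(sum(K * (zx - mu) * (zy - mu)) / (sk * sigma^2), -0.999), 0.999)
    if (is.finite(ll) && abs(ll - ll_old) < eps) break
    ll_old <- ll
  }
  zx <- invert(u, mu, sigma, p)
  zy <- invert(v, mu, sigma, p)
  f1 <- p * dbv(zx, zy, mu, sigma, rho)
  f0 <- (1 - p) * dbv(zx, zy, 0, 1, 0)
  local <- 1 - f1 / (f1 + f0)
  ord <- order(local)
  global <- numeric(n)
  global[ord] <- cumsum(local[ord]) / seq_len(n)
  list(local = local, global = pmin(global, 1),
       params = list(mu = mu, sigma = sigma, rho = rho, p = p))
}

# draw n score pairs from the copula mixture itself (ground-truth process for
# IDR tests): latent bivariate normal for the reproducible component,
# independent standard normals for the rest; scores are a monotone transform
sample_idr_pairs <- function(n, p = 0.5, mu = 2.5, sigma = 1, rho = 0.85,
                             seed = 1) {
  set.seed(seed)
  rep_comp <- runif(n) < p
  z1 <- ifelse(rep_comp, mu, 0) + rnorm(n) * ifelse(rep_comp, sigma, 1)
  e <- rnorm(n)
  z2 <- ifelse(rep_comp,
               mu + sigma * (rho * (z1 - mu) / sigma + sqrt(1 - rho^2) * e),
               rnorm(n))
  data.frame(score1 = exp(z1 / 3), score2 = exp(z2 / 3),
             reproducible = rep_comp)
}

# run the simulate -> call -> IDR pipeline once and score recovery vs truth
recovery_run <- function(seed, reproducible_fraction = 0.7,
                         idr_threshold = 0.01) {
  cfg <- simulation_config(seed = seed,
                           reproducible_fraction = reproducible_fraction)
  toy <- generate_toy_genome(cfg)
  sim <- simulate_occupancy(toy$annotation, cfg)
  filt <- select_well_expressed(sim$rep1, sim$rep2, toy$annotation)
  c1 <- call_pauses(sim$rep1, toy$annotation, filt)
  c2 <- call_pauses(sim$rep2, toy$annotation, filt)
  pairs <- suppressWarnings(estimate_idr(match_pauses(c1, c2)$pairs))
  rep <- reproducible_pauses(pairs, threshold = idr_threshold)
  tr <- sim$truth
  strong <- tr$reproducible & tr$planted_strength >= 8 & tr$expression >= 3
  list(n_strong = sum(strong),
       n_strong_found = sum(pause_key(tr[strong, ]) %in% pause_key(rep)),
       n_rep = nrow(rep),
       n_rep_false = sum(!(pause_key(rep) %in% pause_key(tr))),
       frac_surviving = nrow(rep) / mean(c(nrow(c1), nrow(c2))),
       truth = tr, reproducible = rep, filter = filt, annotation = toy$annotation)
}
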