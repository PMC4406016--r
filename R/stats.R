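# Self-contained statistical primitives used throughout the pipeline.
# Each is written from the defining formula so it can be verified against
# brute-force enumeration oracles; base R's distribution tails (pt, pchisq,
# pnorm) supply p-value lookups.

#' Construct a test result record
#' @noRd
new_test_result <- function(method, statistic, p, n, estimate = NA_real_,
                            reason = NA_character_) {
  structure(
    list(method = method, statistic = statistic, p = p, q = NA_real_,
         n = n, estimate = estimate, reason = reason),
    class = "cna_test")
}

#' @export
print.cna_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.6g, p = %.4g, n = %d\n",
              x$statistic, x$p, x$n))
  if (!is.na(x$q)) cat(sprintf("  q (BH) = %.4g\n", x$q))
  if (!is.na(x$reason)) cat("  note:", x$reason, "\n")
  invisible(x)
}

#' Pearson correlation test
#'
#' Two-sided Pearson product-moment correlation with the t-distribution
#' p-value on n - 2 degrees of freedom. Used to find copy-number-regulated
#' genes (segment-mean log2 ratio vs expression across samples).
#'
#' @param x,y numeric vectors of equal length (>= 3), finite values.
#' @return a `cna_test` with `statistic` = r.
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) return(new_test_result("pearson", NA_real_, NA_real_, n,
                                    reason = "n < 3"))
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("pearson_test requires finite, non-missing inputs")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    return(new_test_result("pearson", NA_real_, NA_real_, n,
                           reason = "zero variance"))
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(t), df = n - 2)
  }
  new_test_result("pearson", r, min(1, p), n)
}

# cache of permutation index matrices for small-n exact Spearman
.perm_cache <- new.env(parent = emptyenv())

#' All permutations of 1:n as an (n! x n) integer matrix
#' @noRd
all_perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perm_rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- vector("list", length(v))
    for (i in seq_along(v)) {
      sub <- perm_rec(v[-i])
      out[[i]] <- cbind(v[i], sub)
    }
    do.call(rbind, out)
  }
  m <- perm_rec(seq_len(n))
  .perm_cache[[key]] <- m
  m
}

#' Spearman rank correlation test
#'
#' rho is the Pearson correlation of average ranks (ties averaged). The
#' two-sided p-value is exact by full enumeration of the n! orderings for
#' n <= `exact_max` and otherwise uses the t-approximation on n - 2 df.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param exact_max largest n for which the permutation null is enumerated.
#' @return a `cna_test` with `statistic` = rho.
#' @export
spearman_test <- function(x, y, exact_max = 9) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) return(new_test_result("spearman", NA_real_, NA_real_, n,
                                    reason = "n < 3"))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3) return(new_test_result("spearman", NA_real_, NA_real_, n,
                                    reason = "n < 3 after NA removal"))
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    return(new_test_result("spearman", NA_real_, NA_real_, n,
                           reason = "all values tied"))
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  rho <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  rho <- max(-1, min(1, rho))
  if (n <= exact_max) {
    P <- all_perms(n)
    # rho for each permutation of one rank vector against the other; with
    # marginals fixed, rho is affine in sum(rx[perm] * ry)
    s <- matrix(rx[P], nrow = nrow(P)) %*% ry
    denom <- sqrt(sum(dx^2) * sum(dy^2))
    rho_perm <- (s - n * mean(rx) * mean(ry)) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    p <- if (abs(rho) == 1) 0 else {
      t <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(t), df = n - 2)
    }
  }
  new_test_result("spearman", rho, min(1, p), n)
}

#' Null distribution of the Mann-Whitney U statistic (no ties)
#'
#' Counting recurrence over the placement of the largest observation:
#' f(m, n, u) = f(m-1, n, u-n) + f(m, n-1, u), where m and n are the group
#' sizes. Returns the probability vector over u = 0..m*n.
#' @noRd
mwu_null_dist <- function(m, n) {
  maxu <- m * n
  A <- array(0, c(m + 1, n + 1, maxu + 1))
  A[1, , 1] <- 1  # no "a" observations: U = 0
  A[, 1, 1] <- 1  # no "b" observations: U = 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    for (u in 0:(i * j)) {
      v <- A[i + 1, j, u + 1]                       # largest is a "b"
      if (u - j >= 0) v <- v + A[i, j + 1, u - j + 1]  # largest is an "a"
      A[i + 1, j + 1, u + 1] <- v
    }
  }
  f <- A[m + 1, n + 1, ]
  f / sum(f)
}

#' Mann-Whitney U test
#'
#' U is reported as the smaller of the two group statistics (min-U
#' convention). The two-sided p-value is exact (own counting recurrence over
#' all labelings) when the combined sample size is <= `exact_max` and the
#' data are tie-free; otherwise a normal approximation with tie correction
#' and, optionally, continuity correction is used.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param exact_max largest combined n for the exact null.
#' @param correct logical: continuity correction in approximate mode.
#' @return a `cna_test` with `statistic` = min-U.
#' @export
mann_whitney_test <- function(a, b, exact_max = 16, correct = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b); n <- na + nb
  if (na < 1 || nb < 1)
    return(new_test_result("mann_whitney", NA_real_, NA_real_, n,
                           reason = "empty group"))
  r <- rank(c(a, b))
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  u <- min(ua, ub)
  ties <- any(duplicated(c(a, b)))
  if (n <= exact_max && !ties) {
    pv <- mwu_null_dist(na, nb)
    lower <- sum(pv[seq_len(u + 1)])             # P(U <= u)
    upper <- sum(pv[(u + 1):length(pv)])         # P(U >= u)
    p <- min(1, 2 * min(lower, upper))
    method <- "mann_whitney_exact"
  } else {
    mu <- na * nb / 2
    tt <- table(c(a, b))
    tiecor <- sum(tt^3 - tt) / (n * (n - 1))
    sig2 <- na * nb / 12 * ((n + 1) - tiecor)
    if (sig2 <= 0)
      return(new_test_result("mann_whitney", u, NA_real_, n,
                             reason = "degenerate (all values tied)"))
    z <- ua - mu
    if (correct) z <- z - sign(z) * 0.5
    z <- z / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "mann_whitney_normal"
  }
  res <- new_test_result(method, u, p, n)
  res$u_a <- ua
  res
}

#' Kruskal-Wallis rank-sum test
#'
#' H with the standard tie correction; p from the chi-square tail on k - 1
#' degrees of freedom. For two groups this agrees with the Mann-Whitney
#' normal approximation without continuity correction.
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty).
#' @return a `cna_test` with `statistic` = H.
#' @export
kruskal_wallis_test <- function(groups) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) g[is.finite(g)])
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  ns <- lengths(groups)
  if (any(ns < 1))
    return(new_test_result("kruskal_wallis", NA_real_, NA_real_, sum(ns),
                           reason = "empty group"))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  if (length(unique(x)) == 1)
    return(new_test_result("kruskal_wallis", NA_real_, NA_real_, N,
                           reason = "all values identical"))
  r <- rank(x)
  gi <- rep(seq_len(k), ns)
  Rs <- tapply(r, gi, sum)
  H <- 12 / (N * (N + 1)) * sum(Rs^2 / ns) - 3 * (N + 1)
  tt <- table(x)
  cf <- 1 - sum(tt^3 - tt) / (N^3 - N)
  H <- H / cf
  p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  new_test_result("kruskal_wallis", H, p, N)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1; NAs are passed
#' through and do not count towards m. Order and names are preserved.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return vector of adjusted p-values (q-values).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(q)
  o <- ok[order(p[ok])]
  qs <- p[o] * m / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  q[o] <- pmin(1, qs)
  names(q) <- names(p)
  q
}

#' Ward hierarchical clustering of numeric sample profiles
#'
#' Agglomerative minimum-variance (Ward) clustering on Euclidean distances,
#' computed by the direct O(n^3) centroid algorithm: at every step the pair
#' of clusters with the smallest increase in within-cluster sum of squares is
#' merged; on exact cost ties the lowest-index pair wins, making the tree
#' reproducible. Heights are on the same scale as `hclust(method="ward.D2")`
#' (the square root of twice the merge cost).
#'
#' Used for clustering samples by their categorical copy-number states
#' (encoded loss = -1, NC = 0, gain = +1, amplification = +2).
#'
#' @param x numeric matrix, one row per sample.
#' @return an object of class `hclust`.
#' @export
ward_cluster <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples to cluster")
  labels <- rownames(x) %||% as.character(seq_len(n))
  cent <- x                      # cluster centroids
  size <- rep(1L, n)
  id <- -(seq_len(n))            # hclust convention: negatives are leaves
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- as.list(seq_len(n)) # leaf sets, for ordering
  ord_tree <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    act <- which(active)
    # pairwise Ward cost between active centroids
    D2 <- as.matrix(dist(cent[act, , drop = FALSE]))^2
    ni <- size[act]
    W <- outer(ni, ni) / outer(ni, ni, "+") * D2
    diag(W) <- Inf
    # lowest-index pair on ties: scan column-major over upper triangle
    best <- c(NA_integer_, NA_integer_); bw <- Inf
    for (j in 2:length(act)) for (i in 1:(j - 1)) {
      if (W[i, j] < bw - 1e-14) { bw <- W[i, j]; best <- c(i, j) }
    }
    i <- act[best[1]]; j <- act[best[2]]
    merge[s, ] <- c(id[i], id[j])
    height[s] <- sqrt(2 * bw)
    # pooled centroid, sizes; merged cluster replaces slot i
    cent[i, ] <- (size[i] * cent[i, ] + size[j] * cent[j, ]) /
      (size[i] + size[j])
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    ord_tree[[s]] <- c(members[[i]], members[[j]])
    members[[i]] <- ord_tree[[s]]
    id[i] <- s
  }
  structure(
    list(merge = merge, height = height,
         order = ord_tree[[n - 1]],
         labels = labels, method = "ward", call = match.call(),
         dist.method = "euclidean"),
    class = "hclust")
}
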