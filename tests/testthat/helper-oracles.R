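# Independent oracles used across the test files. These deliberately share no
# code with the package: different decompositions (SVD / explicit normal
# equations), direct formula evaluations, brute-force enumeration.

# Straight-line re-implementation of the lsGCI pipeline: SVD-based PCA
# (no sign fixing), MVAR fits via explicit normal equations, own SVD
# pseudoinverse. Only valid when C < D - 1 so the reduced fits stay full rank.
naive_lsgc <- function(y, p, var_target) {
  D <- nrow(y); N <- ncol(y)
  yc <- y - rowMeans(y)
  sv <- svd(yc)
  lambda <- sv$d^2 / (N - 1)
  ratio <- cumsum(lambda) / sum(lambda)
  C <- which(ratio >= var_target - 1e-12)[1]
  W <- t(sv$u[, seq_len(C), drop = FALSE])

  pinv_svd <- function(M) {
    s <- svd(M)
    pos <- s$d > max(s$d) * 1e-12
    s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
      t(s$u[, pos, drop = FALSE])
  }
  fit_ne <- function(x) { # returns fitted values x-hat over n = p+1..N
    Nn <- ncol(x)
    Y <- x[, (p + 1):Nn, drop = FALSE]
    Z <- NULL
    for (r in seq_len(p)) Z <- rbind(Z, x[, (p + 1 - r):(Nn - r), drop = FALSE])
    A <- (Y %*% t(Z)) %*% solve(Z %*% t(Z))
    A %*% Z
  }

  x <- W %*% yc
  xhat <- fit_ne(x)
  span <- (p + 1):N
  ehat <- yc[, span, drop = FALSE] - pinv_svd(W) %*% xhat
  s_full <- rowSums(ehat^2) / (N - p)
  gamma <- matrix(NA_real_, D, D)
  for (i in seq_len(D)) {
    Wi <- W[, -i, drop = FALSE]
    xi <- Wi %*% yc[-i, , drop = FALSE]
    xhat_i <- fit_ne(xi)
    e_i <- yc[-i, span, drop = FALSE] - pinv_svd(Wi) %*% xhat_i
    s_i <- rowSums(e_i^2) / (N - p)
    gamma[-i, i] <- log(s_i / s_full[-i])
  }
  gamma
}

# Textbook dynamic-programming Levenshtein distance on two strings.
dp_levenshtein <- function(a, b) {
  s <- strsplit(a, "")[[1]]; t <- strsplit(b, "")[[1]]
  n <- length(s); m <- length(t)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (s[i] != t[j]))
  d[n + 1, m + 1]
}

# Brute-force minimal-cost assignment by permutation enumeration (n <= 7).
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  min(vapply(perms(seq_len(n)),
             function(pm) sum(cost[cbind(seq_len(n), pm)]), numeric(1)))
}

# Breadth-first search connectivity on the symmetrized graph.
bfs_connected <- function(A) {
  D <- nrow(A)
  und <- (A + t(A)) > 0
  seen <- rep(FALSE, D)
  queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(und[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Exhaustive-pair AUC: probability that a random (positive, negative) weight
# pair is correctly ordered, ties counted half (Mann-Whitney U identity).
pairwise_auc <- function(w, status) {
  pos <- w[status == 1]; neg <- w[status == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
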