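# exhaustive support/sign enumeration oracle for the per-group prox problem
#   argmin_u 0.5||u - z||^2 + a ||u||_1 + b ||u||_2
# every stationary candidate is solved in closed form from its pattern and
# the best feasible one is returned
prox_oracle_group <- function(zg, a, b) {
  d <- length(zg)
  fobj <- function(u) 0.5 * sum((u - zg)^2) + a * sum(abs(u)) +
    b * sqrt(sum(u^2))
  best <- rep(0, d)
  fbest <- fobj(best)
  for (code in seq_len(3^d - 1)) {
    s <- integer(d)
    c0 <- code
    for (i in seq_len(d)) { s[i] <- c0 %% 3; c0 <- c0 %/% 3 }
    sg <- c(0, 1, -1)[s + 1]
    S <- which(sg != 0)
    v <- zg[S] - a * sg[S]
    nv <- sqrt(sum(v^2))
    r <- nv - b
    if (r <= 0) next
    u <- rep(0, d)
    u[S] <- v * (r / nv)
    if (any(sign(u[S]) != sg[S])) next
    f <- fobj(u)
    if (f < fbest) { fbest <- f; best <- u }
  }
  best
}

prox_oracle <- function(z, t, l1, l2, groups) {
  u <- numeric(length(z))
  for (g in seq_len(nrow(groups))) {
    idx <- (groups$start[g] + 1L):groups$end[g]
    u[idx] <- prox_oracle_group(z[idx], t * l1, t * l2 * groups$weight[g])
  }
  u
}

random_groups <- function(d, ng) {
  sizes <- as.vector(table(sort(sample(seq_len(ng), d, replace = TRUE))))
  fm <- data.frame(bit_index = seq_len(d) - 1L,
                   group = rep(paste0("g", seq_along(sizes)), sizes),
                   position = seq_len(d), char = "A",
                   stringsAsFactors = FALSE)
  g <- group_structure(fm)
  g$weight <- g$weight * runif(nrow(g), 0.5, 1.5)
  g
}

# small non-separable logistic problem
make_logit_problem <- function(n = 40, p = 10, seed = 11) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- c(1.2, -0.8, rep(0, p - 2))
    pr <- stats::plogis(X %*% beta + 0.3)
    y <- ifelse(runif(n) < pr, 1, -1)
  })
  fm <- data.frame(bit_index = seq_len(p) - 1L, group = "g1",
                   position = seq_len(p), char = "A",
                   stringsAsFactors = FALSE)
  list(X = X, y = y, groups = group_structure(fm))
}
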