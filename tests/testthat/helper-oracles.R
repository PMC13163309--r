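# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately take the slow, literal route and never
# share code with the functions they verify.

# Literal step-up rule: sort ascending, running minimum of p_(i) * m / i from
# the top, clip at 1, map back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  cur <- Inf
  for (i in m:1) {
    cur <- min(cur, ps[i] * m / i)
    adj[i] <- min(cur, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric by direct enumeration over outcome counts.
hyper_upper_oracle <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  js <- k:hi
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Degree and local-clustering statistics straight from an adjacency matrix.
graph_stats_oracle <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    ci[i] <- if (k < 2) 0 else sum(adj[nb, nb]) / (k * (k - 1))
  }
  list(avg_degree = sum(deg) / n, avg_clustering = mean(ci))
}

# Turn an adjacency matrix into a build_network() input (all scores pass the
# default threshold); isolated nodes are carried through the nodes argument.
adj_to_network <- function(adj) {
  ids <- sprintf("n%02d", seq_len(nrow(adj)))
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  el <- data.frame(node_a = ids[idx[, 1]], node_b = ids[idx[, 2]],
                   combined_score = rep(0.9, nrow(idx)),
                   stringsAsFactors = FALSE)
  build_network(el, min_combined = 0.7, nodes = ids)
}

random_adjacency <- function(n, p = 0.5) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  on <- up[stats::runif(length(up)) < p]
  adj[on] <- 1L
  adj + t(adj)
}

# Independent PLS1 + VIP route: per-component closed-form weight
# w_a proportional to X'y on the deflated matrix (no NIPALS iteration),
# explicit scalar accumulation, then the VIP formula evaluated directly.
pls_vip_oracle <- function(X, classes, n_components) {
  cls <- as.factor(classes)
  y <- ifelse(cls == levels(cls)[2], 1, -1)
  y <- y - mean(y)
  Xs <- scale(t(X), center = TRUE, scale = TRUE)
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, n_components)
  ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- numeric(p)
    for (j in seq_len(p)) w[j] <- sum(Xs[, j] * y)
    w <- w / sqrt(sum(w * w))
    tsc <- numeric(n)
    for (i in seq_len(n)) tsc[i] <- sum(Xs[i, ] * w)
    cc <- sum(y * tsc) / sum(tsc * tsc)
    pl <- numeric(p)
    for (j in seq_len(p)) pl[j] <- sum(Xs[, j] * tsc) / sum(tsc * tsc)
    Xs <- Xs - tsc %*% t(pl)
    W[, a] <- w
    ssy[a] <- cc^2 * sum(tsc * tsc)
  }
  vip <- numeric(p)
  for (j in seq_len(p))
    vip[j] <- sqrt(p * sum(ssy * W[j, ]^2) / sum(ssy))
  vip
}

# Deterministic simple graph with 20 nodes and 116 edges (first 116 of the
# 190 unordered pairs), used for the average-degree identity.
graph_20x116 <- function() {
  pairs <- utils::combn(20, 2)[, 1:116]
  data.frame(node_a = sprintf("p%02d", pairs[1, ]),
             node_b = sprintf("p%02d", pairs[2, ]),
             combined_score = 0.9, stringsAsFactors = FALSE)
}

five_targets <- c("BRAF", "GSK3β", "PARP1", "BACE1", "MAOB")
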