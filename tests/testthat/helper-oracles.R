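# Independent brute-force oracles, deliberately written without reference to
# the package's internal implementations.

# TFCE by explicit component labelling at every threshold (igraph)
brute_force_tfce <- function(t_map, edges, weights, E, H, n_steps) {
  V <- length(t_map)
  out <- numeric(V)
  for (sgn in c(1, -1)) {
    u <- sgn * t_map
    m <- max(u)
    if (m <= 0) next
    dh <- m / n_steps
    for (k in seq_len(n_steps)) {
      h <- k * dh
      act <- which(u >= h)
      if (!length(act)) next
      keep <- u[edges[, 1]] >= h & u[edges[, 2]] >= h
      sub <- edges[keep, , drop = FALSE]
      g <- igraph::graph_from_edgelist(sub, directed = FALSE)
      if (igraph::vcount(g) < V) g <- igraph::add_vertices(g, V - igraph::vcount(g))
      memb <- igraph::components(g)$membership
      for (v in act) {
        ext <- sum(weights[act[memb[act] == memb[v]]])
        out[v] <- out[v] + sgn * ext^E * h^H * dh
      }
    }
  }
  out
}

# per-vertex OLS via stats::lm, one vertex at a time
lm_oracle <- function(Y, X) {
  P <- ncol(X)
  beta <- matrix(NA_real_, P, ncol(Y))
  tval <- matrix(NA_real_, P, ncol(Y))
  for (v in seq_len(ncol(Y))) {
    fit <- stats::lm(Y[, v] ~ X - 1)
    sm <- summary(fit)$coefficients
    beta[, v] <- fit$coefficients
    tval[, v] <- sm[, "t value"]
  }
  list(beta = beta, t = tval)
}

# Dice by direct voxel counting
brute_force_dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# trapezoidal ROC area on unique thresholds
trapezoid_auc <- function(probs, labels) {
  th <- sort(unique(probs), decreasing = TRUE)
  tpr <- vapply(c(Inf, th, -Inf),
                function(t) mean(probs[labels == 1] >= t), 0)
  fpr <- vapply(c(Inf, th, -Inf),
                function(t) mean(probs[labels == 0] >= t), 0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
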