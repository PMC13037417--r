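# Independent oracles used across the suite. Each recomputes its quantity
# by a different route than the implementation (enumeration, closed form,
# or direct formula on small inputs).

# Benjamini-Hochberg step-up by literal enumeration of the definition:
# adj_(i) = min over j >= i of p_(j) * m / j, clipped at 1, in input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(ranked[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# GeNorm M by explicit pair enumeration with combn, sd spelled out.
genorm_m_bruteforce <- function(expr) {
  lg <- log2(expr)
  G <- nrow(expr)
  pairs <- utils::combn(G, 2)
  sd_manual <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  V <- matrix(0, G, G)
  for (i in seq_len(ncol(pairs))) {
    j <- pairs[1, i]; k <- pairs[2, i]
    V[j, k] <- V[k, j] <- sd_manual(lg[j, ] - lg[k, ])
  }
  stats::setNames(rowSums(V) / (G - 1), rownames(expr))
}

# GeNorm V curve by explicit per-sample geometric means on the linear scale.
v_curve_bruteforce <- function(expr, ranking) {
  q <- expr[ranking, , drop = FALSE]
  G <- nrow(q)
  geomean <- function(x) prod(x)^(1 / length(x))
  v <- numeric(G - 2)
  for (n in 2:(G - 1)) {
    nf_n <- apply(q[1:n, , drop = FALSE], 2, geomean)
    nf_n1 <- apply(q[1:(n + 1), , drop = FALSE], 2, geomean)
    v[n - 1] <- stats::sd(log2(nf_n / nf_n1))
  }
  v
}

# Upper-tail hypergeometric P(X >= k) by direct pmf summation with choose().
hyper_tail_bruteforce <- function(k, K, N, n) {
  kk <- k:min(n, K)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# All permutations of 1..n (enumeration for the BH order-invariance check).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(combinat_perms(n - 1), function(p) c(i, setdiff(seq_len(n), i)[p]))
  }))
}

# Long-format CT table builder for hand-constructed qPCR scenarios.
make_ct <- function(sample_id, group, assay_id, ct, undetermined = FALSE) {
  data.frame(sample_id = sample_id, group = group, assay_id = assay_id,
             ct = ct, undetermined = undetermined, stringsAsFactors = FALSE)
}
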