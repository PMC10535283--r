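# Independent oracles, deliberately implemented differently from the
# package internals they check.

# U by direct pair counting (package uses the rank-sum identity)
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided permutation p-value of U via pair counting over every
# assignment of the pooled values
oracle_exact_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  centre <- n1 * length(y) / 2
  u_obs <- oracle_u(x, y)
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(i) oracle_u(pooled[i], pooled[-i]))
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-12)
}

# Brute-force per-item case counts: loop over cases, count each item once
oracle_item_counts <- function(item_lists) {
  acc <- new.env()
  for (lst in item_lists) {
    for (item in unique(lst)) {
      acc[[item]] <- (acc[[item]] %||% 0L) + 1L
    }
  }
  items <- ls(acc)
  stats::setNames(vapply(items, function(i) acc[[i]], integer(1)), items)
}
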