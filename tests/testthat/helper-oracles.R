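# Independent oracles, coded from the textbook definitions and kept
# separate from the package's code paths.

# Benjamini-Hochberg step-up: adjusted_(i) = min_{j >= i} m * p_(j) / j,
# capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Mann-Whitney U of a vs b: number of (a, b) pairs with a > b
oracle_u <- function(a, b) sum(outer(a, b, ">"))

# Exact two-sided p by full enumeration of group labelings (continuous
# data, no ties): probability of a U at least as far from its null mean.
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  labelings <- utils::combn(length(pooled), n1)
  us <- apply(labelings, 2, function(idx)
    oracle_u(pooled[idx], pooled[-idx]))
  mu <- n1 * length(b) / 2
  u_obs <- oracle_u(a, b)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# OLS via normal equations plus the textbook t and overall-F formulas
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  df <- n - p
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tval <- beta / se
  tss <- sum((y - mean(y))^2)
  rss <- sum(res^2)
  Fval <- ((tss - rss) / (p - 1)) / (rss / df)
  list(beta = unname(drop(beta)), se = unname(se), t = unname(drop(tval)),
       p_t = unname(2 * pt(-abs(drop(tval)), df)),
       F = Fval, p_F = pf(Fval, p - 1, df, lower.tail = FALSE), df = df)
}

# small abundance-table builder for hand-made fixtures
make_table <- function(values, species, samples = NULL,
                       unit_state = "pmol") {
  if (is.null(samples))
    samples <- paste0("s", seq_len(length(values) / length(species)))
  m <- matrix(values, nrow = length(samples), byrow = TRUE,
              dimnames = list(samples, species))
  abundance_table(m, unit_state)
}

mouse_annotation <- function(samples, genotype, intervention) {
  data.frame(sample = samples, genotype = genotype,
             intervention = intervention, stringsAsFactors = FALSE)
}
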