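# Independent reference implementations: naive double loops and explicit
# normal equations, kept deliberately separate from the package's code
# paths so they can serve as oracles.

oracle_fc <- function(ts) {
  r_n <- ncol(ts)
  out <- matrix(NA_real_, r_n, r_n)
  for (i in seq_len(r_n)) {
    for (j in seq_len(r_n)) {
      if (i == j) next
      x <- ts[, i]; y <- ts[, j]
      r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      r <- min(max(r, -(1 - 1e-12)), 1 - 1e-12)
      out[i, j] <- max(0, atanh(r))
    }
  }
  out
}

oracle_net_summary <- function(z, networks) {
  nets <- unique(networks)
  res <- list()
  for (nm in nets) {
    mem <- which(networks == nm)
    oth <- which(networks != nm)
    ws <- c()
    for (a in mem) for (b in mem) if (a < b) ws <- c(ws, z[a, b])
    bs <- c()
    for (a in mem) for (b in oth) bs <- c(bs, z[a, b])
    w <- mean(ws); b <- mean(bs)
    res[[nm]] <- c(w = w, b = b, sys = (w - b) / w)
  }
  res
}

oracle_pairwise <- function(z, networks, na, nb) {
  vals <- c()
  for (a in which(networks == na)) {
    for (b in which(networks == nb)) vals <- c(vals, z[a, b])
  }
  mean(vals)
}

oracle_ols <- function(X, y, ci_level = 0.99) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  n <- nrow(X); p <- ncol(X) - 1
  s2 <- sum(res^2) / (n - p - 1)
  se <- sqrt(diag(s2 * xtx_inv))
  tval <- c(beta) / se
  pval <- 2 * pt(-abs(tval), n - p - 1)
  q <- qt(1 - (1 - ci_level) / 2, n - p - 1)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(beta = c(beta), se = se, t = tval, p = pval,
       ci_low = c(beta) - q * se, ci_high = c(beta) + q * se,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

# hand-executed forward selection: min partial p via the normal-equations
# oracle, entering while p < alpha
oracle_forward <- function(df, outcome, candidates, alpha = 0.05) {
  retained <- character()
  remaining <- candidates
  y <- df[[outcome]]
  repeat {
    if (length(remaining) == 0) break
    ps <- vapply(remaining, function(cand) {
      X <- cbind(1, as.matrix(df[c(retained, cand)]))
      fit <- oracle_ols(X, y)
      fit$p[length(fit$p)]
    }, numeric(1))
    if (min(ps) >= alpha) break
    retained <- c(retained, remaining[which.min(ps)])
    remaining <- setdiff(remaining, retained)
  }
  retained
}

# random valid connectivity instance: time series plus a parcellation
random_instance <- function(seed, max_r = 12, max_t = 200) {
  set.seed(seed)
  n_net <- sample(2:4, 1)
  sizes <- pmax(2, sample(2:4, n_net, replace = TRUE))
  r_n <- sum(sizes)
  if (r_n > max_r) {
    sizes <- rep(2, n_net)
    r_n <- sum(sizes)
  }
  t_n <- sample(10:max_t, 1)
  parc <- parcellation(data.frame(
    roi = paste0("r", seq_len(r_n)),
    network = rep(paste0("n", seq_len(n_net)), sizes)
  ))
  ts <- matrix(rnorm(t_n * r_n), t_n, r_n,
               dimnames = list(NULL, parc$roi))
  # induce some network structure so values are not all near zero
  for (k in seq_len(n_net)) {
    shared <- rnorm(t_n)
    idx <- which(as.integer(parc$network) == k)
    ts[, idx] <- ts[, idx] + shared
  }
  list(ts = ts, parc = parc)
}

# connectivity-classed matrix from raw symmetric values (diagonal masked)
as_conn <- function(m, rois = paste0("r", seq_len(ncol(m)))) {
  diag(m) <- NA_real_
  dimnames(m) <- list(rois, rois)
  structure(m, class = c("connectivity", "matrix", "array"))
}
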