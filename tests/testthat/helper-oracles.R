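# Independent oracles, coded without reference to the package internals.

# Closed-form normal-equations OLS: beta = (X'X)^-1 X'y, with classical
# coefficient SEs and centered R^2.
ols_oracle <- function(X, y) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(XtX_inv) * sigma2)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(beta = as.numeric(beta), se = as.numeric(se), r_squared = r2)
}

# Brute-force modified Thompson tau: recomputes every deviation each
# round and deletes the worst offender while it exceeds the threshold.
tau_oracle <- function(x, alpha = 0.05) {
  keep <- rep(TRUE, length(x))
  repeat {
    v <- x[keep]
    n <- length(v)
    if (n < 3) break
    mu <- sum(v) / n
    sdev <- sqrt(sum((v - mu)^2) / (n - 1))
    if (sdev == 0) break
    tc <- qt(1 - alpha / 2, n - 2)
    thresh <- tc * (n - 1) / (sqrt(n) * sqrt(n - 2 + tc^2)) * sdev
    devs <- abs(x - mu)
    devs[!keep] <- -Inf
    worst <- which.max(devs)
    if (devs[worst] > thresh) keep[worst] <- FALSE else break
  }
  x[keep]
}

# A small screened-style dataset with known structure, for reuse.
make_two_region_samples <- function(seed = 7, n = 40) {
  set.seed(seed)
  som <- runif(2 * n, 10, 60)
  region <- rep(c("CarbSite", "TerrSite"), each = n)
  slope <- ifelse(region == "CarbSite", 0.46, 0.30)
  oc <- slope * som + rnorm(2 * n, 0, 1)
  oc <- pmin(pmax(oc, 0.01 * som), 0.99 * som)
  data.frame(region = region, som = som, oc = oc,
             ces = ifelse(region == "CarbSite", "CE", "TD"),
             sedimentary = ifelse(region == "CarbSite", "carbonate",
                                  "terrigenous"),
             latitude = ifelse(region == "CarbSite", 25, 29))
}
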