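# independent enumeration oracle: explicit basis construction + OLS per
# breakpoint pair
brute_force_fit <- function(cover, days) {
  keep <- !is.na(cover)
  x <- days[keep]; y <- cover[keep]
  best <- list(rss = Inf)
  for (t1 in min(x):(max(x) - 1)) for (t2 in (t1 + 1):max(x)) {
    b2 <- pmin(1, pmax(0, (x - t1) / (t2 - t1)))
    X <- cbind(1, b2)
    cf <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) cf <- c(mean(y), 0)
    if (cf[2] > 0) cf <- c(mean(y), 0)
    rss <- sum((y - X %*% cf)^2)
    if (rss < best$rss - 1e-12)
      best <- list(t1 = t1, t2 = t2, rss = rss)
  }
  best
}

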