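# Hand-computed oracles, independent of the package's estimation path.

# Brute-force product-limit estimate at the distinct event times.
# Tie convention: deaths precede censorings at the same time, so the risk
# set at time u is everyone with observed time >= u.
km_oracle <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  if (length(ev_times) == 0L) {
    return(data.frame(time = numeric(), surv = numeric()))
  }
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (i in seq_along(ev_times)) {
    u <- ev_times[i]
    d <- sum(time == u & event == 1)
    n <- sum(time >= u)
    s <- s * (1 - d / n)
    out$surv[i] <- s
  }
  out
}

# Cox log partial likelihood for a single numeric covariate, no ties.
cox_pl_oracle <- function(beta, time, event, z) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; z <- z[ord]
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * z[i] - log(sum(exp(beta * z[risk])))
  }
  ll
}

# Two-group log-rank score statistic (observed minus expected, hypergeometric
# variance), squared: equals the k = 2 log-rank chi-square.
logrank_oracle_chisq <- function(time, event, group) {
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (u in ev_times) {
    at_risk <- time >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == levels(factor(group))[1])
    d <- sum(time == u & event == 1)
    d1 <- sum(time == u & event == 1 & group == levels(factor(group))[1])
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}
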