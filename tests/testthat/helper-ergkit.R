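# shared fixtures: all synthetic data is generated in code at test time

# long-format sweep data frame from a list of voltage vectors on one grid
make_sweep_df <- function(time_ms, trials, animal_id = "m1", eye = "right",
                          luminance_log = -0.01) {
  do.call(rbind, lapply(seq_along(trials), function(k)
    data.frame(animal_id = animal_id, eye = eye,
               luminance_log = luminance_log, trial = k,
               time_ms = time_ms, voltage_uV = trials[[k]],
               stringsAsFactors = FALSE)))
}

# small, fast simulation setup used in several tests
quick_params <- function(...) {
  sim_params(pretrial_ms = 20, posttrial_ms = 150,
             luminance_levels = c(-1.2, -0.01), ...)
}

# independent brute-force factorial ANOVA oracle: indicator design
# matrices projected by QR, nothing shared with the implementation
oracle_rss <- function(y, X) {
  sum((y - qr.fitted(qr(X), y))^2)
}

indicators <- function(f) {
  f <- as.factor(f)
  m <- outer(f, levels(f), `==`) + 0
  m
}

oracle_two_way <- function(y, A, B, type = 2) {
  A <- factor(A); B <- factor(B)
  n <- length(y)
  one <- matrix(1, n, 1)
  iA <- indicators(A); iB <- indicators(B)
  iAB <- indicators(interaction(A, B))
  X1 <- one; XA <- cbind(one, iA); XB <- cbind(one, iB)
  XAB <- cbind(one, iA, iB); Xfull <- cbind(one, iAB)
  r1 <- oracle_rss(y, X1); ra <- oracle_rss(y, XA); rb <- oracle_rss(y, XB)
  rab <- oracle_rss(y, XAB); rf <- oracle_rss(y, Xfull)
  if (type == 1) {
    ss <- c(r1 - ra, ra - rab, rab - rf)
  } else if (type == 2) {
    ss <- c(rb - rab, ra - rab, rab - rf)
  } else stop("oracle supports types 1 and 2")
  a <- nlevels(A); b <- nlevels(B)
  dfe <- c(a - 1, b - 1, (a - 1) * (b - 1))
  dfr <- n - a * b
  mse <- rf / dfr
  f <- (ss / dfe) / mse
  list(ss = ss, rss = rf, F = f,
       p = pf(f, dfe, dfr, lower.tail = FALSE))
}

oracle_one_way <- function(y, g) {
  g <- factor(g)
  one <- matrix(1, length(y), 1)
  r1 <- oracle_rss(y, one)
  rg <- oracle_rss(y, cbind(one, indicators(g)))
  k <- nlevels(g); n <- length(y)
  f <- ((r1 - rg) / (k - 1)) / (rg / (n - k))
  list(ss_between = r1 - rg, ss_within = rg, F = f,
       p = pf(f, k - 1, n - k, lower.tail = FALSE))
}
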