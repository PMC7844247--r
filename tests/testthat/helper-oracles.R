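# Independent oracles used by unit and acceptance tests.

# brute-force balanced two-way ANOVA from explicit sums of squares
bf_anova <- function(y, g, t) {
  g <- as.factor(g); t <- as.factor(t)
  grand <- mean(y)
  mg <- tapply(y, g, mean); mt <- tapply(y, t, mean)
  mgt <- tapply(y, list(g, t), mean)
  ng <- table(g); nt <- table(t); ngt <- table(g, t)
  ss_g <- sum(ng * (mg - grand)^2)
  ss_t <- sum(nt * (mt - grand)^2)
  ss_i <- sum(ngt * (sweep(sweep(mgt, 1, mg), 2, mt) + grand)^2)
  ss_e <- sum((y - mgt[cbind(g, t)])^2)
  df_g <- nlevels(g) - 1; df_t <- nlevels(t) - 1
  df_i <- df_g * df_t
  df_e <- length(y) - nlevels(g) * nlevels(t)
  mse <- ss_e / df_e
  f <- c(ss_g / df_g, ss_t / df_t, ss_i / df_i) / mse
  list(f = f, p = stats::pf(f, c(df_g, df_t, df_i), df_e, lower.tail = FALSE))
}
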