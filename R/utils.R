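## Scaled inverse chi-square draws: X = df * scale / chisq(df).
## Used for variance-component full conditionals; df = 0 with scale 0 is the
## improper flat limit handled at the call site.
rinvchisq <- function(n, df, scale) {
  if (df <= 0) stop("rinvchisq requires df > 0")
  df * scale / stats::rchisq(n, df)
}

## Equal-tail credibility interval.
ci_equal_tail <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, probs = c(a, 1 - a), names = FALSE, type = 7)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
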