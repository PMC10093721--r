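# Independent reference implementations used to cross-check the package's
# entropy/fractal estimators and the blood-pressure grade map. These follow
# the definitions directly (template-by-template, pattern-by-pattern) and
# share no code with the implementations under R/.

embed_templates <- function(x, m) {
  nt <- length(x) - m + 1
  sapply(seq_len(m), function(k) x[k:(k + nt - 1)])
}

sampen_naive <- function(x, m, r_frac) {
  sdx <- sd(x)
  if (sdx == 0) return(0)
  r <- r_frac * sdx
  nt <- length(x) - m
  Em <- embed_templates(x, m)[seq_len(nt), , drop = FALSE]
  Em1 <- embed_templates(x, m + 1)[seq_len(nt), , drop = FALSE]
  A <- B <- 0
  for (i in seq_len(nt)) {
    db <- do.call(pmax, as.data.frame(abs(Em - rep(Em[i, ], each = nt))))
    da <- do.call(pmax, as.data.frame(abs(Em1 - rep(Em1[i, ], each = nt))))
    B <- B + sum(db <= r) - 1   # drop self-match
    A <- A + sum(da <= r) - 1
  }
  if (B <= 0) return(0)
  if (A <= 0) return(log(B + 1))
  -log(A / B)
}

apen_naive <- function(x, m, r_frac) {
  sdx <- sd(x)
  if (sdx == 0) return(0)
  r <- r_frac * sdx
  N <- length(x)
  phi <- function(mm) {
    nt <- N - mm + 1
    Em <- embed_templates(x, mm)
    cnt <- vapply(seq_len(nt), function(i) {
      d <- do.call(pmax, as.data.frame(abs(Em - rep(Em[i, ], each = nt))))
      sum(d <= r)
    }, numeric(1))
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1)
}

permen_naive <- function(x, order, delay) {
  n_pat <- length(x) - (order - 1) * delay
  pats <- vapply(seq_len(n_pat), function(t) {
    v <- x[t + (0:(order - 1)) * delay]
    paste(rank(v, ties.method = "first"), collapse = "-")
  }, character(1))
  p <- table(pats) / n_pat
  -sum(p * log(p))
}

higuchi_naive <- function(x, kmax) {
  N <- length(x)
  logL <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Ls <- c()
    for (m in seq_len(k)) {
      n_i <- floor((N - m) / k)
      if (n_i < 1) next
      s <- 0
      for (i in seq_len(n_i)) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      Ls <- c(Ls, s * (N - 1) / (n_i * k^2))
    }
    logL[k] <- log(mean(Ls))
  }
  unname(coef(lm(logL ~ log(1 / seq_len(kmax))))[2])
}

fuzzyen_naive <- function(mu) {
  s <- 0
  for (m_i in mu) {
    t1 <- if (m_i > 0) m_i * log(m_i) else 0
    t2 <- if (m_i < 1) (1 - m_i) * log(1 - m_i) else 0
    s <- s + t1 + t2
  }
  -s / length(mu)
}

# British Hypertension Society grade table, coded as a straight rule chain.
bp_grade_oracle <- function(s, d) {
  if (s >= 140 && d < 90) {
    if (s >= 160) "ISH Grade 2" else "ISH Grade 1"
  } else if (s >= 180 || d >= 110) {
    "Grade 3"
  } else if (s >= 160 || d >= 100) {
    "Grade 2"
  } else if (s >= 140 || d >= 90) {
    "Grade 1"
  } else if (s >= 130 || d >= 85) {
    "High normal"
  } else if (s < 120 && d < 80) {
    "Optimal"
  } else {
    "Normal"
  }
}
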