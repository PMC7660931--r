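# Shared fixtures and independent oracles.

# exhaustive grid-search SSE minimiser over a in [1,1000] x b in [0,10],
# refined around the best cell to ~3 significant figures; independent of
# the package's optimiser.
grid_sse_oracle <- function(t, score, a_range = c(1, 1000),
                            b_range = c(0, 10), n = 201, rounds = 4) {
  sse <- function(a, b) sum((score - a * exp(-b * t))^2)
  for (r in seq_len(rounds)) {
    as <- seq(a_range[1], a_range[2], length.out = n)
    bs <- seq(b_range[1], b_range[2], length.out = n)
    g <- expand.grid(a = as, b = bs)
    v <- mapply(sse, g$a, g$b)
    i <- which.min(v)
    da <- diff(a_range) / (n - 1); db <- diff(b_range) / (n - 1)
    a_range <- c(max(g$a[i] - 2 * da, 1e-6), g$a[i] + 2 * da)
    b_range <- c(max(g$b[i] - 2 * db, 0), g$b[i] + 2 * db)
  }
  list(a = g$a[i], b = g$b[i], sse = v[i])
}

# pairwise ML distance by direct likelihood scan under an empirical
# exchangeability model; builds P(t) by eigendecomposition itself and
# never calls the distance routine under test.
grid_ml_oracle <- function(x, y, Q_lower, bf, d_max = 20, n = 2000) {
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- Q_lower
  S <- S + t(S)
  Q <- S %*% diag(bf)
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(bf * diag(Q))
  B <- diag(sqrt(bf)) %*% Q %*% diag(1 / sqrt(bf))
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  Pt <- function(d) {
    P <- diag(1 / sqrt(bf)) %*% eg$vectors %*% diag(exp(eg$values * d)) %*%
      t(eg$vectors) %*% diag(sqrt(bf))
    pmax(P, 1e-300)
  }
  ll <- function(d) {
    P <- Pt(d)
    sum(log(bf[x] * P[cbind(x, y)]))
  }
  ds <- seq(1e-6, d_max, length.out = n)
  lls <- vapply(ds, ll, numeric(1))
  i <- which.max(lls)
  optimize(ll, c(ds[max(i - 1, 1)], ds[min(i + 1, n)]), maximum = TRUE,
           tol = 1e-6)$maximum
}

# amino-acid alphabet used by the package (exported order)
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# write a 12-column tabular hit file; rows is a data.frame with at least
# qseqid, sseqid, evalue, bitscore (filler values for the rest)
write_hits <- function(rows, path = tempfile(fileext = ".tsv")) {
  n <- nrow(rows)
  full <- data.frame(q = rows$qseqid, s = rows$sseqid, pident = 50,
                     length = 100, mismatch = 50, gapopen = 0, qstart = 1,
                     qend = 100, sstart = 1, send = 100,
                     evalue = rows$evalue, bitscore = rows$bitscore)
  writeLines(apply(full, 1, paste, collapse = "\t"), path)
  path
}

hit_tab <- function(q, s, e, b, qp = NA_character_, sp = NA_character_) {
  read_blast_tab(write_hits(data.frame(qseqid = q, sseqid = s,
                                       evalue = e, bitscore = b)),
                 query_proteome = qp, subject_proteome = sp)
}

# random aligned pair of sequences separated by JTT evolution, for the
# ML-distance oracle tests
sim_jtt_pair <- function(ncol, d, Q_lower, bf) {
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- Q_lower
  S <- S + t(S)
  Q <- S %*% diag(bf)
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(bf * diag(Q))
  B <- diag(sqrt(bf)) %*% Q %*% diag(1 / sqrt(bf))
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / sqrt(bf)) %*% eg$vectors %*% diag(exp(eg$values * d)) %*%
    t(eg$vectors) %*% diag(sqrt(bf))
  x <- sample(20, ncol, replace = TRUE, prob = bf)
  y <- vapply(x, function(i) sample(20, 1, prob = pmax(P[i, ], 0)),
              numeric(1))
  list(x = x, y = y)
}

jtt_params <- function() {
  m <- get(".JTT", envir = environment(phangorn::dist.ml))
  list(Q = m$Q, bf = unname(m$bf))
}
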