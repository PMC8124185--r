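# Shared fixtures and independent brute-force oracles used across tests.

# Small two-condition matrix (n features x 2*reps samples) from a vector or
# generator; condition labels encoded in the sample names.
make_em <- function(values, reps = ncol(values) / 2) {
  stopifnot(is.matrix(values))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%04d", seq_len(nrow(values)))
  condition <- rep(c("control", "treated"), each = reps)
  colnames(values) <- paste0(condition, "_", c(seq_len(reps), seq_len(reps)))
  expression_matrix(values, condition)
}

random_em <- function(n_features, reps = 5, mean = 8, sd = 1,
                      effect = 0, raw = FALSE) {
  eff <- rep(c(0, effect), each = reps)
  vals <- matrix(stats::rnorm(n_features * 2 * reps, mean, sd),
                 n_features, 2 * reps)
  vals <- sweep(vals, 2, eff, `+`)
  if (raw) vals <- 2^vals
  make_em(vals, reps)
}

# Ordinary pooled-variance two-sample t, coded independently of the package.
pooled_t_oracle <- function(x_ctrl, x_trt) {
  n1 <- length(x_ctrl); n2 <- length(x_trt)
  sp2 <- (sum((x_ctrl - mean(x_ctrl))^2) + sum((x_trt - mean(x_trt))^2)) /
    (n1 + n2 - 2)
  d <- mean(x_trt) - mean(x_ctrl)
  tt <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
  c(t = tt, p = p)
}

# Exhaustive uORF finder: for every position pair (i, j) test "codon at i is
# ATG, codon at j is the first in-frame stop after i, both inside the UTR".
brute_force_uorfs <- function(seq) {
  s <- toupper(chartr("u", "t", tolower(seq)))
  n <- nchar(s)
  codon_at <- function(i) substr(s, i, i + 2)
  stops <- c("TAA", "TAG", "TGA")
  res <- NULL
  for (i in seq_len(max(0, n - 5))) {
    if (codon_at(i) != "ATG") next
    j <- i + 3
    while (j + 2 <= n) {
      if (codon_at(j) %in% stops) {
        res <- rbind(res, c(start = i - 1, end = j + 2,
                            length = j + 2 - (i - 1)))
        break
      }
      j <- j + 3
    }
  }
  if (is.null(res))
    return(data.frame(start = integer(), end = integer(),
                      length = integer()))
  as.data.frame(res)
}

random_utr <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Exhaustive hypergeometric right tail by enumerating every n-subset of a
# small universe.
enumerate_hyper_right <- function(k, K, n, N) {
  universe <- seq_len(N)
  annotated <- seq_len(K)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d %in% annotated) >= k))
}

# Hand-applied multiple-testing adjustments per their step definitions.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  run <- Inf
  for (i in m:1) {
    run <- min(run, m * p[o[i]] / i)
    q[o[i]] <- min(1, run)
  }
  q
}

holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

# Scored graph from an edge data.frame, plus helpers for planted models.
graph_from_edges <- function(df, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(df$from, df$to)))
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

two_triangles <- function() {
  g <- graph_from_edges(data.frame(
    from = c("a", "a", "b", "x", "x", "y"),
    to = c("b", "c", "c", "y", "z", "z"),
    score = 1))
  g
}
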