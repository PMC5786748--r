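# Independent brute-force oracle for the balanced split-plot design, written
# from the textbook cell-mean definitions (no shared code with the package).

oracle_split_plot <- function(Y, g) {
  k <- ncol(Y); G <- nlevels(g); n <- table(g)[1]; N <- nrow(Y)
  grand <- mean(Y)
  m_s <- rowMeans(Y)
  m_g <- tapply(m_s, g, mean)
  c_j <- colMeans(Y)
  cell <- matrix(NA, G, k)
  for (gi in seq_len(G))
    cell[gi, ] <- colMeans(Y[g == levels(g)[gi], , drop = FALSE])
  ss_group <- k * sum(n * (m_g - grand)^2)
  ss_subj <- k * sum((m_s - m_g[g])^2)
  ss_cond <- N * sum((c_j - grand)^2)
  ss_int <- 0
  for (gi in seq_len(G)) for (j in seq_len(k))
    ss_int <- ss_int + n * (cell[gi, j] - m_g[gi] - c_j[j] + grand)^2
  res <- Y
  for (i in seq_len(N)) for (j in seq_len(k))
    res[i, j] <- Y[i, j] - m_s[i] - cell[as.integer(g[i]), j] +
      m_g[as.integer(g[i])]
  ss_err <- sum(res^2)
  list(F_group = unname((ss_group / (G - 1)) / (ss_subj / (N - G))),
       F_cond = unname((ss_cond / (k - 1)) / (ss_err / ((k - 1) * (N - G)))),
       F_int = unname((ss_int / ((k - 1) * (G - 1))) /
                        (ss_err / ((k - 1) * (N - G)))))
}

long_from_wide <- function(Y, g) {
  data.frame(subject = rep(rownames(Y), ncol(Y)),
             group = rep(as.character(g), ncol(Y)),
             condition = rep(colnames(Y), each = nrow(Y)),
             value = as.vector(Y))
}

random_table <- function(G = 3, n = 4, k = 3) {
  N <- G * n
  Y <- matrix(rnorm(N * k), N, k,
              dimnames = list(sprintf("S%02d", 1:N), paste0("c", 1:k)))
  g <- factor(rep(LETTERS[1:G], each = n))
  list(Y = Y, g = g)
}
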