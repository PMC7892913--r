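# Independent brute-force implementations used to cross-check the fast paths:
# covariances by explicit loops and plain solve() for the activation-pattern
# transform; direct double summation for the latent-source class weights.

brute_patterns <- function(W, data) {
  d <- dim(data)
  X <- matrix(0, d[2], d[1] * d[3])
  col <- 1
  for (i in seq_len(d[1])) for (t in seq_len(d[3])) {
    X[, col] <- data[i, , t]; col <- col + 1
  }
  Xc <- X - rowMeans(X)
  sigma_X <- matrix(0, d[2], d[2])
  for (j in seq_len(ncol(Xc)))
    sigma_X <- sigma_X + Xc[, j] %*% t(Xc[, j])
  sigma_X <- sigma_X / ncol(Xc)
  S <- t(W) %*% X
  Sc <- S - rowMeans(S)
  sigma_S <- matrix(0, ncol(W), ncol(W))
  for (j in seq_len(ncol(Sc)))
    sigma_S <- sigma_S + Sc[, j] %*% t(Sc[, j])
  sigma_S <- sigma_S / ncol(Sc)
  sigma_X %*% W %*% solve(sigma_S)
}

brute_ls_weights <- function(w, class_index) {
  k <- dim(w)[2]
  num <- numeric(k)
  for (s in seq_len(k)) for (j in seq_len(dim(w)[1]))
    num[s] <- num[s] + abs(w[j, s, class_index + 1])
  num / sum(num)
}
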