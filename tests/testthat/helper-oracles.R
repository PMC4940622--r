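# Brute-force oracles kept deliberately independent of the package's
# computational paths.

# primal ridge with a GLS intercept: (Zc'Zc + lam I)^-1 Zc'(y - mu)
bf_ridge <- function(Z, y, lambda) {
  Zc <- scale(Z, scale = FALSE)
  n <- nrow(Z)
  V <- Zc %*% t(Zc) + lambda * diag(n)
  one <- rep(1, n)
  mu <- solve(t(one) %*% solve(V, one), t(one) %*% solve(V, y))[1]
  u <- solve(crossprod(Zc) + lambda * diag(ncol(Z)), crossprod(Zc, y - mu))
  list(mu = mu, u = as.numeric(u))
}

# brute-force weighted ridge (HEM second stage) in the primal
bf_weighted_ridge <- function(Z, y, w, sigma_e2) {
  Zc <- scale(Z, scale = FALSE)
  n <- nrow(Z)
  pos <- w > 0
  V <- Zc[, pos, drop = FALSE] %*% diag(w[pos], sum(pos)) %*%
    t(Zc[, pos, drop = FALSE]) + sigma_e2 * diag(n)
  one <- rep(1, n)
  mu <- solve(t(one) %*% solve(V, one), t(one) %*% solve(V, y))[1]
  u <- numeric(length(w))
  u[pos] <- as.numeric(
    solve(crossprod(Zc[, pos, drop = FALSE]) +
            sigma_e2 * diag(1 / w[pos], sum(pos)),
          crossprod(Zc[, pos, drop = FALSE], y - mu)))
  u
}

# sequential (Type-I) sums of squares by explicit projection matrices
bf_sequential_ss <- function(data, trait, terms) {
  y <- data[[trait]]
  X <- matrix(1, nrow(data), 1)
  proj <- function(X) X %*% solve(crossprod(X), t(X))
  fitted_prev <- proj(X) %*% y
  out <- numeric(length(terms))
  for (i in seq_along(terms)) {
    f <- stats::as.formula(paste("~", paste(terms[seq_len(i)],
                                            collapse = "+")))
    Xi <- stats::model.matrix(f, data)
    Xi <- Xi[, qr(Xi)$pivot[seq_len(qr(Xi)$rank)], drop = FALSE]
    fitted_i <- proj(Xi) %*% y
    out[i] <- sum((fitted_i - fitted_prev)^2)
    fitted_prev <- fitted_i
  }
  names(out) <- terms
  c(out, Error = sum((y - fitted_prev)^2))
}

# all-pairs interval containment count of significant SNPs per gene
bf_gene_counts <- function(snps, ann) {
  sapply(seq_len(nrow(ann)), function(i) {
    sum(snps$significant &
          snps$chrom == ann$chrom[i] &
          snps$pos >= ann$start[i] &
          snps$pos <= ann$end[i])
  })
}

# small panel helper for engine-level tests
toy_panel <- function(Z, chrom = "chr1") {
  if (is.null(rownames(Z))) rownames(Z) <- sprintf("acc%02d", seq_len(nrow(Z)))
  if (is.null(colnames(Z))) colnames(Z) <- sprintf("s%03d", seq_len(ncol(Z)))
  genotype_panel(Z, data.frame(snp_id = colnames(Z), chrom = chrom,
                               pos = seq_len(ncol(Z)) * 10L))
}

quick_cfg <- function(seed, ...) {
  sim_config(n_snps = 400, n_genes = 50, seed = seed, ...)
}
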