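#' Filter a genotype panel on minor-allele frequency
#'
#' Retains SNPs whose minor-allele frequency (recomputed from the allele
#' matrix) is *strictly* greater than `maf_min`; column order is
#' preserved.
#'
#' @param panel A [genotype_panel()].
#' @param maf_min Frequency threshold (strict inequality).
#' @return A [genotype_panel()] with the retained SNPs.
#' @export
maf_filter <- function(panel, maf_min = 0.2) {
  keep <- compute_maf(panel$alleles) > maf_min
  if (!any(keep)) stop("MAF filter removed every SNP", call. = FALSE)
  genotype_panel(panel$alleles[, keep, drop = FALSE],
                 panel$map[keep, c("snp_id", "chrom", "pos")])
}

# Precomputed quantities shared by every (re)fit against the same
# genotype matrix: centered columns, the eigendecomposition of the n x n
# genomic cross-product K = Zc Zc', and its rotations. Building this once
# is what makes full-pipeline permutation thresholds affordable.
gwa_engine <- function(Z) {
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  n <- nrow(Z)
  Zc <- sweep(Z, 2L, colMeans(Z))
  K <- tcrossprod(Zc)
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  list(n = n, p = ncol(Z), Zc = Zc,
       d = d, U = U,
       UtZ = crossprod(U, Zc),          # n x p
       UtZ2 = crossprod(U, Zc)^2,       # for hat values
       Ut1 = as.numeric(crossprod(U, rep(1, n))),
       snp_ids = colnames(Z))
}

# REML criterion (negative restricted log-likelihood up to a constant) for
# the variance ratio lambda = sigma_e2 / sigma_u2, evaluated in the
# eigenbasis of K. One fixed effect (the intercept); sigma_u2 profiled out.
reml_nll <- function(loglam, yt, xt, d, n) {
  v <- d + exp(loglam)
  xtv <- xt / v
  xx <- sum(xt * xtv)
  mu <- sum(yt * xtv) / xx
  r <- yt - xt * mu
  rss <- sum(r^2 / v)
  s2u <- rss / (n - 1)
  0.5 * ((n - 1) * log(s2u) + sum(log(v)) + log(xx))
}

fit_ridge_engine <- function(engine, y, lambda = NULL) {
  n <- engine$n
  if (length(y) != n) stop("length(y) must match the panel", call. = FALSE)
  if (stats::var(y) == 0) {
    stop("zero phenotypic variance: nothing to fit", call. = FALSE)
  }
  yt <- as.numeric(crossprod(engine$U, y))
  xt <- engine$Ut1
  if (is.null(lambda)) {
    dbar <- mean(engine$d[engine$d > max(engine$d) * 1e-12])
    opt <- stats::optimize(reml_nll, interval = log(dbar) + c(-16, 16),
                           yt = yt, xt = xt, d = engine$d, n = n)
    lambda <- exp(opt$minimum)
    convergence_note <- if (abs(opt$minimum - (log(dbar) - 16)) < 1e-6 ||
                            abs(opt$minimum - (log(dbar) + 16)) < 1e-6)
      "lambda at search boundary" else NA_character_
  } else {
    convergence_note <- NA_character_
  }
  v <- engine$d + lambda
  xtv <- xt / v
  xx <- sum(xt * xtv)
  mu <- sum(yt * xtv) / xx
  r <- yt - xt * mu
  alpha <- r / v
  s2u <- sum(r * alpha) / (n - 1)
  u_hat <- as.numeric(crossprod(engine$UtZ, alpha))
  list(mu = mu, lambda = lambda,
       sigma_u2 = s2u, sigma_e2 = lambda * s2u,
       u_hat = u_hat, alpha = alpha, yt = yt,
       convergence_note = convergence_note)
}

hem_engine <- function(engine, fit, y) {
  lambda <- fit$lambda
  h <- colSums(engine$UtZ2 / (engine$d + lambda))
  if (any(h >= 1)) {
    warning("hat value(s) numerically >= 1; clipping")
    h <- pmin(h, 1 - 1e-10)
  }
  w <- fit$u_hat^2 / (1 - h)
  u_hem <- numeric(engine$p)
  pos <- w > 0
  if (any(pos)) {
    Zs <- sweep(engine$Zc[, pos, drop = FALSE], 2L, sqrt(w[pos]), `*`)
    Vw <- tcrossprod(Zs)
    diag(Vw) <- diag(Vw) + fit$sigma_e2
    ch <- chol(Vw)
    sol <- backsolve(ch, forwardsolve(t(ch), cbind(1, y)))
    muw <- sum(sol[, 2]) / sum(sol[, 1])  # GLS intercept under Vw
    rhs <- backsolve(ch, forwardsolve(t(ch), y - muw))
    u_hem[pos] <- w[pos] * as.numeric(crossprod(engine$Zc[, pos, drop = FALSE],
                                                rhs))
  }
  list(u_hem = u_hem, h = h, w = w)
}

#' SNP-BLUP ridge regression of a trait on all SNPs
#'
#' Fits the random-effect model `y = 1 mu + Z u + e` with
#' `u ~ N(0, sigma_u2 I)` and `e ~ N(0, sigma_e2 I)`, all SNPs in a single
#' model. Genotype columns are centered (not variance-standardized, so
#' effects stay in per-allele trait units). Variance components are
#' estimated by REML on the dual n x n representation
#' `V = sigma_u2 Z Z' + sigma_e2 I` via one eigendecomposition of `Z Z'`
#' and a line search over `lambda = sigma_e2 / sigma_u2`; the BLUP effects
#' are `u_hat = Z' (Z Z' + lambda I)^{-1} (y - 1 mu_hat)` with `mu_hat`
#' the GLS intercept. For fixed `lambda` this equals the primal ridge
#' solution `(Z'Z + lambda I)^{-1} Z' (y - mu_hat)`.
#'
#' @param y Numeric vector of accession trait values (e.g. LS-means), one
#'   per panel accession; names, if present, must match the panel. Missing
#'   values drop the accession with a warning.
#' @param panel A [genotype_panel()] (already MAF-filtered).
#' @param lambda Optional fixed variance ratio; `NULL` (default) estimates
#'   it by REML.
#' @return Object of class `ridge_fit`: `mu`, `lambda`, `sigma_u2`,
#'   `sigma_e2`, `u_hat` (named per SNP), and the internal engine for
#'   reuse by [hem_update()].
#' @export
fit_snp_blup <- function(y, panel, lambda = NULL) {
  Z <- panel$alleles
  if (!is.null(names(y))) {
    if (!all(rownames(Z) %in% names(y))) {
      stop("named y must cover every panel accession", call. = FALSE)
    }
    y <- y[rownames(Z)]
  }
  if (anyNA(y)) {
    keep <- !is.na(y)
    warning(sprintf("dropping %d accession(s) with missing phenotype",
                    sum(!keep)))
    y <- y[keep]
    Z <- Z[keep, , drop = FALSE]
  }
  if (is.null(lambda) && length(y) < 10L) {
    stop("need at least 10 accessions to estimate variance components",
         call. = FALSE)
  }
  engine <- gwa_engine(Z)
  fit <- fit_ridge_engine(engine, as.numeric(y), lambda = lambda)
  fit$u_hat <- stats::setNames(fit$u_hat, engine$snp_ids)
  fit$engine <- engine
  fit$y <- as.numeric(y)
  structure(fit, class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("SNP-BLUP ridge fit: %d SNPs, lambda = %.4g (sigma_u2 = %.4g, sigma_e2 = %.4g)\n",
              length(x$u_hat), x$lambda, x$sigma_u2, x$sigma_e2))
  invisible(x)
}

#' Heteroscedastic-effects (HEM) update of a ridge fit
#'
#' Second-stage re-weighting that gives each SNP its own shrinkage: from
#' the first-stage fit, per-SNP hat values
#' `h_j = diag((Z'Z + lambda I)^{-1} Z'Z)` (computed in the dual) yield
#' deflated effect variances `w_j = u_hat_j^2 / (1 - h_j)`, i.e. SNP-
#' specific penalties `lambda_j = sigma_e2 / w_j`; one weighted re-solve
#' through the dual `Z W Z' + sigma_e2 I` gives the heteroscedastic
#' effects. SNPs with a zero first-stage effect keep a zero HEM effect.
#' A single pass is performed (no iteration).
#'
#' @param fit A `ridge_fit` from [fit_snp_blup()].
#' @return Object of class `hem_result`: `u_hem` (named), `h` (hat
#'   values), `w`, plus the first-stage `lambda`, `sigma_u2`, `sigma_e2`.
#'   Threshold fields (`tau`, `q`, `B`) are filled by
#'   [permutation_threshold()] / [run_gwa()].
#' @export
hem_update <- function(fit) {
  stopifnot(inherits(fit, "ridge_fit"))
  hem <- hem_engine(fit$engine, fit, fit$y)
  structure(list(
    u_hem = stats::setNames(hem$u_hem, names(fit$u_hat)),
    h = stats::setNames(hem$h, names(fit$u_hat)),
    w = stats::setNames(hem$w, names(fit$u_hat)),
    lambda = fit$lambda, sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2,
    mu = fit$mu,
    tau = NA_real_, q = NA_real_, B = NA_integer_,
    sig_calls = NULL
  ), class = "hem_result")
}

#' @export
print.hem_result <- function(x, ...) {
  cat(sprintf("HEM result: %d SNPs, max |effect| = %.4g", length(x$u_hem),
              max(abs(x$u_hem))))
  if (!is.na(x$tau)) {
    cat(sprintf("; tau = %.4g (q = %.3g, B = %d): %d significant",
                x$tau, x$q, x$B, sum(x$sig_calls)))
  }
  cat("\n")
  invisible(x)
}

run_hem_pipeline <- function(engine, y) {
  fit <- fit_ridge_engine(engine, y)
  hem_engine(engine, fit, y)$u_hem
}

#' Permutation significance threshold for HEM effects
#'
#' Shuffles the accession trait means against the genotype rows `B` times,
#' re-runs the *full* pipeline (REML variance components, BLUP, HEM) on
#' each permuted vector, pools the absolute HEM effects across all SNPs
#' and all permutations, and returns their `q`-quantile as the
#' significance threshold `tau`. Variance components are re-estimated
#' within every permutation so the threshold reflects the null behaviour
#' of the whole estimator. `pool = "per_perm_max"` instead takes the
#' `q`-quantile of the per-permutation maxima (a family-wise style
#' threshold).
#'
#' @param y Accession trait vector.
#' @param panel A [genotype_panel()].
#' @param q Quantile level (default 0.99).
#' @param B Number of permutations (1000 for production; smaller values
#'   are fine for tests).
#' @param seed Integer seed; fixed seed gives an identical threshold.
#' @param pool `"pooled"` (default) or `"per_perm_max"`.
#' @param engine Internal: a precomputed engine to reuse.
#' @return List of class `perm_threshold`: `tau`, `q`, `B`, `seed`,
#'   `pool`, `degenerate` (TRUE when `y` is constant, in which case
#'   `tau = 0`).
#' @export
permutation_threshold <- function(y, panel, q = 0.99, B = 1000L,
                                  seed = 1L, pool = c("pooled",
                                                      "per_perm_max"),
                                  engine = NULL) {
  pool <- match.arg(pool)
  stopifnot(q > 0, q <= 1, B >= 1)
  y <- as.numeric(y)
  if (stats::sd(y) == 0) {
    return(structure(list(tau = 0, q = q, B = as.integer(B),
                          seed = as.integer(seed), pool = pool,
                          degenerate = TRUE),
                     class = "perm_threshold"))
  }
  if (is.null(engine)) engine <- gwa_engine(panel$alleles)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  stat <- numeric(0)
  if (pool == "pooled") {
    pooled <- vector("list", B)
    for (b in seq_len(B)) {
      pooled[[b]] <- abs(run_hem_pipeline(engine, sample(y)))
    }
    stat <- unlist(pooled, use.names = FALSE)
  } else {
    stat <- vapply(seq_len(B),
                   function(b) max(abs(run_hem_pipeline(engine, sample(y)))),
                   numeric(1))
  }
  tau <- as.numeric(stats::quantile(stat, q, names = FALSE, type = 7))
  structure(list(tau = tau, q = q, B = as.integer(B),
                 seed = as.integer(seed), pool = pool, degenerate = FALSE),
            class = "perm_threshold")
}
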