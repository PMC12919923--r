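#' @include simulate-traits.R
NULL

## Exact per-variant simple linear regression after residualizing trait and
## genotypes on the covariate design (Frisch-Waugh), vectorized over
## variants.
.gwasLinear <- function(G, y, covariates) {
  n <- length(y)
  if (is.null(covariates)) {
    ry <- y - mean(y)
    mu <- colMeans(G)
    Sgg <- drop(crossprod(G^2, rep(1, n))) - n * mu^2
    Sgy <- drop(crossprod(G, ry)) - mu * sum(ry)
    p <- 1L
  } else {
    X0 <- cbind(1, as.matrix(covariates))
    q <- qr(X0)
    ry <- qr.resid(q, y)
    rg <- qr.resid(q, G)
    Sgg <- colSums(rg^2)
    Sgy <- colSums(rg * ry)
    p <- ncol(X0)
  }
  beta <- Sgy / Sgg
  df <- n - p - 1L
  sigma2 <- pmax(sum(ry^2) - beta^2 * Sgg, 0) / df
  se <- sqrt(sigma2 / Sgg)
  list(beta = beta, se = se)
}

## Exact per-variant logistic regression (intercept + genotype), all
## variants fitted simultaneously by batched Newton-Raphson on the
## per-variant 2x2 Fisher information.
.gwasLogisticBatch <- function(G, y, maxit = 25, tol = 1e-8) {
  n <- length(y)
  J <- ncol(G)
  G2 <- G * G
  ones <- rep(1, n)
  a <- rep(stats::qlogis(mean(y)), J)
  b <- rep(0, J)
  for (it in seq_len(maxit)) {
    eta <- G * rep(b, each = n) + rep(a, each = n)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    r <- y - mu                     # y recycled column-wise
    U1 <- drop(crossprod(r, ones))
    U2 <- colSums(r * G)
    I11 <- drop(crossprod(w, ones))
    I12 <- colSums(w * G)
    I22 <- colSums(w * G2)
    det <- I11 * I22 - I12^2
    da <- (I22 * U1 - I12 * U2) / det
    db <- (I11 * U2 - I12 * U1) / det
    a <- a + da
    b <- b + db
    if (max(abs(da), abs(db)) < tol) break
  }
  list(beta = b, se = sqrt(I11 / det))
}

#' Per-variant association summary statistics
#'
#' Runs a single-variant regression of the trait on each genotype column
#' (linear for continuous traits, logistic for binary), with optional
#' covariate adjustment, and returns GWAS-SSF-like summary statistics.
#' Monomorphic variants are flagged and skipped. The no-covariate logistic
#' path fits all variants simultaneously by batched Newton-Raphson (exact,
#' it matches `glm`); with covariates each variant is fitted by `glm.fit`.
#' P-values are two-sided normal.
#'
#' @param genotypes individuals-by-variants matrix (0/1/2).
#' @param trait numeric trait vector (0/1 for binary).
#' @param panel variant panel giving positions and alleles.
#' @param type `"continuous"` or `"binary"`.
#' @param covariates optional numeric matrix/data.frame of adjustment
#'   covariates.
#' @param traitName trait label stored on the result.
#' @param chunkSize variants per batch (memory control).
#' @return a [GwasSumstats-class]; skipped variant ids are in
#'   `attr(, "skipped")`.
#' @export
computeSummaryStats <- function(genotypes, trait, panel,
                                type = c("continuous", "binary"),
                                covariates = NULL, traitName = "trait",
                                chunkSize = 200L) {
  type <- match.arg(type)
  .stopIfNot(nrow(genotypes) == length(trait),
             "one trait value per individual is required")
  if (type == "binary") {
    .stopIfNot(all(trait %in% c(0, 1)), "binary trait must be coded 0/1")
  }
  G <- genotypes
  storage.mode(G) <- "double"
  J <- ncol(G)
  poly <- (colMeans(G^2) - colMeans(G)^2) > 1e-10
  skipped <- colnames(G)[!poly]
  if (length(skipped)) {
    message(sprintf("skipping %d monomorphic variant(s)", length(skipped)))
  }
  beta <- se <- rep(NA_real_, J)
  use <- which(poly)
  if (type == "continuous") {
    for (start in seq(1L, length(use), by = chunkSize)) {
      idx <- use[start:min(start + chunkSize - 1L, length(use))]
      fit <- .gwasLinear(G[, idx, drop = FALSE], trait, covariates)
      beta[idx] <- fit$beta
      se[idx] <- fit$se
    }
  } else if (is.null(covariates)) {
    for (start in seq(1L, length(use), by = chunkSize)) {
      idx <- use[start:min(start + chunkSize - 1L, length(use))]
      fit <- .gwasLogisticBatch(G[, idx, drop = FALSE], trait)
      beta[idx] <- fit$beta
      se[idx] <- fit$se
    }
  } else {
    X0 <- cbind(1, as.matrix(covariates))
    for (j in use) {
      fit <- stats::glm.fit(cbind(X0, G[, j]), trait,
                            family = stats::binomial())
      k <- ncol(X0) + 1L
      cov <- chol2inv(chol(crossprod(
        qr.R(fit$qr)[seq_len(k), seq_len(k), drop = FALSE])))
      beta[j] <- fit$coefficients[k]
      se[j] <- sqrt(cov[k, k])
    }
  }
  eaf <- colMeans(G) / 2
  keep <- poly & !is.na(beta)
  df <- data.frame(
    variant_id = panel$variant_id,
    chromosome = panel$chromosome,
    base_pair_location = panel$base_pair_location,
    effect_allele = panel$effect_allele,
    other_allele = panel$other_allele,
    effect_allele_frequency = eaf,
    beta = beta, standard_error = se,
    p_value = .z2p(beta / se),
    n = length(trait), stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(df) <- NULL
  out <- new("GwasSumstats", data = df, trait = traitName)
  attr(out, "skipped") <- skipped
  out
}
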