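#' IBS kinship matrix
#'
#' Pairwise identity-by-state sharing: the mean over non-missing markers of
#' an allele-sharing score that is 1 for identical genotypes, 0.5 when one
#' allele is shared and 0 for opposite homozygotes.
#'
#' @param panel a [GenotypePanel-class] with at least two individuals.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
ibsKinship <- function(panel) {
  n <- nIndividuals(panel)
  if (n < 2L) stop("need at least two individuals")
  a1 <- panel@a1; a2 <- panel@a2
  if (any(rowSums(!is.na(a1) & !is.na(a2)) == 0L))
    stop("individual with all-missing genotypes")
  ids <- individualIds(panel)
  K <- diag(1, n)
  dimnames(K) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(a1[i, ]) & !is.na(a2[i, ]) &
            !is.na(a1[j, ]) & !is.na(a2[j, ])
      if (!any(ok)) stop("no shared non-missing markers for pair ",
                         ids[i], "/", ids[j])
      s <- sharingScore(a1[i, ok], a2[i, ok], a1[j, ok], a2[j, ok])
      K[i, j] <- K[j, i] <- mean(s)
    }
  }
  K
}

# per-marker allele-sharing score between two unordered genotypes
sharingScore <- function(x1, x2, y1, y2) {
  # sort so genotype comparison is order-free
  xl <- pmin(x1, x2); xh <- pmax(x1, x2)
  yl <- pmin(y1, y2); yh <- pmax(y1, y2)
  same <- xl == yl & xh == yh
  shareOne <- !same & (xl == yl | xl == yh | xh == yl | xh == yh)
  ifelse(same, 1, ifelse(shareOne, 0.5, 0))
}

#' REML variance components under the null model
#'
#' Single-variance-component model `y = X beta + u + e`,
#' `u ~ N(0, sigma_g^2 K)`, fitted by spectral decomposition of `K`
#' (ridged by 1e-6 for positive-definiteness) and one-dimensional
#' optimization of the restricted log-likelihood in `log(delta)` over
#' `[-10, 10]`, where `delta = sigma_e^2 / sigma_g^2`.
#'
#' @param y phenotype vector.
#' @param X fixed-effect design matrix (including intercept); `NULL` for
#'   intercept only.
#' @param K kinship matrix.
#' @param ridge diagonal ridge added to `K` before decomposition.
#' @return list: `sigmaG2`, `sigmaE2`, `delta`, `logLik`, `flag`
#'   (`"ok"`, `"no genetic variance"` when `delta` hits the upper
#'   boundary, or `"unidentifiable"` when `K` is a scaled identity) and
#'   the eigendecomposition (`eigen`) for reuse by [glsScan()].
#' @export
remlNull <- function(y, X, K, ridge = 1e-6) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  p <- ncol(X)
  if (n <= p) stop("more fixed effects than observations")
  K <- (K + t(K)) / 2 + diag(ridge, n)
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors; d <- pmax(eg$values, 0)
  yt <- crossprod(U, y); Xt <- crossprod(U, X)
  ldXX <- determinant(crossprod(X), logarithm = TRUE)$modulus

  restrLL <- function(logDelta) {
    w <- d + exp(logDelta)
    Xw <- Xt / w
    XtWX <- crossprod(Xt, Xw)
    b <- solve(XtWX, crossprod(Xw, yt))
    r <- yt - Xt %*% b
    rssW <- sum(r^2 / w)
    sg2 <- rssW / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * sg2) + 1) + sum(log(w)) +
              determinant(XtWX, logarithm = TRUE)$modulus - ldXX)
  }
  unident <- (max(d) - min(d)) < 1e-8
  opt <- stats::optimize(restrLL, c(-10, 10), maximum = TRUE, tol = 1e-6)
  if (!is.finite(opt$objective)) stop("non-finite REML likelihood")
  delta <- exp(opt$maximum)
  w <- d + delta
  Xw <- Xt / w
  b <- solve(crossprod(Xt, Xw), crossprod(Xw, yt))
  sg2 <- sum((yt - Xt %*% b)^2 / w) / (n - p)
  flag <- if (unident) "unidentifiable"
          else if (opt$maximum > 10 - 1e-3) "no genetic variance"
          else "ok"
  list(sigmaG2 = sg2, sigmaE2 = delta * sg2, delta = delta,
       logLik = opt$objective, flag = flag, eigen = eg)
}

#' Kinship-adjusted association scan (generalized least squares)
#'
#' Tests each dosage column against the phenotype with the covariance
#' `sigma_g^2 K + sigma_e^2 I` held fixed at the null-model REML estimates
#' (the EMMAX approximation: variance components are not re-estimated per
#' marker).  Reports effect, SE, 1-df F and its p-value.  Individuals with
#' a missing dosage are dropped listwise for that unit; monomorphic or
#' collinear units are flagged with `p = 1` / `NA`.
#'
#' @param dosage numeric matrix, individuals x units (markers or haplotype
#'   windows); column names label the units.
#' @param y phenotype vector.
#' @param X fixed-effect design (with intercept); `NULL` for intercept
#'   only.
#' @param K kinship matrix.
#' @param vc output of [remlNull()] on the same `(y, X, K)`.
#' @param conditionOn optional dosage vector appended to `X`
#'   (conditional analysis).
#' @return data.frame: `unit`, `effect`, `se`, `F`, `p`, `n`, `flag`.
#' @export
glsScan <- function(dosage, y, X, K, vc, conditionOn = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  if (!is.null(conditionOn)) X <- cbind(X, condition = conditionOn)
  dosage <- as.matrix(dosage)
  units <- colnames(dosage)
  if (is.null(units)) units <- paste0("u", seq_len(ncol(dosage)))
  V <- vc$sigmaG2 * (K + t(K)) / 2 + diag(vc$sigmaE2, n)

  res <- vector("list", ncol(dosage))
  for (j in seq_len(ncol(dosage))) {
    g <- dosage[, j]
    use <- !is.na(g) & !is.na(y)
    nn <- sum(use)
    gk <- g[use]
    if (stats::var(gk) < 1e-12) {
      res[[j]] <- data.frame(unit = units[j], effect = NA_real_,
                             se = NA_real_, F = 0, p = 1, n = nn,
                             flag = "monomorphic")
      next
    }
    # whiten with the (sub)covariance and run OLS on the transforms
    L <- chol(V[use, use])
    ys <- backsolve(L, y[use], transpose = TRUE)
    Xs <- backsolve(L, X[use, , drop = FALSE], transpose = TRUE)
    gs <- backsolve(L, gk, transpose = TRUE)
    qrX <- qr(Xs)
    rg <- qr.resid(qrX, gs)
    ry <- qr.resid(qrX, ys)
    spp <- sum(rg^2)
    k <- qrX$rank
    df <- nn - k - 1L
    if (spp < 1e-10 || df < 1L) {
      res[[j]] <- data.frame(unit = units[j], effect = NA_real_,
                             se = NA_real_, F = NA_real_, p = NA_real_,
                             n = nn, flag = "collinear")
      next
    }
    alpha <- sum(rg * ry) / spp
    rss1 <- sum(ry^2) - alpha^2 * spp
    s2 <- rss1 / df
    se <- sqrt(s2 / spp)
    Fst <- (alpha / se)^2
    res[[j]] <- data.frame(unit = units[j], effect = alpha, se = se,
                           F = Fst,
                           p = stats::pf(Fst, 1, df, lower.tail = FALSE),
                           n = nn, flag = "ok")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Deterministic marker thinning
#'
#' Keeps markers whose 0-based index is congruent to one of `offsets`
#' modulo `keepEvery` (e.g. every ninth SNP, or the first and fifth of
#' every nine), merged and sorted.
#'
#' @param map a [MarkerMap-class].
#' @param keepEvery modulus (>= 1).
#' @param offsets 0-based offsets, all `< keepEvery`.
#' @return sorted integer vector of 1-based marker indices.
#' @export
thinMarkers <- function(map, keepEvery, offsets = 0L) {
  m <- nMarkers(map)
  if (m == 0L) stop("empty marker map")
  stopifnot(keepEvery >= 1L, all(offsets >= 0L), all(offsets < keepEvery))
  idx0 <- seq_len(m) - 1L
  sort(unique(unlist(lapply(offsets, function(o)
    which(idx0 %% keepEvery == o)))))
}

#' Sliding-window risk-haplotype dosages
#'
#' Labels each phased haplotype Q in a window iff it matches the Q
#' reference at every non-missing thinned SNP of the window; the
#' individual dosage is the number of Q-labelled haplotypes (0/1/2).
#' Windows advance by `slide` thinned SNPs; windows in which more than
#' half the reference is missing are dropped (with a message).
#'
#' @param panel a phased [GenotypePanel-class].
#' @param qReference the Q-haplotype allele vector over the full map
#'   (`NA` where undefined).
#' @param thinned indices from [thinMarkers()].
#' @param windowSnps SNPs per window (default 20, ~1 Mb at 50-kb spacing).
#' @param slide window advance in SNPs (default 10).
#' @return numeric matrix, individuals x windows; column names give the
#'   window's first thinned SNP, and attribute `windowBp` the bp range.
#' @export
qHaplotypeWindows <- function(panel, qReference, thinned,
                              windowSnps = 20L, slide = 10L) {
  if (!panel@phased) stop("panel must be phased")
  stopifnot(length(qReference) == nMarkers(panel))
  q <- qReference[thinned]
  h1 <- panel@a1[, thinned, drop = FALSE]
  h2 <- panel@a2[, thinned, drop = FALSE]
  starts <- seq(1L, max(1L, length(thinned) - windowSnps + 1L), by = slide)
  dos <- matrix(NA_real_, nrow(h1), 0)
  bps <- NULL
  kept <- integer(0)
  pos <- markerPos(panel@map)[thinned]
  for (s in starts) {
    idx <- s:min(s + windowSnps - 1L, length(thinned))
    if (mean(is.na(q[idx])) > 0.5) {
      message(sprintf("window at thinned SNP %d dropped: >50%% reference missing", s))
      next
    }
    use <- idx[!is.na(q[idx])]
    m1 <- rowSums(h1[, use, drop = FALSE] !=
                    matrix(q[use], nrow(h1), length(use), byrow = TRUE),
                  na.rm = TRUE) == 0
    m2 <- rowSums(h2[, use, drop = FALSE] !=
                    matrix(q[use], nrow(h2), length(use), byrow = TRUE),
                  na.rm = TRUE) == 0
    dos <- cbind(dos, as.numeric(m1) + as.numeric(m2))
    bps <- rbind(bps, c(pos[idx[1]], pos[idx[length(idx)]]))
    kept <- c(kept, s)
  }
  colnames(dos) <- paste0("w", kept)
  rownames(dos) <- individualIds(panel)
  attr(dos, "windowBp") <- bps
  dos
}

#' Allele concordance between two genotype sets
#'
#' Genotypes are compared as allele multisets per individual over the
#' individuals present with non-missing calls in both sets;
#' concordance = `100 * (1 - mismatches / total)` with
#' `total = 2 x` compared individuals.
#'
#' @param a1,a2 alleles of the first call set (vectors named by
#'   individual, or a 2-column matrix).
#' @param b1,b2 alleles of the second call set.
#' @return list: `concordance` (percent), `mismatches`, `total`.
#' @export
concordance <- function(a1, a2, b1, b2) {
  idsA <- names(a1); idsB <- names(b1)
  if (is.null(idsA)) idsA <- as.character(seq_along(a1))
  if (is.null(idsB)) idsB <- as.character(seq_along(b1))
  common <- intersect(idsA, idsB)
  if (!length(common)) stop("disjoint individual sets")
  ia <- match(common, idsA); ib <- match(common, idsB)
  ok <- !is.na(a1[ia]) & !is.na(a2[ia]) & !is.na(b1[ib]) & !is.na(b2[ib])
  ia <- ia[ok]; ib <- ib[ok]
  mm <- mapply(function(x1, x2, y1, y2) {
    # multiset mismatch count between {x1,x2} and {y1,y2}
    2L - max((x1 == y1) + (x2 == y2), (x1 == y2) + (x2 == y1))
  }, a1[ia], a2[ia], b1[ib], b2[ib])
  total <- 2L * length(ia)
  list(concordance = 100 * (1 - sum(mm) / total),
       mismatches = as.integer(sum(mm)), total = as.integer(total))
}
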