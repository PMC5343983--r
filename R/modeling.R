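#' Log-transform and autoscale VOC intensities
#'
#' Applies `log2(x + 1)` followed by per-VOC autoscaling (mean 0, SD 1
#' across samples). When `params` is supplied (e.g. frozen from a training
#' set) its means and SDs are used instead of freshly computed ones, so
#' held-out samples are standardized on the training scale. A VOC constant
#' across the (training) samples gets SD 1 so its standardized values stay
#' finite.
#'
#' @param x a [VOCExperiment-class] or a VOC x sample intensity matrix.
#' @param vocIds optional subset of VOC ids to keep (default all rows).
#' @param params optional list with `center` and `scale` (named per VOC).
#' @return List: `x` (samples x VOC standardized matrix) and `params`
#'   (list of `center`, `scale` on the log2 scale).
#' @export
preprocessIntensities <- function(x, vocIds = NULL, params = NULL) {
    mat <- if (is(x, "VOCExperiment")) assay(x, "intensity") else as.matrix(x)
    if (any(mat < 0)) stop("intensities must be non-negative")
    if (!is.null(vocIds)) {
        missing_ <- setdiff(vocIds, rownames(mat))
        if (length(missing_))
            stop("VOC ids not present: ", paste(missing_, collapse = ", "))
        mat <- mat[vocIds, , drop = FALSE]
    }
    lg <- t(log2(mat + 1))                      # samples x VOCs
    if (is.null(params)) {
        ctr <- colMeans(lg)
        scl <- apply(lg, 2, stats::sd)
        scl[!is.finite(scl) | scl == 0] <- 1
        params <- list(center = ctr, scale = scl)
    } else {
        if (!all(colnames(lg) %in% names(params$center)))
            stop("preprocessing parameters do not cover all VOCs")
        params <- list(center = params$center[colnames(lg)],
                       scale = params$scale[colnames(lg)])
    }
    std <- sweep(sweep(lg, 2, params$center), 2, params$scale, "/")
    list(x = std, params = params)
}

#' Principal component analysis of standardized breath profiles
#'
#' SVD-based PCA of a samples x VOC standardized matrix (typically the
#' gate-selected VOCs). The variance explained per component is the
#' squared singular value over the total; when case/control labels are
#' supplied, each component's scores are compared between the groups with
#' a two-sided Wilcoxon rank-sum test.
#'
#' @param x standardized samples x VOC matrix (see
#'   [preprocessIntensities()]).
#' @param isCase optional logical vector (`TRUE` = case) per sample.
#' @return List with `scores` (samples x component), `loadings`
#'   (VOC x component, orthonormal columns), `varExplained` (fraction per
#'   component, non-increasing) and `componentP` (per-component Wilcoxon
#'   p-value, or `NULL`).
#' @export
pcaBreath <- function(x, isCase = NULL) {
    x <- as.matrix(x)
    if (nrow(x) < 2 || ncol(x) < 1)
        stop("PCA needs at least 2 samples and 1 VOC")
    xc <- scale(x, center = TRUE, scale = FALSE)
    if (all(abs(xc) < 1e-12)) stop("matrix has rank 0 after centering")
    sv <- svd(xc)
    keep <- sv$d > sv$d[1] * 1e-12
    scores <- sv$u[, keep, drop = FALSE] *
        rep(sv$d[keep], each = nrow(x))
    loadings <- sv$v[, keep, drop = FALSE]
    dimnames(scores) <- list(rownames(x),
                             paste0("PC", seq_len(sum(keep))))
    dimnames(loadings) <- list(colnames(x), colnames(scores))
    varExplained <- sv$d^2 / sum(sv$d^2)
    componentP <- NULL
    if (!is.null(isCase)) {
        componentP <- apply(scores, 2, function(s)
            wilcoxonP(s[isCase], s[!isCase]))
    }
    list(scores = scores, loadings = loadings,
         varExplained = varExplained[keep], componentP = componentP)
}

#' Fit a PLS-DA classifier (NIPALS PLS1)
#'
#' Regresses the centered 0/1 class code on a standardized VOC matrix by
#' NIPALS partial least squares with per-component deflation. For a
#' univariate response each component is: weight
#' `w = X'f / ||X'f||`, score `t = Xw`, X-loading `p = X't / t't`,
#' y-loading `q = f't / t't`, then `X <- X - tp'` and `f <- f - qt`. The
#' regression coefficients are `B = W (P'W)^-1 q`. Components whose score
#' variance is numerically zero are dropped, so the effective number of
#' components never exceeds the matrix rank.
#'
#' @param x standardized samples x VOC matrix with sample ids as rownames
#'   (from [preprocessIntensities()]).
#' @param y binary labels: logical, 0/1 numeric, or 2-level factor
#'   (second level = case).
#' @param nComponents maximum number of latent components (default 2).
#' @param params the preprocessing parameters used to build `x`, stored in
#'   the fit so new samples can be standardized identically.
#' @return A [PLSDAFit-class].
#' @export
plsdaFit <- function(x, y, nComponents = 2L, params = NULL) {
    x <- as.matrix(x)
    if (is.null(colnames(x)))
        colnames(x) <- sprintf("X%d", seq_len(ncol(x)))
    y <- if (is.factor(y)) as.numeric(y) - 1 else as.numeric(y)
    if (length(unique(y)) < 2)
        stop("both classes must be present in 'y'")
    if (!all(y %in% c(0, 1))) stop("'y' must be a binary 0/1 code")
    if (nrow(x) != length(y)) stop("'x' rows and 'y' length differ")
    yMean <- mean(y)
    E <- x
    f <- y - yMean
    A <- min(as.integer(nComponents), nrow(x) - 1L, ncol(x))
    W <- P <- matrix(0, ncol(x), A)
    Q <- numeric(A)
    Tmat <- matrix(0, nrow(x), A)
    a <- 0L
    for (k in seq_len(A)) {
        w <- drop(crossprod(E, f))
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12) break
        w <- w / nw
        t_ <- drop(E %*% w)
        tt <- sum(t_^2)
        if (tt < 1e-12) break
        p <- drop(crossprod(E, t_)) / tt
        q <- sum(f * t_) / tt
        E <- E - tcrossprod(t_, p)
        f <- f - q * t_
        a <- k
        W[, k] <- w; P[, k] <- p; Q[k] <- q; Tmat[, k] <- t_
    }
    if (a == 0L) stop("no informative PLS component could be extracted")
    W <- W[, seq_len(a), drop = FALSE]
    P <- P[, seq_len(a), drop = FALSE]
    Q <- Q[seq_len(a)]
    Tmat <- Tmat[, seq_len(a), drop = FALSE]
    coef <- drop(W %*% solve(crossprod(P, W), Q))
    ctr <- if (is.null(params)) setNames(numeric(ncol(x)), colnames(x))
           else params$center
    scl <- if (is.null(params)) setNames(rep(1, ncol(x)), colnames(x))
           else params$scale
    new("PLSDAFit", vocIds = colnames(x), weights = W, loadings = P,
        yLoadings = Q, coefficients = setNames(coef, colnames(x)),
        yMean = yMean, center = ctr, scale = scl,
        trainingScores = Tmat,
        trainingIds = if (is.null(rownames(x))) character() else rownames(x))
}

#' Predicted probability of disease from a PLS-DA fit
#'
#' Standardizes new samples with the preprocessing parameters stored in
#' the fit (training means and SDs of `log2(x + 1)`), applies the PLS
#' regression, and clamps the linear prediction to `[0, 1]`, reported as
#' the predicted probability for the case class. A sample at the training
#' feature mean therefore receives the training prevalence.
#'
#' @param fit a [PLSDAFit-class].
#' @param newdata a [VOCExperiment-class] or raw VOC x sample intensity
#'   matrix covering all of the fit's VOCs, **or** an already-standardized
#'   samples x VOC matrix if `standardized = TRUE`.
#' @param standardized set `TRUE` when `newdata` is already on the fit's
#'   standardized scale.
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @export
plsdaPredict <- function(fit, newdata, standardized = FALSE) {
    stopifnot(is(fit, "PLSDAFit"))
    if (standardized) {
        xs <- as.matrix(newdata)
        if (!all(fit@vocIds %in% colnames(xs)))
            stop("newdata does not cover the fit's VOC set")
        xs <- xs[, fit@vocIds, drop = FALSE]
    } else {
        mat <- if (is(newdata, "VOCExperiment")) assay(newdata, "intensity")
               else as.matrix(newdata)
        if (!all(fit@vocIds %in% rownames(mat)))
            stop("newdata does not cover the fit's VOC set")
        xs <- preprocessIntensities(mat, fit@vocIds,
                                    params = list(center = fit@center,
                                                  scale = fit@scale))$x
    }
    yhat <- fit@yMean + drop(xs %*% fit@coefficients)
    pmin(pmax(yhat, 0), 1)
}
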