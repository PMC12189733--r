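# NIPALS PLS-DA and VIP scoring.
#
# Y is the column-centered one-hot group indicator matrix. Per component:
# alternate w ∝ X'u (normalized), t = Xw, q ∝ Y't, u ∝ Yq until the score
# vector stabilizes; record the drop in ||Y||^2 achieved by deflation as
# that component's explained Y sum of squares; deflate X by t p'
# (p = X't / t't) and Y by t q'. This alternation is a power iteration on
# (X'Y)(X'Y)', so component-1 weights converge to the dominant left
# singular direction of X'Y -- the independent oracle used in the tests.

#' Fit a PLS-DA model by NIPALS
#'
#' @param x numeric matrix, samples x variables, already preprocessed
#'   (see \code{\link{preprocessFeatures}}).
#' @param groups character/factor of group labels, one per row of
#'   \code{x}; at least two distinct groups.
#' @param nComponents number of latent components, at most
#'   \code{min(nrow(x) - 1, ncol(x))}.
#' @param tol convergence tolerance on the relative change of the score
#'   vector between iterations.
#' @param maxIter iteration cap per component; exceeding it is an error
#'   reporting the component and the residual (NIPALS converges slowly
#'   when the leading singular values of the deflated X'Y nearly tie).
#' @return a \linkS4class{PlsdaModel}. The sign of each component is fixed
#'   by requiring the largest-magnitude weight entry to be positive, so
#'   fits are deterministic.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(48), 12, 4)
#' x[1:6, 1] <- x[1:6, 1] + 3
#' m <- fitPlsda(x, rep(c("control", "challenge"), each = 6), 2)
#' computeVip(m)
#' @seealso \code{\link{computeVip}}, \code{\link{projectPlsda}}
#' @export
fitPlsda <- function(x, groups, nComponents = 2L, tol = 1e-10,
                     maxIter = 500L) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  if (length(groups) != nrow(x))
    validationError("groups: expected %d labels, got %d", nrow(x),
                    length(groups))
  classes <- unique(groups)
  if (length(classes) < 2L)
    validationError("PLS-DA requires at least 2 distinct groups, got %d",
                    length(classes))
  A <- as.integer(nComponents)
  Amax <- min(nrow(x) - 1L, ncol(x))
  if (A < 1L || A > Amax)
    validationError("nComponents must be in [1, %d], got %d", Amax, A)

  Y <- 1 * outer(groups, classes, "==")
  colnames(Y) <- classes
  yCenter <- colMeans(Y)
  Y <- sweep(Y, 2L, yCenter, "-")

  n <- nrow(x); p <- ncol(x); g <- length(classes)
  Tm <- matrix(0, n, A); W <- matrix(0, p, A)
  P <- matrix(0, p, A); Q <- matrix(0, g, A)
  ssy <- numeric(A)
  Xa <- x; Ya <- Y

  for (a in seq_len(A)) {
    u <- Ya[, which.max(apply(Ya, 2L, stats::var))]
    if (sum(u^2) < .Machine$double.eps)
      stop(sprintf("degenerate fit: no Y variation left at component %d", a))
    tOld <- rep(0, n)
    converged <- FALSE
    delta <- NA_real_
    for (iter in seq_len(maxIter)) {
      w <- crossprod(Xa, u)[, 1L]
      wn <- sqrt(sum(w^2))
      if (wn < .Machine$double.eps)
        stop(sprintf("degenerate fit: zero covariance at component %d", a))
      w <- w / wn
      tt <- (Xa %*% w)[, 1L]
      q <- crossprod(Ya, tt)[, 1L] / sum(tt^2)
      u <- (Ya %*% q)[, 1L] / sum(q^2)
      delta <- sqrt(sum((tt - tOld)^2)) / max(sqrt(sum(tt^2)),
                                              .Machine$double.eps)
      if (delta < tol) { converged <- TRUE; break }
      tOld <- tt
    }
    if (!converged)
      stop(sprintf("NIPALS did not converge for component %d after %d iterations (residual %.3g)",
                   a, maxIter, delta))
    j <- which.max(abs(w))
    if (w[j] < 0) { w <- -w; tt <- -tt; q <- -q }
    pl <- crossprod(Xa, tt)[, 1L] / sum(tt^2)
    ssyBefore <- sum(Ya^2)
    Ya <- Ya - tcrossprod(tt, q)
    ssy[a] <- ssyBefore - sum(Ya^2)
    Xa <- Xa - tcrossprod(tt, pl)
    Tm[, a] <- tt; W[, a] <- w; P[, a] <- pl; Q[, a] <- q
  }

  comp <- paste0("comp", seq_len(A))
  dimnames(Tm) <- list(rownames(x), comp)
  dimnames(W) <- list(colnames(x), comp)
  dimnames(P) <- list(colnames(x), comp)
  dimnames(Q) <- list(classes, comp)
  names(ssy) <- comp
  model <- methods::new("PlsdaModel", scores = Tm, weights = W,
                        xLoadings = P, yLoadings = Q, explainedYSS = ssy,
                        classOrder = classes, yCenter = yCenter)
  methods::validObject(model)
  model
}

#' Variable importance in projection (VIP)
#'
#' Cumulative VIP over the A fitted components,
#' \deqn{VIP_j = \sqrt{p \, \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a},}
#' where p is the number of variables and SSY_a the Y sum of squares
#' captured by component a. Per-component VIP uses the single-term version
#' of the same formula (which reduces to \eqn{\sqrt{p}\,|w_{ja}|}). The
#' mean of the squared cumulative VIP over variables is exactly 1, so the
#' conventional gate VIP > 1 selects variables contributing more than
#' average.
#'
#' @param model a fitted \linkS4class{PlsdaModel}.
#' @return data.frame with one row per variable: \code{metabolite},
#'   \code{VIP} (cumulative) and \code{VIP1..VIPA} (per component).
#' @export
computeVip <- function(model) {
  stopifnot(methods::is(model, "PlsdaModel"))
  W <- plsdaWeights(model)
  ssy <- explainedYSS(model)
  if (sum(ssy) <= 0)
    stop("degenerate fit: total explained Y sum of squares is zero")
  p <- nrow(W)
  W2 <- W^2                                    # unit-norm columns
  vip <- sqrt(p * as.vector(W2 %*% ssy) / sum(ssy))
  perComp <- sqrt(p * W2)
  colnames(perComp) <- paste0("VIP", seq_len(ncol(W)))
  ids <- rownames(W) %||% paste0("V", seq_len(p))
  out <- data.frame(metabolite = ids, VIP = vip, perComp,
                    row.names = ids, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out
}

#' Project new samples onto a fitted PLS-DA model
#'
#' Uses the deflation-consistent projection \eqn{R = W (P'W)^{-1}},
#' \eqn{T_{new} = X_{new} R}. \code{xNew} must have been preprocessed with
#' the training parameters (\code{\link{applyPreprocess}}). Projecting the
#' training matrix reproduces the training scores.
#'
#' @param model a fitted \linkS4class{PlsdaModel}.
#' @param xNew numeric matrix, samples x variables (training variable
#'   order).
#' @return score matrix, samples x components.
#' @export
projectPlsda <- function(model, xNew) {
  stopifnot(methods::is(model, "PlsdaModel"))
  xNew <- as.matrix(xNew)
  W <- plsdaWeights(model); P <- plsdaLoadings(model)
  if (ncol(xNew) != nrow(W))
    validationError("xNew has %d variables, model expects %d",
                    ncol(xNew), nrow(W))
  R <- W %*% solve(crossprod(P, W))
  scores <- xNew %*% R
  colnames(scores) <- colnames(W)
  scores
}
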