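#' Fit a prewhitened GLM
#'
#' Two-pass estimation of the first-order autoregressive plus white noise
#' model: an ordinary least-squares fit yields residuals, the AR(1)
#' coefficient `phi` is the lag-1 residual autocorrelation pooled over all
#' series, data and design are whitened by the AR(1) filter (first row
#' scaled by `sqrt(1 - phi^2)`), and the model is refit.
#'
#' @param Y numeric vector or matrix, scans x series.
#' @param design a `design_matrix` from [build_design()], or a plain
#'   numeric matrix of regressors.
#' @return An object of class `glm_fit`: `beta` (regressors x series),
#'   `sigma2` (per series), `phi`, `dof`, `XtXinv` (of the whitened
#'   design), and `regressors`.
#' @export
fit_prewhitened <- function(Y, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("Y and design have different numbers of scans")
  if (n <= p + 2) stop("need n_scans > columns(X) + 2")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res0 <- qr.resid(qx, Y)
  num <- sum(res0[-1, , drop = FALSE] * res0[-n, , drop = FALSE])
  den <- sum(res0 * res0)
  phi <- if (den > 0) num / den else 0
  # correct the projection bias of residual autocorrelation: under white
  # noise E[num/den] = -tr(S H)/(n - p) for the lag-shift S and hat matrix
  # H, which is far from negligible with many smooth nuisance columns
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  tr_sh <- sum(Q[-1, , drop = FALSE] * Q[-n, , drop = FALSE])
  phi <- phi + tr_sh / (n - p)
  phi <- max(min(phi, 0.99), -0.99)
  whiten <- function(M) {
    W <- M[-1, , drop = FALSE] - phi * M[-n, , drop = FALSE]
    rbind(sqrt(1 - phi^2) * M[1, , drop = FALSE], W)
  }
  Xw <- whiten(X)
  Yw <- whiten(Y)
  qw <- qr(Xw)
  beta <- qr.coef(qw, Yw)
  resw <- qr.resid(qw, Yw)
  dof <- n - p
  sigma2 <- colSums(resw^2) / dof
  XtXinv <- solve(crossprod(Xw))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  beta <- as.matrix(beta)
  rownames(beta) <- colnames(X)
  structure(list(beta = beta, sigma2 = sigma2, phi = phi, dof = dof,
                 XtXinv = XtXinv, regressors = colnames(X),
                 residuals = resw),
            class = "glm_fit")
}

#' t contrast on a fitted GLM
#'
#' Tests the univariate linear combination `c'beta`; the variance uses the
#' whitened design, `t = c'beta / sqrt(sigma2 * c'(Xw'Xw)^-1 c)`, with a
#' two-tailed p at the fit's residual degrees of freedom.
#'
#' @param fit a `glm_fit`.
#' @param contrast numeric weight vector of length `ncol(X)`, or a named
#'   vector whose names match regressors (others zero).
#' @return data.frame, one row per series: `value`, `se`, `t`, `dof`, `p`.
#' @export
t_contrast <- function(fit, contrast) {
  p <- length(fit$regressors)
  if (!is.null(names(contrast))) {
    cv <- stats::setNames(numeric(p), fit$regressors)
    unknown <- setdiff(names(contrast), fit$regressors)
    if (length(unknown))
      stop("unknown regressor(s) in contrast: ",
           paste(unknown, collapse = ", "))
    cv[names(contrast)] <- contrast
    contrast <- cv
  }
  if (length(contrast) != p) stop("contrast length must equal ncol(X)")
  if (all(contrast == 0)) stop("contrast must not be all zero")
  value <- drop(crossprod(contrast, fit$beta))
  vfac <- drop(crossprod(contrast, fit$XtXinv %*% contrast))
  se <- sqrt(fit$sigma2 * vfac)
  tval <- value / se
  data.frame(value = value, se = se, t = tval, dof = fit$dof,
             p = 2 * stats::pt(-abs(tval), fit$dof))
}

#' Error-versus-control matched contrast
#'
#' In the default pooled mode each condition is one regressor and the
#' contrast is `(+1, -1)` on (`error`, `control`).  In per-pair (beta
#' series) mode -- models built with `matched_mode = "per_pair"` -- each
#' pair has its own regressor pair and the contrast averages the pairwise
#' differences (`+1/m, -1/m` weights).
#'
#' @param fit a `glm_fit` of a role model.
#' @return data.frame as [t_contrast()], with a `mode` column.
#' @export
matched_contrast <- function(fit) {
  rg <- fit$regressors
  if (all(c("error", "control") %in% rg)) {
    res <- t_contrast(fit, c(error = 1, control = -1))
    res$mode <- "pooled"
    return(res)
  }
  ei <- grep("^error_[0-9]+$", rg, value = TRUE)
  ci <- sub("^error", "control", ei)
  if (!length(ei) || !all(ci %in% rg))
    stop("fit has neither pooled nor per-pair error/control regressors")
  m <- length(ei)
  w <- c(stats::setNames(rep(1 / m, m), ei), stats::setNames(rep(-1 / m, m), ci))
  res <- t_contrast(fit, w)
  res$mode <- "per_pair"
  res
}
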