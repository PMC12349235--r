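#' Bayesian signal-space projection
#'
#' Interference suppression by constrained maximum-likelihood factor
#' analysis. The measurement model per sample is
#'
#'     y(t) = A x(t) + B u(t) + e(t)
#'
#' where `A` (channels x p) loads the cardiac signal factors `x(t)`,
#' `B` (channels x q) loads the interference factors `u(t)`, and `e`
#' is stationary noise uncorrelated across channels with diagonal
#' covariance `Psi`. `B` is learned by ordinary factor analysis of an
#' empty-room recording; `A` is then learned from the (averaged) MCG
#' data with the `B` block of the joint loading matrix `[A B]` held
#' fixed. Given both, the posterior factor means under the Gaussian
#' model yield the denoised signal component `y_S = A x_hat`.
#'
#' @name bssp
NULL

# EM for the factor model S ~ L L' + Psi on a sample covariance S.
# When B_fixed is supplied, L = [A B_fixed] and only the A block (p
# columns) and Psi are updated; the M-step is exact (weighted LS rows
# separate for diagonal Psi), so the observed-data log-likelihood is
# non-decreasing, up to the Psi floor that guards Heywood collapse.
fa_em <- function(S, p, B_fixed = NULL, n_obs = 1L,
                  tol = 1e-6, max_iter = 500L, psi_floor_frac = 1e-12) {
  d <- nrow(S)
  q <- if (is.null(B_fixed)) 0L else ncol(B_fixed)
  psi_floor <- psi_floor_frac * mean(diag(S))
  if (psi_floor <= 0) psi_floor <- .Machine$double.xmin

  loglik_of <- function(L, psi) {
    M <- tcrossprod(L) + diag(psi, d)
    cM <- chol(M)
    -0.5 * n_obs * (d * log(2 * pi) + 2 * sum(log(diag(cM))) +
                      sum(diag(chol2inv(cM) %*% S)))
  }

  if (p == 0L && q == 0L) {
    psi <- pmax(diag(S), psi_floor)
    return(list(loadings = matrix(0, d, 0), A = matrix(0, d, 0),
                psi = psi, loglik = loglik_of(matrix(0, d, 0), psi),
                loglik_trace = loglik_of(matrix(0, d, 0), psi),
                iterations = 0L, converged = TRUE))
  }

  # initialization: principal axes of (residual) covariance
  S_res <- if (q > 0L) S - tcrossprod(B_fixed) else S
  ev <- eigen((S_res + t(S_res)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values[seq_len(max(p, 1L))], 0)
  A <- if (p > 0L)
    ev$vectors[, seq_len(p), drop = FALSE] %*% diag(sqrt(lam[seq_len(p)]), p)
  else matrix(0, d, 0L)
  L <- cbind(A, B_fixed)
  psi <- pmax(diag(S) - rowSums(L^2), psi_floor)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M <- tcrossprod(L) + diag(psi, d)
    Minv <- chol2inv(chol(M))
    beta <- crossprod(L, Minv)                   # (p+q) x d
    Cyf <- S %*% t(beta)                          # d x (p+q)
    Cff <- diag(p + q) - beta %*% L + beta %*% Cyf
    if (p > 0L) {
      xs <- seq_len(p)
      if (q > 0L) {
        us <- p + seq_len(q)
        A <- (Cyf[, xs, drop = FALSE] -
                B_fixed %*% Cff[us, xs, drop = FALSE]) %*%
          solve(Cff[xs, xs, drop = FALSE])
      } else {
        A <- Cyf[, xs, drop = FALSE] %*% solve(Cff[xs, xs, drop = FALSE])
      }
    }
    L <- cbind(A, B_fixed)
    psi <- pmax(diag(S - Cyf %*% t(L) - L %*% t(Cyf) + L %*% Cff %*% t(L)),
                psi_floor)
    ll <- loglik_of(L, psi)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged)
    warnf("factor-analysis EM did not converge in %d iterations (rel change %.2e)",
          max_iter, abs(ll_trace[length(ll_trace)] - ll_old) / abs(ll_old))
  # sign convention: largest-magnitude entry of each column positive
  fix_sign <- function(Mx) {
    if (!ncol(Mx)) return(Mx)
    sgn <- apply(Mx, 2, function(v) sign(v[which.max(abs(v))]))
    sweep(Mx, 2, ifelse(sgn == 0, 1, sgn), "*")
  }
  list(loadings = L, A = fix_sign(A), psi = psi,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       iterations = it, converged = converged)
}

# centered channel covariance over the time axis of a channels x time matrix
channel_covariance <- function(Y) {
  Yc <- Y - rowMeans(Y)
  tcrossprod(Yc) / ncol(Y)
}

#' Choose the interference factor count by scree threshold
#'
#' Counts eigenvalues of the covariance exceeding twice the median
#' eigenvalue, capped (default 8) and at least 1.
#'
#' @param S covariance matrix.
#' @param cap maximum factor count (default 8).
#' @return integer factor count.
#' @export
scree_factor_count <- function(S, cap = 8L) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  max(1L, min(as.integer(cap), sum(ev > 2 * stats::median(ev))))
}

#' Choose the signal factor count by evoked-variance dominance
#'
#' R-synchronized averaging concentrates the phase-locked cardiac field
#' into a few dominant covariance components, orders of magnitude above
#' the residual noise. Components below `frac` of the leading
#' eigenvalue are residual noise by that standard and admitting them as
#' signal factors lets the projection reconstruct channel-correlated
#' noise, negating the denoising gain. The rule keeps eigenvalues
#' `>= frac * lambda_1`, with a floor of 1 and a cap (default 4).
#'
#' @param S covariance of the averaged waveform.
#' @param cap maximum signal factor count (default 4).
#' @param frac dominance threshold relative to the leading eigenvalue
#'   (default 0.01).
#' @return integer factor count.
#' @export
dominant_factor_count <- function(S, cap = 4L, frac = 0.01) {
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  max(1L, min(as.integer(cap), sum(ev >= frac * ev[1])))
}

#' Fit the interference spatial model from empty-room noise
#'
#' Maximum-likelihood factor analysis (EM) of the empty-room recording's
#' mcg-channel covariance: `Sigma_ern ~ B B' + Psi_ern`. The column
#' space of `B` captures the spatial signature of the environmental
#' interference reaching the recording array.
#'
#' `cov_scale` rescales the covariance before fitting; the pipeline
#' passes `1/n_epochs` so that `B` is on the scale of the R-averaged
#' waveform (averaging N independent noise epochs divides the noise
#' covariance by N).
#'
#' @param ern an empty-room [mcg_recording()] (mcg channels are used).
#' @param q interference factor count; NULL selects by
#'   [scree_factor_count()]. `q = 0` gives the degenerate diagonal model.
#' @param cov_scale multiplier applied to the sample covariance.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param exclude_transient drop flagged filter-transient edges.
#' @return an object of class `interference_model`: `B`, `psi_ern`, `q`,
#'   log-likelihood trace and convergence diagnostics.
#' @export
fit_interference_model <- function(ern, q = NULL, cov_scale = 1,
                                   tol = 1e-6, max_iter = 500L,
                                   exclude_transient = TRUE) {
  validate_recording(ern)
  i_mcg <- channels_by_role(ern, "mcg")
  d <- length(i_mcg)
  if (!d) stopf("empty-room recording has no mcg channels")
  if (ncol(ern$samples) < 10 * ern$sample_rate)
    stopf("empty-room recording shorter than 10 s")
  Y <- ern$samples[i_mcg, , drop = FALSE]
  tr <- ern$transient_s %||% 0
  if (exclude_transient && tr > 0 && ncol(Y) > 4 * tr * ern$sample_rate) {
    ntr <- round(tr * ern$sample_rate)
    Y <- Y[, (ntr + 1L):(ncol(Y) - ntr), drop = FALSE]
  }
  S <- channel_covariance(Y) * cov_scale
  if (is.null(q)) q <- scree_factor_count(S)
  q <- as.integer(q)
  if (q < 0L || q >= d) stopf("parameter error: need 0 <= q < %d channels", d)
  fit <- fa_em(S, p = q, B_fixed = NULL, n_obs = ncol(Y),
               tol = tol, max_iter = max_iter)
  structure(list(B = fit$A, psi_ern = fit$psi, q = q,
                 loglik_trace = fit$loglik_trace,
                 iterations = fit$iterations, converged = fit$converged,
                 cov_scale = cov_scale, n_samples = ncol(Y),
                 channel_ids = ern$channel_ids[i_mcg]),
            class = "interference_model")
}

#' @export
print.interference_model <- function(x, ...) {
  cat(sprintf("<interference_model> %d ch x q=%d factors, EM %d it (%s)\n",
              nrow(x$B), x$q, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Fit the signal loading matrix with the interference block frozen
#'
#' Constrained EM on the averaged MCG waveform: the joint loading matrix
#' is `[A B]` with `B` fixed to the empty-room estimate; only `A` and
#' the diagonal residual variances are updated. The covariance is taken
#' over the epoch time axis.
#'
#' @param avg an `averaged_waveform` (its mcg channels are used).
#' @param im an [fit_interference_model()] result.
#' @param p signal factor count; NULL (default) selects by
#'   [dominant_factor_count()], capped at 4 — cardiac activity at a
#'   42-sensor array is well captured by a few components, and factors
#'   below the evoked-variance scale would only reconstruct residual
#'   noise.
#' @param tol,max_iter EM settings.
#' @return an object of class `signal_model`: `A`, `psi`, `p`,
#'   log-likelihood trace.
#' @export
fit_signal_model <- function(avg, im, p = NULL, tol = 1e-6, max_iter = 500L) {
  i_mcg <- which(avg$channel_roles == "mcg")
  if (!length(i_mcg)) i_mcg <- seq_len(nrow(avg$samples))
  d <- length(i_mcg)
  if (nrow(im$B) != d)
    stopf("consistency error: interference model has %d channels, waveform %d",
          nrow(im$B), d)
  S <- channel_covariance(avg$samples[i_mcg, , drop = FALSE])
  if (is.null(p)) p <- dominant_factor_count(S)
  p <- as.integer(p)
  if (p < 1L || p + im$q >= d)
    stopf("parameter error: need 1 <= p and p + q < %d channels", d)
  fit <- fa_em(S, p = p, B_fixed = im$B, n_obs = ncol(avg$samples),
               tol = tol, max_iter = max_iter)
  if (im$q > 0L && ncol(fit$A)) {
    ang <- subspace_angle_deg(fit$A, im$B)
    if (ang < 1)
      warnf("signal loadings nearly collinear with interference loadings (angle %.2f deg)", ang)
  }
  structure(list(A = fit$A, psi = fit$psi, p = p,
                 loglik_trace = fit$loglik_trace,
                 iterations = fit$iterations, converged = fit$converged,
                 channel_ids = avg$channel_ids[i_mcg]),
            class = "signal_model")
}

#' @export
print.signal_model <- function(x, ...) {
  cat(sprintf("<signal_model> %d ch x p=%d factors, EM %d it (%s)\n",
              nrow(x$A), x$p, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Denoise an averaged waveform by posterior projection
#'
#' Joint posterior mean of the signal and interference factors under the
#' Gaussian model, per sample:
#'
#'     [x_hat; u_hat] = [A B]' (A A' + B B' + Psi)^-1 y
#'
#' The denoised signal component is `y_S = A x_hat`. Deterministic and
#' linear in the input. A numerically singular model covariance is
#' solved through a symmetric regularized inverse and flagged.
#'
#' @param avg an `averaged_waveform` (mcg channels are used).
#' @param sm a [fit_signal_model()] result.
#' @param im the [fit_interference_model()] result used for `sm`.
#' @return an object of class `denoised_waveform`: `waveform` (an
#'   `averaged_waveform` whose mcg rows hold `y_S`), `x_hat` (p x T),
#'   `u_hat` (q x T), and a `regularized` flag.
#' @export
denoise <- function(avg, sm, im) {
  i_mcg <- which(avg$channel_roles == "mcg")
  if (!length(i_mcg)) i_mcg <- seq_len(nrow(avg$samples))
  if (nrow(sm$A) != length(i_mcg) || nrow(im$B) != length(i_mcg))
    stopf("consistency error: model/waveform channel mismatch")
  L <- cbind(sm$A, im$B)
  d <- nrow(L)
  M <- tcrossprod(L) + diag(sm$psi, d)
  regularized <- FALSE
  Minv <- tryCatch(chol2inv(chol(M)), error = function(e) {
    regularized <<- TRUE
    chol2inv(chol(M + diag(1e-10 * mean(diag(M)), d)))
  })
  fh <- crossprod(L, Minv) %*% avg$samples[i_mcg, , drop = FALSE]
  x_hat <- fh[seq_len(sm$p), , drop = FALSE]
  u_hat <- if (im$q > 0L) fh[sm$p + seq_len(im$q), , drop = FALSE]
           else matrix(0, 0L, ncol(fh))
  out <- avg
  out$samples[i_mcg, ] <- sm$A %*% x_hat
  structure(list(waveform = out, x_hat = x_hat, u_hat = u_hat,
                 regularized = regularized),
            class = "denoised_waveform")
}

#' @export
print.denoised_waveform <- function(x, ...) {
  cat(sprintf("<denoised_waveform> p=%d, q=%d factor time courses, %d samples\n",
              nrow(x$x_hat), nrow(x$u_hat), ncol(x$x_hat)))
  invisible(x)
}

#' Largest principal angle between two subspaces
#'
#' Largest canonical angle (degrees) between the column spaces of two
#' loading matrices; the standard recovery metric for factor subspaces,
#' invariant to column sign, scale and rotation.
#'
#' @param U,V matrices with the same row dimension.
#' @return angle in degrees.
#' @export
principal_angle <- function(U, V) subspace_angle_deg(U, V)
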