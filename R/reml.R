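#' REML variance components for one or several GRMs
#'
#' Fits `y = 1*mu + sum_s g_s + e` with `g_s ~ N(0, G_s sigma2_s)` and
#' `e ~ N(0, I sigma2_e)` by restricted maximum likelihood. With a single
#' GRM this is the GBLUP variance model; with one GRM per annotation group
#' it is the multiple genomic feature BLUP (MGFBLUP). The only fixed effect
#' is the intercept, as phenotypes are pre-corrected trait deviations.
#'
#' Updates are average-information (AI) steps with step-halving, and an
#' expectation-maximization fallback when the AI step fails to improve the
#' restricted likelihood. Variances are floored at `1e-8 * var(y)`;
#' components pinned to the floor for three consecutive iterations are
#' reported as 0. Convergence requires `|delta logLik| < tol_loglik` and a
#' maximum relative parameter change below `tol_par`.
#'
#' A near-singular AI matrix (e.g. a GRM proportional to the identity,
#' which makes genetic and residual variance inseparable) raises the
#' `flat_likelihood` flag and returns with `converged = FALSE`.
#'
#' @param pheno data frame with `sample_id` and the trait column, or a
#'   named numeric vector of phenotypes.
#' @param grms a `grm` or (named) list of `grm`s over the same individuals
#'   (at most 8 -- more groups are unreliable under REML).
#' @param trait name of the trait column when `pheno` is a data frame.
#' @param max_iter,tol_loglik,tol_par iteration controls.
#' @param start optional starting variances (length K + 1, residual last);
#'   default splits `var(y)` equally across all components.
#' @return an object of class `gsannot_reml`: `sigma2_groups` (named),
#'   `sigma2_e`, `h2`, `loglik`, `converged`, `n_iter`, `flags`, `mu`,
#'   `n`, `var_y`.
#' @export
reml_fit <- function(pheno, grms, trait = "value", max_iter = 200,
                     tol_loglik = 1e-6, tol_par = 1e-4, start = NULL) {
  grms <- .as_grm_list(grms)
  K <- length(grms)
  if (K > 8) stop("at most 8 GRMs are supported (REML becomes unstable)")
  ids <- grms[[1]]$sample_ids
  for (g in grms) {
    if (!identical(g$sample_ids, ids)) stop("GRMs cover different individuals")
  }
  y <- .align_pheno(pheno, trait, ids)
  n <- length(y)
  vy <- stats::var(y)
  floor_v <- 1e-8 * vy
  theta <- start %||% rep(vy / (K + 1), K + 1)
  stopifnot(length(theta) == K + 1)
  theta <- pmax(theta, floor_v)

  state_fun <- if (K == 1) .reml_state_eigen(grms[[1]]$values, y)
               else .reml_state_dense(lapply(grms, `[[`, "values"), y)

  st <- state_fun(theta)
  flags <- character(0)
  floor_runs <- integer(K + 1)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    rc <- tryCatch(1 / kappa(st$ai, exact = FALSE), error = function(e) 0)
    if (!is.finite(rc) || rc < 1e-12) {
      flags <- union(flags, "flat_likelihood")
      break
    }
    delta <- solve(st$ai, st$grad)
    step <- 1
    improved <- FALSE
    for (h in 1:12) {
      cand <- pmax(theta + step * delta, floor_v)
      st_new <- state_fun(cand)
      if (is.finite(st_new$loglik) && st_new$loglik >= st$loglik - 1e-10) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) {  # EM fallback step (guaranteed uphill direction)
      cand <- pmax(theta + theta^2 * (st$yPGPy - st$trPG) / n, floor_v)
      st_new <- state_fun(cand)
      if (!is.finite(st_new$loglik)) {
        flags <- union(flags, "em_step_failed")
        break
      }
    }
    dll <- st_new$loglik - st$loglik
    rel <- max(abs(cand - theta) / pmax(abs(theta), floor_v))
    at_floor <- cand <= floor_v * (1 + 1e-12)
    floor_runs <- ifelse(at_floor, floor_runs + 1L, 0L)
    theta <- cand
    st <- st_new
    if (abs(dll) < tol_loglik && rel < tol_par) {
      converged <- TRUE
      break
    }
  }
  if (!converged && !("flat_likelihood" %in% flags)) {
    flags <- union(flags, "max_iter_reached")
  }
  reported <- theta
  reported[floor_runs >= 3] <- 0
  sg <- reported[1:K]
  names(sg) <- names(grms)
  se <- reported[K + 1]
  structure(list(sigma2_groups = sg, sigma2_e = se,
                 h2 = sum(sg) / (sum(sg) + se),
                 loglik = st$loglik, converged = converged, n_iter = it,
                 flags = flags, mu = st$mu, n = n, var_y = vy),
            class = "gsannot_reml")
}

.as_grm_list <- function(grms) {
  if (inherits(grms, "grm")) grms <- list(grms)
  stopifnot(length(grms) >= 1, all(vapply(grms, inherits, logical(1), "grm")))
  if (is.null(names(grms)) || any(names(grms) == "")) {
    names(grms) <- paste0("g", seq_along(grms))
  }
  grms
}

.align_pheno <- function(pheno, trait, ids) {
  if (is.numeric(pheno)) {
    y <- if (!is.null(names(pheno))) pheno[ids] else pheno
  } else {
    pheno <- as.data.frame(pheno)
    if (!trait %in% names(pheno)) stop("trait column not found: ", trait)
    y <- pheno[[trait]][match(ids, pheno$sample_id)]
  }
  if (anyNA(y)) stop("phenotypes must be complete for all GRM individuals")
  as.numeric(y)
}

# Dense multi-GRM REML state: loglik, gradient, AI matrix, EM ingredients.
.reml_state_dense <- function(Gs, y) {
  n <- length(y)
  K <- length(Gs)
  ones <- rep(1, n)
  function(theta) {
    V <- diag(theta[K + 1], n)
    for (i in seq_len(K)) V <- V + theta[i] * Gs[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(loglik = -Inf))
    Vi <- chol2inv(ch)
    vi1 <- Vi %*% ones
    xvx <- sum(vi1)
    mu <- sum(vi1 * y) / xvx
    P <- Vi - tcrossprod(vi1) / xvx
    Py <- drop(P %*% y)
    logdet <- 2 * sum(log(diag(ch)))
    ll <- -0.5 * (logdet + log(xvx) + sum(y * Py))
    W <- vector("list", K + 1)
    for (i in seq_len(K)) W[[i]] <- drop(Gs[[i]] %*% Py)
    W[[K + 1]] <- Py
    trPG <- numeric(K + 1)
    for (i in seq_len(K)) trPG[i] <- sum(P * Gs[[i]])
    trPG[K + 1] <- sum(diag(P))
    yPGPy <- vapply(W, function(w) sum(Py * w), numeric(1))
    PW <- lapply(W, function(w) drop(P %*% w))
    ai <- matrix(0, K + 1, K + 1)
    for (i in seq_len(K + 1)) for (j in i:(K + 1)) {
      ai[i, j] <- ai[j, i] <- 0.5 * sum(W[[i]] * PW[[j]])
    }
    grad <- -0.5 * (trPG - yPGPy)
    list(loglik = ll, grad = grad, ai = ai, trPG = trPG, yPGPy = yPGPy,
         mu = mu)
  }
}

# Single-GRM REML via one eigendecomposition; every iteration is O(n).
.reml_state_eigen <- function(G, y) {
  ed <- eigen(G, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  yt <- drop(crossprod(ed$vectors, y))
  xt <- drop(crossprod(ed$vectors, rep(1, length(y))))
  function(theta) {
    w <- 1 / (theta[1] * d + theta[2])
    if (any(!is.finite(w)) || any(w <= 0)) return(list(loglik = -Inf))
    xwx <- sum(xt^2 * w)
    mu <- sum(xt * yt * w) / xwx
    Py <- w * (yt - xt * mu)
    yPy <- sum(yt * Py)
    ll <- -0.5 * (-sum(log(w)) + log(xwx) + yPy)
    # P applied to a rotated vector
    Pv <- function(v) w * v - w * xt * (sum(xt * w * v) / xwx)
    W1 <- d * Py                       # G P y (rotated)
    W2 <- Py                           # I P y
    trPG <- c(sum(d * w) - sum(xt^2 * w^2 * d) / xwx,
              sum(w) - sum(xt^2 * w^2) / xwx)
    yPGPy <- c(sum(Py * W1), sum(Py * W2))
    PW1 <- Pv(W1); PW2 <- Pv(W2)
    ai <- 0.5 * matrix(c(sum(W1 * PW1), sum(W1 * PW2),
                         sum(W1 * PW2), sum(W2 * PW2)), 2, 2)
    grad <- -0.5 * (trPG - yPGPy)
    list(loglik = ll, grad = grad, ai = ai, trPG = trPG, yPGPy = yPGPy,
         mu = mu)
  }
}

#' @export
print.gsannot_reml <- function(x, ...) {
  cat("<gsannot_reml> n =", x$n, "| logLik =", format(x$loglik),
      "| converged:", x$converged, "(", x$n_iter, "iter )\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  comp <- c(x$sigma2_groups, residual = x$sigma2_e)
  print(round(comp, 6))
  cat("  h2 =", round(x$h2, 4), "\n")
  invisible(x)
}
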