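# EM-REML engine for the Gaussian variance-component model
#   y = X beta + sum_k Z_k u_k + e,  u_k ~ N(0, sig2_k I), e ~ N(0, sig2_e W^-1)
#
# Iterations are classic EM via Henderson's mixed-model equations
# (restricted log-likelihood is non-decreasing by construction), with a
# guarded squared-extrapolation (SQUAREM-style) jump that is only accepted
# when it does not decrease the restricted log-likelihood. The restricted
# log-likelihood convention matches lme4: for unit weights,
#   ll = -1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ].

reml_engine <- function(y, X, groups, weights = NULL, init = NULL,
                        tol = 1e-8, max_iter = 10000L) {
  n <- length(y)
  p <- ncol(X)
  K <- length(groups)
  w <- weights %||% rep(1, n)
  check_that(all(is.finite(y)), "response must be finite")
  check_that(all(is.finite(w) & w > 0), "weights must be positive and finite")
  check_that(n > p, "more observations than fixed-effect parameters required")
  if (qr(X)$rank < p) abort("fixed-effect design is rank deficient")

  flags <- character(0)
  lev <- lapply(groups, function(f) levels(droplevels(as.factor(f))))
  qk <- vapply(lev, length, integer(1))
  for (k in seq_len(K)) {
    if (qk[k] < 2) {
      abort(sprintf("random term `%s` has fewer than 2 levels", names(groups)[k]))
    }
  }
  # detect aliased terms: identical row partitions cannot be separated
  part <- lapply(groups, function(f) match(as.character(f), unique(as.character(f))))
  if (K > 1) {
    for (a in seq_len(K - 1)) for (b in seq((a + 1), K)) {
      if (identical(part[[a]], part[[b]])) {
        flags <- c(flags, paste0("aliased_terms:", names(groups)[a], "+", names(groups)[b]))
      }
    }
  }

  # degenerate: constant response
  if (var(y) < .Machine$double.eps * (1 + mean(y)^2)) {
    sig <- setNames(rep(0, K + 1), c(names(groups), "resid"))
    return(list(sigma = sig, beta = setNames(rep(NA_real_, p), colnames(X)),
                mu = mean(y), se_beta = rep(NA_real_, p), fitted = rep(mean(y), n),
                loglik = NA_real_, loglik_trace = numeric(0), n_obs = n,
                n_levels = qk, converged = TRUE, iterations = 0L,
                flags = c(flags, "degenerate")))
  }

  scale0 <- var(y)
  theta0 <- init %||% rep(scale0 / (K + 1), K + 1) # (sig2_1..sig2_K, sig2_e)
  check_that(length(theta0) == K + 1 && all(theta0 >= 0),
             "init must give K+1 non-negative variances")
  check_that(theta0[K + 1] > 0, "residual variance must start positive")

  # full scaled augmented design [X Z_1 .. Z_K] built once; active subsets of
  # its crossproduct are taken as components drop to the boundary
  sw <- sqrt(w)
  Zs <- lapply(seq_len(K), function(k) {
    f <- droplevels(as.factor(groups[[k]]))
    Z <- matrix(0, n, qk[k])
    Z[cbind(seq_len(n), as.integer(f))] <- 1
    Z * sw
  })
  Wt_full <- do.call(cbind, c(list(X * sw), Zs))
  yt <- y * sw
  A_full <- crossprod(Wt_full)
  Wty_full <- drop(crossprod(Wt_full, yt))
  yty <- sum(yt^2)
  slw <- sum(log(w))
  fullcols <- vector("list", K)
  off <- p
  for (k in seq_len(K)) {
    fullcols[[k]] <- off + seq_len(qk[k])
    off <- off + qk[k]
  }

  # components initialised at exactly zero are held at the boundary: EM
  # cannot leave zero, so they are excluded from the model up front
  act <- which(theta0[seq_len(K)] > 0)
  floor_var <- 1e-10 * scale0

  setup <- function(act) {
    sel <- c(seq_len(p), unlist(fullcols[act]))
    qa <- qk[act]
    nc <- length(sel)
    cols <- vector("list", length(act))
    off <- p
    for (j in seq_along(act)) {
      cols[[j]] <- off + seq_len(qa[j])
      off <- off + qa[j]
    }
    didx <- (seq_len(nc) - 1L) * nc + seq_len(nc)
    list(act = act, Ka = length(act), sel = sel, A = A_full[sel, sel, drop = FALSE],
         Wty = Wty_full[sel], qa = qa, q_act = sum(qa), cols = cols,
         nc = nc, didx = didx, zdidx = didx[setdiff(seq_len(nc), seq_len(p))])
  }

  # one EM step; returns updated theta and the restricted ll AT THE INPUT
  # theta, plus the MME solution there
  em_step <- function(th, st) {
    Ka <- st$Ka
    sige <- th[Ka + 1]
    M <- st$A
    if (Ka > 0) M[st$zdidx] <- M[st$zdidx] + rep(sige / th[seq_len(Ka)], st$qa)
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) abort("mixed-model equations are singular; design is rank deficient")
    a_hat <- backsolve(R, backsolve(R, st$Wty, transpose = TRUE))
    dMinv <- chol2inv(R)[st$didx]
    rss <- max(yty - sum(a_hat * st$Wty), 0)
    logdetM <- 2 * sum(log(R[st$didx]))
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - st$q_act - p) * log(sige) +
                    sum(st$qa * log(th[seq_len(Ka)])) +
                    logdetM + rss / sige - slw)
    th_new <- th
    for (j in seq_len(Ka)) {
      uj <- a_hat[st$cols[[j]]]
      th_new[j] <- (sum(uj * uj) + sige * sum(dMinv[st$cols[[j]]])) / st$qa[j]
    }
    th_new[Ka + 1] <- rss / (n - p)
    list(theta = th_new, ll = ll, a_hat = a_hat, dMinv = dMinv, sige = sige)
  }

  st <- setup(act)
  theta <- c(theta0[act], theta0[K + 1]) # active variances + residual
  trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  last_ll <- -Inf
  # a rejected drop is re-tested once the component is 10x smaller or after
  # 100 further iterations (other parameters will have moved by then)
  no_drop_below <- rep(Inf, K)
  drop_attempt_iter <- rep(-Inf, K)
  reentries <- rep(0L, K)
  prev_cycle_ll <- -Inf
  polishes <- 0L
  while (iter < max_iter) {
    s1 <- em_step(theta, st)
    th1 <- s1$theta
    s2 <- em_step(th1, st)
    th2 <- s2$theta
    iter <- iter + 2L
    trace <- c(trace, s1$ll, s2$ll)
    last_ll <- s2$ll

    r <- th1 - theta
    v <- (th2 - th1) - r
    nv <- sqrt(sum(v^2))
    accepted <- th2
    if (nv > 1e-14) {
      alpha <- -sqrt(sum(r^2)) / nv
      alpha <- min(alpha, -1) # never shorter than a plain EM step
      ths <- theta - 2 * alpha * r + alpha^2 * v
      ths <- pmax(ths, floor_var)
      s3 <- em_step(ths, st)
      iter <- iter + 1L
      # accept the extrapolated point only if it did not lose likelihood
      if (is.finite(s3$ll) && s3$ll >= s2$ll - 1e-10) {
        accepted <- s3$theta
        trace <- c(trace, s3$ll)
        last_ll <- s3$ll
      }
    }
    delta <- max(abs(accepted - theta))
    th_prev <- theta
    theta <- accepted

    # boundary handling: a small, still-shrinking component is removed when
    # the restricted likelihood does not decrease in the limit
    if (st$Ka > 0) {
      ka_idx <- seq_len(st$Ka)
      small <- which(theta[ka_idx] < 0.05 * sum(theta) &
                       theta[ka_idx] < th_prev[ka_idx] &
                       (theta[ka_idx] < no_drop_below[st$act] / 10 |
                          iter - drop_attempt_iter[st$act] > 100))
      if (length(small) > 0) {
        j <- small[which.min(theta[small])]
        k_drop <- st$act[j]
        drop_attempt_iter[k_drop] <- iter
        st_try <- setup(setdiff(st$act, k_drop))
        th_try <- theta[-j]
        # let the reduced model catch up before judging the drop
        ok <- FALSE
        ll_try <- -Inf
        for (dstep in seq_len(30L)) {
          s_try <- em_step(th_try, st_try)
          iter <- iter + 1L
          if (!is.finite(s_try$ll)) break
          th_try <- s_try$theta
          if (s_try$ll >= last_ll - 1e-10) {
            ok <- TRUE
            ll_try <- s_try$ll
            break
          }
          if (s_try$ll < ll_try + 1e-12) break # stalled below the current path
          ll_try <- s_try$ll
        }
        if (ok) {
          flags <- c(flags, paste0("boundary:", names(groups)[k_drop]))
          st <- st_try
          theta <- th_try
          trace <- c(trace, ll_try)
          last_ll <- ll_try
          next
        } else {
          no_drop_below[k_drop] <- theta[j]
        }
      }
    }

    # primary stop: relative parameter change below tol; secondary stop: the
    # restricted likelihood has stalled (< 1e-10 per cycle) with parameters
    # already stable to 1e-5 relative -- the near-flat-ridge case, where
    # further EM crawling cannot change the supported answer
    rel_delta <- delta / max(sum(theta), .Machine$double.eps)
    cyc_gain <- last_ll - prev_cycle_ll
    ll_stall <- is.finite(prev_cycle_ll) &&
      ((cyc_gain < 1e-10 && rel_delta < 1e-5) ||
         (polishes > 0L && cyc_gain < 1e-9 && rel_delta < 1e-4))

    # slow-crawl escape: when EM has not terminated after many iterations
    # (weakly identified components give sub-linear progress), refine the
    # same restricted likelihood directly by quasi-Newton on the
    # log-variances, then hand back to EM for verification
    prev_cycle_ll <- last_ll
    if (!ll_stall && rel_delta >= tol &&
        polishes < 3L && iter > c(600L, 1500L, 3000L)[polishes + 1L]) {
      polishes <- polishes + 1L
      opt <- tryCatch(
        optim(log(pmax(theta, floor_var)),
              function(x) {
                ll <- tryCatch(em_step(exp(x), st)$ll, error = function(e) NA_real_)
                if (is.finite(ll)) -ll else 1e10
              },
              method = "L-BFGS-B", lower = log(floor_var) - 5,
              upper = log(sum(theta) * 100),
              control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) && -opt$value >= last_ll - 1e-10) {
        theta <- exp(opt$par)
        trace <- c(trace, -opt$value)
        last_ll <- -opt$value
        prev_cycle_ll <- -Inf
        next
      }
    }
    if (rel_delta < tol || ll_stall) {
      # before declaring convergence, verify dropped components really belong
      # at the boundary: trial re-entry at a small value; a positive score
      # (the EM step grows it without losing likelihood) brings it back
      re_entered <- FALSE
      for (k_back in setdiff(act, st$act)) {
        if (reentries[k_back] >= 3L) next
        act_try <- sort(c(st$act, k_back))
        st_try <- setup(act_try)
        eps_k <- 1e-3 * sum(theta)
        th_try <- c(vapply(act_try, function(k) {
          if (k == k_back) eps_k else theta[match(k, st$act)]
        }, numeric(1)), theta[st$Ka + 1])
        s_try <- em_step(th_try, st_try)
        iter <- iter + 1L
        pos <- match(k_back, act_try)
        if (is.finite(s_try$ll) && s_try$theta[pos] > eps_k &&
            s_try$ll >= last_ll - 1e-10) {
          reentries[k_back] <- reentries[k_back] + 1L
          flags <- setdiff(flags, paste0("boundary:", names(groups)[k_back]))
          st <- st_try
          theta <- s_try$theta
          trace <- c(trace, s_try$ll)
          last_ll <- s_try$ll
          re_entered <- TRUE
          break
        }
      }
      if (!re_entered) {
        if (ll_stall && rel_delta >= tol) flags <- c(flags, "converged_ll_stall")
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) flags <- c(flags, "max_iter")

  fin <- em_step(theta, st) # restricted ll at the final estimates
  trace <- c(trace, fin$ll)

  sigma <- setNames(rep(0, K + 1), c(names(groups), "resid"))
  sigma[st$act] <- theta[seq_len(st$Ka)]
  sigma[K + 1] <- theta[st$Ka + 1]

  # snap residual-scale dust to zero
  tiny <- sigma[seq_len(K)] > 0 & sigma[seq_len(K)] < 1e-7 * max(sum(sigma), scale0)
  if (any(tiny)) {
    flags <- c(flags, paste0("boundary:", names(groups)[tiny]))
    sigma[seq_len(K)][tiny] <- 0
  }

  beta <- fin$a_hat[seq_len(p)]
  list(
    sigma = sigma,
    beta = setNames(beta, colnames(X)),
    mu = beta[1],
    se_beta = sqrt(pmax(fin$sige * fin$dMinv[seq_len(p)], 0)),
    fitted = drop(Wt_full[, st$sel, drop = FALSE] %*% fin$a_hat) / sw,
    loglik = fin$ll,
    loglik_trace = trace,
    n_obs = n,
    n_levels = qk,
    converged = converged,
    iterations = iter,
    flags = unique(flags)
  )
}

#' Partition variance among dams, sires, blocks, plants and residual by REML
#'
#' Fits the intercept-only Gaussian random-effects model to a per-replicate
#' response (typically the family proportion dead at day 10) by EM-based
#' restricted maximum likelihood. Variances are constrained non-negative
#' (estimates that collapse to the boundary are flagged), the restricted
#' log-likelihood is non-decreasing across iterations, and convergence is
#' declared when the relative parameter change drops below `tol` (default
#' 1e-8) or after `max_iter` iterations.
#'
#' When two random terms group the rows identically (as dam and sire do in a
#' purely full-sib design) their variances are not separately identifiable;
#' the fit is flagged `aliased_terms` and the EM solution splits the shared
#' variance evenly between them.
#'
#' @param data A data frame with the response and grouping columns.
#' @param response Unquoted column (or expression) giving the per-row
#'   response, e.g. `n_dead_day10 / n_nymphs`.
#' @param random Character vector of grouping columns to fit as random
#'   effects.
#' @param weights Optional positive case weights.
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return An object of class `reml_fit` with a `components` tibble (term,
#'   variance, percent share), the fitted intercept, restricted
#'   log-likelihood and its iteration trace, convergence status and flags.
#' @export
#' @examples
#' surv <- simulate_survival_data(paper_survival_config(seed = 1))
#' exposed <- dplyr::filter(surv, treatment == "exposed")
#' fit <- fit_reml(exposed, n_dead_day10 / n_nymphs)
#' fit
fit_reml <- function(data, response,
                     random = c("dam_id", "sire_id", "block_id", "plant_id"),
                     weights = NULL, tol = 1e-8, max_iter = 10000L) {
  y <- rlang::eval_tidy(rlang::enquo(response), data)
  check_that(is.numeric(y) && length(y) == nrow(data), "response must be numeric, one value per row")
  miss <- setdiff(random, names(data))
  if (length(miss) > 0) abort(paste0("random term column(s) not found: ", paste(miss, collapse = ", ")))
  groups <- lapply(data[random], as.factor)
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  eng <- reml_engine(y, X, groups, weights = weights, tol = tol,
                     max_iter = as.integer(max_iter))
  total <- sum(eng$sigma)
  comp <- tibble::tibble(
    term = c(random, "residual"),
    variance = unname(eng$sigma),
    share_pct = if (total > 0) 100 * unname(eng$sigma) / total else NA_real_
  )
  structure(
    list(components = comp, mu = unname(eng$mu), loglik = eng$loglik,
         loglik_trace = eng$loglik_trace, n_obs = eng$n_obs,
         n_levels = eng$n_levels, converged = eng$converged,
         iterations = eng$iterations, flags = eng$flags,
         call = match.call()),
    class = "reml_fit"
  )
}

#' Restricted log-likelihood of the variance-component model
#'
#' Direct dense evaluation of the restricted (REML) log-likelihood at given
#' variances, in the same convention as `lme4` (for unit weights,
#' `-1/2 [(n - p) log 2pi + log|V| + log|X'V^-1 X| + y'Py]`). This routine is
#' independent of the EM machinery in [fit_reml()], so direct numerical
#' maximisation of it provides an external check on the EM estimates.
#'
#' @param sigma Named non-negative variances: one per random term plus
#'   `resid`.
#' @param data,response,random,weights As in [fit_reml()].
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(sigma, data, response,
                              random = c("dam_id", "sire_id", "block_id", "plant_id"),
                              weights = NULL) {
  y <- rlang::eval_tidy(rlang::enquo(response), data)
  n <- length(y)
  w <- weights %||% rep(1, n)
  check_that(all(sigma >= 0), "variances must be non-negative")
  check_that(all(c(random, "resid") %in% names(sigma)),
             "`sigma` must name every random term plus `resid`")
  V <- diag(sigma[["resid"]] / w, n)
  for (k in random) {
    if (sigma[[k]] > 0) {
      f <- droplevels(as.factor(data[[k]]))
      Z <- matrix(0, n, nlevels(f))
      Z[cbind(seq_len(n), as.integer(f))] <- 1
      V <- V + sigma[[k]] * tcrossprod(Z)
    }
  }
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) abort("total covariance is singular at these variances")
  X <- matrix(1, n, 1)
  Vi_y <- backsolve(R, backsolve(R, y, transpose = TRUE))
  Vi_X <- backsolve(R, backsolve(R, X, transpose = TRUE))
  XtViX <- crossprod(X, Vi_X)
  yPy <- sum(y * Vi_y) - drop(crossprod(X, Vi_y))^2 / drop(XtViX)
  -0.5 * ((n - 1) * log(2 * pi) + 2 * sum(log(diag(R))) +
            log(drop(XtViX)) + yPy) + 0.5 * sum(log(w))
}

#' Percent of total variance per component
#'
#' @param x A `reml_fit`, a tibble with `term` and `variance` columns, or a
#'   named numeric vector of variances.
#' @return A tibble with `term`, `variance` and `share_pct` (sums to 100).
#' @export
#' @examples
#' variance_shares(c(dam = 0.45, sire = 0.13, block = 0.09,
#'                   plant = 0.06, residual = 0.24))
variance_shares <- function(x) {
  if (inherits(x, "reml_fit")) {
    tab <- x$components[c("term", "variance")]
  } else if (is.data.frame(x)) {
    check_that(all(c("term", "variance") %in% names(x)),
               "data frame input needs `term` and `variance` columns")
    tab <- tibble::as_tibble(x[c("term", "variance")])
  } else {
    check_that(is.numeric(x) && !is.null(names(x)), "need a named numeric vector")
    tab <- tibble::tibble(term = names(x), variance = unname(x))
  }
  check_that(all(tab$variance >= 0), "variances must be non-negative")
  total <- sum(tab$variance)
  if (total <= 0) abort("variance shares undefined: all components are zero")
  tab$share_pct <- 100 * tab$variance / total
  tab
}

#' @export
print.reml_fit <- function(x, digits = 4, ...) {
  cat("REML variance components (EM), n =", x$n_obs, "\n")
  comp <- x$components
  comp$variance <- signif(comp$variance, digits)
  comp$share_pct <- round(comp$share_pct, 1)
  print(as.data.frame(comp), row.names = FALSE)
  cat(sprintf("restricted logLik: %.4f | converged: %s | iterations: %d\n",
              x$loglik, x$converged, x$iterations))
  if (length(x$flags) > 0) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
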