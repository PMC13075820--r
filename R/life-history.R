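#' Beta-binomial log probability mass
#'
#' Mean/overdispersion parameterisation: `p` is the mean success
#' probability and `rho` the intra-class correlation in \[0, 1). At
#' `rho = 0` this is exactly the binomial pmf (the beta-binomial tends to
#' the binomial as its precision grows).
#'
#' @param x Successes.
#' @param size Trials.
#' @param p Mean probability.
#' @param rho Overdispersion (intra-class correlation).
#' @param log Return log density?
#' @return (Log) probability mass, vectorised.
#' @export
dbetabinom <- function(x, size, p, rho = 0, log = FALSE) {
  if (length(rho) == 1L) rho <- rep(rho, length(x))
  out <- numeric(length(x))
  bin <- rho <= 0
  if (any(bin)) out[bin] <- dbinom(x[bin], size[bin], p[bin], log = TRUE)
  if (any(!bin)) {
    theta <- (1 - rho[!bin]) / rho[!bin]
    a <- p[!bin] * theta
    b <- (1 - p[!bin]) * theta
    out[!bin] <- lchoose(size[!bin], x[!bin]) +
      lbeta(x[!bin] + a, size[!bin] - x[!bin] + b) - lbeta(a, b)
  }
  if (log) out else exp(out)
}

#' Negative-binomial model of eggs laid per disk
#'
#' Fits treatment, disk-day and interaction effects on egg counts with a
#' log-link negative-binomial regression (maximum likelihood, alternating
#' coefficient and dispersion updates via [MASS::glm.nb()]). The pair
#' (replicate within plant) cluster structure is handled either by a fitted
#' random intercept (penalized quasi-likelihood, `mode = "pql"`, via
#' [MASS::glmmPQL()]) or by cluster-robust standard errors
#' (`mode = "robust"`, via [sandwich::vcovCL()]); `mode = "none"` reports
#' the plain maximum-likelihood fit for data without cluster structure. The
#' mode used is recorded in the result. The log-likelihood reported (and
#' used by [lr_test()]) is always that of the marginal negative-binomial
#' maximum-likelihood fit.
#'
#' @param data Data frame (typically a life-history table).
#' @param formula Count model formula; the left side is the egg-count
#'   column.
#' @param cluster Character vector naming the plant and replicate columns
#'   (outer to inner).
#' @param mode Cluster-handling mode.
#' @return Object of class `fecundity_fit`: `coefficients` tibble, `theta`
#'   (NB size), `loglik`, `n_coef`, `mode`, random-effect SDs when
#'   `mode = "pql"`, and flags.
#' @export
#' @examples
#' life <- simulate_life_history(sim_config(seed = 5))
#' fit_fecundity(life, mode = "robust")
fit_fecundity <- function(data,
                          formula = eggs_laid ~ treatment * factor(disk_day),
                          cluster = c("plant_id", "replicate_id"),
                          mode = c("pql", "robust", "none")) {
  mode <- match.arg(mode)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  check_that(all(y >= 0 & y == round(y)), "egg counts must be non-negative integers")
  if (all(y == 0)) abort("all counts are zero: fecundity model undefined")
  rhs_vars <- all.vars(formula[[3]])
  if (length(rhs_vars) > 0) {
    check_that(length(unique(data[[rhs_vars[1]]])) >= 2,
               "need at least 2 levels in the first model term")
  }
  flags <- character(0)

  core <- withCallingHandlers(
    MASS::glm.nb(formula, data = data),
    warning = function(w) {
      if (grepl("iteration limit", conditionMessage(w))) {
        flags <<- c(flags, "dispersion_at_limit")
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!core$converged) flags <- c(flags, "not_converged")
  est <- coef(core)
  vc <- vcov(core)
  random_sd <- NULL

  if (mode == "robust") {
    miss <- setdiff(cluster, names(data))
    if (length(miss) > 0) abort(paste0("cluster column(s) not found: ", paste(miss, collapse = ", ")))
    cl <- interaction(data[[cluster[1]]], data[[cluster[2]]], drop = TRUE)
    vc <- sandwich::vcovCL(core, cluster = cl)
  } else if (mode == "pql") {
    miss <- setdiff(cluster, names(data))
    if (length(miss) > 0) abort(paste0("cluster column(s) not found: ", paste(miss, collapse = ", ")))
    dd <- as.data.frame(data)
    ran <- as.formula(paste0("~ 1 | ", cluster[1], "/", cluster[2]))
    pql <- tryCatch(
      suppressMessages(MASS::glmmPQL(
        fixed = formula, random = ran,
        family = MASS::negative.binomial(theta = core$theta),
        data = dd, verbose = FALSE
      )),
      error = function(e) NULL
    )
    if (is.null(pql)) {
      flags <- c(flags, "pql_failed_robust_fallback")
      cl <- interaction(data[[cluster[1]]], data[[cluster[2]]], drop = TRUE)
      vc <- sandwich::vcovCL(core, cluster = cl)
      mode <- "robust"
    } else {
      est <- nlme::fixef(pql)
      vc <- vcov(pql)
      vcr <- nlme::VarCorr(pql)
      sds <- suppressWarnings(as.numeric(vcr[, "StdDev"]))
      random_sd <- tibble::tibble(
        group = rownames(vcr),
        sd = sds
      )[!is.na(sds) & rownames(vcr) != "Residual", ]
    }
  }

  se <- sqrt(diag(vc))
  zv <- est / se
  co <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(zv),
    p.value = unname(2 * stats::pnorm(-abs(zv)))
  )
  structure(
    list(coefficients = co, theta = core$theta,
         loglik = as.numeric(logLik(core)),
         n_coef = length(coef(core)) + 1L, # NB size is also estimated
         nobs = length(y), mode = mode, random_sd = random_sd,
         flags = unique(flags)),
    class = "fecundity_fit"
  )
}

#' Likelihood-ratio test between nested fits
#'
#' `2 * (loglik(full) - loglik(reduced))` against a chi-square with the
#' difference in parameter count as degrees of freedom. Works for any pair
#' of fits carrying `loglik` and `n_coef` (e.g. [fit_fecundity()],
#' [fit_hatch()]).
#'
#' @param full,reduced Nested model fits (`reduced` within `full`).
#' @return One-row tibble: `statistic`, `df`, `p.value`.
#' @export
lr_test <- function(full, reduced) {
  for (obj in list(full, reduced)) {
    check_that(is.list(obj) && !is.null(obj$loglik) && !is.null(obj$n_coef),
               "fits must carry `loglik` and `n_coef`")
  }
  if (full$loglik < reduced$loglik - 1e-6) {
    abort("full model has lower log-likelihood than the reduced model: optimization failure")
  }
  df <- full$n_coef - reduced$n_coef
  check_that(df >= 0, "`reduced` must have no more parameters than `full`")
  stat <- max(2 * (full$loglik - reduced$loglik), 0)
  p <- if (df == 0) {
    if (stat <= 1e-8) 1 else NA_real_
  } else {
    pchisq(stat, df, lower.tail = FALSE)
  }
  tibble::tibble(statistic = stat, df = df, p.value = p)
}

#' Beta-binomial model of hatch success
#'
#' Fits logit-scale effects on the per-egg hatch probability with a
#' beta-binomial likelihood -- the closed-form counterpart of a binomial
#' model with an observation-level Gaussian random intercept: both let each
#' row's probability wobble around the mean to absorb extra-binomial
#' variation, but the beta-binomial integrates in closed form. The
#' substitution is recorded in the result's `note`.
#'
#' Maximisation is joint over the coefficients and the log precision, from a
#' binomial GLM start. When the likelihood pushes the overdispersion to zero
#' the binomial GLM itself is returned (`rho = 0`); rows that all hatched or
#' all failed are permitted, but a fit in which every trial succeeded or
#' every trial failed is flagged `boundary`.
#'
#' @param data Data frame with one row per observation unit.
#' @param hatched,unhatched Unquoted count columns.
#' @param formula One-sided formula for the logit-mean model, e.g.
#'   `~ treatment * factor(day)`.
#' @return Object of class `hatch_fit`: `coefficients` tibble,
#'   `overdispersion` (intra-class correlation rho), `loglik`, `n_coef`,
#'   flags and `note`.
#' @export
fit_hatch <- function(data, hatched = hatched, unhatched = unhatched,
                      formula = ~treatment) {
  xh <- rlang::eval_tidy(rlang::enquo(hatched), data)
  xu <- rlang::eval_tidy(rlang::enquo(unhatched), data)
  check_that(all(xh >= 0 & xh == round(xh)) && all(xu >= 0 & xu == round(xu)),
             "hatched/unhatched must be non-negative integer counts")
  m <- xh + xu
  keep <- m > 0
  xh <- xh[keep]
  m <- m[keep]
  X <- model.matrix(formula, data[keep, , drop = FALSE])
  check_that(nrow(X) == length(xh), "model frame and counts differ in length")
  note <- paste("beta-binomial likelihood in place of an observation-level",
                "Gaussian random intercept (same overdispersion role,",
                "closed form)")
  flags <- character(0)
  if (all(xh == m) || all(xh == 0)) flags <- c(flags, "boundary")

  glm0 <- suppressWarnings(glm(cbind(xh, m - xh) ~ X - 1, family = binomial()))
  beta0 <- coef(glm0)
  beta0[!is.finite(beta0)] <- 0
  ll_binom <- sum(dbinom(xh, m, plogis(drop(X %*% beta0)), log = TRUE))

  nb <- ncol(X)
  negll <- function(par) {
    p <- plogis(clamp(drop(X %*% par[seq_len(nb)]), -15, 15))
    rho <- 1 / (1 + exp(par[nb + 1])) # log theta -> rho
    ll <- sum(dbetabinom(xh, m, p, rho, log = TRUE))
    if (is.finite(ll)) -ll else 1e10
  }
  # bounded search: the log-precision cap (theta <= e^12) marks the binomial
  # limit; beyond it the beta-function evaluation loses all precision
  lower <- c(rep(-15, nb), -5)
  upper <- c(rep(15, nb), 12)
  start <- c(pmin(pmax(beta0, -14), 14), log_theta = 2)
  opt <- optim(start, negll, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = 500), hessian = TRUE)
  ll_bb <- -opt$value
  theta_hat <- exp(opt$par[nb + 1])
  rho_hat <- 1 / (1 + theta_hat)

  if (ll_bb <= ll_binom + 1e-6 || opt$par[nb + 1] >= upper[nb + 1] - 1e-6) {
    # overdispersion at the boundary: exact binomial fit
    est <- unname(beta0)
    se <- sqrt(diag(vcov(glm0)))
    ll <- ll_binom
    rho_hat <- 0
    flags <- c(flags, "no_overdispersion")
  } else {
    est <- opt$par[seq_len(nb)]
    se <- rep(NA_real_, nb)
    hi <- tryCatch(solve(opt$hessian), error = function(e) NULL)
    if (!is.null(hi)) {
      dv <- diag(hi)[seq_len(nb)]
      se <- sqrt(pmax(dv, 0))
    }
    ll <- ll_bb
  }
  zv <- est / se
  co <- tibble::tibble(
    term = colnames(X), estimate = unname(est), std.error = unname(se),
    statistic = unname(zv), p.value = unname(2 * stats::pnorm(-abs(zv)))
  )
  structure(
    list(coefficients = co, overdispersion = unname(rho_hat), loglik = ll,
         n_coef = nb + 1L, nobs = length(xh), flags = unique(flags),
         note = note),
    class = "hatch_fit"
  )
}

#' Binomial confidence intervals
#'
#' Exact Clopper-Pearson (default) or Wilson score intervals.
#' Clopper-Pearson bounds are the beta-quantile closed form, exactly 0 (lower
#' at 0 successes) and exactly 1 (upper at all successes).
#'
#' @param successes,trials Non-negative integer vectors
#'   (`0 <= successes <= trials`, `trials >= 1`).
#' @param method `"clopper-pearson"` or `"wilson"`.
#' @param level Confidence level.
#' @return Tibble: `successes`, `trials`, `estimate`, `lower`, `upper`,
#'   `method`.
#' @export
#' @examples
#' binom_ci(28, 100)
binom_ci <- function(successes, trials,
                     method = c("clopper-pearson", "wilson"), level = 0.95) {
  method <- match.arg(method)
  check_that(is.numeric(successes) && is.numeric(trials) &&
               all(trials >= 1) && all(successes >= 0) &&
               all(successes <= trials) &&
               all(successes == round(successes)) && all(trials == round(trials)),
             "need integer counts with 0 <= successes <= trials, trials >= 1")
  x <- successes
  n <- trials
  alpha <- 1 - level
  p <- x / n
  if (method == "clopper-pearson") {
    lower <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
    upper <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  } else {
    zc <- qnorm(1 - alpha / 2)
    denom <- 1 + zc^2 / n
    centre <- (p + zc^2 / (2 * n)) / denom
    half <- zc * sqrt(p * (1 - p) / n + zc^2 / (4 * n^2)) / denom
    lower <- pmax(centre - half, 0)
    upper <- pmin(centre + half, 1)
  }
  tibble::tibble(successes = x, trials = n, estimate = p,
                 lower = lower, upper = upper, method = method)
}

#' Life-history cost summary
#'
#' Raw (unmodelled) summaries of the fecundity and hatching experiment:
#' per-treatment mean total eggs per pair over all disk days with a t-based
#' 95% confidence interval, pooled hatch proportion (total hatched by the
#' last observation day over total eggs) with an exact binomial interval,
#' and per-day breakdowns of laying and hatching.
#'
#' @param life A validated life-history table.
#' @param level Confidence level.
#' @return Object of class `cost_summary`: tibbles `fecundity`, `hatch`,
#'   `eggs_by_disk_day` and `hatch_by_day`.
#' @export
#' @examples
#' summarize_costs(simulate_life_history(sim_config(seed = 5)))
summarize_costs <- function(life, level = 0.95) {
  validate_life_history_table(life)
  check_that(nrow(life) > 0, "life-history table is empty")
  arms <- unique(life$treatment)
  if (length(arms) < 2) {
    abort(paste0("no replicates in one treatment arm (only '", arms, "' present)"))
  }
  hcols <- grep("^hatched_day[0-9]+$", names(life), value = TRUE)
  hdays <- sort(as.integer(sub("hatched_day", "", hcols)))
  final_col <- paste0("hatched_day", max(hdays))

  totals <- life |>
    dplyr::group_by(.data$treatment, .data$replicate_id) |>
    dplyr::summarise(total_eggs = sum(.data$eggs_laid), .groups = "drop")
  fec <- totals |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_total_eggs = mean(.data$total_eggs),
      sd_total_eggs = sd(.data$total_eggs),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ci_lower = .data$mean_total_eggs - qt(1 - (1 - level) / 2, pmax(.data$n_pairs - 1, 1)) *
        .data$sd_total_eggs / sqrt(.data$n_pairs),
      ci_upper = .data$mean_total_eggs + qt(1 - (1 - level) / 2, pmax(.data$n_pairs - 1, 1)) *
        .data$sd_total_eggs / sqrt(.data$n_pairs),
      flag = ifelse(.data$n_pairs < 2, "degenerate_ci", "")
    )
  fec$ci_lower[fec$n_pairs < 2] <- NA_real_
  fec$ci_upper[fec$n_pairs < 2] <- NA_real_

  hatch <- life |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(eggs = sum(.data$eggs_laid),
                     hatched = sum(.data[[final_col]]), .groups = "drop")
  ci <- binom_ci(hatch$hatched, pmax(hatch$eggs, 1), level = level)
  hatch$proportion <- ifelse(hatch$eggs > 0, hatch$hatched / hatch$eggs, NA_real_)
  hatch$ci_lower <- ci$lower
  hatch$ci_upper <- ci$upper

  eggs_by_day <- life |>
    dplyr::group_by(.data$treatment, .data$disk_day) |>
    dplyr::summarise(mean_eggs = mean(.data$eggs_laid),
                     sd_eggs = sd(.data$eggs_laid),
                     n = dplyr::n(), .groups = "drop")

  inc <- life
  prev <- 0
  hatch_by_day <- purrr::map_dfr(hdays, function(d) {
    cur <- inc[[paste0("hatched_day", d)]]
    prev_col <- if (d == min(hdays)) 0 else inc[[paste0("hatched_day", hdays[which(hdays == d) - 1])]]
    tibble::tibble(treatment = inc$treatment, day = d,
                   hatched = cur - prev_col, eggs = inc$eggs_laid)
  }) |>
    dplyr::group_by(.data$treatment, .data$day) |>
    dplyr::summarise(hatched = sum(.data$hatched), eggs = sum(.data$eggs),
                     .groups = "drop") |>
    dplyr::mutate(proportion = ifelse(.data$eggs > 0, .data$hatched / .data$eggs, NA_real_))

  structure(
    list(fecundity = fec, hatch = hatch, eggs_by_disk_day = eggs_by_day,
         hatch_by_day = hatch_by_day, level = level),
    class = "cost_summary"
  )
}

#' @export
print.cost_summary <- function(x, ...) {
  cat("Life-history costs\n\nFecundity (total eggs over all disks, per pair):\n")
  print(as.data.frame(x$fecundity), row.names = FALSE, digits = 4)
  cat("\nHatch success (pooled, exact binomial CI):\n")
  print(as.data.frame(x$hatch), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Reshape a life-history table for the hatch models
#'
#' `hatch_totals()` gives one row per pair and disk day with the final
#' cumulative hatch count and its complement -- the input for the
#' hatch-success model. `hatch_increments()` expands to one row per
#' observation day with the number of eggs hatching on that day -- the input
#' for the hatch-timing model.
#'
#' @param life A validated life-history table.
#' @return A tibble (see Details).
#' @export
hatch_totals <- function(life) {
  validate_life_history_table(life)
  hcols <- grep("^hatched_day[0-9]+$", names(life), value = TRUE)
  final_col <- paste0("hatched_day", max(as.integer(sub("hatched_day", "", hcols))))
  dplyr::transmute(
    life,
    plant_id = .data$plant_id, replicate_id = .data$replicate_id,
    treatment = .data$treatment, disk_day = .data$disk_day,
    eggs = .data$eggs_laid,
    hatched = .data[[final_col]],
    unhatched = .data$eggs_laid - .data[[final_col]]
  )
}

#' @rdname hatch_totals
#' @export
hatch_increments <- function(life) {
  validate_life_history_table(life)
  hcols <- grep("^hatched_day[0-9]+$", names(life), value = TRUE)
  hdays <- sort(as.integer(sub("hatched_day", "", hcols)))
  purrr::map_dfr(seq_along(hdays), function(i) {
    d <- hdays[i]
    cur <- life[[paste0("hatched_day", d)]]
    prev <- if (i == 1) 0 else life[[paste0("hatched_day", hdays[i - 1])]]
    tibble::tibble(
      plant_id = life$plant_id, replicate_id = life$replicate_id,
      treatment = life$treatment, disk_day = life$disk_day,
      day = d, hatched = cur - prev,
      unhatched = life$eggs_laid - (cur - prev)
    )
  })
}
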