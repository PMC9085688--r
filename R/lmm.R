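# Linear mixed models with a landscape-window random intercept and,
# for link-level (pairwise) data, an MLPE population-effects correlation.
#
# Marginal covariance: Sigma = s2_w Zw Zw' + s2_p A A' + s2_e I, where Zw
# indicates the window of each row and A is the pair-incidence matrix with
# two unit entries per row (the two populations forming the pair). The
# likelihood is profiled over beta and s2_e and maximized over the log
# variance ratios; all solves use the Woodbury identity on the low-rank
# structure, so a fit costs O(n (q + p)^2) rather than O(n^3).

#' @keywords internal
build_design <- function(data, response, fixed, window, pairs) {
  y <- data[[response]]
  if (is.null(y)) stop("response column '", response, "' not found", call. = FALSE)
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  for (f in fixed) {
    if (is.null(data[[f]])) stop("fixed-term column '", f, "' not found",
                                 call. = FALSE)
    X <- cbind(X, data[[f]])
  }
  colnames(X) <- c("(Intercept)", fixed)
  wfac <- factor(data[[window]])
  Zw <- NULL
  if (nlevels(wfac) >= 1) {
    Zw <- matrix(0, n, nlevels(wfac))
    Zw[cbind(seq_len(n), as.integer(wfac))] <- 1
  }
  A <- NULL
  if (!is.null(pairs)) {
    # populations are identified within windows
    pid <- factor(c(paste(data[[window]], data[[pairs[1]]], sep = "\r"),
                    paste(data[[window]], data[[pairs[2]]], sep = "\r")))
    A <- matrix(0, n, nlevels(pid))
    A[cbind(seq_len(n), as.integer(pid[seq_len(n)]))] <- 1
    A[cbind(seq_len(n), as.integer(pid[n + seq_len(n)]))] <-
      A[cbind(seq_len(n), as.integer(pid[n + seq_len(n)]))] + 1
  }
  list(y = y, X = X, Zw = Zw, A = A)
}

# Profiled negative log-likelihood machinery on precomputed cross products.
#' @keywords internal
mlpe_eval <- function(pre, ratios, method) {
  # ratios: named numeric c(window = r_w, pop = r_p); components with
  # ratio 0 drop out of U.
  n <- pre$n; p <- ncol(pre$XtX)
  lam <- numeric(0)
  cols <- integer(0)
  if (!is.null(pre$nw) && ratios[["window"]] > 0) {
    cols <- c(cols, seq_len(pre$nw))
    lam <- c(lam, rep(ratios[["window"]], pre$nw))
  }
  if (!is.null(pre$np) && ratios[["pop"]] > 0) {
    cols <- c(cols, pre$nw + seq_len(pre$np))
    lam <- c(lam, rep(ratios[["pop"]], pre$np))
  }
  if (length(cols) == 0) {
    XtViX <- pre$XtX; XtViy <- pre$Xty; ytViy <- pre$yty; logdetV <- 0
  } else {
    s <- sqrt(lam)
    M <- diag(length(cols)) + (s %o% s) * pre$UtU[cols, cols, drop = FALSE]
    if (any(!is.finite(M))) return(list(loglik = -Inf))
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(list(loglik = -Inf))
    logdetV <- 2 * sum(log(diag(ch)))
    BX <- s * pre$UtX[cols, , drop = FALSE]
    by <- s * pre$Uty[cols]
    MiBX <- backsolve(ch, forwardsolve(t(ch), BX))
    Miby <- backsolve(ch, forwardsolve(t(ch), by))
    XtViX <- pre$XtX - crossprod(BX, MiBX)
    XtViy <- pre$Xty - crossprod(BX, Miby)[, 1]
    ytViy <- pre$yty - sum(by * Miby)
  }
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(list(loglik = -Inf))
  beta <- backsolve(chX, forwardsolve(t(chX), XtViy))
  rss <- max(ytViy - sum(beta * XtViy), 1e-300)
  if (method == "ML") {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + logdetV + n)
  } else {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) + logdetV +
                  2 * sum(log(diag(chX))) + (n - p))
  }
  list(loglik = ll, beta = beta, sigma2_resid = s2, XtViX = XtViX,
       logdetV = logdetV)
}

#' Fit a window-intercept / MLPE linear mixed model
#'
#' Fits `response ~ fixed terms` with a random intercept per landscape
#' window and, when `pairs` names the two population columns of pairwise
#' (link-level) data, an additional MLPE random effect per population
#' shared by all pairs containing it. Variance ratios are profiled on the
#' log scale and optimized from three fixed starting points (deterministic
#' given the data); `beta` is the generalized-least-squares solution at
#' the optimum.
#'
#' @param data Data frame; all predictors should already be transformed
#'   and standardized (see [transform_columns()]).
#' @param response Response column name.
#' @param fixed Character vector of fixed-term column names (the intercept
#'   is always included).
#' @param window Window (grouping) column name.
#' @param pairs `NULL` for node-level data, or `c("pop1", "pop2")` for
#'   link-level data.
#' @param method `"ML"` (for model comparison) or `"REML"` (for final
#'   estimates).
#' @param fix_ratios Optional named numeric fixing variance ratios
#'   `sigma2/sigma2_resid`, e.g. `c(pop = 0)` forces the MLPE component
#'   to zero.
#' @return An `lg_fit` with coefficients, standard errors, variance
#'   components, `logLik`, `AICc` and bookkeeping needed for refits.
#' @export
fit_mixed <- function(data, response, fixed = character(), window = "window",
                      pairs = NULL, method = c("ML", "REML"),
                      fix_ratios = NULL) {
  method <- match.arg(method)
  des <- build_design(data, response, fixed, window, pairs)
  # components fixed at exactly zero drop out of the design altogether,
  # so the fit is bitwise identical to the model without them
  if (!is.null(fix_ratios)) {
    fr0 <- fix_ratios[!is.na(fix_ratios) & fix_ratios == 0]
    if ("window" %in% names(fr0)) des$Zw <- NULL
    if ("pop" %in% names(fr0)) des$A <- NULL
  }
  n <- length(des$y); p <- ncol(des$X)
  U <- cbind(des$Zw, des$A)
  nw <- if (is.null(des$Zw)) NULL else ncol(des$Zw)
  np <- if (is.null(des$A)) NULL else ncol(des$A)
  pre <- list(n = n, nw = nw, np = np,
              XtX = crossprod(des$X), Xty = crossprod(des$X, des$y)[, 1],
              yty = sum(des$y^2),
              UtU = if (is.null(U)) NULL else crossprod(U),
              UtX = if (is.null(U)) NULL else crossprod(U, des$X),
              Uty = if (is.null(U)) NULL else crossprod(U, des$y)[, 1])
  comp <- c(window = !is.null(nw), pop = !is.null(np))
  fixed_r <- c(window = NA_real_, pop = NA_real_)
  if (!is.null(fix_ratios)) fixed_r[names(fix_ratios)] <- fix_ratios
  free <- names(comp)[comp & is.na(fixed_r[names(comp)])]
  k_var <- 1L + sum(comp & (is.na(fixed_r[names(comp)]) |
                            fixed_r[names(comp)] > 0))
  if (n <= p + k_var) stop("too few observations for the parameter count",
                           call. = FALSE)

  ratios_of <- function(theta) {
    r <- c(window = 0, pop = 0)
    r[free] <- exp(pmin(pmax(theta, -30), 30))
    for (nm in names(comp)) if (comp[[nm]] && !is.na(fixed_r[[nm]]))
      r[[nm]] <- fixed_r[[nm]]
    r
  }
  negll <- function(theta) {
    ll <- mlpe_eval(pre, ratios_of(theta), method)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }

  optimize_free <- function() {
    if (length(free) == 0) return(numeric(0))
    starts <- if (length(free) == 1) list(-4, 0, 3) else
      list(c(-4, -4), c(0, 0), c(3, 3))
    best <- NULL
    for (st in starts) {
      opt <- if (length(free) == 1) {
        stats::optim(st, negll, method = "Brent", lower = -20, upper = 15,
                     control = list(reltol = 1e-12))
      } else {
        stats::optim(st, negll, method = "Nelder-Mead",
                     control = list(reltol = 1e-10, maxit = 500))
      }
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    best$par
  }
  theta_hat <- optimize_free()
  if (length(free) > 0) {
    # collapse ratios that are indistinguishable from the zero boundary
    ll_hat <- -negll(theta_hat)
    r <- ratios_of(theta_hat)
    collapsed <- FALSE
    for (nm in free) {
      r0 <- r; r0[[nm]] <- 0
      if (mlpe_eval(pre, r0, method)$loglik >= ll_hat - 1e-8) {
        fixed_r[[nm]] <- 0
        free <- setdiff(free, nm)
        collapsed <- TRUE
      }
    }
    if (collapsed) theta_hat <- optimize_free()
  }
  r_hat <- ratios_of(theta_hat)
  ev <- mlpe_eval(pre, r_hat, method)
  vc <- chol2inv(chol(ev$XtViX)) * ev$sigma2_resid
  se <- sqrt(diag(vc))
  sigma2 <- c(window = if (comp[["window"]]) r_hat[["window"]] * ev$sigma2_resid else 0,
              pop = if (comp[["pop"]]) r_hat[["pop"]] * ev$sigma2_resid else 0,
              resid = ev$sigma2_resid)
  k <- p + k_var
  beta <- stats::setNames(as.numeric(ev$beta), colnames(des$X))
  fit <- structure(list(
    coefficients = beta, se = stats::setNames(se, names(beta)), vcov = vc,
    sigma2 = sigma2, ratios = r_hat, logLik = ev$loglik, n = n, p = p,
    k = k, method = method, response = response, fixed = fixed,
    window = window, pairs = pairs, fix_ratios = fix_ratios,
    X = des$X, y = des$y, has_pairs = !is.null(pairs),
    fitted_fixed = as.numeric(des$X %*% ev$beta)),
    class = "lg_fit")
  fit$AICc <- aicc(fit)
  fit
}

#' Refit an `lg_fit` with a different estimation method
#' @param fit An `lg_fit`.
#' @param data The data used for the original fit.
#' @param method `"ML"` or `"REML"`.
#' @export
refit_mixed <- function(fit, data, method) {
  fit_mixed(data, fit$response, fit$fixed, fit$window, fit$pairs,
            method = method, fix_ratios = fit$fix_ratios)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`, with `k` counting fixed
#' coefficients plus all variance parameters.
#'
#' @param fit An `lg_fit` (or a list with `logLik`, `k`, `n`).
#' @return AICc value.
#' @export
aicc <- function(fit) {
  n <- fit$n; k <- fit$k
  if (n <= k + 1) stop("AICc undefined: n <= k + 1", call. = FALSE)
  -2 * fit$logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Likelihood ratio test between nested ML fits
#'
#' @param full,reduced Nested `lg_fit` objects fitted with ML (REML fits
#'   with different fixed structures are not comparable and are refused).
#' @return List with `statistic` (clamped at 0), `df` (difference in fixed
#'   coefficients) and `p.value` from the chi-squared distribution.
#' @export
lrt <- function(full, reduced) {
  if (full$method != "ML" || reduced$method != "ML")
    stop("likelihood ratio tests require ML fits", call. = FALSE)
  if (!all(reduced$fixed %in% full$fixed))
    stop("models are not nested", call. = FALSE)
  df <- full$p - reduced$p
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p.value = p)
}

#' Marginal R-squared of a mixed-model fit
#'
#' Nakagawa-Schielzeth variance decomposition:
#' `var(X beta) / (var(X beta) + s2_window + m * s2_pop + s2_resid)`,
#' where `m` is the mean number of population effects per row (2 for MLPE
#' pairwise rows, 0 at node level).
#'
#' @param fit An `lg_fit`.
#' @return Marginal R-squared in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  vf <- stats::var(fit$fitted_fixed)
  m <- if (fit$has_pairs) 2 else 0
  tot <- vf + fit$sigma2[["window"]] + m * fit$sigma2[["pop"]] +
    fit$sigma2[["resid"]]
  if (tot <= 0) stop("zero total variance", call. = FALSE)
  vf / tot
}

#' @export
print.lg_fit <- function(x, ...) {
  cat("<lg_fit> ", x$method, ", n = ", x$n, ", k = ", x$k,
      ", logLik = ", round(x$logLik, 3), ", AICc = ", round(x$AICc, 2),
      "\n", sep = "")
  cat("sigma2: window ", signif(x$sigma2[["window"]], 4),
      if (x$has_pairs) paste0(", pop ", signif(x$sigma2[["pop"]], 4)),
      ", resid ", signif(x$sigma2[["resid"]], 4), "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed-model fit
#' @param x An `lg_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`.
#' @method tidy lg_fit
#' @export
tidy.lg_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = as.numeric(x$coefficients),
                 std.error = as.numeric(x$se),
                 statistic = as.numeric(x$coefficients) / as.numeric(x$se))
}

#' One-row summary of a mixed-model fit
#' @param x An `lg_fit`.
#' @param ... Unused.
#' @method glance lg_fit
#' @export
glance.lg_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, AICc = x$AICc, k = x$k, n = x$n,
                 sigma2_window = x$sigma2[["window"]],
                 sigma2_pop = x$sigma2[["pop"]],
                 sigma2_resid = x$sigma2[["resid"]],
                 r2_marginal = marginal_r2(x), method = x$method)
}
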