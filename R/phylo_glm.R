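#' Phylogenetic generalised linear models for tip traits
#'
#' Fits regressions of a binary or count tip trait on species covariates
#' while accounting for phylogenetic non-independence.
#'
#' * `family = "binomial"` fits a phylogenetic logistic regression by
#'   maximised penalised likelihood (MPLE). The working correlation among
#'   tips is the fixed-root Ornstein-Uhlenbeck transform of the Brownian
#'   covariance: on a depth-normalised tree,
#'   `R_ij = exp(-a d_ij) (1 - exp(-2 a t_ij)) /
#'   sqrt((1 - exp(-2 a T_i))(1 - exp(-2 a T_j)))`,
#'   with `d_ij` the patristic distance, `t_ij` the shared root-to-MRCA
#'   time and `T_i` the tip depth. The signal parameter `a` (`alpha`)
#'   interpolates between Brownian correlation (`a -> 0`) and independence
#'   (`a -> Inf`); on a star phylogeny the correlation is the identity for
#'   every `a` and the fit reduces exactly to Firth-penalised logistic
#'   regression. Coefficients solve the penalised estimating equations
#'   (Firth bias-reduction term), which keeps estimates finite under
#'   (quasi-)separation; `alpha` maximises the Gaussian profile
#'   pseudo-likelihood of standardised working residuals.
#' * `family = "poisson"` fits a phylogenetic GEE for counts with log link.
#'   The working correlation is, by default (`corstr = "ou"`), the same
#'   OU-transformed tree correlation with its decay estimated from the
#'   Pearson residuals; `corstr = "brownian"` forces the full Brownian
#'   correlation and `corstr = "identity"` gives coefficients coinciding
#'   with an ordinary Poisson GLM. Standard errors are model-based, scaled
#'   by the Pearson dispersion, which is returned in the `alpha` slot as
#'   the working-correlation scale (the estimated decay is in
#'   `cor_alpha`). The phylogeny forms a single cluster, so no sandwich
#'   estimator is available; estimating the correlation decay rather than
#'   imposing it is what keeps these model-based SEs honest.
#'
#' Rows of `data` are matched to tree tips through `species` (default:
#' column `species_id`, else row names); the tree is pruned to the data.
#'
#' @param formula model formula, e.g. `declining ~ diel_niche`.
#' @param data data.frame of tip covariates.
#' @param tree rooted `phylo` with branch lengths covering all data species.
#' @param family `"binomial"` or `"poisson"`.
#' @param species column of `data` holding tip labels (default
#'   `"species_id"`; row names used if absent).
#' @param corstr working correlation for the Poisson GEE.
#' @param alpha_bounds search interval for the signal parameter of the
#'   binary model, on a tree rescaled to unit depth.
#' @param tol convergence tolerance on the penalised score norm.
#' @param maxit maximum Newton iterations per inner fit.
#' @param model_id optional label carried into serialised output.
#' @return object of class `phylo_glm` with components `coefficients`,
#'   `se`, `p_values`, `alpha`, `pseudo_r2` (McFadden; Nagelkerke variant
#'   in `pseudo_r2_nagelkerke`), `n_obs`, `converged`, `degenerate`,
#'   `fitted`, `logLik_model`, `logLik_null`.
#' @examples
#' tr <- ape::rphylo(60, 1, 0)
#' d <- data.frame(species_id = tr$tip.label,
#'                 x = rnorm(60))
#' d$y <- rbinom(60, 1, plogis(-0.5 + d$x))
#' fit <- phylo_glm(y ~ x, d, tr, family = "binomial")
#' coef(fit)
#' @export
phylo_glm <- function(formula, data, tree,
                      family = c("binomial", "poisson"),
                      species = "species_id",
                      corstr = c("ou", "brownian", "identity"),
                      alpha_bounds = c(0.01, 50), tol = 1e-8, maxit = 100L,
                      model_id = NULL) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  al <- .align_tree_data(tree, data, species)
  mf <- stats::model.frame(formula, al$data)
  mf <- droplevels(mf)  # an empty factor level would give a singular design
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)

  fit <- if (family == "binomial") {
    .fit_logistic_mple(y, X, al$tree, alpha_bounds, tol, maxit)
  } else {
    .fit_poisson_gee(y, X, al$tree, corstr, tol, maxit)
  }
  fit$call <- match.call()
  fit$formula <- formula
  fit$family <- family
  fit$species <- al$data[[al$species_col]] %||% rownames(al$data)
  fit$model_id <- model_id %||% paste0("phylo_", family)
  class(fit) <- "phylo_glm"
  fit
}

# match data rows to tree tips; prune tree; order data as tips
.align_tree_data <- function(tree, data, species = "species_id") {
  ids <- if (species %in% names(data)) normalize_label(data[[species]])
         else normalize_label(rownames(data))
  if (anyDuplicated(ids)) stop("duplicate species in data", call. = FALSE)
  tips <- normalize_label(tree$tip.label)
  tree$tip.label <- tips
  missing <- setdiff(ids, tips)
  if (length(missing))
    stop("species absent from tree: ", paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "", call. = FALSE)
  if (length(ids) < length(tips)) tree <- ape::keep.tip(tree, ids)
  data <- data[match(tree$tip.label, ids), , drop = FALSE]
  list(tree = tree, data = data,
       species_col = if (species %in% names(data)) species else NULL)
}

# OU-transformed correlation on a unit-depth tree; identity on a star tree
.ou_correlation <- function(C, alpha) .ou_cor_cached(.ou_cache(C), alpha)

# precompute the alpha-independent pieces (patristic distances)
.ou_cache <- function(C) {
  Tdep <- diag(C)
  list(C = C, Tdep = Tdep, d = outer(Tdep, Tdep, "+") - 2 * C)
}

.ou_cor_cached <- function(cache, alpha) {
  vi <- -expm1(-2 * alpha * cache$Tdep)      # 1 - exp(-2 a T_i)
  R <- exp(-alpha * cache$d) * (-expm1(-2 * alpha * cache$C)) /
    sqrt(outer(vi, vi))
  diag(R) <- 1
  R
}

.chol_solve <- function(R) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(R + diag(1e-8, nrow(R)))
  ch
}

# penalised GEE Newton step machinery shared by both families
# returns beta, score norm, working information M, mu
.pen_score_fit <- function(y, X, Rchol, linkinv, varfun, dmu,
                           firth = TRUE, beta0 = NULL, tol = 1e-8,
                           maxit = 100L) {
  p <- ncol(X)
  beta <- beta0 %||% numeric(p)
  score <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- linkinv(eta)
    A <- varfun(mu)               # Var(y)
    D <- dmu(mu)                  # d mu / d eta
    w <- D / sqrt(A)              # A^{-1/2} Delta
    Xa <- X * w                   # R^{-1} applied next
    RiXa <- backsolve(Rchol, backsolve(Rchol, Xa, transpose = TRUE))
    M <- crossprod(Xa, RiXa)
    r <- (y - mu) / sqrt(A)
    g <- crossprod(Xa, backsolve(Rchol, backsolve(Rchol, r, transpose = TRUE)))
    if (firth) {
      Minv <- solve(M)
      u <- rowSums((RiXa %*% Minv) * X)
      # d(A^{1/2})/dbeta term of 0.5 d log det M (logistic: A = D)
      s <- 0.5 * sqrt(A) * (1 - 2 * mu)
      g <- g + crossprod(X, s * u)
    }
    list(g = drop(g), M = M, mu = mu, eta = eta)
  }
  st <- tryCatch(score(beta), error = function(e) NULL)
  if (is.null(st) || !all(is.finite(st$g)))
    return(list(beta = beta, M = diag(p), mu = rep(NA_real_, length(y)),
                score_norm = Inf, converged = FALSE))
  gn <- max(abs(st$g))
  ok <- FALSE
  for (it in seq_len(maxit)) {
    if (gn < tol) { ok <- TRUE; break }
    step <- tryCatch(drop(solve(st$M, st$g)), error = function(e) NULL)
    if (is.null(step)) break  # singular working information: flag, not fail
    lam <- 1
    repeat {
      cand <- beta + lam * step
      stc <- tryCatch(score(cand), error = function(e) NULL)
      if (!is.null(stc) && all(is.finite(stc$g)) &&
          max(abs(stc$g)) < gn * (1 + 1e-8)) break
      lam <- lam / 2
      if (lam < 1e-10) { stc <- st; cand <- beta; break }
    }
    if (identical(cand, beta)) break
    beta <- cand; st <- stc; gn <- max(abs(st$g))
  }
  if (gn < tol) ok <- TRUE
  list(beta = beta, M = st$M, mu = st$mu, score_norm = gn, converged = ok)
}

# Gaussian profile pseudo-loglik of standardised working residuals
.alpha_profile <- function(r, cache, alpha) {
  R <- .ou_cor_cached(cache, alpha)
  ch <- .chol_solve(R)
  z <- backsolve(ch, r, transpose = TRUE)
  n <- length(r)
  phi <- sum(z^2) / n
  -0.5 * (n * log(phi) + 2 * sum(log(diag(ch))))
}

.fit_logistic_mple <- function(y, X, tree, alpha_bounds, tol, maxit) {
  n <- length(y)
  base <- list(coefficients = setNames(rep(NA_real_, ncol(X)), colnames(X)),
               se = setNames(rep(NA_real_, ncol(X)), colnames(X)),
               p_values = setNames(rep(NA_real_, ncol(X)), colnames(X)),
               alpha = NA_real_, pseudo_r2 = NA_real_,
               pseudo_r2_nagelkerke = NA_real_, n_obs = n,
               converged = FALSE, degenerate = FALSE, method = "logistic_mple")
  if (length(unique(y)) < 2L) {
    warning("constant response: degenerate logistic fit")
    base$degenerate <- TRUE
    return(base)
  }
  C <- build_vcv(tree)
  C <- C / max(diag(C))
  cache <- .ou_cache(C)
  lb <- log(alpha_bounds)

  alpha <- 1
  beta <- NULL
  inner <- NULL
  for (outer_it in 1:50) {
    R <- .ou_cor_cached(cache, alpha)
    ch <- .chol_solve(R)
    inner <- .pen_score_fit(y, X, ch, plogis,
                            varfun = function(m) m * (1 - m),
                            dmu = function(m) m * (1 - m),
                            firth = TRUE, beta0 = beta, tol = tol,
                            maxit = maxit)
    beta <- inner$beta
    r <- (y - inner$mu) / sqrt(inner$mu * (1 - inner$mu))
    opt <- optimize(function(la) .alpha_profile(r, cache, exp(la)),
                    interval = lb, maximum = TRUE, tol = 1e-6)
    alpha_new <- exp(opt$maximum)
    done <- abs(log(alpha_new) - log(alpha)) < 1e-5
    alpha <- alpha_new
    if (done) break
  }
  # The upper bound is the independence limit: the boundary model is an
  # ordinary Firth-penalised logistic fit and is accepted as converged.
  # A lower-bound hit (maximal signal) with a non-vanishing profile slope
  # means the signal parameter ran away and the fit is flagged.
  at_lower <- abs(log(alpha) - lb[1]) < 1e-3
  slope_ok <- TRUE
  if (at_lower) {
    r <- (y - inner$mu) / sqrt(inner$mu * (1 - inner$mu))
    eps <- 1e-3
    la <- log(alpha)
    s <- (.alpha_profile(r, cache, exp(la + eps)) -
          .alpha_profile(r, cache, exp(la))) / eps
    slope_ok <- s > -1e-2  # profile not still improving downhill
  }
  R <- .ou_cor_cached(cache, alpha)
  ch <- .chol_solve(R)
  inner <- .pen_score_fit(y, X, ch, plogis,
                          varfun = function(m) m * (1 - m),
                          dmu = function(m) m * (1 - m),
                          firth = TRUE, beta0 = beta, tol = tol, maxit = maxit)
  beta <- inner$beta
  se <- tryCatch(sqrt(diag(solve(inner$M))),
                 error = function(e) rep(NA_real_, ncol(X)))
  z <- beta / se
  mu <- pmin(pmax(inner$mu, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  null <- .null_loglik_logistic(y, cache, alpha, tol, maxit)
  pr2 <- .pseudo_r2_pair(ll, null$ll, n)
  list(coefficients = setNames(beta, colnames(X)),
       se = setNames(se, colnames(X)),
       p_values = setNames(2 * pnorm(-abs(z)), colnames(X)),
       alpha = alpha, pseudo_r2 = pr2$mcfadden,
       pseudo_r2_nagelkerke = pr2$nagelkerke,
       n_obs = n, converged = inner$converged && slope_ok &&
         all(is.finite(se)),
       degenerate = FALSE, method = "logistic_mple",
       fitted = inner$mu, residuals = y - inner$mu,
       vcov = tryCatch(solve(inner$M), error = function(e) NULL),
       logLik_model = ll, logLik_null = null$ll,
       y = y, X = X)
}

# intercept-only fit evaluated at the model's signal parameter, so the
# likelihood-ratio pseudo-R2 compares nested means under one correlation
.null_loglik_logistic <- function(y, cache, alpha, tol, maxit) {
  X0 <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  ch <- .chol_solve(.ou_cor_cached(cache, alpha))
  f <- .pen_score_fit(y, X0, ch, plogis, function(m) m * (1 - m),
                      function(m) m * (1 - m), TRUE, NULL, tol, maxit)
  list(ll = sum(y * log(f$mu) + (1 - y) * log(1 - f$mu)), alpha = alpha)
}

.fit_poisson_gee <- function(y, X, tree, corstr, tol, maxit,
                             alpha_bounds = c(0.01, 50)) {
  n <- length(y)
  base <- list(coefficients = setNames(rep(NA_real_, ncol(X)), colnames(X)),
               se = setNames(rep(NA_real_, ncol(X)), colnames(X)),
               p_values = setNames(rep(NA_real_, ncol(X)), colnames(X)),
               alpha = NA_real_, pseudo_r2 = NA_real_,
               pseudo_r2_nagelkerke = NA_real_, n_obs = n,
               converged = FALSE, degenerate = FALSE, method = "poisson_gee")
  if (all(y == 0)) {
    warning("all-zero response: degenerate Poisson fit")
    base$degenerate <- TRUE
    return(base)
  }
  beta0 <- c(log(mean(y) + 1e-8), rep(0, ncol(X) - 1L))
  if (corstr == "ou") {
    # estimate the correlation decay from the data, as the binary model
    # does: a forced full-Brownian correlation distorts the model-based
    # SEs whenever the residuals carry little phylogenetic signal
    C <- build_vcv(tree)
    C <- C / max(diag(C))
    cache <- .ou_cache(C)
    lb <- log(alpha_bounds)
    alphac <- 1; beta <- beta0; fit <- NULL; ch <- NULL
    for (i in 1:50) {
      ch <- .chol_solve(.ou_cor_cached(cache, alphac))
      fit <- .pen_score_fit(y, X, ch, exp, varfun = function(m) m,
                            dmu = function(m) m, firth = FALSE,
                            beta0 = beta, tol = tol, maxit = maxit)
      beta <- fit$beta
      r <- (y - fit$mu) / sqrt(fit$mu)
      a2 <- exp(optimize(function(la) .alpha_profile(r, cache, exp(la)),
                         interval = lb, maximum = TRUE, tol = 1e-6)$maximum)
      done <- abs(log(a2) - log(alphac)) < 1e-5
      alphac <- a2
      if (done) break
    }
    ch <- .chol_solve(.ou_cor_cached(cache, alphac))
    fit <- .pen_score_fit(y, X, ch, exp, function(m) m, function(m) m,
                          FALSE, beta, tol, maxit)
  } else {
    R <- if (corstr == "identity") diag(n) else {
      C <- build_vcv(tree); stats::cov2cor(C)
    }
    alphac <- NA_real_
    ch <- .chol_solve(R)
    fit <- .pen_score_fit(y, X, ch, exp, varfun = function(m) m,
                          dmu = function(m) m, firth = FALSE, beta0 = beta0,
                          tol = tol, maxit = maxit)
  }
  p <- ncol(X)
  phi <- sum((y - fit$mu)^2 / pmax(fit$mu, 1e-12)) / (n - p)
  se <- tryCatch(sqrt(phi * diag(solve(fit$M))),
                 error = function(e) rep(NA_real_, ncol(X)))
  z <- fit$beta / se
  ll <- sum(stats::dpois(y, fit$mu, log = TRUE))
  f0 <- .pen_score_fit(y, matrix(1, n, 1), ch, exp, function(m) m,
                       function(m) m, FALSE, log(mean(y)), tol, maxit)
  ll0 <- sum(stats::dpois(y, f0$mu, log = TRUE))
  pr2 <- .pseudo_r2_pair(ll, ll0, n)
  list(coefficients = setNames(fit$beta, colnames(X)),
       se = setNames(se, colnames(X)),
       p_values = setNames(2 * pnorm(-abs(z)), colnames(X)),
       alpha = phi, pseudo_r2 = pr2$mcfadden,
       pseudo_r2_nagelkerke = pr2$nagelkerke,
       n_obs = n, converged = fit$converged && all(is.finite(se)),
       degenerate = FALSE,
       method = "poisson_gee", fitted = fit$mu, residuals = y - fit$mu,
       vcov = tryCatch(phi * solve(fit$M), error = function(e) NULL),
       logLik_model = ll, logLik_null = ll0,
       cor_alpha = alphac, y = y, X = X, corstr = corstr)
}

#' Likelihood-ratio pseudo-R-squared
#'
#' McFadden's `1 - l1/l0` (default elsewhere in the package) and the
#' Nagelkerke-rescaled likelihood-ratio variant, computed from a model and
#' its intercept-only null on the working (independence) likelihood.
#'
#' @param fit,null_fit `phylo_glm` fits on the same data (null =
#'   intercept-only), or pass log-likelihoods directly.
#' @return named list `mcfadden`, `nagelkerke`, both in \[0, 1).
#' @export
pseudo_r2 <- function(fit, null_fit) {
  .pseudo_r2_pair(fit$logLik_model, null_fit$logLik_model, fit$n_obs)
}

.pseudo_r2_pair <- function(ll1, ll0, n) {
  # weighted-score fits can leave the independence log-likelihood a hair
  # below the null's; only a material gap is worth flagging
  if (ll1 < ll0 - 0.01)
    warning("model likelihood below null likelihood; pseudo-R2 clipped at 0")
  mcf <- max(0, 1 - ll1 / ll0)
  cs <- 1 - exp(2 * (ll0 - ll1) / n)
  nag <- max(0, cs / (1 - exp(2 * ll0 / n)))
  list(mcfadden = min(mcf, 1 - 1e-12), nagelkerke = min(nag, 1 - 1e-12))
}

#' @export
print.phylo_glm <- function(x, ...) {
  cat("Phylogenetic", if (x$method == "logistic_mple")
    "logistic regression (MPLE)" else "Poisson GEE",
    "-", x$n_obs, "species\n")
  if (x$degenerate) { cat("  degenerate fit (constant response)\n"); return(invisible(x)) }
  print(round(x$coefficients, 4))
  cat(if (x$method == "logistic_mple") "alpha:" else "dispersion:",
      format(x$alpha, digits = 4),
      " pseudo-R2 (McFadden):", format(x$pseudo_r2, digits = 3),
      if (!x$converged) " [not converged]" else "", "\n")
  invisible(x)
}

#' @export
summary.phylo_glm <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$coefficients / object$se,
               `Pr(>|z|)` = object$p_values)
  out <- list(call = object$call, table = tab, alpha = object$alpha,
              pseudo_r2 = object$pseudo_r2, n_obs = object$n_obs,
              converged = object$converged, method = object$method)
  class(out) <- "summary.phylo_glm"
  out
}

#' @export
print.summary.phylo_glm <- function(x, ...) {
  cat("Call: "); print(x$call)
  stats::printCoefmat(x$table, P.values = TRUE, has.Pvalue = TRUE)
  cat("\n", if (x$method == "logistic_mple") "alpha (signal):" else "dispersion:",
      format(x$alpha, digits = 4),
      "  pseudo-R2:", format(x$pseudo_r2, digits = 3),
      "  n =", x$n_obs, "\n")
  invisible(x)
}

#' @export
coef.phylo_glm <- function(object, ...) object$coefficients

#' @export
vcov.phylo_glm <- function(object, ...) object$vcov

#' @export
residuals.phylo_glm <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "pearson") {
    v <- if (object$method == "logistic_mple")
      object$fitted * (1 - object$fitted) else object$fitted
    r <- r / sqrt(v)
  }
  r
}

#' @export
predict.phylo_glm <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- drop(object$X %*% object$coefficients)
  } else {
    X <- stats::model.matrix(stats::delete.response(terms(object$formula)),
                             newdata)
    eta <- drop(X %*% object$coefficients[colnames(X)])
  }
  if (type == "link") return(eta)
  if (object$method == "logistic_mple") plogis(eta) else exp(eta)
}

#' @export
simulate.phylo_glm <- function(object, nsim = 1, seed = NULL, ...) {
  # draws from the fitted marginal distribution (correlation enters the
  # estimator as a working model only)
  with_seed(seed, {
    mu <- object$fitted
    out <- replicate(nsim, if (object$method == "logistic_mple")
      rbinom(length(mu), 1, mu) else rpois(length(mu), mu))
    as.data.frame(out)
  })
}

#' @export
plot.phylo_glm <- function(x, ...) {
  est <- x$coefficients; se <- x$se
  lo <- est - 1.96 * se; hi <- est + 1.96 * se
  idx <- seq_along(est)
  graphics::plot(est, idx, xlim = range(lo, hi), yaxt = "n",
                 xlab = "estimate (95% Wald CI)", ylab = "", pch = 19, ...)
  graphics::axis(2, at = idx, labels = names(est), las = 1)
  graphics::segments(lo, idx, hi, idx)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Serialise a fit to a flat table
#'
#' One row per term: estimate, SE, p, plus the fit-level signal/scale
#' parameter, pseudo-R2, n and convergence flag.
#'
#' @param fit a `phylo_glm`.
#' @return data.frame ready for `write.csv`.
#' @export
serialize_fit <- function(fit) {
  data.frame(model_id = fit$model_id %||% fit$method,
             term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$se), p = unname(fit$p_values),
             alpha = fit$alpha, pseudo_r2 = fit$pseudo_r2,
             n = fit$n_obs, converged = fit$converged,
             stringsAsFactors = FALSE)
}
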