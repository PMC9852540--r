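#' Fit an Mk model of discrete-trait evolution
#'
#' Maximum-likelihood fit of a continuous-time Markov (Mk) model for a
#' discrete tip trait by Felsenstein's pruning algorithm. Tips with missing
#' state enter as uninformative (all-ones partial likelihoods), so the fit
#' uses the observed tips only while the returned posteriors give each
#' missing tip's marginal state probabilities — the basis for phylogenetic
#' imputation of diel niche.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tip_states named character vector over `tree$tip.label`; `NA`
#'   marks missing tips.
#' @param model `"ER"` (equal rates, one parameter, default) or `"ARD"`
#'   (all rates different).
#' @param states state space; defaults to the sorted unique observed states
#'   (use [diel_levels()] to force the full niche order).
#' @return object of class `mk_fit`: `states`, `Q` (rows sum to 0),
#'   `log_likelihood`, `pi` (uniform root prior), `tip_posteriors` (matrix,
#'   missing tips x states, rows sum to 1), `converged`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' fit <- fit_mk(tr, c(A = "x", B = "x", C = "y", D = NA))
#' fit$tip_posteriors
#' @export
fit_mk <- function(tree, tip_states, model = c("ER", "ARD"), states = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree) && tree$Nnode > 1L)
    stop("tree must be rooted", call. = FALSE)
  tip_states <- tip_states[tree$tip.label]
  if (any(is.na(names(tip_states))))
    stop("tip_states must be named by tree tip labels", call. = FALSE)
  obs <- tip_states[!is.na(tip_states)]
  if (is.null(states)) states <- sort(unique(obs))
  if (!all(obs %in% states)) stop("observed state outside state space", call. = FALSE)
  k <- length(states)
  if (length(unique(obs)) < 2L) {
    warning("fewer than two observed states: degenerate fit, rate 0")
    Q <- matrix(0, k, k, dimnames = list(states, states))
    post <- matrix(0, sum(is.na(tip_states)), k,
                   dimnames = list(names(tip_states)[is.na(tip_states)], states))
    if (length(obs)) post[, unique(obs)[1L]] <- 1 else post[] <- 1 / k
    return(structure(list(states = states, Q = Q, log_likelihood = 0,
                          pi = rep(1 / k, k), tip_posteriors = post,
                          model = model, converged = TRUE), class = "mk_fit"))
  }

  pi <- rep(1 / k, k)
  ll_er <- function(logq) mk_loglik(tree, tip_states, states,
                                    .Q_er(exp(logq), k, states), pi)
  opt <- optimize(ll_er, interval = c(-12, 8), maximum = TRUE, tol = 1e-8)
  Q <- .Q_er(exp(opt$maximum), k, states)
  ll <- opt$objective
  converged <- TRUE

  if (model == "ARD") {
    np <- k * (k - 1L)
    f <- function(lp) -mk_loglik(tree, tip_states, states,
                                 .Q_ard(exp(lp), k, states), pi)
    o <- optim(rep(opt$maximum, np), f, method = "L-BFGS-B",
               lower = -12, upper = 8, control = list(maxit = 500))
    Q <- .Q_ard(exp(o$par), k, states)
    ll <- -o$value
    converged <- o$convergence == 0
  }

  post <- .mk_tip_posteriors(tree, tip_states, states, Q, pi)
  structure(list(states = states, Q = Q, log_likelihood = ll, pi = pi,
                 tip_posteriors = post, model = model, converged = converged),
            class = "mk_fit")
}

#' Mk log-likelihood by pruning
#'
#' @param tree rooted `phylo`.
#' @param tip_states named states with `NA` for missing tips.
#' @param states state space.
#' @param Q rate matrix (off-diagonals >= 0, rows summing to 0).
#' @param pi root state prior (default uniform).
#' @return log-likelihood of the observed tip states.
#' @export
mk_loglik <- function(tree, tip_states, states, Q,
                      pi = rep(1 / length(states), length(states))) {
  up <- .mk_up_pass(tree, tip_states, states, Q)
  root <- ape::Ntip(tree) + 1L
  log(sum(pi * up$L[root, ])) + up$logscale
}

# ER rate matrix
.Q_er <- function(q, k, states) {
  Q <- matrix(q, k, k, dimnames = list(states, states))
  diag(Q) <- -(k - 1) * q
  Q
}

# ARD rate matrix from off-diagonal rates (row-wise order)
.Q_ard <- function(rates, k, states) {
  Q <- matrix(0, k, k, dimnames = list(states, states))
  Q[row(Q) != col(Q)] <- 0  # fill row-wise below
  idx <- 1L
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    Q[i, j] <- rates[idx]; idx <- idx + 1L
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# transition probability matrix exp(Q t); closed form for ER, eigen otherwise
.mk_pmat <- function(Q, t) {
  k <- nrow(Q)
  offs <- Q[row(Q) != col(Q)]
  if (length(unique(round(offs, 14))) == 1L) {
    q <- offs[1L]
    ekqt <- exp(-k * q * t)
    P <- matrix((1 - ekqt) / k, k, k)
    diag(P) <- (1 + (k - 1) * ekqt) / k
  } else {
    e <- eigen(Q)
    P <- Re(e$vectors %*% diag(exp(e$values * t), k) %*% solve(e$vectors))
    P[P < 0] <- 0
    P <- P / rowSums(P)
  }
  dimnames(P) <- dimnames(Q)
  P
}

# post-order conditional likelihoods with per-node rescaling
.mk_up_pass <- function(tree, tip_states, states, Q) {
  k <- length(states)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  tree_po <- ape::reorder.phylo(tree, "postorder")
  L <- matrix(1, nnode, k)
  for (i in seq_len(ntip)) {
    s <- tip_states[tree$tip.label[i]]
    if (!is.na(s)) L[i, ] <- as.numeric(states == s)
  }
  logscale <- 0
  # cache per-edge P matrices keyed by branch length
  Pm <- lapply(tree_po$edge.length, function(t) .mk_pmat(Q, t))
  edge <- tree_po$edge
  done <- rep(FALSE, nnode)
  for (e in seq_len(nrow(edge))) {
    child <- edge[e, 2L]
    parent <- edge[e, 1L]
    msg <- as.vector(Pm[[e]] %*% L[child, ])
    L[parent, ] <- L[parent, ] * msg
    if (!done[parent]) done[parent] <- TRUE
    m <- max(L[parent, ])
    if (m < 1e-40) m <- max(m, .Machine$double.xmin)
    if (m < 1e-10) { L[parent, ] <- L[parent, ] / m; logscale <- logscale + log(m) }
  }
  list(L = L, logscale = logscale, edge = edge, Pm = Pm)
}

# marginal state posteriors at missing tips (up-down algorithm)
.mk_tip_posteriors <- function(tree, tip_states, states, Q, pi) {
  k <- length(states)
  ntip <- ape::Ntip(tree)
  up <- .mk_up_pass(tree, tip_states, states, Q)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  D <- matrix(NA_real_, nnode, k)
  D[root, ] <- pi
  edge <- up$edge
  # pre-order: parents before children
  for (e in rev(seq_len(nrow(edge)))) {
    parent <- edge[e, 1L]; child <- edge[e, 2L]
    # message into parent from all children except this one
    sib_msg <- rep(1, k)
    sibs <- which(edge[, 1L] == parent & edge[, 2L] != child)
    for (se in sibs)
      sib_msg <- sib_msg * as.vector(up$Pm[[se]] %*% up$L[edge[se, 2L], ])
    above <- D[parent, ] * sib_msg
    D[child, ] <- as.vector(t(up$Pm[[e]]) %*% above)
    s <- sum(D[child, ])
    if (s > 0) D[child, ] <- D[child, ] / s
  }
  miss <- which(is.na(tip_states[tree$tip.label]))
  post <- matrix(NA_real_, length(miss), k,
                 dimnames = list(tree$tip.label[miss], states))
  for (j in seq_along(miss)) {
    i <- miss[j]
    p <- D[i, ] * up$L[i, ]  # L is all ones at a missing tip
    post[j, ] <- p / sum(p)
  }
  post
}

#' Impute missing tip states from an Mk fit
#'
#' Assigns each missing tip its maximum-posterior state; exact ties are
#' broken by the fixed order of `fit$states` and flagged.
#'
#' @param fit an `mk_fit`.
#' @param rule only `"max_posterior"` is implemented.
#' @return data.frame with `species_id`, `state`, `max_posterior`, `tie`.
#' @export
impute_tips <- function(fit, rule = "max_posterior") {
  rule <- match.arg(rule, "max_posterior")
  post <- fit$tip_posteriors
  if (!nrow(post))
    return(data.frame(species_id = character(), state = character(),
                      max_posterior = numeric(), tie = logical()))
  mx <- apply(post, 1L, max)
  pick <- apply(post, 1L, function(p) which(p >= max(p) - 1e-12)[1L])
  tie <- apply(post, 1L, function(p) sum(p >= max(p) - 1e-12) > 1L)
  if (any(tie))
    message(sum(tie), " tie(s) broken by state order")
  data.frame(species_id = rownames(post), state = fit$states[pick],
             max_posterior = mx, tie = tie, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk", x$model, "fit:", length(x$states), "states, logLik",
      format(x$log_likelihood, digits = 6), "\n")
  cat("rates (off-diagonal):",
      format(unique(round(x$Q[row(x$Q) != col(x$Q)], 8))), "\n")
  if (nrow(x$tip_posteriors))
    cat(nrow(x$tip_posteriors), "missing tip(s) with posteriors\n")
  invisible(x)
}
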