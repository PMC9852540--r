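# Independent oracles used across the suite. Each is deliberately coded by
# a different route than the implementation it checks.

# Firth-penalised logistic by direct BFGS maximisation of
# l(beta) + 0.5 log det(X' W X)  (implementation uses penalised score Newton)
firth_logistic_oracle <- function(y, X) {
  obj <- function(b) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    M <- crossprod(X, X * (mu * (1 - mu)))
    -(sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(M)$modulus)
  }
  optim(rep(0, ncol(X)), obj, method = "BFGS",
        control = list(maxit = 1000, reltol = 1e-14))$par
}

# Mk likelihood by exhaustive summation over every internal-state assignment
enum_mk_loglik <- function(tree, tip_states, states,
                           Q, pi = rep(1 / length(states), length(states))) {
  k <- length(states)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    E <- eigen(Q)
    Re(E$vectors %*% diag(exp(E$values * tree$edge.length[e]), k) %*%
         solve(E$vectors))
  })
  grid <- expand.grid(rep(list(seq_len(k)), nnode))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    assign_int <- as.integer(grid[g, ])
    pr <- pi[assign_int[1L]]  # node ntip+1 is the root
    for (e in seq_len(nrow(tree$edge))) {
      from <- assign_int[tree$edge[e, 1L] - ntip]
      ch <- tree$edge[e, 2L]
      pr <- pr * if (ch <= ntip) {
        s <- tip_states[tree$tip.label[ch]]
        if (is.na(s)) 1 else P[[e]][from, match(s, states)]
      } else P[[e]][from, assign_int[ch - ntip]]
    }
    tot <- tot + pr
  }
  log(tot)
}

# shared-path covariance by explicit per-pair path enumeration
vcv_path_oracle <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nnode)
  plen <- rep(NA_real_, nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2L]] <- tree$edge[e, 1L]
    plen[tree$edge[e, 2L]] <- tree$edge.length[e]
  }
  root <- ntip + 1L
  chain <- function(i) {  # ancestors from node to root, with depths
    path <- i
    while (!is.na(parent[i])) { i <- parent[i]; path <- c(path, i) }
    path
  }
  depth <- rep(0, nnode)
  for (i in seq_len(nnode)) {
    p <- chain(i)
    depth[i] <- sum(plen[p[-length(p)]])
  }
  C <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    common <- intersect(chain(i), chain(j))
    C[i, j] <- max(depth[common])
  }
  diag(C) <- depth[seq_len(ntip)]
  C
}

# decline-proportion layers by naive per-pixel, per-species loops
brute_decline_raster <- function(stack, records, niche, threat,
                                 overrides = NULL, country_raster = NULL,
                                 mask_mode = "richness", thr = 5L) {
  g <- stack$grid
  tc <- paste0("threat_", threat)
  prop <- matrix(NA_real_, g$nrows, g$ncols)
  numer <- denom <- matrix(0L, g$nrows, g$ncols)
  for (r in seq_len(g$nrows)) for (cc in seq_len(g$ncols)) {
    cell <- (r - 1L) * g$ncols + cc
    nd <- 0L; nn <- 0L
    for (sp in rownames(stack$presence)) {
      if (stack$presence[sp, cell] != 1L) next
      rec <- records[records$species_id == sp, ]
      if (is.na(rec$diel_niche) || rec$diel_niche != niche) next
      nd <- nd + 1L
      dec <- rec$trend_class == "declining" && isTRUE(rec$threats_known) &&
        !is.na(rec[[tc]]) && rec[[tc]] == 1L
      if (dec && !is.null(overrides)) {
        ccode <- country_raster[r, cc]
        if (any(overrides$species_id == sp &
                  overrides$country_code == ccode)) dec <- FALSE
      }
      if (dec) nn <- nn + 1L
    }
    denom[r, cc] <- nd; numer[r, cc] <- nn
    masked <- if (mask_mode == "richness") nd <= thr else nn <= thr
    if (!masked) prop[r, cc] <- nn / nd
  }
  list(proportion = prop, numerator = numer, denominator = denom)
}

# minimal valid species table for classification tests
make_records <- function(n = 10, niche = "nocturnal", category = "LC",
                         trend = "unknown", lit = "unknown") {
  df <- data.frame(
    species_id = paste0("sp", seq_len(n)),
    binomial = paste("Genus sp", seq_len(n)),
    order = "Rodentia",
    diel_niche = niche,
    iucn_category = category,
    iucn_trend = trend,
    literature_trend = lit,
    is_marine = FALSE,
    is_fossorial = FALSE,
    body_mass_kg = 1,
    stringsAsFactors = FALSE)
  for (tc in paste0("threat_", threat_categories())) df[[tc]] <- 0L
  validate_species_table(df)
}

# small deterministic study bundle shared by heavier tests
small_bundle <- function(n = 150, seed = 42, ...) {
  cfg <- synth_config(n_species = n, seed = seed, n_trees = 3,
                      grid = grid_spec(12, 12), ...)
  tree <- sim_tree(cfg)
  list(cfg = cfg, tree = tree,
       trees = sim_ensemble(tree, cfg),
       records = sim_traits_and_trends(tree, cfg))
}
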