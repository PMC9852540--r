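# shared fixtures: a star phylogeny (no shared history) and a deterministic
# niche layout
star_fixture <- function(n = 100, seed = 1, p_base = 0.4, diurnal_eff = 0.7) {
  set.seed(seed)
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, n)
  d <- data.frame(
    species_id = star$tip.label,
    niche = factor(sample(diel_levels(), n, TRUE, c(.55, .1, .15, .2)),
                   levels = diel_levels()))
  d$y <- rbinom(n, 1, plogis(qlogis(p_base) +
                               diurnal_eff * (d$niche == "diurnal")))
  list(tree = star, data = d)
}

test_that("logistic MPLE on a star phylogeny equals independent Firth logistic", {
  for (seed in c(1, 2)) {
    fx <- star_fixture(120, seed)
    fit <- phylo_glm(y ~ niche, fx$data, fx$tree, family = "binomial")
    X <- model.matrix(~niche, droplevels(fx$data))
    oracle <- firth_logistic_oracle(fx$data$y, X)
    expect_lt(max(abs(coef(fit) - oracle)), 1e-4)
    expect_true(fit$converged)
  }
})

test_that("penalisation keeps estimates finite under complete separation", {
  fx <- star_fixture(90, 3)
  fx$data$y[fx$data$niche == "crepuscular"] <- 1
  fit <- phylo_glm(y ~ niche, fx$data, fx$tree, family = "binomial")
  expect_true(all(is.finite(coef(fit))))
  expect_true(all(is.finite(fit$se)))
  expect_lt(max(abs(coef(fit))), 10)
})

test_that("balanced identical outcomes across niches give zero niche effects", {
  star <- ape::stree(80, "star")
  star$edge.length <- rep(1, 80)
  d <- data.frame(species_id = star$tip.label,
                  niche = factor(rep(diel_levels(), each = 20),
                                 levels = diel_levels()),
                  y = rep(c(rep(1, 10), rep(0, 10)), 4))
  fit <- phylo_glm(y ~ niche, d, star, family = "binomial")
  expect_equal(unname(coef(fit)[-1]), rep(0, 3), tolerance = 1e-6)
})

test_that("constant responses yield flagged degenerate no-fits", {
  fx <- star_fixture(30, 4)
  fx$data$y <- 1
  expect_warning(fit <- phylo_glm(y ~ niche, fx$data, fx$tree,
                                  family = "binomial"), "degenerate")
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  fx$data$k <- 0
  expect_warning(pfit <- phylo_glm(k ~ niche, fx$data, fx$tree,
                                   family = "poisson"), "degenerate")
  expect_true(pfit$degenerate)
})

test_that("Poisson GEE with identity working correlation matches an ordinary GLM", {
  set.seed(5)
  tr <- ape::rphylo(90, 1, 0.3)
  d <- data.frame(species_id = tr$tip.label,
                  niche = factor(sample(diel_levels(), 90, TRUE),
                                 levels = diel_levels()))
  d$k <- rpois(90, exp(0.4 + 0.3 * (d$niche == "diurnal")))
  fit <- phylo_glm(k ~ niche, d, tr, family = "poisson",
                   corstr = "identity")
  ref <- glm(k ~ niche, poisson, droplevels(d))
  expect_lt(max(abs(coef(fit) - coef(ref))), 1e-6)
})

test_that("intercept-only Poisson fit on constant counts returns log(c)", {
  set.seed(6)
  tr <- ape::rphylo(40, 1, 0.3)
  d <- data.frame(species_id = tr$tip.label, k = 3)
  fit <- phylo_glm(k ~ 1, d, tr, family = "poisson")
  expect_equal(unname(coef(fit)), log(3), tolerance = 1e-8)
})

test_that("fits are invariant to row permutations of the data", {
  set.seed(8)
  tr <- ape::rphylo(60, 1, 0.3)
  d <- data.frame(species_id = tr$tip.label,
                  niche = factor(sample(diel_levels(), 60, TRUE),
                                 levels = diel_levels()))
  d$y <- rbinom(60, 1, 0.45)
  d$k <- rpois(60, 2)
  perm <- sample(60)
  for (fam in c("binomial", "poisson")) {
    resp <- if (fam == "binomial") "y" else "k"
    f1 <- phylo_glm(as.formula(paste(resp, "~ niche")), d, tr, family = fam)
    f2 <- phylo_glm(as.formula(paste(resp, "~ niche")), d[perm, ], tr,
                    family = fam)
    expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
    expect_equal(f1$se, f2$se, tolerance = 1e-8)
    expect_equal(f1$alpha, f2$alpha, tolerance = 1e-6)
  }
})

test_that("pseudo-R2 is bounded, zero for the null and ordered by effect size", {
  fits <- lapply(c(0, 2.5), function(eff) {
    fx <- star_fixture(150, 9, diurnal_eff = eff)
    phylo_glm(y ~ niche, fx$data, fx$tree, family = "binomial")
  })
  for (f in fits) {
    expect_gte(f$pseudo_r2, 0)
    expect_lt(f$pseudo_r2, 1)
  }
  expect_gt(fits[[2]]$pseudo_r2, fits[[1]]$pseudo_r2)
  # model identical to the null
  null_like <- fits[[1]]
  expect_equal(pseudo_r2(null_like, null_like)$mcfadden, 0, tolerance = 1e-9)
})

test_that("fit methods expose the standard modelling surface", {
  fx <- star_fixture(70, 10)
  fit <- phylo_glm(y ~ niche, fx$data, fx$tree, family = "binomial")
  expect_s3_class(fit, "phylo_glm")
  expect_named(coef(fit))
  expect_equal(dim(vcov(fit)), c(4, 4))
  expect_equal(length(predict(fit)), 70)
  expect_true(all(predict(fit) > 0 & predict(fit) < 1))
  expect_equal(predict(fit, type = "link"),
               qlogis(predict(fit, type = "response")), tolerance = 1e-10)
  expect_equal(length(residuals(fit, "pearson")), 70)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(70, 3))
  expect_true(all(unlist(sims) %in% 0:1))
  tab <- serialize_fit(fit)
  expect_equal(nrow(tab), 4)
  expect_named(tab, c("model_id", "term", "estimate", "se", "p", "alpha",
                      "pseudo_r2", "n", "converged"))
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("pseudo-R2", out)))
})

test_that("species absent from the tree are reported by name", {
  fx <- star_fixture(20, 11)
  fx$data$species_id[1] <- "not_in_tree"
  expect_error(phylo_glm(y ~ niche, fx$data, fx$tree, family = "binomial"),
               "not_in_tree")
})
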