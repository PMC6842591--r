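# Small fitting problems exercising the ML machinery; the full-scale
# parameter-recovery study lives in test-acceptance.R.

tiny_repertoire <- function(n_lineages = 3, n_tips = 3, n_codons = 30,
                            seed = 101, branch_scale = 0.4) {
  cfg <- sim_config(n_lineages = n_lineages,
                    clone_size_law = list(law = "fixed", n = n_tips),
                    n_codons = n_codons, branch_scale = branch_scale,
                    seed = seed)
  generate_repertoire_fixture(cfg)
}

test_that("the LRT threshold is half the chi-square quantile", {
  expect_equal(round(ci_threshold(0.05, 1), 2), 1.92)
  expect_equal(ci_threshold(0.05, 1), stats::qchisq(0.95, 1) / 2,
               tolerance = 1e-12)
  expect_equal(ci_threshold(0.05, 2), 2.9957, tolerance = 1e-4)
  expect_lt(ci_threshold(1 - 1e-9, 1), 1e-8)
  expect_error(ci_threshold(0, 1), "alpha")
  expect_error(ci_threshold(0.05, 0), "df")
  expect_error(ci_threshold(0.05, 1.5), "df")
})

test_that("profile search reproduces the Wald interval on a quadratic surface", {
  sigma <- 0.7
  mle <- 2.3
  llmax <- -100
  profile_fn <- function(theta) llmax - (theta - mle)^2 / (2 * sigma^2)
  thr <- ci_threshold(0.05, 1)
  lo <- bcrphylo:::profile_search_side(profile_fn, mle, llmax, thr, -50,
                                       1e-5, "lower")
  hi <- bcrphylo:::profile_search_side(profile_fn, mle, llmax, thr, 50,
                                       1e-5, "upper")
  half <- sigma * sqrt(2 * thr)  # = 1.96 sigma
  expect_false(lo$at_bound || hi$at_bound)
  expect_equal(lo$value, mle - half, tolerance = 1e-4)
  expect_equal(hi$value, mle + half, tolerance = 1e-4)
  # monotone profile runs into the bound and is flagged
  mono <- function(theta) llmax - 0.001 * (theta - mle)
  b <- bcrphylo:::profile_search_side(mono, mle, llmax, thr, 50, 1e-5, "upper")
  expect_true(b$at_bound)
  expect_identical(b$value, 50)
})

test_that("repertoire fit beats the generating parameters in likelihood", {
  rp <- tiny_repertoire()
  fit <- fit_repertoire(rp, model = "hlp19", tol = 0.01, max_rounds = 10)
  truth <- ref_params()
  ll_truth <- as.numeric(repertoire_loglik(rp, truth, model = "hlp19"))
  expect_gte(fit$loglik, ll_truth)
  expect_equal(fit$aic, 2 * fit$n_free_params - 2 * fit$loglik,
               tolerance = 1e-9)
  expect_identical(fit$n_free_params,
                   9L + sum(vapply(fit$branch_lengths, length, integer(1))))
})

test_that("topology refinement inside the fit never hurts the likelihood", {
  rp <- tiny_repertoire(n_lineages = 2, n_tips = 3, n_codons = 20, seed = 81)
  fixed <- fit_repertoire(rp, model = "gy94", tol = 0.02, max_rounds = 6)
  refined <- fit_repertoire(rp, model = "gy94", tol = 0.02, max_rounds = 6,
                            optimize_topology = TRUE)
  expect_gte(refined$loglik, fixed$loglik - 0.05)
  expect_true(is.finite(refined$loglik))
})

test_that("identical-to-germline repertoires collapse to zero", {
  germ <- random_codon_seq(12)
  tr <- ape::read.tree(text = "(GERMLINE:0.05,(s1:0.1,s2:0.1):0.02);")
  lin <- lineage_data(stats::setNames(c(germ, germ), c("s1", "s2")), germ,
                      tree = tr)
  fit <- fit_repertoire(repertoire(list(lin)), model = "gy94", tol = 1e-4)
  expect_lt(sum(unlist(fit$branch_lengths)), 1e-3)
  expect_gt(fit$loglik, -1e-3)
})

test_that("fitted branch lengths sit on the per-branch grid optimum", {
  rp <- tiny_repertoire(n_lineages = 2, n_tips = 2, n_codons = 20, seed = 7)
  fit <- fit_repertoire(rp, model = "hlp19", tol = 1e-4, max_rounds = 20)
  # conditional on the fitted parameters, each branch should maximize the
  # lineage likelihood over a dense grid
  i <- 1
  lin <- rp$lineages[[i]]
  prep <- bcrphylo:::prep_lineage(lin)
  mats <- bcrphylo:::build_model_matrices(
    fit$params_hat, "hlp19", bcrphylo:::fwr_weight_of(list(prep)),
    pi_bar = fit$pi_bar)
  bl <- fit$branch_lengths[[i]]
  for (e in seq_along(bl)) {
    f <- function(t) {
      b <- bl
      b[e] <- t
      bcrphylo:::lineage_ll_engine(prep, mats, b)
    }
    grid <- seq(max(0, bl[e] - 0.02), bl[e] + 0.02, by = 1e-4)
    t_star <- grid[which.max(vapply(grid, f, numeric(1)))]
    expect_equal(bl[e], t_star, tolerance = 2e-4)
  }
})

test_that("single-lineage repertoires give identical individual and
           repertoire-wide estimates", {
  rp <- tiny_repertoire(n_lineages = 1, n_tips = 4, n_codons = 24, seed = 41)
  fit_rw <- fit_repertoire(rp, model = "hlp19", tol = 1e-2, max_rounds = 15)
  ind <- fit_individual_lineages(rp, model = "hlp19", min_seqs = 2,
                                 tol = 1e-2, max_rounds = 15)
  expect_equal(ind$mean_individual, fit_rw$flat, tolerance = 1e-6)
})

test_that("per-lineage omega overfits pathological CDR-only lineages", {
  # two sequences whose only changes are nonsynonymous and inside the CDR:
  # the per-lineage omega_cdr runs away to (or near) its upper bound
  germ <- paste(rep("GGTAAC", 10), collapse = "")  # Gly-Asn repeats
  mask <- region_mask(rep(c("FWR", "CDR"), each = 10))
  chg <- function(s, at, to) {
    substr(s, at, at) <- to
    s
  }
  s1 <- chg(germ, 37, "C")  # GGT -> CGT (Gly->Arg), CDR block
  s2 <- chg(chg(germ, 43, "C"), 49, "C")
  lin <- lineage_data(c(s1 = s1, s2 = s2), germ, mask = mask,
                      tree = ape::read.tree(
                        text = "(GERMLINE:0.02,(s1:0.02,s2:0.02):0.01);"))
  ind <- fit_individual_lineages(repertoire(list(lin)), model = "hlp19",
                                 tol = 1e-2)
  expect_gt(ind$estimates$omega_cdr[1], 5)
})

test_that("error summaries report bias, variance and MSE against truth", {
  rp <- tiny_repertoire(n_lineages = 3, n_tips = 3, n_codons = 24, seed = 51)
  truth <- attr(rp, "truth")$params
  ind <- fit_individual_lineages(rp, model = "hlp19", min_seqs = 2,
                                 truth = truth, tol = 0.05, max_rounds = 8)
  es <- ind$error_summary
  expect_true(all(c("parameter", "bias", "variance", "mse") %in% names(es)))
  row <- es[es$parameter == "omega_cdr", ]
  x <- ind$estimates$omega_cdr
  expect_equal(row$bias, mean(x) - truth[["omega_cdr"]], tolerance = 1e-12)
  expect_equal(row$mse, mean((x - truth[["omega_cdr"]])^2), tolerance = 1e-12)
})

test_that("profile CI endpoints bracket the threshold drop and the MLE", {
  rp <- tiny_repertoire(n_lineages = 3, n_tips = 3, n_codons = 30, seed = 61)
  fit <- fit_repertoire(rp, model = "gy94", tol = 1e-3, max_rounds = 15)
  ci <- profile_ci(fit, "omega", tol = 0.02, probe_rounds = 2,
                   probe_maxit = 12)
  expect_lt(ci[1], fit$flat[["omega"]])
  expect_gt(ci[2], fit$flat[["omega"]])
  expect_true(ci[1] < ci[2])
})

test_that("tree length statistics are plain sums and means", {
  t1 <- ape::read.tree(text = "(GERMLINE:0.1,(s1:0.2,s2:0.3):0.0);")
  t2 <- ape::read.tree(text = "(GERMLINE:0.05,s1:0.15);")
  mk <- function(tr, id) {
    tips <- setdiff(tr$tip.label, "GERMLINE")
    lineage_data(stats::setNames(replicate(length(tips),
                                           random_codon_seq(4)), tips),
                 random_codon_seq(4), tree = tr, id = id)
  }
  rp <- repertoire(list(mk(t1, "a"), mk(t2, "b")))
  st <- tree_length_stats(rp)
  expect_equal(st$per_lineage$tree_length, c(0.6, 0.2))
  expect_equal(st$mean_tree_length, 0.4)
})

test_that("the omega/tree-length regression matches closed-form OLS", {
  fake_fit <- function(omega, tl) {
    structure(list(flat = c(omega_cdr = omega), mean_tree_length = tl),
              class = "bcr_fit")
  }
  # collinear points: exact recovery
  tl <- c(0.1, 0.2, 0.4, 0.8)
  om <- 0.5 - 0.24 * log(tl)
  res <- suppressWarnings(  # lm warns on an exactly collinear toy
    regress_omega_on_treelength(lapply(seq_along(tl), function(i) {
      fake_fit(om[i], tl[i])
    })))
  expect_equal(res$estimate[res$term == "slope"], -0.24, tolerance = 1e-10)
  expect_equal(res$estimate[res$term == "intercept"], 0.5, tolerance = 1e-10)
  # constant omega: zero slope
  res0 <- suppressWarnings(regress_omega_on_treelength(lapply(tl, function(t) {
    fake_fit(0.6, t)
  })))
  expect_equal(res0$estimate[res0$term == "slope"], 0, tolerance = 1e-12)
  # random data against the normal equations
  set.seed(3)
  tl <- runif(8, 0.05, 1)
  om <- 0.4 - 0.2 * log(tl) + rnorm(8, 0, 0.03)
  res <- regress_omega_on_treelength(lapply(seq_along(tl), function(i) {
    fake_fit(om[i], tl[i])
  }))
  X <- cbind(1, log(tl))
  beta <- solve(t(X) %*% X, t(X) %*% om)
  expect_equal(res$estimate, as.numeric(beta), tolerance = 1e-10)
  # zero tree lengths are excluded with a warning
  expect_warning(
    regress_omega_on_treelength(c(lapply(seq_along(tl), function(i) {
      fake_fit(om[i], tl[i])
    }), list(fake_fit(0.5, 0)))),
    "zero mean tree length")
})

test_that("tidy, glance and autoplot expose the fit", {
  rp <- tiny_repertoire(n_lineages = 2, n_tips = 2, n_codons = 15, seed = 71)
  fit <- fit_repertoire(rp, model = "gy94", tol = 0.05, max_rounds = 5)
  td <- tidy(fit)
  expect_identical(td$term, c("kappa", "omega"))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$AIC, fit$aic)
  fit$cis[["omega"]] <- structure(c(0.1, 2), names = c("lower", "upper"),
                                  at_bound = c(FALSE, FALSE))
  td2 <- tidy(fit)
  expect_equal(td2$conf.low[td2$term == "omega"], 0.1)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
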