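# Maximum-likelihood estimation of repertoire-shared substitution parameters
# and per-branch lengths, profile-likelihood confidence intervals,
# likelihood-ratio thresholds, AIC model comparison, and the summaries used
# to compare repertoire-wide with mean-individual estimation.

FLAT_PARAM_NAMES <- c("kappa", "omega_fwr", "omega_cdr",
                      "h_wrc", "h_gyw", "h_wa", "h_tw", "h_syc", "h_grs")

# Free-parameter layout per model on the optimizer's transformed scale
# (log for kappa/omega, log1p for h so the h > -1 constraint is implicit).
par_spec <- function(model) {
  if (model == "gy94") {
    data.frame(name = c("kappa", "omega"),
               lower = c(log(0.01), log(0.001)),
               upper = c(log(20), log(20)),
               trans = c("log", "log"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(name = FLAT_PARAM_NAMES,
               lower = c(log(0.01), log(0.001), log(0.001), rep(log(0.001), 6)),
               upper = c(log(20), log(20), log(20), rep(log(21), 6)),
               trans = c("log", "log", "log", rep("log1p", 6)),
               stringsAsFactors = FALSE)
  }
}

to_trans <- function(x, trans) {
  y <- numeric(length(x))
  i <- trans == "log"
  y[i] <- log(x[i])
  y[!i] <- log1p(x[!i])
  y
}

from_trans <- function(x, trans) {
  y <- numeric(length(x))
  i <- trans == "log"
  y[i] <- exp(x[i])
  y[!i] <- expm1(x[!i])
  y
}

params_to_flat <- function(params, model) {
  if (model == "gy94") {
    c(kappa = params$kappa, omega = params$omega_fwr)
  } else {
    c(kappa = params$kappa, omega_fwr = params$omega_fwr,
      omega_cdr = params$omega_cdr,
      stats::setNames(as.numeric(params$h), paste0("h_", tolower(names(params$h)))))
  }
}

flat_to_params <- function(flat, model, pi) {
  if (model == "gy94") {
    model_params(kappa = flat[["kappa"]], omega_fwr = flat[["omega"]],
                 omega_cdr = flat[["omega"]], pi = pi)
  } else {
    h <- flat[paste0("h_", tolower(shm_motifs()$name))]
    names(h) <- shm_motifs()$name
    model_params(kappa = flat[["kappa"]], omega_fwr = flat[["omega_fwr"]],
                 omega_cdr = flat[["omega_cdr"]], h = h, pi = pi)
  }
}

# Mean root-to-tip path length across all tips of all lineages, from the
# current branch lengths (edges are postorder, so the reverse order walks
# parents before children).
mean_root_to_tip <- function(preps, bls) {
  tot <- 0
  ntip <- 0L
  for (i in seq_along(preps)) {
    plan <- preps[[i]]$plan
    depth <- numeric(plan$n_nodes)
    for (e in rev(seq_len(nrow(plan$edges)))) {
      depth[plan$edges[e, 2] + 1L] <- depth[plan$edges[e, 1] + 1L] + bls[[i]][e]
    }
    tot <- tot + sum(depth[seq_len(plan$n_tips)])
    ntip <- ntip + plan$n_tips
  }
  if (ntip == 0L) 0 else tot / ntip
}

# ---- core coordinate-ascent fit ---------------------------------------------

# Alternates (a) bounded optimization of the shared substitution parameters
# and (b) per-branch univariate optimization, refreshing the HLP19 midpoint
# frequencies between rounds, until the repertoire log-likelihood improves by
# less than `tol`.
fit_core <- function(preps, model, root_mode, emp_pi, germ_pi,
                     init_params = NULL, init_bls = NULL, fixed = NULL,
                     tol = 1e-3, max_rounds = 50L, optim_maxit = 25L,
                     verbose = FALSE) {
  spec <- par_spec(model)
  fwr_w <- fwr_weight_of(preps)
  rmode <- as.integer(root_mode == "pi")

  if (is.null(init_params)) {
    init_params <- model_params(kappa = 2, omega_fwr = 0.4, omega_cdr = 0.4,
                                pi = emp_pi)
  }
  flat <- params_to_flat(init_params, model)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), spec$name)
    if (length(bad) > 0L) stop("unknown parameter(s) to fix: ",
                               paste(bad, collapse = ", "), call. = FALSE)
    flat[names(fixed)] <- unlist(fixed)
  }
  free_idx <- which(!(spec$name %in% names(fixed)))

  bls <- init_bls %||% lapply(preps, function(p) {
    b <- p$plan$bl
    if (all(b == 0)) b[] <- 0.02
    pmin(pmax(b, 0), 10)
  })

  pi_bar <- emp_pi
  context <- NULL

  refresh_pi <- function(flat_now) {
    if (model == "hlp19") {
      p <- flat_to_params(flat_now, model, emp_pi)
      rtt <- mean_root_to_tip(preps, bls)
      pi_bar <<- predict_midpoint_frequencies(germ_pi, rtt, p,
                                              fwr_weight = fwr_w)
    } else {
      pi_bar <<- emp_pi
    }
    if (model != "gy94") context <<- mean_field_context(pi_bar)
  }

  mats_for <- function(flat_now) {
    p <- flat_to_params(flat_now, model, emp_pi)
    build_model_matrices(p, model, fwr_w, pi_bar = pi_bar, context = context)
  }

  cdatas <- lapply(preps, `[[`, "cdata")
  ll_all <- function(mats) {
    sum(cpp_repertoire_loglik(mats$eigF, mats$eigC, cdatas, bls, rmode,
                              unname(mats$pi_bar)))
  }

  refresh_pi(flat)
  mats <- mats_for(flat)
  ll <- ll_all(mats)
  if (!is.finite(ll)) {
    stop("non-finite starting log-likelihood; check alignments and trees",
         call. = FALSE)
  }
  best <- list(ll = ll, flat = flat, bls = bls, pi_bar = pi_bar)

  rounds <- 0L
  converged <- FALSE
  while (rounds < max_rounds) {
    rounds <- rounds + 1L
    ll_prev <- ll
    refresh_pi(flat)

    # (a) shared substitution parameters
    if (length(free_idx) > 0L) {
      obj <- function(theta) {
        fl <- flat
        fl[free_idx] <- from_trans(theta, spec$trans[free_idx])
        m <- mats_for(fl)
        -ll_all(m)
      }
      theta0 <- to_trans(flat[free_idx], spec$trans[free_idx])
      opt <- stats::optim(theta0, obj, method = "L-BFGS-B",
                          lower = spec$lower[free_idx],
                          upper = spec$upper[free_idx],
                          control = list(maxit = if (rounds == 1L) optim_maxit
                                         else max(8L, optim_maxit %/% 2L),
                                         factr = 1e10))
      flat[free_idx] <- from_trans(opt$par, spec$trans[free_idx])
    }
    mats <- mats_for(flat)

    # (b) branch lengths: cached per-branch Brent sweeps in the engine
    for (i in seq_along(preps)) {
      sw <- cpp_branch_sweep(mats$eigF, mats$eigC, cdatas[[i]], bls[[i]],
                             rmode, unname(mats$pi_bar), 2L, 10, 1e-6)
      bls[[i]] <- sw$bl
    }

    ll <- ll_all(mats)
    if (verbose) {
      message(sprintf("round %d: logL = %.4f (delta %.5f)", rounds, ll,
                      ll - ll_prev))
    }
    if (ll >= best$ll) best <- list(ll = ll, flat = flat, bls = bls,
                                    pi_bar = pi_bar)
    if (ll - ll_prev < tol) {
      converged <- TRUE
      break
    }
  }
  # coordinate ascent with capped inner optimizers can end a hair below the
  # best visited point; report the best, then polish the branch lengths so
  # they sit on their conditional optimum under the reported parameters
  flat <- best$flat
  bls <- best$bls
  pi_bar <- best$pi_bar
  ll <- best$ll
  if (model != "gy94") context <- mean_field_context(pi_bar)
  mats <- mats_for(flat)
  for (i in seq_along(preps)) {
    sw <- cpp_branch_sweep(mats$eigF, mats$eigC, cdatas[[i]], bls[[i]],
                           rmode, unname(mats$pi_bar), 3L, 10, 1e-7)
    bls[[i]] <- sw$bl
  }
  ll_pol <- ll_all(mats)
  if (ll_pol >= ll) ll <- ll_pol else bls <- best$bls

  params_hat <- flat_to_params(flat, model, if (model == "hlp19") pi_bar else emp_pi)
  list(loglik = ll, flat = flat, params = params_hat, pi_bar = pi_bar,
       bls = bls, rounds = rounds, converged = converged,
       fwr_weight = fwr_w)
}

# ---- public fit --------------------------------------------------------------

#' Fit a repertoire-wide substitution model
#'
#' Maximizes the repertoire log-likelihood (the sum of germline-rooted
#' lineage log-likelihoods) over the substitution parameters shared by all
#' lineages and every branch length, with tree topologies held fixed.
#' Coordinate ascent alternates bounded quasi-Newton optimization of the
#' shared parameters (kappa, region omegas and the six motif modifiers on a
#' log / log1p scale) with per-branch univariate optimization; for HLP19 the
#' midpoint codon frequencies are re-predicted between rounds.
#'
#' @param rep A [repertoire()]; every lineage needs a tree (see
#'   [parsimony_topology()] for the two-stage protocol).
#' @param model `"hlp19"` (default), `"gy94"` or `"hlp17"`. GY94 estimates a
#'   single omega shared by both regions.
#' @param root_mode `"germline"` (root state known) or `"pi"` (root partials
#'   summed against codon frequencies; use for cross-model AIC only).
#' @param tol Stop when the log-likelihood improves by less than this
#'   between rounds.
#' @param max_rounds Cap on coordinate-ascent rounds.
#' @param optim_maxit Iteration cap of the inner parameter optimizer per
#'   round.
#' @param init_params Optional [model_params()] starting point.
#' @param optimize_topology If `TRUE`, lineage topologies are first refined
#'   by NNI under GY94 with quickly fitted shared kappa/omega
#'   ([gy94_branch_refine()]); otherwise (default) the supplied trees are
#'   held fixed, matching the two-stage protocol.
#' @param verbose Print per-round progress.
#' @return An object of class `bcr_fit`: maximized `loglik`, `params_hat`,
#'   per-lineage `branch_lengths` and `tree_lengths`, `mean_tree_length`,
#'   `n_free_params`, `aic`, and an (initially empty) `cis` list filled by
#'   [profile_ci()].
#' @export
fit_repertoire <- function(rep, model = c("hlp19", "gy94", "hlp17"),
                           root_mode = c("germline", "pi"),
                           tol = 1e-3, max_rounds = 50L, optim_maxit = 25L,
                           init_params = NULL, optimize_topology = FALSE,
                           verbose = FALSE) {
  model <- match.arg(model)
  root_mode <- match.arg(root_mode)
  if (optimize_topology) {
    stage1 <- fit_repertoire(rep, model = "gy94", root_mode = root_mode,
                             tol = 0.05, max_rounds = 4L)
    for (i in seq_along(rep$lineages)) {
      rep$lineages[[i]]$tree <- gy94_branch_refine(
        rep$lineages[[i]], params = stage1$params_hat, nni = TRUE)
    }
  }
  preps <- lapply(rep$lineages, prep_lineage)
  no_tree <- vapply(preps, function(p) is.null(p$plan), logical(1))
  if (any(no_tree)) {
    stop("lineage(s) without a tree: ",
         paste(names(rep$lineages)[no_tree], collapse = ", "), call. = FALSE)
  }
  all_seqs <- unlist(lapply(rep$lineages, `[[`, "sequences"), use.names = FALSE)
  emp_pi <- empirical_codon_freqs(all_seqs, pseudocount = 0.01)
  germ_pi <- empirical_codon_freqs(
    vapply(rep$lineages, `[[`, character(1), "germline"), pseudocount = 0.01)

  core <- fit_core(preps, model, root_mode, emp_pi, germ_pi,
                   init_params = init_params, tol = tol,
                   max_rounds = max_rounds, optim_maxit = optim_maxit,
                   verbose = verbose)

  finalize_fit(core, rep, preps, model, root_mode, emp_pi, germ_pi)
}

finalize_fit <- function(core, rep, preps, model, root_mode, emp_pi, germ_pi) {
  tl <- vapply(core$bls, sum, numeric(1))
  n_branches <- sum(vapply(core$bls, length, integer(1)))
  k_sub <- if (model == "gy94") 2L else 9L
  k <- k_sub + n_branches
  trees <- lapply(seq_along(rep$lineages), function(i) {
    tr <- rep$lineages[[i]]$tree
    plan <- preps[[i]]$plan
    tr$edge.length[plan$orig_edge] <- core$bls[[i]]
    tr
  })
  names(trees) <- names(rep$lineages)
  structure(list(
    loglik = core$loglik,
    params_hat = core$params,
    flat = params_to_flat(core$params, model),
    model = model,
    root_mode = root_mode,
    branch_lengths = stats::setNames(core$bls, names(rep$lineages)),
    trees = trees,
    tree_lengths = stats::setNames(tl, names(rep$lineages)),
    mean_tree_length = mean(tl),
    n_free_params = k,
    aic = 2 * k - 2 * core$loglik,
    cis = list(),
    rounds = core$rounds,
    converged = core$converged,
    pi_bar = core$pi_bar,
    emp_pi = emp_pi,
    germ_pi = germ_pi,
    fwr_weight = core$fwr_weight,
    n_lineages = length(rep$lineages),
    rep = rep
  ), class = "bcr_fit")
}

#' @export
print.bcr_fit <- function(x, ...) {
  cat(sprintf("<bcr_fit> %s (%s root), %d lineages\n", toupper(x$model),
              x$root_mode, x$n_lineages))
  cat(sprintf("  logL %.3f | AIC %.3f | k = %d | mean tree length %.4f\n",
              x$loglik, x$aic, x$n_free_params, x$mean_tree_length))
  fl <- x$flat
  cat("  ", paste(sprintf("%s=%.3g", names(fl), fl), collapse = " "), "\n")
  if (length(x$cis) > 0L) {
    for (nm in names(x$cis)) {
      ci <- x$cis[[nm]]
      cat(sprintf("  95%% CI %s: [%.4g, %.4g]\n", nm, ci[1], ci[2]))
    }
  }
  invisible(x)
}

#' Per-lineage fits and the mean-individual estimate
#'
#' Fits the model independently to each lineage with at least `min_seqs`
#' unique sequences, then averages the per-lineage estimates — the
#' "mean individual" strategy that repertoire-wide estimation is designed to
#' beat. When the generating truth is supplied (simulation studies), bias,
#' variance and MSE of the per-lineage estimates are reported per parameter.
#'
#' @inheritParams fit_repertoire
#' @param min_seqs Keep lineages with at least this many unique sequences.
#' @param truth Optional named vector of generating parameter values (flat
#'   names, e.g. `omega_cdr`, `h_gyw`).
#' @param tol,max_rounds,optim_maxit Per-lineage fit controls (looser than
#'   the repertoire default, matching how noisy these fits are).
#' @return A list with `fits` (per-lineage `bcr_fit`s), `estimates` (tibble
#'   of per-lineage estimates), `mean_individual` (named vector),
#'   `n_failed`, and `error_summary` (tibble, when `truth` given).
#' @export
fit_individual_lineages <- function(rep, model = c("hlp19", "gy94", "hlp17"),
                                    min_seqs = 2L, truth = NULL,
                                    root_mode = c("germline", "pi"),
                                    tol = 1e-2, max_rounds = 20L,
                                    optim_maxit = 20L) {
  model <- match.arg(model)
  root_mode <- match.arg(root_mode)
  keep <- vapply(rep$lineages, function(l) {
    length(unique(unname(l$sequences))) >= min_seqs
  }, logical(1))
  lins <- rep$lineages[keep]
  if (length(lins) == 0L) stop("no lineage has >= ", min_seqs,
                               " unique sequences", call. = FALSE)
  fits <- list()
  failed <- character(0)
  for (id in names(lins)) {
    f <- tryCatch(
      fit_repertoire(repertoire(lins[id]), model = model,
                     root_mode = root_mode, tol = tol,
                     max_rounds = max_rounds, optim_maxit = optim_maxit),
      error = function(e) NULL)
    if (is.null(f)) failed <- c(failed, id) else fits[[id]] <- f
  }
  if (length(failed) > 0L) {
    message(length(failed), " lineage fit(s) failed and were excluded: ",
            paste(failed, collapse = ", "))
  }
  est <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(lineage = f$rep$lineages[[1]]$id,
                   n_seqs = length(f$rep$lineages[[1]]$sequences),
                   !!!as.list(f$flat))
  }))
  pcols <- setdiff(names(est), c("lineage", "n_seqs"))
  mean_ind <- vapply(est[pcols], mean, numeric(1))
  out <- list(fits = fits, estimates = est, mean_individual = mean_ind,
              n_failed = length(failed), failed = failed)
  if (!is.null(truth)) {
    common <- intersect(pcols, names(truth))
    out$error_summary <- dplyr::bind_rows(lapply(common, function(p) {
      x <- est[[p]]
      tv <- unname(truth[[p]])
      tibble::tibble(parameter = p, truth = tv,
                     mean_estimate = mean(x),
                     bias = mean(x) - tv,
                     variance = stats::var(x),
                     mse = mean((x - tv)^2))
    }))
  }
  out
}

# ---- LRT threshold and profile CIs ------------------------------------------

#' Likelihood-ratio threshold for profile confidence intervals
#'
#' Half the `1 - alpha` quantile of the chi-square distribution with `df`
#' degrees of freedom: the log-likelihood drop from the maximum at which a
#' profiled parameter value is rejected at level `alpha`. For one degree of
#' freedom at 5% this is the familiar 1.92.
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom (positive integer).
#' @return The log-likelihood difference threshold.
#' @examples
#' ci_threshold(0.05, 1)  # 1.9207
#' @export
ci_threshold <- function(alpha, df) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(df) || length(df) != 1L || df < 1 || df != round(df)) {
    stop("df must be a positive integer", call. = FALSE)
  }
  stats::qchisq(1 - alpha, df) / 2
}

# Generic one-sided binary search for the parameter value where a profiled
# log-likelihood curve crosses `ll_max - threshold`. `profile_fn(value)` must
# return the re-optimized log-likelihood with the parameter fixed at `value`.
profile_search_side <- function(profile_fn, mle, ll_max, threshold, bound,
                                tol, side = c("lower", "upper")) {
  side <- match.arg(side)
  dir <- if (side == "lower") -1 else 1
  step <- max(abs(mle) * 0.25, 0.05)
  inside <- mle
  outside <- NA_real_
  at_bound <- FALSE
  for (k in 1:40) {
    cand <- mle + dir * step
    hit_bound <- if (side == "lower") cand <= bound else cand >= bound
    if (hit_bound) cand <- bound
    drop <- ll_max - profile_fn(cand)
    if (drop >= threshold) {
      outside <- cand
      break
    }
    inside <- cand
    if (hit_bound) {
      at_bound <- TRUE
      break
    }
    step <- step * 2
  }
  if (at_bound) {
    return(list(value = bound, at_bound = TRUE))
  }
  if (is.na(outside)) {
    return(list(value = bound, at_bound = TRUE))
  }
  while (abs(outside - inside) > tol) {
    mid <- (inside + outside) / 2
    if (ll_max - profile_fn(mid) >= threshold) outside <- mid else inside <- mid
  }
  list(value = (inside + outside) / 2, at_bound = FALSE)
}

#' Profile-likelihood confidence interval for one parameter
#'
#' Each probe fixes the parameter of interest and re-optimizes every other
#' free parameter and all branch lengths (warm-started from the ML fit); the
#' 95% CI endpoints are located by binary search where the profiled
#' log-likelihood has dropped [ci_threshold()] (1.92 for one degree of
#' freedom at 5%) below its maximum. An endpoint that runs into a parameter
#' bound is reported at the bound and flagged.
#'
#' @param rep The [repertoire()] the fit was made on (defaults to the one
#'   stored in `fit`).
#' @param fit A converged [fit_repertoire()] result.
#' @param param_name Flat parameter name (`kappa`, `omega_fwr`, `omega_cdr`,
#'   `h_wrc`, ..., or `omega` for GY94 fits).
#' @param tol Bracket width at which the binary search stops (natural scale).
#' @param alpha Significance level (default 0.05, i.e. a 95% interval).
#' @param probe_rounds,probe_maxit Re-optimization effort per probe.
#' @return Numeric `c(lower, upper)` with attribute `at_bound` (logical 2);
#'   the interval is also stored in the returned fit's `cis` when you use
#'   `fit$cis[[param_name]] <- profile_ci(...)`.
#' @export
profile_ci <- function(fit, param_name, rep = fit$rep, tol = 1e-3,
                       alpha = 0.05, probe_rounds = 3L, probe_maxit = 15L) {
  spec <- par_spec(fit$model)
  if (!param_name %in% spec$name) {
    stop("unknown parameter '", param_name, "' for model ", fit$model,
         call. = FALSE)
  }
  row <- spec[spec$name == param_name, ]
  lower_bound <- from_trans(row$lower, row$trans)
  upper_bound <- from_trans(row$upper, row$trans)
  preps <- lapply(rep$lineages, prep_lineage)
  mle <- fit$flat[[param_name]]
  thr <- ci_threshold(alpha, 1L)

  profile_fn <- function(value) {
    fx <- stats::setNames(list(value), param_name)
    core <- fit_core(preps, fit$model, fit$root_mode, fit$emp_pi, fit$germ_pi,
                     init_params = fit$params_hat,
                     init_bls = unname(fit$branch_lengths), fixed = fx,
                     tol = 1e-3, max_rounds = probe_rounds,
                     optim_maxit = probe_maxit)
    core$loglik
  }

  lo <- profile_search_side(profile_fn, mle, fit$loglik, thr, lower_bound,
                            tol, "lower")
  hi <- profile_search_side(profile_fn, mle, fit$loglik, thr, upper_bound,
                            tol, "upper")
  structure(c(lo$value, hi$value),
            names = c("lower", "upper"),
            at_bound = c(lo$at_bound, hi$at_bound))
}

# ---- model comparison and summaries -----------------------------------------

#' Compare substitution models by AIC
#'
#' Fits each requested model to the same repertoire and trees in pi-at-root
#' mode (root partials multiplied by codon frequencies, the reversible-model
#' convention) so that log-likelihoods are on a comparable footing, and ranks
#' them by `AIC = 2k - 2 lnL`. Free-parameter counts: 2 substitution
#' parameters for GY94, 9 for HLP17 and HLP19 (codon frequencies are
#' empirical, not ML-estimated), plus one per branch length in every model.
#'
#' @param rep A [repertoire()] with trees.
#' @param models Character vector of model tags to compare.
#' @param ... Passed to [fit_repertoire()] (e.g. `tol`, `max_rounds`).
#' @return A tibble with one row per model (`model`, `loglik`, `k`, `aic`,
#'   `delta_aic`), sorted by AIC, with the fits in `attr(, "fits")`.
#' @export
compare_models_aic <- function(rep, models = c("gy94", "hlp17", "hlp19"), ...) {
  fits <- lapply(models, function(m) {
    fit_repertoire(rep, model = m, root_mode = "pi", ...)
  })
  names(fits) <- models
  out <- tibble::tibble(
    model = models,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    k = vapply(fits, `[[`, integer(1), "n_free_params"),
    aic = vapply(fits, `[[`, numeric(1), "aic")
  )
  out <- dplyr::arrange(out, .data$aic)
  out$delta_aic <- out$aic - out$aic[1]
  attr(out, "fits") <- fits
  out
}

#' Tree-length summaries of a fitted repertoire
#'
#' Tree length — the sum of a lineage tree's branch lengths — measures the
#' expected substitutions per codon accumulated within the lineage; its mean
#' across lineages is the repertoire-level diversity summary used alongside
#' omega estimates.
#'
#' @param x A `bcr_fit` (uses fitted branch lengths) or a [repertoire()]
#'   whose trees carry branch lengths.
#' @return A list with `per_lineage` (tibble: lineage, tree_length) and
#'   `mean_tree_length`.
#' @export
tree_length_stats <- function(x) {
  if (inherits(x, "bcr_fit")) {
    tl <- x$tree_lengths
  } else if (inherits(x, "bcr_repertoire")) {
    tl <- vapply(x$lineages, function(l) {
      if (is.null(l$tree) || is.null(l$tree$edge.length)) {
        stop("lineage ", l$id, " has no branch lengths", call. = FALSE)
      }
      sum(l$tree$edge.length)
    }, numeric(1))
  } else {
    stop("x must be a bcr_fit or bcr_repertoire", call. = FALSE)
  }
  list(per_lineage = tibble::tibble(lineage = names(tl), tree_length = unname(tl)),
       mean_tree_length = mean(tl))
}

#' Regress an omega estimate on log mean tree length
#'
#' Ordinary least squares of a fitted selection parameter against the natural
#' log of mean tree length across a collection of fits — the repertoire-level
#' analysis relating diversification to signatures of selection, provided
#' here for synthetic-data studies.
#'
#' @param fits List of `bcr_fit` objects (>= 3).
#' @param param Flat parameter name to regress (default `omega_cdr`).
#' @param conf_level Confidence level for the slope/intercept intervals.
#' @return A tibble with `term`, `estimate`, `conf.low`, `conf.high`,
#'   `p.value`; the `lm` fit is attached as `attr(, "lm")`.
#' @export
regress_omega_on_treelength <- function(fits, param = "omega_cdr",
                                        conf_level = 0.95) {
  if (length(fits) < 3L) stop("need at least 3 fits", call. = FALSE)
  y <- vapply(fits, function(f) f$flat[[param]], numeric(1))
  tlen <- vapply(fits, `[[`, numeric(1), "mean_tree_length")
  keep <- tlen > 0
  if (any(!keep)) {
    warning(sum(!keep), " fit(s) with zero mean tree length excluded")
  }
  if (sum(keep) < 3L) stop("fewer than 3 fits with positive tree length",
                           call. = FALSE)
  d <- data.frame(y = y[keep], x = log(tlen[keep]))
  m <- stats::lm(y ~ x, data = d)
  ci <- stats::confint(m, level = conf_level)
  sm <- summary(m)$coefficients
  out <- tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(stats::coef(m)),
    conf.low = ci[, 1],
    conf.high = ci[, 2],
    p.value = sm[, 4]
  )
  attr(out, "lm") <- m
  out
}

# ---- broom-style methods and plotting ---------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a repertoire fit
#'
#' @param x A `bcr_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` and, where [profile_ci()] results
#'   are stored in `x$cis`, `conf.low` / `conf.high`.
#' @export
tidy.bcr_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$flat), estimate = unname(x$flat))
  if (length(x$cis) > 0L) {
    out$conf.low <- NA_real_
    out$conf.high <- NA_real_
    for (nm in names(x$cis)) {
      i <- match(nm, out$term)
      if (!is.na(i)) {
        out$conf.low[i] <- x$cis[[nm]][1]
        out$conf.high[i] <- x$cis[[nm]][2]
      }
    }
  }
  out
}

#' One-row summary of a repertoire fit
#'
#' @param x A `bcr_fit`.
#' @param ... Unused.
#' @return One-row tibble: `logLik`, `AIC`, `df`, `mean_tree_length`,
#'   `n_lineages`, `converged`.
#' @export
glance.bcr_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, df = x$n_free_params,
                 mean_tree_length = x$mean_tree_length,
                 n_lineages = x$n_lineages, converged = x$converged)
}

#' Plot parameter estimates of a repertoire fit
#'
#' Point estimates (log scale for the rate ratios, natural for h) with any
#' stored profile CIs as error bars.
#'
#' @param object A `bcr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bcr_fit <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = rev(d$term))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point(size = 2)
  if ("conf.low" %in% names(d)) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2, na.rm = TRUE)
  }
  p + ggplot2::labs(x = "estimate", y = NULL,
                    title = sprintf("%s repertoire-wide estimates",
                                    toupper(object$model))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
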