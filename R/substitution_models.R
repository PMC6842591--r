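# GY94, HLP17 and HLP19 instantaneous-rate matrices, the mean-field motif
# context expectation that lets context-sensitive SHM targeting live inside a
# site-independent codon model, and midpoint codon-frequency prediction for
# the nonstationary HLP19 normalization.

#' Substitution-model parameters
#'
#' Container for the free parameters shared by all lineages of a repertoire:
#' the transition/transversion ratio kappa, separate dN/dS ratios for
#' framework (omega_fwr) and CDR (omega_cdr) codon sites, the six additive
#' SHM motif rate modifiers h (multiplier `1 + h`, so h > -1; negative values
#' are cold spots) and a 61-vector of sense-codon frequencies pi.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega_fwr,omega_cdr dN/dS ratios for FWR and CDR sites (> 0).
#' @param h Named numeric vector of motif rate modifiers; names must be a
#'   subset of WRC, GYW, WA, TW, SYC, GRS; missing motifs default to 0. Each
#'   h must exceed -1.
#' @param pi Codon frequency vector of length 61 (nonnegative, sums to 1);
#'   defaults to uniform.
#' @return An object of class `bcr_params`.
#' @examples
#' model_params(kappa = 2, omega_fwr = 0.5, omega_cdr = 0.7,
#'              h = c(WRC = 4, GYW = 6, WA = 4, TW = 2, SYC = -0.6, GRS = -0.6))
#' @export
model_params <- function(kappa = 2, omega_fwr = 0.4, omega_cdr = 0.4,
                         h = NULL, pi = NULL) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0,
            is.numeric(omega_fwr), length(omega_fwr) == 1L, omega_fwr > 0,
            is.numeric(omega_cdr), length(omega_cdr) == 1L, omega_cdr > 0)
  motifs <- shm_motifs()$name
  hh <- stats::setNames(rep(0, 6L), motifs)
  if (!is.null(h)) {
    if (is.null(names(h)) || !all(names(h) %in% motifs)) {
      stop("`h` must be named with motif names (", paste(motifs, collapse = ", "),
           ")", call. = FALSE)
    }
    hh[names(h)] <- as.numeric(h)
  }
  if (any(hh <= -1)) {
    stop("all h must exceed -1 (multiplier 1 + h must stay positive)", call. = FALSE)
  }
  if (is.null(pi)) pi <- uniform_pi()
  pi <- validate_pi(pi)
  structure(list(kappa = kappa, omega_fwr = omega_fwr, omega_cdr = omega_cdr,
                 h = hh, pi = pi),
            class = "bcr_params")
}

#' @export
print.bcr_params <- function(x, ...) {
  cat("<bcr_params>\n")
  cat(sprintf("  kappa      %.4g\n", x$kappa))
  cat(sprintf("  omega_fwr  %.4g\n", x$omega_fwr))
  cat(sprintf("  omega_cdr  %.4g\n", x$omega_cdr))
  cat("  h          ",
      paste(sprintf("%s=%.3g", names(x$h), x$h), collapse = " "), "\n")
  cat(sprintf("  pi         61 codon frequencies (max %.4g)\n", max(x$pi)))
  invisible(x)
}

#' Uniform sense-codon frequencies
#' @return Numeric vector of length 61, each entry 1/61, named by codon.
#' @export
uniform_pi <- function() {
  cs <- codon_space()
  stats::setNames(rep(1 / 61, 61L), cs$codons)
}

validate_pi <- function(pi) {
  pi <- as.numeric(pi)
  if (length(pi) != 61L) stop("pi must have length 61", call. = FALSE)
  if (any(pi < 0)) stop("pi entries must be nonnegative", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-12) {
    if (abs(sum(pi) - 1) > 1e-6) stop("pi must sum to 1", call. = FALSE)
    pi <- pi / sum(pi)
  }
  stats::setNames(pi, codon_space()$codons)
}

#' Empirical codon frequencies of a set of sequences
#'
#' Counts sense codons across in-frame nucleotide sequences (codons containing
#' gaps, ambiguity characters or stops are ignored) and returns the relative
#' frequencies, with an optional pseudocount.
#'
#' @param sequences Character vector of aligned nucleotide sequences.
#' @param pseudocount Added to every codon count (default 0).
#' @return Named numeric 61-vector summing to 1.
#' @export
empirical_codon_freqs <- function(sequences, pseudocount = 0) {
  cs <- codon_space()
  counts <- stats::setNames(rep(pseudocount, 61L), cs$codons)
  for (s in sequences) {
    cods <- codon_strings(s)
    cods <- cods[cods %in% cs$codons]
    if (length(cods) > 0L) {
      tab <- table(cods)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  if (sum(counts) == 0) return(uniform_pi())
  counts / sum(counts)
}

codon_strings <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n %% 3 != 0) stop("sequence length not a multiple of 3", call. = FALSE)
  substring(s, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# ---- Mean-field motif context ------------------------------------------------

# Positional nucleotide marginals of a codon frequency vector: a 3 x 4 matrix,
# row p = distribution of the base at codon position p (1-based).
positional_marginals <- function(pi) {
  cs <- codon_space()
  m <- matrix(0, 3, 4)
  for (p in 1:3) {
    for (b in 1:4) m[p, b] <- sum(pi[cs$nt[, p] == b])
  }
  m
}

#' Mean-field motif context expectation
#'
#' For every (source codon, codon position, motif) triple, the probability
#' that the base at that position is the targeted base of a motif occurrence,
#' with within-codon context read off the source codon itself and flanking
#' bases (in neighbouring codons) marginalized over their pi-derived
#' positional frequencies. This is what keeps the codon process
#' site-independent while still carrying SHM context information: the flank
#' base at absolute offset x from the codon start uses the marginal of codon
#' position `(x mod 3) + 1`.
#'
#' @param pi Codon frequency vector (length 61).
#' @param motifs Motif table as from [shm_motifs()] (the default).
#' @return A 61 x 3 x 6 numeric array `e[a, p, m]` with dimnames
#'   (codon, position, motif); entries in `[0, 1]`, exactly 0 or 1 whenever
#'   the motif occurrence lies fully within the codon.
#' @export
mean_field_context <- function(pi, motifs = shm_motifs()) {
  pi <- validate_pi(pi)
  cs <- codon_space()
  marg <- positional_marginals(pi)
  e <- array(0, dim = c(61L, 3L, nrow(motifs)),
             dimnames = list(cs$codons, NULL, motifs$name))
  for (mi in seq_len(nrow(motifs))) {
    pat <- strsplit(motifs$pattern[mi], "")[[1]]
    off <- motifs$target_offset[mi]
    L <- length(pat)
    allowed <- lapply(pat, function(ch) match(IUPAC_CLASS[[ch]], NUC))
    for (p in 1:3) {
      # motif occupies absolute positions (p-1-off) .. (p-1-off+L-1), 0-based
      start <- (p - 1L) - off
      prob <- rep(1, 61L)
      for (j in seq_len(L)) {
        x <- start + j - 1L
        if (x >= 0L && x <= 2L) {
          prob <- prob * as.numeric(cs$nt[, x + 1L] %in% allowed[[j]])
        } else {
          cp <- (x %% 3L) + 1L  # codon position of the flanking base
          prob <- prob * sum(marg[cp, allowed[[j]]])
        }
      }
      e[, p, mi] <- prob
    }
  }
  e
}

# ---- Rate matrices -----------------------------------------------------------

new_rate_matrix <- function(q, scale, model_tag, region, pi_bar) {
  cs <- codon_space()
  dimnames(q) <- list(cs$codons, cs$codons)
  structure(list(q = q, scale = scale, model_tag = model_tag, region = region,
                 pi_bar = pi_bar),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("<rate_matrix> %s / %s, 61 x 61, normalization scale %.6g\n",
              x$model_tag, x$region, x$scale))
  invisible(x)
}

# Raw (unnormalized) Q assembly shared by the three models. `he_weight` is the
# per-(a, pos) motif multiplier 1 + sum_m h_m e(a, pos, m), floored at 1e-9;
# `pi_b_factor` switches the GY94/HLP17-style target-frequency multiplier.
raw_q <- function(params, region, context = NULL, pi_b_factor = FALSE,
                  use_motifs = TRUE) {
  cs <- codon_space()
  sub <- cs$subs
  omega <- if (region == "CDR") params$omega_cdr else params$omega_fwr
  rate <- params$kappa ^ sub$ts * ifelse(sub$syn, 1, omega)
  if (use_motifs && any(params$h != 0)) {
    if (is.null(context)) stop("context required when any h != 0", call. = FALSE)
    hmat <- context  # 61 x 3 x 6
    hsum <- matrix(0, 61L, 3L)
    for (m in names(params$h)) {
      hsum <- hsum + params$h[[m]] * hmat[, , m]
    }
    w <- 1 + hsum[cbind(sub$a, sub$pos)]
    w[w <= 0] <- 1e-9
    rate <- rate * w
  }
  if (pi_b_factor) rate <- rate * params$pi[sub$b]
  q <- matrix(0, 61L, 61L)
  q[cbind(sub$a, sub$b)] <- rate
  diag(q) <- -rowSums(q)
  q
}

mean_rate <- function(q, pi_bar) {
  -sum(pi_bar * diag(q))
}

#' Build the HLP19 rate matrix
#'
#' Instantaneous rates between sense codons a != b differing at exactly one
#' nucleotide: `kappa^[transition] * omega_region^[nonsynonymous] *
#' (1 + sum_m h_m e(a, pos, m))`, floored at 1e-9 when cold spots drive the
#' motif factor nonpositive; zero for multi-nucleotide changes. Unlike GY94
#' and HLP17 there is no target-codon frequency factor — frequencies enter
#' only through the mean-field context and the normalization, which uses the
#' midpoint frequencies `pi_bar` so branch lengths read as expected
#' substitutions per codon.
#'
#' @param params A [model_params()] object.
#' @param region `"FWR"` or `"CDR"` (selects the omega).
#' @param context Mean-field context array from [mean_field_context()],
#'   computed with the same pi used for normalization. Defaults to
#'   `mean_field_context(pi_bar)`.
#' @param pi_bar Frequencies used for normalization (midpoint frequencies;
#'   defaults to `params$pi`).
#' @return A `rate_matrix` object (fields `q`, `scale`, `model_tag`,
#'   `region`, `pi_bar`); `q` is normalized so `-sum(pi_bar * diag(q)) = 1`.
#' @export
build_q_hlp19 <- function(params, region = c("FWR", "CDR"), context = NULL,
                          pi_bar = NULL) {
  region <- match.arg(region)
  if (is.null(pi_bar)) pi_bar <- params$pi
  pi_bar <- validate_pi(pi_bar)
  if (is.null(context)) context <- mean_field_context(pi_bar)
  q <- raw_q(params, region, context, pi_b_factor = FALSE)
  sc <- mean_rate(q, pi_bar)
  new_rate_matrix(q / sc, sc, "HLP19", region, pi_bar)
}

#' Build the GY94 rate matrix
#'
#' The Goldman–Yang-style codon model: `q_ab = pi_b * kappa^[transition] *
#' omega^[nonsynonymous]` for single-nucleotide differences, normalized to
#' mean rate one under pi (its stationary distribution).
#'
#' @inheritParams build_q_hlp19
#' @return A `rate_matrix`.
#' @export
build_q_gy94 <- function(params, region = c("FWR", "CDR")) {
  region <- match.arg(region)
  q <- raw_q(params, region, context = NULL, pi_b_factor = TRUE,
             use_motifs = FALSE)
  sc <- mean_rate(q, params$pi)
  new_rate_matrix(q / sc, sc, "GY94", region, params$pi)
}

#' Build the HLP17 rate matrix
#'
#' As [build_q_hlp19()] but with the GY94-style target-codon frequency factor
#' `pi_b` on every permitted entry; reduces to GY94 entry-for-entry when all
#' h are zero. Here pi is taken as given (empirical repertoire frequencies)
#' rather than ML-estimated, which keeps the free-parameter count at nine.
#'
#' @inheritParams build_q_hlp19
#' @return A `rate_matrix`.
#' @export
build_q_hlp17 <- function(params, region = c("FWR", "CDR"), context = NULL,
                          pi_bar = NULL) {
  region <- match.arg(region)
  if (is.null(pi_bar)) pi_bar <- params$pi
  pi_bar <- validate_pi(pi_bar)
  if (is.null(context)) context <- mean_field_context(pi_bar)
  q <- raw_q(params, region, context, pi_b_factor = TRUE)
  sc <- mean_rate(q, pi_bar)
  new_rate_matrix(q / sc, sc, "HLP17", region, pi_bar)
}

#' Predict codon frequencies at the phylogeny midpoint
#'
#' The HLP19 model is nonstationary: codon composition starts at the germline
#' and drifts. Normalizing with frequencies predicted at half the mean
#' root-to-tip divergence keeps branch lengths interpretable as expected
#' substitutions per codon. Fixed point: starting from the germline
#' frequencies, build the HLP19 matrix under the current iterate, propagate
#' the germline frequencies forward by `mean_root_to_tip / 2`, and repeat
#' until the vector changes by less than `tol` (the matrix is renormalized
#' under the current iterate at each step).
#'
#' @param germline_freqs Codon frequencies of the germline ancestors.
#' @param mean_root_to_tip Mean root-to-tip path length (substitutions/codon).
#' @param params A [model_params()] object (kappa, omegas, h; the omega used
#'   is the mask-weighted mixture via `fwr_weight`).
#' @param fwr_weight Fraction of scored sites that are FWR (the propagation
#'   uses a single matrix with the mixture omega).
#' @param tol,max_iter Fixed-point stopping rules.
#' @return Named 61-vector of predicted midpoint frequencies.
#' @export
predict_midpoint_frequencies <- function(germline_freqs, mean_root_to_tip,
                                         params, fwr_weight = 0.75,
                                         tol = 1e-8, max_iter = 100L) {
  stopifnot(mean_root_to_tip >= 0)
  g <- validate_pi(germline_freqs)
  if (mean_root_to_tip == 0) return(g)
  t_mid <- mean_root_to_tip / 2
  omega_mix <- fwr_weight * params$omega_fwr + (1 - fwr_weight) * params$omega_cdr
  p_mix <- model_params(kappa = params$kappa, omega_fwr = omega_mix,
                        omega_cdr = omega_mix, h = params$h, pi = params$pi)
  cur <- g
  for (it in seq_len(max_iter)) {
    rm <- build_q_hlp19(p_mix, "FWR", pi_bar = cur)
    P <- transition_probabilities(rm, t_mid)
    nxt <- as.numeric(g %*% P)
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - cur)) < tol) {
      return(stats::setNames(nxt, codon_space()$codons))
    }
    cur <- nxt
  }
  warning("midpoint-frequency fixed point did not converge in ", max_iter,
          " iterations; returning last iterate")
  stats::setNames(cur, codon_space()$codons)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param q A `rate_matrix` (or bare 61 x 61 generator).
#' @param t Branch length (>= 0), expected substitutions per codon.
#' @return A 61 x 61 stochastic matrix (rows sum to 1; entries clipped to
#'   `[0, 1]`); the identity at `t = 0`.
#' @export
transition_probabilities <- function(q, t) {
  if (length(t) != 1L || !is.finite(t) || t < 0) {
    stop("branch length t must be a single nonnegative number", call. = FALSE)
  }
  qm <- if (inherits(q, "rate_matrix")) q$q else q
  eig <- cpp_eig_q(unname(qm))
  P <- cpp_pmat(eig, t)
  dimnames(P) <- dimnames(qm)
  P
}

#' Write a rate matrix to TSV
#'
#' Plain-text serialization (codon labels as header and first column) for
#' debugging and external inspection.
#'
#' @param rm A `rate_matrix`.
#' @param path Output file.
#' @export
write_rate_matrix <- function(rm, path) {
  q <- if (inherits(rm, "rate_matrix")) rm$q else rm
  df <- data.frame(codon = rownames(q), q, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
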