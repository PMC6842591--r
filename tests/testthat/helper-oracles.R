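# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: motif scanning by naive sliding window,
# rate-matrix entries by brute-force flank enumeration, likelihoods by
# explicit summation over internal-node states with Matrix::expm.

IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
              W = c("A", "T"), S = c("C", "G"), R = c("A", "G"),
              Y = c("C", "T"))

oracle_motif_hits <- function(seq, pattern, target_offset) {
  s <- strsplit(seq, "")[[1]]
  pat <- strsplit(pattern, "")[[1]]
  L <- length(pat)
  hits <- integer(0)
  if (length(s) < L) return(hits)
  for (start in 1:(length(s) - L + 1)) {
    win <- s[start:(start + L - 1)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    if (all(mapply(function(b, p) b %in% IUPAC[[p]], win, pat))) {
      hits <- c(hits, start - 1L + target_offset)
    }
  }
  sort(hits)
}

# Probability that codon position p (1-based) of codon `cod` is the target
# of a motif occurrence, with flanking bases drawn independently from the
# positional marginals of pi (the mean-field independence assumption):
# enumerate every flank-base combination of the 7-mer window, weight by the
# marginals, and scan each explicit string naively.
oracle_context_prob <- function(cod, p, pattern, target_offset, pi) {
  cs <- codon_space()
  marg <- function(pos) {  # distribution of codon position pos (1-based)
    vapply(c("A", "C", "G", "T"), function(b) {
      sum(pi[substr(cs$codons, pos, pos) == b])
    }, numeric(1))
  }
  m <- lapply(1:3, marg)
  nuc <- c("A", "C", "G", "T")
  tot <- 0
  for (l2 in 1:4) for (l3 in 1:4) for (r1 in 1:4) for (r2 in 1:4) {
    seven <- paste0(nuc[l2], nuc[l3], cod, nuc[r1], nuc[r2])
    w <- m[[2]][l2] * m[[3]][l3] * m[[1]][r1] * m[[2]][r2]
    hits <- oracle_motif_hits(seven, pattern, target_offset)
    # codon position p sits at 0-based index 1 + p of the 7-mer
    if ((1 + p) %in% hits) tot <- tot + w
  }
  unname(tot)
}

# Brute-force HLP-style Q entry (unnormalized): for codons a != b differing
# at one position, kappa^ts * omega^nonsyn * (1 + sum_m h_m P_m(a, pos)),
# optionally times pi_b.
oracle_q_entry <- function(a, b, params, pi, pi_b_factor = FALSE,
                           region = "FWR") {
  cls <- classify_substitution(a, b)
  if (length(cls$positions_differing) != 1L) return(0)
  p <- cls$positions_differing + 1L
  omega <- if (region == "CDR") params$omega_cdr else params$omega_fwr
  motifs <- shm_motifs()
  hsum <- 0
  for (i in seq_len(nrow(motifs))) {
    hsum <- hsum + params$h[[motifs$name[i]]] *
      oracle_context_prob(a, p, motifs$pattern[i], motifs$target_offset[i], pi)
  }
  val <- params$kappa ^ isTRUE(cls$is_transition) *
    (if (cls$is_synonymous) 1 else omega) * max(1 + hsum, 1e-9)
  if (pi_b_factor) val <- val * pi[[codon_space()$index[[b]]]]
  val
}

# Exhaustive-enumeration log-likelihood for the fixed 3-tip toy topology
#   (GERMLINE:t_g, (s1:t_1, (s2:t_2, s3:t_3):t_n):t_r);
# with per-site region masks and a choice of model / root mode.
oracle_3tip_loglik <- function(lin, params, model, root_mode = "germline",
                               brlens) {
  cs <- codon_space()
  m <- as.character(lin$mask)
  scored <- which(m != "IGNORED")
  ctx <- mean_field_context(params$pi)
  build <- function(region) {
    switch(model,
           hlp19 = build_q_hlp19(params, region, ctx),
           gy94 = build_q_gy94(params, region),
           hlp17 = build_q_hlp17(params, region, ctx))
  }
  qf <- build("FWR"); qc <- build("CDR")
  w <- mean(m[scored] == "FWR")
  S <- w * qf$scale + (1 - w) * qc$scale
  QF <- qf$q * qf$scale / S
  QC <- qc$q * qc$scale / S
  Pm <- function(Q, t) as.matrix(Matrix::expm(Q * t))
  ll <- 0
  for (si in scored) {
    Q <- if (m[si] == "FWR") QF else QC
    g <- cs$index[[substr(lin$germline, 3 * si - 2, 3 * si)]]
    x <- vapply(c("s1", "s2", "s3"), function(nm) {
      cs$index[[substr(lin$sequences[[nm]], 3 * si - 2, 3 * si)]]
    }, integer(1))
    P_gr <- Pm(Q, brlens["t_g"]); P_rn <- Pm(Q, brlens["t_r"])
    P1 <- Pm(Q, brlens["t_1"]); Pn <- Pm(Q, brlens["t_n"])
    P2 <- Pm(Q, brlens["t_2"]); P3 <- Pm(Q, brlens["t_3"])
    tot <- 0
    for (r in 1:61) {
      for (n1 in 1:61) {
        inner <- P1[n1, x[1]] *
          sum(Pn[n1, ] * P2[, x[2]] * P3[, x[3]])
        tot <- tot + P_gr[g, r] * P_rn[r, n1] * inner
      }
    }
    if (root_mode == "pi") tot <- tot * params$pi[[g]]
    ll <- ll + log(tot)
  }
  ll
}

toy_3tip_tree <- function(brlens) {
  ape::read.tree(text = sprintf(
    "(GERMLINE:%g,(s1:%g,(s2:%g,s3:%g):%g):%g);",
    brlens["t_g"], brlens["t_1"], brlens["t_2"], brlens["t_3"],
    brlens["t_n"], brlens["t_r"]))
}

# TRUE if any codon of an in-frame sequence is a stop codon.
has_stop <- function(seq) {
  n <- nchar(seq)
  cods <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  cods %in% c("TAA", "TAG", "TGA")
}

random_codon_seq <- function(n_codons) {
  paste(sample(codon_space()$codons, n_codons, replace = TRUE), collapse = "")
}

random_3tip_lineage <- function(n_codons = 2, mask = NULL, brlens = NULL) {
  if (is.null(brlens)) {
    brlens <- c(t_g = 0.1, t_1 = 0.2, t_2 = 0.15, t_3 = 0.05, t_n = 0.1,
                t_r = 0.12)
  }
  if (is.null(mask)) {
    mask <- region_mask(rep(c("FWR", "CDR"), length.out = n_codons))
  }
  seqs <- stats::setNames(replicate(3, random_codon_seq(n_codons)),
                          c("s1", "s2", "s3"))
  lineage_data(seqs, random_codon_seq(n_codons), mask = mask,
               tree = toy_3tip_tree(brlens))
}

ref_params <- function() {
  model_params(kappa = 2, omega_fwr = 0.5, omega_cdr = 0.7,
               h = c(WRC = 4, GYW = 6, WA = 4, TW = 2, SYC = -0.6,
                     GRS = -0.6))
}

random_params <- function() {
  model_params(kappa = stats::runif(1, 0.2, 8),
               omega_fwr = stats::runif(1, 0.05, 3),
               omega_cdr = stats::runif(1, 0.05, 3),
               h = stats::setNames(stats::runif(6, -0.9, 8),
                                   shm_motifs()$name),
               pi = {
                 x <- stats::rgamma(61, 1)
                 x / sum(x)
               })
}
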