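# Synthetic-repertoire generation: power-law clone sizes, coalescent lineage
# trees grafted onto a germline root, and sequence evolution under either a
# fully context-dependent HLP19 process (motif hits evaluated on the actual
# flanking bases, not the mean-field expectation the estimator uses — the
# deliberate model mismatch used for validation) or a 5-mer mutability table.

#' Simulation configuration
#'
#' Bundles everything needed to generate a synthetic repertoire. The defaults
#' are the validation conditions used throughout the package's tests: clone
#' sizes from a discrete power law steep enough that about 92% of lineages
#' are singletons, random-coalescent topologies scaled to a mean tree length
#' of 0.3 substitutions per codon, 100-codon V-region-like alignments with a
#' quarter of sites in two CDR blocks, and the reference parameter set
#' kappa = 2, omega_fwr = 0.5, omega_cdr = 0.7,
#' h = (WRC 4, GYW 6, WA 4, TW 2, SYC -0.6, GRS -0.6).
#'
#' @param n_lineages Number of clonal lineages.
#' @param clone_size_law Either `list(law = "power_law", exponent = 4)` or
#'   `list(law = "fixed", n = k)` (k tips per clone).
#' @param n_codons Codon sites per alignment.
#' @param cdr_fraction Fraction of sites labelled CDR (see
#'   [default_vregion_mask()]).
#' @param tree_law `"random_coalescent"` (only built-in law; supply trees
#'   yourself for anything else).
#' @param branch_scale Expected tree length per lineage, in expected
#'   substitutions per codon.
#' @param tree_length_units How `branch_scale` is read: `"h0"` (default)
#'   passes `branch_scale` straight through as the simulator's
#'   h = 0-normalized branch-length scale (the units in which the evolver
#'   defines branch lengths); `"realized"` instead targets the expected
#'   number of substitutions per codon under the full generating process,
#'   converting internally via the mean motif rate inflation — with strong
#'   hot spots the realized substitution load then stays at `branch_scale`
#'   instead of exceeding it. The two coincide when all h are 0.
#' @param params Generating [model_params()].
#' @param generator `"hlp19_full_context"` or `"s5f_table"`.
#' @param mutability Mutability table for the `"s5f_table"` generator
#'   (default [synthetic_mutability_table()]).
#' @param seed Integer seed (mandatory; the whole fixture is a deterministic
#'   function of it).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_lineages = 50L,
                       clone_size_law = list(law = "fixed", n = 6L),
                       n_codons = 100L,
                       cdr_fraction = 0.25,
                       tree_law = "random_coalescent",
                       branch_scale = 0.3,
                       params = model_params(
                         kappa = 2, omega_fwr = 0.5, omega_cdr = 0.7,
                         h = c(WRC = 4, GYW = 6, WA = 4, TW = 2,
                               SYC = -0.6, GRS = -0.6)),
                       tree_length_units = c("h0", "realized"),
                       generator = c("hlp19_full_context", "s5f_table"),
                       mutability = NULL,
                       seed) {
  generator <- match.arg(generator)
  tree_length_units <- match.arg(tree_length_units)
  if (missing(seed) || !is.numeric(seed)) stop("`seed` is mandatory",
                                               call. = FALSE)
  stopifnot(n_lineages >= 1, n_codons >= 4, cdr_fraction > 0,
            cdr_fraction < 1, branch_scale >= 0)
  if (!clone_size_law$law %in% c("power_law", "fixed")) {
    stop("clone_size_law$law must be 'power_law' or 'fixed'", call. = FALSE)
  }
  if (generator == "s5f_table" && is.null(mutability)) {
    mutability <- synthetic_mutability_table()
  }
  structure(list(n_lineages = as.integer(n_lineages),
                 clone_size_law = clone_size_law, n_codons = as.integer(n_codons),
                 cdr_fraction = cdr_fraction, tree_law = tree_law,
                 branch_scale = branch_scale,
                 tree_length_units = tree_length_units, params = params,
                 generator = generator, mutability = mutability,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample clone sizes
#'
#' Discrete power law `P(k) proportional to k^-exponent` (truncated at
#' `max_size`), matching the strongly singleton-dominated clone-size
#' distributions of peripheral-blood BCR repertoires: the default exponent 4
#' gives about 92% singleton lineages and over 99% of lineages below five
#' unique sequences.
#'
#' @param n Number of clones.
#' @param law As in [sim_config()].
#' @param max_size Truncation of the power law.
#' @param seed Optional seed (uses the current RNG state when `NULL`).
#' @return Integer vector of clone sizes.
#' @export
sample_clone_sizes <- function(n, law = list(law = "power_law", exponent = 4),
                               max_size = 1000L, seed = NULL) {
  draw <- function() {
    if (law$law == "fixed") {
      rep(as.integer(law$n), n)
    } else {
      k <- seq_len(max_size)
      p <- k ^ (-law$exponent)
      sample(k, n, replace = TRUE, prob = p / sum(p))
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

random_germline <- function(n_codons) {
  cs <- codon_space()
  paste(sample(cs$codons, n_codons, replace = TRUE), collapse = "")
}

# Expected total branch length of a Kingman coalescent tree with n tips
# (rate-1 units): sum_{k=2..n} k * E[T_k] = 2 * H_{n-1}.
expected_coalescent_length <- function(n) {
  if (n < 2L) return(0)
  2 * sum(1 / seq_len(n - 1L))
}

TRUNK_MEAN <- 0.5  # germline-to-MRCA trunk, coalescent units

# A coalescent tree over the clone's tips with the germline grafted below
# the MRCA, scaled so the expected total tree length equals branch_scale.
random_lineage_tree <- function(tip_names, branch_scale,
                                germline_label = GERMLINE_LABEL) {
  n <- length(tip_names)
  if (n == 1L) {
    raw <- stats::rexp(1, rate = 1)
    len <- branch_scale * raw
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);", germline_label,
                                         len / 2, tip_names, len / 2)))
  }
  sub <- ape::rcoal(n, tip.label = tip_names)
  trunk <- stats::rexp(1, rate = 1 / TRUNK_MEAN)
  expected_raw <- expected_coalescent_length(n) + TRUNK_MEAN
  sc <- branch_scale / expected_raw
  sub$edge.length <- sub$edge.length * sc
  inner <- sub(";$", "", ape::write.tree(sub))
  # (GERMLINE:trunk, (coalescent subtree):0); the trunk edge is the
  # germline-to-MRCA path
  ape::read.tree(text = sprintf("(%s:%.10g,%s:0);", germline_label,
                                trunk * sc, inner))
}

# ---- full-context HLP19 evolution -------------------------------------------

# Codon lookup keyed by 1 + 16(n1-1) + 4(n2-1) + (n3-1); NA marks stops.
codon_code_tables <- function() {
  if (!is.null(.bcr$code_tab)) return(.bcr$code_tab)
  cs <- codon_space()
  idx61 <- rep(NA_integer_, 64L)
  aa64 <- rep(NA_character_, 64L)
  for (i in seq_len(61L)) {
    code <- 1L + 16L * (cs$nt[i, 1] - 1L) + 4L * (cs$nt[i, 2] - 1L) +
      (cs$nt[i, 3] - 1L)
    idx61[code] <- i
    aa64[code] <- cs$aa[i]
  }
  .bcr$code_tab <- list(idx61 = idx61, aa64 = aa64)
  .bcr$code_tab
}

nt_ints <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], NUC)
  if (anyNA(v)) stop("simulator requires a fully resolved A/C/G/T sequence",
                     call. = FALSE)
  v
}

ints_nt <- function(v) paste(NUC[v], collapse = "")

# Integer-coded motif specs for the simulator's hot path.
motif_int_specs <- function() {
  if (!is.null(.bcr$motif_int)) return(.bcr$motif_int)
  motifs <- shm_motifs()
  specs <- lapply(seq_len(nrow(motifs)), function(mi) {
    pat <- strsplit(motifs$pattern[mi], "")[[1]]
    list(name = motifs$name[mi],
         classes = lapply(pat, function(ch) match(IUPAC_CLASS[[ch]], NUC)),
         off = motifs$target_offset[mi])
  })
  names(specs) <- motifs$name
  .bcr$motif_int <- specs
  specs
}

# Vectorized motif target positions (0-based) on an integer-coded sequence.
motif_hits_int <- function(ntv, classes, off) {
  L <- length(classes)
  n <- length(ntv)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    ok <- ok & (ntv[j:(n - L + j)] %in% classes[[j]])
  }
  which(ok) - 1L + off
}

# 1 + sum_m h_m * I(site is the target of motif m), evaluated on the actual
# sequence (full context); returns a vector over nucleotide sites.
context_factors <- function(ntv, h) {
  fac <- rep(1, length(ntv))
  for (sp in motif_int_specs()) {
    hm <- h[[sp$name]]
    if (hm == 0) next
    hits <- motif_hits_int(ntv, sp$classes, sp$off)
    fac[hits + 1L] <- fac[hits + 1L] + hm
  }
  pmax(fac, 1e-9)
}

# Per-site, per-replacement-base instantaneous rates for the full-context
# HLP19 process, in units where the h = 0 model has mean rate 1 per codon at
# the generating pi.
hlp19_rate_table <- function(ntv, omega_site, h, kappa, scale0) {
  tab <- codon_code_tables()
  C <- length(ntv) / 3L
  sites <- seq_along(ntv)
  cod_of <- rep(seq_len(C), each = 3L)
  pos_of <- rep(1:3, C)
  n1 <- ntv[3L * cod_of - 2L]
  n2 <- ntv[3L * cod_of - 1L]
  n3 <- ntv[3L * cod_of]
  code_cur <- 1L + 16L * (n1 - 1L) + 4L * (n2 - 1L) + (n3 - 1L)
  aa_cur <- tab$aa64[code_cur]
  fac <- context_factors(ntv, h)
  rates <- matrix(0, length(ntv), 4L)
  for (b in 1:4) {
    delta <- (b - ntv) * c(16L, 4L, 1L)[pos_of]
    code_new <- code_cur + delta
    valid <- b != ntv & !is.na(tab$aa64[code_new])
    ts <- (pmin(ntv, b) == 1L & pmax(ntv, b) == 3L) |
      (pmin(ntv, b) == 2L & pmax(ntv, b) == 4L)
    syn <- tab$aa64[code_new] == aa_cur
    r <- ifelse(valid,
                kappa ^ ts * ifelse(syn, 1, omega_site[cod_of]) * fac,
                0)
    rates[, b] <- r / scale0
  }
  rates
}

# Mean per-codon rate inflation of the full-h model over its h = 0 baseline
# (mask-weighted, mean-field expectation at the generating pi). Used to
# convert a target REALIZED tree length (expected substitutions per codon,
# the quantity reported as "tree length") into the h = 0-normalized branch
# lengths the simulator consumes.
motif_rate_inflation <- function(params, mask) {
  if (all(params$h == 0)) return(1)
  ctx <- mean_field_context(params$pi)
  qf1 <- raw_q(params, "FWR", ctx)
  qc1 <- raw_q(params, "CDR", ctx)
  scored <- mask != "IGNORED"
  w <- if (any(scored)) mean(mask[scored] == "FWR") else 1
  full <- w * mean_rate(qf1, params$pi) + (1 - w) * mean_rate(qc1, params$pi)
  full / h0_scale(params, mask)
}

# h = 0 normalization constant: mask-weighted mean rate per codon at pi.
h0_scale <- function(params, mask) {
  p0 <- model_params(kappa = params$kappa, omega_fwr = params$omega_fwr,
                     omega_cdr = params$omega_cdr, pi = params$pi)
  qf <- raw_q(p0, "FWR", use_motifs = FALSE)
  qc <- raw_q(p0, "CDR", use_motifs = FALSE)
  scored <- mask != "IGNORED"
  w <- if (any(scored)) mean(mask[scored] == "FWR") else 1
  w * mean_rate(qf, params$pi) + (1 - w) * mean_rate(qc, params$pi)
}

#' Evolve sequences under the fully context-dependent HLP19 process
#'
#' Exact stochastic (Gillespie) simulation along every branch of a
#' germline-rooted tree. The total substitution rate is computed from the
#' current sequence with motif membership evaluated on the actual flanking
#' bases; after each substitution all affected contexts are refreshed.
#' Substitutions that would create a stop codon have rate zero. Branch
#' lengths are interpreted as expected substitutions per codon under the
#' h = 0 base normalization, so hot spots raise the realized substitution
#' count above the nominal branch length.
#'
#' @param germline Stop-free in-frame nucleotide sequence (A/C/G/T).
#' @param tree `phylo` with a tip per evolved sequence plus the germline tip.
#' @param params Generating [model_params()].
#' @param mask Optional [region_mask()] (per codon; defaults to all-FWR).
#'   IGNORED sites evolve like FWR but are excluded from the normalization.
#' @param seed Optional seed (`NULL` = use current RNG state).
#' @param germline_label Tip label of the germline in `tree`.
#' @return Named character vector of tip sequences.
#' @export
evolve_hlp19_full_context <- function(germline, tree, params, mask = NULL,
                                      seed = NULL,
                                      germline_label = GERMLINE_LABEL) {
  run <- function() {
    ntv <- nt_ints(germline)
    C <- length(ntv) / 3L
    if (is.null(mask)) mask <- region_mask(rep("FWR", C))
    mask <- as.character(mask)
    omega_site <- ifelse(mask == "CDR", params$omega_cdr, params$omega_fwr)
    scale0 <- h0_scale(params, mask)
    tips <- setdiff(tree$tip.label, germline_label)
    plan <- plan_tree(tree, germline_label, tips)
    node_seq <- vector("list", plan$n_nodes)
    node_seq[[plan$root + 1L]] <- ntv
    for (e in rev(seq_len(nrow(plan$edges)))) {
      parent <- plan$edges[e, 1] + 1L
      child <- plan$edges[e, 2] + 1L
      node_seq[[child]] <- gillespie_branch(node_seq[[parent]], plan$bl[e],
                                            omega_site, params, scale0)
    }
    out <- vapply(seq_along(tips), function(i) ints_nt(node_seq[[i]]),
                  character(1))
    stats::setNames(out, tips)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

gillespie_branch <- function(ntv, t_total, omega_site, params, scale0) {
  if (t_total <= 0) return(ntv)
  t <- 0
  repeat {
    rates <- hlp19_rate_table(ntv, omega_site, params$h, params$kappa, scale0)
    tot <- sum(rates)
    if (tot <= 0) return(ntv)
    t <- t + stats::rexp(1, rate = tot)
    if (t > t_total) return(ntv)
    pick <- sample.int(length(rates), 1L, prob = as.vector(rates))
    site <- (pick - 1L) %% nrow(rates) + 1L
    base <- (pick - 1L) %/% nrow(rates) + 1L
    ntv[site] <- base
  }
}

# ---- 5-mer mutability-table evolution ---------------------------------------

#' Synthetic 5-mer mutability table
#'
#' A mutability and substitution table over all 1024 fully determined 5-mers
#' built from the package's motif definitions rather than from empirical SHM
#' data: the center base's mutability is the product of `1 + h` over the
#' motifs whose target coincides with the center (reference h values 4, 6,
#' 4, 2, -0.6, -0.6 for WRC, GYW, WA, TW, SYC, GRS), and the substitution
#' profile favours transitions 2:1. It reproduces the qualitative hot/cold
#' ranking of empirical 5-mer SHM models and exists so the table-driven
#' simulator can be exercised without any external data; it is synthetic and
#' not a substitute for an empirically derived table.
#'
#' @return A tibble with columns `fivemer`, `mutability`, `sub_A`, `sub_C`,
#'   `sub_G`, `sub_T` (substitution profile over replacement bases; rows sum
#'   to 1, the current base has probability 0).
#' @export
synthetic_mutability_table <- function() {
  h_ref <- c(WRC = 4, GYW = 6, WA = 4, TW = 2, SYC = -0.6, GRS = -0.6)
  kappa <- 2
  grid <- expand.grid(p1 = NUC, p2 = NUC, p3 = NUC, p4 = NUC, p5 = NUC,
                      stringsAsFactors = FALSE)
  fivemers <- apply(grid[, c("p1", "p2", "p3", "p4", "p5")], 1, paste,
                    collapse = "")
  fivemers <- sort(fivemers)
  motifs <- shm_motifs()
  mut <- vapply(fivemers, function(fm) {
    m <- 1
    for (mi in seq_len(nrow(motifs))) {
      if (2L %in% motif_hits(fm, motifs$name[mi])) {
        m <- m * (1 + h_ref[[motifs$name[mi]]])
      }
    }
    m
  }, numeric(1))
  prof <- t(vapply(fivemers, function(fm) {
    center <- substr(fm, 3, 3)
    p <- vapply(NUC, function(b) {
      if (b == center) return(0)
      pair <- sort(c(center, b))
      ts <- identical(pair, c("A", "G")) || identical(pair, c("C", "T"))
      if (ts) kappa else 1
    }, numeric(1))
    p / sum(p)
  }, numeric(4)))
  tibble::tibble(fivemer = fivemers, mutability = unname(mut),
                 sub_A = prof[, 1], sub_C = prof[, 2], sub_G = prof[, 3],
                 sub_T = prof[, 4])
}

# Lookup helpers with fallback: a 5-mer containing N (sequence edges) is
# scored as the average over all table entries matching its resolved bases.
mutability_lookup <- function(table) {
  mu <- stats::setNames(table$mutability, table$fivemer)
  prof <- as.matrix(table[, c("sub_A", "sub_C", "sub_G", "sub_T")])
  rownames(prof) <- table$fivemer
  cache <- new.env(parent = emptyenv())
  get_entry <- function(fm) {
    if (!grepl("N", fm, fixed = TRUE)) {
      if (!is.na(mu[fm])) {
        return(list(mu = mu[[fm]], prof = prof[fm, ]))
      }
      # table may be partial: marginalize over everything
      fm_key <- fm
    } else {
      fm_key <- fm
    }
    if (!is.null(cache[[fm_key]])) return(cache[[fm_key]])
    pat <- gsub("N", "[ACGT]", paste0("^", fm_key, "$"))
    hit <- grepl(pat, table$fivemer)
    if (!any(hit)) {
      ent <- list(mu = mean(table$mutability), prof = colMeans(prof))
    } else {
      ent <- list(mu = mean(table$mutability[hit]),
                  prof = colMeans(prof[hit, , drop = FALSE]))
    }
    cache[[fm_key]] <- ent
    ent
  }
  get_entry
}

#' Evolve sequences under a 5-mer mutability table
#'
#' As [evolve_hlp19_full_context()] but with per-base substitution rates
#' proportional to the 5-mer mutability centred on the base and replacement
#' identities drawn from the table's substitution profile; substitutions
#' creating stop codons are disallowed (their profile mass is dropped).
#' Rates are normalized by the germline's mean mutability so branch lengths
#' remain expected substitutions per codon for a uniform table. 5-mers
#' extending past the sequence ends fall back to the average over matching
#' entries.
#'
#' @inheritParams evolve_hlp19_full_context
#' @param table Mutability table (columns `fivemer`, `mutability`,
#'   `sub_A`..`sub_T`), e.g. [synthetic_mutability_table()] or
#'   [read_mutability_table()].
#' @return Named character vector of tip sequences.
#' @export
evolve_s5f <- function(germline, tree, table, seed = NULL,
                       germline_label = GERMLINE_LABEL) {
  lookup <- mutability_lookup(table)
  run <- function() {
    ntv <- nt_ints(germline)
    germ_mu <- site_mutabilities(ntv, lookup)$mu
    scale0 <- 3 * mean(germ_mu)
    tips <- setdiff(tree$tip.label, germline_label)
    plan <- plan_tree(tree, germline_label, tips)
    node_seq <- vector("list", plan$n_nodes)
    node_seq[[plan$root + 1L]] <- ntv
    for (e in rev(seq_len(nrow(plan$edges)))) {
      parent <- plan$edges[e, 1] + 1L
      child <- plan$edges[e, 2] + 1L
      node_seq[[child]] <- s5f_branch(node_seq[[parent]], plan$bl[e], lookup,
                                      scale0)
    }
    out <- vapply(seq_along(tips), function(i) ints_nt(node_seq[[i]]),
                  character(1))
    stats::setNames(out, tips)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

site_mutabilities <- function(ntv, lookup) {
  n <- length(ntv)
  padded <- c("N", "N", NUC[ntv], "N", "N")
  mu <- numeric(n)
  prof <- matrix(0, n, 4L)
  for (i in seq_len(n)) {
    fm <- paste(padded[i:(i + 4L)], collapse = "")
    ent <- lookup(fm)
    mu[i] <- ent$mu
    prof[i, ] <- ent$prof
  }
  list(mu = mu, prof = prof)
}

s5f_branch <- function(ntv, t_total, lookup, scale0) {
  if (t_total <= 0) return(ntv)
  tab <- codon_code_tables()
  t <- 0
  repeat {
    sm <- site_mutabilities(ntv, lookup)
    C <- length(ntv) / 3L
    cod_of <- rep(seq_len(C), each = 3L)
    pos_of <- rep(1:3, C)
    code_cur <- 1L + 16L * (ntv[3L * cod_of - 2L] - 1L) +
      4L * (ntv[3L * cod_of - 1L] - 1L) + (ntv[3L * cod_of] - 1L)
    rates <- matrix(0, length(ntv), 4L)
    for (b in 1:4) {
      delta <- (b - ntv) * c(16L, 4L, 1L)[pos_of]
      valid <- b != ntv & !is.na(tab$aa64[code_cur + delta])
      rates[, b] <- ifelse(valid, sm$mu * sm$prof[, b], 0) / scale0
    }
    tot <- sum(rates)
    if (tot <= 0) return(ntv)
    t <- t + stats::rexp(1, rate = tot)
    if (t > t_total) return(ntv)
    pick <- sample.int(length(rates), 1L, prob = as.vector(rates))
    site <- (pick - 1L) %% nrow(rates) + 1L
    ntv[site] <- (pick - 1L) %/% nrow(rates) + 1L
  }
}

#' Mean mutability of 5-mers matching an SHM motif
#'
#' Averages a mutability table's scores (uniform weighting) over all fully
#' determined 5-mers whose center base is the targeted base of an occurrence
#' of the motif.
#'
#' @param table Mutability table (see [evolve_s5f()]).
#' @param motif Motif name or spec (see [motif_hits()]).
#' @return The mean mutability (a single number).
#' @export
motif_mean_mutability <- function(table, motif) {
  keep <- grepl("^[ACGT]{5}$", table$fivemer)
  fm <- table$fivemer[keep]
  mu <- table$mutability[keep]
  match_center <- vapply(fm, function(x) 2L %in% motif_hits(x, motif),
                         logical(1))
  if (!any(match_center)) {
    stop("no 5-mer in the table has its center targeted by this motif",
         call. = FALSE)
  }
  mean(mu[match_center])
}

# ---- fixture generation ------------------------------------------------------

#' Generate a synthetic repertoire fixture
#'
#' Draws germline ancestors as random stop-free codon sequences, clone sizes
#' from the configured law, coalescent trees scaled to the configured mean
#' tree length, and evolves tip sequences with the configured generator. The
#' result is a ready-to-fit [repertoire()] whose generating truth travels in
#' `attr(, "truth")`; optionally the fixture is written out as AIRR TSV,
#' per-clone FASTA, Newick trees and a JSON manifest.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory for the on-disk fixture.
#' @return A `bcr_repertoire` with trees, mask and germlines set; attribute
#'   `truth` holds the generating parameters and configuration.
#' @export
generate_repertoire_fixture <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rep_obj <- withr::with_seed(config$seed, {
    mask <- default_vregion_mask(config$n_codons, config$cdr_fraction)
    scale <- config$branch_scale
    if (config$tree_length_units == "realized" &&
        config$generator == "hlp19_full_context") {
      scale <- scale / motif_rate_inflation(config$params, mask)
    }
    sizes <- sample_clone_sizes(config$n_lineages, config$clone_size_law)
    lineages <- vector("list", config$n_lineages)
    for (i in seq_len(config$n_lineages)) {
      id <- sprintf("clone_%04d", i)
      germ <- random_germline(config$n_codons)
      tipn <- sprintf("%s_s%02d", id, seq_len(sizes[i]))
      tr <- random_lineage_tree(tipn, scale)
      tipseq <- if (config$generator == "hlp19_full_context") {
        evolve_hlp19_full_context(germ, tr, config$params, mask = mask)
      } else {
        evolve_s5f(germ, tr, config$mutability)
      }
      lineages[[i]] <- lineage_data(tipseq, germ, mask = mask, tree = tr,
                                    id = id)
    }
    repertoire(lineages)
  })
  truth <- list(params = params_to_flat(config$params, "hlp19"),
                config = config[setdiff(names(config),
                                        c("params", "mutability"))])
  attr(rep_obj, "truth") <- truth
  if (!is.null(out_dir)) write_fixture(rep_obj, out_dir, truth)
  rep_obj
}

write_fixture <- function(rep_obj, out_dir, truth) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_airr(rep_obj, file.path(out_dir, "repertoire.tsv"))
  write_region_mask(rep_obj$lineages[[1]]$mask, file.path(out_dir, "mask.tsv"))
  write_lineage_trees(rep_obj, file.path(out_dir, "trees.nwk"))
  fasta_dir <- file.path(out_dir, "fasta")
  dir.create(fasta_dir, showWarnings = FALSE)
  for (lin in rep_obj$lineages) {
    seqs <- c(stats::setNames(lin$germline, lin$germline_label), lin$sequences)
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)),
               file.path(fasta_dir, paste0(lin$id, ".fasta")))
  }
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Subsample a repertoire's nonsingleton clones
#'
#' Uniformly samples (without replacement) `depth` sequences from the pool of
#' sequences belonging to nonsingleton clones (clones with more than one
#' unique sequence); clones reduced below two unique sequences are dropped,
#' singleton clones pass through untouched. Trees of modified clones are
#' removed (topologies must be re-estimated after subsampling).
#'
#' @param rep A [repertoire()].
#' @param depth Target number of retained nonsingleton-clone sequences.
#' @param seed Optional seed.
#' @return The subsampled `bcr_repertoire`.
#' @export
subsample_repertoire <- function(rep, depth, seed = NULL) {
  stopifnot(depth >= 1)
  run <- function() {
    is_nonsingleton <- vapply(rep$lineages, function(l) {
      length(unique(unname(l$sequences))) > 1L
    }, logical(1))
    pool <- do.call(rbind, lapply(which(is_nonsingleton), function(i) {
      data.frame(lin = i, seq = names(rep$lineages[[i]]$sequences),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pool) || nrow(pool) <= depth) {
      if (!is.null(pool) && nrow(pool) < depth) {
        warning("depth ", depth, " exceeds the ", nrow(pool),
                " available nonsingleton-clone sequences; returning unchanged")
      }
      return(rep)
    }
    keep <- pool[sample.int(nrow(pool), depth), ]
    out <- list()
    for (i in seq_along(rep$lineages)) {
      lin <- rep$lineages[[i]]
      if (!is_nonsingleton[i]) {
        out[[length(out) + 1L]] <- lin
        next
      }
      kept <- keep$seq[keep$lin == i]
      if (length(unique(unname(lin$sequences[kept]))) < 2L) next
      lin$sequences <- lin$sequences[kept]
      lin$tree <- NULL
      out[[length(out) + 1L]] <- lin
    }
    repertoire(out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
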