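# Codon alphabet, genetic-code classifications, SHM motifs and region masks.
# Everything downstream (rate matrices, likelihood, simulators) consumes these
# definitions, so the ordering and coordinate conventions fixed here are final:
# codons are ordered lexicographically with A < C < G < T, stop codons removed,
# and nucleotide coordinates are 0-based half-open wherever they are exchanged
# with other modules.

.bcr <- new.env(parent = emptyenv())

NUC <- c("A", "C", "G", "T")

#' The sense-codon state space
#'
#' Builds (once per session) the ordered set of the 61 sense codons of the
#' standard genetic code, their translations, and the table of all
#' single-nucleotide codon pairs with transition/transversion and
#' synonymous/nonsynonymous classifications. This is the state space of the
#' 61 x 61 instantaneous rate matrices used throughout the package.
#'
#' @return An object of class `codon_space`: a list with elements
#'   * `codons` — character vector of the 61 sense codons, lexicographic
#'     (A < C < G < T), stop codons (TAA, TAG, TGA) excluded;
#'   * `index` — named integer vector mapping codon string to 1-based index;
#'   * `aa` — amino-acid letter per codon;
#'   * `nt` — 61 x 3 integer matrix of nucleotide codes (1=A, 2=C, 3=G, 4=T);
#'   * `subs` — data frame of all ordered sense-codon pairs differing at
#'     exactly one nucleotide, with columns `a`, `b` (1-based codon indices),
#'     `pos` (1..3, the differing codon position), `to` (nucleotide code of
#'     the replacement base), `ts` (transition?), `syn` (synonymous?).
#' @export
codon_space <- function() {
  if (!is.null(.bcr$codon_space)) return(.bcr$codon_space)
  gc_tab <- Biostrings::GENETIC_CODE
  all64 <- sort(names(gc_tab))  # lexicographic, A<C<G<T
  sense <- all64[gc_tab[all64] != "*"]
  stopifnot(length(sense) == 61L)
  nt <- t(vapply(strsplit(sense, ""), function(x) match(x, NUC), integer(3)))
  dimnames(nt) <- NULL
  idx <- stats::setNames(seq_along(sense), sense)
  aa <- unname(gc_tab[sense])

  # enumerate single-nucleotide neighbours
  rows <- list()
  for (a in seq_len(61L)) {
    for (pos in 1:3) {
      for (to in seq_len(4L)[-nt[a, pos]]) {
        bnt <- nt[a, ]
        bnt[pos] <- to
        bstr <- paste(NUC[bnt], collapse = "")
        b <- idx[bstr]
        if (is.na(b)) next  # stop codon target
        ts <- (sort(c(nt[a, pos], to))[1] == 1L && sort(c(nt[a, pos], to))[2] == 3L) ||
          (sort(c(nt[a, pos], to))[1] == 2L && sort(c(nt[a, pos], to))[2] == 4L)
        rows[[length(rows) + 1L]] <- c(a, unname(b), pos, to, as.integer(ts),
                                       as.integer(aa[a] == aa[b]))
      }
    }
  }
  subs <- as.data.frame(do.call(rbind, rows))
  names(subs) <- c("a", "b", "pos", "to", "ts", "syn")
  subs$ts <- as.logical(subs$ts)
  subs$syn <- as.logical(subs$syn)

  cs <- structure(list(codons = sense, index = idx, aa = aa, nt = nt, subs = subs),
                  class = "codon_space")
  .bcr$codon_space <- cs
  cs
}

#' @export
print.codon_space <- function(x, ...) {
  cat("<codon_space>: 61 sense codons, standard genetic code,",
      "lexicographic order (A<C<G<T)\n")
  invisible(x)
}

is_stop_codon <- function(codon) {
  toupper(codon) %in% c("TAA", "TAG", "TGA")
}

check_sense_codon <- function(codon, arg = "codon") {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop(sprintf("`%s` must be a 3-letter A/C/G/T string, got \"%s\"", arg, codon),
         call. = FALSE)
  }
  if (is_stop_codon(codon)) {
    stop(sprintf("`%s` is the stop codon %s; only sense codons are modeled", arg, codon),
         call. = FALSE)
  }
  codon
}

#' Classify a codon-to-codon substitution
#'
#' Reports which nucleotide positions differ between two sense codons, whether
#' the change is a transition (defined only for single-nucleotide differences)
#' and whether it is synonymous. These classifications drive the kappa and
#' omega factors of the substitution models.
#'
#' @param codon_a,codon_b Sense codons (3-letter A/C/G/T strings; stop codons
#'   are rejected).
#' @return A list with `positions_differing` (0-based integer vector),
#'   `is_transition` (logical, `NA` unless exactly one position differs) and
#'   `is_synonymous` (logical).
#' @examples
#' classify_substitution("AAA", "AAG")  # third-position transition, both Lys
#' @export
classify_substitution <- function(codon_a, codon_b) {
  codon_a <- check_sense_codon(codon_a, "codon_a")
  codon_b <- check_sense_codon(codon_b, "codon_b")
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  diff0 <- which(a != b) - 1L
  is_ts <- NA
  if (length(diff0) == 1L) {
    pair <- sort(c(a[diff0 + 1L], b[diff0 + 1L]))
    is_ts <- identical(pair, c("A", "G")) || identical(pair, c("C", "T"))
  }
  cs <- codon_space()
  list(
    positions_differing = diff0,
    is_transition = is_ts,
    is_synonymous = cs$aa[cs$index[[codon_a]]] == cs$aa[cs$index[[codon_b]]]
  )
}

# ---- SHM motifs --------------------------------------------------------------

IUPAC_CLASS <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), S = c("C", "G"), R = c("A", "G"), Y = c("C", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' The six SHM hot-/cold-spot motifs
#'
#' The canonical AID / polymerase-eta targeting motifs used by the HLP models.
#' Each motif modifies the substitution rate of a single base (the target)
#' within an IUPAC pattern: WRC and its reverse complement GYW (AID hot spots,
#' targeting the C resp. G), WA / TW (polymerase-eta hot spots, targeting the
#' A resp. T) and SYC / GRS (cold spots, targeting the C resp. G). The three
#' pairs are reverse complements of each other, with mirrored target offsets.
#'
#' @return A tibble with columns `name`, `pattern` (IUPAC string) and
#'   `target_offset` (0-based position of the targeted base in the pattern).
#' @export
shm_motifs <- function() {
  tibble::tibble(
    name = c("WRC", "GYW", "WA", "TW", "SYC", "GRS"),
    pattern = c("WRC", "GYW", "WA", "TW", "SYC", "GRS"),
    target_offset = c(2L, 0L, 1L, 0L, 2L, 0L)
  )
}

motif_partner <- c(WRC = "GYW", GYW = "WRC", WA = "TW", TW = "WA",
                   SYC = "GRS", GRS = "SYC")

#' Reverse complement of a nucleotide string
#'
#' Handles the full IUPAC alphabet (so motif patterns can be complemented,
#' not just A/C/G/T sequences).
#'
#' @param x A nucleotide string.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", W = "W", S = "S", R = "Y",
            Y = "R", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N")
  chartr_in <- paste(names(comp), collapse = "")
  chartr_out <- paste(comp, collapse = "")
  vapply(x, function(s) {
    paste(rev(strsplit(chartr(chartr_in, chartr_out, toupper(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Locate motif target bases in a sequence
#'
#' Scans `sequence` for occurrences of an SHM motif and returns the 0-based
#' positions of the targeted base of every occurrence (overlapping occurrences
#' allowed). Windows containing ambiguous (non-ACGT) bases are skipped with a
#' message.
#'
#' @param sequence A nucleotide string over A/C/G/T (ambiguity codes allowed
#'   but skipped).
#' @param motif Either a motif name from [shm_motifs()] or a one-row data
#'   frame / list with `pattern` and `target_offset`.
#' @return Integer vector of 0-based target positions (sorted).
#' @examples
#' motif_hits("TACG", "WRC")  # TAC matches W=T, R=A, C: target C at position 2
#' @export
motif_hits <- function(sequence, motif) {
  if (is.character(motif) && length(motif) == 1L) {
    m <- shm_motifs()
    row <- m[m$name == toupper(motif), ]
    if (nrow(row) == 0L) stop("unknown motif name: ", motif, call. = FALSE)
    motif <- as.list(row)
  }
  pat <- strsplit(toupper(motif$pattern), "")[[1]]
  off <- as.integer(motif$target_offset)
  if (off < 0L || off >= length(pat)) {
    stop("target_offset out of pattern bounds", call. = FALSE)
  }
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  L <- length(pat)
  if (n < L) return(integer(0))
  hits <- integer(0)
  n_skipped <- 0L
  for (start in seq_len(n - L + 1L)) {
    win <- s[start:(start + L - 1L)]
    if (any(!win %in% NUC)) {
      n_skipped <- n_skipped + 1L
      next
    }
    ok <- all(vapply(seq_len(L), function(j) win[j] %in% IUPAC_CLASS[[pat[j]]],
                     logical(1)))
    if (ok) hits <- c(hits, start - 1L + off)
  }
  if (n_skipped > 0L) {
    message(n_skipped, " window(s) with ambiguous bases skipped during motif scan")
  }
  sort(hits)
}

# ---- Region masks ------------------------------------------------------------

#' Per-codon region mask
#'
#' Validates a vector of per-codon-site region labels. `FWR` and `CDR` sites
#' use the region-specific omega; `IGNORED` sites (e.g. the excised CDR3,
#' whose germline junction cannot be predicted reliably) contribute likelihood
#' one and are excluded from every computation.
#'
#' @param labels Character vector over `FWR`, `CDR`, `IGNORED`, one entry per
#'   codon site of the alignment.
#' @return The validated mask (character vector, class `region_mask`).
#' @export
region_mask <- function(labels) {
  labels <- toupper(as.character(labels))
  bad <- setdiff(unique(labels), c("FWR", "CDR", "IGNORED"))
  if (length(bad) > 0L) {
    stop("invalid region labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!any(labels != "IGNORED")) {
    stop("mask needs at least one non-IGNORED site", call. = FALSE)
  }
  structure(labels, class = "region_mask")
}

#' Default V-region-like mask
#'
#' A simple stand-in for an IMGT-delimited V region with the CDR3 removed:
#' two contiguous CDR blocks (mimicking CDR1 and CDR2) embedded in framework,
#' jointly covering `cdr_fraction` of the sites.
#'
#' @param n_codons Number of codon sites.
#' @param cdr_fraction Fraction of sites labelled CDR (split over two blocks).
#' @return A [region_mask()].
#' @export
default_vregion_mask <- function(n_codons, cdr_fraction = 0.25) {
  stopifnot(n_codons >= 4, cdr_fraction > 0, cdr_fraction < 1)
  n_cdr <- max(2L, round(n_codons * cdr_fraction))
  b1 <- ceiling(n_cdr / 2)
  b2 <- n_cdr - b1
  lab <- rep("FWR", n_codons)
  s1 <- max(1L, floor(n_codons * 0.25))
  lab[seq(s1, length.out = min(b1, n_codons - s1 + 1L))] <- "CDR"
  s2 <- max(1L, floor(n_codons * 0.65))
  lab[seq(s2, length.out = min(b2, n_codons - s2 + 1L))] <- "CDR"
  region_mask(lab)
}
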