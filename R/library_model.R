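#' Degenerate-codon nucleotide mixtures
#'
#' A `nucleotide_mix` holds the per-position nucleotide fractions of one
#' degenerate codon: a 3 x 4 matrix (codon positions x A/C/G/T). Each row
#' must be non-negative and sum to 1 within 1e-9.
#'
#' @param p1,p2,p3 numeric length-4 vectors of A, C, G, T fractions for the
#'   three codon positions. Names are optional; unnamed vectors are taken in
#'   A, C, G, T order.
#' @return an object of class `nucleotide_mix`.
#' @examples
#' m <- nucleotide_mix(c(.25, .25, .25, .25), c(1, 0, 0, 0), c(0, 0, 1, 0))
#' codon_aa_distribution(m)
#' @export
nucleotide_mix <- function(p1, p2, p3) {
  nt <- c("A", "C", "G", "T")
  norm1 <- function(p) {
    stopifnot(length(p) == 4)
    if (!is.null(names(p))) {
      stopifnot(setequal(names(p), nt))
      p <- p[nt]
    }
    if (any(p < -1e-12))
      stop("nucleotide frequencies must be non-negative", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-9)
      stop("nucleotide frequencies must sum to 1 (got ", sum(p), ")",
           call. = FALSE)
    unname(pmax(p, 0))
  }
  m <- rbind(norm1(p1), norm1(p2), norm1(p3))
  dimnames(m) <- list(pos = 1:3, nt = nt)
  structure(m, class = "nucleotide_mix")
}

#' The CDR' degenerate codon
#'
#' The unbalanced nucleotide mixture used at fully diversified loop sites to
#' approximate the amino-acid bias of antibody CDR-H3: position 1 is
#' 20\% A / 15\% C / 25\% G / 40\% T, position 2 is 50/25/15/10 and position 3
#' is 0/45/10/45. It encodes roughly 18\% tyrosine, 4\% glycine, 5\% cysteine
#' and 2\% stop (TAG only, since position 3 carries no A).
#'
#' @return a [nucleotide_mix()].
#' @export
cdr_prime_mix <- function() {
  nucleotide_mix(c(A = .20, C = .15, G = .25, T = .40),
                 c(A = .50, C = .25, G = .15, T = .10),
                 c(A = .00, C = .45, G = .10, T = .45))
}

#' Exact amino-acid distribution of a degenerate codon
#'
#' Enumerates all 64 codons; the probability of each codon is the product of
#' its three positional nucleotide fractions, and amino-acid probabilities
#' are sums over synonymous codons. Stops (TAA/TAG/TGA) are reported under
#' `"*"`.
#'
#' @param mix a [nucleotide_mix()].
#' @return named numeric vector over [AA21] summing to 1 (class
#'   `aa_distribution`).
#' @export
codon_aa_distribution <- function(mix) {
  stopifnot(inherits(mix, "nucleotide_mix"))
  gc <- .genetic_code()
  nt <- c("A", "C", "G", "T")
  codons <- names(gc)
  p <- mix[1, substr(codons, 1, 1)] *
       mix[2, substr(codons, 2, 2)] *
       mix[3, substr(codons, 3, 3)]
  out <- setNames(numeric(21), AA21)
  agg <- tapply(p, gc, sum)
  out[names(agg)] <- agg
  structure(out, class = "aa_distribution")
}

.aa_dist <- function(probs) {
  # lift a named amino-acid probability vector to the full AA21 support
  .check_aa(names(probs))
  if (any(probs < -1e-12)) stop("negative amino-acid fraction", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-9)
    stop("amino-acid fractions must sum to 1", call. = FALSE)
  out <- setNames(numeric(21), AA21)
  out[names(probs)] <- probs
  structure(out, class = "aa_distribution")
}

#' Sitewise library design elements
#'
#' A `site_spec` describes the designed diversity at one reference site.
#' Three kinds exist: `conserved` (one residue at probability 1),
#' `fixed_set` (an explicit amino-acid probability map, synthesised as e.g.
#' trimer codons or tailored degeneracies) and `degenerate_codon`
#' (a [nucleotide_mix()] sampled at the nucleotide level, so stop codons can
#' arise).
#'
#' @param label reference site label, e.g. `"D23"` (wild-type residue +
#'   residue number) or an insertion label such as `"28a"`.
#' @param aas character vector of amino acids for `fixed_set_site`
#'   (equal fractions) / a single amino acid for `conserved_site`.
#' @param probs optional named fractions for `fixed_set_site` (overrides the
#'   equal split).
#' @param mix a [nucleotide_mix()] for `degenerate_site`.
#' @return an object of class `site_spec`.
#' @name site_spec
NULL

#' @rdname site_spec
#' @export
fixed_set_site <- function(label, aas, probs = NULL) {
  if (is.null(probs)) {
    aas <- strsplit(paste(aas, collapse = ""), "", fixed = TRUE)[[1]]
    .check_aa(aas)
    stopifnot(!anyDuplicated(aas), !"*" %in% aas)
    probs <- setNames(rep(1 / length(aas), length(aas)), aas)
  }
  structure(list(label = label, kind = "fixed_set", probs = probs),
            class = "site_spec")
}

#' @rdname site_spec
#' @export
conserved_site <- function(label, aas) {
  stopifnot(nchar(aas) == 1)
  .check_aa(aas)
  structure(list(label = label, kind = "conserved",
                 probs = setNames(1, aas)), class = "site_spec")
}

#' @rdname site_spec
#' @export
degenerate_site <- function(label, mix = cdr_prime_mix()) {
  stopifnot(inherits(mix, "nucleotide_mix"))
  structure(list(label = label, kind = "degenerate_codon", mix = mix),
            class = "site_spec")
}

# full AA21 distribution of one site_spec (stops only from degenerate codons)
site_aa_distribution <- function(spec) {
  stopifnot(inherits(spec, "site_spec"))
  if (spec$kind == "degenerate_codon") codon_aa_distribution(spec$mix)
  else .aa_dist(spec$probs)
}

site_stop_fraction <- function(spec) {
  unname(site_aa_distribution(spec)["*"])
}

#' Loop designs and length variants
#'
#' A `loop_design` lists, for one loop (BC, DE or FG), the alternative
#' length variants: each variant is an ordered sequence of [site_spec]s with
#' a prior weight. Weights are normalised to sum to 1.
#'
#' @param loop_id one of `"BC"`, `"DE"`, `"FG"`.
#' @param variants list of `list(sites = <list of site_spec>, weight = w)`.
#' @return an object of class `loop_design`.
#' @export
loop_design <- function(loop_id, variants) {
  loop_id <- match.arg(loop_id, c("BC", "DE", "FG"))
  stopifnot(length(variants) >= 1)
  w <- vapply(variants, function(v) v$weight, numeric(1))
  stopifnot(all(w > 0))
  w <- w / sum(w)
  lens <- vapply(variants, function(v) length(v$sites), integer(1))
  if (anyDuplicated(lens))
    stop("loop length variants must have distinct lengths", call. = FALSE)
  variants <- Map(function(v, wi) list(sites = v$sites, weight = wi),
                  variants, w)
  structure(list(loop_id = loop_id, variants = variants),
            class = "loop_design")
}

#' Combinatorial library designs
#'
#' A `library_design` pools sublibraries at given weights; each sublibrary
#' carries one [loop_design()] per loop (BC, DE, FG) plus a shared framework:
#' the conserved reference protein/DNA and the residue-number ranges of the
#' three diversified regions.
#'
#' @param generation free-form tag (e.g. `"gen1"`).
#' @param sublibraries list of
#'   `list(loops = list(BC=, DE=, FG=), weight = w)`; weights are normalised.
#' @param framework list with elements `protein` (reference amino-acid
#'   string), `dna` (in-frame coding DNA, `3 * nchar(protein)` nt) and
#'   `loops`, a named list of `c(first, last)` residue numbers for BC, DE
#'   and FG. Defaults to the packaged synthetic hydrophilic-Fn3 framework.
#' @return an object of class `library_design`.
#' @export
library_design <- function(generation, sublibraries,
                           framework = fn3hp_framework()) {
  if (!length(sublibraries))
    stop("a library design needs at least one sublibrary", call. = FALSE)
  w <- vapply(sublibraries, function(s) s$weight, numeric(1))
  stopifnot(all(w > 0))
  w <- w / sum(w)
  sublibraries <- Map(function(s, wi) list(loops = s$loops, weight = wi),
                      sublibraries, w)
  for (s in sublibraries) {
    stopifnot(setequal(names(s$loops), c("BC", "DE", "FG")))
    for (ld in s$loops) stopifnot(inherits(ld, "loop_design"))
  }
  stopifnot(is.character(framework$protein),
            nchar(framework$dna) == 3 * nchar(framework$protein))
  rg <- framework$loops
  stopifnot(setequal(names(rg), c("BC", "DE", "FG")))
  ord <- rg[order(vapply(rg, `[`, numeric(1), 1))]
  for (i in seq_along(ord)) {
    stopifnot(ord[[i]][1] <= ord[[i]][2])
    if (i > 1) stopifnot(ord[[i]][1] > ord[[i - 1]][2])  # non-overlapping
  }
  structure(list(generation = generation, sublibraries = sublibraries,
                 framework = framework),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat("<library_design>", x$generation, "-", length(x$sublibraries),
      if (length(x$sublibraries) == 1) "sublibrary" else "sublibraries",
      "\n")
  for (loop in c("BC", "DE", "FG")) {
    lens <- sort(unique(unlist(lapply(x$sublibraries, function(s)
      vapply(s$loops[[loop]]$variants, function(v) length(v$sites),
             integer(1))))))
    cat("  ", loop, "loop lengths:", paste(lens, collapse = "/"), "\n")
  }
  invisible(x)
}

# ---- site bookkeeping -------------------------------------------------------

variant_labels <- function(variant) {
  vapply(variant$sites, function(s) s$label, character(1))
}

#' All site labels of a design
#'
#' Labels are returned in loop order (BC, DE, FG) and within a loop in the
#' order of the longest variant.
#'
#' @param design a [library_design()].
#' @param loop_id optionally restrict to one loop.
#' @return character vector of site labels.
#' @export
design_site_labels <- function(design, loop_id = c("BC", "DE", "FG")) {
  loop_id <- match.arg(loop_id, several.ok = TRUE)
  out <- character(0)
  for (loop in loop_id) {
    labs <- character(0)
    for (s in design$sublibraries) {
      vs <- s$loops[[loop]]$variants
      longest <- vs[[which.max(vapply(vs, function(v) length(v$sites),
                                      integer(1)))]]
      li <- variant_labels(longest)
      labs <- if (length(li) > length(labs)) li else labs
    }
    out <- c(out, labs)
  }
  out
}

#' Theoretical sitewise amino-acid distribution
#'
#' The pool-weighted mixture, over all sublibraries and length variants that
#' contain `site_label`, of the per-variant site distributions, renormalised
#' over the containing variants. Includes the stop fraction contributed by
#' degenerate codons.
#'
#' @param design a [library_design()].
#' @param site_label a reference site label.
#' @return an `aa_distribution` (length 21 over [AA21]).
#' @export
theoretical_site_distribution <- function(design, site_label) {
  acc <- setNames(numeric(21), AA21)
  wtot <- 0
  for (s in design$sublibraries) {
    for (ld in s$loops) {
      for (v in ld$variants) {
        labs <- variant_labels(v)
        hit <- which(labs == site_label)
        if (length(hit)) {
          w <- s$weight * v$weight
          acc <- acc + w * site_aa_distribution(v$sites[[hit[1]]])
          wtot <- wtot + w
        }
      }
    }
  }
  if (wtot == 0) stop("unknown site label: ", site_label, call. = FALSE)
  structure(acc / wtot, class = "aa_distribution")
}

#' Stop-free fraction of a design
#'
#' The pool- and length-weighted probability that no diversified codon of a
#' sampled clone encodes a stop: within each sublibrary the product over
#' loops of the variant-weighted product over sites of
#' `1 - stop fraction`.
#'
#' @param design a [library_design()].
#' @return a fraction in (0, 1].
#' @export
stop_free_fraction <- function(design) {
  tot <- 0
  for (s in design$sublibraries) {
    p_sub <- 1
    for (ld in s$loops) {
      p_loop <- 0
      for (v in ld$variants) {
        p_v <- prod(vapply(v$sites,
                           function(sp) 1 - site_stop_fraction(sp),
                           numeric(1)))
        p_loop <- p_loop + v$weight * p_v
      }
      p_sub <- p_sub * p_loop
    }
    tot <- tot + s$weight * p_sub
  }
  tot
}

#' Theoretical loop-length prior of a design
#'
#' @param design a [library_design()].
#' @param loop_id `"BC"`, `"DE"` or `"FG"`.
#' @return named numeric vector: loop length (number of sites) -> prior
#'   probability, pool-weighted over sublibraries.
#' @export
design_length_prior <- function(design, loop_id) {
  acc <- numeric(0)
  for (s in design$sublibraries) {
    for (v in s$loops[[loop_id]]$variants) {
      key <- as.character(length(v$sites))
      acc[key] <- (if (is.na(acc[key])) 0 else acc[key]) +
        s$weight * v$weight
    }
  }
  acc[order(as.integer(names(acc)))]
}

#' Theoretical design model (frequency matrix + length priors)
#'
#' Convenience wrapper used as the exact "naive" reference by the LOOCV
#' scoring: per-site theoretical distributions conditioned on no stop
#' (renormalised over the 20 amino acids), one row per design site label,
#' plus per-loop length priors.
#'
#' @param design a [library_design()].
#' @return list with `fm` (a [frequency_matrix] over all design sites) and
#'   `length_prior` (named list per loop).
#' @export
design_model <- function(design) {
  labs <- design_site_labels(design)
  m <- matrix(0, length(labs), 20, dimnames = list(labs, AA20))
  for (l in labs) {
    d <- theoretical_site_distribution(design, l)[AA20]
    m[l, ] <- d / sum(d)
  }
  fm <- structure(m, class = "frequency_matrix",
                  effective_weight = setNames(rep(1, length(labs)), labs))
  lp <- lapply(setNames(nm = c("BC", "DE", "FG")),
               function(loop) design_length_prior(design, loop))
  list(fm = fm, length_prior = lp)
}
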