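#' Synthetic hydrophilic-Fn3 framework
#'
#' The conserved framework used by the packaged designs: the 94-residue
#' tenth type-III domain of human fibronectin carrying the hydrophilic
#' substitutions V1S, V4S, V11T, A12N, T16N, L19T, V45S and V66Q plus the
#' stabilising D7N. The coding DNA is a *synthetic* back-translation (one
#' fixed codon per residue); the original construct's DNA is not public, and
#' no analysis in the package depends on the codon choice. Diversified
#' regions: BC loop residues 23-31, DE 52-56, FG 76-86.
#'
#' @return list with `protein`, `dna` and `loops` (named residue ranges),
#'   suitable as the `framework` argument of [library_design()].
#' @export
fn3hp_framework <- function() {
  prot <- paste0(
    "SSDSPRNLEV", "TNATPNSLTI", "SWDAPAVTVR", "YYRITYGETG", "GNSPSQEFTV",
    "PGSKSTATIS", "GLKPGQDYTI", "TVYAVTGRGD", "SPASSKPISI", "NYRT")
  aas <- strsplit(prot, "", fixed = TRUE)[[1]]
  dna <- paste(.CODON_OF[aas], collapse = "")
  list(protein = prot, dna = dna,
       loops = list(BC = c(23L, 31L), DE = c(52L, 56L), FG = c(76L, 86L)))
}

# ---- structured design specs ------------------------------------------------

# spec-list helpers (plain lists, JSON-serialisable)
.sp_cons <- function(label, aa)
  list(label = label, kind = "conserved", aas = aa)
.sp_set <- function(label, aas, probs = NULL) {
  x <- list(label = label, kind = "fixed_set", aas = aas)
  if (!is.null(probs)) x$probs <- as.list(probs)
  x
}
.sp_deg <- function(label, mix = "CDR")
  list(label = label, kind = "degenerate_codon", mix = mix)

#' Build a library design from a structured spec
#'
#' Consumes the plain-list (JSON-compatible) design description used by the
#' packaged generation-1/2 files: named degenerate-codon mixes, then
#' sublibraries, each a set of per-loop length variants made of site
#' entries `list(label=, kind=, aas=/probs=/mix=)`.
#'
#' @param spec a list with elements `generation`, `mixes` (named list of
#'   `list(p1=, p2=, p3=)`) and `sublibraries`.
#' @param framework see [library_design()].
#' @return a [library_design()].
#' @seealso [read_design()], [write_design()]
#' @export
build_design <- function(spec, framework = fn3hp_framework()) {
  if (!length(spec$sublibraries))
    stop("design spec has no sublibraries", call. = FALSE)
  mixes <- lapply(spec$mixes, function(m)
    nucleotide_mix(unlist(m$p1), unlist(m$p2), unlist(m$p3)))
  build_site <- function(s) {
    switch(s$kind,
      conserved = conserved_site(s$label, s$aas),
      fixed_set = if (is.null(s$probs)) fixed_set_site(s$label, s$aas)
                  else fixed_set_site(s$label, NULL, unlist(s$probs)),
      degenerate_codon = {
        m <- mixes[[s$mix]]
        if (is.null(m)) stop("unknown mix: ", s$mix, call. = FALSE)
        degenerate_site(s$label, m)
      },
      stop("unknown site kind: ", s$kind, call. = FALSE))
  }
  subs <- lapply(spec$sublibraries, function(sl) {
    loops <- lapply(setNames(nm = c("BC", "DE", "FG")), function(loop) {
      vs <- lapply(sl$loops[[loop]]$variants, function(v)
        list(sites = lapply(v$sites, build_site), weight = v$weight))
      loop_design(loop, vs)
    })
    list(loops = loops, weight = sl$weight)
  })
  library_design(spec$generation, subs, framework)
}

#' Read / write structured design specs (JSON)
#'
#' @param path file path. The package ships `gen1_design.json` and
#'   `gen2_design.json` under `extdata`.
#' @param spec a design spec list (see [build_design()]).
#' @return `read_design` returns a [library_design()].
#' @export
read_design <- function(path) {
  build_design(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

#' @rdname read_design
#' @export
write_design <- function(spec, path) {
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# labels of the variable mid-loop blocks. The first `k` positions reuse the
# wild-type labels of the replaced span; positions beyond the wild-type span
# get insertion labels ("28a", ...), anchored to the last wild-type label.
.block_labels <- function(wt_labels, k) {
  n <- length(wt_labels)
  if (k <= n) return(wt_labels[seq_len(k)])
  last_num <- gsub("[A-Za-z]", "", wt_labels[n])
  c(wt_labels, paste0(last_num, letters[seq_len(k - n)]))
}

.bc_mid_wt <- c("A26", "V27", "T28")
.de_mid_wt <- c("K54")
.fg_mid_wt <- c("D80", "S81", "P82", "A83", "S84")

# one loop spec: fixed flank site builders + a variable CDR-block
.loop_spec <- function(pre, wt_mid, k_range, mid_site, post) {
  variants <- lapply(k_range, function(k) {
    mids <- lapply(.block_labels(wt_mid, k), mid_site)
    list(sites = c(pre, mids, post), weight = 1)
  })
  list(variants = variants)
}

#' Packaged library designs
#'
#' `gen1_design()` is the five-sublibrary first-generation design: BC loop
#' D23/A24/P25 at five diversity levels, one to four CDR' sites replacing
#' A26-T28, V29 constrained to A/S/T, R30 CDR', site 31 from conserved G up
#' to CDR'; DE loop G52-T56 with a zero-to-two-site variable block in place
#' of K54; FG loop with CDR' at G77/R78, G79 constrained to G/D/N/S/Y/C,
#' one to five CDR' sites replacing D80-S84, and graded diversity at
#' T76/S85/K86. Sublibraries are pooled at equal weight and length variants
#' default to equal priors.
#'
#' `gen2_design()` is the single constrained second-generation design:
#' D23/G52/S85 conserved, S85->S and K86->N, A24 and P25 half conserved /
#' half mildly diversified, Y31 G/Y, the DE core S/Y/N/T with an optional
#' K54-like site, T76 T/S/G/A, G77 G/S/Y/A/D/C/N/T, G79 G/S/D/N, and CDR'
#' elsewhere (two to four BC mid sites, one to five FG mid sites).
#'
#' @return a [library_design()].
#' @name packaged_designs
NULL

#' @rdname packaged_designs
#' @export
gen1_design_spec <- function() {
  cdr <- list(p1 = c(.20, .15, .25, .40),
              p2 = c(.50, .25, .15, .10),
              p3 = c(.00, .45, .10, .45))
  # per-sublibrary site sets for the graded positions (Table rows)
  d23 <- list("D",        "DSYA", "DSYA",   "ACDGNSTY", "CDR")
  a24 <- list("A",        "AS",   "ASYD",   "ACDGNSTY", "CDR")
  p25 <- list("P",        "PS",   "PSYH",   "ACDGNSTY", "CDR")
  y31 <- list("G",        "GS",   "GSYCDN", "ACDGNSTY", "CDR")
  g52 <- list("G",        "GS",   "GSYCDN", "ACDGNSTY", "CDR")
  s53 <- list("S",        "S",    "SYNT",   "ACDGNSTY", "CDR")
  k54 <- list("N",        "NS",   "NSYT",   "ACDGNSTY", "CDR")
  s55 <- list("S",        "S",    "SYNT",   "ACDGNSTY", "CDR")
  t56 <- list("T",        "TS",   "TSYN",   "ACDGNSTY", "CDR")
  t76 <- list("T",        "TS",   "TSYN",   "ACDGNSTY", "CDR")
  s85 <- list("S",        "S",    "SYNT",   "ACDGNSTY", "CDR")
  k86 <- list("N",        "NS",   "NSYT",   "ACDGNSTY", "CDR")
  site_of <- function(label, def) {
    if (identical(def, "CDR")) .sp_deg(label)
    else if (nchar(def) == 1) .sp_cons(label, def)
    else .sp_set(label, def)
  }
  subs <- lapply(1:5, function(i) {
    bc <- .loop_spec(
      pre = list(site_of("D23", d23[[i]]), site_of("A24", a24[[i]]),
                 site_of("P25", p25[[i]])),
      wt_mid = .bc_mid_wt, k_range = 1:4, mid_site = .sp_deg,
      post = list(.sp_set("V29", "AST"), .sp_deg("R30"),
                  site_of("Y31", y31[[i]])))
    de_mid <- function(lab) site_of(lab, k54[[i]])
    de <- .loop_spec(
      pre = list(site_of("G52", g52[[i]]), site_of("S53", s53[[i]])),
      wt_mid = .de_mid_wt, k_range = 0:2, mid_site = de_mid,
      post = list(site_of("S55", s55[[i]]), site_of("T56", t56[[i]])))
    fg <- .loop_spec(
      pre = list(site_of("T76", t76[[i]]), .sp_deg("G77"), .sp_deg("R78"),
                 .sp_set("G79", "GDNSYC")),
      wt_mid = .fg_mid_wt, k_range = 1:5, mid_site = .sp_deg,
      post = list(site_of("S85", s85[[i]]), site_of("K86", k86[[i]])))
    list(loops = list(BC = bc, DE = de, FG = fg), weight = 1)
  })
  list(generation = "gen1", mixes = list(CDR = cdr), sublibraries = subs)
}

#' @rdname packaged_designs
#' @export
gen2_design_spec <- function() {
  cdr <- list(p1 = c(.20, .15, .25, .40),
              p2 = c(.50, .25, .15, .10),
              p3 = c(.00, .45, .10, .45))
  # "A/ASYDNT" style half-conserved, half-diversified options are modelled
  # as one site-level 50/50 mixture of the two stated alternatives
  mix_opt <- function(label, wt, set) {
    aas <- strsplit(set, "", fixed = TRUE)[[1]]
    p <- setNames(rep(0.5 / length(aas), length(aas)), aas)
    p[wt] <- p[wt] + 0.5
    .sp_set(label, NULL, probs = p)
  }
  bc <- .loop_spec(
    pre = list(.sp_cons("D23", "D"), mix_opt("A24", "A", "ASYDNT"),
               mix_opt("P25", "P", "PSYH")),
    wt_mid = .bc_mid_wt, k_range = 2:4, mid_site = .sp_deg,
    post = list(.sp_set("V29", "AST"), .sp_deg("R30"),
                .sp_set("Y31", "GY")))
  de <- .loop_spec(
    pre = list(.sp_cons("G52", "G"), .sp_set("S53", "SYNT")),
    wt_mid = .de_mid_wt, k_range = 0:1,
    mid_site = function(lab) .sp_set(lab, "NSYT"),
    post = list(.sp_set("S55", "SYNT"), .sp_set("T56", "TSYN")))
  fg <- .loop_spec(
    pre = list(.sp_set("T76", "TSGA"), .sp_set("G77", "GSYADCNT"),
               .sp_deg("R78"), .sp_set("G79", "GSDN")),
    wt_mid = .fg_mid_wt, k_range = 1:5, mid_site = .sp_deg,
    post = list(.sp_cons("S85", "S"), .sp_cons("K86", "N")))
  list(generation = "gen2", mixes = list(CDR = cdr),
       sublibraries = list(
         list(loops = list(BC = bc, DE = de, FG = fg), weight = 1)))
}

#' @rdname packaged_designs
#' @export
gen1_design <- function() build_design(gen1_design_spec())

#' @rdname packaged_designs
#' @export
gen2_design <- function() build_design(gen2_design_spec())
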