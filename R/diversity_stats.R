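#' Shannon entropy landscape of a frequency matrix
#'
#' Per-site Shannon entropy `H = -sum p log p` with `0 log 0 := 0`. Log
#' base 2 by default, on which a fully conserved site scores 0 and a
#' uniform 5\%-each distribution scores `log2(20) = 4.32` (prints as 4.3).
#' Sites with effective weight 0 are omitted.
#'
#' @param fm a [frequency_matrix].
#' @param base logarithm base.
#' @return named numeric vector of per-site entropies (class
#'   `entropy_profile`).
#' @export
shannon_entropy <- function(fm, base = 2) {
  eff <- attr(fm, "effective_weight")
  m <- unclass(fm)
  if (!is.null(eff)) m <- m[eff > 0, , drop = FALSE]
  h <- apply(m, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p)) / log(base)
  })
  structure(h, class = "entropy_profile", base = base)
}

#' Entropy change between populations
#'
#' @param binder,naive `entropy_profile`s over the same sites.
#' @param constrained_cut report how many sites drop by at least this many
#'   units (the repertoire-analysis convention is 0.15).
#' @return list with `delta` (binder - naive per site), `mean_change`,
#'   `n_constrained` (sites with any reduction) and `n_reduced` (sites
#'   reduced by at least `constrained_cut`).
#' @export
entropy_delta <- function(binder, naive, constrained_cut = 0.15) {
  if (!identical(names(binder), names(naive)))
    stop("mismatched site sets", call. = FALSE)
  d <- unclass(binder) - unclass(naive)
  list(delta = d, mean_change = mean(d),
       n_constrained = sum(d < 0), n_reduced = sum(d <= -constrained_cut))
}

#' Sitewise enrichment significance (two-sample t-test, Bonferroni)
#'
#' Treats each replicate (e.g. one binding campaign) as an observation of
#' the per-(site, amino acid) frequency and runs a two-sample Student's
#' t-test per cell, correcting the familywise error rate by Bonferroni over
#' all tests performed. Flags are set at `p < alpha / m`; both the raw and
#' the Bonferroni-adjusted p-values are reported. Cells with zero variance
#' in both groups (no test possible) get `NA` p-values and are never
#' flagged.
#'
#' @param group_a,group_b lists of [frequency_matrix] replicates (>= 2 each
#'   for defined flags) over identical sites.
#' @param alpha familywise significance level (default 0.005).
#' @return an `enrichment_report` data.table: site, aa, mean frequency per
#'   group, delta, p, p_adj, significant.
#' @export
significance_test <- function(group_a, group_b, alpha = 0.005) {
  sites <- rownames(group_a[[1]])
  for (fm in c(group_a, group_b))
    if (!identical(rownames(fm), sites))
      stop("replicates must share the site set", call. = FALSE)
  undefined <- length(group_a) < 2 || length(group_b) < 2
  if (undefined)
    warning("fewer than 2 replicates per group; significance flags ",
            "are undefined")
  cells <- expand.grid(site = sites, aa = AA20, stringsAsFactors = FALSE)
  pull <- function(grp, s, a) vapply(grp, function(fm) fm[s, a], numeric(1))
  res <- lapply(seq_len(nrow(cells)), function(i) {
    s <- cells$site[i]; a <- cells$aa[i]
    xa <- pull(group_a, s, a); xb <- pull(group_b, s, a)
    p <- if (undefined || (sd(xa) == 0 && sd(xb) == 0)) NA_real_ else
      tryCatch(t.test(xa, xb)$p.value, error = function(e) NA_real_)
    data.table(site = s, aa = a, mean_a = mean(xa), mean_b = mean(xb),
               delta = mean(xb) - mean(xa), p = p)
  })
  out <- rbindlist(res)
  m <- sum(!is.na(out$p))
  out[, p_adj := pmin(1, p * max(m, 1))]
  out[, significant := if (undefined) NA else !is.na(p) & p < alpha / max(m, 1)]
  structure(out, class = c("enrichment_report", class(out)),
            alpha = alpha, n_tests = m)
}

#' Loop length distributions
#'
#' Read-count weighted frequency of each loop length class among aligned
#' full-length clones; frequencies sum to 1 per loop.
#'
#' @param clones a `clone_table`.
#' @return data.table `loop`, `len`, `freq`.
#' @export
loop_length_distribution <- function(clones) {
  ok <- clones[clones$aligned]
  parts <- lapply(c("BC", "DE", "FG"), function(loop) {
    tab <- ok[, .(n_reads = sum(count)), by = c(paste0("len_", loop))]
    data.table(loop = loop, len = tab[[1]], freq = tab$n_reads / sum(tab$n_reads))
  })
  out <- rbindlist(parts)
  setorder(out, loop, len)
  out
}

#' Cysteine count and pair analysis
#'
#' Counts cysteines across the three loops of each aligned clone and
#' returns (i) the per-population cysteine-count histogram and (ii) for
#' clones with exactly two cysteines, the symmetric site-pair frequency
#' matrix and its binder-minus-naive change. Pair frequencies are
#' normalised within the two-cysteine subset by default.
#'
#' @param naive,binder `clone_table`s from the same design.
#' @param normalize `"subset"` (within two-cysteine clones) or
#'   `"population"` (over all clones).
#' @return list with `histogram` (data.table population/n_cys/freq),
#'   `pairs_naive`, `pairs_binder`, `delta` (site x site matrices).
#' @export
cysteine_profile <- function(naive, binder, normalize = c("subset",
                                                          "population")) {
  normalize <- match.arg(normalize)
  design <- attr(naive, "design")
  sites <- design_site_labels(design)
  one <- function(ct, lab) {
    ok <- ct[ct$aligned]
    ncys <- lengths(gregexpr("C", paste0(ok$BC, ok$DE, ok$FG), fixed = TRUE))
    ncys[ncys > 0 & !grepl("C", paste0(ok$BC, ok$DE, ok$FG), fixed = TRUE)] <- 0
    hist <- data.table(population = lab, n_cys = ncys, count = ok$count)[
      , .(n_reads = sum(count)), by = .(population, n_cys)]
    hist[, freq := n_reads / sum(n_reads)]
    pm <- matrix(0, length(sites), length(sites),
                 dimnames = list(sites, sites))
    two <- which(ncys == 2)
    denom <- if (normalize == "subset") sum(ok$count[two]) else sum(ok$count)
    for (i in two) {
      cs <- character(0)
      for (loop in c("BC", "DE", "FG")) {
        labs <- loop_site_labels(design, loop, nchar(ok[[loop]][i]))
        res <- strsplit(ok[[loop]][i], "", fixed = TRUE)[[1]]
        cs <- c(cs, labs[res == "C"])
      }
      if (length(cs) == 2 && denom > 0) {
        pm[cs[1], cs[2]] <- pm[cs[1], cs[2]] + ok$count[i] / denom
        pm[cs[2], cs[1]] <- pm[cs[2], cs[1]] + ok$count[i] / denom
      }
    }
    list(hist = hist, pairs = pm)
  }
  a <- one(naive, "naive"); b <- one(binder, "binder")
  list(histogram = rbindlist(list(a$hist, b$hist)),
       pairs_naive = a$pairs, pairs_binder = b$pairs,
       delta = b$pairs - a$pairs)
}

#' Framework mutation enrichment
#'
#' Compares the translated framework portion of full-length clones against
#' the reference framework and reports, per framework position and
#' non-reference residue, the read frequency in the naive and binder
#' populations, sorted by enrichment. A mutation-free population yields an
#' empty table.
#'
#' @param naive,binder `clone_table`s.
#' @param design a [library_design()].
#' @param min_freq drop mutations never reaching this frequency in either
#'   population.
#' @return data.table `site`, `wt`, `mutant`, `naive_freq`, `binder_freq`,
#'   `enrichment`.
#' @export
framework_enrichment <- function(naive, binder, design, min_freq = 0) {
  fw <- design$framework
  rg <- fw$loops
  prot <- strsplit(fw$protein, "", fixed = TRUE)[[1]]
  fw_pos <- setdiff(seq_along(prot),
                    unlist(lapply(rg, function(r) r[1]:r[2])))
  ref <- prot[fw_pos]
  freqs <- function(ct) {
    ok <- ct[ct$classification == "full_length" &
               nchar(ct$framework) == length(fw_pos)]
    if (!nrow(ok)) return(NULL)
    mat <- .char_matrix(ok$framework)
    tot <- sum(ok$count)
    lapply(seq_along(fw_pos), function(j) {
      tab <- tapply(ok$count, mat[, j], sum) / tot
      tab[setdiff(names(tab), ref[j])]
    })
  }
  fa <- freqs(naive); fb <- freqs(binder)
  rows <- list()
  for (j in seq_along(fw_pos)) {
    muts <- union(names(fa[[j]]), names(fb[[j]]))
    for (mu in muts) {
      nf <- if (mu %in% names(fa[[j]])) fa[[j]][[mu]] else 0
      bf <- if (mu %in% names(fb[[j]])) fb[[j]][[mu]] else 0
      if (max(nf, bf) >= min_freq && max(nf, bf) > 0)
        rows[[length(rows) + 1L]] <- data.table(
          site = paste0(ref[j], fw_pos[j]), wt = ref[j], mutant = mu,
          naive_freq = nf, binder_freq = bf, enrichment = bf - nf)
    }
  }
  out <- if (length(rows)) rbindlist(rows) else
    data.table(site = character(0), wt = character(0),
               mutant = character(0), naive_freq = numeric(0),
               binder_freq = numeric(0), enrichment = numeric(0))
  setorder(out, -enrichment)
  out
}

#' Wild-type conservation per site
#'
#' The frequency of the reference residue at each site of a frequency
#' matrix. Sites without a reference residue (insertion labels) are
#' omitted.
#'
#' @param fm a [frequency_matrix].
#' @param reference named character vector site label -> reference residue;
#'   defaults to the wild-type letter embedded in each site label
#'   (`"D23"` -> `"D"`).
#' @return named numeric vector of wild-type frequencies.
#' @export
wild_type_conservation <- function(fm, reference = NULL) {
  if (is.null(reference)) {
    wt <- sub("^([A-Z]?)[0-9].*$", "\\1", rownames(fm))
    reference <- setNames(wt, rownames(fm))[wt != ""]
  }
  sites <- intersect(rownames(fm), names(reference))
  setNames(fm[cbind(sites, reference[sites])], sites)
}
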