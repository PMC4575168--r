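#' Remove the rarest sequences (background removal)
#'
#' Drops the rarest sequences by cumulative read share: unique sequences are
#' sorted by ascending count and removed while the cumulative share of reads
#' stays at or below `fraction`. Ties are removed together only if the whole
#' tied group keeps the cumulative share within the budget; otherwise the
#' entire tied group is kept. Intended for mid-affinity populations, where
#' rare non-binding clones are carried along by bead sorting.
#'
#' @param pop a `population` or `clone_table` (any data.table with a
#'   `count` column).
#' @param fraction cumulative read share to remove, in `[0, 0.5)`.
#' @return the filtered object (same class).
#' @export
remove_background <- function(pop, fraction = 0.02) {
  stopifnot(fraction >= 0, fraction < 0.5)
  if (!nrow(pop)) stop("empty population", call. = FALSE)
  if (fraction == 0) return(pop)
  total <- sum(pop$count)
  ord <- order(pop$count)
  counts <- pop$count[ord]
  budget <- fraction * total
  drop <- logical(length(ord))
  consumed <- 0
  for (lvl in unique(counts)) {
    grp <- which(counts == lvl)
    add <- sum(counts[grp])
    if (consumed + add <= budget + 1e-9) {
      drop[grp] <- TRUE
      consumed <- consumed + add
    } else break
  }
  keep <- sort(ord[!drop])
  out <- pop[keep]
  # data.table subsetting drops custom attributes; restore them
  for (a in c("label", "design", "class"))
    attr(out, a) <- attr(pop, a)
  out
}

#' Cluster loop sequences by identity
#'
#' Greedy centroid clustering at an identity threshold (default 80\%):
#' sequences are visited in descending read-count order (lexicographic
#' tie-break); each joins the first existing centroid with identity at or
#' above the threshold, else founds a new cluster. Identity is
#' matches / alignment length under a global alignment scoring match 1,
#' mismatch 0, gap 0 (see [pair_identity()]), which permits cross-length
#' clustering.
#'
#' @param seqs character vector of loop amino-acid sequences (duplicates
#'   allowed; they are aggregated first).
#' @param counts integer read counts parallel to `seqs` (default all 1).
#' @param threshold identity threshold in (0, 1].
#' @param loop_id optional loop tag carried in the result.
#' @return a `loop_clusters` data.table: `seq`, `count`, `cluster`,
#'   `centroid`.
#' @export
cluster_loops <- function(seqs, counts = rep(1L, length(seqs)),
                          threshold = 0.8, loop_id = NULL) {
  stopifnot(length(seqs) >= 1, threshold > 0, threshold <= 1,
            length(counts) == length(seqs))
  dt <- data.table(seq = seqs, count = counts)
  dt <- dt[, .(count = sum(count)), by = seq]
  setorder(dt, -count, seq)
  dt[, cluster := .greedy_cluster_cpp(seq, threshold)]
  dt[, centroid := seq[1], by = cluster]
  structure(dt, class = c("loop_clusters", class(dt)),
            threshold = threshold, loop_id = loop_id)
}

#' Pairwise sequence identity
#'
#' Identity used by [cluster_loops()]: matches / alignment length of a
#' global alignment with match 1, mismatch 0, gap 0; among equal-score
#' alignments the one with the fewest gaps is used, so equal-length
#' sequences differing by one substitution score `(n-1)/n`.
#'
#' @param a,b sequences.
#' @return identity in `[0, 1]`.
#' @export
pair_identity <- function(a, b) .pair_identity_cpp(a, b)

# site-label lookup per length, computed once per call site
.label_map <- function(design, loop_id, lens) {
  lapply(setNames(nm = as.character(sort(unique(lens)))),
         function(L) loop_site_labels(design, loop_id, as.integer(L)))
}

# long (site, aa) table for a set of aligned loop sequences
.sitewise_long <- function(seqs, counts, cluster, loop_id, design) {
  lens <- nchar(seqs)
  lmap <- .label_map(design, loop_id, lens)
  valid <- names(lmap)[!vapply(lmap, is.null, logical(1))]
  keep <- as.character(lens) %in% valid
  if (!all(keep)) {
    warning(sum(!keep), " unaligned member sequence(s) excluded")
    seqs <- seqs[keep]; counts <- counts[keep]; cluster <- cluster[keep]
    lens <- lens[keep]
  }
  parts <- list()
  for (L in unique(lens)) {
    sel <- which(lens == L)
    labs <- lmap[[as.character(L)]]
    mat <- .char_matrix(seqs[sel])
    parts[[length(parts) + 1L]] <- data.table(
      cluster = rep(cluster[sel], times = L),
      count = rep(counts[sel], times = L),
      site = rep(labs, each = length(sel)),
      aa = as.vector(mat))
  }
  rbindlist(parts)
}

#' Cluster-weighted sitewise amino-acid counts
#'
#' Within each cluster, raw per-site per-amino-acid read counts `c` are
#' transformed to `c^exponent` (default power one-half, compressing
#' dominant clones), then summed across clusters. The alternative
#' `"cluster_sqrt"` mode instead weights each cluster by the square root of
#' its total read count and distributes that weight over the cluster's
#' internal sitewise frequencies.
#'
#' @param clusters a `loop_clusters` from [cluster_loops()].
#' @param design a [library_design()] providing site labels per length.
#' @param loop_id which loop the sequences belong to.
#' @param exponent the within-cluster count exponent (1 = plain counting).
#' @param mode `"within"` (count transform, default) or `"cluster_sqrt"`.
#' @return data.table `site`, `aa`, `w` of weighted counts.
#' @export
weighted_sitewise_counts <- function(clusters, design, loop_id,
                                     exponent = 0.5,
                                     mode = c("within", "cluster_sqrt")) {
  mode <- match.arg(mode)
  long <- .sitewise_long(clusters$seq, clusters$count, clusters$cluster,
                         loop_id, design)
  long <- long[aa != "*"]
  if (mode == "within") {
    wc <- long[, .(raw = sum(count)), by = .(cluster, site, aa)]
    wc[, w := raw^exponent]
  } else {
    wc <- long[, .(raw = sum(count)), by = .(cluster, site, aa)]
    wc[, w := sqrt(sum(raw)) * raw / sum(raw), by = .(cluster, site)]
  }
  wc[, .(w = sum(w)), by = .(site, aa)]
}

#' Build a frequency matrix from weighted counts
#'
#' Normalises per-site weighted counts over the observed (non-gap)
#' residues. Sites observed in no sequence get effective weight 0 and a row
#' of zeros.
#'
#' @param counts data.table `site`, `aa`, `w` (from
#'   [weighted_sitewise_counts()]), or any nonnegative counts in that shape.
#' @param sites optional site-label order for the rows (defaults to the
#'   sites present, sorted).
#' @return a `frequency_matrix`: sites x 20 matrix of fractions with an
#'   `effective_weight` attribute (per-site total weight).
#' @export
frequency_matrix <- function(counts, sites = NULL) {
  counts <- as.data.table(counts)
  stopifnot(all(counts$w >= 0))
  if (is.null(sites)) sites <- sort(unique(counts$site))
  m <- matrix(0, length(sites), 20, dimnames = list(sites, AA20))
  eff <- setNames(numeric(length(sites)), sites)
  agg <- counts[site %in% sites, .(w = sum(w)), by = .(site, aa)]
  m[cbind(agg$site, agg$aa)] <- agg$w
  eff[] <- rowSums(m)
  pos <- eff > 0
  m[pos, ] <- m[pos, , drop = FALSE] / eff[pos]
  structure(m, class = "frequency_matrix", effective_weight = eff)
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat("<frequency_matrix>", nrow(x), "sites x 20 amino acids\n")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Sitewise frequency differences
#'
#' Elementwise `binder - naive`; per-site differences sum to zero (within
#' 1e-9) wherever both rows carry weight.
#'
#' @param binder,naive `frequency_matrix` objects over identical site sets.
#' @return matrix of signed differences with the same dimnames.
#' @export
frequency_delta <- function(binder, naive) {
  if (!identical(rownames(binder), rownames(naive)))
    stop("mismatched site sets", call. = FALSE)
  unclass(binder) - unclass(naive)
}

#' Full repertoire frequency pipeline
#'
#' Convenience driver from a processed `clone_table` to one
#' [frequency_matrix] over all design sites: per loop, optionally cluster
#' the aligned loop sequences, apply the power-weighted sitewise counting,
#' and stack the per-loop rows. With `cluster = FALSE` every unique
#' sequence forms its own cluster.
#'
#' @param clones a `clone_table` from [process_population()].
#' @param design a [library_design()].
#' @param cluster cluster at `threshold` before weighting?
#' @param threshold,exponent,mode see [cluster_loops()] and
#'   [weighted_sitewise_counts()].
#' @return a `frequency_matrix` with rows in design site order.
#' @export
repertoire_frequencies <- function(clones, design, cluster = TRUE,
                                   threshold = 0.8, exponent = 0.5,
                                   mode = "within") {
  ok <- clones[clones$aligned]
  if (!nrow(ok)) stop("no aligned full-length clones", call. = FALSE)
  parts <- lapply(c("BC", "DE", "FG"), function(loop) {
    agg <- ok[, .(count = sum(count)), by = c(loop)]
    seqs <- agg[[loop]]
    cl <- if (cluster)
      cluster_loops(seqs, agg$count, threshold, loop)
    else {
      d <- data.table(seq = seqs, count = agg$count,
                      cluster = seq_along(seqs))
      d[, centroid := seq]
      d
    }
    weighted_sitewise_counts(cl, design, loop, exponent, mode)
  })
  frequency_matrix(rbindlist(parts), sites = design_site_labels(design))
}
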