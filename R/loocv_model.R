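#' Log-probability of a loop sequence under a sitewise model
#'
#' Sitewise-independent model: `log10 P(length) + sum_sites log10
#' max(f(site, residue), floor)`. Sites absent from the clone's length
#' class contribute nothing. The frequency floor keeps structural zeros
#' finite and is applied symmetrically to naive and evolved models.
#'
#' @param seq loop amino-acid string.
#' @param loop_id `"BC"`, `"DE"` or `"FG"`.
#' @param fm a [frequency_matrix] containing the loop's sites.
#' @param length_prior named numeric vector (length -> prior probability);
#'   `NULL` drops the length term (prior treated as 1).
#' @param design a [library_design()] for the label map.
#' @param floor frequency floor in (0, 0.01].
#' @return list with `log10_p`, `length_term` and `sitewise` (named per-site
#'   log10 frequency terms).
#' @export
sequence_log_probability <- function(seq, loop_id, fm, length_prior,
                                     design, floor = 1e-4) {
  stopifnot(floor > 0, floor <= 0.01)
  labs <- loop_site_labels(design, loop_id, nchar(seq))
  if (is.null(labs)) stop("unaligned clone: no length variant of size ",
                          nchar(seq), call. = FALSE)
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  f <- pmax(fm[cbind(labs, res)], floor)
  sitewise <- setNames(log10(f), labs)
  lt <- if (is.null(length_prior)) 0 else
    log10(max(length_prior[as.character(nchar(seq))], floor, na.rm = TRUE))
  list(log10_p = lt + sum(sitewise), length_term = lt, sitewise = sitewise)
}

#' Leave-one-out cross-validated log-odds of evolvability
#'
#' For each held-out sequence cluster, the evolved sitewise frequency
#' matrix is rebuilt from the remaining clusters with the same power-weight
#' pipeline, and every held-out sequence is scored
#' `log10(P_evolved / P_naive)`. Holding out whole clusters keeps related
#' sequences out of the training set.
#'
#' @param clusters binder `loop_clusters` (>= 2 clusters) from
#'   [cluster_loops()].
#' @param naive_fm naive [frequency_matrix] (typically
#'   `design_model(design)$fm`, the exact theoretical distributions).
#' @param naive_length_prior named naive length prior for this loop, or
#'   `NULL` to drop length terms entirely.
#' @param design a [library_design()].
#' @param loop_id which loop the clusters cover.
#' @param exponent within-cluster count exponent of the training pipeline.
#' @param floor frequency floor (see [sequence_log_probability()]).
#' @param use_length_prior include the loop-length prior term?
#' @return a `log_odds_result`: list with `records` (data.table: cluster,
#'   seq, count, log_odds, length_term), `sitewise` (long data.table of
#'   per-sequence per-site terms) and `summary` (fraction positive,
#'   positive:negative ratio, median log-odds and the median percent
#'   likelihood increase `10^median - 1`).
#' @export
loocv_log_odds <- function(clusters, naive_fm, naive_length_prior, design,
                           loop_id, exponent = 0.5, floor = 1e-4,
                           use_length_prior = TRUE) {
  lmap0 <- .label_map(design, loop_id, nchar(clusters$seq))
  bad_len <- names(lmap0)[vapply(lmap0, is.null, logical(1))]
  if (length(bad_len)) {
    warning("dropping member sequences of unaligned length(s) ",
            paste(bad_len, collapse = ", "))
    clusters <- clusters[!as.character(nchar(seq)) %in% bad_len]
  }
  ids <- sort(unique(clusters$cluster))
  if (length(ids) < 2)
    stop("LOOCV needs at least 2 clusters", call. = FALSE)
  long <- .sitewise_long(clusters$seq, clusters$count, clusters$cluster,
                         loop_id, design)
  long <- long[aa != "*"][, .(raw = sum(count)), by = .(cluster, site, aa)]
  long[, w := raw^exponent]
  sites <- unique(long$site)
  total <- matrix(0, length(sites), 20, dimnames = list(sites, AA20))
  agg <- long[, .(w = sum(w)), by = .(site, aa)]
  total[cbind(agg$site, agg$aa)] <- agg$w
  # per-fold training length priors from read counts of remaining clusters
  lens_all <- nchar(clusters$seq)
  len_levels <- sort(unique(lens_all))
  len_by_cl <- matrix(0, length(ids), length(len_levels),
                      dimnames = list(ids, len_levels))
  lt <- clusters[, .(n_reads = sum(count)), by = .(cluster,
                                                   len = nchar(seq))]
  len_by_cl[cbind(as.character(lt$cluster), as.character(lt$len))] <-
    lt$n_reads
  len_tot <- colSums(len_by_cl)
  log_naive <- log10(pmax(unclass(naive_fm)[sites, , drop = FALSE], floor))
  split_long <- split(long, by = "cluster", keep.by = FALSE)
  split_mem <- split(seq_len(nrow(clusters)), clusters$cluster)
  n_mem <- nrow(clusters)
  rec_lo <- rec_lt <- numeric(n_mem)
  rec_seq <- character(n_mem); rec_cl <- rec_ct <- integer(n_mem)
  sw_seq <- vector("list", n_mem); sw_site <- vector("list", n_mem)
  sw_term <- vector("list", n_mem); sw_cl <- integer(n_mem)
  lmap <- .label_map(design, loop_id, lens_all)
  chars <- strsplit(clusters$seq, "", fixed = TRUE)
  pos <- 0L
  for (k in ids) {
    ck <- split_long[[as.character(k)]]
    loo <- total
    loo[cbind(ck$site, ck$aa)] <- loo[cbind(ck$site, ck$aa)] - ck$w
    eff <- rowSums(loo)
    fm_k <- loo
    nz <- eff > 0
    fm_k[nz, ] <- fm_k[nz, , drop = FALSE] / eff[nz]
    log_ev <- log10(pmax(fm_k, floor))
    lt_k <- len_tot - len_by_cl[as.character(k), ]
    lp_k <- lt_k / sum(lt_k)
    for (i in split_mem[[as.character(k)]]) {
      labs <- lmap[[as.character(lens_all[i])]]
      res <- chars[[i]]
      idx <- cbind(labs, res)
      terms <- log_ev[idx] - log_naive[idx]
      lterm <- if (use_length_prior) {
        lp_ev <- max(lp_k[as.character(lens_all[i])], floor, na.rm = TRUE)
        lp_na <- max(naive_length_prior[as.character(lens_all[i])], floor,
                     na.rm = TRUE)
        log10(lp_ev) - log10(lp_na)
      } else 0
      pos <- pos + 1L
      rec_seq[pos] <- clusters$seq[i]; rec_cl[pos] <- k
      rec_ct[pos] <- clusters$count[i]
      rec_lo[pos] <- lterm + sum(terms); rec_lt[pos] <- lterm
      sw_seq[[pos]] <- rep(clusters$seq[i], length(labs))
      sw_site[[pos]] <- labs; sw_term[[pos]] <- unname(terms)
      sw_cl[pos] <- k
    }
  }
  records <- data.table(cluster = rec_cl[1:pos], seq = rec_seq[1:pos],
                        count = rec_ct[1:pos], log_odds = rec_lo[1:pos],
                        length_term = rec_lt[1:pos])
  sitewise <- data.table(
    seq = unlist(sw_seq), cluster = rep(sw_cl[1:pos],
                                        lengths(sw_site[1:pos])),
    site = unlist(sw_site), term = unlist(sw_term))
  lo_reads <- rep(records$log_odds, records$count)
  summary <- list(
    n_sequences = nrow(records),
    fraction_positive = mean(lo_reads > 0),
    ratio_pos_neg = sum(lo_reads > 0) / max(1, sum(lo_reads < 0)),
    median_log_odds = median(lo_reads),
    median_percent_increase = 100 * (10^median(lo_reads) - 1))
  structure(list(records = records, sitewise = sitewise, summary = summary),
            class = "log_odds_result")
}

#' @export
print.log_odds_result <- function(x, ...) {
  s <- x$summary
  cat("<log_odds_result>", s$n_sequences, "held-out sequences\n",
      sprintf("  fraction positive: %.3f  median log10-odds: %.3f ",
              s$fraction_positive, s$median_log_odds),
      sprintf("(%.0f%% median likelihood increase)\n",
              s$median_percent_increase))
  invisible(x)
}

#' Sitewise aggregation of LOOCV log-odds terms
#'
#' Read-count weighted mean of the per-sequence per-site log10 frequency
#' ratios, reported also as percent change in likelihood
#' (`100 * (10^term - 1)`).
#'
#' @param result a `log_odds_result` from [loocv_log_odds()].
#' @return data.table `site`, `mean_term`, `percent_change`.
#' @export
sitewise_log_odds <- function(result) {
  sw <- merge(result$sitewise,
              result$records[, .(seq, cluster, count)],
              by = c("seq", "cluster"))
  out <- sw[, .(mean_term = sum(term * count) / sum(count)), by = site]
  out[, percent_change := 100 * (10^mean_term - 1)]
  setorder(out, -mean_term)
  out
}
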